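#' Pooled-variance two-sample t test
#'
#' Classic equal-variance two-sample t: `df = n1 + n2 - 2` (126 for 64
#' subjects per group), two-sided p. The statistic is oriented as
#' `mean(xHC) - mean(xMCI)`, so edges reduced in the patient group give
#' positive t.
#'
#' @param xHc,xMci numeric vectors of per-subject values (length >= 2 each).
#' @return list with `t`, `df`, `p`.
#' @examples
#' edgeTTest(c(1, 2, 3), c(0, 1, 2))   # t = 1.2247, df = 4
#' @export
edgeTTest <- function(xHc, xMci) {
  n1 <- length(xHc); n2 <- length(xMci)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(xHc) + (n2 - 1) * var(xMci)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(xHc) - mean(xMci)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone, order-preserving with the input);
#' thin wrapper over `p.adjust(method = "BH")` so the adjustment used
#' throughout the package is explicit and testable.
#'
#' @param p numeric vector of p values in \[0,1\].
#' @return adjusted p values, same order as the input.
#' @export
fdrAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' ROC analysis of one edge
#'
#' AUC via the Mann-Whitney identity: the fraction of (HC, MCI) subject
#' pairs in which the HC value exceeds the MCI value (ties count 1/2), so
#' edges reduced in the patient group give AUC > 0.5. The operating point
#' maximizes Youden's J over thresholds placed between observed values;
#' sensitivity is the fraction of MCI subjects below the threshold,
#' specificity the fraction of HC subjects at or above it.
#'
#' @param xHc,xMci numeric vectors of per-subject values.
#' @return list with `auc`, `sensitivity`, `specificity`, `threshold`.
#' @examples
#' edgeROC(c(4, 5, 6), c(1, 2, 3))   # auc = 1
#' @export
edgeROC <- function(xHc, xMci) {
  stopifnot(length(xHc) >= 1, length(xMci) >= 1)
  cmp <- outer(xHc, xMci, ">") + 0.5 * outer(xHc, xMci, "==")
  auc <- mean(cmp)
  thr <- sort(unique(c(xHc, xMci)))
  thr <- c(thr[1] - 1, (head(thr, -1) + tail(thr, -1)) / 2, thr[length(thr)] + 1)
  sens <- vapply(thr, function(th) mean(xMci < th), numeric(1))
  spec <- vapply(thr, function(th) mean(xHc >= th), numeric(1))
  j <- sens + spec - 1
  k <- which.max(j)
  list(auc = auc, sensitivity = sens[k], specificity = spec[k],
       threshold = thr[k])
}

#' Mass-univariate edge statistics with FDR control and ROC screening
#'
#' For every undirected edge of the supplied per-subject connectivity
#' matrices: group means and SDs, pooled two-sample t with df
#' `n1 + n2 - 2`, raw and Benjamini-Hochberg adjusted p (corrected within
#' this analysis level: 2485 channel edges or 36 ROI edges), Mann-Whitney
#' AUC and the Youden operating point. Edges are flagged `"*"` at
#' `p_fdr < alphaSig` and `"**"` at `p_fdr < alphaStrong`; at ROI level the
#' returned table also carries an `aucSelected` column implementing the
#' `AUC > aucScreen` screening rule used to pick classifier features.
#' Edges missing for any subject (QC-excluded channels) are compared on the
#' subjects that have them; edges with fewer than two values per group get
#' `NA` statistics.
#'
#' @param cms list of [ConnectivityMatrix-class] objects, one per subject,
#'   all at the same level with identical labels.
#' @param alphaSig,alphaStrong FDR significance thresholds (0.05, 0.01).
#' @param aucScreen AUC screening threshold for ROI-level feature selection
#'   (0.65).
#' @return data.frame with one row per edge: `level`, `node_i`, `node_j`,
#'   `mean_hc`, `sd_hc`, `mean_mci`, `sd_mci`, `t`, `df`, `p_raw`, `p_fdr`,
#'   `auc`, `sens`, `spec`, `flag`, plus `aucSelected` at ROI level.
#' @export
runEdgeStats <- function(cms, alphaSig = 0.05, alphaStrong = 0.01,
                         aucScreen = 0.65) {
  stopifnot(length(cms) >= 4)
  level <- cms[[1]]@level
  labs <- rownames(cms[[1]]@z)
  groups <- vapply(cms, groupLabel, character(1))
  stopifnot(sum(groups == "HC") >= 2, sum(groups == "MCI") >= 2)
  ut <- which(upper.tri(cms[[1]]@z), arr.ind = TRUE)
  zmat <- vapply(cms, function(cm) cm@z[ut], numeric(nrow(ut)))  # edges x subj
  if (nrow(ut) == 1L) zmat <- matrix(zmat, nrow = 1L)

  hcIdx <- groups == "HC"; mciIdx <- groups == "MCI"
  out <- data.frame(level = level, node_i = labs[ut[, 1]],
                    node_j = labs[ut[, 2]], stringsAsFactors = FALSE)
  stats <- t(vapply(seq_len(nrow(ut)), function(i) {
    zh <- zmat[i, hcIdx]; zm <- zmat[i, mciIdx]
    zh <- zh[!is.na(zh)]; zm <- zm[!is.na(zm)]
    if (length(zh) < 2 || length(zm) < 2)
      return(rep(NA_real_, 11))
    tt <- edgeTTest(zh, zm)
    roc <- edgeROC(zh, zm)
    c(mean(zh), sd(zh), mean(zm), sd(zm), tt$t, tt$df, tt$p,
      roc$auc, roc$sensitivity, roc$specificity, roc$threshold)
  }, numeric(11)))
  colnames(stats) <- c("mean_hc", "sd_hc", "mean_mci", "sd_mci", "t", "df",
                       "p_raw", "auc", "sens", "spec", "threshold")
  out <- cbind(out, as.data.frame(stats))
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_fdr[ok] <- fdrAdjust(out$p_raw[ok])
  out$flag <- ifelse(is.na(out$p_fdr), "",
                     ifelse(out$p_fdr < alphaStrong, "**",
                            ifelse(out$p_fdr < alphaSig, "*", "")))
  if (level == "roi")
    out$aucSelected <- !is.na(out$auc) & out$auc > aucScreen &
      !is.na(out$p_fdr) & out$p_fdr < alphaSig
  out
}
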