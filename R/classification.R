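#' Train a two-class linear discriminant
#'
#' Classic pooled-covariance LDA: discriminant direction
#' `w = Sigma^-1 (mu_HC - mu_MCI)`, decision threshold at the projected
#' class-mean midpoint shifted by the log prior ratio (priors taken from the
#' training fractions, so equal class sizes give the plain midpoint). A
#' singular pooled covariance is ridged by 1e-8 with a warning.
#'
#' @param x numeric matrix (subjects x features) or vector (one feature).
#' @param labels character/factor vector with levels `"HC"` and `"MCI"`.
#' @return list of class `nirsLda`: `w`, `threshold`, `means`, `priors`.
#' @export
ldaTrain <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels),
            sum(labels == "HC") >= 2, sum(labels == "MCI") >= 2)
  x1 <- x[labels == "HC", , drop = FALSE]
  x0 <- x[labels == "MCI", , drop = FALSE]
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  n1 <- nrow(x1); n0 <- nrow(x0)
  S <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x0, 2, mu0))) /
    (n1 + n0 - 2)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) {
    warning("singular pooled covariance; applying ridge 1e-8")
    solve(S + diag(1e-8, ncol(S)), mu1 - mu0)
  })
  prior1 <- n1 / (n1 + n0)
  m1 <- sum(w * mu1); m0 <- sum(w * mu0)
  threshold <- (m1 + m0) / 2 - log(prior1 / (1 - prior1))
  structure(list(w = w, threshold = threshold,
                 means = rbind(HC = mu1, MCI = mu0),
                 priors = c(HC = prior1, MCI = 1 - prior1)),
            class = "nirsLda")
}

#' @rdname ldaTrain
#' @param model a fitted `nirsLda`.
#' @param newdata matrix or vector of feature values.
#' @return `ldaPredict()` returns a character vector of predicted labels.
#' @export
ldaPredict <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% model$w)
  ifelse(score > model$threshold, "HC", "MCI")
}

## stratified fold assignment: within each class, shuffle and deal into k
## folds so every fold is balanced to within one subject per class
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validated LDA
#'
#' Each repeat draws a fresh class-stratified k-fold partition (every class
#' split (k-1):1 per fold), trains [ldaTrain()] on the training folds and
#' scores the held-out fold; the per-repeat accuracy pools correct/total
#' over the concatenated validation folds (`aggregate = "pooled"`, the
#' default) or averages fold-wise accuracies (`"foldMean"`). Per-repeat
#' fold seeds derive deterministically from `seed`, so a fixed seed gives
#' an identical report.
#'
#' @param x numeric matrix (subjects x features) or vector.
#' @param labels character vector of `"HC"`/`"MCI"` labels.
#' @param k folds (default 5).
#' @param repeats repeats (default 10).
#' @param seed integer seed.
#' @param name feature-set name carried into the report.
#' @param aggregate `"pooled"` or `"foldMean"`.
#' @return list of class `nirsCVReport`: `name`, `accuracy` (per-repeat %),
#'   `mean`, `sd`, `max`, `k`, `repeats`, `seed`, `folds` (list of
#'   per-repeat fold assignments).
#' @export
repeatedCV <- function(x, labels, k = 5, repeats = 10, seed = 1L,
                       name = "feature", aggregate = c("pooled", "foldMean")) {
  aggregate <- match.arg(aggregate)
  x <- as.matrix(x)
  labels <- as.character(labels)
  keep <- rowSums(is.na(x)) == 0L
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (min(table(labels)) < k)
    stop("each class must have at least k subjects")
  acc <- numeric(repeats)
  folds <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    .withSeed(.subjectSeed(seed, r), {
      fold <- .stratifiedFolds(labels, k)
      folds[[r]] <- fold
      correct <- 0L; total <- 0L; foldAcc <- numeric(k)
      for (f in seq_len(k)) {
        test <- fold == f
        model <- ldaTrain(x[!test, , drop = FALSE], labels[!test])
        pred <- ldaPredict(model, x[test, , drop = FALSE])
        correct <- correct + sum(pred == labels[test])
        total <- total + sum(test)
        foldAcc[f] <- mean(pred == labels[test])
      }
      acc[r] <- if (aggregate == "pooled") 100 * correct / total
                else 100 * mean(foldAcc)
    })
  }
  structure(list(name = name, accuracy = acc, mean = mean(acc),
                 sd = sd(acc), max = max(acc), k = k, repeats = repeats,
                 seed = as.integer(seed), folds = folds),
            class = "nirsCVReport")
}

#' @export
print.nirsCVReport <- function(x, ...) {
  cat(sprintf("%s: %s  mean %.2f +/- %.2f %%, max %.2f %% (%d x %d-fold)\n",
              x$name, paste(sprintf("%.2f", x$accuracy), collapse = " "),
              x$mean, x$sd, x$max, x$repeats, x$k))
  invisible(x)
}

## per-subject feature matrix for a set of edges from connectivity matrices
.edgeFeatures <- function(cms, edges) {
  feat <- vapply(seq_len(nrow(edges)), function(i)
    vapply(cms, function(cm) cm@z[edges$node_i[i], edges$node_j[i]],
           numeric(1)),
    numeric(length(cms)))
  feat <- matrix(feat, nrow = length(cms))
  colnames(feat) <- paste(edges$node_i, edges$node_j, sep = "-")
  feat
}

#' Classification over screened connectivity features
#'
#' Builds the feature sets the screening analysis defines - every selected
#' edge alone plus their union per level - and evaluates each with
#' [repeatedCV()]. ROI-level edges are selected by the `AUC > aucScreen`
#' rule (ranked by AUC), channel-level edges by `p_fdr < alphaStrong`.
#'
#' @param cms named list with elements `roi` and/or `channel`, each a list
#'   of per-subject [ConnectivityMatrix-class] objects.
#' @param edgeStats named list with matching elements, each a table from
#'   [runEdgeStats()].
#' @param k,repeats,seed cross-validation settings.
#' @param aucScreen ROI-level AUC screening threshold.
#' @param alphaStrong channel-level adjusted-p threshold.
#' @param maxEdges cap on selected edges per level (6 ROI / 4 channel by
#'   default, `Inf` to disable).
#' @return list of `nirsCVReport` objects (one per feature set, unions named
#'   `"All above"`), with a `table` attribute holding the report grid
#'   (rows = feature sets, columns = per-repeat accuracies, mean, sd, max).
#' @export
runClassification <- function(cms, edgeStats, k = 5, repeats = 10,
                              seed = 1L, aucScreen = 0.65,
                              alphaStrong = 0.01,
                              maxEdges = c(roi = 6, channel = 4)) {
  reports <- list()
  for (level in intersect(c("roi", "channel"), names(cms))) {
    st <- edgeStats[[level]]
    sel <- if (level == "roi") {
      ok <- !is.na(st$auc) & st$auc > aucScreen &
        !is.na(st$p_fdr) & st$p_fdr < 0.05
      st[ok, ][order(-st$auc[ok]), ]
    } else {
      ok <- !is.na(st$p_fdr) & st$p_fdr < alphaStrong
      st[ok, ][order(st$p_fdr[ok]), ]
    }
    cap <- if (level %in% names(maxEdges)) maxEdges[[level]] else Inf
    if (nrow(sel) > cap) sel <- sel[seq_len(cap), ]
    if (nrow(sel) == 0L) next
    labels <- vapply(cms[[level]], groupLabel, character(1))
    feats <- .edgeFeatures(cms[[level]], sel)
    for (j in seq_len(ncol(feats))) {
      nm <- sprintf("%s %s", level, colnames(feats)[j])
      reports[[nm]] <- repeatedCV(feats[, j], labels, k, repeats,
                                  seed = .subjectSeed(seed, j),
                                  name = colnames(feats)[j])
    }
    if (ncol(feats) > 1L) {
      nm <- sprintf("%s All above", level)
      reports[[nm]] <- repeatedCV(feats, labels, k, repeats,
                                  seed = .subjectSeed(seed, 999L),
                                  name = "All above")
    }
  }
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(feature = r$name,
               as.list(setNames(r$accuracy,
                                paste0("N", seq_along(r$accuracy)))),
               mean = r$mean, sd = r$sd, max = r$max,
               stringsAsFactors = FALSE)))
  attr(reports, "table") <- tab
  reports
}
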