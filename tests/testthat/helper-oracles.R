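## Independent reference implementations used to cross-check the package's
## statistics, written deliberately as brute-force definitions.

## Benjamini-Hochberg step-up adjusted p values, straight from the
## definition: adj_(i) = min_{j >= i} min(1, m p_(j) / j) on sorted p.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

## classic BH step-up rejection set at level q
bruteForceBHReject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  if (length(k) == 0L) return(integer(0))
  sort(o[seq_len(max(k))])
}

## empirical ROC curve by threshold sweep + trapezoid integration;
## positives are the group expected to score LOW (patients)
trapezoidAUC <- function(xHc, xMci) {
  thr <- sort(unique(c(xHc, xMci, -Inf, Inf)))
  tpr <- vapply(thr, function(t) mean(xMci < t), numeric(1))
  fpr <- vapply(thr, function(t) mean(xHc < t), numeric(1))
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
}

## pooled two-sample t from first principles
bruteForceT <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

## brute-force interval merge over [start, end] rows
bruteForceMerge <- function(seg, n) {
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(seg))) covered[seg[i, 1]:seg[i, 2]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
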