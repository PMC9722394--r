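## Fisher r-to-z with clipping so perfectly correlated pairs stay finite
.fisherZ <- function(r, clip = 1 - 1e-7) {
  atanh(pmax(pmin(r, clip), -clip))
}

.zMatrix <- function(series, labels) {
  ## series: time x node matrix; zero-variance / NA nodes give NA entries
  mu <- colMeans(series)
  s <- colMeans(series * series) - mu * mu
  ok <- is.finite(s) & s > 0
  z <- matrix(NA_real_, ncol(series), ncol(series),
              dimnames = list(labels, labels))
  if (sum(ok) >= 2) {
    r <- cor(series[, ok, drop = FALSE])
    z[ok, ok] <- .fisherZ(r)
  }
  diag(z) <- NA_real_
  z
}

#' Channel-level functional connectivity
#'
#' Pearson correlation of the full HbO time series between every pair of
#' channels, Fisher r-to-z transformed (`z = atanh(r)`, with `|r|` clipped
#' at `1 - 1e-7` so duplicated channels stay finite). Channels that failed
#' quality control, and zero-variance channels, yield `NA` entries.
#'
#' @param hb an [HbRecording-class].
#' @return a [ConnectivityMatrix-class] at channel level.
#' @export
channelFC <- function(hb) {
  stopifnot(is(hb, "HbRecording"))
  x <- hbo(hb)
  if (ncol(x) < 30) stop("series too short for connectivity estimation")
  pass <- SummarizedExperiment::rowData(hb)$qcPass
  if (sum(pass) < 2) stop("fewer than two channels passed QC")
  if (!all(pass)) x[!pass, ] <- NA_real_
  series <- t(x)
  z <- .zMatrix(series, rownames(hb))
  methods::new("ConnectivityMatrix", level = "channel", z = z,
               subjectId = subjectId(hb) %||% "subject",
               group = groupLabel(hb) %||% "HC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROI-level functional connectivity
#'
#' Averages the HbO time series of each ROI's passing member channels, then
#' correlates the ROI mean series and applies the Fisher transform. An ROI
#' with no passing channel yields `NA` edges.
#'
#' @param hb an [HbRecording-class].
#' @param montage a [NirsMontage-class] defining the ROI partition; member
#'   channels are matched to the recording by `CH<id>` row name.
#' @return a [ConnectivityMatrix-class] at ROI level.
#' @export
roiFC <- function(hb, montage = defaultMontage()) {
  stopifnot(is(hb, "HbRecording"))
  x <- hbo(hb)
  pass <- SummarizedExperiment::rowData(hb)$qcPass
  labs <- roiLabels(montage)
  series <- matrix(NA_real_, ncol(x), length(labs),
                   dimnames = list(NULL, labs))
  for (k in seq_along(labs)) {
    rows <- match(paste0("CH", montage@roiPartition[[k]]), rownames(x))
    rows <- rows[!is.na(rows)]
    rows <- rows[pass[rows]]
    if (length(rows) == 0L) next
    series[, k] <- colMeans(x[rows, , drop = FALSE])
  }
  z <- .zMatrix(series, labs)
  methods::new("ConnectivityMatrix", level = "roi", z = z,
               subjectId = subjectId(hb) %||% "subject",
               group = groupLabel(hb) %||% "HC")
}

#' Whole-brain mean connectivity
#'
#' Mean Fisher-z over all undirected edges (the upper triangle of the
#' matrix, diagonal excluded); 71 channels give 71*70/2 = 2485 edges.
#' Missing edges (QC-failed channels) are excluded and the denominator
#' reported in the `nEdges` attribute.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @return scalar mean z with attribute `nEdges` (number of non-missing
#'   edges averaged).
#' @export
wholeBrainMean <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  z <- cm@z[upper.tri(cm@z)]
  structure(mean(z, na.rm = TRUE), nEdges = sum(!is.na(z)))
}

#' Extract one edge from per-subject connectivity matrices
#'
#' @param cms list of [ConnectivityMatrix-class] objects.
#' @param nodeA,nodeB node labels (e.g. `"RPF"`, `"LO"` at ROI level or
#'   `"CH15"`, `"CH57"` at channel level).
#' @return data.frame with columns `subject_id`, `group`, `z`.
#' @export
edgeValues <- function(cms, nodeA, nodeB) {
  data.frame(
    subject_id = vapply(cms, subjectId, character(1)),
    group = vapply(cms, groupLabel, character(1)),
    z = vapply(cms, function(cm) cm@z[nodeA, nodeB], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Stack connectivity matrices into a long-format table
#'
#' One row per subject per undirected edge: `subject  group  node_i
#' node_j  z`.
#'
#' @param cms list of [ConnectivityMatrix-class] objects (same level and
#'   labels).
#' @return data.frame in long format.
#' @export
stackConnectivity <- function(cms) {
  labs <- rownames(cms[[1]]@z)
  ut <- which(upper.tri(cms[[1]]@z), arr.ind = TRUE)
  do.call(rbind, lapply(cms, function(cm) {
    data.frame(subject = subjectId(cm), group = groupLabel(cm),
               node_i = labs[ut[, 1]], node_j = labs[ut[, 2]],
               z = cm@z[ut], stringsAsFactors = FALSE)
  }))
}
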