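#' Load a probe montage from a tab-separated table
#'
#' Reads a montage table with one row per measurement channel and columns
#' `channel_id`, `x`, `y`, `z` (MNI mm), `roi`, `anatomic_label`, validates
#' it, and builds the ROI partition. ROI labels listed in `normalizeRoi` are
#' rewritten at load time (with a warning); the bundled default montage uses
#' this to fold the stray `"MO"` label of its source table into the
#' right-occipital region so that exactly nine ROIs remain. Rows sharing MNI
#' coordinates with an earlier row are flagged in the validation notes but
#' kept verbatim: ROI membership, not geometry, drives every computation.
#'
#' @param path path to the tab-separated montage file.
#' @param normalizeRoi named character vector mapping raw ROI labels to
#'   canonical ones, e.g. `c(MO = "RO")` (the default).
#' @param expectedRois optional character vector; if supplied, the set of
#'   ROI labels after normalization must equal it.
#' @return a validated [NirsMontage-class].
#' @examples
#' m <- defaultMontage()
#' nChannels(m)      # 71
#' roiLabels(m)      # nine ROI labels
#' @export
loadMontage <- function(path, normalizeRoi = c(MO = "RO"),
                        expectedRois = NULL) {
  ch <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("channel_id", "x", "y", "z", "roi", "anatomic_label")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("montage table lacks columns: ", paste(miss, collapse = ", "))
  ch$channel_id <- as.integer(ch$channel_id)
  if (anyNA(ch$channel_id))
    stop("montage table contains missing channel ids")
  dup <- ch$channel_id[duplicated(ch$channel_id)]
  if (length(dup))
    stop("duplicate channel_id in montage: ", paste(unique(dup), collapse = ", "))
  ch <- ch[order(ch$channel_id), , drop = FALSE]
  rownames(ch) <- NULL

  notes <- character(0)
  hit <- ch$roi %in% names(normalizeRoi)
  if (any(hit)) {
    mapped <- normalizeRoi[ch$roi[hit]]
    warning(sprintf("normalized ROI label(s) %s -> %s for channel(s) %s",
                    paste(unique(ch$roi[hit]), collapse = ","),
                    paste(unique(mapped), collapse = ","),
                    paste(ch$channel_id[hit], collapse = ",")))
    notes <- c(notes, sprintf("ROI label normalized for channel %s (%s -> %s)",
                              ch$channel_id[hit], ch$roi[hit], mapped))
    ch$roi[hit] <- mapped
  }
  if (!is.null(expectedRois)) {
    unknown <- setdiff(unique(ch$roi), expectedRois)
    if (length(unknown))
      stop("unknown ROI label(s) after normalization: ",
           paste(unknown, collapse = ", "))
  }
  coordKey <- paste(ch$x, ch$y, ch$z)
  dupCoord <- duplicated(coordKey)
  if (any(dupCoord))
    notes <- c(notes, sprintf(
      "channel %d repeats the MNI coordinates of channel %d",
      ch$channel_id[dupCoord],
      ch$channel_id[match(coordKey[dupCoord], coordKey)]))

  part <- split(ch$channel_id, factor(ch$roi, levels = unique(ch$roi)))
  methods::new("NirsMontage", channels = ch, roiPartition = part,
               notes = notes)
}

#' The bundled 71-channel, nine-ROI default montage
#'
#' Loads the montage shipped with the package: 71 channels over prefrontal,
#' temporal, parietal and occipital cortex, partitioned into nine ROIs
#' (LPF, RPF, LT, P, RT, LIP, RIP, LO, RO - left/right prefrontal,
#' left/right temporal, superior parietal, left/right inferior parietal,
#' left/right occipital).
#'
#' @param quiet suppress the label-normalization warning for the one channel
#'   whose source label is folded into RO (default `TRUE`).
#' @return a [NirsMontage-class] with 71 channels and 9 ROIs.
#' @export
defaultMontage <- function(quiet = TRUE) {
  path <- system.file("extdata", "montage71.tsv", package = "nirsconn")
  load1 <- function() loadMontage(path, expectedRois = .roiOrder)
  if (quiet) suppressWarnings(load1()) else load1()
}

## canonical ROI ordering used throughout the package
.roiOrder <- c("LPF", "RPF", "LT", "P", "RT", "LIP", "RIP", "LO", "RO")

#' Channels belonging to one ROI
#'
#' @param montage a [NirsMontage-class].
#' @param roi a single ROI label.
#' @return integer vector of member channel ids.
#' @examples
#' roiMembers(defaultMontage(), "LPF")   # channels 1..10
#' @export
roiMembers <- function(montage, roi) {
  stopifnot(is(montage, "NirsMontage"), length(roi) == 1L)
  if (!roi %in% names(montage@roiPartition))
    stop("unknown ROI label: ", roi)
  montage@roiPartition[[roi]]
}

#' Write a montage back to its tab-separated representation
#'
#' Inverse of [loadMontage()]: writing then re-loading yields an identical
#' montage (up to the load-time notes).
#'
#' @param montage a [NirsMontage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMontage <- function(montage, path) {
  stopifnot(is(montage, "NirsMontage"))
  write.table(montage@channels, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## map each channel row (in table order) to the index of its ROI in the
## montage's label order
.channelRoiIndex <- function(montage) {
  match(montage@channels$roi, roiLabels(montage))
}
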