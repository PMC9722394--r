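#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor fft lm.fit median mvfft p.adjust pnorm pt qnorm
#'   quantile rnorm runif rpois sd setNames smooth.spline var predict
#' @importFrom utils read.delim write.table head tail
NULL

#' Probe montage: channel geometry and ROI partition
#'
#' A `NirsMontage` holds one row of metadata per measurement channel
#' (identifier, MNI coordinates in mm, region-of-interest label, free-text
#' anatomical label) together with the partition of channels into regions of
#' interest (ROIs). The partition is derived from the per-channel ROI column
#' and validated so that every channel belongs to exactly one non-empty ROI.
#'
#' @slot channels a `data.frame` with columns `channel_id`, `x`, `y`, `z`,
#'   `roi`, `anatomic_label`, one row per channel, ordered by `channel_id`.
#' @slot roiPartition named list mapping each ROI label to the integer vector
#'   of member channel ids.
#' @slot notes character vector of validation remarks collected at load time
#'   (for example duplicated coordinate rows).
#' @seealso [loadMontage()], [defaultMontage()], [roiMembers()]
#' @export
setClass("NirsMontage",
  slots = c(channels = "data.frame", roiPartition = "list",
            notes = "character"))

setValidity("NirsMontage", function(object) {
  ch <- object@channels
  need <- c("channel_id", "x", "y", "z", "roi", "anatomic_label")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$channel_id))
    return("duplicate channel_id")
  if (!all(is.finite(as.matrix(ch[, c("x", "y", "z")]))))
    return("non-finite MNI coordinates")
  part <- object@roiPartition
  if (length(part) == 0L || is.null(names(part)))
    return("roiPartition must be a named list")
  if (any(lengths(part) == 0L))
    return("empty ROI in partition")
  ids <- sort(unlist(part, use.names = FALSE))
  if (!identical(as.integer(ids), sort(as.integer(ch$channel_id))))
    return("roiPartition must cover every channel exactly once")
  TRUE
})

#' Synthetic cohort specification
#'
#' A `CohortSpec` fixes every parameter of the two-group synthetic resting
#' state generator: acquisition geometry (sampling rate, duration,
#' wavelengths, differential pathlength factor, source-detector separation),
#' the latent inter-ROI correlation structure per group, between-subject
#' heterogeneity, physiological nuisance, drift, sensor noise, and motion
#' artifact rate. See [cohortSpec()] for field documentation and
#' [defaultCohortSpec()] for the calibrated defaults.
#'
#' @slot nPerGroup integer, subjects per group.
#' @slot fs numeric, sampling rate (Hz).
#' @slot duration numeric, recording length (s).
#' @slot wavelengths numeric pair (nm).
#' @slot dpf numeric, differential pathlength factor.
#' @slot sdDistance numeric, source-detector separation (cm).
#' @slot latentZ named list with elements `HC` and `MCI`, each a symmetric
#'   ROI x ROI matrix of latent inter-ROI Fisher-z couplings (diagonal
#'   ignored).
#' @slot subjectZSd,edgeZSd numeric, between-subject global and per-edge
#'   jitter SD of latent z.
#' @slot channelMix numeric in \[0,1\], within-ROI shared-signal fraction.
#' @slot hboSd numeric, SD of channel oxyhemoglobin fluctuation (micromolar).
#' @slot hbrRatio numeric, deterministic HbR/HbO coupling (conventionally
#'   negative).
#' @slot hbrNoiseSd numeric, SD of independent HbR noise (micromolar).
#' @slot band numeric pair, hemodynamic band (Hz).
#' @slot nuisance named list of `c(amp, freq)` pairs (optical-density
#'   amplitude, Hz) for `cardiac`, `respiratory`, `mayer`.
#' @slot driftRange numeric, max absolute linear drift over the recording
#'   (optical density units).
#' @slot sensorNoiseSd numeric, sensor noise SD relative to baseline
#'   intensity.
#' @slot artifactRate numeric, expected motion events per minute.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec",
  slots = c(nPerGroup = "integer", fs = "numeric", duration = "numeric",
            wavelengths = "numeric", dpf = "numeric", sdDistance = "numeric",
            latentZ = "list", subjectZSd = "numeric", edgeZSd = "numeric",
            channelMix = "numeric", hboSd = "numeric", hbrRatio = "numeric",
            hbrNoiseSd = "numeric", band = "numeric", nuisance = "list",
            driftRange = "numeric", sensorNoiseSd = "numeric",
            artifactRate = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nPerGroup < 1L) return("nPerGroup must be >= 1")
  if (object@fs <= 0 || object@duration <= 0)
    return("fs and duration must be positive")
  if (length(object@wavelengths) != 2L)
    return("exactly two wavelengths required")
  if (!all(c("HC", "MCI") %in% names(object@latentZ)))
    return("latentZ must have elements 'HC' and 'MCI'")
  for (g in c("HC", "MCI")) {
    m <- object@latentZ[[g]]
    if (!is.matrix(m) || nrow(m) != ncol(m))
      return("latentZ matrices must be square")
    if (max(abs(m - t(m))) > 1e-12)
      return("latentZ matrices must be symmetric")
    r <- tanh(m); diag(r) <- 1
    if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      return(sprintf("latent correlation matrix for %s not positive semi-definite", g))
  }
  if (object@channelMix < 0 || object@channelMix > 1)
    return("channelMix must lie in [0,1]")
  amps <- vapply(object@nuisance, `[[`, numeric(1), 1L)
  if (any(amps < 0)) return("nuisance amplitudes must be >= 0")
  if (object@band[1] <= 0 || object@band[2] <= object@band[1])
    return("band must be an increasing positive pair")
  TRUE
})

#' Raw dual-wavelength fNIRS recording
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' subject's raw light-intensity time series. Rows are measurement channels
#' (with montage metadata in `rowData`), columns are time points. Assays:
#' `intensity730` and `intensity850` (strictly positive raw intensities) and,
#' for synthetic recordings, `hboTruth` (latent ground-truth oxyhemoglobin,
#' micromolar) used by oracle tests. Subject id, group label, sampling rate
#' and injected-artifact ground truth live in `metadata()`.
#'
#' @seealso [simulateSubject()], [preprocess()]
#' @export
setClass("NirsRecording", contains = "SummarizedExperiment")

setValidity("NirsRecording", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensity730", "intensity850") %in% an))
    return("assays intensity730 and intensity850 required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$fs) || md$fs <= 0) return("metadata fs must be positive")
  if (is.null(md$group) || !md$group %in% c("HC", "MCI"))
    return("metadata group must be 'HC' or 'MCI'")
  TRUE
})

#' Preprocessed hemoglobin recording
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with assays `hbo`
#' and `hbr` (relative concentration change, micromolar; channels x time).
#' `rowData()$qcPass` records the per-channel quality-control outcome;
#' `metadata()` carries the sampling rate, subject id, group label, the QC
#' summary and the per-channel artifact segments that were corrected.
#'
#' @seealso [preprocess()], [channelFC()]
#' @export
setClass("HbRecording", contains = "SummarizedExperiment")

setValidity("HbRecording", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("hbo", "hbr") %in% an))
    return("assays hbo and hbr required")
  if (is.null(SummarizedExperiment::rowData(object)$qcPass))
    return("rowData qcPass required")
  TRUE
})

#' Subject-level connectivity matrix
#'
#' Symmetric node-by-node matrix of Fisher-z transformed Pearson
#' correlations, at `"channel"` (one node per measurement channel) or
#' `"roi"` (one node per region) level. The diagonal is `NA` and excluded
#' from all summaries; channels that failed quality control produce `NA`
#' rows/columns.
#'
#' @slot level `"channel"` or `"roi"`.
#' @slot z symmetric numeric matrix of Fisher-z values with node labels as
#'   dimnames; diagonal `NA`.
#' @slot subjectId character.
#' @slot group character, `"HC"` or `"MCI"`.
#' @seealso [channelFC()], [roiFC()], [wholeBrainMean()]
#' @export
setClass("ConnectivityMatrix",
  slots = c(level = "character", z = "matrix", subjectId = "character",
            group = "character"))

setValidity("ConnectivityMatrix", function(object) {
  if (!object@level %in% c("channel", "roi"))
    return("level must be 'channel' or 'roi'")
  z <- object@z
  if (nrow(z) != ncol(z)) return("z must be square")
  if (is.null(rownames(z)) || !identical(rownames(z), colnames(z)))
    return("z must carry identical row/column labels")
  off <- z[upper.tri(z)]
  tz <- t(z)[upper.tri(z)]
  same <- (is.na(off) & is.na(tz)) | (!is.na(off) & !is.na(tz) &
                                        abs(off - tz) < 1e-12)
  if (!all(same)) return("z must be symmetric")
  TRUE
})
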