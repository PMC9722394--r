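#' Accessor generics
#'
#' Small accessor generics shared by the recording and result classes:
#' `samplingRate()` (Hz), `subjectId()`, `groupLabel()` (`"HC"`/`"MCI"`),
#' `nChannels()`, `roiLabels()`, `hbo()`/`hbr()` (channels x time matrices),
#' and `connMatrix()` (the Fisher-z matrix of a [ConnectivityMatrix-class]).
#'
#' @param x an object of one of the package classes.
#' @return the corresponding metadata field or matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("hbo", function(x) standardGeneric("hbo"))

#' @rdname accessors
#' @export
setGeneric("hbr", function(x) standardGeneric("hbr"))

#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

setMethod("samplingRate", "NirsRecording",
          function(x) S4Vectors::metadata(x)$fs)
setMethod("samplingRate", "HbRecording",
          function(x) S4Vectors::metadata(x)$fs)
setMethod("subjectId", "NirsRecording",
          function(x) S4Vectors::metadata(x)$subjectId)
setMethod("subjectId", "HbRecording",
          function(x) S4Vectors::metadata(x)$subjectId)
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)
setMethod("groupLabel", "NirsRecording",
          function(x) S4Vectors::metadata(x)$group)
setMethod("groupLabel", "HbRecording",
          function(x) S4Vectors::metadata(x)$group)
setMethod("groupLabel", "ConnectivityMatrix", function(x) x@group)
setMethod("nChannels", "NirsMontage", function(x) nrow(x@channels))
setMethod("nChannels", "NirsRecording", function(x) nrow(x))
setMethod("nChannels", "HbRecording", function(x) nrow(x))
setMethod("roiLabels", "NirsMontage", function(x) names(x@roiPartition))
setMethod("hbo", "HbRecording",
          function(x) SummarizedExperiment::assay(x, "hbo"))
setMethod("hbr", "HbRecording",
          function(x) SummarizedExperiment::assay(x, "hbr"))
setMethod("connMatrix", "ConnectivityMatrix", function(x) x@z)

setMethod("show", "NirsMontage", function(object) {
  cat(sprintf("NirsMontage: %d channels, %d ROIs\n",
              nrow(object@channels), length(object@roiPartition)))
  sizes <- lengths(object@roiPartition)
  cat("  ", paste(sprintf("%s(%d)", names(sizes), sizes), collapse = " "),
      "\n", sep = "")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects/group, %g Hz x %g s, wavelengths %s nm\n",
    object@nPerGroup, object@fs, object@duration,
    paste(object@wavelengths, collapse = "/")))
  cat(sprintf("  %d ROIs, channel mix %.2f, subject/edge z jitter %.3f/%.3f, seed %d\n",
              nrow(object@latentZ$HC), object@channelMix,
              object@subjectZSd, object@edgeZSd, object@seed))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  z <- object@z[upper.tri(object@z)]
  cat(sprintf(
    "ConnectivityMatrix [%s] %s/%s: %d nodes, %d edges (%d missing), mean z %.3f\n",
    object@level, object@subjectId, object@group, nrow(object@z),
    length(z), sum(is.na(z)), mean(z, na.rm = TRUE)))
})
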