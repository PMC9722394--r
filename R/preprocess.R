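#' Preprocessing configuration
#'
#' Collects every preprocessing parameter. Names mirror the conventional
#' motion-correction parameter names (`SDThresh`, `AMPThresh`, `tMotion`,
#' `tMask`, `p`): a sliding window of length `tMotion` seconds is flagged as
#' artifactual when its max-min excursion exceeds `sdThresh` times the
#' robust SD of the first-differenced series, or exceeds `ampThresh` in
#' absolute optical-density units; flagged windows are dilated by `tMask`
#' seconds on each side and corrected with a cubic smoothing spline with
#' parameter `splineP` (1 = interpolation, 0 = straight line).
#'
#' @param snrThresholdDb channel quality threshold (dB); a channel is
#'   excluded when either wavelength falls below it.
#' @param snrDbFactor 20 (amplitude-ratio convention, default) or 10
#'   (power-ratio) for the dB conversion.
#' @param sdThresh motion threshold as a multiple of the robust SD of the
#'   differenced series.
#' @param ampThresh absolute motion threshold (optical-density units).
#' @param tMotion sliding-window length (s).
#' @param tMask dilation of flagged windows (s, each side).
#' @param splineP smoothing-spline parameter in \[0,1\].
#' @param band band-pass edges (Hz).
#' @param filterOrder order of each zero-phase Butterworth stage.
#' @param dpf differential pathlength factor.
#' @param sdDistance source-detector separation (cm); `NA` means take it
#'   from the recording metadata.
#' @param subjectDropFrac drop a subject when more than this fraction of
#'   channels fails quality control.
#' @return a list of class `PreprocConfig`.
#' @export
preprocConfig <- function(snrThresholdDb = 10, snrDbFactor = 20,
                          sdThresh = 20, ampThresh = 3, tMotion = 0.5,
                          tMask = 1.0, splineP = 0.99, band = c(0.01, 0.1),
                          filterOrder = 3, dpf = 6.0, sdDistance = NA_real_,
                          subjectDropFrac = 0.2) {
  stopifnot(splineP >= 0, splineP <= 1, sdThresh > 0, ampThresh > 0,
            band[1] > 0, band[2] > band[1])
  structure(list(snrThresholdDb = snrThresholdDb,
                 snrDbFactor = snrDbFactor, sdThresh = sdThresh,
                 ampThresh = ampThresh, tMotion = tMotion, tMask = tMask,
                 splineP = splineP, band = band, filterOrder = filterOrder,
                 dpf = dpf, sdDistance = sdDistance,
                 subjectDropFrac = subjectDropFrac),
            class = "PreprocConfig")
}

#' Signal-to-noise ratio of a raw intensity series, in dB
#'
#' SNR is the mean of the strictly positive raw intensity divided by its
#' standard deviation, converted to dB (`factor * log10`, amplitude-ratio
#' factor 20 by default). A constant series has infinite SNR and passes
#' quality control trivially.
#'
#' @param d strictly positive numeric series, length >= 2.
#' @param dbFactor 20 (default) or 10.
#' @return SNR in dB (possibly `Inf`).
#' @examples
#' computeSnrDb(rnorm(1000, 100, 1))   # ~40 dB
#' @export
computeSnrDb <- function(d, dbFactor = 20) {
  stopifnot(length(d) >= 2)
  if (any(d <= 0)) stop("intensity series must be strictly positive")
  s <- sd(d)
  if (s == 0) return(Inf)
  dbFactor * log10(mean(d) / s)
}

#' Channel quality control
#'
#' Computes the SNR (dB) of every channel at both wavelengths; a channel
#' fails when either wavelength falls below `cfg$snrThresholdDb`.
#'
#' @param rec a [NirsRecording-class].
#' @param cfg a [preprocConfig()] list.
#' @return list with `snr` (channels x 2 matrix), `pass` (logical vector),
#'   and `summary` (mean and SD of the passing channels' SNR values).
#' @export
qcChannels <- function(rec, cfg = preprocConfig()) {
  stopifnot(is(rec, "NirsRecording"))
  snr <- vapply(c("intensity730", "intensity850"), function(a) {
    m <- SummarizedExperiment::assay(rec, a)
    n <- ncol(m)
    mu <- rowMeans(m)
    s2 <- pmax(0, (rowSums(m * m) - n * mu^2) / (n - 1))
    ifelse(s2 == 0, Inf, cfg$snrDbFactor * log10(mu / sqrt(s2)))
  }, numeric(nrow(rec)))
  pass <- snr[, 1] >= cfg$snrThresholdDb & snr[, 2] >= cfg$snrThresholdDb
  vals <- snr[pass, ][is.finite(snr[pass, ])]
  list(snr = snr, pass = unname(pass),
       summary = c(meanDb = mean(vals), sdDb = sd(vals),
                   nFail = sum(!pass)))
}

#' Intensity to optical density
#'
#' `OD(t) = -log10(I(t) / mean(I))`, per channel; zero-mean by construction
#' of the reference level.
#'
#' @param intensity strictly positive numeric vector, or channels x time
#'   matrix (row-wise conversion).
#' @return optical density, same shape as the input.
#' @export
intensityToOD <- function(intensity) {
  if (min(intensity) <= 0) {
    if (is.matrix(intensity)) {
      bad <- which(intensity <= 0, arr.ind = TRUE)
      stop(sprintf("non-positive intensity at channel %d, sample %d",
                   bad[1, 1], bad[1, 2]))
    }
    stop(sprintf("non-positive intensity at sample %d",
                 which(intensity <= 0)[1]))
  }
  if (is.matrix(intensity)) cpp_od(intensity)
  else -log10(intensity / mean(intensity))
}

## merge overlapping/adjacent [start, end] rows of an integer matrix
.mergeSegments <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    if (seg[i, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], seg[i, 2])
    } else {
      out <- rbind(out, seg[i, , drop = FALSE])
    }
  }
  out
}

## matrix version of detectMotion: list of segment matrices, one per channel
.detectMotionMat <- function(od, fs, cfg) {
  nch <- nrow(od); n <- ncol(od)
  w <- max(2L, round(cfg$tMotion * fs))
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (n <= w) return(rep(list(empty), nch))
  ## robust SD of the first difference; a thinned subsample is ample for
  ## the median-based estimate on long recordings
  step <- max(1L, (n - 1L) %/% 4000L)
  i2 <- seq(2L, n, by = step)
  dx <- od[, i2, drop = FALSE] - od[, i2 - 1L, drop = FALSE]
  med <- apply(dx, 1, median)
  sdRef <- 1.4826 * apply(abs(dx - med), 1, median)
  rng <- cpp_roll_range(od, w)
  ## exceeding either threshold == exceeding the smaller of the two
  bad <- rng > pmin(cfg$sdThresh * sdRef, cfg$ampThresh)
  pad <- round(cfg$tMask * fs)
  lapply(seq_len(nch), function(ch) {
    idx <- which(bad[ch, ])
    if (!length(idx)) return(empty)
    .mergeSegments(cbind(start = pmax(1L, idx - pad),
                         end = pmin(n, idx + w - 1L + pad)))
  })
}

#' Detect motion-artifact segments in an optical-density series
#'
#' Slides a window of `tMotion` seconds along the series; a window is
#' artifactual when its max-min excursion exceeds `sdThresh` times a robust
#' SD of the first-differenced series (1.4826 x median absolute deviation),
#' or exceeds `ampThresh` absolutely. Flagged windows are dilated by
#' `tMask` seconds on each side and overlapping windows are merged.
#'
#' @param od numeric optical-density series.
#' @param fs sampling rate (Hz).
#' @param cfg a [preprocConfig()] list.
#' @return integer matrix with columns `start`, `end` (sample indices);
#'   zero rows when the series is clean.
#' @export
detectMotion <- function(od, fs, cfg = preprocConfig()) {
  .detectMotionMat(matrix(od, nrow = 1L), fs, cfg)[[1]]
}

#' Correct motion-artifact segments with a smoothing spline
#'
#' For each artifact segment a cubic smoothing spline (parameter
#' `cfg$splineP`, csaps convention: the roughness weight is
#' `(1 - p) / p`) is fitted to the segment and subtracted, removing the
#' artifact shape; the corrected segment and all subsequent samples are then
#' shifted so the series is level-continuous at both segment boundaries.
#' Segments shorter than four samples fall back to linear-trend
#' subtraction. Samples outside flagged segments are only affected by the
#' documented level re-anchoring offset.
#'
#' @param od numeric optical-density series.
#' @param segments integer matrix from [detectMotion()].
#' @param fs sampling rate (Hz).
#' @param cfg a [preprocConfig()] list.
#' @return corrected series, same length as `od`.
#' @export
splineCorrect <- function(od, segments, fs, cfg = preprocConfig()) {
  if (is.null(segments) || nrow(segments) == 0L) return(od)
  n <- length(od)
  stopifnot(all(segments[, 1] >= 1), all(segments[, 2] <= n))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, 1]; e <- segments[i, 2]
    idx <- s:e
    y <- od[idx]
    ## csaps convention with x in sample units; smooth.spline rescales x to
    ## [0,1], which multiplies the roughness integral by (range)^3
    lambda <- (1 - cfg$splineP) / cfg$splineP / max(1, length(idx) - 1)^3
    if (length(idx) < 4L) {
      fit <- lm.fit(cbind(1, seq_along(idx)), y)$fitted.values
    } else {
      sp <- if (length(idx) < 50)
        smooth.spline(seq_along(idx), y, lambda = lambda,
                      keep.data = FALSE, all.knots = TRUE)
      else
        smooth.spline(seq_along(idx), y, lambda = lambda,
                      keep.data = FALSE, nknots = 30L)
      fit <- predict(sp, seq_along(idx))$y
    }
    resid <- y - fit
    ref <- if (s > 1) od[s - 1] else y[1] - resid[1]
    newSeg <- resid + (ref - resid[1])
    if (e < n) {
      delta <- newSeg[length(newSeg)] - od[e]
      od[(e + 1):n] <- od[(e + 1):n] + delta
    }
    od[idx] <- newSeg
  }
  od
}

## cached zero-phase Butterworth cascade (high-pass then low-pass)
.bandFilters <- local({
  cache <- new.env(parent = emptyenv())
  function(band, fs, order) {
    key <- paste(band[1], band[2], fs, order)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ny <- fs / 2
    if (band[2] >= ny) stop("upper band edge must lie below Nyquist")
    flt <- list(hp = signal::butter(order, band[1] / ny, type = "high"),
                lp = signal::butter(order, band[2] / ny, type = "low"))
    cache[[key]] <- flt
    flt
  }
})

## forward-backward filtering of matrix rows (same end-padding convention
## as signal::filtfilt)
.filtfiltRows <- function(flt, x) {
  cpp_filtfilt_rows(flt$b / flt$a[1], flt$a / flt$a[1], x)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, implemented as a
#' cascade of a high-pass and a low-pass stage of order `order` each, which
#' is numerically better conditioned than a single narrow band-pass at
#' these normalized frequencies. DC is removed and out-of-band components
#' (cardiac, respiratory) are attenuated by well over 20 dB.
#'
#' @param x numeric series, or channels x time matrix (row-wise filtering).
#' @param band filter edges (Hz).
#' @param fs sampling rate (Hz).
#' @param order Butterworth order per stage.
#' @return filtered series, same shape as `x`.
#' @export
bandpass <- function(x, band = c(0.01, 0.1), fs, order = 3) {
  flt <- .bandFilters(band, fs, order)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) < 12 * order)
    stop("series too short for the filter warm-up")
  ## remove the mean first: exact DC rejection regardless of the numerical
  ## conditioning of the narrow high-pass stage
  x <- x - rowMeans(x)
  y <- .filtfiltRows(flt$lp, .filtfiltRows(flt$hp, x))
  if (vec) drop(y) else y
}

#' Optical density to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert system
#' `OD(lambda) = (eps_HbO(lambda) HbO + eps_HbR(lambda) HbR) * DPF * L`
#' for the two chromophores at every time point, with concentrations in
#' micromolar. The inversion is exact (a 2 x 2 linear solve) and linear in
#' its inputs.
#'
#' @param od730,od850 optical-density series (vectors or channels x time
#'   matrices of identical shape) at the two wavelengths.
#' @param dpf differential pathlength factor.
#' @param sdDistance source-detector separation (cm).
#' @param wavelengths the two wavelengths (nm), used to look up extinction
#'   coefficients.
#' @return list with elements `hbo` and `hbr` (micromolar), same shape as
#'   the inputs.
#' @export
odToHb <- function(od730, od850, dpf = 6.0, sdDistance = 3.0,
                   wavelengths = c(730, 850)) {
  stopifnot(length(od730) == length(od850))
  eps <- extinctionCoefficients(wavelengths)
  E <- eps * 1e-6 * dpf * sdDistance
  if (abs(det(E)) < 1e-18)
    stop("singular extinction matrix; check wavelengths")
  Einv <- solve(E)
  if (is.matrix(od730))
    return(cpp_mbll(od730, od850, Einv[1, 1], Einv[1, 2],
                    Einv[2, 1], Einv[2, 2]))
  list(hbo = Einv[1, 1] * od730 + Einv[1, 2] * od850,
       hbr = Einv[2, 1] * od730 + Einv[2, 2] * od850)
}

#' Preprocess a raw recording into hemoglobin time series
#'
#' Full preprocessing chain in order: channel quality control (SNR
#' threshold), intensity to optical density, motion-artifact detection and
#' smoothing-spline correction on optical density (segments pooled across
#' both wavelengths per channel), zero-phase band-pass filtering, and
#' modified Beer-Lambert inversion to HbO/HbR. All stage diagnostics (QC
#' table, corrected segments per channel) are retained in the result's
#' metadata.
#'
#' @param rec a [NirsRecording-class].
#' @param cfg a [preprocConfig()] list.
#' @return an [HbRecording-class]; `rowData()$qcPass` flags channels that
#'   passed QC, `metadata()$subjectUsable` is `FALSE` when more than
#'   `cfg$subjectDropFrac` of channels failed.
#' @export
preprocess <- function(rec, cfg = preprocConfig()) {
  stopifnot(is(rec, "NirsRecording"))
  fs <- samplingRate(rec)
  L <- if (is.na(cfg$sdDistance))
    S4Vectors::metadata(rec)$sdDistance else cfg$sdDistance
  if (is.null(L)) L <- 3.0
  wl <- S4Vectors::metadata(rec)$wavelengths
  if (is.null(wl)) wl <- c(730, 850)

  qc <- qcChannels(rec, cfg)
  od1 <- intensityToOD(SummarizedExperiment::assay(rec, "intensity730"))
  od2 <- intensityToOD(SummarizedExperiment::assay(rec, "intensity850"))

  seg1 <- .detectMotionMat(od1, fs, cfg)
  seg2 <- .detectMotionMat(od2, fs, cfg)
  artifacts <- vector("list", nrow(od1))
  for (ch in seq_len(nrow(od1))) {
    seg <- rbind(seg1[[ch]], seg2[[ch]])
    if (nrow(seg)) {
      seg <- .mergeSegments(seg)
      od1[ch, ] <- splineCorrect(od1[ch, ], seg, fs, cfg)
      od2[ch, ] <- splineCorrect(od2[ch, ], seg, fs, cfg)
    }
    artifacts[[ch]] <- seg
  }

  od1 <- bandpass(od1, cfg$band, fs, cfg$filterOrder)
  od2 <- bandpass(od2, cfg$band, fs, cfg$filterOrder)
  hb <- odToHb(od1, od2, dpf = cfg$dpf, sdDistance = L, wavelengths = wl)

  md <- S4Vectors::metadata(rec)
  rd <- SummarizedExperiment::rowData(rec)
  rd$qcPass <- qc$pass
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(hbo = hb$hbo, hbr = hb$hbr),
    rowData = rd,
    metadata = list(fs = fs, subjectId = md$subjectId, group = md$group,
                    qc = qc, artifacts = artifacts,
                    subjectUsable = mean(!qc$pass) <= cfg$subjectDropFrac))
  rownames(se) <- rownames(rec)
  methods::as(se, "HbRecording")
}
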