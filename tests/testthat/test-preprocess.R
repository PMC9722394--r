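cfg <- preprocConfig()

test_that("SNR in dB follows the amplitude-ratio convention", {
  d <- c(99, 101)                       # mean 100, sd sqrt(2)
  expect_equal(computeSnrDb(d), 20 * log10(100 / sqrt(2)), tolerance = 1e-12)
  expect_equal(computeSnrDb(d, dbFactor = 10), computeSnrDb(d) / 2)
  expect_identical(computeSnrDb(rep(5, 10)), Inf)
  expect_error(computeSnrDb(c(1, -1, 2)), "positive")
  ## boundary: mean 100, sd just above 31.62 falls below 10 dB
  expect_lt(20 * log10(100 / 31.99), 10)
})

test_that("channel QC excludes exactly the corrupted channel and is monotone", {
  spec <- tinySpec(duration = 60)
  rec <- simulateSubject(spec, "HC", 3L)
  ## corrupt channel 17 at both wavelengths with huge noise
  for (a in c("intensity730", "intensity850")) {
    m <- SummarizedExperiment::assay(rec, a)
    m[17, ] <- abs(m[17, ] + rnorm(ncol(m), 0, mean(m[17, ])))
    m[17, m[17, ] <= 0] <- 1e-6
    SummarizedExperiment::assay(rec, a) <- m
  }
  qc <- qcChannels(rec, cfg)
  expect_false(qc$pass[17])
  expect_equal(sum(!qc$pass), 1L)
  ## monotonicity: raising the threshold never re-admits a channel
  passLoose <- qcChannels(rec, preprocConfig(snrThresholdDb = 5))$pass
  passTight <- qcChannels(rec, preprocConfig(snrThresholdDb = 25))$pass
  expect_true(all(passLoose[!passTight] | !passTight[!passLoose]))
  expect_true(all(which(passTight) %in% which(passLoose)))
})

test_that("optical-density conversion is zero-mean log-attenuation", {
  expect_equal(intensityToOD(rep(3, 100)), rep(0, 100))
  i <- rep(100, 1000)
  i[500] <- 10                           # one dip to a tenth of the level
  od <- intensityToOD(i)
  expect_equal(od[500], 1, tolerance = 0.05)
  expect_lt(max(abs(od[-500])), 0.05)
  expect_error(intensityToOD(c(1, 0, 2)), "non-positive")
  ## matrix form matches the vector form row by row
  m <- matrix(runif(200, 50, 150), 2)
  expect_equal(intensityToOD(m)[1, ], intensityToOD(m[1, ]))
})

test_that("motion detection finds spikes, dilates by tMask and merges windows", {
  fs <- 19
  set.seed(41)
  n <- fs * 120
  clean <- bandpass(rnorm(n, 0, 0.002), c(0.01, 0.1), fs) +
    cumsum(rnorm(n, 0, 1e-4))
  clean <- clean + rnorm(n, 0, 5e-4)    # sensor-like jitter sets SD_ref
  expect_equal(nrow(detectMotion(clean, fs, cfg)), 0L)

  spiked <- clean
  at <- fs * 60
  spiked[at:(at + 5)] <- spiked[at:(at + 5)] + 0.2
  seg <- detectMotion(spiked, fs, cfg)
  expect_equal(nrow(seg), 1L)
  pad <- cfg$tMask * fs
  expect_lte(seg[1, "start"], at)
  expect_gte(seg[1, "start"], at - pad - round(cfg$tMotion * fs))
  expect_gte(seg[1, "end"], at + 5)
  expect_lte(seg[1, "end"], at + 5 + pad + round(cfg$tMotion * fs))

  ## two spikes 0.5 s apart with tMask = 1 s merge into one segment
  double <- clean
  double[at:(at + 2)] <- double[at:(at + 2)] + 0.2
  at2 <- at + round(0.5 * fs)
  double[at2:(at2 + 2)] <- double[at2:(at2 + 2)] + 0.2
  expect_equal(nrow(detectMotion(double, fs, cfg)), 1L)
})

test_that("interval merging matches a brute-force coverage oracle", {
  set.seed(7)
  for (i in 1:25) {
    n <- 500L
    k <- sample(1:8, 1)
    start <- sort(sample.int(n - 30L, k))
    seg <- cbind(start = start, end = pmin(n, start + sample(1:40, k, TRUE)))
    merged <- nirsconn:::.mergeSegments(seg)
    oracle <- bruteForceMerge(seg, n)
    expect_equal(unname(merged[, 1]), unname(oracle[, 1]))
    expect_equal(unname(merged[, 2]), unname(oracle[, 2]))
  }
})

test_that("spline correction removes steps, is near-idempotent and localized", {
  fs <- 19
  set.seed(11)
  n <- fs * 60
  base <- bandpass(rnorm(n, 0, 0.3), c(0.01, 0.1), fs) * 0.01
  od <- base
  od[(n %/% 2):n] <- od[(n %/% 2):n] + 0.15    # step artifact
  seg <- matrix(c(n %/% 2 - 20L, n %/% 2 + 60L), 1,
                dimnames = list(NULL, c("start", "end")))

  expect_identical(splineCorrect(od, seg[0, , drop = FALSE], fs, cfg), od)

  fixed <- splineCorrect(od, seg, fs, cfg)
  stepBefore <- abs(mean(od[(seg[1, 2] + 1):(seg[1, 2] + 40)]) -
                      mean(od[(seg[1, 1] - 40):(seg[1, 1] - 1)]))
  stepAfter <- abs(mean(fixed[(seg[1, 2] + 1):(seg[1, 2] + 40)]) -
                     mean(fixed[(seg[1, 1] - 40):(seg[1, 1] - 1)]))
  expect_lt(stepAfter, 0.1 * stepBefore)

  ## samples before the segment untouched; after it only level-shifted
  pre <- seq_len(seg[1, 1] - 1)
  expect_identical(fixed[pre], od[pre])
  post <- (seg[1, 2] + 1):n
  expect_lt(sd((fixed - od)[post]), 1e-12)

  twice <- splineCorrect(fixed, seg, fs, cfg)
  expect_lt(sqrt(mean((twice - fixed)^2)) / sd(fixed), 0.01)

  ## degenerate segment (< 4 samples) falls back to linear detrending
  tiny <- matrix(c(50L, 52L), 1, dimnames = list(NULL, c("start", "end")))
  expect_silent(splineCorrect(od, tiny, fs, cfg))
})

test_that("band-pass meets its passband/stopband contract and is zero-phase", {
  fs <- 19
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  mid <- seq(round(length(t) / 3), round(2 * length(t) / 3))

  inBand <- sin(2 * pi * 0.05 * t)
  y <- bandpass(inBand, c(0.01, 0.1), fs)
  amp <- max(abs(y[mid]))
  expect_gte(amp, 0.89)
  expect_lte(amp, 1.0)

  cardiac <- sin(2 * pi * 1.1 * t)
  expect_lt(max(abs(bandpass(cardiac, c(0.01, 0.1), fs)[mid])), 0.1)
  resp <- sin(2 * pi * 0.25 * t)
  expect_lt(max(abs(bandpass(resp, c(0.01, 0.1), fs)[mid])), 0.1)
  expect_lt(max(abs(bandpass(rep(2, length(t)), c(0.01, 0.1), fs)[mid])),
            1e-6)

  ## zero phase: cross-correlation with a passband input peaks at lag 0
  cc <- ccf(y[mid], inBand[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  ## matches the reference forward-backward cascade (zero-mean input; the
  ## narrow high-pass amplifies even last-bit DC differences, so compare
  ## at 1e-6)
  set.seed(2)
  v <- rnorm(800); v <- v - mean(v)
  hp <- signal::butter(3, 0.01 / (fs / 2), type = "high")
  lp <- signal::butter(3, 0.1 / (fs / 2), type = "low")
  ref <- signal::filtfilt(lp, signal::filtfilt(hp, v))
  expect_equal(bandpass(v, c(0.01, 0.1), fs), ref, tolerance = 1e-6)

  expect_error(bandpass(rnorm(10), c(0.01, 0.1), fs), "too short")
})

test_that("Beer-Lambert inversion is exact and linear", {
  expect_equal(odToHb(0, 0), list(hbo = 0, hbr = 0))
  set.seed(3)
  hbo <- matrix(rnorm(400, 0, 0.5), 4)
  hbr <- matrix(rnorm(400, 0, 0.2), 4)
  eps <- extinctionCoefficients()
  k <- 1e-6 * 6.0 * 3.0
  od730 <- (eps[1, 1] * hbo + eps[1, 2] * hbr) * k
  od850 <- (eps[2, 1] * hbo + eps[2, 2] * hbr) * k
  back <- odToHb(od730, od850)
  expect_equal(back$hbo, hbo, tolerance = 1e-10)
  expect_equal(back$hbr, hbr, tolerance = 1e-10)

  ## linearity: inversion of a sum equals the sum of inversions
  a730 <- matrix(rnorm(400), 4) * 1e-3; a850 <- matrix(rnorm(400), 4) * 1e-3
  s <- odToHb(od730 + a730, od850 + a850)
  p1 <- odToHb(od730, od850); p2 <- odToHb(a730, a850)
  expect_equal(s$hbo, p1$hbo + p2$hbo, tolerance = 1e-10)
  expect_equal(s$hbr, p1$hbr + p2$hbr, tolerance = 1e-10)
})

test_that("motion correction brings recovered HbO closer to ground truth", {
  spec <- tinySpec(duration = 150, artifactRate = 2.0, seed = 5L)
  rec <- simulateSubject(spec, "HC", 77L)
  expect_gt(nrow(S4Vectors::metadata(rec)$artifactTruth), 0)
  truth <- SummarizedExperiment::assay(rec, "hboTruth")
  truthBp <- bandpass(truth, cfg$band, samplingRate(rec))

  hbOn <- preprocess(rec, cfg)
  hbOff <- preprocess(rec, preprocConfig(sdThresh = 1e9, ampThresh = 1e9))
  expect_gt(sum(vapply(S4Vectors::metadata(hbOn)$artifacts, nrow,
                       integer(1))), 0)
  rmse <- function(est) sqrt(mean((est - truthBp)^2))
  expect_lt(rmse(hbo(hbOn)), rmse(hbo(hbOff)))
})

test_that("preprocess composes the stages and keeps an audit trail", {
  spec <- tinySpec(duration = 90)
  rec <- simulateSubject(spec, "MCI", 8L)
  hb <- preprocess(rec)
  expect_s4_class(hb, "HbRecording")
  expect_equal(dim(hbo(hb)), c(71L, 90L * 19L))
  expect_equal(groupLabel(hb), "MCI")
  md <- S4Vectors::metadata(hb)
  expect_length(md$artifacts, 71L)
  expect_true(is.matrix(md$qc$snr))
  expect_true(is.logical(SummarizedExperiment::rowData(hb)$qcPass))
  expect_true(md$subjectUsable)
})
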