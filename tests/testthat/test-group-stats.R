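test_that("pooled t statistic matches hand computation and t.test", {
  r <- edgeTTest(c(1, 2, 3), c(0, 1, 2))
  expect_equal(r$t, 1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4L)

  same <- edgeTTest(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_equal(edgeTTest(rnorm(64), rnorm(64))$df, 126L)
  expect_error(edgeTTest(rep(1, 5), rep(1, 5)), "pooled variance")

  set.seed(10)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), 0.4)
    r <- edgeTTest(x, y)
    expect_equal(r$t, bruteForceT(x, y), tolerance = 1e-12)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("FDR adjustment equals the brute-force BH definition", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(rep(1, 10)), rep(1, 10))
  expect_error(fdrAdjust(c(0.5, 1.2)))

  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- fdrAdjust(p)
    expect_equal(adj, bruteForceBH(p), tolerance = 1e-12)
    ## adjusted-p thresholding reproduces the classic step-up rejection set
    for (q in c(0.01, 0.05, 0.2))
      expect_equal(which(adj <= q), bruteForceBHReject(p, q))
  }
})

test_that("edge ROC follows the Mann-Whitney identity and Youden rule", {
  expect_equal(edgeROC(c(4, 5, 6), c(1, 2, 3))$auc, 1)
  expect_equal(edgeROC(c(0.9, 0.8), c(0.7, 0.85))$auc, 0.75)
  expect_equal(edgeROC(c(1, 1), c(1, 1))$auc, 0.5)

  perfect <- edgeROC(c(4, 5, 6), c(1, 2, 3))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  set.seed(12)
  for (i in 1:1000) {
    hc <- rnorm(sample(2:12, 1), 0.3)
    mci <- rnorm(sample(2:12, 1))
    r <- edgeROC(hc, mci)
    expect_equal(r$auc, trapezoidAUC(hc, mci), tolerance = 1e-12)
    ## Youden point: no threshold does better than the reported one
    thr <- sort(c(hc, mci))
    thr <- c(thr - 1e-9, thr + 1e-9)
    bestJ <- max(vapply(thr, function(t)
      mean(mci < t) + mean(hc >= t) - 1, numeric(1)))
    expect_equal(r$sensitivity + r$specificity - 1, bestJ,
                 tolerance = 1e-12)
    expect_true(r$sensitivity >= 0 && r$sensitivity <= 1)
    expect_true(r$specificity >= 0 && r$specificity <= 1)
  }
})

test_that("AUC orientation favors edges reduced in the patient group", {
  set.seed(13)
  hc <- rnorm(64, 0.8, 0.2)
  mci <- rnorm(64, 0.6, 0.2)
  expect_gt(edgeROC(hc, mci)$auc, 0.5)
  ## matches pROC with HC treated as the higher-valued class
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), each = 64), predictor = c(hc, mci),
    direction = "<"))
  expect_equal(edgeROC(hc, mci)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("edge-stats tables carry one row per undirected edge with flags", {
  set.seed(14)
  cms <- lapply(1:12, function(i) {
    g <- if (i <= 6) "HC" else "MCI"
    x <- matrix(rnorm(9 * 400), 9)
    if (g == "HC") x[1, ] <- x[1, ] + 40 * x[2, ]   # strong edge 1-2 in HC
    cm <- channelFC(hbRecordingFromMatrix(x, subjectId = paste0("s", i),
                                          group = g))
    cm
  })
  st <- runEdgeStats(cms)
  expect_equal(nrow(st), choose(9, 2))
  expect_true(all(st$p_fdr >= st$p_raw - 1e-12))
  expect_true(all(st$df == 10))
  expect_true(all(st$flag %in% c("", "*", "**")))
  strongest <- st[which.max(abs(st$t)), ]
  expect_setequal(c(strongest$node_i, strongest$node_j), c("CH1", "CH2"))

  ## ROI-level screening column
  roiCms <- lapply(cms, function(cm) {
    z <- connMatrix(cm)[1:9, 1:9]
    dimnames(z) <- list(roiLabels(defaultMontage()),
                        roiLabels(defaultMontage()))
    new("ConnectivityMatrix", level = "roi", z = z,
        subjectId = cm@subjectId, group = cm@group)
  })
  str <- runEdgeStats(roiCms)
  expect_true("aucSelected" %in% names(str))
  expect_true(all(str$aucSelected[str$aucSelected] &
                    str$auc[str$aucSelected] > 0.65))
})

test_that("missing edges are compared pairwise and reported as NA when empty", {
  set.seed(15)
  cms <- lapply(1:8, function(i) {
    pass <- rep(TRUE, 4)
    if (i == 1) pass[4] <- FALSE
    channelFC(hbRecordingFromMatrix(matrix(rnorm(4 * 500), 4),
                                    qcPass = pass,
                                    subjectId = paste0("s", i),
                                    group = if (i <= 4) "HC" else "MCI"))
  })
  st <- runEdgeStats(cms)
  expect_false(any(is.na(st$t)))         # subject 1 simply drops out
  ## edges touching CH4 lose subject 1: df = 3 + 4 - 2
  expect_equal(st$df[st$node_i == "CH3" & st$node_j == "CH4"], 5)
  expect_equal(st$df[st$node_i == "CH1" & st$node_j == "CH2"], 6)
})
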