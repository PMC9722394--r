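test_that("LDA reduces to the midpoint rule in one dimension", {
  x <- c(1, 2, 3, 7, 8, 9)
  labels <- c(rep("MCI", 3), rep("HC", 3))
  m <- ldaTrain(x, labels)
  ## equal priors: decision boundary at the midpoint of projected means
  expect_equal(m$threshold / m$w, (2 + 8) / 2, tolerance = 1e-12)
  expect_equal(unname(ldaPredict(m, c(0, 10))), c("MCI", "HC"))
})

test_that("symmetric class means give a symmetric discriminant", {
  set.seed(20)
  half <- matrix(rnorm(2 * 100), ncol = 2)
  base <- rbind(half, half[, 2:1])       # exactly exchangeable coordinates
  x <- rbind(base, sweep(base, 2, c(1, 1), "+"))
  labels <- rep(c("MCI", "HC"), each = 200)
  w <- ldaTrain(x, labels)$w
  expect_equal(w[1] / w[2], 1, tolerance = 1e-10)
})

test_that("LDA decisions agree with MASS::lda on Gaussian data", {
  skip_if_not_installed("MASS")
  set.seed(21)
  for (i in 1:10) {
    d <- sample(1:3, 1)
    n <- 40
    x <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 0.8), n))
    labels <- rep(c("HC", "MCI"), each = n)
    m <- ldaTrain(x, labels)
    ref <- MASS::lda(x, grouping = labels)
    expect_equal(unname(ldaPredict(m, x)),
                 as.character(predict(ref, x)$class))
  }
})

test_that("singular covariance is ridged with a warning", {
  x <- cbind(c(1, 1, 2, 2), c(2, 2, 4, 4))   # collinear features
  expect_warning(m <- ldaTrain(x, c("HC", "HC", "MCI", "MCI")), "ridge")
  expect_true(all(is.finite(m$w)))
})

test_that("cross-validation folds are stratified partitions", {
  set.seed(22)
  x <- rnorm(23 + 19)
  labels <- c(rep("HC", 23), rep("MCI", 19))
  rep5 <- repeatedCV(x, labels, k = 5, repeats = 3, seed = 9L)
  for (fold in rep5$folds) {
    expect_equal(length(fold), 42L)
    expect_true(all(fold %in% 1:5))          # every subject in one fold
    for (g in c("HC", "MCI")) {
      counts <- table(factor(fold[labels == g], levels = 1:5))
      expect_lte(max(counts) - min(counts), 1)  # balanced within +/- 1
    }
  }
  expect_error(repeatedCV(rnorm(8), c(rep("HC", 4), rep("MCI", 4)), k = 5),
               "at least k")
})

test_that("repeated CV is deterministic, consistent and affine-invariant", {
  set.seed(23)
  x <- c(rnorm(32, 1), rnorm(32, 0))
  labels <- rep(c("HC", "MCI"), each = 32)
  a <- repeatedCV(x, labels, seed = 77L)
  b <- repeatedCV(x, labels, seed = 77L)
  expect_identical(a, b)
  expect_false(identical(a$accuracy,
                         repeatedCV(x, labels, seed = 78L)$accuracy))
  expect_equal(a$mean, mean(a$accuracy), tolerance = 1e-12)
  expect_equal(a$sd, sd(a$accuracy), tolerance = 1e-12)
  expect_equal(a$max, max(a$accuracy))
  ## affine rescaling of a 1-D feature cannot change LDA decisions
  c2 <- repeatedCV(3 * x - 7, labels, seed = 77L)
  expect_equal(c2$accuracy, a$accuracy)
})

test_that("separated, constant and label-permuted features behave as expected", {
  labels <- rep(c("HC", "MCI"), each = 32)
  sep <- repeatedCV(c(rnorm(32, 10), rnorm(32, -10)), labels, seed = 1L)
  expect_true(all(sep$accuracy == 100))

  const <- suppressWarnings(repeatedCV(rep(1, 64), labels, seed = 2L))
  expect_true(all(abs(const$accuracy - 50) <= 10))

  set.seed(24)
  x <- c(rnorm(64, 0.7, 0.2), rnorm(64, 0.55, 0.2))
  permLabels <- sample(rep(c("HC", "MCI"), each = 64))
  null <- repeatedCV(x, permLabels, k = 5, repeats = 10, seed = 3L)
  expect_gte(null$mean, 40)
  expect_lte(null$mean, 60)
})

test_that("pooled and fold-mean aggregation differ only by weighting", {
  set.seed(25)
  x <- c(rnorm(17, 0.8), rnorm(13, 0.2))
  labels <- c(rep("HC", 17), rep("MCI", 13))
  pooled <- repeatedCV(x, labels, repeats = 2, seed = 4L)
  fm <- repeatedCV(x, labels, repeats = 2, seed = 4L,
                   aggregate = "foldMean")
  expect_equal(length(fm$accuracy), 2L)
  expect_true(all(abs(pooled$accuracy - fm$accuracy) < 15))
})

test_that("feature-set construction mirrors the screening rules", {
  set.seed(26)
  labs <- roiLabels(defaultMontage())
  mk <- function(id, group, boost) {
    z <- matrix(0.5, 9, 9, dimnames = list(labs, labs))
    z[upper.tri(z)] <- 0.5 + rnorm(36, 0, 0.05)
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    z["RPF", "LO"] <- z["LO", "RPF"] <- 0.5 + boost + rnorm(1, 0, 0.05)
    z["LPF", "P"] <- z["P", "LPF"] <- 0.5 + boost + rnorm(1, 0, 0.05)
    diag(z) <- NA
    new("ConnectivityMatrix", level = "roi", z = z, subjectId = id,
        group = group)
  }
  cms <- c(lapply(1:20, function(i) mk(paste0("h", i), "HC", 0.4)),
           lapply(1:20, function(i) mk(paste0("m", i), "MCI", 0)))
  st <- runEdgeStats(cms)
  reports <- runClassification(list(roi = cms), list(roi = st),
                               repeats = 3, seed = 5L)
  expect_gte(length(reports), 3L)        # two single edges + the union
  expect_true(any(vapply(reports, function(r) r$name == "All above",
                         logical(1))))
  tab <- attr(reports, "table")
  expect_true(all(c("feature", "N1", "N2", "N3", "mean", "sd", "max") %in%
                    names(tab)))
  singles <- vapply(reports, `[[`, character(1), "name")
  expect_true(any(grepl("RPF-LO|LO-RPF", singles)))
  ## the boosted edges separate the groups well
  expect_gt(max(tab$mean), 80)
})
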