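# Synthetic-data generators: RR tachograms, MVAR networks, lesion cohorts,
# atlas partitions.

test_that("RR generator: constant case, determinism and validation", {
  rr <- genRRSeries(meanRR = 800, lfAmp = 0, hfAmp = 0, noiseSd = 0,
                    durationS = 60, seed = 1)
  expect_true(all(intervals(rr) == 800))

  a <- genRRSeries(seed = 7); b <- genRRSeries(seed = 7)
  expect_identical(intervals(a), intervals(b))
  c2 <- genRRSeries(seed = 8)
  expect_false(identical(intervals(a), intervals(c2)))

  expect_error(genRRSeries(meanRR = -5), "meanRR")
  expect_error(genRRSeries(lfFreq = 0.2), "lfFreq")
  expect_error(genRRSeries(hfFreq = 0.1), "hfFreq")
  expect_error(genRRSeries(durationS = 0), "durationS")
})

test_that("RR generator: LF-only modulation concentrates power in the LF band", {
  rr <- genRRSeries(lfAmp = 50, hfAmp = 0, noiseSd = 0, seed = 2)
  sp <- rrPSD(rr)
  total <- bandPower(sp, c(0.003, 1.9))
  lf <- bandPower(sp, c(0.04, 0.14))
  expect_gt(lf / total, 0.95)
})

test_that("RR generator: interval variance matches the analytic closed form", {
  for (s in 1:3) {
    rr <- genRRSeries(lfAmp = 40, hfAmp = 20, noiseSd = 10, seed = s)
    analytic <- 40^2 / 2 + 20^2 / 2 + 10^2
    expect_lt(abs(var(intervals(rr)) - analytic) / analytic, 0.10)
  }
})

test_that("MVAR generator: zero coupling gives independent white noise", {
  A <- array(0, c(3, 3, 1))
  sim <- genMVARNetwork(A, nSamples = 5000, seed = 1)
  y <- tsData(sim$ts)
  cc <- cor(t(y))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("MVAR generator: lagged regression recovers the true coupling", {
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
  sim <- genMVARNetwork(A, nSamples = 5000, seed = 3)
  est <- oracleVAR(tsData(sim$ts), 1)
  expect_lt(abs(est[2, 1, 1] - 0.5), 0.05)
  expect_lt(abs(est[1, 2, 1]), 0.05)
})

test_that("MVAR generator: scheduled coefficient switch is recovered per window", {
  A0 <- array(0, c(2, 2, 1)); diag(A0[, , 1]) <- 0.2
  A1 <- A0; A1[2, 1, 1] <- 0.5
  sim <- genMVARNetwork(list(A0, A1), nSamples = 4000,
                        schedule = c(1L, 2001L), seed = 4)
  y <- tsData(sim$ts)
  pre <- oracleVAR(y[, 1:2000], 1)
  post <- oracleVAR(y[, 2001:4000], 1)
  expect_lt(abs(pre[2, 1, 1]), 0.06)
  expect_lt(abs(post[2, 1, 1] - 0.5), 0.06)
  # the returned model carries the exact schedule
  expect_equal(coeffArray(sim$model)[2, 1, 1, 2000], 0)
  expect_equal(coeffArray(sim$model)[2, 1, 1, 2001], 0.5)
})

test_that("MVAR generator: residuals under the true model match innovationSd", {
  A <- bivarVAR2()
  sim <- genMVARNetwork(A, nSamples = 5000, innovationSd = c(1, 2), seed = 5)
  y <- tsData(sim$ts)
  n <- ncol(y)
  pred <- A[, , 1] %*% y[, 2:(n - 1)] + A[, , 2] %*% y[, 1:(n - 2)]
  res <- y[, 3:n] - pred
  expect_lt(abs(var(res[1, ]) - 1) / 1, 0.10)
  expect_lt(abs(var(res[2, ]) - 4) / 4, 0.10)
})

test_that("MVAR generator rejects unstable coefficients citing spectral radius", {
  A <- array(0, c(2, 2, 1)); diag(A[, , 1]) <- 1.05
  expect_error(genMVARNetwork(A, nSamples = 100), "spectral radius")
})

test_that("lesion cohort: correlation is built in by construction", {
  ch <- genLesionCohort(loadingCorr = 1, noiseSd = 0, seed = 1)
  # noiseless, corr 1: covariate is an affine function of the map mean over
  # the component support
  sup <- ch$componentMap > 0
  means <- vapply(ch$maps, function(m) mean(mapValues(m)[sup]), numeric(1))
  expect_gt(abs(cor(ch$covariate, means)), 1 - 1e-10)

  ch0 <- genLesionCohort(loadingCorr = 0, seed = 2)
  expect_lt(abs(cor(ch0$covariate, ch0$loadings)), 2 / sqrt(42))

  ch9 <- genLesionCohort(loadingCorr = 0.9, seed = 3)
  expect_lt(abs(cor(ch9$covariate, ch9$loadings) - 0.9), 0.1)
  expect_length(ch9$maps, 42L)  # the study cohort size is the default
})

test_that("lesion cohort generators are reproducible and validated", {
  a <- genLesionCohort(seed = 11); b <- genLesionCohort(seed = 11)
  expect_identical(a$covariate, b$covariate)
  expect_identical(mapValues(a$maps[[3]]), mapValues(b$maps[[3]]))
  expect_error(genLesionCohort(loadingCorr = 1.2), "loadingCorr")
})

test_that("atlas partition covers the grid and names the seven networks", {
  at1 <- genAtlas(c(6L, 6L, 6L), nRois = 1L)
  expect_true(all(mapValues(at1) == 1L))

  at7 <- genAtlas(c(6L, 6L, 6L), nRois = 7L)
  expect_identical(as.character(roiNames(at7)), sevenNetworks())
  h <- table(mapValues(at7))
  expect_equal(sum(h), 216)
  expect_length(h, 7L)

  at3 <- genAtlas(c(5L, 4L, 3L), nRois = 3L)
  expect_identical(sort(unique(as.integer(mapValues(at3)))), 1:3)
  expect_error(genAtlas(c(2L, 2L, 1L), nRois = 10L), "partition")
})
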