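# HRV: cleanup, time-domain metrics, spectral band powers, z-scoring.

test_that("cleanRR leaves clean series untouched and fixes a doubled beat", {
  clean <- RRISeries(rep(800, 20))
  out <- cleanRR(clean)
  expect_identical(intervals(out), rep(800, 20))
  expect_identical(sum(out@cleanedFlags), 0L)

  iv <- rep(800, 21); iv[11] <- 1600
  fixed <- cleanRR(RRISeries(iv))
  expect_true(fixed@cleanedFlags[11])
  expect_equal(intervals(fixed)[11], 800)
  expect_identical(sum(fixed@cleanedFlags), 1L)

  tiny <- cleanRR(RRISeries(c(800, 800, 800)))
  expect_identical(intervals(tiny), c(800, 800, 800))
  expect_error(cleanRR(RRISeries(c(800, 800))), "3 intervals")
})

test_that("cleanRR flags heavily corrupted series as suspect", {
  set.seed(1)
  iv <- rep(800, 20)
  iv[c(2, 5, 8, 11, 14, 17)] <- 2000
  expect_warning(out <- cleanRR(RRISeries(iv)), "20%")
  expect_identical(out@quality, "suspect")
  expect_s4_class(out, "RRISeries")
})

test_that("time-domain metrics match hand calculations", {
  expect_equal(hrvTimeDomain(RRISeries(c(800, 800, 800))),
               c(vc = 0, rmssd = 0))
  expect_equal(hrvTimeDomain(RRISeries(c(800, 820)))[["rmssd"]], 20)
  td <- hrvTimeDomain(RRISeries(c(750, 800, 850)))
  expect_equal(td[["vc"]], 0.0625)
  expect_equal(td[["rmssd"]], 50)
  expect_error(hrvTimeDomain(RRISeries(800)), "2 intervals")
})

test_that("rrPSD satisfies Parseval for a pure sinusoidal modulation", {
  rr <- genRRSeries(lfAmp = 30, hfAmp = 0, noiseSd = 0, lfFreq = 0.10,
                    seed = 1)
  sp <- rrPSD(rr)
  total <- bandPower(sp, c(min(sp$freq[sp$freq > 0]), max(sp$freq)))
  expect_lt(abs(total - 30^2 / 2) / (30^2 / 2), 0.05)
  # frequency resolution is bounded by 1/duration
  expect_lte(diff(sp$freq[1:2]), 1.05 / duration(rr))

  const <- genRRSeries(lfAmp = 0, hfAmp = 0, noiseSd = 0, seed = 1)
  spc <- rrPSD(const)
  expect_lt(max(spc$density[spc$freq > 0]), 1e-12)

  short <- RRISeries(rep(800, 10))
  expect_error(rrPSD(short), "short")
})

test_that("bandPower integrates exactly, splits additively and checks bands", {
  sp <- data.frame(freq = seq(0, 2, by = 0.01), density = 1)
  expect_equal(bandPower(sp, c(0.04, 0.14)), 0.10)
  # additivity over disjoint adjacent bands
  expect_equal(bandPower(sp, c(0.04, 0.09)) + bandPower(sp, c(0.09, 0.14)),
               bandPower(sp, c(0.04, 0.14)))
  expect_error(bandPower(sp, c(0.5, 0.5)), "empty band")
  expect_error(bandPower(sp, c(1.5, 3)), "range")
})

test_that("two-sinusoid tachogram recovers the analytic LF/HF power ratio", {
  rr <- genRRSeries(lfAmp = 40, hfAmp = 20, noiseSd = 0, seed = 3)
  m <- hrvMetrics(rr)
  expect_lt(abs(m[["lf"]] / m[["hf"]] - 4) / 4, 0.10)
})

test_that("VC is scale-invariant and RMSSD scale-equivariant", {
  for (s in 1:5) {
    rr <- genRRSeries(noiseSd = 15, seed = s, durationS = 120)
    sc <- RRISeries(intervals(rr) * 1.7)
    a <- hrvTimeDomain(rr); b <- hrvTimeDomain(sc)
    expect_equal(b[["vc"]], a[["vc"]])
    expect_equal(b[["rmssd"]], a[["rmssd"]] * 1.7)
  }
})

test_that("z-scoring uses the strict z < -1 reduction rule", {
  norms <- list(mean = c(vc = 0.05, lf = 500), sd = c(vc = 0.01, lf = 100),
                nControls = 30)
  atMean <- zscorePanel(c(vc = 0.05, lf = 500), norms)
  expect_equal(atMean$z, c(0, 0))
  expect_false(any(atMean$abnormal))

  atMinus1 <- zscorePanel(c(vc = 0.04, lf = 400), norms)
  expect_equal(atMinus1$z, c(-1, -1))
  expect_false(any(atMinus1$abnormal))   # exactly -1 is NOT abnormal

  atMinus2 <- zscorePanel(c(vc = 0.03, lf = 300), norms)
  expect_true(all(atMinus2$abnormal))
  # reductions only: high values are never abnormal
  high <- zscorePanel(c(vc = 0.10, lf = 900), norms)
  expect_false(any(high$abnormal))
})

test_that("control cohort self-z has mean 0 and sd 1 per metric", {
  set.seed(9)
  ctrl <- cbind(vc = rnorm(25, 0.05, 0.01), lf = rnorm(25, 500, 120))
  norms <- controlNorms(ctrl)
  panel <- zscorePanel(ctrl, norms)
  for (m in c("vc", "lf")) {
    z <- panel$z[panel$metric == m]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  expect_error(controlNorms(ctrl[1, , drop = FALSE]), "2 control")
})
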