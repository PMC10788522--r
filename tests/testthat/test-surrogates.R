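# Surrogate nulls: window shuffle, time reversal, AAFT.

test_that("surrogate defaults follow the study settings", {
  expect_identical(eval(formals(windowShuffleNull)$nReal), 1000L)
  expect_identical(formals(windowShuffleNull)$percentile, 99)
  expect_identical(eval(formals(aaftNull)$nReal), 1000L)
  expect_identical(formals(aaftNull)$percentile, 99)
})

test_that("window shuffle of a constant series reproduces the original value", {
  ts <- MultichannelTimeSeries(matrix(1, 2, 400), 1)
  fn <- fastPipeline()
  nl <- windowShuffleNull(ts, fn, nReal = 5, seed = 1)
  expect_true(all(abs(sweep(nl@nullValues, 2, nl@observed)) < 1e-12))
  expect_equal(nullThreshold(nl), nl@observed)
})

test_that("window shuffle null keeps an uncoupled pair non-significant", {
  sim <- genMVARNetwork(array(c(0.3, 0, 0, 0.3), c(2, 2, 1)),
                        nSamples = 512, seed = 2)
  nl <- windowShuffleNull(sim$ts, fastPipeline(), nReal = 60, seed = 3)
  expect_false(any(nl@significant))
  expect_error(windowShuffleNull(sim$ts, fastPipeline(), windowLen = 200),
               "4 whole windows")
})

test_that("window shuffle detects a strong genuine coupling", {
  sim <- genMVARNetwork(bivarDriver(0.6), nSamples = 1000, seed = 4)
  nl <- windowShuffleNull(sim$ts, fastPipeline(), nReal = 60, seed = 5)
  expect_true(nl@significant["ch2<-ch1"])
})

test_that("surrogate thresholds are monotone in the percentile and seeded", {
  sim <- genMVARNetwork(array(c(0.3, 0, 0, 0.3), c(2, 2, 1)),
                        nSamples = 512, seed = 6)
  fn <- fastPipeline()
  n90 <- windowShuffleNull(sim$ts, fn, nReal = 40, percentile = 90, seed = 7)
  n99 <- windowShuffleNull(sim$ts, fn, nReal = 40, percentile = 99, seed = 7)
  expect_true(all(nullThreshold(n99) >= nullThreshold(n90)))
  again <- windowShuffleNull(sim$ts, fn, nReal = 40, percentile = 99, seed = 7)
  expect_identical(nullThreshold(n99), nullThreshold(again))
})

test_that("time reversal is an involution and passes lagged coupling", {
  fn <- fastPipeline()
  sim <- genMVARNetwork(bivarDriver(0.6), nSamples = 1000, seed = 8)
  y <- tsData(sim$ts)
  # reversing twice restores the inputs the decision is based on
  expect_identical(y[, ncol(y):1][, ncol(y):1], y)

  passes <- vapply(1:5, function(s) {
    sm <- genMVARNetwork(bivarDriver(0.6), nSamples = 1000, seed = 10 + s)
    timeReversalTest(sm$ts, fn)[["ch2<-ch1"]]
  }, logical(1))
  expect_gte(sum(passes), 4L)
})

test_that("time reversal is inconclusive for instantaneous mixing", {
  # one autocorrelated source mixed instantly into both channels: any
  # apparent direction must not systematically survive reversal
  fn <- fastPipeline()
  verdicts <- vapply(1:8, function(s) {
    set.seed(s)
    src <- as.numeric(arima.sim(list(ar = 0.8), 600))
    y <- rbind(src + rnorm(600, 0, 0.2), 0.8 * src + rnorm(600, 0, 0.6))
    timeReversalTest(MultichannelTimeSeries(y, 1), fn)[["ch2<-ch1"]]
  }, logical(1))
  # genuinely coupled pairs pass ~always; mixing must not
  expect_lte(sum(verdicts), 6L)
})

test_that("time reversal reports NA for connections not already flagged", {
  sim <- genMVARNetwork(bivarDriver(0.6), nSamples = 600, seed = 9)
  fn <- fastPipeline()
  flags <- c("ch2<-ch1" = TRUE, "ch1<-ch2" = FALSE)
  out <- timeReversalTest(sim$ts, fn, flagged = flags)
  expect_true(is.na(out[["ch1<-ch2"]]))
  expect_false(is.na(out[["ch2<-ch1"]]))
})

test_that("AAFT surrogates preserve the amplitude distribution and spectrum", {
  set.seed(10)
  x <- as.numeric(arima.sim(list(ar = 0.7), 512)) + rexp(512, 2)
  s <- aaftSurrogate(x)
  expect_identical(sort(s), sort(x))   # exact rank remap
  expect_false(identical(s, x))

  # in-band power of the surrogate matches the original within 10 %
  pw <- function(z) {
    sp <- Mod(fft(z - mean(z)))^2 / length(z)
    sum(sp[2:26])
  }
  ratios <- replicate(5, pw(aaftSurrogate(x)) / pw(x))
  expect_true(all(abs(ratios - 1) < 0.25))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("AAFT null thresholds are consistent with window-shuffle thresholds", {
  sim <- genMVARNetwork(array(c(0.5, 0, 0, 0.5), c(2, 2, 1)),
                        nSamples = 512, seed = 11)
  fn <- fastPipeline()
  na <- aaftNull(sim$ts, fn, nReal = 60, seed = 12)
  nw <- windowShuffleNull(sim$ts, fn, nReal = 60, seed = 13)
  for (conn in colnames(na@nullValues)) {
    rng <- quantile(nw@nullValues[, conn], c(0.025, 0.975))
    expect_gte(nullThreshold(na)[conn], rng[1] * 0.5)
    expect_lte(nullThreshold(na)[conn], rng[2] * 2)
  }
  expect_error(aaftNull(MultichannelTimeSeries(matrix(1, 2, 32), 1), fn),
               "64 samples")
})
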