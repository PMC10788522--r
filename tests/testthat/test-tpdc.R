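# TPDC: filtering, signal extraction, order selection, DEKF estimation,
# PDC computation and averaging.

test_that("bandpass filter passes in-band and rejects out-of-band sinusoids", {
  fs <- 2; n <- 4000
  t <- seq_len(n) / fs
  inband <- sin(2 * pi * 0.05 * t)
  outband <- sin(2 * pi * 0.3 * t)
  ts <- MultichannelTimeSeries(rbind(inband, outband, 0), fs)
  f <- bandpassFilter(ts, 0.01, 0.1)
  mid <- 1000:3000  # avoid the filter's edge transients
  ampIn <- max(abs(tsData(f)[1, mid]))
  ampOut <- max(abs(tsData(f)[2, mid]))
  expect_gt(ampIn, 0.95)
  expect_lt(ampOut, 0.1)
  expect_true(all(tsData(f)[3, ] == 0))
  expect_error(bandpassFilter(ts, 0.5, 1.5), "Nyquist")
})

test_that("seed/network extraction pools active voxels and names channels", {
  d <- c(4L, 4L, 4L); nT <- 30L
  set.seed(1)
  vol <- array(rnorm(prod(d) * nT), c(d, nT))
  atlas <- genAtlas(d, 7L)

  pat1 <- array(0, d); pat1[2, 3, 1] <- 1
  ts1 <- extractSeedNetworks(vol, LesionMap(pat1, 1), atlas)
  expect_equal(tsData(ts1)["Seed", ], vol[2, 3, 1, ])
  expect_identical(channelNames(ts1), c("Seed", sevenNetworks()))

  # two antisymmetric voxels cancel
  vol2 <- vol
  vol2[1, 1, 1, ] <- 5 * sin(seq_len(nT))
  vol2[2, 1, 1, ] <- -vol2[1, 1, 1, ]
  pat2 <- array(0, d); pat2[1:2, 1, 1] <- 1
  ts2 <- extractSeedNetworks(vol2, LesionMap(pat2, 1), atlas)
  expect_equal(max(abs(tsData(ts2)["Seed", ])), 0)

  # a spatially uniform volume makes all 8 channels identical
  u <- array(rep(sin(seq_len(nT)), each = prod(d)), c(d, nT))
  ts3 <- extractSeedNetworks(u, LesionMap(pat1, 1), atlas)
  expect_lt(max(abs(sweep(tsData(ts3), 2, tsData(ts3)[1, ]))), 1e-12)

  expect_error(extractSeedNetworks(vol, LesionMap(array(0, d), 1), atlas),
               "empty seed")
})

test_that("AIC order selection finds the generating order", {
  hits <- 0L
  for (s in 1:10) {
    sim <- genMVARNetwork(bivarVAR2(), nSamples = 2000, seed = s)
    sel <- selectOrder(sim$ts, candidates = 1:6)
    if (sel$order %in% c(2L, 3L)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)

  ones <- 0L
  for (s in 1:10) {
    wn <- genMVARNetwork(array(0, c(2, 2, 1)), nSamples = 2000, seed = 100 + s)
    if (selectOrder(wn$ts, candidates = 1:5)$order == 1L) ones <- ones + 1L
  }
  expect_gte(ones, 6L)

  expect_error(selectOrder(sim$ts, candidates = c(1, 25)), "1..20")
})

test_that("DEKF recovers constant coefficients and agrees with least squares", {
  A <- bivarVAR2()
  for (s in 1:3) {
    sim <- genMVARNetwork(A, nSamples = 2000, seed = s)
    fit <- fitDEKF(sim$ts, order = 2)
    mc <- meanCoeffs(fit)
    expect_lt(sqrt(mean((mc - A)^2)), 0.1)
    expect_lt(sqrt(mean((mc - oracleVAR(tsData(sim$ts), 2))^2)), 0.05)
  }
})

test_that("DEKF off-diagonal estimates stay near zero for uncoupled noise", {
  # the random-walk tracker wanders pointwise (excursions scale with the
  # process-noise variance), so the null property is checked on the
  # time-averaged coefficients and on the typical excursion size
  for (s in 4:6) {
    sim <- genMVARNetwork(array(0, c(2, 2, 1)), nSamples = 2000, seed = s)
    fit <- fitDEKF(sim$ts, order = 1)
    traj <- rbind(coeffArray(fit)[1, 2, 1, ], coeffArray(fit)[2, 1, 1, ])
    expect_lt(max(abs(rowMeans(traj))), 0.1)
    expect_lt(quantile(abs(traj), 0.9), 0.2)
  }
})

test_that("DEKF tracks a scheduled coefficient switch near the midpoint", {
  A0 <- array(0, c(2, 2, 1)); diag(A0[, , 1]) <- 0.2
  A1 <- A0; A1[2, 1, 1] <- 0.5
  n <- 3000
  sim <- genMVARNetwork(list(A0, A1), nSamples = n,
                        schedule = c(1L, as.integer(n / 2) + 1L), seed = 5)
  fit <- fitDEKF(sim$ts, order = 1)
  traj <- coeffArray(fit)[2, 1, 1, ]
  crossing <- fit@times[which(traj > 0.25)[1]]  # crosses the halfway value
  expect_lt(abs(crossing - n / 2), 0.15 * n)
})

test_that("PDC of the zero model is the identity at every frequency", {
  co <- array(0, c(3, 3, 2, 4))
  model <- new("TVMVARModel", order = 2L, coeffs = co,
               innovationCov = diag(3), times = 1:4,
               channelNames = paste0("ch", 1:3))
  pdc <- pdcFromModel(model, freqGrid = c(0.05, 0.2, 0.4))
  v <- pdcValues(pdc)
  for (tt in 1:4) for (ff in 1:3) {
    expect_equal(v[tt, ff, , ], diag(3))
  }
})

test_that("PDC matches the brute-force complex-arithmetic oracle", {
  A <- bivarDriver(0.5)
  co <- array(A, c(2, 2, 1, 5))  # constant over 5 time points
  model <- new("TVMVARModel", order = 1L, coeffs = co,
               innovationCov = diag(2), times = 1:5,
               channelNames = c("a", "b"))
  freqs <- seq(0.02, 0.45, length.out = 10)
  pdc <- pdcFromModel(model, freqGrid = freqs, sampleRateHz = 1)
  v <- pdcValues(pdc)
  for (ff in seq_along(freqs)) {
    expect_equal(v[3, ff, , ], oraclePDC(A, freqs[ff]), tolerance = 1e-12)
  }
  # no reverse-direction influence for unidirectional coupling
  expect_true(all(v[, , 1, 2] < 1e-20))
  expect_true(all(v[, , 2, 1] > 0))
})

test_that("PDC columns are normalized and bounded", {
  sim <- genMVARNetwork(bivarVAR2(), nSamples = 800, seed = 6)
  fit <- fitDEKF(sim$ts, order = 2)
  pdc <- pdcFromModel(fit, timeStride = 5)
  v <- pdcValues(pdc)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
  sums <- apply(v, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("band/time averaging distinguishes in-band from whole-grid means", {
  freqs <- seq(0.01, 0.45, length.out = 20)
  vals <- array(0, c(3, 20, 2, 2))
  vals[, freqs <= 0.08, 1, 1] <- 1   # in-band signal only
  pdc <- new("PDCTensor", values = vals, freqGrid = freqs, times = 1:3,
             channelNames = c("x", "y"))
  inband <- bandTimeAverage(pdc, c(0.009, 0.08))
  expect_equal(inband["x", "x"], 1)
  whole <- bandTimeAverage(pdc, c(0.009, 0.45))
  expect_lt(whole["x", "x"], 1)

  const <- new("PDCTensor", values = array(0.25, c(3, 20, 2, 2)),
               freqGrid = freqs, times = 1:3, channelNames = c("x", "y"))
  expect_true(all(bandTimeAverage(const, c(0.009, 0.08)) == 0.25))
  expect_error(bandTimeAverage(const, c(0.6, 0.8)), "intersect")
})

test_that("connectivity profile ranks the truly coupled network first", {
  nets <- sevenNetworks()
  A <- array(0, c(8, 8, 1)); diag(A[, , 1]) <- 0.3
  A[6, 1, 1] <- 0.6   # seed drives network 5 (Control)
  sim <- genMVARNetwork(A, nSamples = 1200, seed = 7,
                        channelNames = c("Seed", nets))
  prof <- connectivityProfile(sim$ts, order = 2, nFreq = 32, timeStride = 4)
  fwd <- forwardValues(prof)
  expect_identical(names(which.max(fwd)), "Control")
  expect_identical(names(fwd), nets)
  expect_identical(prof@threshold, 0.1)
  expect_true(all(fwd >= 0 & fwd <= 1))
  expect_error(connectivityProfile(
    MultichannelTimeSeries(matrix(rnorm(300), 3), 1)), "8 channels")
})

test_that("PDC is invariant to a common rescaling of all channels", {
  sim <- genMVARNetwork(bivarVAR2(), nSamples = 1500, seed = 8)
  fn <- fastPipeline(order = 2L)
  a <- fn(tsData(sim$ts))
  b <- fn(tsData(sim$ts) * 7.3)
  expect_lt(max(abs(a - b)), 0.02)
})
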