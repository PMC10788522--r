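#' @include AllClasses.R
#' @useDynLib BrainHeart, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Time-resolved partial directed coherence: band-pass filtering, seed and
## network signal extraction, MVAR order selection, the dual extended Kalman
## filter, PDC computation and band/time averaging.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase) per channel.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param lo,hi band edges in Hz; must satisfy `0 < lo < hi < sampleRate/2`.
#' @param orderFilt Butterworth order (default 4).
#' @return A filtered [MultichannelTimeSeries-class].
#' @export
bandpassFilter <- function(ts, lo, hi, orderFilt = 4) {
  fs <- sampleRate(ts)
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("band must satisfy 0 < lo < hi < Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(orderFilt, c(lo, hi) / (fs / 2), type = "pass")
  d <- ts@data
  out <- t(apply(d, 1, function(x) signal::filtfilt(bf, x)))
  MultichannelTimeSeries(out, fs, channelNames(ts))
}

#' Extract the pooled seed and the seven network signals
#'
#' Channel 1 is the unweighted mean over the active (nonzero) voxels of the
#' lesion pattern; channels 2-8 are the means over each network's voxels in
#' the parcellation.
#'
#' @param vol4d 4-D array `[x, y, z, time]` of volume time series.
#' @param lesionPattern a [LesionMap-class]; nonzero voxels are "active".
#' @param parcellation an [AtlasLabels-class] with seven labels.
#' @param sampleRateHz sampling rate of the volumes (default 1, a TR of 1 s).
#' @return A [MultichannelTimeSeries-class] with 8 channels
#'   (`Seed` + the seven networks).
#' @export
extractSeedNetworks <- function(vol4d, lesionPattern, parcellation,
                                sampleRateHz = 1) {
  d <- dim(vol4d)
  if (length(d) != 4L) stop("vol4d must be a 4-D array [x, y, z, time]")
  if (!all(d[1:3] == dim(mapValues(lesionPattern))) ||
      !all(d[1:3] == dim(mapValues(parcellation))))
    stop("grids of volume, lesion pattern and parcellation must align")
  nms <- roiNames(parcellation)
  if (length(nms) != 7L) stop("parcellation must have exactly 7 labels")
  nT <- d[4]
  flat <- matrix(vol4d, prod(d[1:3]), nT)
  act <- which(mapValues(lesionPattern) != 0)
  if (!length(act)) stop("empty seed: lesion pattern has no active voxels")
  seed <- colMeans(flat[act, , drop = FALSE])
  lab <- as.integer(mapValues(parcellation))
  nets <- t(vapply(seq_along(nms), function(k) {
    vox <- which(lab == as.integer(names(nms)[k]))
    if (!length(vox)) rep(0, nT) else colMeans(flat[vox, , drop = FALSE])
  }, numeric(nT)))
  MultichannelTimeSeries(rbind(seed, nets), sampleRateHz,
                         c("Seed", as.character(nms)))
}

#' Least-squares (stationary) VAR fit
#'
#' Ordinary least squares fit of a stationary MVAR model; used for order
#' selection and available as a reference for the Kalman-filter estimates.
#'
#' @param ts a [MultichannelTimeSeries-class] or channels x samples matrix.
#' @param order lag count.
#' @return list with `coeffs` (`[c, c, lag]` array), `residCov` (channels x
#'   channels), `nEff` (effective sample count).
#' @export
lsVAR <- function(ts, order) {
  y <- if (is(ts, "MultichannelTimeSeries")) ts@data else as.matrix(ts)
  cdim <- nrow(y); n <- ncol(y)
  if (n <= order * cdim + 1) stop("insufficient samples for order ", order)
  idx <- (order + 1):n
  X <- do.call(cbind, lapply(seq_len(order), function(r) t(y[, idx - r, drop = FALSE])))
  Y <- t(y[, idx, drop = FALSE])
  fit <- stats::lm.fit(X, Y)
  Bt <- fit$coefficients                 # (c*order) x c
  res <- Y - X %*% Bt
  coeffs <- array(0, c(cdim, cdim, order))
  for (r in seq_len(order))
    coeffs[, , r] <- t(Bt[((r - 1) * cdim + 1):(r * cdim), , drop = FALSE])
  list(coeffs = coeffs,
       residCov = crossprod(res) / length(idx),
       nEff = length(idx))
}

#' Select the MVAR model order by AIC
#'
#' Fits a stationary VAR per candidate order and returns the AIC minimizer,
#' with `AIC(p) = n_eff log det(Sigma_res) + 2 p c^2`. The pipeline default
#' order is 5; this check guards against over-parameterization.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param candidates integer candidate orders within 1..20.
#' @return list with `order` (the argmin), `aic` (named numeric per
#'   candidate).
#' @export
selectOrder <- function(ts, candidates = 1:10) {
  if (any(candidates < 1 | candidates > 20))
    stop("candidate orders must lie in 1..20")
  cdim <- nrow(ts@data); n <- ncol(ts@data)
  ok <- candidates[n > candidates * cdim * 2 + cdim]
  if (!length(ok)) stop("insufficient samples for any candidate order")
  if (length(ok) < length(candidates))
    warning("candidate set truncated to ", max(ok), " by sample count")
  aic <- vapply(ok, function(p) {
    f <- lsVAR(ts, p)
    f$nEff * log(det(f$residCov)) + 2 * p * cdim^2
  }, numeric(1))
  names(aic) <- ok
  list(order = ok[which.min(aic)], aic = aic)
}

#' Fit a time-varying MVAR model with the dual extended Kalman filter
#'
#' Two coupled Kalman recursions run over the samples: one tracks the signal
#' state (companion form) under the current coefficient estimates; the other
#' treats the stacked MVAR coefficients as a random-walk state and updates
#' them from the first filter's innovation, feeding the result back. The
#' first `burnInFrac` of the coefficient trajectory is discarded.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param order model order (pipeline default 5).
#' @param qParam parameter random-walk variance (default 1e-4).
#' @param p0Param initial parameter covariance scale (default 0.5).
#' @param obsNoiseFrac state-filter observation-noise variance as a fraction
#'   of channel variance (default 0.01).
#' @param burnInFrac fraction of the trajectory discarded (default 0.1).
#' @return A [TVMVARModel-class].
#' @examples
#' A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
#' sim <- genMVARNetwork(A, nSamples = 500, seed = 1)
#' fit <- fitDEKF(sim$ts, order = 1)
#' meanCoeffs(fit)[2, 1, 1]  # close to 0.5
#' @export
fitDEKF <- function(ts, order = 5L, qParam = 1e-4, p0Param = 0.5,
                    obsNoiseFrac = 0.01, burnInFrac = 0.1) {
  y <- ts@data
  cdim <- nrow(y); n <- ncol(y)
  if (cdim < 2) stop("need at least 2 channels")
  if (n <= 10 * order * cdim)
    warning("fewer than 10 * order * channels samples; estimates may be noisy")
  res <- .dekfFitCpp(y, as.integer(order), qParam, p0Param, obsNoiseFrac)
  keep <- (order + 1):n
  burn <- floor(length(keep) * burnInFrac)
  keep <- keep[(burn + 1):length(keep)]
  co <- res$coeffs[, keep, drop = FALSE]          # (c*c*order) x T
  coeffs <- array(co, c(cdim, cdim * order, length(keep)))
  out <- array(0, c(cdim, cdim, order, length(keep)))
  for (r in seq_len(order))
    out[, , r, ] <- coeffs[, ((r - 1) * cdim + 1):(r * cdim), , drop = FALSE]
  innov <- res$resid[, keep, drop = FALSE]
  new("TVMVARModel", order = as.integer(order), coeffs = out,
      innovationCov = tcrossprod(innov) / ncol(innov),
      times = as.integer(keep), channelNames = channelNames(ts))
}

#' Squared, normalized partial directed coherence from MVAR coefficients
#'
#' For each retained time point t and frequency f,
#' `Abar(f, t) = I - sum_r A_r(t) exp(-i 2 pi f r)` (f in cycles/sample);
#' the squared PDC from source j to target i is
#' `|Abar_ij|^2 / sum_k |Abar_kj|^2` (column normalization over targets), so
#' every value lies in [0, 1] and, for each (time, frequency, source), the
#' values sum to 1 over targets.
#'
#' @param model a [TVMVARModel-class].
#' @param freqGrid frequencies in Hz; default 64 points evenly spaced in
#'   (0, sampleRate/2).
#' @param sampleRateHz sampling rate used to map Hz to cycles/sample
#'   (default 1).
#' @param timeStride evaluate every `timeStride`-th time point (default 1).
#' @return A [PDCTensor-class].
#' @export
pdcFromModel <- function(model, freqGrid = NULL, sampleRateHz = 1,
                         timeStride = 1L) {
  A <- coeffArray(model)
  cdim <- dim(A)[1]; p <- dim(A)[3]
  tIdx <- seq(1, dim(A)[4], by = timeStride)
  nT <- length(tIdx)
  if (is.null(freqGrid))
    freqGrid <- seq(0, sampleRateHz / 2, length.out = 66)[2:65]
  fNorm <- freqGrid / sampleRateHz
  if (any(fNorm < 0 | fNorm >= 0.5))
    stop("frequencies must map to [0, 0.5) cycles/sample")
  nF <- length(freqGrid)

  # A as [c*c, p, T'] for vectorized lag sums
  Am <- array(A[, , , tIdx, drop = FALSE], c(cdim * cdim, p, nT))
  vals <- array(0, c(nT, nF, cdim, cdim))
  eye <- as.numeric(diag(cdim))
  for (fi in seq_len(nF)) {
    wts <- exp(-2i * pi * fNorm[fi] * seq_len(p))
    acc <- matrix(0 + 0i, cdim * cdim, nT)
    for (r in seq_len(p)) acc <- acc + wts[r] * Am[, r, ]
    Abar2 <- Mod(eye - acc)^2                       # [c*c, T']
    dim(Abar2) <- c(cdim, cdim, nT)
    colnorm <- apply(Abar2, c(2, 3), sum)           # [source j, T']
    colnorm[colnorm == 0] <- NA
    pdc <- sweep(Abar2, c(2, 3), colnorm, "/")
    if (anyNA(pdc)) {
      warning("zero column norm encountered; PDC set to 0")
      pdc[is.na(pdc)] <- 0
    }
    vals[, fi, , ] <- aperm(pdc, c(3, 1, 2))
  }
  new("PDCTensor", values = vals, freqGrid = freqGrid,
      times = model@times[tIdx], channelNames = channelNames(model))
}

#' Band- and time-averaged PDC matrix
#'
#' Mean over the in-band frequencies, then mean over time. The default band
#' is the low-frequency BOLD range 0.009-0.08 Hz.
#'
#' @param pdc a [PDCTensor-class].
#' @param band numeric `[lo, hi]` in Hz (default `c(0.009, 0.08)`).
#' @return target x source matrix of band/time-averaged squared PDC.
#' @export
bandTimeAverage <- function(pdc, band = c(0.009, 0.08)) {
  sel <- which(freqGrid(pdc) >= band[1] & freqGrid(pdc) <= band[2])
  if (!length(sel)) stop("band does not intersect the frequency grid")
  v <- pdcValues(pdc)[, sel, , , drop = FALSE]
  out <- apply(v, c(3, 4), mean)
  dimnames(out) <- list(target = channelNames(pdc), source = channelNames(pdc))
  out
}

#' Build the TPDC pipeline closure
#'
#' Returns a function mapping a channels x samples matrix to the band- and
#' time-averaged PDC matrix (target x source) by running [fitDEKF()],
#' [pdcFromModel()] and [bandTimeAverage()]. Surrogate tests re-evaluate
#' this closure on resampled data.
#'
#' @param order MVAR order (default 5).
#' @param band frequency band in Hz (default `c(0.009, 0.08)`).
#' @param sampleRateHz sampling rate (default 1).
#' @param nFreq frequency grid resolution (default 64).
#' @param timeStride PDC time thinning (default 1).
#' @param ... further arguments to [fitDEKF()].
#' @return function(matrix) -> target x source matrix.
#' @export
makeTPDCPipeline <- function(order = 5L, band = c(0.009, 0.08),
                             sampleRateHz = 1, nFreq = 64L, timeStride = 1L,
                             ...) {
  grid <- seq(0, sampleRateHz / 2, length.out = nFreq + 2)[seq_len(nFreq) + 1]
  grid <- grid[grid >= band[1] & grid <= band[2]]
  if (!length(grid)) stop("band does not intersect the frequency grid")
  force(order)
  function(mat) {
    ts <- MultichannelTimeSeries(mat, sampleRateHz)
    model <- fitDEKF(ts, order = order, ...)
    pdc <- pdcFromModel(model, freqGrid = grid, sampleRateHz = sampleRateHz,
                        timeStride = timeStride)
    bandTimeAverage(pdc, band)
  }
}

#' Seed-to-network connectivity profile
#'
#' Runs the full TPDC chain on an 8-channel series (seed + seven networks)
#' and reports the forward (seed -> network) and backward (network -> seed)
#' band/time-averaged squared PDC values. Values at or below `threshold`
#' (default 0.1) are flagged non-significant pending the surrogate tests.
#'
#' @param ts a [MultichannelTimeSeries-class] with 8 channels, channel 1 the
#'   seed.
#' @param order MVAR order (default 5).
#' @param band frequency band in Hz (default `c(0.009, 0.08)`).
#' @param threshold significance floor (default 0.1).
#' @param subjectId label carried in the output.
#' @param ... further arguments to [fitDEKF()] / [pdcFromModel()] via
#'   [makeTPDCPipeline()].
#' @return A [ConnectivityProfile-class].
#' @export
connectivityProfile <- function(ts, order = 5L, band = c(0.009, 0.08),
                                threshold = 0.1, subjectId = "subject",
                                ...) {
  if (nrow(ts@data) != 8L)
    stop("expected 8 channels: seed + 7 networks")
  fn <- makeTPDCPipeline(order = order, band = band,
                         sampleRateHz = sampleRate(ts), ...)
  m <- fn(ts@data)
  nets <- channelNames(ts)[-1]
  fwd <- m[-1, 1]; names(fwd) <- nets      # target = network, source = seed
  bwd <- m[1, -1]; names(bwd) <- nets      # target = seed, source = network
  new("ConnectivityProfile", forward = fwd, backward = bwd,
      band = band, threshold = threshold,
      significantForward = fwd > threshold,
      significantBackward = bwd > threshold,
      subjectId = subjectId)
}
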