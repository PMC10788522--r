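#' @include AllClasses.R
NULL

## Surrogate-data significance testing for TPDC values: window-shuffle
## bootstrap nulls, the time-reversal second test, and AAFT surrogates.

connectionNames <- function(ch) {
  nms <- outer(ch, ch, function(t, s) paste0(t, "<-", s))
  as.character(nms[row(nms) != col(nms)])
}

flattenConnections <- function(m) {
  ch <- rownames(m)
  if (is.null(ch)) ch <- paste0("ch", seq_len(nrow(m)))
  v <- m[row(m) != col(m)]
  names(v) <- connectionNames(ch)
  v
}

#' Window-shuffle bootstrap null for TPDC values
#'
#' Divides each series into non-overlapping windows and permutes the window
#' order to create surrogates; the TPDC pipeline is evaluated per
#' realization and the per-connection significance threshold is the stated
#' percentile (default 99) of the `nReal` (default 1000) surrogate values.
#' By default every channel gets its own independent window permutation,
#' which destroys the cross-lag coupling (a joint shuffle applied to all
#' channels at once would preserve cross-correlation and is not a null for
#' coupling); pass `channels` to shuffle only a putative source channel.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param pipelineFn function(matrix) -> target x source matrix, typically
#'   from [makeTPDCPipeline()].
#' @param windowLen window length in samples (default 10 x `order`).
#' @param nReal surrogate count (default 1000).
#' @param percentile threshold percentile (default 99).
#' @param channels channel indices to shuffle (default all).
#' @param order used only for the default window length (default 5).
#' @param seed RNG seed.
#' @return A [SurrogateNull-class].
#' @export
windowShuffleNull <- function(ts, pipelineFn, windowLen = NULL,
                              nReal = 1000L, percentile = 99,
                              channels = NULL, order = 5L, seed = 1L) {
  y <- tsData(ts)
  n <- ncol(y)
  if (is.null(windowLen)) windowLen <- 10L * order
  if (windowLen < order + 1) stop("windowLen must exceed the model order")
  nW <- n %/% windowLen
  if (nW < 4L) stop("need at least 4 whole windows (have ", nW, ")")
  if (is.null(channels)) channels <- seq_len(nrow(y))
  used <- nW * windowLen
  obs <- flattenConnections(pipelineFn(y))

  set.seed(seed)
  nullVals <- matrix(NA_real_, nReal, length(obs),
                     dimnames = list(NULL, names(obs)))
  for (b in seq_len(nReal)) {
    ys <- y
    for (chn in channels) {
      perm <- sample.int(nW)
      src <- as.vector(outer(seq_len(windowLen), (perm - 1L) * windowLen, "+"))
      ys[chn, seq_len(used)] <- y[chn, src]
    }
    nullVals[b, ] <- flattenConnections(pipelineFn(ys))
  }
  thr <- apply(nullVals, 2, quantile, probs = percentile / 100, names = FALSE)
  new("SurrogateNull", method = "window-shuffle",
      nRealizations = as.integer(nReal), nullValues = nullVals,
      threshold = thr, percentile = percentile, observed = obs,
      significant = obs > thr)
}

#' Time-reversal second significance test
#'
#' Re-runs the TPDC pipeline on the time-reversed series. A connection
#' passes when its original-data value exceeds its reversed-data value:
#' genuinely lagged directed coupling flips under time reversal, whereas
#' instantaneous (mixing) effects do not. Applied to connections already
#' flagged by a surrogate null when `flagged` is given.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param pipelineFn function(matrix) -> target x source matrix.
#' @param flagged optional named logical (from a [SurrogateNull-class]);
#'   connections not flagged are reported `NA`.
#' @return named logical per connection.
#' @export
timeReversalTest <- function(ts, pipelineFn, flagged = NULL) {
  y <- tsData(ts)
  fwd <- flattenConnections(pipelineFn(y))
  rev <- flattenConnections(pipelineFn(y[, ncol(y):1, drop = FALSE]))
  pass <- fwd > rev[names(fwd)]
  if (!is.null(flagged)) pass[!flagged[names(pass)]] <- NA
  pass
}

#' One AAFT surrogate of a single series
#'
#' Amplitude-adjusted Fourier transform: rank-remap the series to a Gaussian,
#' randomize the phases of its spectrum, then rank-remap back onto the
#' original amplitude distribution. The surrogate has exactly the original's
#' sorted values and approximately its power spectrum.
#'
#' @param x numeric series.
#' @return numeric surrogate of the same length.
#' @export
aaftSurrogate <- function(x) {
  n <- length(x)
  g <- sort(rnorm(n))[rank(x, ties.method = "first")]   # gaussianize
  # phase randomization preserving conjugate symmetry
  ph <- runif(n, 0, 2 * pi)
  G <- fft(g)
  half <- seq(2, ceiling(n / 2))
  rot <- rep(0, n)
  rot[half] <- ph[half]
  rot[n + 2 - half] <- -ph[half]
  gs <- Re(fft(G * exp(1i * rot), inverse = TRUE)) / n
  sort(x)[rank(gs, ties.method = "first")]              # restore amplitudes
}

#' AAFT surrogate null for TPDC values
#'
#' Applies [aaftSurrogate()] independently per channel, evaluates the TPDC
#' pipeline per realization, and thresholds at the stated percentile
#' (default 99 over 1000 realizations).
#'
#' @inheritParams windowShuffleNull
#' @return A [SurrogateNull-class].
#' @export
aaftNull <- function(ts, pipelineFn, nReal = 1000L, percentile = 99,
                     seed = 1L) {
  y <- tsData(ts)
  if (ncol(y) < 64) stop("need at least 64 samples for AAFT surrogates")
  obs <- flattenConnections(pipelineFn(y))
  set.seed(seed)
  nullVals <- matrix(NA_real_, nReal, length(obs),
                     dimnames = list(NULL, names(obs)))
  for (b in seq_len(nReal)) {
    ys <- t(apply(y, 1, aaftSurrogate))
    rownames(ys) <- rownames(y)
    nullVals[b, ] <- flattenConnections(pipelineFn(ys))
  }
  thr <- apply(nullVals, 2, quantile, probs = percentile / 100, names = FALSE)
  new("SurrogateNull", method = "aaft", nRealizations = as.integer(nReal),
      nullValues = nullVals, threshold = thr, percentile = percentile,
      observed = obs, significant = obs > thr)
}
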