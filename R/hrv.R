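#' @include AllClasses.R
NULL

## Heart rate variability: ectopic-beat cleanup, time-domain metrics (VC,
## RMSSD), FFT-based spectral band powers (LF, HF) and cohort-referenced
## z-scoring with the strict z < -1 abnormality rule.

#' Clean ectopic beats from an R-R series
#'
#' Flags intervals deviating more than `relTol` (default 30 %) from the
#' running median of their 5-interval neighbourhood and replaces them by
#' linear interpolation between the nearest unflagged intervals. If more than
#' 20 % of intervals are replaced, the series is marked `quality = "suspect"`
#' and a warning is issued (the cleaned series is still returned).
#'
#' @param rr an [RRISeries-class].
#' @param relTol relative deviation tolerance (default 0.30).
#' @return A cleaned [RRISeries-class] with `cleanedFlags` set; the number of
#'   replacements is available as `sum(x@cleanedFlags)`.
#' @examples
#' iv <- rep(800, 20); iv[10] <- 1600
#' cleaned <- cleanRR(RRISeries(iv))
#' sum(cleaned@cleanedFlags)  # 1
#' @export
cleanRR <- function(rr, relTol = 0.30) {
  iv <- intervals(rr)
  n <- length(iv)
  if (n < 3L) stop("need at least 3 intervals to clean an R-R series")
  # running median over a centred window of 5 intervals (shrunk at edges)
  med <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - 2L):min(n, i + 2L)
    median(iv[w])
  }, numeric(1))
  flags <- abs(iv - med) / med > relTol
  out <- iv
  if (any(flags)) {
    idx <- seq_len(n)
    good <- idx[!flags]
    if (length(good) >= 2L) {
      out[flags] <- approx(good, iv[good], xout = idx[flags], rule = 2)$y
    } else {
      out[flags] <- med[flags]
    }
  }
  quality <- "ok"
  if (mean(flags) > 0.20) {
    warning(sprintf("cleaned %.0f%% of intervals (>20%%); flagging series quality",
                    100 * mean(flags)))
    quality <- "suspect"
  }
  res <- RRISeries(out, cleanedFlags = flags)
  res@quality <- quality
  res
}

#' Time-domain HRV metrics: VC and RMSSD
#'
#' VC (coefficient of variation) is the sample (n-1) standard deviation of
#' the intervals divided by their mean; RMSSD is the root mean square of
#' successive interval differences.
#'
#' @param rr an [RRISeries-class] (>= 2 intervals).
#' @return named numeric: `vc` (dimensionless), `rmssd` (ms).
#' @examples
#' hrvTimeDomain(RRISeries(c(750, 800, 850)))  # vc 0.0625, rmssd 50
#' @export
hrvTimeDomain <- function(rr) {
  iv <- intervals(rr)
  if (length(iv) < 2L) stop("need at least 2 intervals for time-domain metrics")
  c(vc = sd(iv) / mean(iv),
    rmssd = sqrt(mean(diff(iv)^2)))
}

#' Power spectral density of the R-R tachogram
#'
#' The irregularly sampled tachogram (interval value at the time of its
#' closing beat) is interpolated to a uniform grid by cubic spline at
#' `resampleHz` (4 Hz, the common HRV convention), linearly detrended, Hann
#' windowed with power correction, and transformed to a one-sided power
#' spectral density in ms^2/Hz, so that the integral of the density recovers
#' the interval variance (Parseval).
#'
#' @param rr an [RRISeries-class]; duration must be >= 60 s.
#' @param resampleHz uniform resampling rate (default 4).
#' @return data.frame with columns `freq` (Hz) and `density` (ms^2/Hz).
#' @export
rrPSD <- function(rr, resampleHz = 4) {
  if (duration(rr) < 60) stop("recording too short: need >= 60 s for a PSD")
  tv <- beatTimes(rr)[-1]           # interval assigned to its closing beat
  iv <- intervals(rr)
  tg <- seq(tv[1], tv[length(tv)], by = 1 / resampleHz)
  x <- spline(tv, iv, xout = tg, method = "fmm")$y
  # linear detrend
  x <- stats::residuals(lm(x ~ tg))
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  xw <- x * w
  X <- fft(xw)
  # one-sided PSD with window power correction
  psd <- (Mod(X)^2) / (resampleHz * n * mean(w^2))
  half <- seq_len(floor(n / 2) + 1)
  psd <- psd[half]
  if (n %% 2 == 0) psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  else psd[2:length(psd)] <- 2 * psd[2:length(psd)]
  freq <- (half - 1) * resampleHz / n
  data.frame(freq = freq, density = psd)
}

#' Integrated band power of a spectrum
#'
#' Trapezoidal integral of the power spectral density over `[lo, hi)`,
#' treating the density as piecewise linear between grid points (so band
#' edges are interpolated and adjacent half-open bands never double-count a
#' bin). The LF band is `[0.04, 0.14)` Hz and the HF band `[0.15, 0.50)` Hz.
#'
#' @param spectrum data.frame with `freq` and `density` (from [rrPSD()]).
#' @param band numeric length-2 `[lo, hi)` in Hz.
#' @return power in ms^2.
#' @export
bandPower <- function(spectrum, band) {
  lo <- band[1]; hi <- band[2]
  if (!(lo < hi)) stop("empty band: need lo < hi")
  f <- spectrum$freq; d <- spectrum$density
  if (lo < min(f) - 1e-12 || hi > max(f) + 1e-12)
    stop("band outside spectrum range")
  inner <- f[f > lo & f < hi]
  grid <- unique(sort(c(lo, inner, hi)))
  dv <- approx(f, d, xout = grid)$y
  sum(diff(grid) * (head(dv, -1) + tail(dv, -1)) / 2)
}

#' The LF and HF band edges (Hz)
#' @return named list of length-2 numeric vectors `lf`, `hf`.
#' @export
hrvBands <- function() list(lf = c(0.04, 0.14), hf = c(0.15, 0.50))

#' All HRV metrics for one subject
#'
#' Convenience wrapper combining [hrvTimeDomain()] and spectral band powers.
#'
#' @param rr an [RRISeries-class].
#' @param resampleHz passed to [rrPSD()].
#' @return named numeric: `vc`, `rmssd` (ms), `lf` and `hf` powers (ms^2),
#'   `mean_rr` (ms), `n_beats`.
#' @export
hrvMetrics <- function(rr, resampleHz = 4) {
  td <- hrvTimeDomain(rr)
  sp <- rrPSD(rr, resampleHz)
  b <- hrvBands()
  c(td,
    lf = bandPower(sp, b$lf),
    hf = bandPower(sp, b$hf),
    mean_rr = mean(intervals(rr)),
    n_beats = nBeats(rr))
}

#' Control-cohort norms for z-scoring
#'
#' Per-metric mean and sample standard deviation of an (age-matched) healthy
#' control cohort.
#'
#' @param controlMetrics numeric matrix or data.frame, controls x metrics.
#' @return list with `mean`, `sd` (named numeric) and `nControls`.
#' @export
controlNorms <- function(controlMetrics) {
  m <- as.matrix(controlMetrics)
  if (nrow(m) < 2L) stop("need at least 2 control subjects")
  sds <- apply(m, 2, sd)
  if (any(sds <= 0)) stop("control sd must be > 0 for every metric")
  list(mean = colMeans(m), sd = sds, nControls = nrow(m))
}

#' Cohort-referenced z-scores with the strict reduction rule
#'
#' `z = (x - mean) / sd` per metric against the control norms; a metric is
#' "abnormal" if and only if `z < -1` strictly (one standard deviation below
#' the control mean). Only reductions count: there is no upper abnormality
#' bound for HRV.
#'
#' @param metrics named numeric (a subject's metrics) or a subjects x metrics
#'   matrix.
#' @param norms from [controlNorms()].
#' @return data.frame with columns `metric`, `z`, `abnormal` (one row per
#'   metric, or long over subjects for matrix input with a `subject` column).
#' @export
zscorePanel <- function(metrics, norms) {
  if (any(norms$sd <= 0)) stop("norms sd must be > 0")
  one <- function(x) {
    keys <- names(norms$mean)
    z <- as.numeric((x[keys] - norms$mean[keys]) / norms$sd[keys])
    # strict z < -1; the epsilon keeps inputs sitting exactly on the
    # boundary from tipping over through floating-point rounding
    data.frame(metric = keys, z = z,
               abnormal = z < -1 - 1e-9, row.names = NULL)
  }
  if (is.matrix(metrics) || is.data.frame(metrics)) {
    m <- as.matrix(metrics)
    out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      cbind(subject = i, one(m[i, ]))
    }))
    return(out)
  }
  one(metrics)
}
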