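#' @include AllClasses.R
NULL

## Synthetic-data generators. Every generator is a pure function of its
## arguments including `seed`, so all downstream stages can be tested against
## known ground truth without any external data.

#' Simulate an R-R interval series with controllable LF/HF oscillations
#'
#' Generates a 5-minute-style resting tachogram by direct interval
#' modulation:
#' `rr(t) = meanRR + lfAmp sin(2 pi lfFreq t) + hfAmp sin(2 pi hfFreq t) + e`,
#' with Gaussian noise `e`. Beat times are the cumulative sum of intervals.
#' Direct modulation (rather than integral pulse frequency modulation) keeps
#' the band-power ground truth analytic: total interval variance is
#' `lfAmp^2/2 + hfAmp^2/2 + noiseSd^2`.
#'
#' @param meanRR mean R-R interval in ms (default 800, i.e. 75 bpm).
#' @param lfAmp,hfAmp modulation amplitudes in ms.
#' @param lfFreq,hfFreq modulation frequencies in Hz; must lie inside the LF
#'   (0.04-0.14 Hz) and HF (0.15-0.50 Hz) bands respectively.
#' @param noiseSd per-beat Gaussian noise sd in ms.
#' @param durationS recording duration in seconds (default 300, a 5-min rest
#'   recording).
#' @param seed integer RNG seed.
#' @return An [RRISeries-class].
#' @examples
#' rr <- genRRSeries(lfAmp = 40, hfAmp = 20, noiseSd = 10, seed = 1)
#' hrvMetrics(rr)
#' @export
genRRSeries <- function(meanRR = 800, lfAmp = 40, hfAmp = 20,
                        lfFreq = 0.10, hfFreq = 0.25, noiseSd = 10,
                        durationS = 300, seed = 1L) {
  if (!is.numeric(meanRR) || meanRR <= 0)
    stop("invalid RR generator spec: 'meanRR' must be > 0")
  if (lfFreq < 0.04 || lfFreq > 0.14)
    stop("invalid RR generator spec: 'lfFreq' must lie in [0.04, 0.14] Hz")
  if (hfFreq < 0.15 || hfFreq > 0.50)
    stop("invalid RR generator spec: 'hfFreq' must lie in [0.15, 0.50] Hz")
  if (durationS <= 0)
    stop("invalid RR generator spec: 'durationS' must be > 0")
  if (noiseSd < 0 || lfAmp < 0 || hfAmp < 0)
    stop("invalid RR generator spec: amplitudes and 'noiseSd' must be >= 0")

  set.seed(seed)
  nMax <- ceiling(durationS / (meanRR / 1000)) * 2 + 10
  noise <- rnorm(nMax, 0, noiseSd)
  tk <- 0
  rrs <- numeric(0)
  for (k in seq_len(nMax)) {
    rr <- meanRR + lfAmp * sin(2 * pi * lfFreq * tk) +
      hfAmp * sin(2 * pi * hfFreq * tk) + noise[k]
    rr <- max(rr, meanRR * 0.1)  # guards against nonphysical negatives
    tk <- tk + rr / 1000
    rrs <- c(rrs, rr)
    if (tk >= durationS) break
  }
  RRISeries(rrs)
}

companionMatrix <- function(A) {
  # A: [c, c, p] -> companion form (c*p) x (c*p)
  cdim <- dim(A)[1]; p <- dim(A)[3]
  top <- matrix(aperm(A, c(1, 2, 3)), cdim, cdim * p)
  Fm <- rbind(top, cbind(diag(cdim * (p - 1)), matrix(0, cdim * (p - 1), cdim)))
  if (p == 1) Fm <- top
  Fm
}

spectralRadius <- function(A) max(Mod(eigen(companionMatrix(A),
                                           only.values = TRUE)$values))

#' Simulate a (possibly time-varying) MVAR network with known coupling
#'
#' Draws from `y_t = sum_r A_r(t) y_{t-r} + e_t` with Gaussian innovations.
#' Coefficients may switch over time via `schedule`; each scheduled segment
#' must be stationary (companion spectral radius < 1). The first
#' `burnIn` samples (simulated from a zero initial state) are discarded.
#'
#' @param coeffs `[channel, channel, lag]` array of MVAR coefficients
#'   (`coeffs[i, j, r]` = influence of channel j on channel i at lag r), or a
#'   list of such arrays when `schedule` is given.
#' @param nSamples number of retained samples.
#' @param innovationSd per-channel innovation standard deviation (recycled).
#' @param sampleRateHz sampling rate attached to the output (default 1 Hz, a
#'   TR of 1 s).
#' @param schedule optional integer vector of segment start samples (first
#'   must be 1) when `coeffs` is a list; segment i uses `coeffs[[i]]` from
#'   `schedule[i]` until the next start.
#' @param burnIn samples discarded from a zero initial state (default 500).
#' @param seed integer RNG seed.
#' @param channelNames optional channel names.
#' @return A list with elements `ts` ([MultichannelTimeSeries-class]) and
#'   `model` ([TVMVARModel-class] holding the true per-sample coefficients).
#' @examples
#' A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
#' sim <- genMVARNetwork(A, nSamples = 1000, seed = 1)
#' @export
genMVARNetwork <- function(coeffs, nSamples, innovationSd = 1,
                           sampleRateHz = 1, schedule = NULL,
                           burnIn = 500L, seed = 1L, channelNames = NULL) {
  if (!is.list(coeffs)) coeffs <- list(coeffs)
  if (is.null(schedule)) schedule <- 1L
  if (length(schedule) != length(coeffs))
    stop("'schedule' must name a start sample per coefficient segment")
  if (schedule[1] != 1L) stop("the first scheduled segment must start at 1")
  cdim <- dim(coeffs[[1]])[1]
  p <- dim(coeffs[[1]])[3]
  if (p < 1L) stop("order must be >= 1")
  for (seg in seq_along(coeffs)) {
    sr <- spectralRadius(coeffs[[seg]])
    if (sr >= 1)
      stop(sprintf(
        "unstable coefficients in segment %d: companion spectral radius %.3f >= 1",
        seg, sr))
  }
  sdv <- rep(innovationSd, length.out = cdim)

  set.seed(seed)
  nTot <- nSamples + burnIn
  segOf <- findInterval(seq_len(nSamples), schedule)
  y <- matrix(0, cdim, nTot)
  innov <- matrix(rnorm(cdim * nTot, 0, sdv), cdim, nTot)
  for (t in seq_len(nTot)) {
    # burn-in runs under the first segment's coefficients
    A <- coeffs[[if (t <= burnIn) 1L else segOf[t - burnIn]]]
    acc <- innov[, t]
    for (r in seq_len(p)) if (t - r >= 1) acc <- acc + A[, , r] %*% y[, t - r]
    y[, t] <- acc
  }
  y <- y[, (burnIn + 1):nTot, drop = FALSE]

  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(cdim))
  trueCoeffs <- array(0, c(cdim, cdim, p, nSamples))
  for (t in seq_len(nSamples)) trueCoeffs[, , , t] <- coeffs[[segOf[t]]]
  model <- new("TVMVARModel", order = as.integer(p), coeffs = trueCoeffs,
               innovationCov = diag(sdv^2, cdim), times = seq_len(nSamples),
               channelNames = channelNames)
  list(ts = MultichannelTimeSeries(y, sampleRateHz, channelNames),
       model = model)
}

#' Default smooth lesion component pattern
#'
#' A Gaussian blob centred in the grid: the spatial pattern embedded in the
#' synthetic lesion cohort.
#'
#' @param gridShape integer length-3 voxel dimensions.
#' @return 3-D array in [0, 1].
#' @export
defaultComponentPattern <- function(gridShape = c(12L, 12L, 12L)) {
  ax <- lapply(gridShape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 4))
  g <- outer(outer(exp(-ax[[1]]^2), exp(-ax[[2]]^2)), exp(-ax[[3]]^2))
  g <- array(g, gridShape)
  g[g < 0.05] <- 0
  g
}

#' Simulate a lesion cohort with an embedded covarying component
#'
#' Each subject's lesion map is `loading * componentMap + noise`; a scalar
#' covariate (the HRV measure in the real study) is built to correlate with
#' the loadings at `loadingCorr` by mixing the standardized loadings with
#' independent Gaussian noise at the analytically required ratio. The study
#' cohort size (42 subjects) is the default.
#'
#' @param nSubjects cohort size (default 42).
#' @param gridShape voxel grid (default 12 x 12 x 12).
#' @param voxelSize mm per axis (default 2 mm isotropic).
#' @param componentMap 3-D pattern; defaults to [defaultComponentPattern()].
#' @param loadingCorr target correlation between map loadings and the
#'   covariate, in [-1, 1] (default 0.9).
#' @param noiseSd per-voxel noise sd (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `maps` (list of [LesionMap-class]), `covariate`
#'   (numeric), `loadings` (numeric ground truth) and `componentMap`.
#' @export
genLesionCohort <- function(nSubjects = 42L, gridShape = c(12L, 12L, 12L),
                            voxelSize = c(2, 2, 2),
                            componentMap = NULL, loadingCorr = 0.9,
                            noiseSd = 0.5, seed = 1L) {
  if (abs(loadingCorr) > 1) stop("|loadingCorr| must be <= 1")
  if (any(gridShape < 1)) stop("gridShape entries must be >= 1")
  if (nSubjects < 2) stop("need at least 2 subjects")
  if (is.null(componentMap)) componentMap <- defaultComponentPattern(gridShape)
  if (!all(dim(componentMap) == gridShape))
    stop("componentMap must match gridShape")

  set.seed(seed)
  loadings <- rnorm(nSubjects)
  zl <- as.numeric(scale(loadings))
  eps <- as.numeric(scale(rnorm(nSubjects)))
  # residualize then standardize so the target correlation holds by construction
  eps <- as.numeric(scale(eps - zl * sum(eps * zl) / sum(zl^2)))
  covariate <- loadingCorr * zl + sqrt(1 - loadingCorr^2) * eps

  maps <- lapply(seq_len(nSubjects), function(s) {
    vals <- loadings[s] * componentMap +
      array(rnorm(prod(gridShape), 0, noiseSd), gridShape)
    LesionMap(vals, voxelSize)
  })
  list(maps = maps, covariate = covariate, loadings = loadings,
       componentMap = componentMap)
}

#' Partition a voxel grid into contiguous ROI blocks
#'
#' Splits the grid into `nRois` contiguous, nearly equal blocks of voxels (in
#' column-major order). With `nRois = 7` the blocks carry the seven canonical
#' resting-state network names; otherwise `ROI_1..ROI_k`.
#'
#' @param gridShape integer length-3 voxel dimensions.
#' @param nRois number of regions (>= 1, <= voxel count).
#' @param voxelSize mm per axis.
#' @return An [AtlasLabels-class]; every voxel is labelled (no background).
#' @export
genAtlas <- function(gridShape = c(12L, 12L, 12L), nRois = 7L,
                     voxelSize = c(2, 2, 2)) {
  nvox <- prod(gridShape)
  if (nRois < 1 || nRois > nvox)
    stop("cannot partition ", nvox, " voxels into ", nRois, " ROIs")
  lab <- as.integer(ceiling(seq_len(nvox) / (nvox / nRois)))
  lab <- pmin(lab, nRois)
  labels <- array(lab, gridShape)
  nms <- if (nRois == 7L) sevenNetworks() else paste0("ROI_", seq_len(nRois))
  names(nms) <- as.character(seq_len(nRois))
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("AtlasLabels", labels = labels, names = nms,
      voxelSize = as.numeric(voxelSize))
}
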