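#' @import methods
#' @importFrom stats approx ar.ols coef cor fft lm median na.omit p.adjust
#'   predict qt quantile rnorm runif sd spline splinefun var
#' @importFrom utils head tail combn
NULL

#' RRISeries: a cleaned sequence of R-R intervals
#'
#' Container for a beat-to-beat interval series: the substrate of all heart
#' rate variability (HRV) metrics. Beat times are in seconds and strictly
#' increasing; intervals are in milliseconds and satisfy
#' `intervals[i] == (beatTimes[i+1] - beatTimes[i]) * 1000` up to float
#' tolerance. `cleanedFlags` marks intervals that were replaced during
#' ectopic-beat cleanup.
#'
#' @slot beatTimes numeric, beat times in seconds, strictly increasing.
#' @slot intervals numeric, R-R intervals in ms (length = beats - 1).
#' @slot cleanedFlags logical, one per interval; `TRUE` when the interval was
#'   interpolated by [cleanRR()].
#' @slot quality character, `"ok"` or `"suspect"` (set when cleanup replaced
#'   more than 20 % of intervals).
#'
#' @seealso [genRRSeries()], [cleanRR()], [hrvMetrics()]
#' @export
setClass("RRISeries",
  representation(
    beatTimes = "numeric",
    intervals = "numeric",
    cleanedFlags = "logical",
    quality = "character"
  ),
  prototype(quality = "ok")
)

setValidity("RRISeries", function(object) {
  msg <- character()
  n <- length(object@beatTimes)
  if (length(object@intervals) != max(n - 1L, 0L))
    msg <- c(msg, "length(intervals) must equal length(beatTimes) - 1")
  if (n >= 2L && any(diff(object@beatTimes) <= 0))
    msg <- c(msg, "beatTimes must be strictly increasing")
  if (any(object@intervals <= 0))
    msg <- c(msg, "intervals must be positive")
  if (length(object@cleanedFlags) != length(object@intervals))
    msg <- c(msg, "cleanedFlags must have one entry per interval")
  if (length(object@intervals) > 0L) {
    implied <- diff(object@beatTimes) * 1000
    if (max(abs(implied - object@intervals)) > 1e-6 * max(object@intervals))
      msg <- c(msg, "intervals must equal successive beat-time differences (ms)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an RRISeries from beat times or intervals
#'
#' @param intervals R-R intervals in milliseconds.
#' @param beatTimes optional beat times in seconds; computed as the cumulative
#'   sum of intervals (starting at 0) when missing.
#' @param cleanedFlags optional logical flags, one per interval.
#' @return An [RRISeries-class] object.
#' @examples
#' rr <- RRISeries(c(800, 820, 790))
#' nBeats(rr)
#' @export
RRISeries <- function(intervals, beatTimes = NULL, cleanedFlags = NULL) {
  intervals <- as.numeric(intervals)
  if (is.null(beatTimes)) beatTimes <- c(0, cumsum(intervals) / 1000)
  if (is.null(cleanedFlags)) cleanedFlags <- rep(FALSE, length(intervals))
  new("RRISeries", beatTimes = as.numeric(beatTimes), intervals = intervals,
      cleanedFlags = as.logical(cleanedFlags))
}

#' MultichannelTimeSeries: channels x samples data
#'
#' A regularly sampled multichannel series (for instance a seed signal pooled
#' from a lesion pattern plus the mean signals of seven resting-state
#' networks).
#'
#' @slot data numeric matrix, channels x samples.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelNames character, one name per channel.
#' @export
setClass("MultichannelTimeSeries",
  representation(
    data = "matrix",
    sampleRate = "numeric",
    channelNames = "character"
  )
)

setValidity("MultichannelTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@data) < 1L) msg <- c(msg, "need at least one channel")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames must have one entry per channel")
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a MultichannelTimeSeries
#'
#' @param data channels x samples numeric matrix.
#' @param sampleRate sampling rate in Hz.
#' @param channelNames optional channel names; defaults to `ch1..chk`.
#' @return A [MultichannelTimeSeries-class] object.
#' @export
MultichannelTimeSeries <- function(data, sampleRate, channelNames = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames)) channelNames <- rownames(data)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- NULL
  new("MultichannelTimeSeries", data = data, sampleRate = sampleRate,
      channelNames = channelNames)
}

#' TVMVARModel: time-varying multivariate autoregressive coefficients
#'
#' Coefficient trajectories of an order-p MVAR model,
#' `y_t = sum_r A_r(t) y_{t-r} + e_t`, as estimated by the dual extended
#' Kalman filter or as used by the simulator.
#'
#' @slot order model order p (number of lags).
#' @slot coeffs 4-D array `[channel, channel, lag, time]`; `coeffs[i, j, r, t]`
#'   is the influence of channel j at lag r on channel i.
#' @slot innovationCov channels x channels innovation covariance.
#' @slot times integer sample indices (into the analysed series) at which the
#'   coefficients are defined.
#' @slot channelNames character.
#' @export
setClass("TVMVARModel",
  representation(
    order = "integer",
    coeffs = "array",
    innovationCov = "matrix",
    times = "integer",
    channelNames = "character"
  )
)

setValidity("TVMVARModel", function(object) {
  msg <- character()
  d <- dim(object@coeffs)
  if (length(d) != 4L) msg <- c(msg, "coeffs must be a 4-D array [c, c, lag, time]")
  else {
    if (d[1] != d[2]) msg <- c(msg, "coefficient matrices must be square")
    if (d[3] != object@order) msg <- c(msg, "third dim of coeffs must equal order")
    if (d[4] != length(object@times)) msg <- c(msg, "fourth dim must match times")
  }
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PDCTensor: squared, normalized partial directed coherence
#'
#' Squared PDC values indexed by (time, frequency, target channel, source
#' channel). After squaring and column normalization every value lies in
#' [0, 1] and, for each (time, frequency, source), the values sum to 1 over
#' targets.
#'
#' @slot values 4-D array `[time, frequency, target, source]`.
#' @slot freqGrid numeric, frequencies in Hz.
#' @slot times integer sample indices.
#' @slot channelNames character.
#' @export
setClass("PDCTensor",
  representation(
    values = "array",
    freqGrid = "numeric",
    times = "integer",
    channelNames = "character"
  )
)

setValidity("PDCTensor", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L) msg <- c(msg, "values must be [time, freq, target, source]")
  else {
    if (d[2] != length(object@freqGrid)) msg <- c(msg, "freq dim must match freqGrid")
    if (d[3] != d[4]) msg <- c(msg, "target and source dims must agree")
  }
  rng <- range(object@values)
  if (rng[1] < -1e-10 || rng[2] > 1 + 1e-10)
    msg <- c(msg, "squared normalized PDC must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' LesionMap: a 3-D lesion probability / statistic volume
#'
#' @slot values 3-D numeric array on a voxel grid.
#' @slot voxelSize numeric length-3, mm per axis.
#' @slot spaceTag character, e.g. `"MNI"` or `"synthetic"`.
#' @export
setClass("LesionMap",
  representation(
    values = "array",
    voxelSize = "numeric",
    spaceTag = "character"
  ),
  prototype(spaceTag = "synthetic")
)

setValidity("LesionMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive numbers (mm)")
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a LesionMap
#' @param values 3-D numeric array.
#' @param voxelSize mm per axis (length 1 recycled or length 3).
#' @param spaceTag coordinate-space label.
#' @return A [LesionMap-class].
#' @export
LesionMap <- function(values, voxelSize = c(1, 1, 1), spaceTag = "synthetic") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("LesionMap", values = values, voxelSize = as.numeric(voxelSize),
      spaceTag = spaceTag)
}

#' AtlasLabels: an integer parcellation volume
#'
#' @slot labels 3-D integer array; 0 is background.
#' @slot names named character vector mapping label id (as name) to ROI name.
#' @slot voxelSize numeric length-3, mm per axis.
#' @export
setClass("AtlasLabels",
  representation(
    labels = "array",
    names = "character",
    voxelSize = "numeric"
  )
)

setValidity("AtlasLabels", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
  labs <- sort(unique(as.integer(object@labels)))
  labs <- labs[labs != 0L]
  if (length(labs) && !all(as.character(labs) %in% names(object@names)))
    msg <- c(msg, "every nonzero label needs a name")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive numbers (mm)")
  if (length(msg)) msg else TRUE
})

#' ComponentSet: paired independent components from parallel ICA
#'
#' @slot loadings1 subjects x k mixing matrix of the first modality (lesions).
#' @slot sources1 k x features source maps of the first modality.
#' @slot loadings2 subjects x k loading matrix of the second modality (for a
#'   scalar covariate this is the covariate replicated across components).
#' @slot k integer, component count.
#' @slot crossCorr data.frame with columns `component`, `r`, `p` giving the
#'   cross-modality loading correlation of each component.
#' @slot selectedPair integer index of the component with the most significant
#'   cross-modality correlation.
#' @slot converged logical.
#' @slot featureDim integer dims of the source feature space (for reshaping
#'   voxel sources back to 3-D).
#' @export
setClass("ComponentSet",
  representation(
    loadings1 = "matrix",
    sources1 = "matrix",
    loadings2 = "matrix",
    k = "integer",
    crossCorr = "data.frame",
    selectedPair = "integer",
    converged = "logical",
    featureDim = "integer"
  )
)

setValidity("ComponentSet", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (ncol(object@loadings1) != object@k) msg <- c(msg, "loadings1 must be subjects x k")
  if (nrow(object@sources1) != object@k) msg <- c(msg, "sources1 must be k x features")
  if (nrow(object@crossCorr) && any(abs(object@crossCorr$r) > 1 + 1e-12))
    msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' SurrogateNull: empirical null distribution for connectivity values
#'
#' @slot method one of `"window-shuffle"`, `"time-reversal"`, `"aaft"`.
#' @slot nRealizations integer.
#' @slot nullValues realizations x connections matrix of surrogate
#'   connectivity values (columns named `target<-source`).
#' @slot threshold named numeric, per-connection percentile threshold.
#' @slot percentile the percentile used (default 99).
#' @slot observed named numeric, the original-data connectivity values.
#' @slot significant named logical, `observed > threshold`.
#' @export
setClass("SurrogateNull",
  representation(
    method = "character",
    nRealizations = "integer",
    nullValues = "matrix",
    threshold = "numeric",
    percentile = "numeric",
    observed = "numeric",
    significant = "logical"
  )
)

setValidity("SurrogateNull", function(object) {
  msg <- character()
  if (object@nRealizations < 1L) msg <- c(msg, "nRealizations must be >= 1")
  if (nrow(object@nullValues) != object@nRealizations)
    msg <- c(msg, "nullValues must have nRealizations rows")
  if (length(object@threshold) != ncol(object@nullValues))
    msg <- c(msg, "one threshold per connection")
  if (length(msg)) msg else TRUE
})

#' ConnectivityProfile: seed-to-network directed connectivity values
#'
#' Band- and time-averaged squared PDC between a seed (pooled lesion-pattern
#' signal) and the seven canonical resting-state networks, in both
#' directions.
#'
#' @slot forward named numeric, seed -> network influence per network.
#' @slot backward named numeric, network -> seed influence per network.
#' @slot band numeric length-2, frequency band in Hz.
#' @slot threshold significance floor used for flagging (default 0.1).
#' @slot significantForward,significantBackward named logical flags (pending
#'   surrogate confirmation).
#' @slot subjectId character.
#' @export
setClass("ConnectivityProfile",
  representation(
    forward = "numeric",
    backward = "numeric",
    band = "numeric",
    threshold = "numeric",
    significantForward = "logical",
    significantBackward = "logical",
    subjectId = "character"
  )
)

setValidity("ConnectivityProfile", function(object) {
  msg <- character()
  if (length(object@forward) != length(object@backward))
    msg <- c(msg, "forward and backward must have the same length")
  vals <- c(object@forward, object@backward)
  if (length(vals) && (min(vals) < -1e-10 || max(vals) > 1 + 1e-10))
    msg <- c(msg, "connectivity values must lie in [0, 1]")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msg <- c(msg, "band must be [lo, hi] with lo < hi")
  if (length(msg)) msg else TRUE
})

#' The seven canonical resting-state network names
#'
#' Visual, somatomotor, dorsal attention, salience/ventral attention,
#' control, limbic and default networks.
#' @return character vector of length 7.
#' @export
sevenNetworks <- function() {
  c("Visual", "Somatomotor", "DorsalAttention", "SalienceVentralAttention",
    "Control", "Limbic", "Default")
}
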