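#' @include AllClasses.R
NULL

#' Number of beats in an R-R series
#' @param x an [RRISeries-class].
#' @return integer beat count.
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' @rdname nBeats
#' @export
setMethod("nBeats", "RRISeries", function(x) length(x@beatTimes))

#' R-R intervals accessor
#' @param x an [RRISeries-class].
#' @return numeric intervals in ms.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname intervals
#' @export
setMethod("intervals", "RRISeries", function(x) x@intervals)

#' Beat times accessor
#' @param x an [RRISeries-class].
#' @return numeric beat times in seconds.
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname beatTimes
#' @export
setMethod("beatTimes", "RRISeries", function(x) x@beatTimes)

#' Recording duration in seconds
#' @param x an [RRISeries-class] or [MultichannelTimeSeries-class].
#' @return numeric duration (s).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname duration
#' @export
setMethod("duration", "RRISeries", function(x) {
  if (nBeats(x) < 2L) 0 else diff(range(x@beatTimes))
})

#' @rdname duration
#' @export
setMethod("duration", "MultichannelTimeSeries", function(x) {
  ncol(x@data) / x@sampleRate
})

#' Channel data accessor
#' @param x a [MultichannelTimeSeries-class].
#' @return channels x samples matrix.
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname tsData
#' @export
setMethod("tsData", "MultichannelTimeSeries", function(x) {
  d <- x@data
  rownames(d) <- x@channelNames
  d
})

#' Sample rate accessor
#' @param x a [MultichannelTimeSeries-class].
#' @return numeric Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "MultichannelTimeSeries", function(x) x@sampleRate)

#' Channel names accessor
#' @param x a [MultichannelTimeSeries-class], [TVMVARModel-class] or
#'   [PDCTensor-class].
#' @return character.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "MultichannelTimeSeries", function(x) x@channelNames)

#' @rdname channelNames
#' @export
setMethod("channelNames", "TVMVARModel", function(x) x@channelNames)

#' @rdname channelNames
#' @export
setMethod("channelNames", "PDCTensor", function(x) x@channelNames)

#' Model order accessor
#' @param x a [TVMVARModel-class].
#' @return integer lag count.
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname modelOrder
#' @export
setMethod("modelOrder", "TVMVARModel", function(x) x@order)

#' Coefficient trajectory accessor
#' @param x a [TVMVARModel-class].
#' @return 4-D array `[channel, channel, lag, time]`.
#' @export
setGeneric("coeffArray", function(x) standardGeneric("coeffArray"))

#' @rdname coeffArray
#' @export
setMethod("coeffArray", "TVMVARModel", function(x) x@coeffs)

#' Time-averaged coefficient matrices
#' @param x a [TVMVARModel-class].
#' @return `[channel, channel, lag]` array, the mean over time.
#' @export
setGeneric("meanCoeffs", function(x) standardGeneric("meanCoeffs"))

#' @rdname meanCoeffs
#' @export
setMethod("meanCoeffs", "TVMVARModel", function(x) {
  apply(x@coeffs, 1:3, mean)
})

#' Innovation covariance accessor
#' @param x a [TVMVARModel-class].
#' @return channels x channels matrix.
#' @export
setGeneric("innovationCov", function(x) standardGeneric("innovationCov"))

#' @rdname innovationCov
#' @export
setMethod("innovationCov", "TVMVARModel", function(x) x@innovationCov)

#' PDC values accessor
#' @param x a [PDCTensor-class].
#' @return 4-D array `[time, frequency, target, source]`.
#' @export
setGeneric("pdcValues", function(x) standardGeneric("pdcValues"))

#' @rdname pdcValues
#' @export
setMethod("pdcValues", "PDCTensor", function(x) x@values)

#' Frequency grid accessor
#' @param x a [PDCTensor-class].
#' @return numeric frequencies (Hz).
#' @export
setGeneric("freqGrid", function(x) standardGeneric("freqGrid"))

#' @rdname freqGrid
#' @export
setMethod("freqGrid", "PDCTensor", function(x) x@freqGrid)

#' Voxel values accessor
#' @param x a [LesionMap-class] or [AtlasLabels-class].
#' @return 3-D array.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
#' @export
setMethod("mapValues", "LesionMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "AtlasLabels", function(x) x@labels)

#' Voxel size accessor
#' @param x a [LesionMap-class] or [AtlasLabels-class].
#' @return numeric length-3, mm per axis.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LesionMap", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "AtlasLabels", function(x) x@voxelSize)

#' ROI names of an atlas
#' @param x an [AtlasLabels-class].
#' @return named character vector (names are label ids).
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname roiNames
#' @export
setMethod("roiNames", "AtlasLabels", function(x) x@names)

#' Cross-modality correlations of a component set
#' @param x a [ComponentSet-class].
#' @return data.frame with columns component, r, p.
#' @export
setGeneric("crossCorr", function(x) standardGeneric("crossCorr"))

#' @rdname crossCorr
#' @export
setMethod("crossCorr", "ComponentSet", function(x) x@crossCorr)

#' Index of the selected (most significant) component pair
#' @param x a [ComponentSet-class].
#' @return integer.
#' @export
setGeneric("selectedPair", function(x) standardGeneric("selectedPair"))

#' @rdname selectedPair
#' @export
setMethod("selectedPair", "ComponentSet", function(x) x@selectedPair)

#' Per-connection significance thresholds of a surrogate null
#' @param x a [SurrogateNull-class].
#' @return named numeric.
#' @export
setGeneric("nullThreshold", function(x) standardGeneric("nullThreshold"))

#' @rdname nullThreshold
#' @export
setMethod("nullThreshold", "SurrogateNull", function(x) x@threshold)

#' Forward (seed -> network) connectivity values
#' @param x a [ConnectivityProfile-class].
#' @return named numeric of length 7.
#' @export
setGeneric("forwardValues", function(x) standardGeneric("forwardValues"))

#' @rdname forwardValues
#' @export
setMethod("forwardValues", "ConnectivityProfile", function(x) x@forward)

#' Backward (network -> seed) connectivity values
#' @param x a [ConnectivityProfile-class].
#' @return named numeric of length 7.
#' @export
setGeneric("backwardValues", function(x) standardGeneric("backwardValues"))

#' @rdname backwardValues
#' @export
setMethod("backwardValues", "ConnectivityProfile", function(x) x@backward)

## -- show methods ------------------------------------------------------------

setMethod("show", "RRISeries", function(object) {
  cat(sprintf("RRISeries: %d beats, %.1f s, mean RR %.1f ms",
              nBeats(object), duration(object),
              mean(object@intervals)), "\n")
  ncl <- sum(object@cleanedFlags)
  if (ncl > 0) cat(sprintf("  %d interval(s) cleaned; quality: %s\n",
                           ncl, object@quality))
})

setMethod("show", "MultichannelTimeSeries", function(object) {
  cat(sprintf("MultichannelTimeSeries: %d channels x %d samples @ %g Hz\n",
              nrow(object@data), ncol(object@data), object@sampleRate))
  cat("  channels:", paste(head(object@channelNames, 8), collapse = ", "),
      if (nrow(object@data) > 8) "..." else "", "\n")
})

setMethod("show", "TVMVARModel", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("TVMVARModel: order %d, %d channels, %d time points\n",
              object@order, d[1], d[4]))
})

setMethod("show", "PDCTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "PDCTensor: %d time x %d freq x %d targets x %d sources (range %.3g..%.3g)\n",
    d[1], d[2], d[3], d[4], min(object@values), max(object@values)))
})

setMethod("show", "LesionMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("LesionMap: %dx%dx%d voxels (%.3g mm3/voxel, space %s)\n",
              d[1], d[2], d[3], prod(object@voxelSize), object@spaceTag))
})

setMethod("show", "AtlasLabels", function(object) {
  d <- dim(object@labels)
  cat(sprintf("AtlasLabels: %dx%dx%d voxels, %d ROIs\n",
              d[1], d[2], d[3], length(object@names)))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: k = %d, selected pair %d (r = %.3f, p = %.3g)%s\n",
              object@k, object@selectedPair,
              object@crossCorr$r[object@selectedPair],
              object@crossCorr$p[object@selectedPair],
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "SurrogateNull", function(object) {
  cat(sprintf("SurrogateNull (%s): %d realizations, %gth percentile\n",
              object@method, object@nRealizations, object@percentile))
  if (length(object@significant))
    cat(sprintf("  significant connections: %d / %d\n",
                sum(object@significant), length(object@significant)))
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat(sprintf("ConnectivityProfile [%s], band %.3g-%.3g Hz\n",
              object@subjectId, object@band[1], object@band[2]))
  m <- rbind(forward = object@forward, backward = object@backward)
  print(round(m, 3))
})
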