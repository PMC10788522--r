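#' @include AllClasses.R
NULL

## File interfaces: RR series as two-column CSV, volumes as NIfTI-1,
## multichannel series as CSV with channel-name header.

#' Write / read an R-R series as CSV
#'
#' Two columns: `beat_time_s` (the time of the interval's closing beat) and
#' `rr_ms`.
#'
#' @param rr an [RRISeries-class].
#' @param path file path.
#' @return `writeRRSeries` returns `path` invisibly; `readRRSeries` returns
#'   an [RRISeries-class].
#' @export
writeRRSeries <- function(rr, path) {
  df <- data.frame(beat_time_s = beatTimes(rr)[-1], rr_ms = intervals(rr))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRRSeries
#' @export
readRRSeries <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("beat_time_s", "rr_ms") %in% names(df)))
    stop("expected columns beat_time_s, rr_ms")
  t0 <- df$beat_time_s[1] - df$rr_ms[1] / 1000
  RRISeries(df$rr_ms, beatTimes = c(t0, df$beat_time_s))
}

#' Write / read a lesion map as NIfTI-1
#'
#' @param map a [LesionMap-class].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `writeLesionMap` returns `path` invisibly; `readLesionMap`
#'   returns a [LesionMap-class].
#' @export
writeLesionMap <- function(map, path) {
  img <- RNifti::asNifti(mapValues(map))
  RNifti::pixdim(img) <- voxelSize(map)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeLesionMap
#' @param spaceTag space label attached on read (default "NIfTI").
#' @export
readLesionMap <- function(path, spaceTag = "NIfTI") {
  img <- RNifti::readNifti(path)
  LesionMap(array(as.numeric(img), dim(img)),
            voxelSize = RNifti::pixdim(img)[1:3], spaceTag = spaceTag)
}

#' Write / read atlas labels as NIfTI-1 plus a name table
#'
#' The integer label volume goes to `path`; ROI names go to a two-column CSV
#' (`label`, `name`) at `namesPath` (default: `path` with a `_labels.csv`
#' suffix).
#'
#' @param atlas an [AtlasLabels-class].
#' @param path NIfTI file path.
#' @param namesPath CSV path for the label names.
#' @return `writeAtlas` returns `path` invisibly; `readAtlas` an
#'   [AtlasLabels-class].
#' @export
writeAtlas <- function(atlas, path, namesPath = NULL) {
  if (is.null(namesPath)) namesPath <- paste0(sub("\\.nii(\\.gz)?$", "", path),
                                              "_labels.csv")
  img <- RNifti::asNifti(mapValues(atlas))
  RNifti::pixdim(img) <- voxelSize(atlas)
  RNifti::writeNifti(img, path, datatype = "int16")
  utils::write.csv(data.frame(label = names(roiNames(atlas)),
                              name = as.character(roiNames(atlas))),
                   namesPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path, namesPath = NULL) {
  if (is.null(namesPath)) namesPath <- paste0(sub("\\.nii(\\.gz)?$", "", path),
                                              "_labels.csv")
  img <- RNifti::readNifti(path)
  df <- utils::read.csv(namesPath)
  nms <- as.character(df$name); names(nms) <- as.character(df$label)
  new("AtlasLabels", labels = array(as.integer(img), dim(img)),
      names = nms, voxelSize = RNifti::pixdim(img)[1:3])
}

#' Write / read a multichannel series as CSV
#'
#' One column per channel (header = channel names) plus a `time_s` column.
#'
#' @param ts a [MultichannelTimeSeries-class].
#' @param path file path.
#' @return `writeMultichannel` returns `path` invisibly; `readMultichannel`
#'   a [MultichannelTimeSeries-class].
#' @export
writeMultichannel <- function(ts, path) {
  df <- as.data.frame(t(tsData(ts)))
  names(df) <- channelNames(ts)
  df <- cbind(time_s = (seq_len(ncol(ts@data)) - 1) / sampleRate(ts), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMultichannel
#' @export
readMultichannel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("expected a time_s column")
  dt <- diff(df$time_s)
  fs <- 1 / median(dt)
  dat <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  MultichannelTimeSeries(dat, fs, rownames(dat))
}
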