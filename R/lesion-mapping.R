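#' @include AllClasses.R
NULL

## Lesion-map combination, threshold + cluster-size filtering, and
## atlas-based overlay quantification.

#' Combine subject lesion maps into a group map
#'
#' Voxelwise sum (default) or maximum across maps on identical grids.
#'
#' @param maps list of [LesionMap-class] objects.
#' @param mode `"sum"` or `"max"`.
#' @return A combined [LesionMap-class].
#' @export
combineMaps <- function(maps, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (!length(maps)) stop("no maps to combine")
  ref <- dim(mapValues(maps[[1]]))
  for (m in maps) if (!all(dim(mapValues(m)) == ref))
    stop("grid mismatch: all maps must share the same voxel grid")
  acc <- mapValues(maps[[1]])
  for (m in maps[-1]) {
    v <- mapValues(m)
    acc <- if (mode == "sum") acc + v else pmax(acc, v)
  }
  LesionMap(acc, voxelSize(maps[[1]]), maps[[1]]@spaceTag)
}

## 3-D connected components under 26-connectivity (BFS on voxel indices).
## No pre-installed package labels 3-D components, so this is hand-written;
## grids at the scales this package works with are small.
labelComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6, 18 or 26")

  lab <- array(0L, d)
  nextLab <- 0L
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coords <- arrayInd(idx, d)
  inMask <- array(FALSE, d); inMask[idx] <- TRUE
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(coords[s, ], 1)
    lab[idx[s]] <- nextLab
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
      hit <- inMask[lin] & lab[lin] == 0L
      if (any(hit)) {
        lab[lin[hit]] <- nextLab
        queue <- rbind(queue, nb[hit, , drop = FALSE])
      }
    }
  }
  lab
}

#' Threshold a lesion map and remove small clusters
#'
#' Retains voxels with value strictly greater than `tThresh`, labels the
#' suprathreshold set into connected components (26-connectivity by
#' default), and removes components whose size is not strictly greater than
#' `minVoxels` (so a 10-voxel cluster is removed under the default
#' `minVoxels = 10`, an 11-voxel cluster survives).
#'
#' @param map a [LesionMap-class].
#' @param tThresh statistic threshold (default 3).
#' @param minVoxels cluster-size floor; clusters must exceed it (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return The filtered [LesionMap-class] (subthreshold voxels set to 0).
#' @export
thresholdCluster <- function(map, tThresh = 3, minVoxels = 10L,
                             connectivity = 26) {
  if (minVoxels < 1) stop("minVoxels must be >= 1")
  v <- mapValues(map)
  mask <- v > tThresh
  out <- array(0, dim(v))
  if (any(mask)) {
    lab <- labelComponents(mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > minVoxels)
    sel <- mask & array(lab %in% keep, dim(v))
    out[sel] <- v[sel]
  }
  LesionMap(out, voxelSize(map), map@spaceTag)
}

#' Quantify lesion overlay on an atlas
#'
#' For each ROI, counts suprathreshold (nonzero) lesion voxels carrying that
#' label; volume is count times voxel volume (mm^3) and the overlay percent
#' is 100 x ROI volume / total suprathreshold volume. ROIs with fewer than
#' `minVoxels` lesion voxels are omitted, so reported percents may sum to
#' less than 100.
#'
#' @param map a thresholded [LesionMap-class] (zeros = background).
#' @param atlas an [AtlasLabels-class] on the same grid.
#' @param minVoxels ROIs with fewer lesion voxels than this are dropped
#'   (default 10; use 1 to report everything).
#' @return data.frame with columns `roi_name`, `n_voxels`,
#'   `lesion_volume_mm3`, `overlay_percent`, sorted by decreasing volume.
#' @export
atlasOverlay <- function(map, atlas, minVoxels = 10L) {
  v <- mapValues(map)
  lab <- mapValues(atlas)
  if (!all(dim(v) == dim(lab))) stop("map and atlas grids differ")
  lesion <- v != 0
  voxVol <- prod(voxelSize(map))
  totalVox <- sum(lesion)
  nms <- roiNames(atlas)
  if (!length(nms) || totalVox == 0)
    return(data.frame(roi_name = character(), n_voxels = integer(),
                      lesion_volume_mm3 = numeric(),
                      overlay_percent = numeric()))
  counts <- table(factor(lab[lesion & lab > 0], levels = names(nms)))
  df <- data.frame(roi_name = as.character(nms),
                   n_voxels = as.integer(counts),
                   stringsAsFactors = FALSE)
  df$lesion_volume_mm3 <- df$n_voxels * voxVol
  df$overlay_percent <- 100 * df$n_voxels / totalVox
  df <- df[df$n_voxels >= minVoxels, , drop = FALSE]
  df <- df[order(-df$lesion_volume_mm3), , drop = FALSE]
  rownames(df) <- NULL
  df
}
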