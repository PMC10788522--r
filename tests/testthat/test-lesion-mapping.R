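# Lesion-map combination, threshold/cluster filtering, atlas overlay.

mkMap <- function(vals, dims = c(10L, 10L, 10L), voxelSize = 1) {
  a <- array(0, dims)
  a[vals] <- 1
  LesionMap(a, voxelSize)
}

test_that("combineMaps sums or maxes voxelwise and checks grids", {
  m1 <- mkMap(1:20)
  expect_identical(mapValues(combineMaps(list(m1))), mapValues(m1))

  m2 <- mkMap(21:40)
  u <- combineMaps(list(m1, m2))
  expect_identical(sum(mapValues(u)), 40)
  expect_true(all(mapValues(u) %in% c(0, 1)))

  m3 <- mkMap(15:25)  # overlaps both
  s <- combineMaps(list(m1, m2, m3))
  expect_identical(max(mapValues(s)), 2)
  expect_identical(sum(mapValues(s) == 2), 11L)

  mx <- combineMaps(list(m1, m3), mode = "max")
  expect_identical(max(mapValues(mx)), 1)

  bad <- LesionMap(array(0, c(5, 5, 5)))
  expect_error(combineMaps(list(m1, bad)), "grid mismatch")
})

test_that("combineMaps(sum) is permutation invariant", {
  set.seed(1)
  maps <- lapply(1:4, function(i) LesionMap(array(rnorm(125), c(5, 5, 5))))
  a <- combineMaps(maps)
  b <- combineMaps(maps[c(3, 1, 4, 2)])
  expect_equal(mapValues(a), mapValues(b))
})

test_that("cluster filter enforces the strict > minVoxels rule", {
  a <- array(0, c(20L, 10L, 10L))
  a[1:10, 1, 1] <- 5    # a 10-voxel line cluster
  a[1:11, 5, 5] <- 5    # an 11-voxel line cluster
  m <- LesionMap(a, 1)
  out <- thresholdCluster(m, tThresh = 3, minVoxels = 10)
  v <- mapValues(out)
  expect_identical(sum(v[, 1, 1] != 0), 0L)    # 10-voxel cluster removed
  expect_identical(sum(v[, 5, 5] != 0), 11L)   # 11-voxel cluster retained
})

test_that("cluster filter respects the threshold and handles empty maps", {
  a <- array(1, c(6L, 6L, 6L))  # all below t = 3
  out <- thresholdCluster(LesionMap(a, 1))
  expect_true(all(mapValues(out) == 0))

  # diagonal voxels touch under 26- but not 6-connectivity
  b <- array(0, c(12L, 12L, 3L))
  for (i in 1:12) b[i, i, 2] <- 5
  diag26 <- thresholdCluster(LesionMap(b, 1), minVoxels = 10)
  expect_identical(sum(mapValues(diag26) != 0), 12L)
  diag6 <- thresholdCluster(LesionMap(b, 1), minVoxels = 10, connectivity = 6)
  expect_true(all(mapValues(diag6) == 0))
})

test_that("thresholdCluster is idempotent", {
  set.seed(2)
  a <- array(rnorm(1000, 2, 2), c(10L, 10L, 10L))
  m <- LesionMap(a, 1)
  once <- thresholdCluster(m)
  twice <- thresholdCluster(once)
  expect_equal(mapValues(once), mapValues(twice))
})

test_that("atlas overlay reproduces hand-counted volumes and percents", {
  lab <- array(0L, c(10L, 10L, 10L))
  lab[1:5, , ] <- 1L; lab[6:10, , ] <- 2L
  nms <- c("1" = "ROI_A", "2" = "ROI_B")
  atlas <- new("AtlasLabels", labels = lab, names = nms,
               voxelSize = c(1, 1, 1))
  v <- array(0, c(10L, 10L, 10L))
  v[1:5, 1:6, 1] <- 4   # 30 voxels in ROI_A
  v[6:10, 1:2, 1] <- 4  # 10 voxels in ROI_B
  rep <- atlasOverlay(LesionMap(v, 1), atlas)
  expect_identical(rep$roi_name, c("ROI_A", "ROI_B"))
  expect_identical(rep$lesion_volume_mm3, c(30, 10))
  expect_identical(rep$overlay_percent, c(75, 25))

  # volumes scale with voxel size cubed
  rep2 <- atlasOverlay(LesionMap(v, 2),
                       new("AtlasLabels", labels = lab, names = nms,
                           voxelSize = c(2, 2, 2)))
  expect_identical(rep2$lesion_volume_mm3, c(30, 10) * 8)
  expect_identical(rep2$overlay_percent, c(75, 25))

  # lesion wholly inside one ROI
  v1 <- array(0, c(10L, 10L, 10L)); v1[1:3, 1:4, 1] <- 5
  rep1 <- atlasOverlay(LesionMap(v1, 1), atlas)
  expect_identical(rep1$overlay_percent, 100)
})

test_that("atlas overlay omits ROIs under the voxel floor and sums to total", {
  lab <- array(0L, c(10L, 10L, 10L))
  lab[1:5, , ] <- 1L; lab[6:10, , ] <- 2L
  atlas <- new("AtlasLabels", labels = lab,
               names = c("1" = "A", "2" = "B"), voxelSize = c(1, 1, 1))
  v <- array(0, c(10L, 10L, 10L))
  v[1:5, 1:6, 1] <- 4   # 30 voxels in A
  v[6, 1:5, 1] <- 4     # 5 voxels in B: under the floor of 10
  rep <- atlasOverlay(LesionMap(v, 1), atlas)
  expect_identical(rep$roi_name, "A")
  expect_lt(sum(rep$overlay_percent), 100)

  # with no floor, volumes sum to the total suprathreshold volume
  repAll <- atlasOverlay(LesionMap(v, 1), atlas, minVoxels = 1)
  expect_identical(sum(repAll$lesion_volume_mm3), 35)
  expect_equal(sum(repAll$overlay_percent), 100)

  empty <- atlasOverlay(LesionMap(array(0, c(10L, 10L, 10L)), 1), atlas)
  expect_identical(nrow(empty), 0L)
})
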