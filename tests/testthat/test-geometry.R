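test_that("exterior distance map matches brute-force pairwise search", {
  for (seed in 1:5) {
    ph <- randomTinyPhantom(seed)
    ss <- structureSet(ph$grid, list(hrctv = ph$hrctv))
    d <- exteriorDistanceMap(ss)
    bf <- bruteDistanceMap(ph$grid, ph$hrctv)
    expect_lt(max(abs(d - bf)), 1e-9)
  }
})

test_that("distance is zero inside the target and bounded at the boundary", {
  g <- voxelGrid(c(20, 20, 20), spacing = c(1.5, 2, 2.5))
  m <- array(FALSE, gridShape(g))
  m[8:13, 8:13, 8:13] <- TRUE
  ss <- structureSet(g, list(hrctv = m))
  d <- exteriorDistanceMap(ss)
  expect_true(all(d[m] == 0))
  # face neighbor of a flat boundary: distance equals the axis spacing
  expect_equal(d[14, 10, 10], 1.5)
  expect_equal(d[10, 14, 10], 2.0)
  expect_equal(d[10, 10, 14], 2.5)
  expect_true(all(is.finite(d)) && all(d >= 0))
})

test_that("distance to a voxelized sphere approximates |p| - R", {
  g <- voxelGrid(c(56, 56, 56), spacing = c(1, 1, 1))
  ax <- gridAxes(g)
  rad <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  m <- rad <= 15
  ss <- structureSet(g, list(hrctv = m))
  d <- exteriorDistanceMap(ss)
  out <- !m & rad <= 25
  expect_lt(max(abs(d[out] - (rad[out] - 15))), sqrt(3))
})

test_that("empty HR-CTV is rejected", {
  g <- voxelGrid(c(8, 8, 8))
  expect_error(structureSet(g, list(hrctv = array(FALSE, gridShape(g)))),
               "empty")
})

test_that("ring membership uses half-open intervals ((k-1)w, kw]", {
  # flat slab target; OAR = columns at known distances along x (2 mm voxels)
  g <- voxelGrid(c(30, 10, 10), spacing = c(2, 2, 2))
  m <- array(FALSE, gridShape(g)); m[1:5, , ] <- TRUE
  oar <- array(FALSE, gridShape(g)); oar[6:20, , ] <- TRUE
  ss <- structureSet(g, list(hrctv = m, rectum = oar))
  dec <- deriveSubOrgans(ss, "rectum", ringWidthMm = 4, nRings = 5)
  # distances along x: 2, 4, 6, 8, ... ; ring 1 = (0,4] -> two columns
  vv <- voxelVolumeCc(g) * 100 # one full column of 10x10 voxels
  expect_equal(ringVolumesCc(dec)[1], 2 * vv)
  expect_equal(ringVolumesCc(dec)[2], 2 * vv)
  expect_equal(sum(ringVolumesCc(dec)), 10 * vv)
  expect_equal(dec@farVolumeCc, 5 * vv)
  expect_equal(dec@insideVolumeCc, 0)
})

test_that("OAR equal to the first expansion shell gives [1, 0, ..., 0]", {
  ph <- randomTinyPhantom(11)
  ss0 <- structureSet(ph$grid, list(hrctv = ph$hrctv))
  d <- exteriorDistanceMap(ss0)
  shell <- d > 0 & d <= 3
  expect_true(any(shell))
  ss <- structureSet(ph$grid, list(hrctv = ph$hrctv, bladder = shell))
  dec <- deriveSubOrgans(ss, "bladder")
  expect_equal(normalizedVolumes(dec), c(1, rep(0, 14)))
})

test_that("OAR beyond the last ring yields all-zero features", {
  g <- voxelGrid(c(40, 12, 12), spacing = c(2, 2, 2))
  m <- array(FALSE, gridShape(g)); m[1:2, , ] <- TRUE
  oar <- array(FALSE, gridShape(g)); oar[38:40, , ] <- TRUE # > 70 mm away
  ss <- structureSet(g, list(hrctv = m, sigmoid = oar))
  dec <- deriveSubOrgans(ss, "sigmoid", ringWidthMm = 3, nRings = 15)
  expect_equal(normalizedVolumes(dec), rep(0, 15))
  expect_equal(dec@farVolumeCc, oarVolumeCc(dec))
})

test_that("rings partition the OAR and conserve voxel counts", {
  for (seed in 6:9) {
    ph <- randomTinyPhantom(seed)
    if (!any(ph$oar)) next
    ss <- structureSet(ph$grid, list(hrctv = ph$hrctv, rectum = ph$oar))
    dec <- deriveSubOrgans(ss, "rectum", ringWidthMm = 2, nRings = 7)
    expect_equal(sum(ringVolumesCc(dec)) + dec@insideVolumeCc +
                   dec@farVolumeCc, oarVolumeCc(dec), tolerance = 1e-12)
    expect_true(all(normalizedVolumes(dec) >= 0 &
                      normalizedVolumes(dec) <= 1))
    expect_lte(sum(normalizedVolumes(dec)), 1 + 1e-12)
  }
})

test_that("doubling the spacing doubles distances and scales volumes by 8", {
  ph <- randomTinyPhantom(13)
  g2 <- voxelGrid(gridShape(ph$grid), gridSpacing(ph$grid) * 2)
  ss1 <- structureSet(ph$grid, list(hrctv = ph$hrctv, bladder = ph$oar))
  ss2 <- structureSet(g2, list(hrctv = ph$hrctv, bladder = ph$oar))
  d1 <- exteriorDistanceMap(ss1)
  d2 <- exteriorDistanceMap(ss2)
  expect_equal(d2, d1 * 2, tolerance = 1e-12)
  dec1 <- deriveSubOrgans(ss1, "bladder", ringWidthMm = 2, nRings = 10)
  dec2 <- deriveSubOrgans(ss2, "bladder", ringWidthMm = 4, nRings = 10)
  expect_equal(ringVolumesCc(dec2), ringVolumesCc(dec1) * 8,
               tolerance = 1e-12)
  expect_equal(normalizedVolumes(dec2), normalizedVolumes(dec1),
               tolerance = 1e-12)
})

test_that("ring label volume is consistent with the decomposition", {
  ph <- randomTinyPhantom(17)
  ss <- structureSet(ph$grid, list(hrctv = ph$hrctv, rectum = ph$oar))
  dec <- deriveSubOrgans(ss, "rectum", ringWidthMm = 3, nRings = 5)
  lab <- ringLabelVolume(ss, "rectum", ringWidthMm = 3, nRings = 5)
  vv <- voxelVolumeCc(ph$grid)
  for (k in 1:5)
    expect_equal(sum(lab == k) * vv, ringVolumesCc(dec)[k])
})
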