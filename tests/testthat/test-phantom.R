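test_that("structure sampling is bit-identical under a fixed (seed, index)", {
  p <- tinyPhantomParams(seed = 5)
  a <- sampleStructures(p, 3)
  b <- sampleStructures(p, 3)
  for (lab in structureLabels(a))
    expect_identical(maskArray(a, lab), maskArray(b, lab))
  c2 <- sampleStructures(p, 4)
  expect_false(identical(maskArray(a, "hrctv"), maskArray(c2, "hrctv")))
})

test_that("masks are pairwise disjoint and the HR-CTV is an ellipsoid", {
  p <- tinyPhantomParams(seed = 8)
  ss <- sampleStructures(p, 1)
  labs <- structureLabels(ss)
  for (i in seq_along(labs))
    for (j in seq_len(i - 1L))
      expect_equal(sum(maskArray(ss, labs[i]) & maskArray(ss, labs[j])), 0)
  # realized HR-CTV volume within the analytic ellipsoid range (+/- a layer)
  vol <- structureVolumeCc(ss, "hrctv") * 1000 # mm3
  lo <- 4 / 3 * pi * p$hrctvSemiAxesMm[1]^3
  hi <- 4 / 3 * pi * p$hrctvSemiAxesMm[2]^3
  expect_gt(vol, lo * 0.85)
  expect_lt(vol, hi * 1.15)
})

test_that("realized HR-CTV volumes stay inside the analytic ellipsoid range", {
  p <- phantomParams(shape = c(112L, 112L, 112L), spacing = c(2, 2, 2),
                     hrctvSemiAxesMm = c(15, 35), gapMm = c(0, 3),
                     bladderSemiYMm = c(12, 15), seed = 21)
  vols <- vapply(1:12, function(i)
    structureVolumeCc(sampleStructures(p, i), "hrctv") * 1000, numeric(1))
  lo <- 4 / 3 * pi * 15^3
  hi <- 4 / 3 * pi * 35^3
  # one voxel layer on a sphere of radius r adds ~ 4 pi r^2 * dx
  layer <- 4 * pi * 35^2 * 2
  expect_true(all(vols > lo - layer) && all(vols < hi + layer))
})

test_that("zero gap range places OARs within a voxel diagonal of the target", {
  p <- phantomParams(shape = c(96L, 96L, 96L), spacing = c(1.5, 1.5, 1.5),
                     hrctvSemiAxesMm = c(12, 15),
                     bladderSemiXMm = c(16, 20), bladderSemiYMm = c(12, 15),
                     bladderSemiZMm = c(16, 20),
                     rectumRadiusMm = c(7, 9), rectumLengthMm = c(40, 50),
                     sigmoidRadiusMm = c(6, 8), sigmoidArcRadiusMm = c(22, 30),
                     sigmoidArcSpanDeg = c(90, 120),
                     gapMm = c(0, 0), seed = 31)
  ss <- sampleStructures(p, 1)
  g <- structureGrid(ss)
  ax <- gridAxes(g)
  cen <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  hr <- t(cen[as.vector(maskArray(ss, "hrctv")), , drop = FALSE])
  diag_mm <- sqrt(sum(gridSpacing(g)^2))
  for (oar in c("bladder", "rectum", "sigmoid")) {
    pts <- cen[as.vector(maskArray(ss, oar)), , drop = FALSE]
    dmin <- sqrt(min(vapply(seq_len(nrow(pts)), function(i)
      min(colSums((hr - pts[i, ])^2)), numeric(1))))
    expect_lte(dmin, diag_mm)
  }
})

test_that("a grid too small for the sampled organs fails naming the organ", {
  p <- tinyPhantomParams(seed = 2)
  p$shape <- c(24L, 24L, 24L) # 48 mm extent cannot hold bladder + gap
  expect_error(sampleStructures(p, 1), "grid too small")
})

test_that("every dwell lies inside the HR-CTV and plans are deterministic", {
  p <- tinyPhantomParams(seed = 12)
  ss <- sampleStructures(p, 2)
  plan <- sampleDwellPlan(ss, p, 2)
  g <- structureGrid(ss)
  idx <- round(sweep(sweep(dwellPositions(plan), 2, gridOrigin(g)), 2,
                     gridSpacing(g), "/")) + 1
  hr <- maskArray(ss, "hrctv")
  expect_true(all(hr[idx]))
  expect_true(nNeedles(plan) >= 2 && nNeedles(plan) <= 8)
  expect_true(prescriptionGy(plan) %in% c(6, 7))
  plan2 <- sampleDwellPlan(ss, p, 2)
  expect_identical(dwellPositions(plan), dwellPositions(plan2))
  expect_identical(dwellWeights(plan), dwellWeights(plan2))
})

test_that("needle-count law has mean near 3.7 within the 2-8 range", {
  p <- tinyPhantomParams(seed = 3)
  # the configured law pins the long-run mean
  expect_equal(sum(p$needleCounts * p$needleProbs), 3.71, tolerance = 1e-9)
  ss <- sampleStructures(p, 1)
  ns <- vapply(1:400, function(i) nNeedles(sampleDwellPlan(ss, p, i)),
               integer(1))
  expect_gte(min(ns), 2)
  expect_lte(max(ns), 8)
  expect_gte(mean(ns), 3.5)
  expect_lte(mean(ns), 3.9)
})

test_that("dose kernel is inverse-square and superposes linearly", {
  g <- voxelGrid(c(41, 41, 41), spacing = c(2, 2, 2))
  m <- array(FALSE, gridShape(g)); m[15:27, 15:27, 15:27] <- TRUE
  ss <- structureSet(g, list(hrctv = m))
  one <- function(pos) new("DwellPlan", positions = matrix(pos, 1),
                           weights = 1, nNeedles = 2L, prescriptionGy = 6)
  d1 <- doseArray(computeDose(ss, one(c(0, 0, 0)), normalizeD90 = FALSE))
  # voxel centers on the x axis at 10 mm and 20 mm from the dwell
  c0 <- 21
  expect_equal(d1[c0 + 5, c0, c0] / d1[c0 + 10, c0, c0], 4,
               tolerance = 1e-12)
  d2 <- doseArray(computeDose(ss, one(c(8, 0, 0)), normalizeD90 = FALSE))
  both <- new("DwellPlan", positions = rbind(c(0, 0, 0), c(8, 0, 0)),
              weights = c(1, 1), nNeedles = 2L, prescriptionGy = 6)
  d12 <- doseArray(computeDose(ss, both, normalizeD90 = FALSE))
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
})

test_that("dose renormalization pins HR-CTV D90 to the prescription", {
  p <- tinyPhantomParams(seed = 19)
  ss <- sampleStructures(p, 1)
  plan <- sampleDwellPlan(ss, p, 1)
  dose <- computeDose(ss, plan)
  d90 <- doseAtVolumeFraction(dose, maskArray(ss, "hrctv"), 0.9)
  expect_equal(d90, prescriptionGy(plan), tolerance = 1e-9)
  expect_error(computeDose(ss, new("DwellPlan",
                                   positions = matrix(numeric(0), 0, 3),
                                   weights = numeric(0), nNeedles = 2L,
                                   prescriptionGy = 6)), "empty")
})

test_that("mini cohorts are reproducible with plausible records", {
  p <- tinyPhantomParams(seed = 77)
  co <- generateCohort(p, 4)
  expect_identical(co, generateCohort(p, 4))
  expect_equal(nrow(co), 4)
  expect_equal(nrow(generateCohort(p, 1)), 1)
  expect_true(all(co$d90_gy > 0))
  for (oar in c("bladder", "rectum", "sigmoid")) {
    rings <- as.matrix(co[, sprintf("%s_ring%02d", oar, 1:15)])
    expect_true(all(rings >= 0 & rings <= 1))
    expect_true(all(rowSums(rings) <= 1 + 1e-12))
    expect_true(all(is.finite(co[[paste0(oar, "_ratio")]])))
    expect_true(all(co[[paste0(oar, "_ratio")]] > 0))
  }
  # consecutive plans share patients in groups of 2-5
  runs <- rle(co$patient_id)
  expect_true(all(runs$lengths <= 5))
})
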