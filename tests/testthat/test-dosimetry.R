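test_that("uniform dose returns the uniform value for any volume", {
  g <- voxelGrid(c(10, 10, 10), spacing = c(10, 10, 10)) # 1 cm3 voxels
  dg <- doseGrid(g, array(7, gridShape(g)))
  mask <- array(TRUE, gridShape(g))
  expect_equal(doseAtVolume(dg, mask, 2), 7)
  expect_equal(doseAtVolume(dg, mask, 999.9), 7)
  expect_equal(doseAtVolumeFraction(dg, mask, 0.9), 7)
  expect_equal(doseAtVolumeFraction(dg, mask, 1), 7)
})

test_that("full-volume request returns the minimum dose on the mask", {
  set.seed(4)
  g <- voxelGrid(c(8, 8, 8), spacing = c(5, 5, 5))
  vals <- array(stats::runif(512, 1, 9), gridShape(g))
  dg <- doseGrid(g, vals)
  mask <- array(TRUE, gridShape(g))
  expect_equal(doseAtVolume(dg, mask, sum(mask) * voxelVolumeCc(g)),
               min(vals))
  expect_equal(doseAtVolumeFraction(dg, mask, 1), min(vals))
})

test_that("D90 of a linear ramp equals the brute-force 10th percentile", {
  g <- voxelGrid(c(100, 5, 5), spacing = c(2, 2, 2))
  ramp <- array(rep(seq(1, 10, length.out = 100), 25), gridShape(g))
  dg <- doseGrid(g, ramp)
  mask <- array(TRUE, gridShape(g))
  d90 <- doseAtVolumeFraction(dg, mask, 0.9)
  srt <- sort(as.vector(ramp), decreasing = TRUE)
  n <- length(srt)
  # exhaustive sort: interpolate the cumulative-volume DVH at 0.9 * total
  vv <- voxelVolumeCc(g)
  oracle <- stats::approx(vv * seq_len(n), srt, xout = 0.9 * n * vv)$y
  expect_equal(d90, oracle, tolerance = 1e-12)
})

test_that("point-source dose on a spherical shell reproduces the closed-form D2cm3", {
  # hottest v cm3 of S/r^2 on shell [r0, r1] is the sub-shell [r0, rv] with
  # rv = (r0^3 + 3v/(4pi))^(1/3); here a scaled-down 1 mm lattice version
  g <- voxelGrid(c(85, 85, 85), spacing = c(1, 1, 1))
  ax <- gridAxes(g)
  rad <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  mask <- rad >= 20 & rad <= 40
  S <- 1e5
  dg <- doseGrid(g, array(S / pmax(rad, 1)^2, dim = dim(rad)))
  rv <- (20^3 + 3 * 2000 / (4 * pi))^(1 / 3)
  expect_equal(doseAtVolume(dg, mask, 2), S / rv^2, tolerance = 0.02)
})

test_that("dose-volume metrics are monotone and scale-covariant", {
  set.seed(9)
  g <- voxelGrid(c(12, 12, 12), spacing = c(4, 4, 4))
  vals <- array(stats::runif(12^3, 0, 10), gridShape(g))
  dg <- doseGrid(g, vals)
  mask <- array(stats::runif(12^3) < 0.7, gridShape(g))
  vols <- seq(0.5, sum(mask) * voxelVolumeCc(g), length.out = 25)
  ds <- vapply(vols, function(v) doseAtVolume(dg, mask, v), numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
  dg3 <- doseGrid(g, vals * 3)
  for (v in vols[c(1, 10, 25)])
    expect_equal(doseAtVolume(dg3, mask, v), 3 * doseAtVolume(dg, mask, v),
                 tolerance = 1e-12)
})

test_that("invalid volume requests and empty masks are rejected", {
  g <- voxelGrid(c(6, 6, 6), spacing = c(5, 5, 5))
  dg <- doseGrid(g, array(1, gridShape(g)))
  mask <- array(FALSE, gridShape(g)); mask[1:2, 1, 1] <- TRUE
  expect_error(doseAtVolume(dg, mask, 10), "exceeds")
  expect_error(doseAtVolume(dg, array(FALSE, gridShape(g)), 1), "empty")
  expect_error(doseAtVolume(dg, mask, 0), "> 0")
  expect_error(doseAtVolumeFraction(dg, mask, 1.2), "fraction")
})

test_that("EQD2 conversion matches the linear-quadratic formula", {
  expect_equal(eqd2(30, 6, 10), 40)               # 30 * 16 / 12
  expect_equal(eqd2(50, 2, 3), 50)                # 2 Gy/fraction identity
  expect_equal(eqd2(30, 6, 1e9), 30, tolerance = 1e-6) # large alpha/beta
  expect_error(eqd2(-1, 2, 10), "> 0")
  expect_error(eqd2(30, 0, 10), "> 0")
})

test_that("plan constraint audit applies inclusive clinical limits", {
  r <- checkPlanConstraints(85, 90, 75, 75)
  expect_true(all(r$pass))
  r2 <- checkPlanConstraints(84.9, 90, 75, 75)
  expect_false(r2$pass[r2$structure == "hrctv"])
  expect_true(all(r2$pass[r2$structure != "hrctv"]))
  r3 <- checkPlanConstraints(200, 0, 0, 0)
  expect_true(all(r3$pass))
  expect_error(checkPlanConstraints(Inf, 0, 0, 0), "finite")
})
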