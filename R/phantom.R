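#' Parameters of the synthetic pelvic phantom cohort
#'
#' Bundles every knob of the phantom generator: lattice, organ shape
#' families and size ranges, HR-CTV-to-OAR surface gap range, needle-count
#' law, dwell spacing, dose-kernel constants and the dwell-weight noise.
#' Defaults emulate a needle-insertion brachytherapy cohort: HR-CTV a
#' voxelized ellipsoid; bladder an anterior ellipsoid; rectum a posterior
#' vertical tube; sigmoid a superior curved tube; 2-8 needles per plan with
#' long-run mean 3.7; 6 or 7 Gy per fraction; plans grouped 2-5 per patient.
#'
#' @param shape,spacing lattice definition (voxels, mm); default 96^3 at
#'   2 mm isotropic.
#' @param hrctvSemiAxesMm range (mm) the three HR-CTV semi-axes are drawn
#'   from, independently and uniformly.
#' @param bladderSemiXMm,bladderSemiYMm,bladderSemiZMm bladder ellipsoid
#'   semi-axis ranges (mm); Y is the anteroposterior stand-off axis.
#' @param rectumRadiusMm,rectumLengthMm rectum tube radius and length ranges
#'   (mm).
#' @param sigmoidRadiusMm,sigmoidArcRadiusMm,sigmoidArcSpanDeg sigmoid tube
#'   radius, arc radius and arc angular span ranges (mm, mm, degrees).
#' @param gapMm range (mm) of the sampled HR-CTV-to-OAR surface gap; lower
#'   bound must be >= 0.
#' @param needleCounts,needleProbs needle-count support and probabilities;
#'   the defaults put the mean at 3.71 within the observed 2-8 range.
#' @param dwellStepMm spacing of dwell positions along tandem and needles
#'   (mm; 2.5 is the usual afterloader source step).
#' @param needleWeightFactor base relative weight of needle dwells vs 1.0
#'   for tandem dwells (tandem-dominant loading).
#' @param kernelConstant inverse-square kernel constant (Gy mm^2 per unit
#'   weight); immaterial after D90 renormalization.
#' @param rMinMm kernel clamp radius (mm) avoiding the 1/r^2 singularity.
#' @param weightNoiseSigma sigma of the multiplicative log-normal noise on
#'   dwell weights (0 disables).
#' @param prescriptionsGy per-fraction prescriptions sampled per plan.
#' @param fractionsPerPatient inclusive range of consecutive plans sharing a
#'   patient id.
#' @param seed base seed; every draw of the generator is a deterministic
#'   function of `(seed, plan index)`.
#' @return a validated named list of class `PhantomParams`.
#' @export
phantomParams <- function(shape = c(96L, 96L, 96L), spacing = c(2, 2, 2),
                          hrctvSemiAxesMm = c(15, 30),
                          bladderSemiXMm = c(25, 35),
                          bladderSemiYMm = c(15, 22),
                          bladderSemiZMm = c(25, 35),
                          rectumRadiusMm = c(9, 15),
                          rectumLengthMm = c(60, 100),
                          sigmoidRadiusMm = c(8, 13),
                          sigmoidArcRadiusMm = c(30, 50),
                          sigmoidArcSpanDeg = c(90, 150),
                          gapMm = c(0, 20),
                          needleCounts = 2:8,
                          needleProbs = c(0.25, 0.30, 0.20, 0.10,
                                          0.07, 0.05, 0.03),
                          dwellStepMm = 2.5,
                          needleWeightFactor = 0.3,
                          kernelConstant = 1,
                          rMinMm = 1,
                          weightNoiseSigma = 0.1,
                          prescriptionsGy = c(6, 7),
                          fractionsPerPatient = c(2L, 5L),
                          seed = 42L) {
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            hrctvSemiAxesMm = hrctvSemiAxesMm,
            bladderSemiXMm = bladderSemiXMm,
            bladderSemiYMm = bladderSemiYMm,
            bladderSemiZMm = bladderSemiZMm,
            rectumRadiusMm = rectumRadiusMm,
            rectumLengthMm = rectumLengthMm,
            sigmoidRadiusMm = sigmoidRadiusMm,
            sigmoidArcRadiusMm = sigmoidArcRadiusMm,
            sigmoidArcSpanDeg = sigmoidArcSpanDeg,
            gapMm = gapMm, needleCounts = as.integer(needleCounts),
            needleProbs = needleProbs, dwellStepMm = dwellStepMm,
            needleWeightFactor = needleWeightFactor,
            kernelConstant = kernelConstant, rMinMm = rMinMm,
            weightNoiseSigma = weightNoiseSigma,
            prescriptionsGy = prescriptionsGy,
            fractionsPerPatient = as.integer(fractionsPerPatient),
            seed = as.integer(seed))
  validatePhantomParams(p)
  class(p) <- "PhantomParams"
  p
}

validatePhantomParams <- function(p) {
  rng <- c("hrctvSemiAxesMm", "bladderSemiXMm", "bladderSemiYMm",
           "bladderSemiZMm", "rectumRadiusMm", "rectumLengthMm",
           "sigmoidRadiusMm", "sigmoidArcRadiusMm", "sigmoidArcSpanDeg",
           "gapMm", "fractionsPerPatient")
  for (f in rng) {
    v <- p[[f]]
    if (length(v) != 2L || any(!is.finite(v)) || v[1] > v[2])
      stop("range '", f, "' must be c(lo, hi) with lo <= hi")
  }
  if (p$gapMm[1] < 0) stop("gap range lower bound must be >= 0")
  if (length(p$needleCounts) != length(p$needleProbs) ||
      any(p$needleProbs < 0) || abs(sum(p$needleProbs) - 1) > 1e-8)
    stop("needleProbs must be a probability vector matching needleCounts")
  if (any(p$needleCounts < 2L) || any(p$needleCounts > 8L))
    stop("needleCounts must lie in [2, 8]")
  if (p$dwellStepMm <= 0 || p$rMinMm <= 0 || p$kernelConstant <= 0)
    stop("dwellStepMm, rMinMm and kernelConstant must be > 0")
  if (p$needleWeightFactor <= 0)
    stop("needleWeightFactor must be > 0")
  if (p$weightNoiseSigma < 0) stop("weightNoiseSigma must be >= 0")
  if (!all(p$prescriptionsGy %in% c(6, 7)))
    stop("prescriptionsGy must be drawn from {6, 7}")
  invisible(TRUE)
}

#' @export
print.PhantomParams <- function(x, ...) {
  cat("PhantomParams:", paste(x$shape, collapse = "x"), "voxels @",
      paste(x$spacing, collapse = "x"), "mm; seed", x$seed, "\n")
  cat("  HR-CTV semi-axes U(", x$hrctvSemiAxesMm[1], ",",
      x$hrctvSemiAxesMm[2], ") mm; gap U(", x$gapMm[1], ",", x$gapMm[2],
      ") mm; needle mean",
      signif(sum(x$needleCounts * x$needleProbs), 3), "\n")
  invisible(x)
}

# One deterministic 32-bit sub-seed per (base seed, plan index, stage).
planSeed <- function(seed, index, stage = 0L) {
  as.integer(((as.numeric(seed) %% 100003) * 20011 +
                as.numeric(index) * 131 + stage * 17) %% 2147483647)
}

ellipsoidMask <- function(grid, center, semi) {
  ax <- gridAxes(grid)
  qx <- ((ax[[1]] - center[1]) / semi[1])^2
  qy <- ((ax[[2]] - center[2]) / semi[2])^2
  qz <- ((ax[[3]] - center[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

cylinderMaskZ <- function(grid, center_xy, radius, z_range) {
  ax <- gridAxes(grid)
  qx <- (ax[[1]] - center_xy[1])^2
  qy <- (ax[[2]] - center_xy[2])^2
  inxy <- outer(qx, qy, "+") <= radius^2
  inz <- ax[[3]] >= z_range[1] & ax[[3]] <= z_range[2]
  outer(inxy, inz, "&")
}

# Tube of radius r around the horizontal arc
# p(t) = (R sin t, R (cos t - 1), z0), |t| <= span/2: passes over the world
# origin at t = 0 and bulges posteriorly/laterally.
arcTubeMask <- function(grid, z0, arcRadius, spanRad, radius) {
  ax <- gridAxes(grid)
  tmax <- spanRad / 2
  ts <- seq(-tmax, tmax, length.out = max(8L, ceiling(arcRadius * spanRad)))
  px <- arcRadius * sin(ts)
  py <- arcRadius * (cos(ts) - 1)
  ix <- which(ax[[1]] >= min(px) - radius & ax[[1]] <= max(px) + radius)
  iy <- which(ax[[2]] >= min(py) - radius & ax[[2]] <= max(py) + radius)
  iz <- which(ax[[3]] >= z0 - radius & ax[[3]] <= z0 + radius)
  mask <- array(FALSE, gridShape(grid))
  if (!length(ix) || !length(iy) || !length(iz)) return(mask)
  nb <- c(length(ix), length(iy), length(iz))
  xs <- ax[[1]][ix]; ys <- ax[[2]][iy]; zs <- ax[[3]][iz]
  dz2 <- (zs - z0)^2
  d2min <- array(Inf, nb)
  for (k in seq_along(ts)) {
    dxy <- outer((xs - px[k])^2, (ys - py[k])^2, "+")
    d2 <- outer(dxy, dz2, "+")
    d2min <- pmin(d2min, d2)
  }
  mask[ix, iy, iz] <- d2min <= radius^2
  mask
}

checkOrganExtent <- function(grid, organ, bbox_lo, bbox_hi) {
  lo <- gridOrigin(grid)
  hi <- gridOrigin(grid) + (gridShape(grid) - 1L) * gridSpacing(grid)
  if (any(bbox_lo < lo) || any(bbox_hi > hi))
    stop("grid too small to contain sampled ", organ)
  invisible(TRUE)
}

#' Sample one synthetic structure set
#'
#' Draws the HR-CTV (central ellipsoid), anterior bladder ellipsoid,
#' posterior rectum tube and superior sigmoid arc, each placed at an
#' independently sampled surface gap from the HR-CTV, and voxelizes them on
#' the parameter lattice. Deterministic given `(params$seed, index)`. OAR
#' masks are guaranteed pairwise disjoint and non-overlapping with the
#' HR-CTV (abutment allowed).
#'
#' @param params a [phantomParams()] list.
#' @param index plan index (>= 0) selecting the deterministic draw.
#' @return a [StructureSet-class].
#' @export
sampleStructures <- function(params, index) {
  validatePhantomParams(params)
  if (index < 0) stop("index must be >= 0")
  set.seed(planSeed(params$seed, index, 0L))
  grid <- voxelGrid(params$shape, params$spacing)

  hrSemi <- stats::runif(3, params$hrctvSemiAxesMm[1], params$hrctvSemiAxesMm[2])
  gaps <- stats::runif(3, params$gapMm[1], params$gapMm[2])
  blSemi <- c(stats::runif(1, params$bladderSemiXMm[1], params$bladderSemiXMm[2]),
              stats::runif(1, params$bladderSemiYMm[1], params$bladderSemiYMm[2]),
              stats::runif(1, params$bladderSemiZMm[1], params$bladderSemiZMm[2]))
  reR <- stats::runif(1, params$rectumRadiusMm[1], params$rectumRadiusMm[2])
  reL <- stats::runif(1, params$rectumLengthMm[1], params$rectumLengthMm[2])
  siR <- stats::runif(1, params$sigmoidRadiusMm[1], params$sigmoidRadiusMm[2])
  siArc <- stats::runif(1, params$sigmoidArcRadiusMm[1], params$sigmoidArcRadiusMm[2])
  siSpan <- stats::runif(1, params$sigmoidArcSpanDeg[1],
                         params$sigmoidArcSpanDeg[2]) * pi / 180

  checkOrganExtent(grid, "HR-CTV", -hrSemi, hrSemi)
  hrctv <- ellipsoidMask(grid, c(0, 0, 0), hrSemi)

  blCenter <- c(0, hrSemi[2] + gaps[1] + blSemi[2], 0)
  checkOrganExtent(grid, "bladder", blCenter - blSemi, blCenter + blSemi)
  bladder <- ellipsoidMask(grid, blCenter, blSemi)

  reY <- -(hrSemi[2] + gaps[2] + reR)
  checkOrganExtent(grid, "rectum", c(-reR, reY - reR, -reL / 2),
                   c(reR, reY + reR, reL / 2))
  rectum <- cylinderMaskZ(grid, c(0, reY), reR, c(-reL / 2, reL / 2))

  siZ0 <- hrSemi[3] + gaps[3] + siR
  checkOrganExtent(grid, "sigmoid",
                   c(-siArc * sin(siSpan / 2) - siR,
                     siArc * (cos(siSpan / 2) - 1) - siR, siZ0 - siR),
                   c(siArc * sin(siSpan / 2) + siR, siR, siZ0 + siR))
  sigmoid <- arcTubeMask(grid, siZ0, siArc, siSpan, siR)

  # analytic placement keeps structures apart; carving guarantees the
  # disjointness invariant against voxelization corner cases
  bladder <- bladder & !hrctv
  rectum <- rectum & !hrctv & !bladder
  sigmoid <- sigmoid & !hrctv & !bladder & !rectum
  for (lab in c("bladder", "rectum", "sigmoid"))
    if (!any(get(lab))) stop("sampled ", lab, " voxelized to an empty mask")

  structureSet(grid, list(hrctv = hrctv, bladder = bladder,
                          rectum = rectum, sigmoid = sigmoid))
}

worldToIndex <- function(grid, pts) {
  idx <- sweep(sweep(pts, 2, gridOrigin(grid)), 2, gridSpacing(grid), "/")
  round(idx) + 1
}

insideMask <- function(grid, mask, pts) {
  idx <- worldToIndex(grid, pts)
  ok <- idx[, 1] >= 1 & idx[, 1] <= gridShape(grid)[1] &
    idx[, 2] >= 1 & idx[, 2] <= gridShape(grid)[2] &
    idx[, 3] >= 1 & idx[, 3] <= gridShape(grid)[3]
  res <- logical(nrow(pts))
  if (any(ok)) res[ok] <- mask[idx[ok, , drop = FALSE]]
  res
}

#' Sample a dwell plan inside the HR-CTV
#'
#' Places one tandem dwell line through the HR-CTV centroid plus
#' `n_needles` straight vertical needle tracks whose dwells all lie inside
#' the HR-CTV mask; the needle count is drawn from the parameter law (mean
#' 3.7, support 2-8) and dwell weights carry multiplicative log-normal
#' noise. Deterministic given `(params$seed, index)`.
#'
#' @inheritParams sampleStructures
#' @param structures the [StructureSet-class] to plan on.
#' @return a [DwellPlan-class].
#' @export
sampleDwellPlan <- function(structures, params, index) {
  validatePhantomParams(params)
  set.seed(planSeed(params$seed, index, 1L))
  grid <- structureGrid(structures)
  hrctv <- maskArray(structures, "hrctv")
  if (!any(hrctv)) stop("HR-CTV mask is empty")
  vox <- which(hrctv, arr.ind = TRUE)
  centroid <- gridOrigin(grid) + (colMeans(vox) - 1) * gridSpacing(grid)
  zAll <- gridAxes(grid)[[3]]

  trackDwells <- function(x, y) {
    zc <- centroid[3]
    zs <- sort(unique(c(seq(zc, min(zAll), by = -params$dwellStepMm),
                        seq(zc, max(zAll), by = params$dwellStepMm))))
    pts <- cbind(x, y, zs)
    pts[insideMask(grid, hrctv, pts), , drop = FALSE]
  }

  nNeedles <- sample(params$needleCounts, 1, prob = params$needleProbs)
  tandem <- trackDwells(centroid[1], centroid[2])
  if (nrow(tandem) == 0L)
    stop("cannot place the tandem inside the HR-CTV")

  # template-like needle pattern: equiangular ring at ~60% of the HR-CTV
  # cross-section half-widths, with a random rotation per plan
  halfX <- (max(vox[, 1]) - min(vox[, 1])) * gridSpacing(grid)[1] / 2
  halfY <- (max(vox[, 2]) - min(vox[, 2])) * gridSpacing(grid)[2] / 2
  dwells <- list(tandem)
  placed <- 0L
  shrink <- 0.6
  while (placed < nNeedles) {
    if (shrink < 0.1)
      stop("cannot place ", nNeedles, " needles inside the HR-CTV")
    angles <- 2 * pi * seq_len(nNeedles) / nNeedles
    cand <- lapply(angles, function(a)
      trackDwells(centroid[1] + shrink * halfX * cos(a),
                  centroid[2] + shrink * halfY * sin(a)))
    if (all(vapply(cand, nrow, integer(1)) >= 1L)) {
      dwells <- c(dwells, cand)
      placed <- nNeedles
    } else {
      shrink <- shrink - 0.1 # pull the ring inward until all tracks land
    }
  }
  pos <- do.call(rbind, dwells)
  base <- rep(c(1, params$needleWeightFactor),
              c(nrow(tandem), nrow(pos) - nrow(tandem)))
  w <- if (params$weightNoiseSigma > 0)
    base * exp(stats::rnorm(nrow(pos), 0, params$weightNoiseSigma)) else base
  rx <- sample(length(params$prescriptionsGy), 1)
  new("DwellPlan", positions = unname(pos), weights = w,
      nNeedles = as.integer(nNeedles),
      prescriptionGy = params$prescriptionsGy[rx])
}

#' Compute the dose grid of a dwell plan
#'
#' Superposes an inverse-square point kernel
#' `dose(v) = sum_i w_i k / max(r_vi, rMin)^2` over all dwells and, by
#' default, rescales the whole grid so that the HR-CTV D90 equals the plan
#' prescription — the phantom counterpart of normalizing every clinical plan
#' to its prescribed coverage, which makes the D2cm3/D90 target scale-free.
#'
#' @param structures the [StructureSet-class] the plan belongs to.
#' @param plan a [DwellPlan-class].
#' @param kernelConstant kernel constant (Gy mm^2 per unit weight).
#' @param rMinMm clamp radius (mm).
#' @param normalizeD90 rescale so HR-CTV D90 = prescription (default TRUE).
#' @return a [DoseGrid-class].
#' @export
computeDose <- function(structures, plan, kernelConstant = 1, rMinMm = 1,
                        normalizeD90 = TRUE) {
  stopifnot(is(structures, "StructureSet"), is(plan, "DwellPlan"))
  if (nrow(plan@positions) == 0L) stop("dwell list is empty")
  grid <- structureGrid(structures)
  lo <- gridOrigin(grid)
  hi <- lo + (gridShape(grid) - 1L) * gridSpacing(grid)
  if (any(sweep(plan@positions, 2, lo) < -1e-9) ||
      any(sweep(plan@positions, 2, hi) > 1e-9))
    stop("dwell positions fall outside the voxel lattice")
  vals <- .doseKernel(gridShape(grid), gridSpacing(grid), gridOrigin(grid),
                      plan@positions, plan@weights, kernelConstant, rMinMm)
  dg <- doseGrid(grid, array(vals, gridShape(grid)))
  if (normalizeD90) {
    d90 <- doseAtVolumeFraction(dg, maskArray(structures, "hrctv"), 0.9)
    dg <- doseGrid(grid, doseArray(dg) * (plan@prescriptionGy / d90))
  }
  dg
}

#' Generate a synthetic cohort table
#'
#' Runs the full per-plan chain — structures, dwell plan, dose, ring
#' decomposition of each OAR, DVH targets — for `nPlans` plans and returns
#' the assembled cohort table (one row per plan). Consecutive groups of 2-5
#' plans share a `patient_id`, mimicking multi-fraction patients. Fully
#' reproducible from `params$seed`.
#'
#' @param params a [phantomParams()] list.
#' @param nPlans number of fraction plans (>= 1).
#' @param ringWidthMm,nRings ring decomposition settings.
#' @param outDir optional directory; when given, per-plan masks and dose are
#'   written as NIfTI volumes.
#' @param verbose print a progress line every 25 plans.
#' @return the cohort `data.frame` (see [cohortColumns()] for the schema).
#' @export
generateCohort <- function(params, nPlans, ringWidthMm = 3, nRings = 15L,
                           outDir = NULL, verbose = FALSE) {
  validatePhantomParams(params)
  if (nPlans < 1) stop("nPlans must be >= 1")
  set.seed(planSeed(params$seed, 0L, 2L))
  fracChoices <- seq(params$fractionsPerPatient[1],
                     params$fractionsPerPatient[2])
  sizes <- integer(0)
  while (sum(sizes) < nPlans)
    sizes <- c(sizes, fracChoices[sample.int(length(fracChoices), 1)])
  patient <- rep(seq_along(sizes), sizes)[seq_len(nPlans)]

  rows <- vector("list", nPlans)
  for (i in seq_len(nPlans)) {
    rows[[i]] <- tryCatch({
      ss <- sampleStructures(params, i)
      plan <- sampleDwellPlan(ss, params, i)
      dose <- computeDose(ss, plan, params$kernelConstant, params$rMinMm)
      dmap <- exteriorDistanceMap(ss)
      decomps <- lapply(stats::setNames(OAR_LABELS, OAR_LABELS), function(oar)
        deriveSubOrgans(ss, oar, ringWidthMm, nRings, distanceMap = dmap))
      mets <- lapply(stats::setNames(OAR_LABELS, OAR_LABELS), function(oar)
        dvhMetrics(dose, ss, oar))
      if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (lab in structureLabels(ss))
          writeVolume(file.path(outDir, sprintf("plan%04d_%s.nii", i, lab)),
                      structureGrid(ss), maskArray(ss, lab))
        writeVolume(file.path(outDir, sprintf("plan%04d_dose.nii", i)),
                    structureGrid(ss), doseArray(dose))
      }
      assemblePlanRecord(decomps, mets, planId = sprintf("plan_%04d", i),
                         patientId = sprintf("pt_%03d", patient[i]),
                         prescriptionGy = prescriptionGy(plan),
                         nNeedles = nNeedles(plan), nRings = nRings)
    }, error = function(e)
      stop("plan ", i, ": ", conditionMessage(e), call. = FALSE))
    if (verbose && i %% 25 == 0)
      message("generated ", i, "/", nPlans, " plans")
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort
}
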