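#' Exterior Euclidean distance map of the HR-CTV
#'
#' Computes, for every voxel of the lattice, the Euclidean distance in mm
#' from the voxel center to the HR-CTV region (nearest HR-CTV voxel center),
#' with anisotropic spacing honored inside the transform. Voxels inside the
#' HR-CTV get exactly 0. This realizes the external ring expansion of the
#' target as a distance field: ring k is the set of voxels with
#' `(k-1)*w < d <= k*w`.
#'
#' @param structures a [StructureSet-class] with a nonempty `hrctv` mask.
#' @return numeric 3D array of distances (mm) on the structure grid.
#' @examples
#' g <- voxelGrid(c(16, 16, 16), spacing = c(2, 2, 2))
#' m <- array(FALSE, gridShape(g)); m[7:10, 7:10, 7:10] <- TRUE
#' ss <- structureSet(g, list(hrctv = m))
#' d <- exteriorDistanceMap(ss)
#' range(d[m])  # all zero inside
#' @export
exteriorDistanceMap <- function(structures) {
  stopifnot(is(structures, "StructureSet"))
  hrctv <- maskArray(structures, "hrctv")
  if (!any(hrctv)) stop("HR-CTV mask is empty")
  g <- structureGrid(structures)
  d <- .edtExterior(as.vector(hrctv), gridShape(g), gridSpacing(g))
  array(d, dim = gridShape(g))
}

#' Decompose an OAR into exterior distance rings of the HR-CTV
#'
#' Intersects the OAR mask with concentric exterior distance shells
#' ("rings") of the HR-CTV, each `ringWidthMm` wide, producing the sub-organ
#' volumes and their normalized versions (divided by the total OAR volume)
#' that serve as the dose-prediction features. Ring membership uses the
#' half-open interval `(k-1)*w < d <= k*w`; OAR voxels at distance 0 (inside
#' the HR-CTV) are reported in `insideVolumeCc` and not assigned to any
#' ring, so the features measure stand-off geometry only; voxels beyond ring
#' `nRings` land in `farVolumeCc`.
#'
#' @param structures a [StructureSet-class] containing `hrctv` and `oarLabel`.
#' @param oarLabel one of `"bladder"`, `"rectum"`, `"sigmoid"`.
#' @param ringWidthMm ring width in mm; default 3 (0.3 cm).
#' @param nRings number of rings, 1..15; default 15.
#' @param distanceMap optional precomputed [exteriorDistanceMap()] array to
#'   reuse across the OARs of one plan.
#' @return A [SubOrganDecomposition-class].
#' @export
deriveSubOrgans <- function(structures, oarLabel, ringWidthMm = 3,
                            nRings = 15L, distanceMap = NULL) {
  stopifnot(is(structures, "StructureSet"))
  nRings <- as.integer(nRings)
  if (ringWidthMm <= 0) stop("ringWidthMm must be > 0")
  if (nRings < 1L || nRings > 15L) stop("nRings must lie in [1, 15]")
  oar <- maskArray(structures, oarLabel)
  if (!any(oar)) stop("OAR mask '", oarLabel, "' is empty")
  if (is.null(distanceMap)) distanceMap <- exteriorDistanceMap(structures)
  vv <- voxelVolumeCc(structureGrid(structures))

  d <- distanceMap[oar]
  inside <- d <= 0
  ring <- ceiling(d / ringWidthMm) # d in ((k-1)w, kw] -> k
  ring[inside] <- 0L
  counts <- tabulate(ring[ring >= 1L & ring <= nRings], nbins = nRings)
  oarVol <- length(d) * vv
  ringVol <- counts * vv
  new("SubOrganDecomposition",
      oarLabel = oarLabel, ringWidthMm = as.numeric(ringWidthMm),
      nRings = nRings, ringVolumesCc = ringVol,
      normalizedVolumes = ringVol / oarVol, oarVolumeCc = oarVol,
      hrctvVolumeCc = structureVolumeCc(structures, "hrctv"),
      insideVolumeCc = sum(inside) * vv,
      farVolumeCc = sum(ring > nRings) * vv)
}

#' Ring label volume for visual checks
#'
#' Assigns each voxel its ring index (1..nRings) from the HR-CTV distance
#' field, 0 elsewhere, optionally restricted to one OAR; exportable with
#' [writeVolume()] for tomogram-style inspection of the sub-organs.
#'
#' @inheritParams deriveSubOrgans
#' @param oarLabel optional OAR label to restrict to; `NULL` keeps all voxels.
#' @return integer 3D array of ring labels on the structure grid.
#' @export
ringLabelVolume <- function(structures, oarLabel = NULL, ringWidthMm = 3,
                            nRings = 15L, distanceMap = NULL) {
  if (is.null(distanceMap)) distanceMap <- exteriorDistanceMap(structures)
  ring <- ceiling(distanceMap / ringWidthMm)
  ring[distanceMap <= 0 | ring > nRings] <- 0L
  if (!is.null(oarLabel)) ring[!maskArray(structures, oarLabel)] <- 0L
  array(as.integer(ring), dim = dim(distanceMap))
}
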