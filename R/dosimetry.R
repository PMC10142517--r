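#' Dose at an absolute volume (DVH metric)
#'
#' The largest dose level D such that at least `vCc` cm3 of the structure
#' receives >= D — e.g. `vCc = 2` gives D2cm3, the dose to the hottest
#' 2 cm3. Voxel doses are sorted in descending order and the cumulative-
#' volume DVH is interpolated linearly between voxel dose levels, which
#' removes voxel-quantization jumps.
#'
#' @param dose a [DoseGrid-class].
#' @param mask logical (or 0/1) 3D array on the same lattice.
#' @param vCc volume in cm3; must satisfy `0 < vCc <=` mask volume.
#' @return dose in Gy.
#' @examples
#' g <- voxelGrid(c(10, 10, 10), spacing = c(10, 10, 10)) # 1 cm3 voxels
#' dg <- doseGrid(g, array(7, gridShape(g)))
#' doseAtVolume(dg, array(TRUE, gridShape(g)), vCc = 2) # uniform: 7 Gy
#' @export
doseAtVolume <- function(dose, mask, vCc) {
  stopifnot(is(dose, "DoseGrid"))
  if (!is.logical(mask)) mask <- mask != 0
  if (!identical(dim(mask), gridShape(dose@grid)))
    stop("mask dims do not match the dose lattice")
  n <- sum(mask)
  if (n == 0L) stop("mask is empty")
  vv <- voxelVolumeCc(dose@grid)
  total <- n * vv
  if (!is.finite(vCc) || vCc <= 0) stop("vCc must be > 0")
  if (vCc > total * (1 + 1e-9))
    stop("requested volume ", vCc, " cm3 exceeds the mask volume ",
         signif(total, 6), " cm3")
  d <- sort(doseArray(dose)[mask], decreasing = TRUE)
  if (n == 1L) return(d)
  cum <- vv * seq_len(n)
  if (vCc <= cum[1L]) return(d[1L])
  stats::approx(cum, d, xout = min(vCc, total), rule = 2, ties = "ordered")$y
}

#' Dose at a volume fraction (DVH metric)
#'
#' `doseAtVolume` with `vCc = fraction * (mask volume)`; `fraction = 0.9` on
#' the HR-CTV gives D90, the dose covering 90% of the target.
#'
#' @inheritParams doseAtVolume
#' @param fraction volume fraction in (0, 1].
#' @return dose in Gy.
#' @export
doseAtVolumeFraction <- function(dose, mask, fraction) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (!is.logical(mask)) mask <- mask != 0
  total <- sum(mask) * voxelVolumeCc(dose@grid)
  doseAtVolume(dose, mask, fraction * total)
}

#' Equivalent dose in 2-Gy fractions (EQD2)
#'
#' Linear-quadratic conversion
#' `EQD2 = total * (d + alpha/beta) / (2 + alpha/beta)` where `d` is the
#' dose per fraction and alpha/beta the tissue fractionation sensitivity
#' (Gy; convention: 10 for tumor targets, 3 for late-responding OARs).
#'
#' @param totalDoseGy total physical dose (Gy), > 0.
#' @param dosePerFractionGy dose per fraction (Gy), > 0.
#' @param alphaBetaGy alpha/beta ratio (Gy), > 0.
#' @return EQD2 in Gy.
#' @examples
#' eqd2(30, 6, 10) # 40 Gy
#' @export
eqd2 <- function(totalDoseGy, dosePerFractionGy, alphaBetaGy) {
  if (any(!is.finite(c(totalDoseGy, dosePerFractionGy, alphaBetaGy))) ||
      any(c(totalDoseGy, dosePerFractionGy, alphaBetaGy) <= 0))
    stop("all EQD2 arguments must be finite and > 0")
  totalDoseGy * (dosePerFractionGy + alphaBetaGy) / (2 + alphaBetaGy)
}

#' Audit a plan against clinical EQD2 constraints
#'
#' Pass/fail report for the standard planning aims: HR-CTV D90 EQD2 >= 85 Gy;
#' bladder D2cm3 EQD2 <= 90 Gy; rectum and sigmoid D2cm3 EQD2 <= 75 Gy.
#' Limits are inclusive and configurable.
#'
#' @param hrctvD90Eqd2,bladderD2ccEqd2,rectumD2ccEqd2,sigmoidD2ccEqd2
#'   EQD2 values in Gy.
#' @param limits named numeric vector of limits (Gy); names `hrctv`,
#'   `bladder`, `rectum`, `sigmoid`.
#' @return data.frame with columns structure, value_eqd2_gy, limit_eqd2_gy,
#'   direction, pass.
#' @export
checkPlanConstraints <- function(hrctvD90Eqd2, bladderD2ccEqd2,
                                 rectumD2ccEqd2, sigmoidD2ccEqd2,
                                 limits = c(hrctv = 85, bladder = 90,
                                            rectum = 75, sigmoid = 75)) {
  vals <- c(hrctv = hrctvD90Eqd2, bladder = bladderD2ccEqd2,
            rectum = rectumD2ccEqd2, sigmoid = sigmoidD2ccEqd2)
  if (any(!is.finite(vals))) stop("all EQD2 values must be finite")
  dirs <- c(hrctv = ">=", bladder = "<=", rectum = "<=", sigmoid = "<=")
  pass <- ifelse(dirs == ">=", vals >= limits[names(vals)],
                 vals <= limits[names(vals)])
  data.frame(structure = names(vals), value_eqd2_gy = unname(vals),
             limit_eqd2_gy = unname(limits[names(vals)]),
             direction = unname(dirs), pass = unname(pass),
             stringsAsFactors = FALSE)
}

#' DVH metric pair for one plan structure
#'
#' Convenience wrapper computing the OAR D2cm3, the target D90 and their
#' scale-free ratio D2cm3/D90, the model's prediction target.
#'
#' @param dose a [DoseGrid-class].
#' @param structures a [StructureSet-class] on the same lattice.
#' @param oarLabel the OAR to evaluate.
#' @param vCc hot-spot volume, cm3 (default 2).
#' @param fraction target coverage fraction (default 0.9).
#' @return list with `d2cc_gy`, `d90_gy`, `ratio`.
#' @export
dvhMetrics <- function(dose, structures, oarLabel, vCc = 2, fraction = 0.9) {
  if (!sameGrid(dose@grid, structureGrid(structures)))
    stop("dose and structures are on different lattices")
  d2 <- doseAtVolume(dose, maskArray(structures, oarLabel), vCc)
  d90 <- doseAtVolumeFraction(dose, maskArray(structures, "hrctv"), fraction)
  list(d2cc_gy = d2, d90_gy = d90, ratio = d2 / d90)
}
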