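#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ringdose, .registration = TRUE
NULL

OAR_LABELS <- c("bladder", "rectum", "sigmoid")
STRUCTURE_LABELS <- c("hrctv", OAR_LABELS)

#' VoxelGrid: a regular 3D voxel lattice
#'
#' Describes the common lattice that all masks and dose grids of one plan
#' share: array shape, anisotropic voxel spacing in mm and the world
#' coordinate (mm) of the first voxel's center. Voxel values are located at
#' voxel centers; the center of 0-based index `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`.
#'
#' @slot shape integer(3), array dimensions (all >= 1).
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), world coordinate of the first voxel center (mm).
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
      return("shape must be 3 integers, all >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive reals (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite reals (mm)")
    TRUE
  }
)

#' Construct a VoxelGrid
#'
#' @param shape integer(3) array dimensions.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world coordinate of the first voxel center (mm);
#'   the default centers the lattice on the world origin.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(c(96, 96, 96), spacing = c(2, 2, 2))
#' voxelVolumeCc(g)
#' @export
voxelGrid <- function(shape, spacing = c(2, 2, 2), origin = NULL) {
  shape <- as.integer(shape)
  if (is.null(origin)) origin <- -(shape - 1L) * spacing / 2
  new("VoxelGrid", shape = shape, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn voxelGrid Volume of one voxel in cm3.
#' @param grid a [VoxelGrid-class].
#' @export
voxelVolumeCc <- function(grid) prod(grid@spacing) / 1000

#' @describeIn voxelGrid Array dimensions.
#' @export
gridShape <- function(grid) grid@shape

#' @describeIn voxelGrid Voxel spacing (mm).
#' @export
gridSpacing <- function(grid) grid@spacing

#' @describeIn voxelGrid World coordinate of the first voxel center (mm).
#' @export
gridOrigin <- function(grid) grid@origin

#' @describeIn voxelGrid Per-axis vectors of voxel-center coordinates (mm).
#' @export
gridAxes <- function(grid) {
  lapply(1:3, function(a) grid@origin[a] + (seq_len(grid@shape[a]) - 1) *
           grid@spacing[a])
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@shape, collapse = " x "),
      "voxels @", paste(object@spacing, collapse = " x "), "mm\n")
  cat("  origin (mm):", paste(signif(object@origin, 5), collapse = ", "),
      "| voxel volume:", signif(voxelVolumeCc(object), 5), "cm3\n")
})

sameGrid <- function(a, b, tol = 1e-9) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacing - b@spacing) < tol) &&
    all(abs(a@origin - b@origin) < tol)
}

#' StructureSet: binary masks on a shared lattice
#'
#' Holds the HR-CTV (high-risk clinical target volume) and OAR (bladder,
#' rectum, sigmoid colon) segmentation masks of one brachytherapy fraction
#' plan, all voxelized on one [VoxelGrid-class].
#'
#' @slot grid the shared [VoxelGrid-class].
#' @slot masks named list of logical 3D arrays; names from
#'   `c("hrctv", "bladder", "rectum", "sigmoid")`; `hrctv` mandatory and
#'   nonempty.
#' @export
setClass("StructureSet",
  representation(grid = "VoxelGrid", masks = "list"),
  validity = function(object) {
    nm <- names(object@masks)
    if (is.null(nm) || !"hrctv" %in% nm)
      return("masks must be a named list containing 'hrctv'")
    bad <- setdiff(nm, STRUCTURE_LABELS)
    if (length(bad))
      return(paste0("unknown structure label(s): ", paste(bad, collapse = ", ")))
    for (label in nm) {
      m <- object@masks[[label]]
      if (!is.logical(m) || !identical(dim(m), object@grid@shape))
        return(paste0("mask '", label, "' must be a logical array on the grid"))
    }
    if (!any(object@masks[["hrctv"]]))
      return("hrctv mask is empty")
    TRUE
  }
)

#' Construct a StructureSet
#'
#' @param grid a [VoxelGrid-class].
#' @param masks named list of logical (or 0/1) arrays with dims equal to
#'   `gridShape(grid)`; must contain a nonempty `hrctv`.
#' @return A [StructureSet-class].
#' @export
structureSet <- function(grid, masks) {
  masks <- lapply(masks, function(m) {
    if (!is.logical(m)) {
      v <- unique(as.vector(m))
      if (!all(v %in% c(0, 1)))
        stop("mask values must be 0/1; found: ",
             paste(utils::head(setdiff(v, c(0, 1)), 3), collapse = ", "))
      m <- array(m != 0, dim = dim(m))
    }
    m
  })
  new("StructureSet", grid = grid, masks = masks)
}

#' @describeIn structureSet Labels of the structures present.
#' @param x a [StructureSet-class].
#' @export
structureLabels <- function(x) names(x@masks)

#' @describeIn structureSet Extract one mask as a logical array.
#' @param label structure label.
#' @export
maskArray <- function(x, label) {
  if (!label %in% names(x@masks)) stop("no mask with label '", label, "'")
  x@masks[[label]]
}

#' @describeIn structureSet Volume of one structure in cm3.
#' @export
structureVolumeCc <- function(x, label)
  sum(maskArray(x, label)) * voxelVolumeCc(x@grid)

#' @describeIn structureSet The shared lattice.
#' @export
structureGrid <- function(x) x@grid

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet on", paste(object@grid@shape, collapse = " x "),
      "grid @", paste(object@grid@spacing, collapse = " x "), "mm\n")
  for (label in names(object@masks))
    cat(sprintf("  %-8s %8.2f cm3 (%d voxels)\n", label,
                structureVolumeCc(object, label), sum(object@masks[[label]])))
})

#' DwellPlan: source dwell positions and weights
#'
#' One fraction's dwell configuration: a tandem line through the HR-CTV plus
#' straight intratumoral needle tracks, each dwell carrying a relative
#' emission weight.
#'
#' @slot positions numeric matrix (n x 3), dwell centers in world mm.
#' @slot weights nonnegative relative emission strengths, one per dwell.
#' @slot nNeedles integer in \[2, 8\], number of needles (tandem excluded).
#' @slot prescriptionGy prescription dose per fraction, 6 or 7 Gy.
#' @export
setClass("DwellPlan",
  representation(positions = "matrix", weights = "numeric",
                 nNeedles = "integer", prescriptionGy = "numeric"),
  validity = function(object) {
    if (ncol(object@positions) != 3L) return("positions must be n x 3")
    if (nrow(object@positions) != length(object@weights))
      return("positions and weights lengths differ")
    if (any(object@weights < 0) || any(!is.finite(object@weights)))
      return("weights must be finite and nonnegative")
    if (object@nNeedles < 2L || object@nNeedles > 8L)
      return("nNeedles must lie in [2, 8]")
    if (!object@prescriptionGy %in% c(6, 7))
      return("prescriptionGy must be 6 or 7 Gy")
    TRUE
  }
)

#' @rdname DwellPlan-class
#' @param x a `DwellPlan`.
#' @export
dwellPositions <- function(x) x@positions

#' @rdname DwellPlan-class
#' @export
dwellWeights <- function(x) x@weights

#' @rdname DwellPlan-class
#' @export
nNeedles <- function(x) x@nNeedles

#' @rdname DwellPlan-class
#' @export
prescriptionGy <- function(x) x@prescriptionGy

setMethod("show", "DwellPlan", function(object) {
  cat("DwellPlan:", nrow(object@positions), "dwells,",
      object@nNeedles, "needles,", object@prescriptionGy, "Gy/fraction\n")
})

#' DoseGrid: a dose distribution on a voxel lattice
#'
#' @slot grid the [VoxelGrid-class] the dose lives on.
#' @slot doseGy numeric 3D array of absorbed dose in Gy, finite and >= 0.
#' @export
setClass("DoseGrid",
  representation(grid = "VoxelGrid", doseGy = "array"),
  validity = function(object) {
    if (!identical(dim(object@doseGy), object@grid@shape))
      return("dose array dims must match the grid shape")
    if (any(!is.finite(object@doseGy)) || any(object@doseGy < 0))
      return("dose values must be finite and >= 0")
    TRUE
  }
)

#' Construct a DoseGrid
#' @param grid a [VoxelGrid-class].
#' @param doseGy numeric 3D array of dose in Gy.
#' @return A [DoseGrid-class].
#' @export
doseGrid <- function(grid, doseGy) new("DoseGrid", grid = grid, doseGy = doseGy)

#' @describeIn doseGrid The dose array (Gy).
#' @param x a [DoseGrid-class].
#' @export
doseArray <- function(x) x@doseGy

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid on", paste(object@grid@shape, collapse = " x "),
      "grid; dose range", signif(min(object@doseGy), 4), "-",
      signif(max(object@doseGy), 4), "Gy\n")
})

#' SubOrganDecomposition: ring-shell decomposition of one OAR
#'
#' The result of intersecting an OAR with the exterior distance rings of the
#' HR-CTV: ring k collects OAR voxels whose Euclidean distance d to the
#' HR-CTV satisfies (k-1)w < d <= kw (ring width w, default 3 mm). Normalized
#' ring volumes (ring volume divided by the whole OAR volume) are the model's
#' geometric features. OAR voxels at nonpositive distance (inside the HR-CTV)
#' are booked separately as `insideVolumeCc`; voxels beyond the last ring as
#' `farVolumeCc`.
#'
#' @slot oarLabel which OAR was decomposed.
#' @slot ringWidthMm ring width in mm (default 3).
#' @slot nRings number of rings (<= 15).
#' @slot ringVolumesCc absolute ring volumes, cm3, length `nRings`.
#' @slot normalizedVolumes ring volumes / OAR volume, each in \[0, 1\].
#' @slot oarVolumeCc total OAR volume, cm3 (> 0).
#' @slot hrctvVolumeCc HR-CTV volume, cm3 (> 0).
#' @slot insideVolumeCc OAR volume at distance 0 (inside HR-CTV), cm3.
#' @slot farVolumeCc OAR volume beyond ring `nRings`, cm3.
#' @export
setClass("SubOrganDecomposition",
  representation(oarLabel = "character", ringWidthMm = "numeric",
                 nRings = "integer", ringVolumesCc = "numeric",
                 normalizedVolumes = "numeric", oarVolumeCc = "numeric",
                 hrctvVolumeCc = "numeric", insideVolumeCc = "numeric",
                 farVolumeCc = "numeric"),
  validity = function(object) {
    if (object@nRings < 1L || object@nRings > 15L)
      return("nRings must lie in [1, 15]")
    if (length(object@ringVolumesCc) != object@nRings ||
        length(object@normalizedVolumes) != object@nRings)
      return("ring vectors must have length nRings")
    if (object@oarVolumeCc <= 0) return("oarVolumeCc must be > 0")
    if (object@hrctvVolumeCc <= 0) return("hrctvVolumeCc must be > 0")
    if (any(object@normalizedVolumes < 0) || any(object@normalizedVolumes > 1))
      return("normalized volumes must lie in [0, 1]")
    tot <- sum(object@ringVolumesCc) + object@insideVolumeCc +
      object@farVolumeCc
    if (abs(tot - object@oarVolumeCc) > 1e-6 * max(1, object@oarVolumeCc))
      return("ring + inside + far volumes must sum to the OAR volume")
    TRUE
  }
)

#' @rdname SubOrganDecomposition-class
#' @param x a `SubOrganDecomposition`.
#' @export
normalizedVolumes <- function(x) x@normalizedVolumes

#' @rdname SubOrganDecomposition-class
#' @export
ringVolumesCc <- function(x) x@ringVolumesCc

#' @rdname SubOrganDecomposition-class
#' @export
oarVolumeCc <- function(x) x@oarVolumeCc

#' @rdname SubOrganDecomposition-class
#' @export
hrctvVolumeCc <- function(x) x@hrctvVolumeCc

setMethod("show", "SubOrganDecomposition", function(object) {
  cat("SubOrganDecomposition of", object@oarLabel, "(",
      object@nRings, "rings x", object@ringWidthMm, "mm )\n")
  cat("  OAR", signif(object@oarVolumeCc, 4), "cm3 | HR-CTV",
      signif(object@hrctvVolumeCc, 4), "cm3 | inside",
      signif(object@insideVolumeCc, 4), "| far",
      signif(object@farVolumeCc, 4), "\n")
  cat("  normalized:", paste(signif(object@normalizedVolumes, 3),
                             collapse = " "), "\n")
})

#' NetworkModel: one-hidden-layer tanh regression network
#'
#' The per-OAR D2cm3/D90 predictor: inputs are min-max scaled to \[-1, 1\],
#' passed through a tanh hidden layer, combined linearly, and the output is
#' mapped back through the inverse target scaling.
#'
#' @slot hiddenWeights h x d matrix.
#' @slot hiddenBias numeric(h).
#' @slot outputWeights numeric(h).
#' @slot outputBias numeric(1).
#' @slot inputScaler list(min, max) per input variable.
#' @slot targetScaler list(min, max) of the target.
#' @slot trained logical flag set by the trainer.
#' @export
setClass("NetworkModel",
  representation(hiddenWeights = "matrix", hiddenBias = "numeric",
                 outputWeights = "numeric", outputBias = "numeric",
                 inputScaler = "list", targetScaler = "list",
                 trained = "logical"),
  validity = function(object) {
    h <- nrow(object@hiddenWeights)
    d <- ncol(object@hiddenWeights)
    if (length(object@hiddenBias) != h) return("hiddenBias length != h")
    if (length(object@outputWeights) != h) return("outputWeights length != h")
    if (length(object@outputBias) != 1L) return("outputBias must be scalar")
    if (length(object@inputScaler$min) != d ||
        length(object@inputScaler$max) != d)
      return("inputScaler min/max must have length d")
    if (length(object@targetScaler$min) != 1L ||
        length(object@targetScaler$max) != 1L)
      return("targetScaler min/max must be scalars")
    TRUE
  }
)

#' @rdname NetworkModel-class
#' @param x a `NetworkModel`.
#' @export
hiddenSize <- function(x) nrow(x@hiddenWeights)

#' @rdname NetworkModel-class
#' @export
inputSize <- function(x) ncol(x@hiddenWeights)

#' @rdname NetworkModel-class
#' @export
isTrained <- function(x) isTRUE(x@trained)

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", inputSize(object), "inputs ->", hiddenSize(object),
      "tanh units -> 1 linear output;",
      if (isTrained(object)) "trained" else "untrained", "\n")
})

#' FitReport: per-split accuracy of one OAR model
#'
#' Regression R and MSE per split (train/validation/test/all), mean and SD
#' of the absolute prediction difference of the D2cm3/D90 ratio, and the
#' paired t test between predicted and planned ratios over all sets.
#'
#' @slot oarLabel which OAR the report covers.
#' @slot metrics data.frame with columns set, n, r, mse, delta_mean, delta_sd.
#' @slot tStat paired t statistic over all sets.
#' @slot pValue two-sided p of the paired t test.
#' @export
setClass("FitReport",
  representation(oarLabel = "character", metrics = "data.frame",
                 tStat = "numeric", pValue = "numeric"),
  validity = function(object) {
    need <- c("set", "n", "r", "mse", "delta_mean", "delta_sd")
    if (!all(need %in% names(object@metrics)))
      return("metrics must have columns set, n, r, mse, delta_mean, delta_sd")
    ok <- is.na(object@metrics$r) | abs(object@metrics$r) <= 1 + 1e-12
    if (!all(ok)) return("r values must lie in [-1, 1]")
    if (any(object@metrics$mse < 0)) return("mse must be >= 0")
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  }
)

#' @rdname FitReport-class
#' @param x a `FitReport`.
#' @export
fitMetrics <- function(x) x@metrics

setMethod("show", "FitReport", function(object) {
  cat("FitReport (", object@oarLabel, ")\n", sep = "")
  m <- object@metrics
  cat(sprintf("  %-11s %4s %8s %11s %9s %9s\n",
              "set", "n", "R", "MSE", "d.mean", "d.sd"))
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-11s %4d %8.5f %11.3e %9.4f %9.4f\n",
                m$set[i], m$n[i], m$r[i], m$mse[i],
                m$delta_mean[i], m$delta_sd[i]))
  cat(sprintf("  paired t (all sets): t = %.4f, p = %.4f\n",
              object@tStat, object@pValue))
})
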