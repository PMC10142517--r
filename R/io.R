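#' Write a volume as NIfTI
#'
#' Stores a 3D array on a [VoxelGrid-class] with the lattice metadata
#' (spacing via pixdim, origin via the qform/sform offset) in the header.
#'
#' @param path output file (`.nii` or `.nii.gz`).
#' @param grid the [VoxelGrid-class].
#' @param values numeric or logical 3D array matching the grid shape.
#' @return the path, invisibly.
#' @export
writeVolume <- function(path, grid, values) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!identical(dim(values), gridShape(grid)))
    stop("values dims do not match the grid shape")
  storage.mode(values) <- "double"
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(gridSpacing(grid))
  affine[1:3, 4] <- gridOrigin(grid)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- gridSpacing(grid)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume
#'
#' Recovers the array and its lattice; with `mask = TRUE` values are checked
#' to be 0/1 and returned as a logical array.
#'
#' @param path NIfTI file.
#' @param mask enforce 0/1 values and return logical.
#' @return list with `grid` (a [VoxelGrid-class]) and `values`.
#' @export
readVolume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D data")
  affine <- RNifti::xform(img)
  if (any(abs(affine[1:3, 1:3] - diag(diag(affine[1:3, 1:3]))) > 1e-6) ||
      any(diag(affine[1:3, 1:3]) <= 0))
    stop("unsupported NIfTI orientation: expected an axis-aligned, ",
         "positively oriented lattice")
  spacing <- diag(affine[1:3, 1:3])
  origin <- affine[1:3, 4]
  vals <- as.array(img)
  grid <- voxelGrid(dim(vals), spacing, origin)
  if (mask) {
    u <- unique(as.vector(vals))
    bad <- setdiff(u, c(0, 1))
    if (length(bad))
      stop("mask file contains non-binary value(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
    vals <- array(vals != 0, dim = dim(vals))
  }
  list(grid = grid, values = vals)
}

#' Write / read a cohort CSV
#'
#' Round-trip-stable CSV with the [cohortColumns()] schema; the header is
#' name-keyed, so column permutations are accepted on read.
#'
#' @param path CSV file.
#' @param cohort cohort `data.frame`.
#' @param nRings rings per OAR expected in the schema.
#' @return `writeCohort`: the path, invisibly; `readCohort`: the cohort
#'   `data.frame` in canonical column order.
#' @export
writeCohort <- function(path, cohort, nRings = 15L) {
  missing <- setdiff(cohortColumns(nRings), names(cohort))
  if (length(missing))
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(cohort[, cohortColumns(nRings)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, nRings = 15L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  want <- cohortColumns(nRings)
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  numeric_cols <- setdiff(want, c("plan_id", "patient_id"))
  for (cn in numeric_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell at row ", bad[1], ", column '", cn, "'")
      df[[cn]] <- coerced
    }
  }
  df[, want]
}

#' Serialize / load a trained network as JSON
#'
#' Stores weights, scalers, architecture and any extra metadata (per-restart
#' log, config) in a plain-text JSON file.
#'
#' @param model a [NetworkModel-class].
#' @param path JSON file.
#' @param extra optional named list stored alongside the model.
#' @return `writeModelJson`: the path, invisibly; `readModelJson`: a list
#'   with `model` and `extra`.
#' @export
writeModelJson <- function(model, path, extra = list()) {
  stopifnot(is(model, "NetworkModel"))
  obj <- list(architecture = list(inputs = inputSize(model),
                                  hidden = hiddenSize(model),
                                  activation = "tanh"),
              hidden_weights = model@hiddenWeights,
              hidden_bias = model@hiddenBias,
              output_weights = model@outputWeights,
              output_bias = model@outputBias,
              input_scaler = model@inputScaler,
              target_scaler = model@targetScaler,
              trained = isTrained(model), extra = extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$architecture$hidden
  d <- obj$architecture$inputs
  model <- new("NetworkModel",
               hiddenWeights = matrix(as.numeric(t(obj$hidden_weights)),
                                      h, d, byrow = TRUE),
               hiddenBias = as.numeric(obj$hidden_bias),
               outputWeights = as.numeric(obj$output_weights),
               outputBias = as.numeric(obj$output_bias),
               inputScaler = list(min = as.numeric(obj$input_scaler$min),
                                  max = as.numeric(obj$input_scaler$max)),
               targetScaler = list(min = as.numeric(obj$target_scaler$min),
                                   max = as.numeric(obj$target_scaler$max)),
               trained = isTRUE(obj$trained))
  list(model = model, extra = obj$extra)
}
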