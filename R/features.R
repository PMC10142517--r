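#' Cohort table column names
#'
#' The documented CSV schema: identifiers, prescription, HR-CTV geometry and
#' D90, then per OAR its volume, inside-target volume, D2cm3, the D2cm3/D90
#' target and the `nRings` normalized ring volumes (`<oar>_ring01` ...).
#'
#' @param nRings rings per OAR (default 15).
#' @return character vector of column names in canonical order.
#' @export
cohortColumns <- function(nRings = 15L) {
  perOar <- function(oar) c(paste0(oar, "_volume_cc"),
                            paste0(oar, "_inside_cc"),
                            paste0(oar, "_d2cc_gy"),
                            paste0(oar, "_ratio"),
                            sprintf("%s_ring%02d", oar, seq_len(nRings)))
  c("plan_id", "patient_id", "prescription_gy", "n_needles",
    "hrctv_volume_cc", "d90_gy", unlist(lapply(OAR_LABELS, perOar)))
}

#' Assemble one plan record
#'
#' Combines the three OAR ring decompositions and DVH metric sets of one
#' plan into a single cohort row with the fixed feature ordering (ring 1..15
#' then HR-CTV volume); decompositions with fewer rings are zero-padded.
#'
#' @param decomps named list of [SubOrganDecomposition-class] objects for
#'   `bladder`, `rectum`, `sigmoid`.
#' @param metrics named list of [dvhMetrics()] results for the same OARs.
#' @param planId,patientId identifiers.
#' @param prescriptionGy prescription dose per fraction (Gy).
#' @param nNeedles needle count of the plan.
#' @param nRings feature vector ring count (default 15).
#' @return one-row `data.frame` following [cohortColumns()].
#' @export
assemblePlanRecord <- function(decomps, metrics, planId, patientId,
                               prescriptionGy, nNeedles = NA_integer_,
                               nRings = 15L) {
  if (!all(OAR_LABELS %in% names(decomps)) ||
      !all(OAR_LABELS %in% names(metrics)))
    stop("decomps and metrics must be named lists covering bladder, ",
         "rectum and sigmoid")
  hrv <- vapply(decomps, function(d) d@hrctvVolumeCc, numeric(1))
  if (diff(range(hrv)) > 1e-9 * max(hrv))
    stop("inconsistent HR-CTV volumes across the decompositions of one plan")
  d90 <- vapply(metrics, function(m) m$d90_gy, numeric(1))
  if (diff(range(d90)) > 1e-9 * max(d90))
    stop("inconsistent D90 across the metric sets of one plan")

  row <- data.frame(plan_id = planId, patient_id = patientId,
                    prescription_gy = prescriptionGy,
                    n_needles = as.integer(nNeedles),
                    hrctv_volume_cc = hrv[[1]], d90_gy = d90[[1]],
                    stringsAsFactors = FALSE)
  for (oar in OAR_LABELS) {
    d <- decomps[[oar]]
    m <- metrics[[oar]]
    v <- numeric(nRings)
    v[seq_len(min(d@nRings, nRings))] <-
      d@normalizedVolumes[seq_len(min(d@nRings, nRings))]
    row[[paste0(oar, "_volume_cc")]] <- d@oarVolumeCc
    row[[paste0(oar, "_inside_cc")]] <- d@insideVolumeCc
    row[[paste0(oar, "_d2cc_gy")]] <- m$d2cc_gy
    row[[paste0(oar, "_ratio")]] <- m$ratio
    for (k in seq_len(nRings))
      row[[sprintf("%s_ring%02d", oar, k)]] <- v[k]
  }
  row[, cohortColumns(nRings)]
}

#' Model feature matrix and target for one OAR
#'
#' Extracts the fixed 16-column feature block (15 normalized ring volumes
#' then the HR-CTV volume in cm3) and the D2cm3/D90 target for one OAR from
#' a cohort table. The own-OAR volume can be appended as an optional 17th
#' feature.
#'
#' @param cohort cohort `data.frame`.
#' @param oarLabel one of `"bladder"`, `"rectum"`, `"sigmoid"`.
#' @param nRings rings per OAR in the table (default 15).
#' @param includeOarVolume append the OAR volume as an extra feature.
#' @return list with `features` (matrix) and `target` (numeric).
#' @export
cohortFeatures <- function(cohort, oarLabel, nRings = 15L,
                           includeOarVolume = FALSE) {
  ringCols <- sprintf("%s_ring%02d", oarLabel, seq_len(nRings))
  cols <- c(ringCols, "hrctv_volume_cc")
  if (includeOarVolume) cols <- c(cols, paste0(oarLabel, "_volume_cc"))
  missing <- setdiff(c(cols, paste0(oarLabel, "_ratio")), names(cohort))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  list(features = as.matrix(cohort[, cols]),
       target = cohort[[paste0(oarLabel, "_ratio")]])
}

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation between two vectors with the p value from the
#' t transform of r on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return list with `r` and `p`.
#' @examples
#' pearsonR(1:10, (1:10) * 2 + 1)$r # 1
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson r is undefined for a constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cohort correlation report
#'
#' For each OAR's D2cm3/D90 target, the Pearson correlation against the
#' HR-CTV volume, the own-OAR volume and every normalized sub-organ volume,
#' with significance marked at the bilateral 0.01 level.
#'
#' @param cohort cohort `data.frame` with >= 3 rows.
#' @param nRings rings per OAR (default 15).
#' @return `data.frame` with columns target, predictor, r, p, significant;
#'   cells where r is undefined (constant predictor) carry `NA`.
#' @export
correlationReport <- function(cohort, nRings = 15L) {
  if (nrow(cohort) < 3L) stop("need at least 3 plans")
  out <- list()
  for (oar in OAR_LABELS) {
    target <- cohort[[paste0(oar, "_ratio")]]
    preds <- c(hrctv_volume = "hrctv_volume_cc",
               stats::setNames(paste0(oar, "_volume_cc"), "oar_volume"),
               stats::setNames(sprintf("%s_ring%02d", oar, seq_len(nRings)),
                               sprintf("ring%02d", seq_len(nRings))))
    for (nm in names(preds)) {
      res <- tryCatch(pearsonR(cohort[[preds[[nm]]]], target),
                      error = function(e) list(r = NA_real_, p = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        target = paste0(oar, "_ratio"), predictor = nm,
        r = res$r, p = res$p,
        significant = !is.na(res$p) & res$p < 0.01,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Format a correlation report as a text table
#'
#' Wide layout: one row per OAR target, one column per predictor, entries
#' `r` with an asterisk marking significance at the 0.01 level.
#'
#' @param report output of [correlationReport()].
#' @return character vector of formatted lines (also printed).
#' @export
formatCorrelationReport <- function(report) {
  preds <- unique(report$predictor)
  targets <- unique(report$target)
  lines <- paste(c(sprintf("%-22s", "D2cm3/D90"),
                   sprintf("%10s", preds)), collapse = "")
  for (tg in targets) {
    sub <- report[report$target == tg, ]
    cells <- vapply(preds, function(p) {
      row <- sub[sub$predictor == p, ]
      if (!nrow(row) || is.na(row$r)) return(sprintf("%10s", "."))
      sprintf("%9.3f%s", row$r, ifelse(row$significant, "*", " "))
    }, character(1))
    lines <- c(lines, paste(c(sprintf("%-22s", tg), cells), collapse = ""))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
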