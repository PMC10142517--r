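#' Regression R and mean squared error
#'
#' The two headline accuracy measures of the predictor: the Pearson
#' correlation between outputs and targets (R of 1 = close relationship, 0 =
#' random) and the mean squared difference (0 = no error). With a constant
#' target, R is undefined and returned as `NA` while the MSE is still
#' computed.
#'
#' @param predicted,actual numeric vectors of equal length >= 2.
#' @return list with `r` and `mse`.
#' @export
regressionMetrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  if (length(predicted) < 2L) stop("need at least 2 pairs")
  mse <- mean((predicted - actual)^2)
  r <- if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    NA_real_ else stats::cor(predicted, actual)
  list(r = r, mse = mse)
}

#' Mean and SD of the absolute prediction difference
#'
#' `delta = |actual - predicted|` of the D2cm3/D90 ratio, summarized as its
#' mean and sample (n-1) standard deviation.
#'
#' @inheritParams regressionMetrics
#' @return list with `mean` and `sd`.
#' @export
deltaStats <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  if (length(predicted) < 2L) stop("need at least 2 pairs")
  d <- abs(actual - predicted)
  list(mean = mean(d), sd = stats::sd(d))
}

#' Paired t test between predicted and planned values
#'
#' `t = mean(diff) / (sd(diff) / sqrt(n))` with the two-sided p value from
#' the t distribution on n - 1 degrees of freedom.
#'
#' @inheritParams regressionMetrics
#' @return list with `t` and `p`.
#' @export
pairedTTest <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("lengths differ")
  if (length(predicted) < 2L) stop("need at least 2 pairs")
  if (stats::sd(predicted - actual) == 0)
    stop("paired t is undefined for zero-variance differences")
  tt <- stats::t.test(predicted, actual, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' QA gate on the predicted vs planned dose ratio
#'
#' Flags a plan when the absolute difference between the model-predicted and
#' the planned D2cm3/D90 exceeds the threshold (strictly); flagged rows
#' carry the recommendation that the plan should be further optimized.
#' Vectorized for batch mode.
#'
#' @param predictedRatio,plannedRatio numeric vectors (recycled to common
#'   length).
#' @param threshold positive flagging threshold on the ratio (default 0.10).
#' @return `data.frame` with columns predicted, planned, abs_diff, flagged,
#'   recommendation.
#' @export
qaCheck <- function(predictedRatio, plannedRatio, threshold = 0.10) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  n <- max(length(predictedRatio), length(plannedRatio))
  predicted <- rep_len(predictedRatio, n)
  planned <- rep_len(plannedRatio, n)
  d <- abs(predicted - planned)
  flagged <- d > threshold
  data.frame(predicted = predicted, planned = planned, abs_diff = d,
             flagged = flagged,
             recommendation = ifelse(
               flagged, "plan should be further optimized", "within threshold"),
             stringsAsFactors = FALSE)
}

#' Per-split fit report of one OAR model
#'
#' Computes regression R, MSE and the absolute-difference statistics on the
#' train, validation, test and pooled sets, plus the paired t test between
#' predicted and planned ratios over all sets.
#'
#' @param oarLabel label carried into the report.
#' @param predicted,actual ratio vectors over all rows.
#' @param split a [makeSplit()] assignment over the rows.
#' @return a [FitReport-class].
#' @export
fitReport <- function(oarLabel, predicted, actual, split) {
  sets <- list(training = split$train, validation = split$val,
               test = split$test,
               all = sort(c(split$train, split$val, split$test)))
  rows <- lapply(names(sets), function(nm) {
    i <- sets[[nm]]
    rm <- regressionMetrics(predicted[i], actual[i])
    ds <- deltaStats(predicted[i], actual[i])
    data.frame(set = nm, n = length(i), r = rm$r, mse = rm$mse,
               delta_mean = ds$mean, delta_sd = ds$sd,
               stringsAsFactors = FALSE)
  })
  allIdx <- sets$all
  tt <- tryCatch(pairedTTest(predicted[allIdx], actual[allIdx]),
                 error = function(e) list(t = NA_real_, p = NA_real_))
  new("FitReport", oarLabel = oarLabel, metrics = do.call(rbind, rows),
      tStat = tt$t, pValue = tt$p)
}

#' Evaluate a trained model on a cohort
#'
#' Predicts the D2cm3/D90 ratio for every cohort row of one OAR and wraps
#' the result in a [fitReport()].
#'
#' @param model a trained [NetworkModel-class].
#' @param cohort cohort `data.frame`.
#' @param oarLabel which OAR.
#' @param split a [makeSplit()] assignment.
#' @param nRings rings per OAR in the table.
#' @return list with `report` (a [FitReport-class]), `predicted`, `actual`.
#' @export
evaluateModel <- function(model, cohort, oarLabel, split, nRings = 15L) {
  fx <- cohortFeatures(cohort, oarLabel, nRings)
  predicted <- as.vector(nnForward(model, fx$features))
  list(report = fitReport(oarLabel, predicted, fx$target, split),
       predicted = predicted, actual = fx$target)
}
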