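#' Assemble a full run configuration
#'
#' One nested configuration object driving the whole pipeline: phantom
#' parameters, ring decomposition settings, DVH/EQD2 parameters and
#' constraint limits, training configuration and the QA threshold. Every
#' field has a documented default; a single top-level seed feeds every
#' stochastic stage.
#'
#' @param seed top-level seed.
#' @param nPlans cohort size (default 218).
#' @param phantom a [phantomParams()] list; its seed is overridden by
#'   `seed`.
#' @param rings list with `width_mm` (default 3) and `n_rings` (default 15).
#' @param dvh list with `alpha_beta_target` (Gy, default 10),
#'   `alpha_beta_oar` (Gy, default 3) and the EQD2 `limits` used by
#'   [checkPlanConstraints()].
#' @param training a [trainingConfig()]; its seed is derived from `seed`.
#' @param qa list with the QA `threshold` on the ratio (default 0.10).
#' @return nested list of class `RunConfig`.
#' @export
runConfig <- function(seed = 42L, nPlans = 218L,
                      phantom = phantomParams(),
                      rings = list(width_mm = 3, n_rings = 15L),
                      dvh = list(alpha_beta_target = 10, alpha_beta_oar = 3,
                                 limits = c(hrctv = 85, bladder = 90,
                                            rectum = 75, sigmoid = 75)),
                      training = trainingConfig(),
                      qa = list(threshold = 0.10)) {
  phantom$seed <- as.integer(seed)
  training$seed <- as.integer((as.numeric(seed) + 104729) %% 2147483647)
  cfg <- list(seed = as.integer(seed), nPlans = as.integer(nPlans),
              phantom = phantom, rings = rings, dvh = dvh,
              training = training, qa = qa)
  if (cfg$nPlans < 1L) stop("nPlans must be >= 1")
  if (cfg$rings$width_mm <= 0) stop("ring width must be > 0")
  if (cfg$qa$threshold <= 0) stop("QA threshold must be > 0")
  class(cfg) <- "RunConfig"
  cfg
}

flattenConfig <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flattenConfig(v, key))
    else out[[key]] <- v
  }
  out
}

#' Write / read a run configuration as a key-value text file
#'
#' Flat `section.key = value` lines (vectors comma-separated). On read,
#' values are laid over the defaults of [runConfig()]; unknown keys are
#' rejected.
#'
#' @param config a [runConfig()] object.
#' @param path text file.
#' @return `writeRunConfig`: the path, invisibly; `readRunConfig`: a
#'   `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  flat <- flattenConfig(unclass(config))
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    vs <- if (is.numeric(v) && !is.null(names(v)))
      paste(sprintf("%s:%s", names(v), format(v, digits = 17)),
            collapse = ", ")
    else paste(format(v, digits = 17, trim = TRUE), collapse = ", ")
    paste0(k, " = ", vs)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  base <- runConfig()
  known <- flattenConfig(unclass(base))
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  overrides <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("cannot parse config line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    kv <- c(ln, key, substr(ln, eq + 1, nchar(ln)))
    if (!key %in% names(known)) stop("unknown config key: ", key)
    raw <- trimws(strsplit(kv[3], ",")[[1]])
    tmpl <- known[[key]]
    val <- if (all(grepl(":", raw)) && !is.null(names(tmpl))) {
      parts <- strsplit(raw, ":")
      stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                      vapply(parts, `[`, "", 1))
    } else if (is.numeric(tmpl) || is.integer(tmpl)) {
      as.numeric(raw)
    } else raw
    if (is.integer(tmpl)) val <- as.integer(val)
    overrides[[key]] <- val
  }
  assignFlat <- function(cfg, key, value) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    expr <- cfg
    if (length(parts) == 1L) cfg[[parts]] <- value
    else if (length(parts) == 2L) cfg[[parts[1]]][[parts[2]]] <- value
    else cfg[[parts[1]]][[parts[2]]][[parts[3]]] <- value
    cfg
  }
  cfg <- unclass(base)
  for (key in names(overrides)) cfg <- assignFlat(cfg, key, overrides[[key]])
  # re-derive the dependent seeds from the (possibly overridden) top seed
  runConfig(seed = cfg$seed, nPlans = cfg$nPlans,
            phantom = structure(cfg$phantom, class = "PhantomParams"),
            rings = cfg$rings, dvh = cfg$dvh,
            training = structure(cfg$training, class = "TrainingConfig"),
            qa = cfg$qa)
}

#' Semantic hash of a run configuration
#'
#' MD5 of the canonical deparsed configuration; changes iff any semantic
#' field changes.
#'
#' @param config a `RunConfig`.
#' @return 32-character hash string.
#' @export
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(flattenConfig(unclass(config))), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full prediction pipeline
#'
#' Generate the synthetic cohort, decompose and tabulate it, split it
#' 70/15/15, train one network per OAR with the restart protocol, evaluate
#' every model and emit the QA report. Artifacts written to `outDir`:
#' `cohort.csv`, `model_<oar>.json` (weights + per-restart log),
#' `fit_reports.json`, `qa_report.csv`, `correlations.csv` and
#' `run_info.json` (config hash, seed, split sizes).
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if needed).
#' @param verbose print stage progress.
#' @return list with `cohort`, `split`, `models`, `reports`, `qa`,
#'   invisibly.
#' @export
runPipeline <- function(config, outDir, verbose = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  stamp <- list(config_hash = configHash(config), seed = config$seed)

  say("stage 1/4: generating ", config$nPlans, " phantom plans")
  cohort <- generateCohort(config$phantom, config$nPlans,
                           ringWidthMm = config$rings$width_mm,
                           nRings = config$rings$n_rings, verbose = verbose)
  writeCohort(file.path(outDir, "cohort.csv"), cohort,
              nRings = config$rings$n_rings)
  utils::write.csv(correlationReport(cohort, config$rings$n_rings),
                   file.path(outDir, "correlations.csv"), row.names = FALSE)

  split <- makeSplit(nrow(cohort), seed = config$seed)

  models <- list()
  reports <- list()
  qa <- list()
  for (oar in OAR_LABELS) {
    say("stage 2/4: training ", oar, " model (",
        config$training$nRestarts, " restarts)")
    fx <- cohortFeatures(cohort, oar, config$rings$n_rings)
    tcfg <- config$training
    tcfg$seed <- as.integer((as.numeric(tcfg$seed) +
                               match(oar, OAR_LABELS) * 7919) %% 2147483647)
    fit <- trainWithRestarts(fx$features, fx$target, split, tcfg)
    models[[oar]] <- fit$model
    writeModelJson(fit$model, file.path(outDir, paste0("model_", oar, ".json")),
                   extra = c(stamp, list(oar = oar, restarts = fit$summary,
                                         best_restart = fit$best)))
    ev <- evaluateModel(fit$model, cohort, oar, split, config$rings$n_rings)
    reports[[oar]] <- ev$report
    qa[[oar]] <- cbind(plan_id = cohort$plan_id, oar = oar,
                       qaCheck(ev$predicted, ev$actual, config$qa$threshold))
  }

  say("stage 3/4: writing fit reports")
  repJson <- lapply(reports, function(rp)
    list(metrics = fitMetrics(rp), paired_t = rp@tStat, p_value = rp@pValue))
  jsonlite::write_json(c(stamp, repJson),
                       file.path(outDir, "fit_reports.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  qaAll <- do.call(rbind, qa)
  rownames(qaAll) <- NULL
  utils::write.csv(qaAll, file.path(outDir, "qa_report.csv"),
                   row.names = FALSE)

  say("stage 4/4: run info")
  jsonlite::write_json(c(stamp, list(n_plans = nrow(cohort),
                                     split_sizes = lengths(split))),
                       file.path(outDir, "run_info.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(cohort = cohort, split = split, models = models,
                 reports = reports, qa = qaAll))
}
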