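#' Build a pipeline run configuration
#'
#' @param input_dir cohort directory to score (`NULL` to simulate instead).
#' @param output_dir where report artifacts are written.
#' @param simulation a `simulation_config` used when `input_dir` is `NULL`.
#' @param seed integer seed; overrides `simulation$seed` when given.
#' @param var_equal,ci_method analysis flags, see [analyze_cohort()].
#' @param make_plots write Bland-Altman and scatter plots (PNG).
#' @param write_cohort_dir also dump the simulated cohort (trial CSVs +
#'   manifest) under `output_dir/cohort/`.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, output_dir = "results",
                       simulation = simulation_config(), seed = NULL,
                       var_equal = FALSE, ci_method = "normal",
                       make_plots = TRUE, write_cohort_dir = FALSE,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!is.null(seed)) simulation$seed <- as.integer(seed)
  gs_check_scalar(simulation$duration, "duration")
  gs_check_scalar(simulation$sample_rate, "sample_rate")
  gs_check_scalar(simulation$period, "period")
  structure(as.list(environment()), class = "run_config")
}

gs_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

# analysis_report -> plain nested list for JSON serialization
report_to_list <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  c(list(schema_version = "1.0"), strip(unclass(report)))
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (full nested report, numbers at full precision)
#' plus flat CSV tables: `scores.csv` (group MAE summaries),
#' `improvement.csv` and `correlation_pairs.csv`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  sc <- report$scores
  rows <- Filter(Negate(is.null), sc)
  if (length(rows)) {
    utils::write.csv(
      data.frame(group = names(rows),
                 mean_mae = vapply(rows, `[[`, numeric(1), "mean"),
                 sd_mae = vapply(rows, `[[`, numeric(1), "sd"),
                 n = vapply(rows, `[[`, numeric(1), "n")),
      file.path(dir, "scores.csv"), row.names = FALSE)
  }
  if (!is.null(report$improvement$per_patient)) {
    utils::write.csv(report$improvement$per_patient,
                     file.path(dir, "improvement.csv"), row.names = FALSE)
  }
  if (!is.null(report$correlation)) {
    utils::write.csv(report$correlation$pairs,
                     file.path(dir, "correlation_pairs.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Structural validation of a report against the shipped schema
#'
#' Checks the deserialized report JSON for the required fields and types
#' declared in `inst/schema/analysis-report-schema.json`.
#'
#' @param report_list a list as read by `jsonlite::read_json`.
#' @return `TRUE` invisibly; aborts with a validation error otherwise.
#' @export
validate_report <- function(report_list) {
  need <- c("schema_version", "n_control", "n_patient", "scores",
            "improvement", "settings")
  missing <- setdiff(need, names(report_list))
  if (length(missing)) {
    gs_abort(sprintf("report lacks required field(s): %s",
                     paste(missing, collapse = ", ")), "gs_schema_error")
  }
  if (!is.numeric(report_list$n_control) ||
      !is.numeric(report_list$n_patient)) {
    gs_abort("report group sizes must be numeric", "gs_schema_error")
  }
  for (g in report_list$scores) {
    if (!is.null(g) && !all(c("mean", "sd", "n") %in% names(g))) {
      gs_abort("score summaries need mean/sd/n", "gs_schema_error")
    }
  }
  invisible(TRUE)
}

plot_report <- function(report, dir) {
  if (!capabilities("png")) return(invisible())
  if (!is.null(report$agreement) && !is.null(report$correlation)) {
    pairs <- report$correlation$pairs
    ag <- report$agreement
    grDevices::png(file.path(dir, "bland_altman.png"), width = 720,
                   height = 540)
    means <- (pairs$mae_fraction + pairs$odi) / 2
    diffs <- pairs$mae_fraction - pairs$odi
    graphics::plot(means, diffs, pch = 19,
                   xlab = "Mean of MAE fraction and ODI",
                   ylab = "MAE fraction - ODI",
                   main = "Bland-Altman agreement")
    graphics::abline(h = c(ag$bias, ag$loa_lower, ag$loa_upper),
                     lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
    grDevices::dev.off()

    grDevices::png(file.path(dir, "mae_vs_odi.png"), width = 720,
                   height = 540)
    graphics::plot(pairs$odi, pairs$mae_fraction,
                   pch = ifelse(pairs$outlier, 4, 19),
                   col = ifelse(pairs$outlier, "red", "black"),
                   xlab = "ODI index", ylab = "MAE fraction",
                   main = "Tracking error vs disability index")
    graphics::abline(report$correlation$regression$intercept,
                     report$correlation$regression$slope, col = "grey40")
    grDevices::dev.off()
  }
  invisible()
}

#' Run the full pipeline: simulate/load, score, analyze, report
#'
#' Stages run in a fixed order and each is logged.  On success the output
#' directory contains `report.json`, the CSV tables, optional plots, and a
#' `MANIFEST.json` recording the completion state of every stage; on
#' failure the partial outputs are retained and the MANIFEST names the
#' stage that failed.
#'
#' @param config a `run_config`.
#' @return the `analysis_report`, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  manifest_path <- file.path(config$output_dir, "MANIFEST.json")
  write_manifest <- function(status, error = NULL) {
    jsonlite::write_json(
      list(status = status, completed_stages = stages, error = error,
           seed = config$simulation$seed),
      manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  result <- tryCatch({
    if (is.null(config$input_dir)) {
      gs_log(config, "simulate: seed %d, %d controls + %d patients",
             config$simulation$seed, config$simulation$n_control,
             config$simulation$n_patient)
      dataset <- simulate_cohort(config$simulation)
    } else {
      gs_log(config, "load: %s", config$input_dir)
      dataset <- read_cohort(config$input_dir)
    }
    stages <- c(stages, "acquire")
    if (isTRUE(config$write_cohort_dir)) {
      write_cohort(dataset, file.path(config$output_dir, "cohort"))
      stages <- c(stages, "dump_cohort")
    }
    gs_log(config, "score: %d visits", length(dataset$visits))
    gs_log(config, "analyze: var_equal=%s, ci=%s", config$var_equal,
           config$ci_method)
    report <- analyze_cohort(dataset, var_equal = config$var_equal,
                             ci_method = config$ci_method)
    stages <- c(stages, "analyze")
    write_report(report, config$output_dir)
    stages <- c(stages, "report")
    if (isTRUE(config$make_plots)) {
      plot_report(report, config$output_dir)
      stages <- c(stages, "plots")
    }
    write_manifest("complete")
    gs_log(config, "done: %s", config$output_dir)
    report
  }, error = function(e) {
    write_manifest("failed", error = conditionMessage(e))
    stop(e)
  })
  invisible(result)
}
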