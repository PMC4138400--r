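# Readers/writers for the plain-text interchange formats: trial CSVs and
# the cohort manifest JSON.

TRIAL_HEADER <- c("t_s", "target_pct_mvc", "response_pct_mvc")

#' Read a tracking trial from CSV
#'
#' Expects the header `t_s,target_pct_mvc,response_pct_mvc`, one row per
#' sample, '.' decimal separator.  Row order is preserved and the trial
#' invariants (strictly increasing time, finite non-negative response) are
#' validated on read.
#'
#' @param path file path.
#' @param subject_id,visit_id,trial_index identifiers to stamp on the
#'   trial (not stored in the CSV itself).
#' @return a `tracking_trial`.
#' @export
read_trial_csv <- function(path, subject_id = "", visit_id = "",
                           trial_index = 1L) {
  if (!file.exists(path)) {
    gs_abort(sprintf("trial file not found: %s", path), "gs_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(TRIAL_HEADER, names(df))
  if (length(missing)) {
    gs_abort(sprintf("trial file %s lacks column(s): %s", path,
                     paste(missing, collapse = ", ")), "gs_format_error")
  }
  num <- lapply(TRIAL_HEADER, function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad)) {
      gs_abort(sprintf("non-numeric value in %s, column %s, row %d",
                       path, col, bad[1L]), "gs_parse_error")
    }
    v
  })
  tracking_trial(num[[1L]], num[[2L]], num[[3L]],
                 subject_id = subject_id, visit_id = visit_id,
                 trial_index = trial_index)
}

#' Write a tracking trial to CSV
#'
#' @param trial a `tracking_trial`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "tracking_trial"))
  df <- data.frame(t_s = trial$sample_times,
                   target_pct_mvc = trial$target,
                   response_pct_mvc = trial$response)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort dataset to a directory
#'
#' Produces the same formats the scoring pipeline reads back: one trial
#' CSV per trial under `trials/`, and a `manifest.json` listing subjects,
#' visits (with trial file references), survey item scores, and the
#' simulation provenance (config + seed) when the cohort is synthetic.
#'
#' @param dataset a `cohort_dataset` (trials must have been kept).
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  visits <- lapply(dataset$visits, function(v) {
    if (is.null(v$trials)) {
      gs_abort("cohort has no raw trials (keep_trials was FALSE)",
               "gs_invalid_input")
    }
    files <- vapply(v$trials, function(tr) {
      f <- sprintf("trials/%s_%s_%d.csv", tr$subject_id, tr$visit_id,
                   tr$trial_index)
      write_trial_csv(tr, file.path(dir, f))
      f
    }, character(1))
    list(subject_id = v$subject_id, visit_id = v$visit_id,
         timepoint_label = v$timepoint_label,
         session_index = v$session_index, group = v$group,
         trial_files = as.list(files),
         odi_index = if (is.na(v$odi_index)) NULL else v$odi_index)
  })
  odi <- lapply(dataset$odi, function(o) {
    list(subject_id = o$subject_id, visit_id = o$visit_id,
         item_scores = as.list(o$item_scores))
  })
  manifest <- list(
    format_version = "1.0",
    subjects = dataset$subjects,
    visits = visits,
    odi = odi,
    provenance = unclass(dataset$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Read a cohort dataset from a directory
#'
#' Reads `manifest.json` and all referenced trial CSVs, rescores every
#' visit from the raw curves, and rebuilds the `cohort_dataset`.
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    gs_abort(sprintf("no manifest.json in %s", dir), "gs_io_error")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  subjects <- do.call(rbind, lapply(manifest$subjects, function(s) {
    s[vapply(s, is.null, logical(1))] <- NA
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  visits <- lapply(manifest$visits, function(v) {
    trials <- lapply(seq_along(v$trial_files), function(k) {
      read_trial_csv(file.path(dir, v$trial_files[[k]]),
                     subject_id = v$subject_id, visit_id = v$visit_id,
                     trial_index = k)
    })
    vr <- visit_score(trials, timepoint_label = v$timepoint_label,
                      odi_index = v$odi_index,
                      expected_trials = length(trials))
    vr$trials <- trials
    vr$session_index <- v$session_index
    vr$group <- v$group
    vr
  })
  odi <- lapply(manifest$odi, function(o) {
    items <- vapply(o$item_scores, function(x)
      if (is.null(x)) NA_integer_ else as.integer(x), integer(1))
    odi_response(items, subject_id = o$subject_id, visit_id = o$visit_id)
  })
  cfg <- manifest$provenance
  config <- if (!is.null(cfg)) {
    cfg <- lapply(cfg, function(x) if (is.list(x)) unlist(x) else x)
    do.call(simulation_config, cfg)
  } else {
    simulation_config()
  }
  structure(list(subjects = subjects, visits = visits, odi = odi,
                 config = config),
            class = "cohort_dataset")
}
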