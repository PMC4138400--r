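# Cohort-level analysis: group score summaries, percent improvement,
# MAE-ODI correlation with Cook's-distance screening, Bland-Altman.

group_summary <- function(x) {
  if (length(x) == 0L) return(NULL)
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
       n = length(x))
}

first_last <- function(df) {
  # per-subject first and last visit MAE (chronological = session order)
  do.call(rbind, lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$session_index), , drop = FALSE]
    data.frame(subject_id = d$subject_id[1L], group = d$group[1L],
               first_mae = d$visit_mae[1L],
               last_mae = d$visit_mae[nrow(d)],
               stringsAsFactors = FALSE)
  }))
}

#' Run the full cohort analysis
#'
#' Executes the analysis stages in a fixed order: score visits, classify
#' patients functional/nonfunctional from the post-intervention disability
#' index, summarize group MAEs, compute per-subject percent improvement
#' with group contrasts against controls, correlate pooled MAE (as a
#' fraction, %MVC / 100) with the ODI index, screen that regression for
#' influential points with the Cook's-distance `4/(n-2)` rule (single
#' pass), re-correlate without the flagged points, and run the
#' Bland-Altman agreement analysis on the same pairs.  Percent-improvement
#' agreement between the two instruments is analyzed the same way.
#'
#' @param dataset a `cohort_dataset` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param ci_method Bland-Altman bias CI method, `"normal"` or `"t"`.
#' @param pre_label,post_label patient timepoints used for the pre/post
#'   contrasts.
#' @return An `analysis_report` (nested list; see the JSON schema shipped
#'   in `inst/schema/`).  Stages that lack the required data (e.g. no
#'   surveys) are reported as `NULL` fields, not errors.
#' @export
analyze_cohort <- function(dataset, var_equal = FALSE,
                           ci_method = c("normal", "t"),
                           pre_label = "pre", post_label = "post_3mo") {
  ci_method <- match.arg(ci_method)
  vt <- as.data.frame(dataset)
  ctl <- vt[vt$group == "control", , drop = FALSE]
  pat <- vt[vt$group == "patient", , drop = FALSE]

  # --- classification from post-intervention ODI -------------------------
  post <- pat[pat$timepoint == post_label & !is.na(pat$odi), , drop = FALSE]
  functional_ids <- post$subject_id[classify_functional(post$odi) == "functional"]
  nonfunctional_ids <- setdiff(post$subject_id, functional_ids)

  # --- Table-2-style score summary ---------------------------------------
  ctl_fl <- if (nrow(ctl)) first_last(ctl) else NULL
  pre_mae <- pat[pat$timepoint == pre_label, , drop = FALSE]
  post_mae <- pat[pat$timepoint == post_label, , drop = FALSE]
  scores <- list(
    control_first = group_summary(ctl_fl$first_mae),
    control_last = group_summary(ctl_fl$last_mae),
    patient_pre = group_summary(pre_mae$visit_mae),
    patient_post = group_summary(post_mae$visit_mae),
    functional_post = group_summary(
      post_mae$visit_mae[post_mae$subject_id %in% functional_ids]),
    nonfunctional_post = group_summary(
      post_mae$visit_mae[post_mae$subject_id %in% nonfunctional_ids])
  )

  # --- Table-3-style percent improvement ---------------------------------
  # improvement_magnitude: positive = tracking error decreased
  imp_ctl <- if (!is.null(ctl_fl)) {
    improvement_magnitude(ctl_fl$first_mae, ctl_fl$last_mae)
  }
  pre_by_id <- stats::setNames(pre_mae$visit_mae, pre_mae$subject_id)
  post_by_id <- stats::setNames(post_mae$visit_mae, post_mae$subject_id)
  both_ids <- intersect(names(pre_by_id), names(post_by_id))
  imp_pat <- stats::setNames(
    improvement_magnitude(pre_by_id[both_ids], post_by_id[both_ids]),
    both_ids)
  imp_group <- function(ids) {
    v <- imp_pat[intersect(both_ids, ids)]
    if (!length(v)) return(NULL)
    c(group_summary(unname(v)),
      list(t_vs_control = if (length(v) >= 2L && length(imp_ctl) >= 2L)
        unclass(welch_t_test(unname(v), imp_ctl, var_equal = var_equal))))
  }
  improvement <- list(
    control = group_summary(imp_ctl),
    patients_aggregate = imp_group(both_ids),
    patients_functional = imp_group(functional_ids),
    patients_nonfunctional = imp_group(nonfunctional_ids),
    per_patient = if (length(imp_pat))
      data.frame(subject_id = names(imp_pat),
                 improvement_magnitude = unname(imp_pat),
                 stringsAsFactors = FALSE)
  )

  # --- MAE-ODI correlation with Cook's screen ----------------------------
  paired <- vt[!is.na(vt$odi), , drop = FALSE]
  correlation <- NULL
  agreement <- NULL
  if (nrow(paired) >= 4L) {
    mae_frac <- paired$visit_mae / 100   # harmonize scales: both in [0, 1]
    odi <- paired$odi
    r_all <- pearson(odi, mae_frac)
    diag <- fit_simple_regression(x = odi, y = mae_frac)
    d <- cooks_distance(diag, x = odi, y = mae_frac)
    flags <- flag_outliers(d, n = diag$n, k = diag$k)
    r_screened <- if (sum(!flags) >= 3L && stats::sd(odi[!flags]) > 0 &&
                      stats::sd(mae_frac[!flags]) > 0)
      pearson(odi[!flags], mae_frac[!flags])
    correlation <- list(
      pairs = data.frame(subject_id = paired$subject_id,
                         timepoint = paired$timepoint,
                         odi = odi, mae_fraction = mae_frac,
                         cooks_d = d, outlier = flags,
                         stringsAsFactors = FALSE),
      with_outliers = unclass(r_all),
      without_outliers = if (!is.null(r_screened)) unclass(r_screened),
      n_flagged = sum(flags),
      outlier_threshold = 4 / (diag$n - (diag$k + 1L)),
      regression = list(slope = diag$slope, intercept = diag$intercept,
                        rmse_s = diag$rmse_s)
    )
    ba <- bland_altman(mae_frac, odi, ci_method = ci_method)
    agreement <- list(bias = ba$bias, bias_ci = ba$bias_ci,
                      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
                      sd_diff = ba$sd_diff, n = ba$n,
                      direction = "mae_fraction - odi")
  }

  # --- percent-improvement correlation (both instruments) ----------------
  improvement_correlation <- NULL
  odi_pre <- stats::setNames(paired$odi[paired$timepoint == pre_label],
                             paired$subject_id[paired$timepoint == pre_label])
  odi_post <- stats::setNames(paired$odi[paired$timepoint == post_label],
                              paired$subject_id[paired$timepoint == post_label])
  ids <- Reduce(intersect, list(names(odi_pre), names(odi_post), both_ids))
  ids <- ids[odi_pre[ids] > 0]
  if (length(ids) >= 4L) {
    imp_odi <- improvement_magnitude(odi_pre[ids], odi_post[ids])
    imp_mae <- imp_pat[ids]
    if (stats::sd(imp_odi) > 0 && stats::sd(imp_mae) > 0) {
      r_imp <- pearson(unname(imp_odi), unname(imp_mae))
      diag_i <- fit_simple_regression(x = unname(imp_odi), y = unname(imp_mae))
      d_i <- cooks_distance(diag_i, unname(imp_odi), unname(imp_mae))
      fl_i <- flag_outliers(d_i, n = diag_i$n, k = diag_i$k)
      r_imp_screened <- if (sum(!fl_i) >= 3L &&
                            stats::sd(imp_odi[!fl_i]) > 0 &&
                            stats::sd(imp_mae[!fl_i]) > 0)
        pearson(unname(imp_odi)[!fl_i], unname(imp_mae)[!fl_i])
      improvement_correlation <- list(
        with_outliers = unclass(r_imp),
        without_outliers = if (!is.null(r_imp_screened))
          unclass(r_imp_screened),
        n_flagged = sum(fl_i)
      )
    }
  }

  # --- control vs patient group contrast at baseline ---------------------
  baseline_contrast <- if (!is.null(ctl_fl) && nrow(pre_mae) >= 2L &&
                           nrow(ctl_fl) >= 2L)
    unclass(welch_t_test(pre_mae$visit_mae, ctl_fl$first_mae,
                         var_equal = var_equal))

  structure(
    list(
      n_control = sum(dataset$subjects$group == "control"),
      n_patient = sum(dataset$subjects$group == "patient"),
      functional_ids = functional_ids,
      nonfunctional_ids = nonfunctional_ids,
      scores = scores,
      improvement = improvement,
      baseline_contrast = baseline_contrast,
      correlation = correlation,
      agreement = agreement,
      improvement_correlation = improvement_correlation,
      settings = list(var_equal = var_equal, ci_method = ci_method,
                      pre_label = pre_label, post_label = post_label,
                      seed = dataset$config$seed)
    ),
    class = "analysis_report"
  )
}

fmt_ms <- function(g, digits = 2) {
  if (is.null(g)) return("--")
  sprintf(paste0("%.", digits, "f ± %.", digits, "f (n=%d)"),
          g$mean, g$sd, g$n)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  Tracking MAE (%MVC), mean ± SD\n")
  cat("    control first visit:   ", fmt_ms(x$scores$control_first), "\n")
  cat("    control last visit:    ", fmt_ms(x$scores$control_last), "\n")
  cat("    patient pre:           ", fmt_ms(x$scores$patient_pre), "\n")
  cat("    patient post:          ", fmt_ms(x$scores$patient_post), "\n")
  cat("    functional post:       ", fmt_ms(x$scores$functional_post), "\n")
  cat("    nonfunctional post:    ", fmt_ms(x$scores$nonfunctional_post), "\n")
  if (!is.null(x$correlation)) {
    w <- x$correlation$with_outliers
    cat(sprintf("  MAE-ODI correlation: r = %.3f (p = %.3g, n = %d), %d flagged",
                w$r, w$p_value, w$n, x$correlation$n_flagged))
    if (!is.null(x$correlation$without_outliers)) {
      wo <- x$correlation$without_outliers
      cat(sprintf("; screened r = %.3f (p = %.3g)", wo$r, wo$p_value))
    }
    cat("\n")
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  Bland-Altman (MAE/100 - ODI): bias %.3f, LoA [%.3f, %.3f]\n",
                x$agreement$bias, x$agreement$loa_lower, x$agreement$loa_upper))
  }
  invisible(x)
}
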