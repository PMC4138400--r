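#' Generate the sinusoidal tracking target
#'
#' Builds the target waveform shown to a subject during a force-tracking
#' trial.  The waveform is an offset sinusoid
#' \deqn{v(t) = 50 (1 - \cos(2\pi t / \mathrm{period}))}
#' in units of %MVC, so it spans exactly \[0, 100\]: grip force cannot be
#' negative and the peak of the target equals the subject's measured maximum
#' voluntary contraction (MVC).
#'
#' @param duration trial length in seconds (default 45, the standard trial).
#' @param sample_rate sampling rate in Hz (default 50).
#' @param period period of the sinusoid in seconds (default 9).
#' @return A `target_waveform` object: list with `sample_times` (seconds,
#'   uniform grid including both endpoints), `values` (%MVC), `period`,
#'   `duration` and `sample_rate`.
#' @examples
#' tgt <- generate_target(duration = 45, sample_rate = 50, period = 9)
#' range(tgt$values)  # 0 .. 100 %MVC
#' @export
generate_target <- function(duration = 45, sample_rate = 50, period = 9) {
  gs_check_scalar(duration, "duration")
  gs_check_scalar(sample_rate, "sample_rate")
  gs_check_scalar(period, "period")
  n <- round(duration * sample_rate)
  t <- seq(0, by = 1 / sample_rate, length.out = n + 1L)
  structure(
    list(
      sample_times = t,
      values = 50 * (1 - cos(2 * pi * t / period)),
      period = period,
      duration = duration,
      sample_rate = sample_rate
    ),
    class = "target_waveform"
  )
}

#' Evaluate a target waveform at arbitrary times
#'
#' Times before the start of the trial return the initial target value
#' (the cursor sits at the origin until the target arrives).
#'
#' @param target a `target_waveform`.
#' @param t numeric vector of times in seconds.
#' @return target force in %MVC at each `t`.
#' @export
target_at <- function(target, t) {
  stopifnot(inherits(target, "target_waveform"))
  t <- pmax(t, 0)
  50 * (1 - cos(2 * pi * t / target$period))
}

#' Construct a force-tracking trial
#'
#' A trial holds the target curve and the subject's force response, both in
#' %MVC and sampled on the same uniform time grid.  Responses above the
#' calibration MVC are tolerated up to 120 %MVC (the calibration maximum can
#' be exceeded transiently); negative forces are rejected.
#'
#' @param sample_times sample times in seconds, strictly increasing.
#' @param target target force in %MVC.
#' @param response measured force in %MVC.
#' @param subject_id,visit_id identifiers (character).
#' @param trial_index integer index of the trial within the visit.
#' @return A `tracking_trial` object.
#' @export
tracking_trial <- function(sample_times, target, response,
                           subject_id = "", visit_id = "", trial_index = 1L) {
  n <- length(sample_times)
  if (n < 2L) {
    gs_abort("a trial needs at least 2 samples", "gs_invalid_input")
  }
  if (length(target) != n || length(response) != n) {
    gs_abort(sprintf(
      "target (%d) and response (%d) must match sample_times (%d)",
      length(target), length(response), n), "gs_shape_error")
  }
  if (anyNA(sample_times) || any(diff(sample_times) <= 0)) {
    gs_abort("sample_times must be finite and strictly increasing",
             "gs_invalid_data")
  }
  if (anyNA(response) || any(!is.finite(response))) {
    gs_abort("response contains non-finite values", "gs_invalid_data")
  }
  if (any(response < 0)) {
    gs_abort("negative response force is not physical", "gs_invalid_data")
  }
  if (any(response > 120)) {
    gs_abort("response exceeds 120 %MVC; check calibration", "gs_invalid_data")
  }
  structure(
    list(
      sample_times = as.numeric(sample_times),
      target = as.numeric(target),
      response = as.numeric(response),
      duration = sample_times[n] - sample_times[1L],
      subject_id = as.character(subject_id),
      visit_id = as.character(visit_id),
      trial_index = as.integer(trial_index)
    ),
    class = "tracking_trial"
  )
}

#' @export
print.tracking_trial <- function(x, ...) {
  cat(sprintf(
    "<tracking_trial> subject=%s visit=%s trial=%d: %d samples over %.1f s, MAE %.2f %%MVC\n",
    x$subject_id, x$visit_id, x$trial_index,
    length(x$sample_times), x$duration, mae_score(x)))
  invisible(x)
}

#' Mean absolute tracking error of a trial
#'
#' The performance metric of the tracking test: the mean absolute vertical
#' distance between the target curve and the subject's force trace at
#' matched sample times,
#' \deqn{\mathrm{MAE} = \frac{1}{N}\sum_{i=1}^{N} |r_i - v_i|,}
#' in %MVC.  Lower is better; 0 means perfect tracking.  The error is taken
#' on the force axis only, because the time axis is driven by the display,
#' not the subject.
#'
#' @param trial a `tracking_trial`, or a list with numeric `target` and
#'   `response` of equal length.
#' @return the MAE in %MVC (non-negative scalar).
#' @examples
#' tgt <- generate_target()
#' tr <- tracking_trial(tgt$sample_times, tgt$values, pmin(tgt$values + 5, 120))
#' mae_score(tr)  # 5: constant 5 %MVC offset
#' @export
mae_score <- function(trial) {
  target <- trial$target
  response <- trial$response
  if (length(target) != length(response)) {
    gs_abort("target and response lengths differ", "gs_shape_error")
  }
  if (length(target) == 0L) {
    gs_abort("empty trial", "gs_invalid_input")
  }
  if (anyNA(target) || anyNA(response) ||
      any(!is.finite(target)) || any(!is.finite(response))) {
    gs_abort("NaN/NA in trial curves; refusing to drop samples silently",
             "gs_invalid_data")
  }
  mean(abs(response - target))
}

#' Aggregate trials into a visit score
#'
#' At every clinical visit a subject performs (up to) three tracking trials;
#' the visit score is the arithmetic mean of the per-trial MAEs.  Fewer than
#' three trials is allowed with a warning, so incomplete visits remain
#' scoreable.
#'
#' @param trials list of `tracking_trial` objects from one subject and visit.
#' @param timepoint_label label such as `"pre"` or `"post_3mo"`.
#' @param odi_index optional ODI index in \[0, 1\] recorded at the visit.
#' @param expected_trials nominal number of trials per visit (default 3).
#' @return A `visit_record`: subject/visit ids, per-trial MAEs (`trial_maes`),
#'   their mean (`visit_mae`), and the optional ODI index.
#' @export
visit_score <- function(trials, timepoint_label = "", odi_index = NULL,
                        expected_trials = 3L) {
  if (length(trials) == 0L) {
    gs_abort("no trials supplied for visit", "gs_invalid_input")
  }
  subj <- unique(vapply(trials, `[[`, character(1), "subject_id"))
  vis <- unique(vapply(trials, `[[`, character(1), "visit_id"))
  if (length(subj) != 1L || length(vis) != 1L) {
    gs_abort("trials mix subjects or visits", "gs_consistency_error")
  }
  if (length(trials) < expected_trials) {
    warning(sprintf("visit %s/%s has %d trial(s), expected %d",
                    subj, vis, length(trials), expected_trials),
            call. = FALSE)
  }
  maes <- vapply(trials, mae_score, numeric(1))
  structure(
    list(
      subject_id = subj,
      visit_id = vis,
      timepoint_label = timepoint_label,
      trial_maes = maes,
      visit_mae = mean(maes),
      odi_index = if (length(odi_index)) as.numeric(odi_index) else NA_real_
    ),
    class = "visit_record"
  )
}

#' @export
print.visit_record <- function(x, ...) {
  cat(sprintf("<visit_record> %s/%s (%s): visit MAE %.2f %%MVC from %d trial(s)%s\n",
              x$subject_id, x$visit_id, x$timepoint_label, x$visit_mae,
              length(x$trial_maes),
              if (is.na(x$odi_index)) "" else sprintf(", ODI %.2f", x$odi_index)))
  invisible(x)
}
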