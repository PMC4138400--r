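#' Default simulation configuration
#'
#' Parameters of the synthetic cohort generator.  Subjects carry a latent
#' impairment level `theta` (dimensionless, >= 0; 0 = unimpaired) that
#' drives both tracking noise and disability-survey responses.  The force
#' response in a trial is the target, delayed by a motor delay `tau`, plus
#' AR(1) noise whose innovation SD is `(sigma0 + sigma1 * theta) *
#' lambda^session`, so noise grows with impairment and decays with practice
#' (motor learning).  The default cohort mirrors a two-group clinical
#' study: 18 healthy controls tested at weeks 0, 2-3 and 4-6, and 11
#' patients tested pre-operatively and at 24 h, 48 h, 2 weeks and 3 months
#' after intervention, with disability surveys at the pre and 3-month
#' visits.
#'
#' `sigma0` and `sigma1` are calibrated so that the simulated group means
#' land near the reference values of 8.09 %MVC (controls, first visit) and
#' 11.24 %MVC (patients, pre-operative); `lambda` reproduces the observed
#' ~17% control improvement over three sessions.
#'
#' @param n_control,n_patient group sizes.
#' @param theta_control_mean,theta_control_sd,theta_patient_mean,theta_patient_sd
#'   parameters of the per-group impairment distributions (normal truncated
#'   at 0).
#' @param surgery_effect fractional reduction of `theta` in responders.
#' @param delta_adverse fractional increase of `theta` in non-responders.
#' @param responder_fraction probability a patient responds to intervention.
#' @param noise_base,noise_gain `sigma0`, `sigma1` in %MVC.
#' @param ar_coefficient AR(1) coefficient `phi` of the tracking noise.
#' @param learning_rate per-session multiplier `lambda` on innovation SD.
#' @param motor_delay response delay `tau` in seconds.
#' @param odi_intercept,odi_slope,odi_noise latent disability index model
#'   `clip(beta0 + beta1 * theta + N(0, odi_noise), 0, 1)`.
#' @param mvc_mean,mvc_sd grip strength distribution in lbs (truncated at
#'   20 lbs).
#' @param control_schedule,patient_schedule visit labels per group, in
#'   chronological order.
#' @param odi_visits patient visits at which the survey is administered.
#' @param trials_per_visit tracking trials per visit.
#' @param duration,sample_rate,period target waveform parameters
#'   (see [generate_target()]).
#' @param keep_trials retain raw trial curves in the dataset (set `FALSE`
#'   for large simulation studies where only visit MAEs are needed).
#' @param seed integer seed making the cohort reproducible.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_control = 18L, n_patient = 11L,
                              theta_control_mean = 0, theta_control_sd = 0.19,
                              theta_patient_mean = 0, theta_patient_sd = 0.80,
                              surgery_effect = 0.20, delta_adverse = 1.40,
                              responder_fraction = 0.64,
                              noise_base = 9.3, noise_gain = 8.4,
                              ar_coefficient = 0.3, learning_rate = 0.91,
                              motor_delay = 0.05,
                              odi_intercept = 0.20, odi_slope = 0.41,
                              odi_noise = 0.06,
                              mvc_mean = 80, mvc_sd = 20,
                              control_schedule = c("week0", "week2_3", "week4_6"),
                              patient_schedule = c("pre", "post_24h", "post_48h",
                                                   "post_2wk", "post_3mo"),
                              odi_visits = c("pre", "post_3mo"),
                              trials_per_visit = 3L,
                              duration = 45, sample_rate = 50, period = 9,
                              keep_trials = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_control >= 0, cfg$n_patient >= 0,
            cfg$noise_base >= 0, cfg$noise_gain >= 0,
            abs(cfg$ar_coefficient) < 1,
            cfg$learning_rate > 0, cfg$learning_rate <= 1,
            cfg$responder_fraction >= 0, cfg$responder_fraction <= 1,
            cfg$motor_delay >= 0)
  structure(cfg, class = "simulation_config")
}

# normal truncated below at `lower`, by inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Construct the latent state of a simulated subject
#'
#' @param subject_id identifier.
#' @param group `"control"` or `"patient"`.
#' @param theta latent impairment (>= 0).
#' @param mvc grip strength in lbs.
#' @param learning_rate per-session noise multiplier in (0, 1\].
#' @param motor_delay response delay in seconds.
#' @param responder logical; patients only.
#' @return a `subject_state`.
#' @export
subject_state <- function(subject_id, group = c("control", "patient"),
                          theta, mvc = 80, learning_rate = 0.91,
                          motor_delay = 0.05, responder = NA) {
  group <- match.arg(group)
  if (theta < 0) gs_abort("theta must be >= 0", "gs_invalid_parameter")
  if (learning_rate <= 0 || learning_rate > 1) {
    gs_abort("learning_rate must lie in (0, 1]", "gs_invalid_parameter")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         theta = theta, mvc = mvc, learning_rate = learning_rate,
         motor_delay = motor_delay, responder = responder),
    class = "subject_state"
  )
}

#' Simulate one tracking trial
#'
#' The response is the target delayed by the subject's motor delay plus a
#' stationary AR(1) noise process: innovation SD
#' `(sigma0 + sigma1 * theta) * lambda^session_index`, AR coefficient
#' `phi`.  The response is clipped to the physical range \[0, 120\] %MVC.
#' Randomness comes from the R session RNG; seed it (`set.seed`) for
#' reproducibility.
#'
#' @param state a `subject_state`.
#' @param target a `target_waveform`.
#' @param session_index 0-based count of previously completed sessions.
#' @param config a `simulation_config` (noise parameters are read from it).
#' @param visit_id,trial_index identifiers stamped on the trial.
#' @return a `tracking_trial`.
#' @export
simulate_trial <- function(state, target, session_index = 0L,
                           config = simulation_config(),
                           visit_id = "", trial_index = 1L) {
  stopifnot(inherits(state, "subject_state"),
            inherits(target, "target_waveform"))
  t <- target$sample_times
  n <- length(t)
  shifted <- target_at(target, t - state$motor_delay)
  sd_innov <- (config$noise_base + config$noise_gain * state$theta) *
    state$learning_rate^session_index
  if (sd_innov == 0) {
    eps <- numeric(n)
  } else {
    phi <- config$ar_coefficient
    innov <- stats::rnorm(n, 0, sd_innov)
    init <- stats::rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
    eps <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                    init = init))
  }
  response <- pmin(pmax(shifted + eps, 0), 120)
  tracking_trial(t, target$values, response,
                 subject_id = state$subject_id, visit_id = visit_id,
                 trial_index = trial_index)
}

#' Simulate a disability-survey response coupled to impairment
#'
#' A latent disability index `clip(beta0 + beta1 * theta + noise, 0, 1)` is
#' converted to 10 item scores: the total `round(50 * index)` is spread
#' across the items (each capped at 5), distributing the remainder from
#' item 1 onward.  The scheme is deterministic given the latent index, so
#' [odi_index()] recovers the index to within rounding (< 0.01).
#'
#' @param state a `subject_state`.
#' @param config a `simulation_config`.
#' @param visit_id identifier stamped on the response.
#' @return an `odi_response`.
#' @export
simulate_odi <- function(state, config = simulation_config(), visit_id = "") {
  latent <- config$odi_intercept + config$odi_slope * state$theta +
    stats::rnorm(1, 0, config$odi_noise)
  latent <- min(max(latent, 0), 1)
  odi_items_from_index(latent, subject_id = state$subject_id,
                       visit_id = visit_id)
}

# deterministic item allocation: total = round(50*index), base floor plus
# remainder handed out one point at a time starting at item 1
odi_items_from_index <- function(index, subject_id = "", visit_id = "") {
  total <- round(50 * index)
  base <- total %/% 10L
  rem <- total %% 10L
  items <- rep.int(base, 10L)
  if (rem > 0L) items[seq_len(rem)] <- items[seq_len(rem)] + 1L
  odi_response(as.integer(items), subject_id = subject_id,
               visit_id = visit_id)
}

#' Apply the intervention to a patient's latent impairment
#'
#' With probability `responder_fraction` the patient responds:
#' `theta_post = theta * (1 - surgery_effect)`.  Otherwise the impairment
#' worsens: `theta_post = theta * (1 + delta_adverse)`, modelling patients
#' who decline after intervention.
#'
#' @param state a patient `subject_state`.
#' @param config a `simulation_config`.
#' @return the updated `subject_state` with `theta` replaced and
#'   `responder` set.
#' @export
apply_intervention <- function(state, config = simulation_config()) {
  if (state$group != "patient") {
    gs_abort("intervention applies to patients only", "gs_invalid_group")
  }
  responder <- stats::runif(1) < config$responder_fraction
  state$theta <- if (responder) {
    state$theta * (1 - config$surgery_effect)
  } else {
    state$theta * (1 + config$delta_adverse)
  }
  state$responder <- responder
  state
}

#' Simulate a full two-group cohort
#'
#' Draws control and patient subjects, walks each through their group's
#' visit schedule with `trials_per_visit` tracking trials per visit (the
#' session index increments across visits, so later sessions benefit from
#' motor learning), applies the intervention to patients after their first
#' (pre) visit, and attaches disability surveys at the configured visits.
#' Fully reproducible from `config$seed`.
#'
#' @param config a `simulation_config`.
#' @return A `cohort_dataset`: `subjects` (data.frame of ground truth:
#'   `theta_pre`, `theta_post`, `responder`, ...), `visits` (list of
#'   `visit_record`, with raw trials if `keep_trials`), `odi` (list of
#'   `odi_response`), and `config` provenance.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  target <- generate_target(config$duration, config$sample_rate, config$period)

  draw_subjects <- function(n, group, prefix, mean, sd) {
    if (n == 0L) return(list())
    theta <- rtruncnorm(n, mean, sd)
    mvc <- rtruncnorm(n, config$mvc_mean, config$mvc_sd, lower = 20)
    lapply(seq_len(n), function(i) {
      subject_state(sprintf("%s%02d", prefix, i), group,
                    theta = theta[i], mvc = mvc[i],
                    learning_rate = config$learning_rate,
                    motor_delay = config$motor_delay)
    })
  }
  controls <- draw_subjects(config$n_control, "control", "C",
                            config$theta_control_mean, config$theta_control_sd)
  patients <- draw_subjects(config$n_patient, "patient", "P",
                            config$theta_patient_mean, config$theta_patient_sd)

  subjects_truth <- list()
  visits <- list()
  odi <- list()

  run_subject <- function(state, schedule) {
    theta_pre <- state$theta
    post_state <- state
    if (state$group == "patient") {
      post_state <- apply_intervention(state, config)
    }
    for (vi in seq_along(schedule)) {
      label <- schedule[vi]
      st <- if (state$group == "patient" && vi > 1L) post_state else state
      trials <- lapply(seq_len(config$trials_per_visit), function(k) {
        simulate_trial(st, target, session_index = vi - 1L, config = config,
                       visit_id = label, trial_index = k)
      })
      odi_here <- state$group == "patient" && label %in% config$odi_visits
      odi_val <- NA_real_
      if (odi_here) {
        resp <- simulate_odi(st, config, visit_id = label)
        odi_val <- odi_index(resp)$value
        odi[[length(odi) + 1L]] <<- resp
      }
      vr <- visit_score(trials, timepoint_label = label,
                        odi_index = if (odi_here) odi_val else NULL,
                        expected_trials = config$trials_per_visit)
      if (!config$keep_trials) trials <- NULL
      vr$trials <- trials
      vr$session_index <- vi - 1L
      vr$group <- state$group
      visits[[length(visits) + 1L]] <<- vr
    }
    subjects_truth[[length(subjects_truth) + 1L]] <<- data.frame(
      subject_id = state$subject_id, group = state$group,
      theta_pre = theta_pre, theta_post = post_state$theta,
      responder = if (state$group == "patient") post_state$responder else NA,
      mvc = state$mvc, learning_rate = state$learning_rate,
      motor_delay = state$motor_delay, stringsAsFactors = FALSE)
  }

  for (s in controls) run_subject(s, config$control_schedule)
  for (s in patients) run_subject(s, config$patient_schedule)

  structure(
    list(
      subjects = do.call(rbind, subjects_truth),
      visits = visits,
      odi = odi,
      config = config
    ),
    class = "cohort_dataset"
  )
}

#' Visit-level summary table of a cohort
#'
#' @param x a `cohort_dataset`.
#' @param ... unused.
#' @return data.frame with one row per visit: `subject_id`, `group`,
#'   `timepoint`, `session_index`, `visit_mae` (%MVC), `odi`.
#' @export
as.data.frame.cohort_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$visits, function(v) {
    data.frame(subject_id = v$subject_id, group = v$group,
               timepoint = v$timepoint_label,
               session_index = v$session_index,
               visit_mae = v$visit_mae, odi = v$odi_index,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d controls + %d patients, %d visits, %d surveys (seed %d)\n",
    sum(x$subjects$group == "control"), sum(x$subjects$group == "patient"),
    length(x$visits), length(x$odi), x$config$seed))
  invisible(x)
}
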