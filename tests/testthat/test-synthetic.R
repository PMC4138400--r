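# small waveform used throughout: 45 s at 50 Hz, 9 s period (the standard
# trial the simulator emulates)
std_target <- generate_target(45, 50, 9)

test_that("noiseless simulation reproduces the target exactly", {
  cfg <- simulation_config(noise_base = 0, noise_gain = 0, motor_delay = 0)
  st <- subject_state("S1", "control", theta = 0, motor_delay = 0)
  set.seed(1)
  tr <- simulate_trial(st, std_target, 0, cfg)
  expect_equal(tr$response, std_target$values, tolerance = 1e-12)
  expect_equal(mae_score(tr), 0)
})

test_that("with zero noise the only error is delay-induced and deterministic", {
  cfg <- simulation_config(noise_base = 0, noise_gain = 0, motor_delay = 0.2)
  st <- subject_state("S1", "patient", theta = 1, motor_delay = 0.2)
  set.seed(1); tr1 <- simulate_trial(st, std_target, 0, cfg)
  set.seed(99); tr2 <- simulate_trial(st, std_target, 0, cfg)
  expect_identical(tr1$response, tr2$response)
  expect_gt(mae_score(tr1), 0)
})

test_that("expected MAE increases with impairment theta", {
  cfg <- simulation_config()
  mean_mae <- function(theta, n_rep = 100) {
    st <- subject_state("S", "patient", theta = theta,
                        motor_delay = cfg$motor_delay)
    mean(vapply(seq_len(n_rep), function(i)
      mae_score(simulate_trial(st, std_target, 0, cfg)), numeric(1)))
  }
  set.seed(101)
  m <- vapply(c(0, 1, 2), mean_mae, numeric(1))
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("motor learning lowers expected MAE at later sessions", {
  cfg <- simulation_config()  # learning_rate < 1
  st <- subject_state("S", "control", theta = 0.5,
                      learning_rate = cfg$learning_rate)
  set.seed(103)
  m0 <- mean(vapply(1:60, function(i)
    mae_score(simulate_trial(st, std_target, 0, cfg)), numeric(1)))
  m3 <- mean(vapply(1:60, function(i)
    mae_score(simulate_trial(st, std_target, 3, cfg)), numeric(1)))
  expect_lt(m3, m0)
})

test_that("phi = 0 yields serially uncorrelated tracking noise", {
  cfg <- simulation_config(ar_coefficient = 0, noise_base = 6, noise_gain = 0)
  st <- subject_state("S", "control", theta = 0, motor_delay = 0)
  set.seed(107)
  r1 <- vapply(1:3, function(i) {
    tr <- simulate_trial(st, std_target, 0, cfg)
    e <- tr$response - tr$target
    ok <- tr$response > 0 & tr$response < 120  # drop clipped samples
    keep <- which(ok[-length(ok)] & ok[-1])
    cor(e[keep], e[keep + 1])
  }, numeric(1))
  expect_lt(abs(mean(r1)), 0.05)
})

test_that("survey items round-trip the latent disability index", {
  st <- subject_state("S", "patient", theta = 1)
  # degenerate: no coupling, no noise -> index equals the intercept
  cfg <- simulation_config(odi_slope = 0, odi_noise = 0, odi_intercept = 0.36)
  set.seed(5)
  resp <- simulate_odi(st, cfg)
  expect_equal(odi_index(resp)$value, 0.36, tolerance = 1e-12)
  # saturation under strong coupling
  cfg_hi <- simulation_config(odi_slope = 2, odi_noise = 0)
  st_hi <- subject_state("S", "patient", theta = 5)
  expect_equal(odi_index(simulate_odi(st_hi, cfg_hi))$value, 1)
})

test_that("intervention scales impairment by responder status", {
  cfg0 <- simulation_config(surgery_effect = 0, delta_adverse = 0)
  st <- subject_state("P", "patient", theta = 1.3)
  set.seed(7)
  expect_equal(apply_intervention(st, cfg0)$theta, 1.3)
  cfg1 <- simulation_config(responder_fraction = 1, surgery_effect = 0.5)
  out <- apply_intervention(st, cfg1)
  expect_equal(out$theta, 0.65)
  expect_true(out$responder)
  ctl <- subject_state("C", "control", theta = 0)
  expect_error(apply_intervention(ctl, cfg1), class = "gs_invalid_group")
})

test_that("cohort simulation is reproducible and structurally complete", {
  cfg <- simulation_config(n_control = 2, n_patient = 2, seed = 11)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  vt <- as.data.frame(d1)
  # schedule: 3 control visits, 5 patient visits, 3 trials each
  expect_equal(nrow(vt), 2 * 3 + 2 * 5)
  expect_true(all(vapply(d1$visits, function(v)
    length(v$trial_maes) == 3, logical(1))))
  # surveys at pre and 3-month post for every patient
  pat <- vt[vt$group == "patient", ]
  expect_true(all(!is.na(pat$odi[pat$timepoint %in% c("pre", "post_3mo")])))
  expect_true(all(is.na(pat$odi[!pat$timepoint %in% c("pre", "post_3mo")])))
  # ground truth retained
  expect_named(d1$subjects,
               c("subject_id", "group", "theta_pre", "theta_post",
                 "responder", "mvc", "learning_rate", "motor_delay"))
  expect_true(all(vt$session_index[vt$timepoint == "post_3mo"] == 4))
})

test_that("cohort visit MAEs lie between their trial extremes", {
  d <- simulate_cohort(simulation_config(n_control = 1, n_patient = 1,
                                         seed = 13))
  for (v in d$visits) {
    expect_gte(v$visit_mae, min(v$trial_maes))
    expect_lte(v$visit_mae, max(v$trial_maes))
    expect_equal(v$visit_mae, mean(v$trial_maes), tolerance = 1e-12)
  }
})
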