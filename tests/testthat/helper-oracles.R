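# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (element-wise loops, direct textbook
# formulas) and never call the code paths they verify.

# element-by-element MAE summation
oracle_mae <- function(target, response) {
  total <- 0
  for (i in seq_along(target)) total <- total + abs(response[i] - target[i])
  total / length(target)
}

# direct covariance / stddev Pearson formula with t-based p
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# textbook Welch statistic and Welch-Satterthwaite dof
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

# direct mean/SD Bland-Altman
oracle_bland_altman <- function(a, b) {
  d <- a - b
  list(bias = mean(d), sd = sd(d),
       upper = mean(d) + 1.96 * sd(d), lower = mean(d) - 1.96 * sd(d))
}

# brute-force spring subset choice: enumerate every subset, apply the
# band / midpoint / stiffer-tie rule literally
oracle_select_springs <- function(mvc, disp, constants, subset_size = 3,
                                  band = c(0.70, 0.80)) {
  idx <- combn(length(constants), subset_size)
  eff <- apply(idx, 2, function(j) sum(constants[j]))
  frac <- eff * disp / mvc
  mid <- mean(band)
  in_band <- frac >= band[1] & frac <= band[2]
  pool <- if (any(in_band)) which(in_band) else seq_along(frac)
  best <- pool[1]
  for (j in pool) {
    dj <- abs(frac[j] - mid); db <- abs(frac[best] - mid)
    if (dj < db || (dj == db && eff[j] > eff[best])) best <- j
  }
  list(constants = sort(constants[idx[, best]]), eff = eff[best],
       out_of_band = !any(in_band))
}

# random trial on the standard grid, response perturbed from target
make_random_trial <- function(n = 20, subject = "S", visit = "V") {
  t <- seq(0, by = 0.02, length.out = n)
  target <- runif(n, 0, 100)
  response <- pmin(pmax(target + rnorm(n, 0, 10), 0), 120)
  tracking_trial(t, target, response, subject_id = subject, visit_id = visit)
}

# trial whose response is target + delta (constant offset)
make_offset_trial <- function(delta, subject = "S", visit = "V") {
  tgt <- generate_target(duration = 9, sample_rate = 10, period = 9)
  tracking_trial(tgt$sample_times, tgt$values,
                 pmin(pmax(tgt$values + delta, 0), 120),
                 subject_id = subject, visit_id = visit)
}
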