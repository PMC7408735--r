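# Independent numerical oracles used across the suite.  These integrate the
# model's defining integrals directly (stats::integrate) or solve the
# Kolmogorov forward equations (deSolve); they never call the closed-form
# kernels they are checking.

# P(onset in (a,b], still pre-clinical at T) by direct quadrature
oracle_kernel <- function(lambda1, lambda2, a, b, T) {
  stats::integrate(function(u) lambda1 * exp(-lambda1 * u) *
                     exp(-lambda2 * (T - u)),
                   a, b, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# screen-detection probability at round j by quadrature over every onset
# window with the geometric chain of misses
oracle_screen_detected <- function(lambda1, lambda2, s, screens, j) {
  bounds <- c(0, screens[seq_len(j)])
  tj <- screens[j]
  tot <- 0
  for (i in seq_len(j))
    tot <- tot + (1 - s)^(j - i) *
      oracle_kernel(lambda1, lambda2, bounds[i], bounds[i + 1L], tj)
  s * tot
}

oracle_interval_density <- function(lambda1, lambda2, s, screens, v) {
  k <- length(screens)
  bounds <- c(0, screens)
  tot <- 0
  for (i in seq_len(k))
    tot <- tot + (1 - s)^(k - i + 1L) *
      oracle_kernel(lambda1, lambda2, bounds[i], bounds[i + 1L], v)
  lambda2 * (tot + oracle_kernel(lambda1, lambda2, screens[k], v, v))
}

oracle_censored <- function(lambda1, lambda2, s, screens, tau) {
  k <- length(screens)
  p <- exp(-lambda1 * tau)
  if (k) {
    bounds <- c(0, screens)
    for (i in seq_len(k))
      p <- p + (1 - s)^(k - i + 1L) *
        oracle_kernel(lambda1, lambda2, bounds[i], bounds[i + 1L], tau)
    p <- p + oracle_kernel(lambda1, lambda2, screens[k], tau, tau)
  } else {
    p <- p + oracle_kernel(lambda1, lambda2, 0, tau, tau)
  }
  p
}

# total detection-mode mass of a schedule: screen detections, integrated
# interval/clinical surfacing density over every window, plus censoring
oracle_total_mass <- function(params, screens, tau) {
  l1 <- params$lambda1; l2 <- params$lambda2
  k <- length(screens)
  tot <- 0
  for (j in seq_len(k))
    tot <- tot + lik_screen_detected(params, screens, j)
  lo <- 0
  for (j in seq_len(k + 1L)) {
    hi <- if (j <= k) screens[j] else tau
    if (hi > lo) {
      dens <- if (j == 1L)
        function(v) lik_clinical_unscreened_density(params, v)
      else
        function(v) lik_interval_cancer_density(params,
                                                screens[seq_len(j - 1L)], v)
      tot <- tot + stats::integrate(Vectorize(dens), lo, hi,
                                    rel.tol = 1e-11)$value
    }
    lo <- hi
  }
  tot + lik_censored(params, screens, tau)
}

# forward-equation solution of the occupancy probabilities from `free`
oracle_ode_occupancy <- function(lambda1, lambda2, t) {
  rhs <- function(t, y, parms)
    list(c(-parms[1] * y[1],
           parms[1] * y[1] - parms[2] * y[2],
           parms[2] * y[2]))
  out <- deSolve::ode(c(1, 0, 0), c(0, t), rhs, c(lambda1, lambda2),
                      method = "ode45", rtol = 1e-11, atol = 1e-12)
  unname(out[nrow(out), -1L])
}

# single-feature cohort shortcut used all over the inference tests
make_single_feature_config <- function(n, lambda1 = 20e-5, mst = 3.76,
                                       sensitivity = 0.95, interval = 2,
                                       horizon = 12, lead_in = 2, seed,
                                       keep_truth = FALSE) {
  scenario_config("custom", n = n,
                  features = nh_params_set(list(nh_params(
                    "stellate", lambda1 = lambda1, mst = mst,
                    sensitivity = sensitivity))),
                  interval = interval, horizon = horizon, lead_in = lead_in,
                  keep_truth = keep_truth, seed = seed)
}

tiny_cohort <- function() {
  as_cohort(list(
    woman_record("a", c(2, 4), "screen_detected", 4, "stellate",
                 outcome_round = 2L),
    woman_record("b", c(2, 4), "interval_cancer", 5.1, "circular"),
    woman_record("c", numeric(), "clinical", 3.3, "stellate"),
    woman_record("d", c(2, 4, 6), "censored", 8),
    woman_record("e", numeric(), "censored", 8),
    woman_record("f", c(2), "interval_cancer", 2.9,
                 "powdery_crushed_stone")))
}
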