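# Exact screening-history likelihood against brute-force quadrature.

p_std <- nh_params("stellate", lambda1 = 0.002, lambda2 = 0.266,
                   sensitivity = 0.8)

test_that("screen-detection probability matches the quadrature oracle", {
  expect_equal(lik_screen_detected(p_std, c(2, 4), 2),
               oracle_screen_detected(0.002, 0.266, 0.8, c(2, 4), 2),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:10) {
    l1 <- runif(1, 1e-4, 1); l2 <- runif(1, 1e-4, 1)
    s <- runif(1, 0.3, 1)
    scr <- sort(runif(sample(1:4, 1), 0.5, 10))
    j <- sample(seq_along(scr), 1)
    p <- nh_params("circular", lambda1 = l1, lambda2 = l2, sensitivity = s)
    expect_equal(lik_screen_detected(p, scr, j),
                 oracle_screen_detected(l1, l2, s, scr, j),
                 tolerance = 1e-10)
  }
  expect_error(lik_screen_detected(p_std, c(2, 4), 3), "out of range")
  expect_error(lik_screen_detected(p_std, c(4, 2), 1), "increasing")
})

test_that("perfect sensitivity collapses the geometric chain of misses", {
  p1 <- nh_params("stellate", lambda1 = 0.002, lambda2 = 0.266,
                  sensitivity = 1)
  # only onset in the last inter-screen window can reach round 2
  expect_equal(lik_screen_detected(p1, c(2, 4), 2),
               oracle_kernel(0.002, 0.266, 2, 4, 4))
  # and no false-negative component exists for interval cancers
  cmp <- lik_interval_cancer_density(p1, c(2), 2.5, components = TRUE)
  expect_equal(cmp$false_negative, 0)
  expect_equal(cmp$total, cmp$newly_arising)
})

test_that("round-detection probabilities order exactly as the oracle orders them", {
  # with a slow sojourn, round 2 sees fresh onsets plus the misses of
  # round 1 and exceeds round 1; both values and the ordering must match
  # the quadrature oracle
  r1 <- lik_screen_detected(p_std, c(2, 4), 1)
  r2 <- lik_screen_detected(p_std, c(2, 4), 2)
  o1 <- oracle_screen_detected(0.002, 0.266, 0.8, c(2, 4), 1)
  o2 <- oracle_screen_detected(0.002, 0.266, 0.8, c(2, 4), 2)
  expect_equal(r1, o1, tolerance = 1e-10)
  expect_equal(r2, o2, tolerance = 1e-10)
  expect_equal(r2 > r1, o2 > o1)
  # a perfect test leaves no carried-over pool: round 1 then dominates
  p1 <- nh_params("stellate", lambda1 = 0.002, lambda2 = 0.266,
                  sensitivity = 1)
  expect_gt(lik_screen_detected(p1, c(2, 4), 1),
            lik_screen_detected(p1, c(2, 4), 2))
})

test_that("interval-cancer density matches quadrature and splits into its two components", {
  expect_equal(lik_interval_cancer_density(p_std, c(2), 2.5),
               oracle_interval_density(0.002, 0.266, 0.8, c(2), 2.5),
               tolerance = 1e-10)
  set.seed(32)
  for (i in 1:10) {
    l1 <- runif(1, 1e-4, 1); l2 <- runif(1, 1e-4, 1)
    s <- runif(1, 0.3, 1)
    scr <- sort(runif(sample(1:4, 1), 0.5, 8))
    v <- max(scr) + runif(1, 0.01, 3)
    p <- nh_params("circular", lambda1 = l1, lambda2 = l2, sensitivity = s)
    expect_equal(lik_interval_cancer_density(p, scr, v),
                 oracle_interval_density(l1, l2, s, scr, v),
                 tolerance = 1e-10)
    cmp <- lik_interval_cancer_density(p, scr, v, components = TRUE)
    expect_equal(cmp$false_negative + cmp$newly_arising, cmp$total)
    expect_true(cmp$false_negative >= 0 && cmp$newly_arising >= 0)
  }
  expect_error(lik_interval_cancer_density(p_std, c(2), 1.5),
               "strictly after")
})

test_that("censored probability matches quadrature and its reductions", {
  # no screens: disease-free or silently pre-clinical
  expect_equal(lik_censored(p_std, numeric(), 6),
               exp(-0.002 * 6) + oracle_kernel(0.002, 0.266, 0, 6, 6),
               tolerance = 1e-12)
  expect_equal(lik_censored(p_std, c(2, 4), 6),
               oracle_censored(0.002, 0.266, 0.8, c(2, 4), 6),
               tolerance = 1e-10)
  # essentially no disease: probability one
  p0 <- nh_params("stellate", lambda1 = 1e-14, lambda2 = 0.3,
                  sensitivity = 0.8)
  expect_equal(lik_censored(p0, c(1, 2, 3), 5), 1, tolerance = 1e-12)
  # non-increasing in lambda1
  l1s <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5)
  vals <- sapply(l1s, function(l1)
    lik_censored(nh_params("stellate", lambda1 = l1, lambda2 = 0.3,
                           sensitivity = 0.8), c(2, 4), 6))
  expect_true(all(diff(vals) < 0))
  expect_error(lik_censored(p_std, c(2, 4), 3), "precedes")
})

test_that("unscreened clinical density integrates to the complement of silent histories", {
  expect_equal(lik_clinical_unscreened_density(p_std, 1e-9), 0,
               tolerance = 1e-10)
  # forced degenerate branch: lambda1 = lambda2
  pd <- nh_params("stellate", lambda1 = 0.3, lambda2 = 0.3)
  expect_equal(lik_clinical_unscreened_density(pd, 1), 0.09 * exp(-0.3))
  tau <- 7
  mass <- integrate(Vectorize(function(v)
    lik_clinical_unscreened_density(p_std, v)), 0, tau,
    rel.tol = 1e-11)$value
  expect_equal(mass, 1 - lik_censored(p_std, numeric(), tau),
               tolerance = 1e-9)
})

test_that("detection-mode masses sum to one over any schedule", {
  set.seed(33)
  for (i in 1:8) {
    p <- nh_params("circular", lambda1 = runif(1, 1e-4, 1),
                   lambda2 = runif(1, 1e-4, 1),
                   sensitivity = runif(1, 0.3, 1))
    scr <- sort(runif(sample(0:4, 1), 0.5, 9))
    tau <- if (length(scr)) max(scr) + runif(1, 0.5, 3) else runif(1, 2, 10)
    expect_equal(oracle_total_mass(p, scr, tau), 1, tolerance = 1e-8)
  }
})

test_that("integrated interval mass shrinks as sensitivity rises", {
  scr <- c(2, 4)
  mass_s <- sapply(c(0.3, 0.5, 0.7, 0.9, 1), function(s) {
    p <- nh_params("stellate", lambda1 = 0.002, lambda2 = 0.266,
                   sensitivity = s)
    integrate(Vectorize(function(v)
      lik_interval_cancer_density(p, scr, v)), 4, 6, rel.tol = 1e-10)$value
  })
  expect_true(all(diff(mass_s) < 0))
})

test_that("single-round interval mass reproduces the steady-state I/E as onset becomes rare", {
  # with S = 1 and onset window (t1, t1 + delta], the interval mass per
  # unit of onset flow equals the closed-form I/E ratio
  delta <- 2; mst_v <- 3.76
  p <- nh_params("stellate", lambda1 = 1e-6, lambda2 = 1 / mst_v,
                 sensitivity = 1)
  mass <- integrate(Vectorize(function(v)
    lik_interval_cancer_density(p, c(2), v)), 2, 2 + delta,
    rel.tol = 1e-12)$value
  expect_equal(mass / (1e-6 * delta), ie_closed_form(mst_v, 1, delta),
               tolerance = 1e-4)
})

test_that("woman-level dispatch agrees with the single operations and handles features independently", {
  ps <- nh_params_set(
    nh_params("stellate", lambda1 = 2e-4, mst = 3.76, sensitivity = 0.9),
    nh_params("circular", lambda1 = 1e-4, mst = 2.65, sensitivity = 0.85))
  # single-feature reduction
  rec <- woman_record("x", c(2, 4), "screen_detected", 4, "stellate",
                      outcome_round = 2L)
  expect_equal(woman_log_likelihood(ps$stellate, rec),
               log(lik_screen_detected(ps$stellate, c(2, 4), 2)))
  # two-feature record: event term for its own feature, censored form for
  # the other at the detection time
  expect_equal(woman_log_likelihood(ps, rec),
               log(lik_screen_detected(ps$stellate, c(2, 4), 2)) +
                 log(lik_censored(ps$circular, c(2, 4), 4)))
  cens <- woman_record("y", c(2, 4), "censored", 7)
  expect_equal(woman_log_likelihood(ps, cens),
               log(lik_censored(ps$stellate, c(2, 4), 7)) +
                 log(lik_censored(ps$circular, c(2, 4), 7)))
  # negligible incidence: a censored woman carries no information
  p0 <- nh_params_set(list(nh_params("stellate", lambda1 = 1e-15,
                                     mst = 3, sensitivity = 0.9)))
  expect_equal(woman_log_likelihood(p0, cens), 0, tolerance = 1e-12)
  expect_error(
    woman_log_likelihood(ps, woman_record("z", c(2), "interval_cancer",
                                          2.5, "stellate")),
    NA)
})

test_that("cohort likelihood sums records, and schedule aggregation equals the naive loop", {
  ps <- nh_params_set(
    nh_params("stellate", lambda1 = 2e-4, mst = 3.76, sensitivity = 0.9),
    nh_params("circular", lambda1 = 1e-4, mst = 2.65, sensitivity = 0.85),
    nh_params("powdery_crushed_stone", lambda1 = 1e-4, mst = 4.26,
              sensitivity = 0.9))
  empty <- as_cohort(data.frame(
    id = character(), entry_time = numeric(), screen_times = character(),
    outcome = character(), outcome_round = integer(),
    outcome_time = numeric(), feature = character(), period = character()))
  expect_equal(cohort_log_likelihood(ps, empty), 0)

  co <- tiny_cohort()
  ll1 <- cohort_log_likelihood(ps, co)
  # two identical records double the log-likelihood
  df <- as.data.frame(co)
  df$excluded <- NULL
  co2 <- as_cohort(rbind(df, within(df, id <- paste0(id, "_dup"))))
  expect_equal(cohort_log_likelihood(ps, co2), 2 * ll1, tolerance = 1e-12)

  # a 500-woman synthetic cohort: aggregated path equals the naive sum
  cfg <- scenario_config("service_1996", n = 500, seed = 303,
                         attendance = 0.85)
  ch <- generate_cohort(cfg)
  expect_equal(cohort_log_likelihood(params_service_1996(), ch),
               cohort_log_likelihood(params_service_1996(), ch,
                                     method = "naive"),
               tolerance = 1e-10)
})

test_that("the likelihood ignores the calendar entry offset", {
  ps <- nh_params_set(list(nh_params("stellate", lambda1 = 2e-4,
                                     mst = 3.76, sensitivity = 0.9)))
  co <- tiny_cohort()
  shifted <- as.data.frame(co)
  shifted$excluded <- NULL
  shifted$entry_time <- shifted$entry_time + 11.5
  expect_equal(cohort_log_likelihood(ps, as_cohort(shifted)),
               cohort_log_likelihood(ps, co))
})
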