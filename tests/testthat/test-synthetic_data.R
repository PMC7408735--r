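# The cohort generator and the likelihood must describe the same process.

test_that("generation is deterministic given the seed, down to the written file", {
  cfg <- scenario_config("service_1996", n = 2000, seed = 99,
                         attendance = 0.9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed gives a different cohort
  c3 <- generate_cohort(scenario_config("service_1996", n = 2000,
                                        seed = 100, attendance = 0.9))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generated records always satisfy the data-model invariants", {
  for (preset in c("service_1996", "trial_1977")) {
    cfg <- scenario_config(preset, n = 5000, seed = 7, attendance = 0.8)
    ch <- generate_cohort(cfg)
    # as_cohort() already validates; spot-check the mode-specific rules
    expect_true(all(ch$outcome %in% OUTCOMES))
    scr <- parse_screens(ch$screen_times)
    last <- vapply(scr, function(s) if (length(s)) max(s) else -Inf, 0)
    ic <- ch$outcome == "interval_cancer"
    expect_true(all(ch$outcome_time[ic] > last[ic]))
    cl <- ch$outcome == "clinical"
    expect_true(all(lengths(scr)[cl] == 0L))
    expect_true(all(is.na(ch$feature[ch$outcome == "censored"])))
  }
})

test_that("the trial design screens invited women on the age-dependent schedule", {
  cfg <- scenario_config("trial_1977", n = 4000, seed = 13,
                         keep_truth = TRUE)
  ch <- generate_cohort(cfg)
  truth <- attr(ch, "truth")
  scr <- parse_screens(ch$screen_times)
  screened <- lengths(scr) > 0
  # roughly half the cohort is uninvited and never screened
  expect_gt(mean(!screened), 0.40)
  expect_lt(mean(!screened), 0.60)
  gaps <- unlist(lapply(scr[screened], diff))
  # with full attendance the gaps are exactly 24 or 33 months
  expect_true(all(abs(gaps - 2) < 1e-9 | abs(gaps - 2.75) < 1e-9))
  young <- truth$entry_age < 50 & screened
  gap_young <- unlist(lapply(scr[young], diff))
  expect_true(all(abs(gap_young - 2) < 1e-9))
})

test_that("detection-mode frequencies match the likelihood probabilities", {
  set.seed(41)
  n <- 1e5
  for (rep in 1:5) {
    l1 <- runif(1, 1e-3, 6e-3); mstv <- runif(1, 1.5, 6)
    s <- runif(1, 0.5, 1)
    p <- nh_params("stellate", lambda1 = l1, mst = mstv, sensitivity = s)
    cfg <- make_single_feature_config(n, lambda1 = l1, mst = mstv,
                                      sensitivity = s, seed = 500 + rep)
    ch <- generate_cohort(cfg)
    scr <- seq(2, 12, 2)
    p_sd <- sum(sapply(seq_along(scr), function(j)
      lik_screen_detected(p, scr, j)))
    p_ce <- lik_censored(p, scr, 12)
    p_cl <- integrate(Vectorize(function(v)
      lik_clinical_unscreened_density(p, v)), 0, 2, rel.tol = 1e-10)$value
    p_ic <- 1 - p_sd - p_ce - p_cl
    obs <- table(factor(ch$outcome, levels = OUTCOMES)) / n
    for (pair in list(c("screen_detected", p_sd), c("censored", p_ce),
                      c("clinical", p_cl), c("interval_cancer", p_ic))) {
      pr <- as.numeric(pair[2])
      expect_lt(abs(obs[[pair[1]]] - pr), 3 * sqrt(pr * (1 - pr) / n) + 1e-9)
    }
  }
})

test_that("latent sojourns of unscreened clinical cancers are exponential with the nominal mean", {
  mstv <- 3.76
  cfg <- suppressWarnings(scenario_config("custom", n = 15000,
                         features = nh_params_set(list(nh_params(
                           "stellate", lambda1 = 0.05, mst = mstv,
                           sensitivity = 0.95))),
                         interval = 2, horizon = 60, lead_in = 70,
                         keep_truth = TRUE, seed = 61))
  # lead-in beyond the horizon: nobody is ever screened (a "none" arm)
  ch <- generate_cohort(cfg)
  expect_true(all(ch$outcome %in% c("clinical", "censored")))
  truth <- attr(ch, "truth")
  keep <- ch$outcome == "clinical" & truth$onset < 30
  expect_gt(sum(keep), 8000)
  sj <- ch$outcome_time[keep] - truth$onset[keep]
  ks <- suppressWarnings(ks.test(sj, "pexp", rate = 1 / mstv))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(sj), mstv, tolerance = 0.05)
})

test_that("generator and policy engine agree on the interval-to-expected ratio", {
  # service-era stellate parameters under biennial screening: empirical
  # I/E from late-window event rates against the steady-state closed form
  p <- nh_params("stellate", lambda1 = 20e-5, mst = 3.76,
                 sensitivity = 0.95)
  mk <- function(lead) scenario_config(
    "custom", n = 1e6, features = nh_params_set(list(p)), interval = 2,
    horizon = 30, lead_in = lead, seed = 71)
  screened <- generate_cohort(mk(2))
  none <- generate_cohort(mk(40))       # first screen beyond follow-up
  w <- 18
  rate <- function(ch, mode) {
    sum(ch$outcome == mode & ch$outcome_time > w) /
      sum(pmax(ch$outcome_time - w, 0))
  }
  emp <- rate(screened, "interval_cancer") / rate(none, "clinical")
  expect_lt(abs(100 * emp - 100 * ie_closed_form(3.76, 0.95, 2)), 2)
})

test_that("descriptive tabulation counts every cancer exactly once", {
  expect_equal(nrow(tabulate_cohort(generate_cohort(
    scenario_config("custom", n = 50,
                    features = nh_params_set(list(nh_params(
                      "stellate", lambda1 = 1e-6, mst = 3))),
                    seed = 3)))), 0)
  co <- tiny_cohort()
  tab <- tabulate_cohort(co)
  expect_equal(sum(tab$n), 4)
  expect_equal(sum(tab$percent), 100)
  expect_equal(tab$n[tab$feature == "stellate" &
                       tab$outcome == "screen_detected"], 1)
  expect_true(all(tab$size_stratum == "lt15mm"))
  # equal onset rates: the three feature shares even out at scale
  cfg <- scenario_config("custom", n = 2e5,
                         features = data.frame(
                           feature = FEATURES_SMALL,
                           lambda1 = rep(2e-3, 3), mst = rep(3, 3),
                           sensitivity = rep(0.9, 3)),
                         interval = 2, horizon = 12, seed = 83)
  tab <- tabulate_cohort(generate_cohort(cfg))
  shares <- tapply(tab$percent, tab$feature, sum)
  expect_true(all(abs(shares - 100 / 3) < 2))
})

test_that("implausible configurations draw warnings but excluded labels survive round trips", {
  expect_warning(scenario_config("custom", n = 10,
                                 features = data.frame(
                                   feature = "stellate", lambda1 = 0.02,
                                   mst = 3, sensitivity = 0.9),
                                 seed = 1),
                 "implausibly high")
  expect_warning(scenario_config("service_1996", n = 10, interval = 1,
                                 seed = 1), "18 months")
  # casting-type records are carried but flagged excluded and never fitted
  rec <- woman_record("c1", c(2), "interval_cancer", 3, "casting")
  co <- as_cohort(rbind(as.data.frame(rec),
                        as.data.frame(woman_record("c2", c(2), "censored",
                                                   5))))
  expect_true(co$excluded[1])
  ps <- nh_params_set(list(nh_params("stellate", lambda1 = 1e-4,
                                     mst = 3, sensitivity = 0.9)))
  ll <- cohort_log_likelihood(ps, co)
  expect_equal(ll, log(lik_censored(ps$stellate, c(2), 5)))
})
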