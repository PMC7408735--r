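# Proportional interval-cancer incidence (the I/E ratio): interval cancers
# as a fraction of the expected background incidence without screening,
# as a function of mean sojourn time, per-screen sensitivity and the
# inter-screening interval.

#' Round half away from zero
#'
#' Display rounding used for integer-percent I/E cells (base `round()`
#' rounds half to even, which is not how the published tables are printed).
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Closed-form steady-state I/E ratio
#'
#' Under repeated screening every `delta` years at per-screen sensitivity
#' `S`, with tumour onset in steady state (uniform within a screening
#' cycle) and exponential sojourn at rate `lambda = 1/mst`, a tumour
#' becomes an interval cancer iff it surfaces clinically before any screen
#' detects it.  Conditioning on onset at `u ~ U(0, delta)` before the next
#' screen and summing the geometric chain of misses over subsequent rounds
#' gives the screen-detection probability
#' `S (1 - a) / (lambda delta (1 - (1 - S) a))` with `a = exp(-lambda
#' delta)`, hence
#' \deqn{I/E = 1 - \frac{S (1 - a)}{\lambda \Delta (1 - (1 - S) a)}.}
#' At `S = 1` this reduces to `1 - (1 - a)/(lambda delta)`; at `S = 0` it
#' equals 1 exactly (screening detects nothing).  The derivation is spelled
#' out in the package vignette and the formula is cross-checked against an
#' independent renewal microsimulation ([ie_simulate()]) in the test suite.
#'
#' @param mst mean sojourn time in years, `> 0`.
#' @param sensitivity per-screen detection probability in `[0, 1]`.
#' @param delta inter-screening interval in years, `> 0`.
#' @return I/E as a proportion in `[0, 1]`.  Vectorised with recycling.
#' @examples
#' # service-era MSTs, perfect sensitivity, annual/biennial/triennial
#' round_half_away(100 * outer(c(3.76, 2.65, 4.26), 1:3,
#'   function(m, d) ie_closed_form(m, 1, d)))
#' @export
ie_closed_form <- function(mst, sensitivity, delta) {
  if (any(mst <= 0)) stop("'mst' must be positive", call. = FALSE)
  if (any(delta <= 0)) stop("'delta' must be positive", call. = FALSE)
  if (any(sensitivity < 0 | sensitivity > 1))
    stop("'sensitivity' must lie in [0, 1]", call. = FALSE)
  n <- max(length(mst), length(sensitivity), length(delta))
  mst <- rep_len(mst, n); s <- rep_len(sensitivity, n)
  delta <- rep_len(delta, n)
  lam <- 1 / mst
  a <- exp(-lam * delta)
  1 - s * (1 - a) / (lam * delta * (1 - (1 - s) * a))
}

#' Renewal microsimulation of the steady-state I/E ratio
#'
#' Independent stochastic check of [ie_closed_form()]: simulate `n` tumours
#' with onset uniform within a screening cycle, exponential sojourn with
#' mean `mst`, and an independent Bernoulli(`sensitivity`) detection chance
#' at every screen falling inside the sojourn; a tumour missed (or never
#' screened) before its sojourn ends surfaces as an interval cancer.
#'
#' @inheritParams ie_closed_form
#' @param n number of simulated tumours.
#' @param seed integer seed (required).
#' @return list: `ie` (interval fraction), `se` (binomial Monte-Carlo
#'   standard error), `n_interval`, `n_detected`, `n`.
#' @export
ie_simulate <- function(mst, sensitivity, delta, n = 1e6, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(length(mst) == 1L, length(sensitivity) == 1L,
            length(delta) == 1L, mst > 0, delta > 0,
            sensitivity >= 0, sensitivity <= 1, n >= 1)
  set.seed(as.integer(seed))
  u <- stats::runif(n, 0, delta)            # onset position within a cycle
  sj <- stats::rexp(n, 1 / mst)             # sojourn in PCDP
  # screens while in PCDP sit at delta - u, 2 delta - u, ...: their count
  k <- floor((sj + u) / delta)
  # at least one of k independent Bernoulli(S) screens succeeds
  detected <- stats::runif(n) < 1 - (1 - sensitivity)^k
  ie <- mean(!detected)
  list(ie = ie, se = sqrt(ie * (1 - ie) / n),
       n_interval = sum(!detected), n_detected = sum(detected), n = n)
}

#' Specify one arm of a simulated screening trial
#'
#' @param arm one of `"annual"`, `"biennial"`, `"triennial"`, `"none"`.
#' @param interval inter-screening interval in years; defaults to 1, 2, 3
#'   by arm label and is ignored (infinite) for `"none"`.
#' @param horizon follow-up horizon in years (`>= interval` for screening
#'   arms).
#' @param attendance per-invitation attendance probability in `(0, 1]`.
#' @param lead_in disease-free run-in before the first screen, years.
#' @return a `regime_spec` with derived `rounds = floor((horizon -
#'   lead_in)/interval) + 1`.
#' @export
regime_spec <- function(arm = c("annual", "biennial", "triennial", "none"),
                        interval = NULL, horizon = 12,
                        attendance = 1, lead_in = NULL) {
  arm <- match.arg(arm)
  if (is.null(interval))
    interval <- switch(arm, annual = 1, biennial = 2, triennial = 3,
                       none = Inf)
  if (is.null(lead_in)) lead_in <- if (is.finite(interval)) interval else 0
  stopifnot(attendance > 0, attendance <= 1, horizon > 0, lead_in >= 0)
  if (arm != "none") {
    stopifnot(interval > 0, is.finite(interval))
    if (horizon < interval)
      stop("'horizon' must be at least one interval", call. = FALSE)
  }
  screens <- if (arm == "none") numeric() else
    seq(lead_in, horizon, by = interval)
  structure(list(arm = arm, interval = interval, horizon = horizon,
                 attendance = attendance, lead_in = lead_in,
                 screens = screens, rounds = length(screens)),
            class = "regime_spec")
}

#' Four-arm microsimulated screening trial
#'
#' Individual-level simulation of a randomised design with annual,
#' biennial, triennial and no-screening arms: per woman, onset of the
#' pre-clinical phase at rate `lambda1`, exponential sojourn with mean
#' `1/lambda2`, Bernoulli attendance per invitation and Bernoulli(`S`)
#' detection per attended screen while pre-clinical.  The empirical I/E of
#' a screening arm is its interval-cancer rate per person-year divided by
#' the clinical-cancer rate per person-year in the `none` arm.
#'
#' @param params single-feature [nh_params].
#' @param regimes list of [regime_spec()]s; must contain a `"none"` arm for
#'   the I/E denominator (otherwise I/E is reported as `NA` with a
#'   warning).
#' @param n_per_arm women per arm.
#' @param seed integer seed (required).
#' @param rate_window_start events and person-years entering the I/E rates
#'   are counted from this time (years from entry) onward.  The default 0
#'   uses the whole follow-up, which includes the ramp-up transient before
#'   the standing pre-clinical pool reaches equilibrium; to compare against
#'   the steady-state closed form, start the window a few sojourn times
#'   after the first screen.  Outcome counts are always reported for the
#'   full follow-up.
#' @return a `rct_result`: per-arm outcome counts (screen-detected by
#'   round, interval, clinical, censored), person-years, rates, and
#'   empirical I/E per screening arm.
#' @export
simulate_rct <- function(params, regimes = list(
                           regime_spec("annual"), regime_spec("biennial"),
                           regime_spec("triennial"), regime_spec("none")),
                         n_per_arm = 1e5, seed, rate_window_start = 0) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(inherits(params, "nh_params"), n_per_arm >= 1,
            rate_window_start >= 0)
  names(regimes) <- vapply(regimes, `[[`, "", "arm")
  set.seed(as.integer(seed))
  arms <- lapply(regimes, function(rg) {
    h <- simulate_histories_engine(
      n = n_per_arm, lambda1 = params$lambda1, mst = 1 / params$lambda2,
      sensitivity = params$sensitivity, screens = rg$screens,
      attendance = rg$attendance, horizon = rg$horizon)
    h
  })
  w <- rate_window_start
  summarise <- function(h, rg) {
    py <- sum(h$outcome_time)
    by_round <- if (rg$rounds)
      tabulate(h$round[h$outcome == "screen_detected"], rg$rounds)
    else integer()
    in_win <- h$outcome_time > w
    py_w <- sum(pmax(h$outcome_time - w, 0))
    list(arm = rg$arm,
         counts = c(table(factor(h$outcome, levels = OUTCOMES))),
         screen_detected_by_round = by_round,
         person_years = py,
         interval_rate = sum(h$outcome == "interval_cancer" & in_win) / py_w,
         clinical_rate = sum(h$outcome == "clinical" & in_win) / py_w)
  }
  summ <- Map(summarise, arms, regimes)
  ie <- rep(NA_real_, length(summ)); names(ie) <- names(summ)
  if (!"none" %in% names(summ)) {
    warning("no 'none' arm: empirical I/E undefined", call. = FALSE)
  } else {
    e_rate <- summ$none$clinical_rate
    if (e_rate == 0) {
      warning("zero clinical cancers in the control arm: I/E undefined",
              call. = FALSE)
    } else {
      for (a in names(summ))
        if (a != "none") ie[a] <- summ[[a]]$interval_rate / e_rate
    }
  }
  structure(list(arms = summ, ie = ie[names(ie) != "none"],
                 params = params, n_per_arm = n_per_arm, seed = seed),
            class = "rct_result")
}

#' @export
print.rct_result <- function(x, ...) {
  cat("<rct_result>", x$n_per_arm, "women per arm\n")
  for (a in x$arms)
    cat(sprintf("  %-9s  %s  py=%.0f\n", a$arm,
                paste(names(a$counts), a$counts, sep = "=",
                      collapse = " "), a$person_years))
  cat("empirical I/E (%):",
      paste(names(x$ie), sprintf("%.1f", 100 * x$ie), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Grid of I/E ratios by feature, interval and sensitivity
#'
#' Evaluates the I/E ratio for every combination of feature, interval and
#' sensitivity specification, in the layout of the published policy table.
#' `"estimated"` rows take each feature's fitted sensitivity from `params`.
#' A validation pass asserts the qualitative laws the grid must obey: for a
#' fixed feature, I/E never decreases with the interval and never increases
#' with sensitivity.
#'
#' @param params an [nh_params_set].
#' @param deltas intervals in years.
#' @param sensitivities fixed sensitivity values.
#' @param include_estimated add rows at each feature's own sensitivity.
#' @param method `"closed_form"` or `"simulation"`.
#' @param n_sim,seed tumours per cell and seed for `method =
#'   "simulation"`.
#' @return an `ie_table` data.frame: feature, delta, sensitivity_spec,
#'   sensitivity, `ie` (proportion), `ie_percent` (unrounded) and
#'   `ie_percent_int` (half-away-from-zero integer display value).
#' @export
build_ie_table <- function(params, deltas = c(1, 2, 3),
                           sensitivities = c(0.4, 0.5, 0.6, 0.8, 1.0),
                           include_estimated = TRUE,
                           method = c("closed_form", "simulation"),
                           n_sim = 1e6, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(params, "nh_params_set"))
  rows <- list()
  for (f in names(params)) {
    p <- params[[f]]
    specs <- c(as.list(sensitivities),
               if (include_estimated) list("estimated"))
    for (sp in specs) {
      s <- if (identical(sp, "estimated")) p$sensitivity else sp
      for (d in deltas) {
        ie <- if (method == "closed_form")
          ie_closed_form(1 / p$lambda2, s, d)
        else
          ie_simulate(1 / p$lambda2, s, d, n = n_sim,
                      seed = seed + length(rows))$ie
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, delta = d,
          sensitivity_spec = if (identical(sp, "estimated")) "estimated"
                             else formatC(sp, format = "g"),
          sensitivity = s, ie = ie, ie_percent = 100 * ie,
          ie_percent_int = round_half_away(100 * ie))
      }
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("ie_table", "data.frame")
  validate_ie_table(tab, strict = method == "closed_form")
  tab
}

#' @rdname build_ie_table
#' @param tab an `ie_table`.
#' @param strict error (rather than warn) on a monotonicity violation;
#'   simulation grids are allowed Monte-Carlo wiggle.
#' @export
validate_ie_table <- function(tab, strict = TRUE) {
  stopifnot(inherits(tab, "ie_table"))
  complain <- function(msg) if (strict) stop(msg, call. = FALSE)
                            else warning(msg, call. = FALSE)
  if (any(tab$ie < 0 | tab$ie > 1)) complain("I/E outside [0, 1]")
  for (f in unique(tab$feature)) {
    sub <- tab[tab$feature == f, ]
    for (sp in unique(sub$sensitivity_spec)) {
      x <- sub[sub$sensitivity_spec == sp, ]
      if (is.unsorted(x$ie[order(x$delta)]))
        complain(paste0("I/E not non-decreasing in interval (", f, ")"))
    }
    for (d in unique(sub$delta)) {
      x <- sub[sub$delta == d, ]
      if (is.unsorted(rev(x$ie[order(x$sensitivity)])))
        complain(paste0("I/E not non-increasing in sensitivity (", f, ")"))
    }
  }
  invisible(tab)
}

#' Feasible (interval, sensitivity) policy frontier
#'
#' For each candidate inter-screening interval, the minimal per-screen
#' sensitivity at which the closed-form I/E ratio stays at or below the
#' criterion for every supplied feature simultaneously (the worst-case
#' feature binds).  A stricter criterion never loosens the required
#' sensitivity.
#'
#' @param params an [nh_params_set] (only the sojourn rates are used).
#' @param criterion maximal acceptable I/E in percent, in `(0, 100]`.
#' @param deltas candidate intervals in years.
#' @return data.frame: delta, minimal sensitivity (`NA` if infeasible even
#'   at `S = 1`), feasibility flag, and the binding (worst-case) feature.
#' @export
policy_threshold_search <- function(params, criterion,
                                    deltas = c(1, 2, 3)) {
  stopifnot(inherits(params, "nh_params_set"),
            criterion > 0, criterion <= 100)
  target <- criterion / 100
  worst_ie <- function(s, d) {
    v <- vapply(params, function(p) ie_closed_form(1 / p$lambda2, s, d), 0)
    max(v)
  }
  binding_feature <- function(s, d) {
    v <- vapply(params, function(p) ie_closed_form(1 / p$lambda2, s, d), 0)
    names(params)[which.max(v)]
  }
  out <- lapply(deltas, function(d) {
    f_hi <- worst_ie(1, d) - target
    if (f_hi > 0)
      return(data.frame(delta = d, s_min = NA_real_, feasible = FALSE,
                        binding = binding_feature(1, d)))
    if (worst_ie(0, d) - target <= 0)
      return(data.frame(delta = d, s_min = 0, feasible = TRUE,
                        binding = binding_feature(0, d)))
    r <- stats::uniroot(function(s) worst_ie(s, d) - target, c(0, 1),
                        tol = 1e-10)
    data.frame(delta = d, s_min = r$root, feasible = TRUE,
               binding = binding_feature(r$root, d))
  })
  do.call(rbind, out)
}
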