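# Exact likelihood of an individual screening history under the
# three-state exponential model with imperfect per-screen sensitivity.
#
# Everything is built from the kernel
#   A(a, b; T) = int_a^b lambda1 e^{-lambda1 u} e^{-lambda2 (T - u)} du,
# the probability of entering the pre-clinical phase in (a, b] and still
# being pre-clinical (undetected by nature, screens handled separately) at
# time T >= b.  Closed form:
#   A = lambda1/(lambda2 - lambda1) * (e^{lambda2 b - lambda2 T - lambda1 b
#        + lambda2 b ...})  -- implemented with exponents combined so that
# no large intermediate exponential is formed; the lambda1 == lambda2 limit
# is lambda1 e^{-lambda1 T} (b - a).

#' Pre-clinical occupancy kernel
#'
#' Probability that disease onset (rate `lambda1` from a disease-free start
#' at time 0) occurs in `(a, b]` and the tumour is still in the
#' pre-clinical detectable phase at time `T` (sojourn rate `lambda2`).
#' Vectorised over `a`, `b`, `T`.
#'
#' @param lambda1,lambda2 positive rates per year.
#' @param a,b window of onset, `0 <= a <= b <= T`.
#' @param T evaluation time in years.
#' @return probability vector.
#' @keywords internal
#' @export
pcdp_kernel <- function(lambda1, lambda2, a, b, T) {
  d <- lambda2 - lambda1
  if (abs(d) < .DEGENERATE_TOL)
    lambda1 * exp(-lambda1 * T) * (b - a)
  else
    lambda1 / d * (exp(d * b - lambda2 * T) - exp(d * a - lambda2 * T))
}

check_screens <- function(screen_times) {
  if (length(screen_times) &&
      (any(screen_times < 0) || is.unsorted(screen_times, strictly = TRUE)))
    stop("screen times must be non-negative and strictly increasing",
         call. = FALSE)
  invisible(screen_times)
}

#' Probability of screen detection at a given round
#'
#' Probability that a woman, disease-free at entry and attending screens at
#' `screen_times`, has her cancer detected at round `j`: onset in some
#' inter-screen window `(t_{i-1}, t_i]`, a false negative (probability
#' `1 - S` each) at every intervening screen, survival in the pre-clinical
#' phase to `t_j`, and a true positive at `t_j`.
#'
#' @param params single-feature [nh_params].
#' @param screen_times strictly increasing attended screen times (years
#'   from entry).
#' @param j round index, `1 <= j <= length(screen_times)`.
#' @return probability in `(0, 1)`.
#' @export
lik_screen_detected <- function(params, screen_times, j) {
  stopifnot(inherits(params, "nh_params"))
  check_screens(screen_times)
  if (j < 1L || j > length(screen_times))
    stop("round index j out of range", call. = FALSE)
  l1 <- params$lambda1; l2 <- params$lambda2; s <- params$sensitivity
  tj <- screen_times[j]
  bounds <- c(0, screen_times[seq_len(j)])
  i <- seq_len(j)
  terms <- (1 - s)^(j - i) *
    pcdp_kernel(l1, l2, bounds[i], bounds[i + 1L], tj)
  s * sum(terms)
}

#' Interval-cancer density at a clinical surfacing time
#'
#' Density (per year) of surfacing clinically at time `v` after the last
#' attended screen.  Interval cancers comprise two components: false
#' negatives missed at one or more previous screens, and newly arising
#' cancers with onset after the last screen; both are returned.
#'
#' @inheritParams lik_screen_detected
#' @param v surfacing time, strictly after the last attended screen.
#' @param components if `TRUE`, return a list with elements
#'   `false_negative`, `newly_arising` and `total`.
#' @return density (per year), or the component list.
#' @export
lik_interval_cancer_density <- function(params, screen_times, v,
                                        components = FALSE) {
  stopifnot(inherits(params, "nh_params"))
  check_screens(screen_times)
  k <- length(screen_times)
  if (k < 1L || v <= screen_times[k])
    stop("surfacing time must lie strictly after the last attended screen",
         call. = FALSE)
  l1 <- params$lambda1; l2 <- params$lambda2; s <- params$sensitivity
  bounds <- c(0, screen_times)
  i <- seq_len(k)
  fn <- l2 * sum((1 - s)^(k - i + 1L) *
                   pcdp_kernel(l1, l2, bounds[i], bounds[i + 1L], v))
  new <- l2 * pcdp_kernel(l1, l2, screen_times[k], v, v)
  if (components) list(false_negative = fn, newly_arising = new,
                       total = fn + new)
  else fn + new
}

#' Probability of a censored (event-free) history
#'
#' Probability of showing nothing through censor time `tau`: still
#' disease-free, or in the pre-clinical phase with every attended screen a
#' false negative (including tumours arising after the last screen).
#'
#' @inheritParams lik_screen_detected
#' @param tau censor time, `>=` the last attended screen (screens may be
#'   empty).
#' @return probability in `(0, 1]`.
#' @export
lik_censored <- function(params, screen_times, tau) {
  stopifnot(inherits(params, "nh_params"))
  check_screens(screen_times)
  k <- length(screen_times)
  if (k && tau < screen_times[k])
    stop("censor time precedes the last attended screen", call. = FALSE)
  if (tau < 0) stop("'tau' must be non-negative", call. = FALSE)
  l1 <- params$lambda1; l2 <- params$lambda2; s <- params$sensitivity
  p <- exp(-l1 * tau)
  if (k) {
    bounds <- c(0, screen_times)
    i <- seq_len(k)
    p <- p + sum((1 - s)^(k - i + 1L) *
                   pcdp_kernel(l1, l2, bounds[i], bounds[i + 1L], tau)) +
      pcdp_kernel(l1, l2, screen_times[k], tau, tau)
  } else {
    p <- p + pcdp_kernel(l1, l2, 0, tau, tau)
  }
  p
}

#' Clinical-incidence density for an unscreened woman
#'
#' Density of surfacing clinically at time `v` with no screening at all:
#' `lambda2 * A(0, v; v)`.  This is the microdata analogue of the expected
#' (background) incidence used as the denominator of the I/E ratio.
#'
#' @inheritParams lik_screen_detected
#' @param v surfacing time, `> 0`.
#' @return density (per year).
#' @export
lik_clinical_unscreened_density <- function(params, v) {
  stopifnot(inherits(params, "nh_params"))
  if (any(v <= 0)) stop("'v' must be positive", call. = FALSE)
  params$lambda2 * pcdp_kernel(params$lambda1, params$lambda2, 0, v, v)
}

# event-term log density/probability of a record for its own feature
record_event_loglik <- function(params, scr, outcome, outcome_round,
                                outcome_time) {
  switch(outcome,
    screen_detected = log(lik_screen_detected(params, scr, outcome_round)),
    interval_cancer = log(lik_interval_cancer_density(params, scr,
                                                      outcome_time)),
    clinical = log(lik_clinical_unscreened_density(params, outcome_time)),
    stop("no event term for outcome ", outcome, call. = FALSE))
}

#' Log-likelihood of one woman's record
#'
#' Dispatches on the record's detection mode.  Under a multi-feature model
#' the feature-specific disease processes are treated as independent (their
#' per-year onset rates are of order 1e-3 or less, so synchronous cancers
#' are negligible): a woman with a cancer of feature `f` contributes `f`'s
#' event term times every other fitted feature's censored-form term at her
#' outcome time; a censored woman contributes every fitted feature's
#' censored term.
#'
#' @param params an [nh_params] (single-feature model) or [nh_params_set].
#' @param record a [woman_record()] (or one-row cohort slice).
#' @return log-probability (log-density for surfacing outcomes).
#' @export
woman_log_likelihood <- function(params, record) {
  if (inherits(params, "nh_params")) params <- nh_params_set(list(params))
  stopifnot(inherits(params, "nh_params_set"))
  rec <- as.data.frame(record)
  if (nrow(rec) != 1L) stop("'record' must be a single row", call. = FALSE)
  scr <- parse_screens(rec$screen_times)[[1L]]
  outcome <- rec$outcome
  feat <- rec$feature
  is_cancer <- outcome != "censored"
  if (is_cancer && (is.na(feat) || !nzchar(feat)))
    stop("cancer outcome without a feature [id: ", rec$id, "]",
         call. = FALSE)
  # a cancer of a feature outside the fitted set still contributes the
  # fitted features' no-event terms up to her exit time
  ll <- 0
  # screens relevant to the no-event terms: those at or before outcome_time
  scr_trunc <- scr[scr <= rec$outcome_time + 1e-12]
  for (f in names(params)) {
    p <- params[[f]]
    ll <- ll + if (is_cancer && f == feat)
      record_event_loglik(p, scr, outcome, rec$outcome_round,
                          rec$outcome_time)
    else
      log(lik_censored(p, scr_trunc, max(rec$outcome_time,
                                         if (length(scr_trunc))
                                           scr_trunc[length(scr_trunc)]
                                         else 0)))
  }
  ll
}

#' Log-likelihood of a cohort
#'
#' Sum of [woman_log_likelihood()] over records.  With
#' `method = "aggregated"` (default) records sharing a schedule/outcome
#' signature are evaluated once and weighted by their count -- identical to
#' the naive per-record sum to floating-point accuracy, and the path used by
#' the fitting routines.  Records carrying excluded features are skipped
#' (they are outside the fitted model).
#'
#' @param params an [nh_params] or [nh_params_set]; every cancer feature in
#'   the cohort must be present in the set.
#' @param cohort an [as_cohort()] object.
#' @param method `"aggregated"` or `"naive"`.
#' @return total log-likelihood (0 for an empty cohort).
#' @export
cohort_log_likelihood <- function(params, cohort,
                                  method = c("aggregated", "naive")) {
  method <- match.arg(method)
  if (inherits(params, "nh_params")) params <- nh_params_set(list(params))
  stopifnot(inherits(params, "nh_params_set"), inherits(cohort, "cohort"))
  cohort <- cohort[!cohort$excluded, , drop = FALSE]
  if (!nrow(cohort)) return(0)
  if (method == "naive") {
    return(sum(vapply(seq_len(nrow(cohort)), function(i)
      tryCatch(woman_log_likelihood(params, cohort[i, , drop = FALSE]),
               error = function(e) stop(conditionMessage(e), call. = FALSE)),
      0)))
  }
  sum(vapply(names(params), function(f) {
    prep <- prepare_feature_data(cohort, f)
    feature_loglik(params[[f]], prep)
  }, 0))
}

# ---- aggregated evaluation -------------------------------------------------
#
# For one feature f, the cohort log-likelihood splits into
#   event records of f       : screen_detected / interval / clinical terms
#   all other records        : censored-form terms with screens truncated at
#                              the record's own outcome time
# Records are grouped by (schedule, outcome signature) so each distinct
# probability is computed once; interval/clinical surfacing times are kept
# as vectors and evaluated with the vectorised kernel.

prepare_feature_data <- function(cohort, feature) {
  stopifnot(inherits(cohort, "cohort"))
  scr <- parse_screens(cohort$screen_times)
  is_event <- !is.na(cohort$feature) & cohort$feature == feature
  out <- list(sd = NULL, ic = list(), cl = numeric(), cens = NULL)

  ev <- cohort[is_event, , drop = FALSE]
  scr_ev <- scr[is_event]
  if (nrow(ev)) {
    sd_i <- ev$outcome == "screen_detected"
    if (any(sd_i)) {
      key <- paste(ev$screen_times[sd_i], ev$outcome_round[sd_i], sep = "|")
      tab <- tapply(seq_along(key), key, identity, simplify = FALSE)
      out$sd <- lapply(tab, function(ix) list(
        screens = scr_ev[sd_i][[ix[1L]]],
        j = ev$outcome_round[sd_i][ix[1L]], n = length(ix)))
    }
    ic_i <- ev$outcome == "interval_cancer"
    if (any(ic_i)) {
      key <- ev$screen_times[ic_i]
      tab <- tapply(seq_along(key), key, identity, simplify = FALSE)
      out$ic <- lapply(tab, function(ix) list(
        screens = scr_ev[ic_i][[ix[1L]]],
        v = ev$outcome_time[ic_i][ix]))
    }
    out$cl <- ev$outcome_time[ev$outcome == "clinical"]
  }

  oth <- cohort[!is_event, , drop = FALSE]
  if (nrow(oth)) {
    scr_oth <- scr[!is_event]
    trunc <- mapply(function(s, tt) s[s <= tt + 1e-12], scr_oth,
                    oth$outcome_time, SIMPLIFY = FALSE)
    key <- paste(vapply(trunc, join_screens, ""),
                 formatC(oth$outcome_time, digits = 12, format = "g"),
                 sep = "|")
    tab <- tapply(seq_along(key), key, identity, simplify = FALSE)
    out$cens <- lapply(tab, function(ix) list(
      screens = trunc[[ix[1L]]], tau = oth$outcome_time[ix[1L]],
      n = length(ix)))
  }
  out
}

# vectorised interval-density over surfacing times v (shared schedule)
ic_density_vec <- function(l1, l2, s, screens, v) {
  k <- length(screens)
  bounds <- c(0, screens)
  fn <- 0
  for (i in seq_len(k))
    fn <- fn + (1 - s)^(k - i + 1L) *
      pcdp_kernel(l1, l2, bounds[i], bounds[i + 1L], v)
  l2 * (fn + pcdp_kernel(l1, l2, screens[k], v, v))
}

feature_loglik <- function(params, prep) {
  l1 <- params$lambda1; l2 <- params$lambda2; s <- params$sensitivity
  ll <- 0
  for (g in prep$sd)
    ll <- ll + g$n * log(lik_screen_detected(params, g$screens, g$j))
  for (g in prep$ic)
    ll <- ll + sum(log(ic_density_vec(l1, l2, s, g$screens, g$v)))
  if (length(prep$cl))
    ll <- ll + sum(log(l2 * pcdp_kernel(l1, l2, 0, prep$cl, prep$cl)))
  for (g in prep$cens)
    ll <- ll + g$n * log(lik_censored(params, g$screens, g$tau))
  ll
}
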