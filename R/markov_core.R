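# Three-state progressive Markov model of screen-detectable cancer:
#   free  --lambda1-->  pcdp  --lambda2-->  cp
# Time-homogeneous exponential rates; no regression between states.

#' Mammographic feature classes
#'
#' The analysis strata: three mammographic appearance categories for small
#' (1--14 mm) invasive tumours plus a single unstratified stratum for
#' tumours of 15 mm or larger.  Casting-type calcifications and
#' architectural distortion can appear in input data but are never fitted
#' (they mark ductal-type disease outside the model's scope); see
#' [feature_excluded()].
#'
#' @format Character vectors.
#' @name features
NULL

#' @rdname features
#' @export
FEATURES_SMALL <- c("stellate", "circular", "powdery_crushed_stone")

#' @rdname features
#' @export
FEATURES_ALL <- c(FEATURES_SMALL, "large_ge15mm")

#' @rdname features
#' @export
FEATURES_EXCLUDED <- c("casting", "architectural_distortion")

#' Is a feature label excluded from fitting?
#'
#' @param feature character vector of feature labels.
#' @return logical vector, `TRUE` for labels that are parsed but never
#'   fitted.
#' @export
feature_excluded <- function(feature) feature %in% FEATURES_EXCLUDED

#' Model states
#' @export
STATES <- c("free", "pcdp", "cp")

check_feature <- function(feature, allow_excluded = FALSE) {
  ok <- FEATURES_ALL
  if (allow_excluded) ok <- c(ok, FEATURES_EXCLUDED)
  if (!is.character(feature) || length(feature) != 1L || !feature %in% ok)
    stop("unknown feature class: ", paste(feature, collapse = ", "),
         call. = FALSE)
  invisible(feature)
}

#' Natural-history parameters for one feature class
#'
#' The estimand triple of the model: the pre-clinical incidence rate
#' `lambda1` (rate of entering the pre-clinical detectable phase, PCDP, per
#' person-year), the PCDP-to-clinical-phase transition rate `lambda2` (per
#' year; its reciprocal is the mean sojourn time, MST), and the per-screen
#' test `sensitivity`.  Rates are always stored per person-year; per-100,000
#' formatting is an output concern only.
#'
#' @param feature feature class label (see [features]).
#' @param lambda1 pre-clinical incidence rate, per person-year, `> 0`.
#' @param lambda2 PCDP-to-CP transition rate, per year, `> 0`.  Give either
#'   `lambda2` or `mst`.
#' @param mst mean sojourn time in years (`lambda2 = 1/mst`).
#' @param sensitivity per-screen detection probability, in `(0, 1]`.
#' @param period free-text period label (e.g. `"1996-2010"`).
#' @return An object of class `nh_params`.
#' @examples
#' p <- nh_params("stellate", lambda1 = 20e-5, mst = 3.76, sensitivity = 0.95)
#' mst(p)
#' @export
nh_params <- function(feature, lambda1, lambda2 = NULL, mst = NULL,
                      sensitivity = 1, period = NA_character_) {
  check_feature(feature)
  if (is.null(lambda2) == is.null(mst))
    stop("give exactly one of 'lambda2' or 'mst'", call. = FALSE)
  if (is.null(lambda2)) {
    if (!is.numeric(mst) || length(mst) != 1L || !is.finite(mst) || mst <= 0)
      stop("'mst' must be a positive number (years)", call. = FALSE)
    lambda2 <- 1 / mst
  }
  if (!is.numeric(lambda1) || length(lambda1) != 1L || !is.finite(lambda1) ||
      lambda1 <= 0)
    stop("'lambda1' must be a positive rate per person-year", call. = FALSE)
  if (!is.numeric(lambda2) || length(lambda2) != 1L || !is.finite(lambda2) ||
      lambda2 <= 0)
    stop("'lambda2' must be a positive rate per year", call. = FALSE)
  if (!is.numeric(sensitivity) || length(sensitivity) != 1L ||
      !is.finite(sensitivity) || sensitivity <= 0 || sensitivity > 1)
    stop("'sensitivity' must lie in (0, 1]", call. = FALSE)
  structure(
    list(feature = feature, lambda1 = lambda1, lambda2 = lambda2,
         sensitivity = sensitivity, period = as.character(period)),
    class = "nh_params")
}

#' @export
print.nh_params <- function(x, ...) {
  cat(sprintf(
    "<nh_params> %s%s\n  lambda1 = %.6g /person-year (%.4g per 100,000/yr)\n  lambda2 = %.6g /year  (MST %.3g y)\n  sensitivity = %.3g\n",
    x$feature,
    if (is.na(x$period)) "" else paste0(" [", x$period, "]"),
    x$lambda1, x$lambda1 * 1e5, x$lambda2, 1 / x$lambda2, x$sensitivity))
  invisible(x)
}

#' Mean sojourn time
#'
#' Expected time spent in the pre-clinical detectable phase before clinical
#' surfacing: `1 / lambda2` years under the exponential model.
#'
#' @param params an [nh_params] object.
#' @return MST in years.
#' @export
mst <- function(params) {
  stopifnot(inherits(params, "nh_params"))
  1 / params$lambda2
}

#' Bundle per-feature parameters into a set
#'
#' @param ... `nh_params` objects, or a single list of them.
#' @return A named list of class `nh_params_set`, keyed by feature.
#' @export
nh_params_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && !inherits(ps[[1L]], "nh_params")) ps <- ps[[1L]]
  if (!length(ps) || !all(vapply(ps, inherits, TRUE, "nh_params")))
    stop("all elements must be nh_params objects", call. = FALSE)
  feats <- vapply(ps, `[[`, "", "feature")
  if (anyDuplicated(feats))
    stop("duplicate feature in parameter set: ",
         feats[duplicated(feats)][1L], call. = FALSE)
  names(ps) <- feats
  structure(ps, class = "nh_params_set")
}

#' @export
`[.nh_params_set` <- function(x, i) {
  structure(NextMethod(), class = "nh_params_set")
}

#' @export
print.nh_params_set <- function(x, ...) {
  cat("<nh_params_set> ", length(x), " feature(s)\n", sep = "")
  df <- data.frame(
    feature = names(x),
    lambda1_per1e5 = vapply(x, function(p) p$lambda1 * 1e5, 0),
    mst_years = vapply(x, function(p) 1 / p$lambda2, 0),
    sensitivity = vapply(x, function(p) p$sensitivity, 0),
    row.names = NULL)
  print(df, row.names = FALSE)
  invisible(x)
}

# tolerance below which lambda1 ~ lambda2 switches to the l'Hopital branch;
# avoids catastrophic cancellation in (e^{-l1 t} - e^{-l2 t})/(l2 - l1)
.DEGENERATE_TOL <- 1e-9

#' Transition probability of the three-state process
#'
#' Time-homogeneous transition probabilities of the progressive process
#' free -> pcdp -> cp.  For distinct rates,
#' `P(free -> pcdp; t) = lambda1/(lambda2 - lambda1) (e^{-lambda1 t} -
#' e^{-lambda2 t})`; when `|lambda2 - lambda1|` falls below an internal
#' tolerance the limiting form `lambda1 t e^{-lambda1 t}` is used.
#' Remaining masses follow by complement, so each row of the implied
#' transition matrix sums to one.
#'
#' @param params an [nh_params] object (sensitivity is not used here).
#' @param from,to state labels among `"free"`, `"pcdp"`, `"cp"`.
#' @param t elapsed time in years, `>= 0` (vectorised).
#' @return probability (vector along `t`).
#' @export
transition_probability <- function(params, from, to, t) {
  stopifnot(inherits(params, "nh_params"))
  if (!from %in% STATES || !to %in% STATES)
    stop("unknown state pair: ", from, " -> ", to, call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  l1 <- params$lambda1; l2 <- params$lambda2
  p_fp <- function(t) {
    if (abs(l2 - l1) < .DEGENERATE_TOL) l1 * t * exp(-l1 * t)
    else l1 / (l2 - l1) * (exp(-l1 * t) - exp(-l2 * t))
  }
  switch(paste(from, to, sep = "."),
    free.free = exp(-l1 * t),
    free.pcdp = p_fp(t),
    free.cp   = 1 - exp(-l1 * t) - p_fp(t),
    pcdp.free = rep(0, length(t)),
    pcdp.pcdp = exp(-l2 * t),
    pcdp.cp   = 1 - exp(-l2 * t),
    cp.free   = rep(0, length(t)),
    cp.pcdp   = rep(0, length(t)),
    cp.cp     = rep(1, length(t)))
}

#' Cumulative risk of clinical surfacing from the pre-clinical phase
#'
#' Probability that a tumour already in the pre-clinical detectable phase at
#' time 0 has progressed to clinical (symptomatic) disease by time `t`, in
#' the absence of any early detection: `1 - exp(-lambda2 t)`.
#'
#' @inheritParams transition_probability
#' @return probability, monotone non-decreasing in `t`.
#' @export
cumulative_risk_cp <- function(params, t) {
  stopifnot(inherits(params, "nh_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  1 - exp(-params$lambda2 * t)
}

#' Median time from pre-clinical to clinical phase
#'
#' `log(2) / lambda2` years: the time at which [cumulative_risk_cp()]
#' reaches one half.
#'
#' @param params an [nh_params] object with `lambda2 > 0`.
#' @return years.
#' @export
median_time_to_cp <- function(params) {
  stopifnot(inherits(params, "nh_params"))
  if (params$lambda2 <= 0) stop("'lambda2' must be positive", call. = FALSE)
  log(2) / params$lambda2
}

#' Proportional-hazards reparameterisation of the transition rates
#'
#' The per-feature rates can equivalently be written as a baseline rate
#' times a feature-specific log-rate offset (two proportional-hazards
#' regression forms, one for each transition):
#' `lambda1(f) = lambda1_0 exp(beta1)`, `lambda2(f) = lambda2_0 exp(beta2)`,
#' with the reference feature's offsets fixed at zero.  This mapping is a
#' bijection with the per-feature rate parameterisation; [rate_offsets()]
#' is its inverse.
#'
#' @param baseline reference-feature [nh_params].
#' @param beta1,beta2 finite log-rate offsets for the target feature.
#' @param feature target feature label (defaults to the baseline's).
#' @return an [nh_params] for `feature` with the offset rates.
#' @export
proportional_hazards_rates <- function(baseline, beta1 = 0, beta2 = 0,
                                       feature = baseline$feature) {
  stopifnot(inherits(baseline, "nh_params"))
  if (!is.finite(beta1) || !is.finite(beta2))
    stop("offsets must be finite", call. = FALSE)
  nh_params(feature,
            lambda1 = baseline$lambda1 * exp(beta1),
            lambda2 = baseline$lambda2 * exp(beta2),
            sensitivity = baseline$sensitivity,
            period = baseline$period)
}

#' @rdname proportional_hazards_rates
#' @param target an [nh_params] whose rates are expressed relative to
#'   `baseline`.
#' @return for `rate_offsets()`: named vector `c(beta1, beta2)`.
#' @export
rate_offsets <- function(baseline, target) {
  stopifnot(inherits(baseline, "nh_params"), inherits(target, "nh_params"))
  c(beta1 = log(target$lambda1 / baseline$lambda1),
    beta2 = log(target$lambda2 / baseline$lambda2))
}

#' Published service-era (1996--2010) parameter set
#'
#' Mean sojourn times for the three small-tumour mammographic appearance
#' classes are the published sensitivity-adjusted estimates (stellate 3.76,
#' circular 2.65, powdery/crushed-stone 4.26 years) with per-screen
#' sensitivity 0.95 for every class (the published estimates are 0.95 or
#' above).  Pre-clinical incidence rates and the large-tumour stratum are
#' synthetic defaults chosen to be epidemiologically plausible for a
#' Swedish screening population aged 40+; see the package vignette.
#'
#' @return an [nh_params_set].
#' @export
params_service_1996 <- function() {
  nh_params_set(
    nh_params("stellate", lambda1 = 95e-5, mst = 3.76,
              sensitivity = 0.95, period = "1996-2010"),
    nh_params("circular", lambda1 = 47e-5, mst = 2.65,
              sensitivity = 0.95, period = "1996-2010"),
    nh_params("powdery_crushed_stone", lambda1 = 38e-5, mst = 4.26,
              sensitivity = 0.95, period = "1996-2010"),
    nh_params("large_ge15mm", lambda1 = 90e-5, mst = 2.0,
              sensitivity = 0.95, period = "1996-2010"))
}

#' Synthetic trial-era (1977--1985) parameter set
#'
#' All numeric values here are synthetic: only qualitative constraints are
#' encoded (sojourn times longer than in the service era, sensitivity lower
#' -- lowest for stellate masses among small tumours; small-tumour incidence
#' about 26% lower and large-tumour incidence about 1.8x higher than the
#' service era; a powdery/crushed-stone share about half its later value).
#'
#' @return an [nh_params_set].
#' @export
params_trial_1977 <- function() {
  nh_params_set(
    nh_params("stellate", lambda1 = 85e-5, mst = 4.3,
              sensitivity = 0.75, period = "1977-1985"),
    nh_params("circular", lambda1 = 43e-5, mst = 3.2,
              sensitivity = 0.85, period = "1977-1985"),
    nh_params("powdery_crushed_stone", lambda1 = 15e-5, mst = 4.4,
              sensitivity = 0.85, period = "1977-1985"),
    nh_params("large_ge15mm", lambda1 = 160e-5, mst = 1.9,
              sensitivity = 0.70, period = "1977-1985"))
}
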