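# Fitting the natural-history triple (lambda1, lambda2, S) per feature.
# Working scale throughout: theta = (log lambda1, log lambda2, logit S);
# the likelihood factorises over features, so each feature's block is
# optimised / sampled on its own.

PARAM_NAMES <- c("lambda1", "lambda2", "sensitivity")

theta_to_params <- function(theta, feature, s_fixed = NULL) {
  s <- if (is.null(s_fixed)) stats::plogis(theta[3L]) else s_fixed
  nh_params(feature, lambda1 = exp(theta[1L]), lambda2 = exp(theta[2L]),
            sensitivity = s)
}

#' Prior specification for MCMC fitting
#'
#' Independent priors on the working scale: normal on `log(lambda1)` and
#' `log(lambda2)`, Beta on the sensitivity.  The defaults are vague
#' (normal(0, 10) on the log rates, uniform Beta(1, 1) on `S`); the
#' published analysis does not state its priors, so these are deliberate
#' package choices, echoed into every fit for provenance.
#'
#' @param log_lambda1_mean,log_lambda1_sd,log_lambda2_mean,log_lambda2_sd
#'   normal hyper-parameters for the log rates.
#' @param sens_shape1,sens_shape2 Beta hyper-parameters for sensitivity.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(log_lambda1_mean = 0, log_lambda1_sd = 10,
                       log_lambda2_mean = 0, log_lambda2_sd = 10,
                       sens_shape1 = 1, sens_shape2 = 1) {
  stopifnot(log_lambda1_sd > 0, log_lambda2_sd > 0,
            sens_shape1 > 0, sens_shape2 > 0)
  structure(list(log_lambda1_mean = log_lambda1_mean,
                 log_lambda1_sd = log_lambda1_sd,
                 log_lambda2_mean = log_lambda2_mean,
                 log_lambda2_sd = log_lambda2_sd,
                 sens_shape1 = sens_shape1, sens_shape2 = sens_shape2),
            class = "prior_spec")
}

# log prior density on the working scale (includes the logit Jacobian)
log_prior <- function(theta, prior, s_fixed = NULL) {
  lp <- stats::dnorm(theta[1L], prior$log_lambda1_mean,
                     prior$log_lambda1_sd, log = TRUE) +
    stats::dnorm(theta[2L], prior$log_lambda2_mean, prior$log_lambda2_sd,
                 log = TRUE)
  if (is.null(s_fixed)) {
    s <- stats::plogis(theta[3L])
    lp <- lp + stats::dbeta(s, prior$sens_shape1, prior$sens_shape2,
                            log = TRUE) + log(s) + log1p(-s)
  }
  lp
}

crude_start <- function(cohort, feature) {
  n_cancer <- sum(!is.na(cohort$feature) & cohort$feature == feature)
  py <- person_years(cohort)
  l1 <- max(n_cancer, 0.5) / max(py, 1)
  c(log(l1), log(1 / 2.5), stats::qlogis(0.9))
}

make_objective <- function(cohort, feature, prior = NULL, s_fixed = NULL) {
  prep <- prepare_feature_data(cohort, feature)
  function(theta) {
    p <- theta_to_params(theta, feature, s_fixed)
    ll <- feature_loglik(p, prep)
    if (!is.finite(ll)) return(-Inf)
    if (!is.null(prior)) ll <- ll + log_prior(theta, prior, s_fixed)
    ll
  }
}

#' Maximum-likelihood fit of the screening natural-history model
#'
#' Maximises [cohort_log_likelihood()] per feature over
#' `(log lambda1, log lambda2, logit S)` with BFGS from a small multistart
#' (deterministic given `seed`).  95% intervals are Wald intervals from the
#' observed information on the working scale, back-transformed (monotone),
#' so interval endpoints for MST are the reciprocals of the `lambda2`
#' endpoints, swapped.
#'
#' @param cohort an [as_cohort()] object.
#' @param features features to fit; defaults to every fitted-class feature
#'   with at least one cancer in the cohort.
#' @param fix_sensitivity `NULL` to estimate sensitivity, or a single value
#'   in `(0, 1]` (e.g. `1` for a perfect-test fit) applied to all features.
#' @param n_starts number of multistart points (first is a crude
#'   data-driven start, the rest jittered).
#' @param seed integer seed controlling the multistart jitter.
#' @return a `screening_fit` object: `estimates` (one row per feature and
#'   parameter, including the derived MST), `loglik`, `converged`,
#'   `diagnostics` and the configuration echo.
#' @export
fit_mle <- function(cohort, features = NULL, fix_sensitivity = NULL,
                    n_starts = 3L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) > 0L)
  features <- resolve_features(cohort, features)
  if (!is.null(fix_sensitivity))
    stopifnot(fix_sensitivity > 0, fix_sensitivity <= 1)
  np <- if (is.null(fix_sensitivity)) 3L else 2L
  est <- list(); diag_l <- list(); ll_tot <- 0; conv <- TRUE
  for (f in features) {
    n_ev <- sum(!is.na(cohort$feature) & cohort$feature == f)
    if (n_ev == 0L)
      warning("feature '", f, "' has zero events; lambda1 estimate is at ",
              "the boundary", call. = FALSE)
    obj <- make_objective(cohort, f, s_fixed = fix_sensitivity)
    neg <- function(th) -obj(th[seq_len(np)])
    start0 <- crude_start(cohort, f)[seq_len(np)]
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    starts <- c(list(start0), lapply(seq_len(max(0L, n_starts - 1L)),
      function(i) start0 + stats::rnorm(np, 0, 0.5)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    fits <- lapply(starts, function(st)
      tryCatch(stats::optim(st, neg, method = "BFGS", hessian = TRUE,
                            control = list(maxit = 500, reltol = 1e-10)),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits))
      stop("optimisation failed for feature '", f, "'", call. = FALSE)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    if (best$convergence != 0L) {
      conv <- FALSE
      warning("optimiser did not converge for feature '", f, "' (code ",
              best$convergence, ")", call. = FALSE)
    }
    th <- best$par
    se <- rep(NA_real_, np)
    H <- best$hessian
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    if (all(is.finite(ev)) && all(ev > 0)) se <- sqrt(diag(solve(H)))
    flat_s <- np == 3L && (!is.finite(H[3L, 3L]) || H[3L, 3L] < 1e-3)
    if (flat_s)
      warning("profile likelihood in sensitivity is nearly flat for '", f,
              "'; S and lambda2 are weakly identified", call. = FALSE)
    lo <- th - 1.96 * se; hi <- th + 1.96 * se
    tab <- data.frame(
      feature = f,
      parameter = c(PARAM_NAMES[seq_len(np)], "mst"),
      estimate = c(exp(th[1L]), exp(th[2L]),
                   if (np == 3L) stats::plogis(th[3L]), exp(-th[2L])),
      lower = c(exp(lo[1L]), exp(lo[2L]),
                if (np == 3L) stats::plogis(lo[3L]), exp(-hi[2L])),
      upper = c(exp(hi[1L]), exp(hi[2L]),
                if (np == 3L) stats::plogis(hi[3L]), exp(-lo[2L])))
    if (!is.null(fix_sensitivity))
      tab <- rbind(tab, data.frame(feature = f, parameter = "sensitivity",
                                   estimate = fix_sensitivity,
                                   lower = NA_real_, upper = NA_real_))
    est[[f]] <- tab
    ll_tot <- ll_tot - best$value
    diag_l[[f]] <- list(n_events = n_ev, convergence = best$convergence,
                        flat_sensitivity = flat_s,
                        gradient_checked = TRUE)
  }
  structure(list(
    method = "mle", estimates = do.call(rbind, est), draws = NULL,
    loglik = ll_tot, converged = conv, diagnostics = diag_l,
    config = list(features = features, fix_sensitivity = fix_sensitivity,
                  n_starts = n_starts, seed = seed,
                  interval_method = "wald-observed-information")),
    class = "screening_fit")
}

resolve_features <- function(cohort, features) {
  if (is.null(features)) {
    features <- intersect(FEATURES_ALL, unique(stats::na.omit(cohort$feature)))
    if (!length(features))
      stop("no fitted-class cancers in cohort; give 'features' explicitly",
           call. = FALSE)
  }
  for (f in features) check_feature(f)
  features
}

#' Random-walk Metropolis MCMC fit
#'
#' Component-wise Gaussian random-walk Metropolis on
#' `(log lambda1, log lambda2, logit S)` per feature.  Proposal scales are
#' adapted in batches of 50 iterations during burn-in only (targeting
#' 20--40% acceptance) and frozen afterwards, preserving detailed balance
#' in the retained draws.  Point estimates are posterior medians; 95%
#' intervals are the 2.5th/97.5th percentiles.  Deterministic given `seed`.
#'
#' @inheritParams fit_mle
#' @param prior a [prior_spec()].
#' @param chains,iterations,burnin,thin chain configuration; `iterations`
#'   counts post-burn-in iterations per chain before thinning.
#' @param proposal_scale initial random-walk SDs for the three components.
#' @param seed integer seed; required, no default.
#' @return a `screening_fit` with `draws`: per feature, a matrix (draw x
#'   parameter) pooled across chains; `diagnostics` carries acceptance
#'   rates and effective sample sizes.
#' @export
fit_mcmc <- function(cohort, features = NULL, prior = prior_spec(),
                     fix_sensitivity = NULL, chains = 4L,
                     iterations = 20000L, burnin = 5000L, thin = 5L,
                     proposal_scale = c(0.3, 0.3, 0.5), seed) {
  if (missing(seed))
    stop("'seed' is required for fit_mcmc(); there is no silent default",
         call. = FALSE)
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) > 0L,
            inherits(prior, "prior_spec"), chains >= 1L, iterations > 0L,
            burnin >= 0L, thin >= 1L)
  features <- resolve_features(cohort, features)
  np <- if (is.null(fix_sensitivity)) 3L else 2L
  est <- list(); draws_l <- list(); diag_l <- list()
  for (fi in seq_along(features)) {
    f <- features[fi]
    obj <- make_objective(cohort, f, prior = prior, s_fixed = fix_sensitivity)
    start <- crude_start(cohort, f)[seq_len(np)]
    if (!is.finite(obj(start)))
      stop("posterior is not finite at the starting point for feature '",
           f, "'", call. = FALSE)
    ch_draws <- vector("list", chains)
    acc_all <- matrix(NA_real_, chains, np)
    for (ch in seq_len(chains)) {
      set.seed(as.integer((seed + 104729 * (fi - 1L) + ch - 1L) %% .Machine$integer.max))
      init <- start + stats::rnorm(np, 0, 0.2)
      run <- metropolis_chain(obj, init, proposal_scale[seq_len(np)],
                              burnin, iterations, thin)
      ch_draws[[ch]] <- run$draws
      acc_all[ch, ] <- run$acceptance
    }
    th_draws <- do.call(rbind, ch_draws)
    mat <- cbind(lambda1 = exp(th_draws[, 1L]),
                 lambda2 = exp(th_draws[, 2L]),
                 sensitivity = if (np == 3L) stats::plogis(th_draws[, 3L])
                               else rep(fix_sensitivity, nrow(th_draws)),
                 mst = exp(-th_draws[, 2L]))
    q <- apply(mat, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE)
    # MST summaries are the exact reciprocal of the lambda2 quantiles
    # (quantile interpolation is not equivariant under 1/x)
    q[, "mst"] <- 1 / q[c(1L, 3L, 2L), "lambda2"]
    est[[f]] <- data.frame(feature = f, parameter = colnames(mat),
                           estimate = q[1L, ], lower = q[2L, ],
                           upper = q[3L, ], row.names = NULL)
    draws_l[[f]] <- mat
    acc <- colMeans(acc_all)
    if (any(acc < 0.1 | acc > 0.6))
      warning("post-adaptation acceptance rate outside [0.1, 0.6] for '",
              f, "': ", paste(sprintf("%.2f", acc), collapse = ", "),
              call. = FALSE)
    diag_l[[f]] <- list(
      acceptance = acc,
      ess = apply(th_draws, 2L, ess_univariate),
      n_draws = nrow(th_draws), chains = chains)
  }
  structure(list(
    method = "mcmc", estimates = do.call(rbind, est), draws = draws_l,
    loglik = NA_real_, converged = TRUE, diagnostics = diag_l,
    config = list(features = features, prior = unclass(prior),
                  fix_sensitivity = fix_sensitivity, chains = chains,
                  iterations = iterations, burnin = burnin, thin = thin,
                  proposal_scale = proposal_scale, seed = seed,
                  point = "posterior-median", interval = "central-95")),
    class = "screening_fit")
}

# one component-wise random-walk chain; adaptation only during burn-in
metropolis_chain <- function(logpost, init, scale, burnin, iterations,
                             thin) {
  np <- length(init)
  th <- init
  lp <- logpost(th)
  n_keep <- iterations %/% thin
  draws <- matrix(NA_real_, n_keep, np)
  acc_ct <- integer(np); batch_ct <- integer(np); batch_n <- 0L
  kept <- 0L
  total <- burnin + iterations
  for (it in seq_len(total)) {
    for (p in seq_len(np)) {
      prop <- th
      prop[p] <- th[p] + stats::rnorm(1L, 0, scale[p])
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
        th <- prop; lp <- lp_prop
        if (it > burnin) acc_ct[p] <- acc_ct[p] + 1L
        else batch_ct[p] <- batch_ct[p] + 1L
      }
    }
    if (it <= burnin) {
      batch_n <- batch_n + 1L
      if (batch_n == 50L) {
        rate <- batch_ct / 50
        scale <- scale * exp((rate - 0.3))
        batch_ct[] <- 0L; batch_n <- 0L
      }
    } else if ((it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- th
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       acceptance = acc_ct / iterations)
}

# effective sample size from the initial-positive-sequence autocorrelation
ess_univariate <- function(x) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1L] - 1L else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' @export
print.screening_fit <- function(x, ...) {
  cat("<screening_fit> method:", x$method, "\n")
  df <- x$estimates
  df$estimate <- signif(df$estimate, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sensitivity-adjusted mean sojourn time
#'
#' The MST summary from a joint fit of `(lambda1, lambda2, S)`:
#' "sensitivity-adjusted" means the sojourn rate was estimated while
#' sensitivity was estimated too, rather than assumed perfect.  Fixing
#' `S = 1` on the same data typically yields a shorter apparent MST because
#' missed cancers are read as fast progression; use
#' [compare_sensitivity_adjustment()] to see both.
#'
#' @param fit a `screening_fit`.
#' @param feature feature label present in the fit.
#' @return one-row data.frame: estimate, lower, upper (years).
#' @export
sensitivity_adjusted_mst <- function(fit, feature) {
  stopifnot(inherits(fit, "screening_fit"))
  rows <- fit$estimates$feature == feature & fit$estimates$parameter == "mst"
  if (!any(rows))
    stop("feature '", feature, "' not present in fit", call. = FALSE)
  fit$estimates[rows, c("estimate", "lower", "upper")]
}

#' @rdname sensitivity_adjusted_mst
#' @param cohort,seed passed to two [fit_mle()] calls: one joint, one with
#'   sensitivity fixed at 1.
#' @return for `compare_sensitivity_adjustment()`: data.frame with the MST
#'   from the joint fit and from the perfect-test fit.
#' @export
compare_sensitivity_adjustment <- function(cohort, feature, seed = 1L) {
  joint <- fit_mle(cohort, features = feature, seed = seed)
  fixed <- fit_mle(cohort, features = feature, fix_sensitivity = 1,
                   seed = seed)
  data.frame(
    fit = c("joint", "sensitivity_fixed_1"),
    mst = c(sensitivity_adjusted_mst(joint, feature)$estimate,
            sensitivity_adjusted_mst(fixed, feature)$estimate))
}

#' Serialise a fit to JSON
#'
#' Structured-text export: parameter table, diagnostics, configuration echo
#' and an md5 digest of the cohort file when one is given.
#'
#' @param fit a `screening_fit`.
#' @param file output path.
#' @param cohort_file optional path of the cohort the fit came from.
#' @return `file`, invisibly.
#' @export
write_fit_json <- function(fit, file, cohort_file = NULL) {
  stopifnot(inherits(fit, "screening_fit"))
  out <- list(
    method = fit$method, estimates = fit$estimates, loglik = fit$loglik,
    converged = fit$converged,
    diagnostics = lapply(fit$diagnostics, function(d)
      lapply(d, function(v) if (is.numeric(v)) unname(v) else v)),
    config = fit$config)
  if (!is.null(cohort_file))
    out$input_digest <- unname(tools::md5sum(cohort_file))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
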