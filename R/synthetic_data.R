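# Synthetic screening cohorts with the statistical structure the analysis
# assumes: feature-specific competing exponential onset, exponential
# sojourn, Bernoulli attendance per invitation and Bernoulli(S) detection
# per attended screen while pre-clinical.  The generator and the screening
# likelihood describe the same stochastic process; the test suite checks
# that their detection-mode frequencies agree.

# Classify n simulated disease courses against a common screen schedule.
# onset/sojourn/sensitivity are per-woman vectors; screens is the shared
# schedule (years from entry).  Draws attendance and detection uniforms in
# a fixed order, so results are reproducible given the RNG state.
classify_histories <- function(onset, sojourn, sensitivity, screens,
                               attendance, horizon, records = TRUE) {
  n <- length(onset)
  k <- length(screens)
  surf <- onset + sojourn
  att <- if (k) matrix(stats::runif(n * k) < attendance, n, k)
         else matrix(FALSE, n, 0L)
  udet <- if (k) matrix(stats::runif(n * k), n, k) else NULL
  outcome <- rep("censored", n)
  outcome_time <- rep(horizon, n)
  round_idx <- rep(NA_integer_, n)
  detected <- rep(FALSE, n)
  att_count <- integer(n)              # attended screens so far
  for (j in seq_len(k)) {
    sj <- screens[j]
    if (sj > horizon) break
    a <- att[, j]
    eligible <- !detected & a & onset <= sj & surf > sj
    det <- eligible & udet[, j] < sensitivity
    # attended-round index of this schedule round, per woman
    att_count_j <- att_count + as.integer(a)
    round_idx[det] <- att_count_j[det]
    detected[det] <- TRUE
    outcome[det] <- "screen_detected"
    outcome_time[det] <- sj
    # women already out (detected or surfaced) stop attending
    still_in <- !detected & surf > sj
    att_count[still_in | det] <- att_count_j[still_in | det]
    att[!still_in & !det, j] <- FALSE   # screens after exit never happened
  }
  surfaced <- !detected & surf <= horizon
  outcome_time[surfaced] <- surf[surfaced]
  n_before <- if (k) {
    before <- att & outer(surf, screens, ">")
    as.integer(rowSums(before))
  } else integer(n)
  outcome[surfaced & n_before >= 1L] <- "interval_cancer"
  outcome[surfaced & n_before < 1L] <- "clinical"
  res <- list(outcome = outcome, outcome_time = outcome_time,
              round = round_idx, detected = detected, surfaced = surfaced)
  if (records) {
    # attended-screen strings, built column-wise (same formatting as
    # join_screens)
    str <- character(n)
    if (k) {
      fmt <- formatC(screens, digits = 12, format = "g", width = 1)
      for (j in seq_len(k)) {
        sel <- att[, j] & screens[j] <= outcome_time + 1e-12
        str[sel] <- ifelse(nzchar(str[sel]), paste(str[sel], fmt[j],
                                                   sep = ";"), fmt[j])
      }
    }
    res$screen_str <- str
  }
  res
}

# schedule from first screen to horizon; empty when the lead-in already
# exceeds follow-up (an unscreened design)
screen_seq <- function(lead_in, horizon, interval) {
  if (lead_in > horizon) numeric() else seq(lead_in, horizon, by = interval)
}

# single-feature engine: draws onset and sojourn, then classifies
simulate_histories_engine <- function(n, lambda1, mst, sensitivity,
                                      screens, attendance, horizon,
                                      records = FALSE) {
  onset <- stats::rexp(n, lambda1)
  sojourn <- stats::rexp(n) * mst
  classify_histories(onset, sojourn, rep(sensitivity, n), screens,
                     attendance, horizon, records = records)
}

params_to_df <- function(params) {
  data.frame(feature = names(params),
             lambda1 = vapply(params, `[[`, 0, "lambda1"),
             mst = vapply(params, function(p) 1 / p$lambda2, 0),
             sensitivity = vapply(params, `[[`, 0, "sensitivity"),
             row.names = NULL)
}

#' Scenario configuration for the cohort generator
#'
#' Presets encode the two emulated study designs.  `"trial_1977"`: an
#' invited arm screened at 24 months for entry ages under 50 and 33 months
#' at 50 or older, against an uninvited arm, entry ages uniform on 40--74.
#' `"service_1996"`: an observational service-screening schedule with a
#' single configurable interval (18--36 months; default 24).  Feature
#' parameters default to [params_trial_1977()] / [params_service_1996()].
#'
#' @param preset `"trial_1977"`, `"service_1996"` or `"custom"`.
#' @param n number of women.
#' @param features per-feature parameters: an [nh_params_set] or a
#'   data.frame with columns feature, lambda1, mst, sensitivity.
#' @param interval inter-screening interval in years (service/custom
#'   presets).
#' @param attendance per-invitation attendance probability.
#' @param lead_in years from entry to the first screen; the first screen
#'   therefore detects an accumulated (prevalence-like) pool.
#' @param horizon follow-up in years from entry.
#' @param entry_age_range ages drawn uniformly on this range; ages only
#'   gate the trial schedule rule, rates never depend on them.
#' @param invited_fraction fraction invited to screening (trial preset).
#' @param keep_truth attach the latent onset/sojourn table to the cohort.
#' @param seed integer seed; mandatory.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(preset = c("service_1996", "trial_1977",
                                       "custom"),
                            n = 10000L, features = NULL, interval = 2,
                            attendance = 1, lead_in = NULL, horizon = 12,
                            entry_age_range = c(40, 74),
                            invited_fraction = 0.5, keep_truth = FALSE,
                            seed) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (is.null(features))
    features <- switch(preset, trial_1977 = params_trial_1977(),
                       params_service_1996())
  if (inherits(features, "nh_params_set")) features <- params_to_df(features)
  stopifnot(is.data.frame(features),
            all(c("feature", "lambda1", "mst", "sensitivity") %in%
                  names(features)),
            n >= 1, horizon > 0, attendance > 0, attendance <= 1,
            invited_fraction > 0, invited_fraction <= 1)
  if (preset == "service_1996" && (interval < 1.5 || interval > 3))
    warning("service-era schedules ranged from 18 months to 3 years; ",
            "interval ", interval, " y is outside that range",
            call. = FALSE)
  if (is.null(lead_in)) lead_in <- 2
  total_l1 <- sum(features$lambda1)
  if (total_l1 > 1000e-5)
    warning(sprintf(
      "total pre-clinical incidence %.0f per 100,000/yr is implausibly high",
      total_l1 * 1e5), call. = FALSE)
  structure(list(preset = preset, n = as.integer(n), features = features,
                 interval = interval, attendance = attendance,
                 lead_in = lead_in, horizon = horizon,
                 entry_age_range = entry_age_range,
                 invited_fraction = invited_fraction,
                 keep_truth = keep_truth, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic screening cohort
#'
#' Per woman: feature-specific competing onset times (exponential at each
#' feature's `lambda1`; the earliest wins), an exponential sojourn at the
#' winning feature's rate, the preset's screening schedule, Bernoulli
#' attendance per invitation and Bernoulli(S) detection per attended screen
#' during the pre-clinical phase.  Detection modes, record fields and
#' validation follow the cohort data model exactly; the output is
#' byte-stable given the seed.
#'
#' @param config a [scenario_config()].
#' @return a [as_cohort()] object; if `config$keep_truth`, the latent
#'   per-woman truth (winning feature, onset, sojourn) is attached as
#'   `attr(, "truth")`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n
  fdf <- cf$features
  nf <- nrow(fdf)
  ages <- stats::runif(n, cf$entry_age_range[1L], cf$entry_age_range[2L])
  onsets <- matrix(stats::rexp(n * nf,
                               rate = rep(fdf$lambda1, each = n)), n, nf)
  win <- max.col(-onsets, ties.method = "first")
  onset <- onsets[cbind(seq_len(n), win)]
  sojourn <- stats::rexp(n) * fdf$mst[win]
  sens <- fdf$sensitivity[win]
  feature <- fdf$feature[win]

  # schedule groups: trial = invited under/over 50 + uninvited;
  # service/custom = one screened group
  if (cf$preset == "trial_1977") {
    invited <- stats::runif(n) < cf$invited_fraction
    grp <- ifelse(!invited, "uninvited",
                  ifelse(ages < 50, "invited_lt50", "invited_ge50"))
    schedules <- list(
      invited_lt50 = screen_seq(cf$lead_in, cf$horizon, 2),
      invited_ge50 = screen_seq(cf$lead_in, cf$horizon, 2.75),
      uninvited = numeric())
  } else {
    grp <- rep("screened", n)
    schedules <- list(screened = screen_seq(cf$lead_in, cf$horizon,
                                            cf$interval))
  }

  out <- vector("list", length(schedules))
  names(out) <- names(schedules)
  idx_all <- integer(0)
  for (g in names(schedules)) {
    ix <- which(grp == g)
    if (!length(ix)) next
    cl <- classify_histories(onset[ix], sojourn[ix], sens[ix],
                             schedules[[g]], cf$attendance, cf$horizon,
                             records = TRUE)
    out[[g]] <- cl
    idx_all <- c(idx_all, ix)
  }
  ord <- order(idx_all)
  pull <- function(fld) unlist(lapply(out[!vapply(out, is.null, TRUE)],
                                      `[[`, fld), use.names = FALSE)[ord]
  outcome <- pull("outcome")
  records <- data.frame(
    id = sprintf("w%07d", seq_len(n)),
    entry_time = 0,
    screen_times = pull("screen_str"),
    outcome = outcome,
    outcome_round = as.integer(pull("round")),
    outcome_time = pull("outcome_time"),
    feature = ifelse(outcome == "censored", NA_character_, feature),
    period = switch(cf$preset, trial_1977 = "1977-1985",
                    service_1996 = "1996-2010", "custom"),
    stringsAsFactors = FALSE)
  cohort <- as_cohort(records, period = records$period[1L])
  if (cf$keep_truth)
    attr(cohort, "truth") <- data.frame(
      id = records$id, feature = feature, onset = onset, sojourn = sojourn,
      entry_age = ages)
  attr(cohort, "config") <- cf
  cohort
}

#' Descriptive tabulation of a cohort's cancers
#'
#' Counts and percentages of cancer records by feature class, size stratum
#' and detection mode; the shape of a descriptive feature/size breakdown.
#'
#' @param cohort a `cohort`.
#' @return data.frame with one row per feature x detection mode present
#'   (zero rows if the cohort holds no cancers); percentages are of all
#'   cancer records and sum to 100 within rounding.
#' @export
tabulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ca <- cohort[cohort$outcome != "censored", , drop = FALSE]
  if (!nrow(ca))
    return(data.frame(feature = character(), size_stratum = character(),
                      outcome = character(), n = integer(),
                      percent = numeric()))
  tab <- as.data.frame(table(feature = ca$feature, outcome = ca$outcome),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  tab$size_stratum <- ifelse(tab$feature == "large_ge15mm", "ge15mm",
                             "lt15mm")
  tab$percent <- 100 * tab$Freq / nrow(ca)
  out <- data.frame(feature = tab$feature,
                    size_stratum = tab$size_stratum,
                    outcome = tab$outcome, n = tab$Freq,
                    percent = tab$percent)
  out[order(out$feature, out$outcome), ]
}
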