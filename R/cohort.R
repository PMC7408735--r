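# Individual screening event histories.  One row per woman, times in years
# on her own clock (0 = entry, assumed disease-free).  Attended screens are
# stored as a semicolon-joined ascending list; unattended invitations never
# appear.

OUTCOMES <- c("screen_detected", "interval_cancer", "clinical", "censored")

#' Build a single woman's screening record
#'
#' The unit of data of the screening likelihood: entry time, attended screen
#' times, and how (and when) follow-up ended.  All times are years since the
#' woman's entry, at which she is assumed free of detectable disease.
#'
#' @param id identifier (coerced to character; unique within a cohort).
#' @param screen_times numeric vector of attended screen times, strictly
#'   increasing, all `>= 0`; may be empty.
#' @param outcome one of `"screen_detected"`, `"interval_cancer"`,
#'   `"clinical"` (surfaced with no attended screen), `"censored"`.
#' @param outcome_time years since entry: the detection screen's time for a
#'   screen-detected cancer, the clinical surfacing time for interval or
#'   clinical cancers, the censoring time otherwise.
#' @param feature feature class of the cancer; `NA` iff censored.  Excluded
#'   labels (casting, architectural distortion) are accepted but flagged.
#' @param outcome_round round index of a screen-detected cancer (`NA`
#'   otherwise).
#' @param entry_time entry time on an external calendar (bookkeeping only;
#'   the likelihood is invariant to it).
#' @param period free-text period label.
#' @return one-row `data.frame` with class `woman_record`.
#' @export
woman_record <- function(id, screen_times = numeric(), outcome,
                         outcome_time, feature = NA_character_,
                         outcome_round = NA_integer_, entry_time = 0,
                         period = NA_character_) {
  rec <- data.frame(
    id = as.character(id), entry_time = as.numeric(entry_time),
    screen_times = join_screens(screen_times),
    outcome = as.character(outcome),
    outcome_round = as.integer(outcome_round),
    outcome_time = as.numeric(outcome_time),
    feature = as.character(feature), period = as.character(period),
    stringsAsFactors = FALSE)
  msg <- validate_record_df(rec)
  if (length(msg)) stop(paste(msg, collapse = "\n"), call. = FALSE)
  class(rec) <- c("woman_record", "data.frame")
  rec
}

join_screens <- function(x) {
  if (!length(x)) "" else paste(formatC(x, digits = 12, format = "g",
                                        width = 1), collapse = ";")
}

#' Parse a semicolon-joined screen-time field
#' @param x character vector.
#' @return list of numeric vectors.
#' @export
parse_screens <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(s) as.numeric(s[nzchar(s)]))
}

# row-level invariant checks on the data.frame representation; returns a
# character vector of messages tagged with ids (empty when valid)
validate_record_df <- function(df) {
  msg <- character()
  bad <- function(cond, what)
    if (any(cond)) msg <<- c(msg, paste0(
      what, " [id: ", paste(utils::head(df$id[cond], 5L), collapse = ", "),
      if (sum(cond) > 5L) ", ..." else "", "]"))
  bad(!df$outcome %in% OUTCOMES, "unknown outcome")
  scr <- parse_screens(df$screen_times)
  incr <- vapply(scr, function(s)
    !length(s) || (all(s >= 0) && all(diff(s) > 0)), TRUE)
  bad(!incr, "screen_times must be non-negative and strictly increasing")
  bad(!is.finite(df$outcome_time) | df$outcome_time < 0,
      "outcome_time must be a non-negative number")
  last <- vapply(scr, function(s) if (length(s)) s[length(s)] else -Inf, 0)
  nscr <- lengths(scr)
  is_sd <- df$outcome == "screen_detected"
  is_ic <- df$outcome == "interval_cancer"
  is_cl <- df$outcome == "clinical"
  is_ce <- df$outcome == "censored"
  bad(is_sd & (is.na(df$outcome_round) | df$outcome_round < 1L |
                 df$outcome_round > nscr),
      "screen_detected needs a valid outcome_round")
  sd_ok <- rep(TRUE, nrow(df))
  idx <- which(is_sd & !is.na(df$outcome_round) & df$outcome_round >= 1L &
                 df$outcome_round <= nscr)
  if (length(idx))
    sd_ok[idx] <- vapply(idx, function(i)
      isTRUE(all.equal(scr[[i]][df$outcome_round[i]], df$outcome_time[i],
                       tolerance = 1e-8)), TRUE)
  bad(!sd_ok, "screen_detected outcome_time must equal its round's screen time")
  bad(is_ic & (nscr == 0L | df$outcome_time <= last),
      "interval_cancer requires a prior screen and surfacing strictly after it")
  bad(is_cl & nscr > 0L, "clinical outcome requires zero attended screens")
  bad(is_ce & df$outcome_time < pmax(last, 0),
      "censor time precedes last screen")
  cancer <- is_sd | is_ic | is_cl
  bad(cancer & (is.na(df$feature) | df$feature == ""),
      "cancer outcome needs a feature")
  bad(is_ce & !is.na(df$feature) & df$feature != "",
      "censored record must have no feature")
  known <- c(FEATURES_ALL, FEATURES_EXCLUDED)
  bad(cancer & !is.na(df$feature) & !df$feature %in% known, "unknown feature")
  msg
}

#' Assemble a cohort of screening records
#'
#' @param records a `data.frame` with the columns of [woman_record()] (or a
#'   list of `woman_record`s).
#' @param period optional period label attached to the cohort.
#' @return a `data.frame` of class `cohort`.  Excluded-feature records are
#'   kept but flagged in column `excluded`; they are never fitted.
#' @export
as_cohort <- function(records, period = NULL) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(is.data.frame(records))
  need <- c("id", "entry_time", "screen_times", "outcome", "outcome_round",
            "outcome_time", "feature", "period")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)[need]
  records$id <- as.character(records$id)
  records$outcome_round <- as.integer(records$outcome_round)
  records$outcome_time <- as.numeric(records$outcome_time)
  if (anyDuplicated(records$id))
    stop("duplicate ids in cohort: ",
         paste(utils::head(unique(records$id[duplicated(records$id)]), 5L),
               collapse = ", "), call. = FALSE)
  msg <- validate_record_df(records)
  if (length(msg)) stop(paste(msg, collapse = "\n"), call. = FALSE)
  records$excluded <- !is.na(records$feature) &
    records$feature %in% FEATURES_EXCLUDED
  if (!is.null(period)) attr(records, "period") <- period
  class(records) <- c("cohort", "data.frame")
  records
}

#' @export
print.cohort <- function(x, ...) {
  py <- sum(x$outcome_time)
  cat(sprintf("<cohort> %d women, %.0f person-years%s\n", nrow(x), py,
              if (is.null(attr(x, "period"))) ""
              else paste0(" [", attr(x, "period"), "]")))
  print(table(outcome = x$outcome))
  if (any(x$excluded))
    cat(sum(x$excluded), "record(s) carry excluded features",
        "(not fitted)\n")
  invisible(x)
}

#' Person-years of follow-up in a cohort
#' @param cohort a [as_cohort()] object.
#' @return total years from entry to outcome across records.
#' @export
person_years <- function(cohort) sum(cohort$outcome_time)

#' Read / write a cohort CSV
#'
#' Delimited-text round-trip of the event-history table.  Times are written
#' with 12 significant digits, which round-trips the stored values exactly
#' at that precision; a comment header (lines starting `#`) may carry
#' provenance and is ignored on read.
#'
#' @param file path.
#' @return `read_cohort()`: a `cohort`.
#' @export
read_cohort <- function(file) {
  df <- utils::read.csv(file, colClasses = c(
    id = "character", entry_time = "numeric", screen_times = "character",
    outcome = "character", outcome_round = "integer",
    outcome_time = "numeric", feature = "character", period = "character"),
    comment.char = "#")
  df$feature[df$feature == ""] <- NA_character_
  as_cohort(df)
}

#' @rdname read_cohort
#' @param cohort a `cohort` object.
#' @param header optional character vector written as `#`-prefixed comment
#'   lines before the table.
#' @export
write_cohort <- function(cohort, file, header = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  out <- as.data.frame(cohort)
  out$excluded <- NULL
  for (col in c("entry_time", "outcome_time"))
    out[[col]] <- formatC(out[[col]], digits = 12, format = "g", width = 1)
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}
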