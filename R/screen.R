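#' Wear-time screening and documented-nonwear imputation
#'
#' Window occurrences are valid when at least a minimum fraction of the
#' scheduled time carries usable energy-expenditure data (worn plus imputed
#' minutes); default 70%, boundary inclusive ("at least"). A participant
#' enters an item's calibration when the item's window type has at least
#' `min_valid_periods` valid occurrences in the week (default 3), relaxed
#' to 1 for window types that occur at most once or twice a week (PE class,
#' Saturday, Sunday). Documented nonwear bouts from a daily activity log
#' are imputed with compendium MET values before validity is assessed, so
#' imputed minutes count toward both the wear fraction and percent MVPA.
#'
#' @name screen
NULL

#' Screening rules
#'
#' @param min_valid_fraction minimum accounted (worn + imputed) fraction of
#'   scheduled minutes for a window occurrence to be valid; inclusive.
#' @param min_valid_periods minimum valid occurrences per window type.
#' @param exception_windows window types requiring only 1 valid occurrence.
#' @param mode `"item_wise"` (retention decided per window type, the
#'   sample-maximising design) or `"whole_week"` (traditional screening: a
#'   participant is retained only if every scheduled window type meets its
#'   requirement).
#' @return object of class `screening_rules`.
#' @export
screening_rules <- function(min_valid_fraction = 0.70,
                            min_valid_periods = 3L,
                            exception_windows = c("physical_education",
                                                  "saturday", "sunday"),
                            mode = c("item_wise", "whole_week")) {
  mode <- match.arg(mode)
  if (!(min_valid_fraction > 0 && min_valid_fraction <= 1)) {
    stop("min_valid_fraction must be in (0, 1]", call. = FALSE)
  }
  if (min_valid_periods < 1) stop("min_valid_periods must be >= 1",
                                  call. = FALSE)
  structure(list(min_valid_fraction = min_valid_fraction,
                 min_valid_periods = as.integer(min_valid_periods),
                 exception_windows = exception_windows, mode = mode),
            class = "screening_rules")
}

#' @export
print.screening_rules <- function(x, ...) {
  cat(sprintf(
    "Screening rules: >= %.0f%% accounted time, >= %d valid periods (>= 1 for %s); mode %s\n",
    100 * x$min_valid_fraction, x$min_valid_periods,
    paste(x$exception_windows, collapse = "/"), x$mode))
  invisible(x)
}

#' A small MET lookup table for activity-log labels
#'
#' Activity label to MET value map used to impute documented nonwear bouts.
#' Values are typical compendium-style assignments, bundled for testing;
#' studies should supply their own table.
#' @return data.frame with `activity`, `met`.
#' @export
default_met_table <- function() {
  data.frame(
    activity = c("basketball", "soccer", "swimming", "cycling", "walking",
                 "dance", "shower", "sleeping", "video_games", "homework",
                 "eating"),
    met = c(6.5, 7.0, 6.0, 6.8, 3.5, 5.0, 1.5, 0.95, 1.0, 1.3, 1.5),
    stringsAsFactors = FALSE)
}

#' Impute documented nonwear minutes with logged MET values
#'
#' For every window occurrence, nonwear minutes overlapping a logged
#' activity bout get that activity's MET value; minutes at or above
#' `mvpa_threshold` METs count as MVPA. Worn minutes are never altered.
#' Percent MVPA is recomputed over worn + imputed minutes. Log entries
#' whose activity label is absent from the MET table are skipped with a
#' warning and returned in the `"skipped_log_entries"` attribute.
#'
#' @param summaries window summaries from [segment_stream()] /
#'   [segment_cohort()] (carrying `start_min`/`end_min` bounds).
#' @param streams minute-level records (used to locate nonwear minutes).
#' @param log_entries data.frame `participant_id`, `date`, `start`, `end`
#'   (clock times "HH:MM", half-open), `activity`. May have zero rows.
#' @param met_table data.frame `activity`, `met`.
#' @param mvpa_threshold MET cut point for MVPA (default 3.0).
#' @return summaries with imputation columns and `pct_mvpa` updated.
#' @export
impute_nonwear <- function(summaries, streams, log_entries,
                           met_table = default_met_table(),
                           mvpa_threshold = 3.0) {
  if (is.null(log_entries) || nrow(log_entries) == 0) {
    attr(summaries, "skipped_log_entries") <- NULL
    return(summaries)
  }
  check_columns(log_entries, c("participant_id", "date", "start", "end",
                               "activity"), "nonwear log")
  check_columns(met_table, c("activity", "met"), "MET table")
  check_columns(summaries, c("start_min", "end_min"), "window summaries")
  log_entries$date <- as.Date(log_entries$date)
  streams$date <- as.Date(streams$date)
  summaries$date <- as.Date(summaries$date)

  known <- log_entries$activity %in% met_table$activity
  skipped <- log_entries[!known, , drop = FALSE]
  if (nrow(skipped)) {
    warning("skipping ", nrow(skipped),
            " nonwear log entr(y/ies) with activity label(s) absent from MET table: ",
            paste(unique(skipped$activity), collapse = ", "), call. = FALSE)
  }
  log_entries <- log_entries[known, , drop = FALSE]
  if (nrow(log_entries) == 0) {
    attr(summaries, "skipped_log_entries") <- skipped
    return(summaries)
  }
  log_entries$met <- met_table$met[match(log_entries$activity,
                                         met_table$activity)]
  log_entries$start_min <- parse_clock(log_entries$start)
  log_entries$end_min <- parse_clock(log_entries$end)
  if (any(log_entries$start_min >= log_entries$end_min)) {
    stop("nonwear log entry with start >= end", call. = FALSE)
  }

  # expand logged bouts to a per-minute MET lookup (participant, abs minute);
  # overlapping entries resolve to the later entry
  lens <- log_entries$end_min - log_entries$start_min
  bout_minute <- unlist(lapply(seq_len(nrow(log_entries)), function(i) {
    seq.int(log_entries$start_min[i], log_entries$end_min[i] - 1L)
  }))
  bout_key <- paste(rep(log_entries$participant_id, lens),
                    rep(as.integer(log_entries$date), lens) * 1440L +
                      bout_minute)
  bout_met <- rep(log_entries$met, lens)
  keep <- !duplicated(bout_key, fromLast = TRUE)
  met_of <- bout_met[keep]
  names(met_of) <- bout_key[keep]

  # nonwear stream minutes covered by a documented bout
  nw <- streams[!as.logical(streams$wear), , drop = FALSE]
  if (nrow(nw) > 0) {
    nw_key <- paste(nw$participant_id, as.integer(nw$date) * 1440L + nw$minute)
    nw$met <- unname(met_of[nw_key])
    nw <- nw[!is.na(nw$met), , drop = FALSE]
  }
  if (nrow(nw) > 0) {
    cov_group <- paste(nw$participant_id, as.integer(nw$date))
    by_group <- split(seq_len(nrow(nw)), cov_group)
    sum_group <- paste(summaries$participant_id, as.integer(summaries$date))
    for (i in which(sum_group %in% names(by_group))) {
      idx <- by_group[[sum_group[i]]]
      inw <- nw$minute[idx] >= summaries$start_min[i] &
             nw$minute[idx] < summaries$end_min[i]
      if (any(inw)) {
        mets <- nw$met[idx][inw]
        summaries$imputed_minutes[i] <- summaries$imputed_minutes[i] +
          sum(inw)
        summaries$imputed_mvpa_minutes[i] <-
          summaries$imputed_mvpa_minutes[i] + sum(mets >= mvpa_threshold)
      }
    }
  }
  acc <- summaries$worn_minutes + summaries$imputed_minutes
  summaries$pct_mvpa <- ifelse(
    acc > 0,
    100 * (summaries$mvpa_minutes + summaries$imputed_mvpa_minutes) / acc,
    NA_real_)
  attr(summaries, "skipped_log_entries") <- skipped
  summaries
}

#' Flag valid window occurrences
#'
#' A window occurrence is valid iff `(worn + imputed) / scheduled >=
#' min_valid_fraction` (inclusive). Occurrences with zero scheduled minutes
#' are invalid with an audit reason.
#'
#' @param summaries window summaries.
#' @param rules a [screening_rules()].
#' @return summaries with logical column `valid` (and `invalid_reason`).
#' @export
flag_valid_windows <- function(summaries, rules = screening_rules()) {
  stopifnot(inherits(rules, "screening_rules"))
  acc <- summaries$worn_minutes + summaries$imputed_minutes
  zero <- summaries$scheduled_minutes <= 0
  frac <- ifelse(zero, 0, acc / summaries$scheduled_minutes)
  summaries$valid <- !zero & frac >= rules$min_valid_fraction
  summaries$invalid_reason <- ifelse(
    summaries$valid, NA_character_,
    ifelse(zero, "zero scheduled minutes",
           sprintf("accounted %.0f%% < %.0f%%", 100 * frac,
                   100 * rules$min_valid_fraction)))
  summaries
}

#' Decide per-(participant, window type) calibration retention
#'
#' In `item_wise` mode a participant enters the calibration of the item
#' linked to window type `w` iff `w` has at least `min_valid_periods` valid
#' occurrences (at least 1 for exception windows). In `whole_week` mode the
#' participant is retained for all items iff every window type scheduled
#' for them meets its requirement — the traditional screening design. The
#' item-wise retained set is therefore always a superset of the whole-week
#' set for every window type.
#'
#' @param summaries window summaries with `valid` flags set.
#' @param rules a [screening_rules()]; `rules$mode` picks the design.
#' @return data.frame `participant_id`, `window_type`, `n_valid`,
#'   `required`, `retained`.
#' @export
retain_participants <- function(summaries, rules = screening_rules()) {
  stopifnot(inherits(rules, "screening_rules"))
  if (!"valid" %in% names(summaries)) {
    stop("summaries lack a 'valid' flag; run flag_valid_windows() first",
         call. = FALSE)
  }
  agg <- aggregate(valid ~ participant_id + window_type, data = summaries,
                   FUN = sum)
  names(agg)[names(agg) == "valid"] <- "n_valid"
  agg$required <- ifelse(agg$window_type %in% rules$exception_windows, 1L,
                         rules$min_valid_periods)
  agg$meets <- agg$n_valid >= agg$required
  if (rules$mode == "item_wise") {
    agg$retained <- agg$meets
  } else {
    # retained for all items iff every scheduled window type meets
    all_ok <- tapply(agg$meets, agg$participant_id, all)
    agg$retained <- unname(all_ok[agg$participant_id])
  }
  agg$meets <- NULL
  agg[order(agg$participant_id, agg$window_type), , drop = FALSE]
}
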