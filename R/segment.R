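#' Weekly window schedule and stream segmentation
#'
#' The calibration design links each questionnaire item to a discrete daily
#' time window. Eight window types occur on school days and one whole-day
#' window on each weekend day:
#'
#' * `before_school`: 60 min before the transport-to-school window
#' * `transport_to_school`: 30 min ending at school start
#' * `recess`, `physical_education`, `lunch`: school-supplied times per date
#' * `transport_from_school`: 30 min starting at school end
#' * `after_school`: end of transport-from-school until 18:00
#' * `evening`: fixed 18:00-22:00
#' * `saturday`, `sunday`: fixed 07:00-22:00
#'
#' All intervals are half-open `[start, end)`; a minute stamped `t` belongs
#' to the interval containing `t`, so abutting windows never double count.
#'
#' @name segment
NULL

#' The closed set of window types
#' @return character vector of the 10 window type labels
#' @export
window_types <- function() {
  c("before_school", "transport_to_school", "recess", "physical_education",
    "lunch", "transport_from_school", "after_school", "evening",
    "saturday", "sunday")
}

#' Construct a weekly schedule configuration
#'
#' @param school_start,school_end clock times "HH:MM" of the school day.
#' @param recess,physical_education,lunch named lists mapping date strings
#'   ("YYYY-MM-DD") to `c(start, end)` clock times; dates without an entry
#'   have no such window.
#' @param evening,weekend,transport_minutes,before_school_minutes fixed
#'   bounds and derived-window lengths; defaults follow the weekly
#'   processing schedule (evening 18:00-22:00, weekend 07:00-22:00,
#'   30-min transport windows, 60-min before-school window).
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(school_start = "08:15", school_end = "15:30",
                            recess = list(), physical_education = list(),
                            lunch = list(),
                            evening = c("18:00", "22:00"),
                            weekend = c("07:00", "22:00"),
                            transport_minutes = 30L,
                            before_school_minutes = 60L) {
  obj <- structure(list(
    school_start = school_start, school_end = school_end,
    recess = recess, physical_education = physical_education, lunch = lunch,
    evening = evening, weekend = weekend,
    transport_minutes = as.integer(transport_minutes),
    before_school_minutes = as.integer(before_school_minutes)),
    class = "schedule_config")
  stopifnot(parse_clock(school_start) < parse_clock(school_end))
  obj
}

#' @export
print.schedule_config <- function(x, ...) {
  cat(sprintf("Schedule: school %s-%s; recess/PE/lunch dates: %d/%d/%d\n",
              x$school_start, x$school_end, length(x$recess),
              length(x$physical_education), length(x$lunch)))
  invisible(x)
}

#' Build the window occurrences of one week
#'
#' @param schedule a [schedule_config()].
#' @param week_dates 7 consecutive `Date`s (Monday through Sunday).
#' @return data.frame with one row per window occurrence: `window_type`,
#'   `date`, `start_min`, `end_min` (minutes since midnight, half-open).
#' @export
build_weekly_windows <- function(schedule, week_dates) {
  week_dates <- as.Date(week_dates)
  if (length(week_dates) != 7 ||
      !all(diff(as.integer(week_dates)) == 1)) {
    stop("week_dates must be 7 consecutive dates", call. = FALSE)
  }
  wd <- as.POSIXlt(week_dates)$wday  # 0 = Sunday, 6 = Saturday
  ss <- parse_clock(schedule$school_start)
  se <- parse_clock(schedule$school_end)
  tmin <- schedule$transport_minutes
  bmin <- schedule$before_school_minutes
  ev <- parse_clock(schedule$evening)
  we <- parse_clock(schedule$weekend)

  rows <- list()
  add <- function(type, date, s, e) {
    rows[[length(rows) + 1L]] <<- data.frame(
      window_type = type, date = date, start_min = as.integer(s),
      end_min = as.integer(e), stringsAsFactors = FALSE)
  }
  provided <- function(lst, date) {
    key <- format(date, "%Y-%m-%d")
    if (!is.null(lst[[key]])) parse_clock(lst[[key]]) else NULL
  }

  for (i in seq_along(week_dates)) {
    d <- week_dates[i]
    if (wd[i] == 6) { add("saturday", d, we[1], we[2]); next }
    if (wd[i] == 0) { add("sunday", d, we[1], we[2]); next }
    add("before_school", d, ss - tmin - bmin, ss - tmin)
    add("transport_to_school", d, ss - tmin, ss)
    for (type in c("recess", "physical_education", "lunch")) {
      tt <- provided(schedule[[type]], d)
      if (!is.null(tt)) {
        if (tt[1] >= tt[2]) {
          stop(type, " on ", format(d), ": start must be before end",
               call. = FALSE)
        }
        add(type, d, tt[1], tt[2])
      }
    }
    add("transport_from_school", d, se, se + tmin)
    add("after_school", d, se + tmin, parse_clock("18:00"))
    add("evening", d, ev[1], ev[2])
  }
  out <- do.call(rbind, rows)

  # overlap check within each date (half-open intervals)
  for (d in unique(out$date)) {
    w <- out[out$date == d, ]
    w <- w[order(w$start_min), ]
    if (nrow(w) > 1) {
      clash <- which(w$end_min[-nrow(w)] > w$start_min[-1])
      if (length(clash)) {
        msgs <- sprintf("%s [%s-%s) overlaps %s [%s-%s) on %s",
                        w$window_type[clash], format_clock(w$start_min[clash]),
                        format_clock(w$end_min[clash]),
                        w$window_type[clash + 1],
                        format_clock(w$start_min[clash + 1]),
                        format_clock(w$end_min[clash + 1]), format(as.Date(d, origin = "1970-01-01")))
        stop("overlapping windows: ", paste(msgs, collapse = "; "),
             call. = FALSE)
      }
    }
  }
  if (any(out$start_min >= out$end_min)) {
    stop("window with start >= end produced; check schedule times",
         call. = FALSE)
  }
  out
}

#' Scheduled minutes and weekly frequency per window type
#'
#' Used to weight per-window percent MVPA into weekly minutes. Minutes are
#' the mean scheduled length of the type's occurrences; frequency is the
#' number of occurrences in the week.
#'
#' @param windows output of [build_weekly_windows()].
#' @return data.frame with `window_type`, `minutes`, `per_week`.
#' @export
window_weekly_weights <- function(windows) {
  len <- windows$end_min - windows$start_min
  agg <- aggregate(len, by = list(window_type = windows$window_type), FUN = mean)
  cnt <- table(windows$window_type)
  data.frame(window_type = agg$window_type,
             minutes = agg$x,
             per_week = as.integer(cnt[agg$window_type]),
             stringsAsFactors = FALSE)
}

#' Assign minute-level records to schedule windows
#'
#' Each stream minute falls in at most one window (windows within a date are
#' validated non-overlapping, intervals half-open). Percent MVPA is computed
#' over worn minutes only at this stage; imputation happens in the screening
#' step.
#'
#' @param stream data.frame with columns `participant_id`, `date` (`Date`),
#'   `minute` (minutes since midnight), `wear` (logical/0-1), `mvpa`
#'   (logical/0-1).
#' @param windows output of [build_weekly_windows()].
#' @return data.frame of window summaries: one row per window occurrence
#'   with `participant_id`, `window_type`, `date`, `scheduled_minutes`,
#'   `worn_minutes`, `mvpa_minutes`, `imputed_minutes`,
#'   `imputed_mvpa_minutes`, `pct_mvpa` (NA when no minutes accounted).
#' @export
segment_stream <- function(stream, windows) {
  check_columns(stream, c("participant_id", "date", "minute", "wear", "mvpa"),
                "stream")
  stream$date <- as.Date(stream$date)
  windows$date <- as.Date(windows$date)
  pid <- unique(stream$participant_id)
  if (length(pid) > 1) {
    stop("segment_stream expects one participant per stream; got ",
         length(pid), call. = FALSE)
  }
  if (nrow(stream) > 0 && !any(stream$date %in% windows$date)) {
    stop("stream dates do not overlap the scheduled week (stream ",
         format(min(stream$date)), "..", format(max(stream$date)),
         ", week ", format(min(windows$date)), "..",
         format(max(windows$date)), ")", call. = FALSE)
  }

  n <- nrow(windows)
  worn <- integer(n); mvpa <- integer(n)
  if (nrow(stream) > 0) {
    # absolute minute key: date index * 1440 + minute
    skey <- as.integer(stream$date) * 1440 + stream$minute
    wkey_start <- as.integer(windows$date) * 1440 + windows$start_min
    wkey_end <- as.integer(windows$date) * 1440 + windows$end_min
    ord <- order(wkey_start)
    idx <- findInterval(skey, wkey_start[ord])
    hit <- idx >= 1 & skey < wkey_end[ord][pmax(idx, 1)]
    widx <- ord[idx[hit]]
    wearv <- as.logical(stream$wear)[hit]
    mvpav <- as.logical(stream$mvpa)[hit] & wearv
    worn <- as.integer(tapply(wearv, factor(widx, levels = seq_len(n)), sum))
    mvpa <- as.integer(tapply(mvpav, factor(widx, levels = seq_len(n)), sum))
    worn[is.na(worn)] <- 0L; mvpa[is.na(mvpa)] <- 0L
  }
  out <- data.frame(
    participant_id = if (length(pid)) pid else NA_character_,
    window_type = windows$window_type,
    date = windows$date,
    start_min = windows$start_min,
    end_min = windows$end_min,
    scheduled_minutes = windows$end_min - windows$start_min,
    worn_minutes = worn,
    mvpa_minutes = mvpa,
    imputed_minutes = 0L,
    imputed_mvpa_minutes = 0L,
    stringsAsFactors = FALSE)
  out$pct_mvpa <- ifelse(out$worn_minutes > 0,
                         100 * out$mvpa_minutes / out$worn_minutes, NA_real_)
  out
}

#' Segment several participants' streams against per-participant schedules
#'
#' @param streams data.frame of stacked minute records for many participants.
#' @param schedules either a single [schedule_config()] or a named list of
#'   them keyed by participant id.
#' @param week_dates 7 consecutive dates.
#' @return stacked window-summary data.frame.
#' @export
segment_cohort <- function(streams, schedules, week_dates) {
  ids <- unique(streams$participant_id)
  out <- lapply(ids, function(id) {
    sch <- if (inherits(schedules, "schedule_config")) schedules
           else schedules[[id]]
    if (is.null(sch)) stop("no schedule for participant ", id, call. = FALSE)
    segment_stream(streams[streams$participant_id == id, , drop = FALSE],
                   build_weekly_windows(sch, week_dates))
  })
  do.call(rbind, out)
}
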