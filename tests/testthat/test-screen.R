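week <- as.Date("2025-09-15") + 0:6

mk_summary <- function(worn, scheduled = 100, imputed = 0, mvpa = 0,
                       type = "evening", date = week[1], pid = "P1") {
  data.frame(participant_id = pid, window_type = type, date = date,
             start_min = 1080, end_min = 1080 + scheduled,
             scheduled_minutes = scheduled, worn_minutes = worn,
             mvpa_minutes = mvpa, imputed_minutes = imputed,
             imputed_mvpa_minutes = 0,
             pct_mvpa = ifelse(worn > 0, 100 * mvpa / worn, NA),
             stringsAsFactors = FALSE)
}

test_that("the 70% validity rule is boundary-inclusive", {
  rules <- screening_rules()
  expect_true(flag_valid_windows(mk_summary(75), rules)$valid)
  expect_true(flag_valid_windows(mk_summary(70), rules)$valid)   # exactly 70%
  expect_false(flag_valid_windows(mk_summary(69), rules)$valid)
  expect_false(flag_valid_windows(mk_summary(0), rules)$valid)
  # imputed minutes count toward the fraction
  expect_true(flag_valid_windows(mk_summary(40, imputed = 30), rules)$valid)
  z <- flag_valid_windows(mk_summary(0, scheduled = 0), rules)
  expect_false(z$valid)
  expect_match(z$invalid_reason, "zero scheduled")
})

test_that("screening rule parameters are validated", {
  expect_error(screening_rules(min_valid_fraction = 0), "min_valid_fraction")
  expect_error(screening_rules(min_valid_fraction = 1.2), "min_valid_fraction")
  expect_error(screening_rules(min_valid_periods = 0), "min_valid_periods")
})

test_that("documented nonwear is imputed with MET values, worn minutes untouched", {
  sc <- schedule_config()
  w <- build_weekly_windows(sc, week)
  # evening minutes fully present; a 30-min nonwear gap 18:30-19:00
  st <- data.frame(participant_id = "P1", date = week[1],
                   minute = 1080:1319, ee_mets = 2,
                   wear = !(1080:1319 %in% 1110:1139), mvpa = FALSE)
  s <- segment_stream(st, w)
  ev <- which(s$window_type == "evening" & s$date == week[1])
  expect_equal(s$worn_minutes[ev], 210)

  # no log entries: identity
  s_id <- impute_nonwear(s, st, NULL)
  expect_equal(s_id$imputed_minutes, s$imputed_minutes)

  log <- data.frame(participant_id = "P1", date = week[1], start = "18:30",
                    end = "19:00", activity = "basketball")
  s2 <- impute_nonwear(s, st, log)
  expect_equal(s2$imputed_minutes[ev], 30)
  expect_equal(s2$imputed_mvpa_minutes[ev], 30)  # basketball 6.5 MET >= 3
  expect_equal(s2$worn_minutes, s$worn_minutes)  # conservation
  expect_equal(s2$pct_mvpa[ev], 100 * 30 / 240)

  # sedentary activity imputes time but not MVPA
  log_sed <- data.frame(participant_id = "P1", date = week[1],
                        start = "18:30", end = "19:00",
                        activity = "video_games")
  s3 <- impute_nonwear(s, st, log_sed)
  expect_equal(s3$imputed_minutes[ev], 30)
  expect_equal(s3$imputed_mvpa_minutes[ev], 0)

  # unknown activity label: warning, entry skipped, audited
  log_bad <- data.frame(participant_id = "P1", date = week[1],
                        start = "18:30", end = "19:00",
                        activity = "quidditch")
  expect_warning(s4 <- impute_nonwear(s, st, log_bad), "quidditch")
  expect_equal(s4$imputed_minutes, s$imputed_minutes)
  expect_equal(nrow(attr(s4, "skipped_log_entries")), 1)
})

test_that("imputation matches a per-minute brute-force overlap computation", {
  sc <- schedule_config(lunch = list("2025-09-15" = c("12:00", "12:30")))
  w <- build_weekly_windows(sc, week)
  met_tab <- default_met_table()
  for (seed in 1:6) {
    set.seed(seed)
    st <- random_stream(seed + 500, n_min = 1500)
    s <- segment_stream(st, w)
    logs <- do.call(rbind, lapply(1:5, function(i) {
      d <- sample(week, 1)
      a <- sample(360:1250, 1)
      data.frame(participant_id = "P1", date = d,
                 start = format_clock_t(a),
                 end = format_clock_t(a + sample(10:90, 1)),
                 activity = sample(met_tab$activity, 1),
                 stringsAsFactors = FALSE)
    }))
    got <- impute_nonwear(s, st, logs, met_tab)

    # brute force: loop every nonwear stream minute, every log, every window
    exp_imp <- integer(nrow(s)); exp_mvpa <- integer(nrow(s))
    logs$s0 <- sapply(strsplit(logs$start, ":"),
                      function(p) as.integer(p[1]) * 60 + as.integer(p[2]))
    logs$e0 <- sapply(strsplit(logs$end, ":"),
                      function(p) as.integer(p[1]) * 60 + as.integer(p[2]))
    for (i in seq_len(nrow(st))) {
      if (st$wear[i]) next
      met <- NA
      for (l in seq_len(nrow(logs))) {
        if (st$date[i] == logs$date[l] && st$minute[i] >= logs$s0[l] &&
            st$minute[i] < logs$e0[l]) {
          met <- met_tab$met[met_tab$activity == logs$activity[l]]
        }
      }
      if (is.na(met)) next
      for (j in seq_len(nrow(s))) {
        if (st$date[i] == s$date[j] && st$minute[i] >= s$start_min[j] &&
            st$minute[i] < s$end_min[j]) {
          exp_imp[j] <- exp_imp[j] + 1L
          if (met >= 3) exp_mvpa[j] <- exp_mvpa[j] + 1L
        }
      }
    }
    expect_equal(got$imputed_minutes, exp_imp)
    expect_equal(got$imputed_mvpa_minutes, exp_mvpa)
  }
})

test_that("item-wise retention keeps windows the whole-week design would discard", {
  # participant A: 3 valid evenings + 1 valid PE, nothing else
  s <- rbind(mk_summary(100, type = "evening", date = week[1], pid = "A"),
             mk_summary(100, type = "evening", date = week[2], pid = "A"),
             mk_summary(100, type = "evening", date = week[3], pid = "A"),
             mk_summary(10, type = "evening", date = week[4], pid = "A"),
             mk_summary(45, scheduled = 45, type = "physical_education",
                        date = week[2], pid = "A"),
             mk_summary(900, scheduled = 900, type = "saturday",
                        date = week[6], pid = "A"),
             # the rest of the schedule exists but was never worn
             mk_summary(0, scheduled = 60, type = "before_school",
                        date = week[1], pid = "A"),
             mk_summary(0, scheduled = 900, type = "sunday",
                        date = week[7], pid = "A"))
  s <- flag_valid_windows(s, screening_rules())
  it <- retain_participants(s, screening_rules(mode = "item_wise"))
  expect_true(it$retained[it$window_type == "evening"])
  expect_true(it$retained[it$window_type == "physical_education"])  # >= 1 rule
  ww <- retain_participants(s, screening_rules(mode = "whole_week"))
  expect_false(any(ww$retained))  # evening-only compliance fails whole-week

  # when everything is valid the two modes agree
  s_all <- do.call(rbind, lapply(week[1:5], function(d)
    mk_summary(240, scheduled = 240, type = "evening", date = d, pid = "B")))
  s_all <- flag_valid_windows(s_all, screening_rules())
  it2 <- retain_participants(s_all, screening_rules(mode = "item_wise"))
  ww2 <- retain_participants(s_all, screening_rules(mode = "whole_week"))
  expect_equal(it2$retained, ww2$retained)
})

test_that("item-wise retention dominates whole-week on simulated cohorts", {
  for (seed in 1:3) {
    coh <- quick_cohort(n = 50, seed = seed,
                        nonwear_rate = c(elementary = 1.5, middle = 2.5,
                                         high = 3.5))
    s <- flag_valid_windows(coh$summaries, screening_rules())
    it <- retain_participants(s, screening_rules(mode = "item_wise"))
    ww <- retain_participants(s, screening_rules(mode = "whole_week"))
    m <- merge(it, ww, by = c("participant_id", "window_type"))
    # whole-week retained implies item-wise retained, never the reverse
    expect_true(all(!m$retained.y | m$retained.x))
    expect_gte(sum(it$retained), sum(ww$retained))
  }
})

test_that("loosening screening thresholds never shrinks retained sets", {
  coh <- quick_cohort(n = 40, seed = 9,
                      nonwear_rate = c(elementary = 2, middle = 3, high = 4))
  base <- screening_rules(min_valid_fraction = 0.70, min_valid_periods = 3)
  looser_frac <- screening_rules(min_valid_fraction = 0.50,
                                 min_valid_periods = 3)
  looser_per <- screening_rules(min_valid_fraction = 0.70,
                                min_valid_periods = 2)
  ret <- function(r) {
    s <- flag_valid_windows(coh$summaries, r)
    x <- retain_participants(s, r)
    paste(x$participant_id, x$window_type)[x$retained]
  }
  r0 <- ret(base)
  expect_true(all(r0 %in% ret(looser_frac)))
  expect_true(all(r0 %in% ret(looser_per)))
})
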