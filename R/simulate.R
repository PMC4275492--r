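#' Synthetic cohort simulation
#'
#' Generates synthetic calibration cohorts with the statistical structure
#' the calibration design assumes: a latent true percent-MVPA per
#' (participant, window type) drawn from a truncated normal with age-group,
#' gender and season shifts; per-occurrence day-to-day variation; ordinal
#' item responses produced by a monotone (optionally plateauing) link from
#' truth plus rounded Gaussian reporting noise; minute-level accelerometer
#' streams whose MVPA flags are Bernoulli draws around the occurrence
#' truth; and age-graded nonwear bouts, a configurable fraction of which is
#' documented in an activity log.
#'
#' @name simulate
NULL

#' Monotone item-response links
#'
#' A link maps an ordinal item score to the expected window percent MVPA.
#' `make_linear_link` is linear across the whole scale;
#' `make_plateau_link` is linear up to `knot_score` and flat at and above
#' it, mirroring items whose top response categories are indistinguishable
#' in observed activity.
#'
#' @param intercept expected percent MVPA at the bottom of the scale.
#' @param slope percent MVPA per score unit; must be non-negative.
#' @param knot_score score at which the plateau starts.
#' @param scale_min,scale_max ordinal scale bounds.
#' @return a function of class `item_link` mapping score to percent MVPA.
#' @export
make_linear_link <- function(intercept, slope, scale_min = 1, scale_max = 5) {
  if (slope < 0) stop("link slope must be non-negative", call. = FALSE)
  f <- function(score) intercept + slope * (score - scale_min)
  structure(f, class = c("item_link", "function"), type = "linear",
            intercept = intercept, slope = slope,
            scale_min = scale_min, scale_max = scale_max)
}

#' @rdname make_linear_link
#' @export
make_plateau_link <- function(knot_score, slope, intercept = 0,
                              scale_min = 1, scale_max = 5) {
  if (slope < 0) stop("link slope must be non-negative", call. = FALSE)
  if (knot_score < scale_min || knot_score > scale_max) {
    stop("knot_score must lie within the scale bounds", call. = FALSE)
  }
  f <- function(score) intercept + slope * (pmin(score, knot_score) - scale_min)
  structure(f, class = c("item_link", "function"), type = "plateau",
            intercept = intercept, slope = slope, knot = knot_score,
            scale_min = scale_min, scale_max = scale_max)
}

#' Generalized inverse of an item link (percent MVPA to latent score)
#' @param link an `item_link`
#' @param pct percent MVPA values
#' @return latent (continuous, unclipped) scores; plateau links cap at the
#'   knot since higher truth is unidentifiable from the report.
#' @export
link_inverse <- function(link, pct) {
  a <- attr(link, "intercept"); b <- attr(link, "slope")
  smin <- attr(link, "scale_min")
  if (b <= 0) return(rep(smin, length(pct)))
  v <- smin + (pct - a) / b
  if (identical(attr(link, "type"), "plateau")) v <- pmin(v, attr(link, "knot"))
  v
}

default_group_schedules <- function() {
  wk <- function(days, times) {
    # helper resolved against week dates at simulation time
    list(days = days, times = times)
  }
  list(
    elementary = list(
      school_start = "08:45", school_end = "15:30",
      recess = wk(1:5, c("10:15", "10:30")),
      lunch = wk(1:5, c("12:00", "12:30")),
      physical_education = wk(c(2, 4), c("13:30", "14:15"))),
    middle = list(
      school_start = "08:15", school_end = "15:15",
      recess = wk(1:5, c("10:00", "10:15")),
      lunch = wk(1:5, c("11:45", "12:15")),
      physical_education = wk(c(1, 3), c("14:00", "14:45"))),
    high = list(
      school_start = "08:00", school_end = "15:05",
      recess = wk(1:5, c("09:55", "10:05")),
      lunch = wk(1:5, c("11:30", "12:00")),
      physical_education = wk(c(2, 4), c("13:00", "13:50")))
  )
}

#' Simulation configuration ("paper-like" preset by default)
#'
#' Defaults encode the study conditions the pipeline is designed for: an
#' elementary-heavy school cohort (roughly the 60/20/20 age-group split of
#' the reported nonwear subset), balanced genders, four seasons, window
#' percent-MVPA means highest at recess/PE and lowest before school,
#' activity declining with age and slightly higher in boys, nonwear bout
#' rates increasing from elementary to high school, about half of nonwear
#' documented in the activity log, and a plateau-from-score-4 response link
#' for the PE item with linear links elsewhere.
#'
#' @param n_participants cohort size.
#' @param age_group_mix,gender_mix,season_mix named probability vectors.
#' @param window_mvpa_mean named vector: baseline true percent MVPA per
#'   window type (at age 12, female, neutral season).
#' @param between_sd between-participant SD of true window percent MVPA.
#' @param age_effect percent MVPA per year of age (centred at 12).
#' @param gender_effect male minus female shift in percent MVPA.
#' @param season_effect named shifts per season.
#' @param within_week_sd day-to-day SD of occurrence truth around the
#'   participant's window mean.
#' @param mvpa_measurement_noise_sd SD of device noise added to occurrence
#'   truth before minute-level Bernoulli sampling.
#' @param reporting_noise_sd SD (score units) of self-report noise.
#' @param discretize_scores round and clip responses to the ordinal scale
#'   (`TRUE`, the realistic default); `FALSE` keeps continuous latent
#'   scores, used for exact parameter-recovery checks.
#' @param item_links named list of `item_link`s keyed by item id;
#'   unspecified activity items get a linear link spanning the window's
#'   typical truth range.
#' @param nonwear_rate named bouts-per-day rates per age group
#'   (non-decreasing with age in this preset).
#' @param nonwear_mean_minutes mean documented/undocumented bout length.
#' @param nonwear_documented_fraction fraction of bouts that appear in the
#'   activity log.
#' @param week_start Monday of the simulated week ("YYYY-MM-DD").
#' @param schedules per-age-group school schedules.
#' @param instrument the questionnaire being simulated.
#' @param detail `"stream"` emits minute-level streams plus logs;
#'   `"summary"` emits window summaries directly (fast path for large-n
#'   evaluation studies; no logs, imputation not exercised).
#' @param rng_seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 300,
                       age_group_mix = c(elementary = 0.6, middle = 0.2,
                                         high = 0.2),
                       gender_mix = c(female = 0.5, male = 0.5),
                       season_mix = c(fall = 0.25, winter = 0.25,
                                      spring = 0.25, summer = 0.25),
                       window_mvpa_mean = c(before_school = 18,
                                            transport_to_school = 35,
                                            recess = 45,
                                            physical_education = 50,
                                            lunch = 24,
                                            transport_from_school = 35,
                                            after_school = 30,
                                            evening = 22,
                                            saturday = 26,
                                            sunday = 22),
                       between_sd = 12,
                       age_effect = -0.8,
                       gender_effect = 5,
                       season_effect = c(fall = 0, winter = -4, spring = 1,
                                         summer = 3),
                       within_week_sd = 8,
                       mvpa_measurement_noise_sd = 3,
                       reporting_noise_sd = 0.6,
                       discretize_scores = TRUE,
                       item_links = NULL,
                       nonwear_rate = c(elementary = 0.4, middle = 0.8,
                                        high = 1.2),
                       nonwear_mean_minutes = 45,
                       nonwear_documented_fraction = 0.5,
                       week_start = "2025-09-15",
                       schedules = default_group_schedules(),
                       instrument = NULL,
                       detail = c("stream", "summary"),
                       rng_seed = 1L) {
  detail <- match.arg(detail)
  if (n_participants <= 0) stop("n_participants must be positive",
                                call. = FALSE)
  stopifnot(abs(sum(age_group_mix) - 1) < 1e-8,
            abs(sum(gender_mix) - 1) < 1e-8,
            abs(sum(season_mix) - 1) < 1e-8,
            between_sd >= 0, within_week_sd >= 0,
            mvpa_measurement_noise_sd >= 0, reporting_noise_sd >= 0,
            all(nonwear_rate >= 0))
  if (is.null(instrument)) instrument <- default_instrument()
  # default links: linear span of mu +/- 1.5 between-SD across the scale;
  # PE item plateaus from score 4 (the preset's nonlinear item)
  act <- activity_items(instrument)
  links <- item_links %||% list()
  nsteps <- instrument$scale_max - instrument$scale_min
  for (k in seq_len(nrow(act))) {
    id <- act$item_id[k]
    if (is.null(links[[id]])) {
      mu <- window_mvpa_mean[[act$window_type[k]]]
      slope <- 3 * between_sd / nsteps
      intercept <- mu - 1.5 * between_sd
      links[[id]] <- if (act$window_type[k] == "physical_education") {
        make_plateau_link(knot_score = 4, slope = slope,
                          intercept = intercept,
                          scale_min = instrument$scale_min,
                          scale_max = instrument$scale_max)
      } else {
        make_linear_link(intercept, slope, instrument$scale_min,
                         instrument$scale_max)
      }
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    age_group_mix = age_group_mix, gender_mix = gender_mix,
    season_mix = season_mix, window_mvpa_mean = window_mvpa_mean,
    between_sd = between_sd, age_effect = age_effect,
    gender_effect = gender_effect, season_effect = season_effect,
    within_week_sd = within_week_sd,
    mvpa_measurement_noise_sd = mvpa_measurement_noise_sd,
    reporting_noise_sd = reporting_noise_sd,
    discretize_scores = discretize_scores,
    item_links = links, nonwear_rate = nonwear_rate,
    nonwear_mean_minutes = nonwear_mean_minutes,
    nonwear_documented_fraction = nonwear_documented_fraction,
    week_start = week_start, schedules = schedules,
    instrument = instrument, detail = detail,
    rng_seed = as.integer(rng_seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: n=%d, detail=%s, seed=%d, reporting SD=%.2f, measurement SD=%.2f\n",
    x$n_participants, x$detail, x$rng_seed, x$reporting_noise_sd,
    x$mvpa_measurement_noise_sd))
  invisible(x)
}

rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  if (all(sd == 0)) return(clip(mean + numeric(n), lo, hi))
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# resolve a group schedule spec (days/times lists) into a schedule_config
# for concrete week dates
resolve_schedule <- function(spec, week_dates) {
  to_dates <- function(entry) {
    if (is.null(entry)) return(list())
    out <- list()
    for (d in entry$days) out[[format(week_dates[d], "%Y-%m-%d")]] <- entry$times
    out
  }
  schedule_config(school_start = spec$school_start,
                  school_end = spec$school_end,
                  recess = to_dates(spec$recess),
                  physical_education = to_dates(spec$physical_education),
                  lunch = to_dates(spec$lunch))
}

#' Simulate a synthetic calibration cohort
#'
#' Deterministic given `config$rng_seed`; participant-level draws use a
#' per-participant sub-seed so growing `n_participants` extends the cohort
#' without reshuffling earlier participants.
#'
#' @param config a [sim_config()].
#' @return object of class `yap_cohort`: list with `participants`, `truth`
#'   (per-occurrence true percent MVPA), `truth_mean` (participant-level
#'   window means), `responses`, `streams` (stream detail) or `summaries`
#'   (summary detail), `nonwear_log`, `schedules`, `week_dates`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  week_dates <- as.Date(config$week_start) + 0:6
  instrument <- config$instrument
  act <- activity_items(instrument)
  sed <- instrument$items[is.na(instrument$items$window_type), , drop = FALSE]

  schedules <- lapply(config$schedules, resolve_schedule,
                      week_dates = week_dates)
  group_windows <- lapply(schedules, build_weekly_windows,
                          week_dates = week_dates)

  part_l <- list(); truth_l <- list(); resp_l <- list(); stream_l <- list()
  summ_l <- list(); log_l <- list()
  met_tab <- default_met_table()
  sedentary_labels <- c("shower", "sleeping", "video_games", "homework",
                        "eating")
  active_labels <- c("basketball", "soccer", "swimming", "cycling",
                     "walking", "dance")
  age_bounds <- list(elementary = c(9, 11.5), middle = c(11.5, 14.5),
                     high = c(14.5, 18))

  # one sub-seeded block per participant: growing n extends the cohort
  # without reshuffling earlier participants
  for (i in seq_len(n)) {
    res <- with_seed(split_seed(config$rng_seed, i), {
      grp <- sample(names(config$age_group_mix), 1,
                    prob = config$age_group_mix)
      ab <- age_bounds[[grp]]
      p <- data.frame(
        participant_id = sprintf("P%04d", i),
        age_group = grp,
        age_years = round(runif(1, ab[1], ab[2]), 1),
        gender = as.integer(runif(1) < config$gender_mix[["male"]]),
        season = sample(names(config$season_mix), 1,
                        prob = config$season_mix),
        stringsAsFactors = FALSE)
      win <- group_windows[[p$age_group]]
      shift <- config$age_effect * (p$age_years - 12) +
        config$gender_effect * p$gender +
        config$season_effect[[p$season]]
      types <- unique(win$window_type)
      mu_w <- config$window_mvpa_mean[types] + shift
      m_iw <- rtruncnorm01(length(types), mu_w, config$between_sd)
      names(m_iw) <- types

      truth <- win
      truth$participant_id <- p$participant_id
      truth$true_mean_pct <- unname(m_iw[truth$window_type])
      truth$true_pct <- rtruncnorm01(nrow(truth), truth$true_mean_pct,
                                     config$within_week_sd)

      # responses
      resp <- list(participant_id = p$participant_id)
      for (k in seq_len(nrow(act))) {
        id <- act$item_id[k]
        wt <- act$window_type[k]
        if (!wt %in% names(m_iw)) { resp[[id]] <- NA_real_; next }
        latent <- link_inverse(config$item_links[[id]], m_iw[[wt]])
        latent <- latent + rnorm(1, 0, config$reporting_noise_sd)
        resp[[id]] <- if (config$discretize_scores) {
          clip(round(latent), instrument$scale_min, instrument$scale_max)
        } else latent
      }
      for (id in sed$item_id) {
        resp[[id]] <- clip(round(rnorm(1, 3, 1)), instrument$scale_min,
                           instrument$scale_max)
      }

      # nonwear bouts over the waking span of each day
      rate <- config$nonwear_rate[[p$age_group]]
      bouts <- NULL; logs <- NULL
      span_lo <- pmin(tapply(win$start_min, format(win$date), min), 7 * 60)
      span_hi <- 22 * 60
      if (rate > 0) {
        bl <- list()
        for (d in seq_along(week_dates)) {
          nb <- rpois(1, rate)
          if (nb == 0) next
          key <- format(week_dates[d], "%Y-%m-%d")
          lo <- if (key %in% names(span_lo)) span_lo[[key]] else 7 * 60
          st <- sort(as.integer(runif(nb, lo, span_hi - 10)))
          du <- pmax(5L, as.integer(rlnorm(nb,
                 log(config$nonwear_mean_minutes) - 0.125, 0.5)))
          en <- pmin(st + du, span_hi)
          ok <- en > st
          if (any(ok)) {
            bl[[length(bl) + 1L]] <- data.frame(
              date = week_dates[d], start_min = st[ok], end_min = en[ok])
          }
        }
        if (length(bl)) {
          bouts <- do.call(rbind, bl)
          doc <- runif(nrow(bouts)) < config$nonwear_documented_fraction
          if (any(doc)) {
            lab <- ifelse(runif(sum(doc)) < 0.4,
                          sample(active_labels, sum(doc), replace = TRUE),
                          sample(sedentary_labels, sum(doc), replace = TRUE))
            logs <- data.frame(
              participant_id = p$participant_id,
              date = bouts$date[doc],
              start = format_clock(bouts$start_min[doc]),
              end = format_clock(bouts$end_min[doc]),
              activity = lab, stringsAsFactors = FALSE)
          }
        }
      }

      if (config$detail == "stream") {
        stream <- simulate_stream_minutes(p$participant_id, truth, bouts,
                                          week_dates, span_lo, config)
        list(p = p, truth = truth, resp = resp, stream = stream,
             logs = logs, summ = NULL)
      } else {
        summ <- simulate_summaries(p$participant_id, truth, bouts, config)
        list(p = p, truth = truth, resp = resp, stream = NULL, logs = NULL,
             summ = summ)
      }
    })
    part_l[[i]] <- res$p
    truth_l[[i]] <- res$truth
    resp_l[[i]] <- as.data.frame(res$resp, stringsAsFactors = FALSE)
    if (!is.null(res$stream)) stream_l[[i]] <- res$stream
    if (!is.null(res$summ)) summ_l[[i]] <- res$summ
    if (!is.null(res$logs)) log_l[[length(log_l) + 1L]] <- res$logs
  }

  truth <- do.call(rbind, truth_l)
  truth <- truth[, c("participant_id", "window_type", "date", "start_min",
                     "end_min", "true_mean_pct", "true_pct")]
  logs <- if (length(log_l)) do.call(rbind, log_l) else
    data.frame(participant_id = character(0), date = as.Date(character(0)),
               start = character(0), end = character(0),
               activity = character(0), stringsAsFactors = FALSE)
  structure(list(
    participants = do.call(rbind, part_l),
    truth = truth,
    responses = do.call(rbind, resp_l),
    streams = if (length(stream_l)) do.call(rbind, stream_l) else NULL,
    summaries = if (length(summ_l)) do.call(rbind, summ_l) else NULL,
    nonwear_log = logs,
    met_table = met_tab,
    schedules = schedules,
    week_dates = week_dates,
    config = config), class = "yap_cohort")
}

# minute-level stream for one participant (vectorized over the whole week)
simulate_stream_minutes <- function(pid, truth, bouts, week_dates, span_lo,
                                    config) {
  day_l <- list()
  for (d in seq_along(week_dates)) {
    key <- format(week_dates[d], "%Y-%m-%d")
    lo <- if (key %in% names(span_lo)) span_lo[[key]] else 7 * 60
    mins <- seq.int(lo, 22 * 60 - 1L)
    p <- rep(0.08, length(mins))  # background activity outside windows
    tw <- truth[format(truth$date) == key, , drop = FALSE]
    if (nrow(tw)) {
      occ_p <- clip(tw$true_pct +
                      rnorm(nrow(tw), 0, config$mvpa_measurement_noise_sd),
                    0, 100) / 100
      for (j in seq_len(nrow(tw))) {
        sel <- mins >= tw$start_min[j] & mins < tw$end_min[j]
        p[sel] <- occ_p[j]
      }
    }
    mvpa <- runif(length(mins)) < p
    ee <- ifelse(mvpa, runif(length(mins), 3.0, 8.0),
                 runif(length(mins), 1.0, 2.9))
    wear <- rep(TRUE, length(mins))
    if (!is.null(bouts)) {
      bd <- bouts[format(bouts$date) == key, , drop = FALSE]
      for (j in seq_len(nrow(bd))) {
        wear[mins >= bd$start_min[j] & mins < bd$end_min[j]] <- FALSE
      }
    }
    day_l[[d]] <- data.frame(
      participant_id = pid, date = week_dates[d], minute = mins,
      ee_mets = round(ee, 2), wear = wear, mvpa = mvpa,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, day_l)
}

# direct window-summary generation (summary detail): worn minutes are
# scheduled minutes minus nonwear-bout overlap; MVPA minutes are binomial
# around the occurrence truth (device noise added at occurrence level)
simulate_summaries <- function(pid, truth, bouts, config) {
  n <- nrow(truth)
  worn <- truth$end_min - truth$start_min
  if (!is.null(bouts)) {
    for (j in seq_len(nrow(bouts))) {
      same <- format(truth$date) == format(bouts$date[j])
      ov <- pmax(0, pmin(truth$end_min, bouts$end_min[j]) -
                    pmax(truth$start_min, bouts$start_min[j]))
      worn <- worn - ifelse(same, ov, 0)
    }
    worn <- pmax(0L, as.integer(worn))
  }
  p <- clip(truth$true_pct + rnorm(n, 0, config$mvpa_measurement_noise_sd),
            0, 100) / 100
  mvpa <- rbinom(n, worn, p)
  out <- data.frame(
    participant_id = pid, window_type = truth$window_type,
    date = truth$date, start_min = truth$start_min,
    end_min = truth$end_min,
    scheduled_minutes = truth$end_min - truth$start_min,
    worn_minutes = as.integer(worn), mvpa_minutes = as.integer(mvpa),
    imputed_minutes = 0L, imputed_mvpa_minutes = 0L,
    stringsAsFactors = FALSE)
  out$pct_mvpa <- ifelse(out$worn_minutes > 0,
                         100 * out$mvpa_minutes / out$worn_minutes, NA_real_)
  out
}

#' Oracle window summaries from the cohort's truth table
#'
#' The simulator's noiseless view: every occurrence fully worn with
#' `pct_mvpa` equal to the latent occurrence truth. Used for parameter
#' recovery and as the evaluation reference in cross-validation.
#'
#' @param cohort a `yap_cohort`.
#' @return window-summary data.frame.
#' @export
cohort_truth_summaries <- function(cohort) {
  tr <- cohort$truth
  data.frame(
    participant_id = tr$participant_id, window_type = tr$window_type,
    date = tr$date, start_min = tr$start_min, end_min = tr$end_min,
    scheduled_minutes = tr$end_min - tr$start_min,
    worn_minutes = tr$end_min - tr$start_min,
    mvpa_minutes = NA_integer_, imputed_minutes = 0L,
    imputed_mvpa_minutes = 0L, pct_mvpa = tr$true_pct,
    stringsAsFactors = FALSE)
}

#' @export
print.yap_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d participants, week of %s, detail=%s\n",
    nrow(x$participants), format(x$week_dates[1]), x$config$detail))
  tab <- table(x$participants$age_group)
  cat("  age groups:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one item's calibration dataset directly from the regression model
#'
#' Draws (age, gender, score) covariates and generates the mean window
#' percent MVPA from `intercept + beta_age * age + beta_gender * gender +
#' link(score) + noise` — the calibration model itself. This is the
#' generator used for coefficient-recovery and encoding-selection studies,
#' where the estimand must be known exactly.
#'
#' @param n rows to generate.
#' @param link an `item_link` giving the score term.
#' @param intercept,beta_age,beta_gender regression coefficients.
#' @param noise_sd residual SD of percent MVPA.
#' @param score_probs sampling probabilities of the ordinal scores.
#' @param seed RNG seed.
#' @param item_id label for the generated rows.
#' @return a calibration-dataset data.frame (columns `participant_id`,
#'   `item_id`, `mean_pct_mvpa`, `item_score`, `age_years`, `gender`).
#' @export
simulate_item_data <- function(n, link = make_linear_link(10, 6),
                               intercept = 10, beta_age = 0.5,
                               beta_gender = 4, noise_sd = 6,
                               score_probs = rep(0.2, 5), seed = 1,
                               item_id = "item") {
  with_seed(seed, {
    age <- runif(n, 9, 18)
    gender <- rbinom(n, 1, 0.5)
    scores <- seq(attr(link, "scale_min"), attr(link, "scale_max"))
    score <- sample(scores, n, replace = TRUE, prob = score_probs)
    pct <- intercept + beta_age * age + beta_gender * gender + link(score) +
      rnorm(n, 0, noise_sd)
    data.frame(participant_id = sprintf("S%05d", seq_len(n)),
               item_id = item_id, mean_pct_mvpa = clip(pct, 0, 100),
               item_score = score, age_years = age, gender = gender,
               stringsAsFactors = FALSE)
  })
}

#' Write a cohort's observable files to a directory
#'
#' Emits the pipeline's input files: `streams.csv` (stream detail only),
#' `schedule.yml`, `responses.csv` (item scores plus demographics),
#' `nonwear_log.csv` and `met_table.csv`. Round-trips losslessly through
#' the corresponding readers.
#'
#' @param cohort a `yap_cohort`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir,
                                 call. = FALSE)
  meta <- output_metadata(seed = cohort$config$rng_seed)
  paths <- c()
  if (!is.null(cohort$streams)) {
    s <- cohort$streams
    s$timestamp <- sprintf("%s %s", format(s$date), format_clock(s$minute))
    s$wear <- as.integer(s$wear); s$mvpa <- as.integer(s$mvpa)
    paths["streams"] <- write_csv_meta(
      s[, c("participant_id", "timestamp", "ee_mets", "wear", "mvpa")],
      file.path(out_dir, "streams.csv"), meta)
  }
  resp <- merge(cohort$participants[, c("participant_id", "age_years",
                                        "gender", "age_group", "season")],
                cohort$responses, by = "participant_id", sort = TRUE)
  paths["responses"] <- write_csv_meta(resp,
                                       file.path(out_dir, "responses.csv"),
                                       meta)
  lg <- cohort$nonwear_log
  lg$date <- format(as.Date(lg$date))
  paths["nonwear_log"] <- write_csv_meta(lg,
    file.path(out_dir, "nonwear_log.csv"), meta)
  paths["met_table"] <- write_csv_meta(cohort$met_table,
    file.path(out_dir, "met_table.csv"), meta)
  sched <- lapply(cohort$schedules, function(s) {
    list(school_start = s$school_start, school_end = s$school_end,
         recess = s$recess, physical_education = s$physical_education,
         lunch = s$lunch)
  })
  yaml::write_yaml(list(
    week_start = format(cohort$week_dates[1]),
    assignment = stats::setNames(as.list(cohort$participants$age_group),
                                 cohort$participants$participant_id),
    schedules = sched), file.path(out_dir, "schedule.yml"))
  paths["schedule"] <- file.path(out_dir, "schedule.yml")
  invisible(paths)
}
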