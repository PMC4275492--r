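#' Agreement metrics, equivalence testing and power analysis
#'
#' Individual error for participant i is `(predicted_i - observed_i) /
#' mean(observed) * 100`; group error is `(mean(predicted) -
#' mean(observed)) / mean(observed) * 100`. Because the group error is the
#' mean of the individual errors, aggregation dilutes individual error: the
#' absolute group error can never exceed the mean absolute individual
#' error.
#'
#' Group-level equivalence uses two one-sided tests (TOST): the measures
#' are declared equivalent when both one-sided 95% confidence bounds of the
#' mean paired difference fall inside a region of +/- 10% (by default) of
#' the observed (accelerometer) group mean.
#'
#' @name evaluate
NULL

#' Individual and group percent-error report
#'
#' @param predicted,observed paired numeric vectors (self-report-calibrated
#'   and accelerometer estimates). Pairs with missing values are dropped
#'   and counted in `n_dropped`.
#' @return object of class `agreement_report`: list with `n`, `n_dropped`,
#'   `individual_error_pct` (vector), `min`, `max`, `mean`, `sd`,
#'   `mean_abs`, `group_error_pct`.
#' @export
agreement_report <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  ok <- !(is.na(predicted) | is.na(observed))
  dropped <- sum(!ok)
  p <- predicted[ok]; o <- observed[ok]
  if (length(p) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  mo <- mean(o)
  if (mo <= 0) stop("mean observed must be positive to express percent error",
                    call. = FALSE)
  err <- (p - o) / mo * 100
  structure(list(
    n = length(p), n_dropped = dropped,
    individual_error_pct = err,
    min = min(err), max = max(err), mean = mean(err), sd = stats::sd(err),
    mean_abs = mean(abs(err)),
    group_error_pct = (mean(p) - mo) / mo * 100), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement (n=%d, %d pairs dropped):\n  individual error %% : min %.1f, max %.1f, mean %.1f (SD %.1f), mean |err| %.1f\n  group error %%      : %.2f\n",
    x$n, x$n_dropped, x$min, x$max, x$mean, x$sd, x$mean_abs,
    x$group_error_pct))
  invisible(x)
}

#' TOST equivalence test with a proportional region
#'
#' Paired differences `predicted - observed`; the two one-sided
#' `(1 - alpha)` confidence bounds of the mean difference are
#' `mean(d) -/+ t_{1-alpha, n-1} * se`. The equivalence region is
#' `+/- region_fraction * mean(observed)`. Verdict is `"equivalent"` iff
#' both bounds lie inside the region. With zero variance of the
#' differences the verdict comes from the constant difference alone.
#'
#' @param predicted,observed paired numeric vectors.
#' @param region_fraction half-width of the region as a fraction of the
#'   observed group mean (default 0.10).
#' @param alpha one-sided test level (default 0.05, i.e. two one-sided 95%
#'   bounds — numerically the 90% two-sided interval).
#' @return object of class `equivalence_result`.
#' @export
tost_equivalence <- function(predicted, observed, region_fraction = 0.10,
                             alpha = 0.05) {
  ok <- !(is.na(predicted) | is.na(observed))
  p <- predicted[ok]; o <- observed[ok]
  n <- length(p)
  if (n < 3) stop("need at least 3 complete pairs for TOST", call. = FALSE)
  if (mean(o) == 0) stop("observed group mean is zero; proportional region undefined",
                         call. = FALSE)
  d <- p - o
  md <- mean(d)
  sdd <- stats::sd(d)
  margin <- region_fraction * mean(o)
  region <- sort(c(-margin, margin))
  if (sdd == 0) {
    lower <- upper <- md
  } else {
    se <- sdd / sqrt(n)
    tcrit <- stats::qt(1 - alpha, df = n - 1)
    lower <- md - tcrit * se
    upper <- md + tcrit * se
  }
  verdict <- if (lower >= region[1] && upper <= region[2]) "equivalent"
             else "not_equivalent"
  structure(list(
    n = n, mean_difference = md, sd_difference = sdd,
    reference_mean = mean(o), region_fraction = region_fraction,
    region = region, lower_bound = lower, upper_bound = upper,
    alpha = alpha, verdict = verdict), class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "TOST equivalence (n=%d): mean diff %.3f, one-sided %.0f%% bounds [%.3f, %.3f]\n  region +/- %.1f%% of reference mean %.3f = [%.3f, %.3f] -> %s\n",
    x$n, x$mean_difference, 100 * (1 - x$alpha), x$lower_bound,
    x$upper_bound, 100 * x$region_fraction, x$reference_mean, x$region[1],
    x$region[2], x$verdict))
  invisible(x)
}

#' Power of the R-squared-change F test
#'
#' Tests the increment from a reduced to a full multiple-regression model.
#' Effect size `f2 = (r2_full - r2_reduced) / (1 - r2_full)`; the test
#' statistic under the alternative follows a noncentral F with
#' `df1 = n_tested_predictors`, `df2 = n - n_predictors_full - 1` and
#' noncentrality `n * f2`.
#'
#' @param n sample size (vectorized).
#' @param r2_full,r2_reduced population R-squared of the two models.
#' @param n_predictors_full predictors in the full model.
#' @param n_tested_predictors predictors added by the full model.
#' @param alpha test level.
#' @return power values in (0, 1); `NA` where `df2 < 1`.
#' @export
r2_change_power <- function(n, r2_full = 0.35, r2_reduced = 0.25,
                            n_predictors_full = 3, n_tested_predictors = 1,
                            alpha = 0.05) {
  stopifnot(r2_reduced >= 0, r2_full < 1, alpha > 0, alpha < 1)
  if (r2_full <= r2_reduced) {
    stop("r2_full must exceed r2_reduced for a testable increment",
         call. = FALSE)
  }
  f2 <- (r2_full - r2_reduced) / (1 - r2_full)
  df1 <- n_tested_predictors
  df2 <- n - n_predictors_full - 1
  out <- rep(NA_real_, length(n))
  ok <- df2 >= 1
  if (any(ok)) {
    crit <- stats::qf(1 - alpha, df1, df2[ok])
    out[ok] <- stats::pf(crit, df1, df2[ok], ncp = n[ok] * f2,
                         lower.tail = FALSE)
  }
  out
}

#' Required sample size for the R-squared-change test
#'
#' Smallest `n` whose power reaches the target; verified directly against
#' the noncentral-F power function (power(n) >= target > power(n - 1)).
#'
#' @inheritParams r2_change_power
#' @param power target power (default 0.80).
#' @param n_max search ceiling.
#' @return list with `n`, `f2`, `power_at_n`, `power_at_n_minus_1`.
#' @export
sample_size_r2_change <- function(r2_full = 0.35, r2_reduced = 0.25,
                                  n_predictors_full = 3,
                                  n_tested_predictors = 1, alpha = 0.05,
                                  power = 0.80, n_max = 100000L) {
  stopifnot(power > 0, power < 1)
  pw <- function(n) r2_change_power(n, r2_full, r2_reduced,
                                    n_predictors_full, n_tested_predictors,
                                    alpha)
  lo <- n_predictors_full + 2L
  hi <- lo
  while (hi < n_max && (is.na(pw(hi)) || pw(hi) < power)) hi <- hi * 2L
  if (hi >= n_max && pw(n_max) < power) {
    stop("target power not reachable below n_max", call. = FALSE)
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (!is.na(pw(mid)) && pw(mid) >= power) hi <- mid else lo <- mid + 1L
  }
  n <- hi
  list(n = n,
       f2 = (r2_full - r2_reduced) / (1 - r2_full),
       power_at_n = pw(n),
       power_at_n_minus_1 = if (n - 1 >= n_predictors_full + 2) pw(n - 1)
                            else NA_real_)
}

#' Holdout cross-validation of the calibration pipeline
#'
#' Splits a simulated cohort's participants, fits per-item models on the
#' training split, predicts weekly composite minutes for the held-out
#' participants, and compares them to the held-out truth-derived weekly
#' minutes (the simulator's oracle; with field data the accelerometer
#' estimate plays this role). Deterministic given `seed`.
#'
#' @param cohort a `yap_cohort`.
#' @param split_fraction fraction of participants in the training split.
#' @param seed RNG seed for the split.
#' @param rules [screening_rules()] applied to the observed summaries.
#' @param encoding passed to [fit_all_items()].
#' @param region_fraction,alpha passed to [tost_equivalence()].
#' @return list with `agreement` ([agreement_report()]), `equivalence`
#'   ([tost_equivalence()]), `models`, `n_train`, `n_test`.
#' @export
holdout_cross_validate <- function(cohort, split_fraction = 0.5, seed = 1,
                                   rules = screening_rules(),
                                   encoding = "auto",
                                   region_fraction = 0.10, alpha = 0.05) {
  stopifnot(inherits(cohort, "yap_cohort"))
  ids <- cohort$participants$participant_id
  n_train <- max(2L, round(length(ids) * split_fraction))
  train_ids <- with_seed(seed, sample(ids, n_train))
  test_ids <- setdiff(ids, train_ids)

  summaries <- cohort$summaries
  if (is.null(summaries)) {
    summaries <- segment_cohort(
      cohort$streams,
      stats::setNames(
        cohort$schedules[cohort$participants$age_group],
        cohort$participants$participant_id),
      cohort$week_dates)
    summaries <- impute_nonwear(summaries, cohort$streams,
                                cohort$nonwear_log, cohort$met_table)
  }
  summaries <- flag_valid_windows(summaries, rules)
  tr_sum <- summaries[summaries$participant_id %in% train_ids, ,
                      drop = FALSE]
  retention <- retain_participants(tr_sum, rules)
  ds <- assemble_dataset(tr_sum, cohort$responses, cohort$participants,
                         cohort$config$instrument, retention)
  models <- fit_all_items(ds, cohort$config$instrument, encoding = encoding)
  act_ids <- activity_items(cohort$config$instrument)$item_id
  missing_models <- setdiff(act_ids, names(models))
  if (length(missing_models)) {
    stop("training split left item(s) without a fittable model: ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }

  # per-participant weights follow each participant's own schedule
  group_weights <- lapply(cohort$schedules, function(s) {
    window_weekly_weights(build_weekly_windows(s, cohort$week_dates))
  })
  wlist <- stats::setNames(
    group_weights[cohort$participants$age_group],
    cohort$participants$participant_id)

  test_resp <- cohort$responses[cohort$responses$participant_id %in%
                                  test_ids, , drop = FALSE]
  pred <- predict_composites(models, test_resp, cohort$participants, wlist,
                             cohort$config$instrument)
  truth_obs <- observed_weekly_minutes(
    cohort_truth_summaries(cohort)[
      cohort$truth$participant_id %in% test_ids, , drop = FALSE],
    wlist, strict = TRUE)
  mm <- merge(pred[, c("participant_id", "weekly_min_week")],
              truth_obs[, c("participant_id", "weekly_min_week")],
              by = "participant_id", suffixes = c("_pred", "_obs"))
  list(agreement = agreement_report(mm$weekly_min_week_pred,
                                    mm$weekly_min_week_obs),
       equivalence = tost_equivalence(mm$weekly_min_week_pred,
                                      mm$weekly_min_week_obs,
                                      region_fraction = region_fraction,
                                      alpha = alpha),
       models = models, n_train = length(train_ids),
       n_test = length(test_ids))
}
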