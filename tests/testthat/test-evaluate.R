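test_that("agreement errors follow their defining formulas exactly", {
  # identical vectors: all errors zero
  a <- agreement_report(c(10, 20, 30), c(10, 20, 30))
  expect_equal(a$individual_error_pct, c(0, 0, 0))
  expect_equal(a$group_error_pct, 0)

  # symmetric +/-10%: group error cancels, mean |error| stays
  obs <- c(100, 100)
  pred <- c(90, 110)
  a2 <- agreement_report(pred, obs)
  expect_equal(a2$individual_error_pct, c(-10, 10))
  expect_equal(a2$group_error_pct, 0)
  expect_equal(a2$mean_abs, 10)

  # random pairs against a direct spreadsheet-style recomputation
  set.seed(8)
  for (i in 1:10) {
    o <- runif(25, 50, 150)
    p <- o + rnorm(25, 0, 20)
    a3 <- agreement_report(p, o)
    manual <- (p - o) / mean(o) * 100
    expect_equal(a3$individual_error_pct, manual, tolerance = 1e-12)
    expect_equal(a3$group_error_pct, (mean(p) - mean(o)) / mean(o) * 100,
                 tolerance = 1e-12)
    expect_equal(a3$mean, mean(manual), tolerance = 1e-12)
    # dilution identity: |mean| <= mean |.|
    expect_lte(abs(a3$group_error_pct), a3$mean_abs)
  }

  # missing pairs dropped with audit count
  a4 <- agreement_report(c(1, NA, 3, 4), c(1, 2, NA, 4))
  expect_equal(a4$n, 2); expect_equal(a4$n_dropped, 2)
  expect_error(agreement_report(c(1, 2), c(0, 0)), "positive")
  expect_error(agreement_report(1, c(1, 2)), "equal length")
})

test_that("TOST verdicts follow the proportional equivalence region", {
  # all differences exactly zero: bounds collapse inside any region
  r0 <- tost_equivalence(rep(50, 100), rep(50, 100))
  expect_equal(r0$verdict, "equivalent")
  expect_equal(r0$lower_bound, 0); expect_equal(r0$upper_bound, 0)

  # constant difference at 25% of the reference: outside the 10% region
  r25 <- tost_equivalence(rep(125, 20), rep(100, 20))
  expect_equal(r25$verdict, "not_equivalent")
  expect_equal(r25$mean_difference, 25)

  # constant difference inside the region: degenerate exact equivalence
  r5 <- tost_equivalence(rep(105, 20), rep(100, 20))
  expect_equal(r5$verdict, "equivalent")

  expect_error(tost_equivalence(1:2, 1:2), "at least 3")
})

test_that("swapping the measure labels flips the difference sign only", {
  set.seed(4)
  o <- rnorm(40, 100, 10)
  p <- o + rnorm(40, 2, 8)
  # symmetric construction: compare swap on vectors with equal means
  p2 <- p - mean(p) + mean(o)
  f <- tost_equivalence(p2, o)
  b <- tost_equivalence(o, p2)
  expect_equal(f$mean_difference, -b$mean_difference)
  expect_equal(f$lower_bound, -b$upper_bound)
  expect_equal(f$verdict, b$verdict)
})

test_that("widening the equivalence region never revokes equivalence", {
  set.seed(12)
  for (i in 1:20) {
    o <- rnorm(30, 100, 15)
    p <- o + rnorm(30, runif(1, -15, 15), 10)
    regions <- c(0.05, 0.10, 0.20, 0.50)
    verdicts <- vapply(regions, function(r)
      tost_equivalence(p, o, region_fraction = r)$verdict, character(1))
    eq <- verdicts == "equivalent"
    # once equivalent, stays equivalent as the region widens
    expect_true(all(diff(as.integer(eq)) >= 0))
  }
})

test_that("R^2-change effect size and power follow the noncentral F", {
  res <- sample_size_r2_change(r2_full = 0.35, r2_reduced = 0.25,
                               alpha = 0.05, power = 0.80)
  expect_equal(res$f2, 0.10 / 0.65, tolerance = 1e-12)
  # self-consistency: smallest n reaching the target
  expect_gte(res$power_at_n, 0.80)
  expect_lt(res$power_at_n_minus_1, 0.80)
  # direct evaluation agrees
  expect_equal(res$power_at_n, r2_change_power(res$n), tolerance = 1e-12)

  # monotone in n and in f2
  ns <- seq(10, 200, by = 10)
  pw <- r2_change_power(ns)
  expect_true(all(diff(pw) > 0))
  f2s <- seq(0.05, 0.5, by = 0.05)
  pw2 <- vapply(f2s, function(f2) {
    r2r <- 0.25; r2f <- (f2 + r2r) / (1 + f2)
    r2_change_power(60, r2_full = r2f, r2_reduced = r2r)
  }, numeric(1))
  expect_true(all(diff(pw2) > 0))

  # more power costs more sample
  res90 <- sample_size_r2_change(power = 0.90)
  expect_gt(res90$n, res$n)
  expect_error(sample_size_r2_change(r2_full = 0.25, r2_reduced = 0.25),
               "exceed")
})

test_that("holdout cross-validation is split-deterministic", {
  coh <- quick_cohort(n = 80, seed = 14)
  a <- suppressWarnings(holdout_cross_validate(coh, seed = 2,
                                               encoding = "linear"))
  b <- suppressWarnings(holdout_cross_validate(coh, seed = 2,
                                               encoding = "linear"))
  expect_equal(a$agreement$individual_error_pct,
               b$agreement$individual_error_pct)
  expect_equal(a$equivalence$verdict, b$equivalence$verdict)
  expect_equal(a$n_train + a$n_test, 80)
})

test_that("a noiseless cohort cross-validates with near-zero group error", {
  ins <- default_instrument()
  cfg <- sim_config(n_participants = 120, detail = "summary",
                    reporting_noise_sd = 0, within_week_sd = 0,
                    mvpa_measurement_noise_sd = 0,
                    discretize_scores = FALSE,
                    item_links = linear_links_for(ins),
                    nonwear_rate = c(elementary = 0, middle = 0, high = 0),
                    rng_seed = 6)
  coh <- simulate_cohort(cfg)
  # replace observed summaries with the oracle view: a perfect device
  coh$summaries <- cohort_truth_summaries(coh)
  cv <- suppressWarnings(holdout_cross_validate(coh, seed = 1,
                                                encoding = "linear"))
  expect_lt(abs(cv$agreement$group_error_pct), 0.5)
})
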