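week <- as.Date("2025-09-15") + 0:6

test_that("assemble_dataset averages valid occurrences and honours retention", {
  ins <- default_instrument()
  s <- data.frame(
    participant_id = "A", window_type = "evening", date = week[1:3],
    start_min = 1080, end_min = 1320, scheduled_minutes = 240,
    worn_minutes = 240, mvpa_minutes = c(24, 48, 24),
    imputed_minutes = 0, imputed_mvpa_minutes = 0,
    pct_mvpa = c(10, 20, 10), valid = TRUE, stringsAsFactors = FALSE)
  resp <- data.frame(participant_id = "A", q08_evening = 3)
  demo <- data.frame(participant_id = "A", age_years = 12, gender = 0)
  ret <- data.frame(participant_id = "A", window_type = "evening",
                    n_valid = 3, required = 3, retained = TRUE)
  ds <- assemble_dataset(s, resp, demo, ins, ret)
  expect_equal(nrow(ds), 1)
  expect_equal(ds$item_id, "q08_evening")
  expect_equal(ds$mean_pct_mvpa, mean(c(10, 20, 10)))
  expect_equal(ds$n_occasions, 3)

  # equal pct on all occurrences -> mean equals that value
  s$pct_mvpa <- 15
  expect_equal(assemble_dataset(s, resp, demo, ins, ret)$mean_pct_mvpa, 15)

  # invalid occurrences are excluded from the average
  s$valid <- c(TRUE, TRUE, FALSE); s$pct_mvpa <- c(10, 20, 99)
  expect_equal(assemble_dataset(s, resp, demo, ins, ret)$mean_pct_mvpa, 15)

  # empty retention -> empty dataset, no error
  ret0 <- ret; ret0$retained <- FALSE
  expect_equal(nrow(assemble_dataset(s, resp, demo, ins, ret0)), 0)

  # missing demographics -> excluded with audit
  demo_na <- data.frame(participant_id = "A", age_years = NA, gender = 0)
  ds_na <- assemble_dataset(s, resp, demo_na, ins, ret)
  expect_equal(nrow(ds_na), 0)
  expect_equal(attr(ds_na, "excluded"), "A")
})

test_that("noiseless linear data is recovered to numerical precision", {
  link <- make_linear_link(12, 7)
  d <- simulate_item_data(600, link = link, intercept = 6, beta_age = 0.9,
                          beta_gender = 3.5, noise_sd = 0, seed = 11)
  m <- suppressWarnings(fit_item_model(d, "item", "linear"))
  # link(s) = 12 + 7 (s - 1): slope 7, intercept contribution 5
  expect_equal(unname(m$coefficients), c(6 + 5, 0.9, 3.5, 7),
               tolerance = 1e-8)
  expect_lt(abs(sum(stats::residuals(m$fit))), 1e-8)
})

test_that("OLS residuals of noisy fits sum to zero", {
  d <- simulate_item_data(400, noise_sd = 8, seed = 2)
  for (enc in c("linear", "categorical")) {
    m <- fit_item_model(d, "item", enc)
    expect_lt(abs(sum(stats::residuals(m$fit))), 1e-9)
    expect_gte(m$residual_sd, 0)
    expect_gte(m$n_used, 10 * length(m$coefficients))
  }
})

test_that("categorical encoding captures a plateau that a slope cannot", {
  d <- simulate_item_data(600, link = make_plateau_link(4, 8, 10),
                          noise_sd = 6, seed = 7)
  lin <- fit_item_model(d, "item", "linear")
  cat_ <- fit_item_model(d, "item", "categorical")
  rss <- function(m) sum(stats::residuals(m$fit)^2)
  expect_lt(rss(cat_), rss(lin))
  sel <- select_encoding(d, "item")
  expect_equal(sel$encoding, "categorical")
  # the fitted level effects flatten between the knot and the top score
  b <- cat_$coefficients
  expect_lt(abs(b[["score_term5"]] - b[["score_term4"]]),
            0.5 * (b[["score_term4"]] - b[["score_term3"]]))
})

test_that("a linear generator selects the linear encoding", {
  d <- simulate_item_data(600, link = make_linear_link(10, 6), noise_sd = 6,
                          seed = 19)
  expect_equal(select_encoding(d, "item")$encoding, "linear")
})

test_that("degenerate designs fail loudly or fall back with a warning", {
  d <- simulate_item_data(200, noise_sd = 5, seed = 3)
  d$item_score <- 3  # constant response
  expect_error(fit_item_model(d, "item", "categorical"), "degenerate")
  expect_warning(sel <- select_encoding(d, "item"), "falling back")
  expect_equal(sel$encoding, "linear")
  expect_error(fit_item_model(d[1:20, ], "item", "linear"), "fit floor")
  expect_error(fit_item_model(d, "nonexistent"), "no rows")
})

test_that("composite predictions weight windows by minutes and frequency", {
  ins <- default_instrument()
  act <- activity_items(ins)
  # hand-built models: intercept-only at 50% for every item
  mk <- function(id, b0) {
    structure(list(item_id = id, encoding = "linear",
                   coefficients = c("(Intercept)" = b0, age_years = 0,
                                    gender = 0, score_term = 0),
                   residual_sd = 0, n_used = 100, r_squared = 0,
                   shapiro_p = NA_real_, score_levels = NULL,
                   mean_score = 3, fit = NULL),
              class = "item_calibration")
  }
  models <- structure(lapply(act$item_id, mk, b0 = 50),
                      class = "item_calibration_set")
  names(models) <- act$item_id
  sc <- schedule_config(recess = list("2025-09-15" = c("10:00", "10:15")),
                        physical_education = list("2025-09-16" =
                                                    c("13:30", "14:15")),
                        lunch = list("2025-09-15" = c("12:00", "12:30")))
  w <- window_weekly_weights(build_weekly_windows(sc, week))
  resp <- data.frame(participant_id = "A")
  for (id in act$item_id) resp[[id]] <- 3
  demo <- data.frame(participant_id = "A", age_years = 12, gender = 1)
  cp <- predict_composites(models, resp, demo, w, ins)
  manual <- sum(w$minutes * w$per_week) * 0.5
  expect_equal(cp$weekly_min_week, manual)
  expect_equal(cp$weekly_min_week,
               cp$school_min_week + cp$out_of_school_min_week)

  # evening at 10%: 240 min x 5 weekdays x 0.10 = 120 min/week
  models10 <- models
  models10$q08_evening <- mk("q08_evening", 10)
  cp10 <- predict_composites(models10, resp, demo, w, ins)
  expect_equal(cp10$min_q08_evening, 120)

  # missing response: flagged, predicted at the mean calibration score
  resp_na <- resp; resp_na$q08_evening <- NA
  cp_na <- predict_composites(models10, resp_na, demo, w, ins)
  expect_match(cp_na$imputed_items, "q08_evening")
  expect_equal(cp_na$min_q08_evening, 120)  # intercept-only: score irrelevant
  cp_skip <- predict_composites(models10, resp_na, demo, w, ins,
                                missing = "skip")
  expect_equal(cp_skip$min_q08_evening, 0)

  # a model missing entirely is an error
  expect_error(predict_composites(models[-1], resp, demo, w, ins),
               "no fitted model")
})

test_that("exported models predict identically after a JSON round trip", {
  d <- simulate_item_data(300, link = make_plateau_link(4, 8, 10),
                          noise_sd = 6, seed = 13)
  models <- structure(list(item = fit_item_model(d, "item", "categorical")),
                      class = "item_calibration_set")
  path <- withr::local_tempfile(fileext = ".json")
  write_models(models, path)
  back <- read_models(path)
  nd <- data.frame(age_years = c(9.5, 13, 17), gender = c(0, 1, 0),
                   item_score = c(1, 4, 5))
  expect_equal(predict(back$item, nd), predict(models$item, nd))
  expect_equal(back$item$encoding, "categorical")
  expect_equal(back$item$n_used, models$item$n_used)
})

test_that("group-level error never exceeds mean individual error on cohorts", {
  for (seed in c(2, 5)) {
    coh <- quick_cohort(n = 120, seed = seed)
    cv <- suppressWarnings(holdout_cross_validate(coh, seed = seed,
                                                  encoding = "linear"))
    ag <- cv$agreement
    expect_lte(abs(ag$group_error_pct), ag$mean_abs)
    expect_gte(min(ag$individual_error_pct), ag$min - 1e-12)
    expect_true(ag$group_error_pct >= ag$min &&
                  ag$group_error_pct <= ag$max)
  }
})
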