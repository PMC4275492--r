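#' Per-item calibration regressions and composite scores
#'
#' Each window-linked questionnaire item gets its own ordinary-least-squares
#' calibration model relating the participant's mean valid-occurrence
#' percent MVPA in that item's window to age, gender and the raw item
#' score:
#'
#'   `MVPA = b0 + b1 * age + b2 * gender + b3 * score + e`
#'
#' The score term is entered either linearly or categorically (one effect
#' per observed score level); the categorical encoding accommodates items
#' whose relation to measured activity plateaus at the top of the scale.
#' Calibrated per-item percent predictions are converted to minutes per
#' week via the window's scheduled length and weekly frequency, then summed
#' into school, out-of-school and weekly composites.
#'
#' @name calibrate
NULL

#' Assemble the calibration dataset
#'
#' One row per retained (participant, item): the participant's percent MVPA
#' averaged with equal weight over the valid occurrences of the item's
#' window type, joined to the item response and demographics. Retained
#' participants missing age or gender are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param summaries window summaries with `valid` flags.
#' @param responses wide data.frame: `participant_id` plus item-id columns.
#' @param demographics data.frame `participant_id`, `age_years`, `gender`
#'   (0 = female, 1 = male).
#' @param instrument a [yap_instrument()].
#' @param retention output of [retain_participants()]; only rows with
#'   `retained = TRUE` enter.
#' @return data.frame `participant_id`, `item_id`, `mean_pct_mvpa`,
#'   `item_score`, `age_years`, `gender`, `n_occasions`.
#' @export
assemble_dataset <- function(summaries, responses, demographics, instrument,
                             retention) {
  check_columns(demographics, c("participant_id", "age_years", "gender"),
                "demographics")
  check_columns(retention, c("participant_id", "window_type", "retained"),
                "retention")
  act <- activity_items(instrument)
  kept <- retention[retention$retained, , drop = FALSE]
  empty <- data.frame(participant_id = character(0), item_id = character(0),
                      mean_pct_mvpa = numeric(0), item_score = numeric(0),
                      age_years = numeric(0), gender = numeric(0),
                      n_occasions = integer(0), stringsAsFactors = FALSE)
  if (nrow(kept) == 0) { attr(empty, "excluded") <- character(0); return(empty) }

  v <- summaries[summaries$valid & !is.na(summaries$pct_mvpa), , drop = FALSE]
  means <- aggregate(pct_mvpa ~ participant_id + window_type, data = v,
                     FUN = mean)
  counts <- aggregate(pct_mvpa ~ participant_id + window_type, data = v,
                      FUN = length)
  names(counts)[3] <- "n_occasions"
  means <- merge(means, counts, by = c("participant_id", "window_type"))

  kept <- merge(kept, means, by = c("participant_id", "window_type"))
  kept <- merge(kept, act[, c("item_id", "window_type")], by = "window_type")

  # attach responses (long form)
  item_cols <- intersect(act$item_id, names(responses))
  long <- do.call(rbind, lapply(item_cols, function(id) {
    data.frame(participant_id = responses$participant_id, item_id = id,
               item_score = responses[[id]], stringsAsFactors = FALSE)
  }))
  kept <- merge(kept, long, by = c("participant_id", "item_id"))
  kept <- merge(kept, demographics[, c("participant_id", "age_years",
                                       "gender")], by = "participant_id")
  excluded <- unique(kept$participant_id[is.na(kept$age_years) |
                                           is.na(kept$gender)])
  kept <- kept[!kept$participant_id %in% excluded &
                 !is.na(kept$item_score), , drop = FALSE]
  out <- kept[order(kept$item_id, kept$participant_id),
              c("participant_id", "item_id", "pct_mvpa", "item_score",
                "age_years", "gender", "n_occasions")]
  names(out)[names(out) == "pct_mvpa"] <- "mean_pct_mvpa"
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Fit one item's calibration regression
#'
#' @param data calibration dataset (from [assemble_dataset()] or
#'   [simulate_item_data()]).
#' @param item_id item to fit.
#' @param encoding `"linear"` (score as a numeric slope) or `"categorical"`
#'   (one effect per observed score level, reference = lowest observed).
#' @param min_n_per_coef fit floor: `n >= min_n_per_coef` per estimated
#'   coefficient (default 10).
#' @return object of class `item_calibration`: coefficients, encoding,
#'   residual SD, n, R-squared, a residual-normality summary
#'   (Shapiro-Wilk p) and the underlying `lm` fit.
#' @export
fit_item_model <- function(data, item_id, encoding = c("linear",
                                                       "categorical"),
                           min_n_per_coef = 10) {
  encoding <- match.arg(encoding)
  d <- data[data$item_id == item_id, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for item ", item_id, call. = FALSE)
  d <- d[stats::complete.cases(d[, c("mean_pct_mvpa", "item_score",
                                     "age_years", "gender")]), , drop = FALSE]
  n_levels <- length(unique(d$item_score))
  if (encoding == "categorical" && n_levels < 2) {
    stop("degenerate design for item ", item_id,
         ": a single observed score level cannot support the categorical ",
         "encoding", call. = FALSE)
  }
  n_coef <- if (encoding == "linear") 4L else 3L + (n_levels - 1L)
  if (nrow(d) < min_n_per_coef * n_coef) {
    stop("item ", item_id, ": n = ", nrow(d), " below the fit floor of ",
         min_n_per_coef, " rows per coefficient (", n_coef, " coefficients)",
         call. = FALSE)
  }
  d$score_term <- if (encoding == "linear") d$item_score
                  else factor(d$item_score)
  if (encoding == "linear" && n_levels < 2) {
    # constant response: the score slope is inestimable; fit demographics
    # only and pin the slope at zero so the model stays usable
    fit <- stats::lm(mean_pct_mvpa ~ age_years + gender, data = d)
    cf <- c(stats::coef(fit), score_term = 0)
  } else {
    fit <- stats::lm(mean_pct_mvpa ~ age_years + gender + score_term,
                     data = d)
    cf <- stats::coef(fit)
  }
  if (anyNA(cf)) {
    stop("degenerate design for item ", item_id, ": rank-deficient model",
         call. = FALSE)
  }
  res <- stats::residuals(fit)
  sw <- if (nrow(d) >= 3 && nrow(d) <= 5000 && stats::sd(res) > 0) {
    tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  } else NA_real_
  structure(list(
    item_id = item_id, encoding = encoding,
    coefficients = cf,
    residual_sd = summary(fit)$sigma,
    n_used = nrow(d),
    r_squared = summary(fit)$r.squared,
    shapiro_p = sw,
    score_levels = if (encoding == "categorical")
      sort(unique(d$item_score)) else NULL,
    mean_score = mean(d$item_score),
    fit = fit), class = "item_calibration")
}

#' @export
print.item_calibration <- function(x, ...) {
  cat(sprintf("Item calibration [%s]: %s encoding, n=%d, R^2=%.3f, sigma=%.2f\n",
              x$item_id, x$encoding, x$n_used, x$r_squared, x$residual_sd))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict window percent MVPA from a fitted item model
#' @param object an `item_calibration`
#' @param newdata data.frame with `age_years`, `gender`, `item_score`
#' @param ... unused
#' @return numeric predictions clipped to `[0, 100]`
#' @export
predict.item_calibration <- function(object, newdata, ...) {
  # prediction uses the stored coefficients (not the lm object) so that
  # models re-imported from their JSON export predict identically
  b <- object$coefficients
  base <- b[["(Intercept)"]] + b[["age_years"]] * newdata$age_years +
    b[["gender"]] * newdata$gender
  if (object$encoding == "linear") {
    pred <- base + b[["score_term"]] * newdata$item_score
  } else {
    # snap any unseen score to the nearest level observed at fit time;
    # the reference (lowest observed) level has effect zero
    lev <- object$score_levels
    snap <- lev[vapply(newdata$item_score,
                       function(s) which.min(abs(lev - s)), integer(1))]
    eff <- vapply(snap, function(s) {
      nm <- paste0("score_term", s)
      if (nm %in% names(b)) b[[nm]] else 0
    }, numeric(1))
    pred <- base + eff
  }
  clip(unname(pred), 0, 100)
}

#' Choose the score encoding for one item
#'
#' Fits both encodings and keeps the categorical one only when it improves
#' the selection criterion (default BIC, a consistent choice that picks the
#' linear encoding under a truly linear relation and the categorical one
#' under a clear plateau; AIC/AICc are available). Falls back to linear
#' with a warning when the categorical fit is degenerate.
#'
#' @param data calibration dataset.
#' @param item_id item to examine.
#' @param criterion `"bic"`, `"aicc"` or `"aic"`.
#' @param min_n_per_coef fit floor passed to [fit_item_model()].
#' @return the selected `item_calibration`, with `$selection` recording
#'   both criterion values.
#' @export
select_encoding <- function(data, item_id, criterion = c("bic", "aicc",
                                                         "aic"),
                            min_n_per_coef = 10) {
  criterion <- match.arg(criterion)
  lin <- fit_item_model(data, item_id, "linear",
                        min_n_per_coef = min_n_per_coef)
  cat_fit <- tryCatch(
    fit_item_model(data, item_id, "categorical",
                   min_n_per_coef = min_n_per_coef),
    error = function(e) e)
  if (inherits(cat_fit, "error")) {
    warning("item ", item_id,
            ": categorical encoding unavailable (",
            conditionMessage(cat_fit), "); falling back to linear",
            call. = FALSE)
    lin$selection <- list(criterion = criterion, linear = NA_real_,
                          categorical = NA_real_, fallback = TRUE)
    return(lin)
  }
  crit <- function(fit, n) {
    k <- length(stats::coef(fit)) + 1  # + residual variance
    switch(criterion,
           bic = stats::BIC(fit),
           aic = stats::AIC(fit),
           aicc = stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1))
  }
  c_lin <- crit(lin$fit, lin$n_used)
  c_cat <- crit(cat_fit$fit, cat_fit$n_used)
  chosen <- if (c_cat < c_lin) cat_fit else lin
  chosen$selection <- list(criterion = criterion, linear = c_lin,
                           categorical = c_cat, fallback = FALSE)
  chosen
}

#' Fit calibration models for every activity item
#'
#' @param data calibration dataset.
#' @param instrument a [yap_instrument()].
#' @param encoding `"auto"` (per-item [select_encoding()]), `"linear"` or
#'   `"categorical"`.
#' @param min_n_per_coef fit floor.
#' @return named list of `item_calibration` objects (class
#'   `item_calibration_set`).
#' @export
fit_all_items <- function(data, instrument, encoding = "auto",
                          min_n_per_coef = 10) {
  act <- activity_items(instrument)
  ids <- intersect(act$item_id, unique(data$item_id))
  models <- lapply(ids, function(id) {
    if (encoding == "auto") {
      select_encoding(data, id, min_n_per_coef = min_n_per_coef)
    } else {
      fit_item_model(data, id, encoding, min_n_per_coef = min_n_per_coef)
    }
  })
  names(models) <- ids
  structure(models, class = "item_calibration_set")
}

#' @export
print.item_calibration_set <- function(x, ...) {
  cat(sprintf("Calibration models for %d items:\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-26s %-11s n=%4d R^2=%.3f\n", m$item_id, m$encoding,
                m$n_used, m$r_squared))
  }
  invisible(x)
}

#' Predict calibrated activity composites per participant
#'
#' Each activity item's model predicts the participant's window percent
#' MVPA (clipped to 0-100); minutes per week are `pct/100 * scheduled
#' window minutes * weekly frequency`. Composites sum the items of each
#' activity section; `weekly = school + out_of_school`. A missing item
#' response contributes the model's prediction at the calibration-sample
#' mean score and is flagged (`imputed_items`), or is skipped when
#' `missing = "skip"`.
#'
#' @param models an `item_calibration_set` covering every activity item.
#' @param responses wide response data.frame (`participant_id` + item ids).
#' @param demographics `participant_id`, `age_years`, `gender`.
#' @param weights window weights from [window_weekly_weights()] (or a
#'   per-participant named list of them keyed by participant id).
#' @param instrument a [yap_instrument()].
#' @param missing `"mean_score"` or `"skip"`.
#' @return data.frame per participant: per-item predicted minutes columns
#'   (`min_<item>`), `school_min_week`, `out_of_school_min_week`,
#'   `weekly_min_week`, `imputed_items`.
#' @export
predict_composites <- function(models, responses, demographics, weights,
                               instrument, missing = c("mean_score",
                                                       "skip")) {
  missing <- match.arg(missing)
  act <- activity_items(instrument)
  absent <- setdiff(act$item_id, names(models))
  if (length(absent)) {
    stop("no fitted model for activity item(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  resp_cols <- c("participant_id", intersect(act$item_id, names(responses)))
  df <- merge(responses[, resp_cols, drop = FALSE],
              demographics[, c("participant_id", "age_years", "gender")],
              by = "participant_id")
  per_part_weights <- !is.data.frame(weights)
  out <- data.frame(participant_id = df$participant_id,
                    stringsAsFactors = FALSE)
  out$school_min_week <- 0; out$out_of_school_min_week <- 0
  out$imputed_items <- ""
  for (k in seq_len(nrow(act))) {
    id <- act$item_id[k]; wt <- act$window_type[k]
    m <- models[[id]]
    score <- df[[id]]
    miss <- is.na(score)
    if (any(miss)) {
      if (missing == "skip") score[miss] <- NA
      else score[miss] <- m$mean_score
      out$imputed_items <- ifelse(miss & missing == "mean_score",
                                  paste0(out$imputed_items, id, ";"),
                                  out$imputed_items)
    }
    nd <- data.frame(age_years = df$age_years, gender = df$gender,
                     item_score = score)
    pred <- rep(NA_real_, nrow(nd))
    ok <- !is.na(nd$item_score)
    if (any(ok)) pred[ok] <- predict.item_calibration(m, nd[ok, , drop = FALSE])
    if (per_part_weights) {
      wmin <- vapply(df$participant_id, function(p) {
        w <- weights[[p]]
        i <- match(wt, w$window_type)
        if (is.na(i)) 0 else w$minutes[i] * w$per_week[i]
      }, numeric(1))
    } else {
      i <- match(wt, weights$window_type)
      wmin <- if (is.na(i)) 0 else weights$minutes[i] * weights$per_week[i]
    }
    minutes <- ifelse(is.na(pred), 0, pred / 100 * wmin)
    out[[paste0("min_", id)]] <- minutes
    sec <- act$section[k]
    if (sec == "activity_school") {
      out$school_min_week <- out$school_min_week + minutes
    } else {
      out$out_of_school_min_week <- out$out_of_school_min_week + minutes
    }
  }
  out$weekly_min_week <- out$school_min_week + out$out_of_school_min_week
  out
}

#' Weekly observed MVPA minutes from window summaries
#'
#' The accelerometer-side analogue of [predict_composites()]: for each
#' participant, the mean valid-occurrence percent MVPA of each window type
#' weighted by the same scheduled-minutes-times-frequency weights. Used as
#' the criterion in cross-validation and equivalence testing. Participants
#' lacking a valid occurrence for some window type get that type's weight
#' at the cohort-mean percent when `strict = FALSE`, or are dropped when
#' `strict = TRUE`.
#'
#' @param summaries window summaries with `valid` flags (or the truth
#'   oracle view, where every occurrence is valid).
#' @param weights window weights ([window_weekly_weights()]) or a named
#'   per-participant list of them.
#' @param strict drop participants with unobserved window types.
#' @return data.frame `participant_id`, `school_min_week`,
#'   `out_of_school_min_week`, `weekly_min_week`.
#' @export
observed_weekly_minutes <- function(summaries, weights, strict = TRUE) {
  s <- summaries
  if (!"valid" %in% names(s)) s$valid <- TRUE
  s <- s[s$valid & !is.na(s$pct_mvpa), , drop = FALSE]
  means <- aggregate(pct_mvpa ~ participant_id + window_type, data = s,
                     FUN = mean)
  school_types <- c("transport_to_school", "recess", "physical_education",
                    "lunch", "transport_from_school")
  per_part <- !is.data.frame(weights)
  ids <- unique(means$participant_id)
  rows <- lapply(ids, function(p) {
    w <- if (per_part) weights[[p]] else weights
    m <- means[means$participant_id == p, ]
    i <- match(w$window_type, m$window_type)
    if (strict && anyNA(i)) return(NULL)
    pct <- m$pct_mvpa[i]
    pct[is.na(pct)] <- mean(means$pct_mvpa)
    minutes <- pct / 100 * w$minutes * w$per_week
    data.frame(participant_id = p,
               school_min_week = sum(minutes[w$window_type %in% school_types]),
               out_of_school_min_week =
                 sum(minutes[!w$window_type %in% school_types]),
               weekly_min_week = sum(minutes), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0),
                      school_min_week = numeric(0),
                      out_of_school_min_week = numeric(0),
                      weekly_min_week = numeric(0))
  }
  out
}
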