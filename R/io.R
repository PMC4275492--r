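#' Readers and writers for the pipeline's file formats
#'
#' All tabular files are comma-delimited UTF-8 with a single header row,
#' preceded by `#`-prefixed metadata lines (tool version, seed, config
#' hash) so that reruns are exactly reproducible. Timestamps are ISO-8601
#' local clock ("YYYY-MM-DD HH:MM"); schedules are local school clocks, so
#' no timezone arithmetic is performed.
#'
#' @name io
NULL

#' Metadata header for output files
#' @param seed the run seed recorded in every output.
#' @param config_hash optional hash identifying the configuration.
#' @return named character vector of metadata fields.
#' @export
output_metadata <- function(seed = NA, config_hash = NULL) {
  c(tool = paste0("yapcal ",
                  as.character(utils::packageVersion("yapcal"))),
    seed = as.character(seed),
    config_hash = config_hash %||% "none")
}

#' Write a data.frame as CSV with a metadata header
#' @param df data.frame.
#' @param path output path.
#' @param meta named character vector from [output_metadata()].
#' @return the path, invisibly usable in pipelines.
#' @export
write_csv_meta <- function(df, path, meta = output_metadata()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a metadata-headed CSV, validating row shape
#'
#' Malformed rows (wrong field count) abort with the offending line
#' number; missing required columns are a hard failure.
#'
#' @param path input path.
#' @param required character vector of required column names.
#' @return data.frame; metadata lines in attribute `"metadata"`.
#' @export
read_csv_meta <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- sub("^#\\s*", "", lines[is_meta])
  body <- lines[!is_meta]
  body_lineno <- which(!is_meta)
  if (length(body) == 0) stop("no header row in ", path, call. = FALSE)
  nfield <- utils::count.fields(textConnection(body), sep = ",",
                                quote = "\"")
  bad <- which(nfield != nfield[1])
  if (length(bad)) {
    stop("malformed row in ", path, " at line ", body_lineno[bad[1]],
         ": expected ", nfield[1], " fields, found ", nfield[bad[1]],
         call. = FALSE)
  }
  df <- utils::read.csv(textConnection(body), stringsAsFactors = FALSE)
  check_columns(df, required, path)
  attr(df, "metadata") <- meta
  df
}

#' Read minute-level accelerometer streams
#'
#' Expects columns `participant_id`, `timestamp` ("YYYY-MM-DD HH:MM"),
#' `ee_mets`, `wear` (0/1) and optionally `mvpa` (0/1). When `mvpa` is
#' absent it is derived as `ee_mets >= mvpa_threshold`.
#'
#' @param path CSV path.
#' @param mvpa_threshold MET cut for the derived MVPA flag (default 3.0).
#' @return data.frame `participant_id`, `date`, `minute`, `ee_mets`,
#'   `wear`, `mvpa`.
#' @export
read_streams <- function(path, mvpa_threshold = 3.0) {
  df <- read_csv_meta(path, required = c("participant_id", "timestamp",
                                         "ee_mets", "wear"))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2} [0-2]\\d:[0-5]\\d$", df$timestamp)
  if (any(!ok)) {
    stop("malformed timestamp in ", path, " (row ", which(!ok)[1], "): '",
         df$timestamp[!ok][1], "'", call. = FALSE)
  }
  if (any(df$ee_mets < 0, na.rm = TRUE)) {
    stop("negative energy expenditure in ", path, call. = FALSE)
  }
  out <- data.frame(
    participant_id = df$participant_id,
    date = as.Date(substr(df$timestamp, 1, 10)),
    minute = parse_clock(substr(df$timestamp, 12, 16)),
    ee_mets = df$ee_mets,
    wear = as.logical(as.integer(df$wear)),
    stringsAsFactors = FALSE)
  out$mvpa <- if ("mvpa" %in% names(df)) as.logical(as.integer(df$mvpa))
              else df$ee_mets >= mvpa_threshold
  out
}

#' Read questionnaire responses (wide; one row per participant)
#' @param path CSV with `participant_id`, item-id columns (blank = missing)
#'   and optionally `age_years`, `gender`, `age_group`, `season`.
#' @return data.frame.
#' @export
read_responses <- function(path) {
  read_csv_meta(path, required = "participant_id")
}

#' Read a nonwear activity log
#' @param path CSV with `participant_id`, `date`, `start`, `end`,
#'   `activity`.
#' @return data.frame with `date` parsed.
#' @export
read_nonwear_log <- function(path) {
  df <- read_csv_meta(path, required = c("participant_id", "date", "start",
                                         "end", "activity"))
  df$date <- as.Date(df$date)
  df
}

#' Read an activity-label to MET lookup table
#' @param path two-column CSV `activity`, `met`.
#' @return data.frame.
#' @export
read_met_table <- function(path) {
  df <- read_csv_meta(path, required = c("activity", "met"))
  if (any(df$met <= 0)) stop("MET values must be positive in ", path,
                             call. = FALSE)
  df
}

#' Read a schedule configuration file
#'
#' YAML with `week_start` (Monday), `schedules` (named group entries with
#' `school_start`, `school_end` and date-keyed `recess` /
#' `physical_education` / `lunch` time pairs) and `assignment` mapping
#' participant ids to schedule names.
#'
#' @param path YAML path.
#' @return list with `week_dates`, `schedules` (list of
#'   [schedule_config()]), `assignment` (named character vector).
#' @export
read_schedule <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse schedule config '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  for (k in c("week_start", "schedules")) {
    if (is.null(cfg[[k]])) stop("schedule config missing key '", k, "'",
                                call. = FALSE)
  }
  schedules <- lapply(cfg$schedules, function(s) {
    schedule_config(school_start = s$school_start,
                    school_end = s$school_end,
                    recess = s$recess %||% list(),
                    physical_education = s$physical_education %||% list(),
                    lunch = s$lunch %||% list())
  })
  list(week_dates = as.Date(cfg$week_start) + 0:6,
       schedules = schedules,
       assignment = unlist(cfg$assignment %||% list()))
}

#' Write / read window summaries
#' @param summaries window-summary data.frame.
#' @param path CSV path.
#' @param meta metadata header fields.
#' @return the path ([write_window_summaries()]) or the data.frame.
#' @export
write_window_summaries <- function(summaries, path,
                                   meta = output_metadata()) {
  s <- summaries
  s$date <- format(as.Date(s$date))
  attr(s, "skipped_log_entries") <- NULL
  write_csv_meta(s, path, meta)
}

#' @rdname write_window_summaries
#' @export
read_window_summaries <- function(path) {
  df <- read_csv_meta(path, required = c("participant_id", "window_type",
                                         "date", "scheduled_minutes",
                                         "worn_minutes", "pct_mvpa"))
  df$date <- as.Date(df$date)
  if ("valid" %in% names(df)) df$valid <- as.logical(df$valid)
  df
}

#' Export / import fitted item models as JSON
#'
#' The JSON record per item carries the encoding, named coefficients,
#' score levels (categorical), sample size and diagnostics, so the fitted
#' equations can be embedded in other software. Re-imported models predict
#' identically (prediction uses the stored coefficients, not the original
#' fit object).
#'
#' @param models an `item_calibration_set`.
#' @param path JSON path.
#' @param meta metadata fields embedded in the JSON.
#' @return the path ([write_models()]) or an `item_calibration_set`.
#' @export
write_models <- function(models, path, meta = output_metadata()) {
  recs <- lapply(unclass(models), function(m) {
    list(item_id = m$item_id, encoding = m$encoding,
         coefficients = as.list(m$coefficients),
         score_levels = m$score_levels, mean_score = m$mean_score,
         residual_sd = m$residual_sd, n_used = m$n_used,
         r_squared = m$r_squared, shapiro_p = m$shapiro_p)
  })
  jsonlite::write_json(list(metadata = as.list(meta), models = recs), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(obj$models, function(r) {
    structure(list(
      item_id = r$item_id, encoding = r$encoding,
      coefficients = unlist(r$coefficients),
      score_levels = if (length(r$score_levels)) unlist(r$score_levels)
                     else NULL,
      mean_score = r$mean_score, residual_sd = r$residual_sd,
      n_used = r$n_used, r_squared = r$r_squared,
      shapiro_p = if (is.null(r$shapiro_p)) NA_real_ else r$shapiro_p,
      fit = NULL), class = "item_calibration")
  })
  names(models) <- vapply(models, `[[`, character(1), "item_id")
  structure(models, class = "item_calibration_set")
}
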