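#' End-to-end pipeline
#'
#' Runs simulate (optional) -> segment -> screen (impute, flag, retain) ->
#' calibrate -> score -> evaluate, writing each stage's table plus a log of
#' record counts. Rerunning with an identical configuration and seed
#' reproduces byte-identical outputs (no timestamps are written).
#'
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' Either `simulate` (a list of [sim_config()] arguments) or the four
#' input paths (`streams`, `schedule`, `responses`, `nonwear_log`, plus
#' `met_table`) must be given.
#'
#' @param out_dir output directory.
#' @param seed run seed (also the simulator seed).
#' @param simulate optional named list of [sim_config()] arguments.
#' @param streams,schedule,responses,nonwear_log,met_table input paths
#'   (ignored when `simulate` is given).
#' @param rules a [screening_rules()].
#' @param encoding `"auto"`, `"linear"` or `"categorical"`.
#' @param min_n_per_coef fit floor passed to [fit_all_items()].
#' @param region_fraction,alpha equivalence-test settings.
#' @param verbose emit per-stage record counts on stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            streams = NULL, schedule = NULL,
                            responses = NULL, nonwear_log = NULL,
                            met_table = NULL,
                            rules = screening_rules(),
                            encoding = "auto", min_n_per_coef = 10,
                            region_fraction = 0.10,
                            alpha = 0.05, verbose = TRUE) {
  if (is.null(simulate)) {
    for (p in c(streams, schedule, responses)) {
      if (!file.exists(p)) stop("input path does not exist: ", p,
                                call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, streams = streams,
                 schedule = schedule, responses = responses,
                 nonwear_log = nonwear_log, met_table = met_table,
                 rules = rules, encoding = encoding,
                 min_n_per_coef = min_n_per_coef,
                 region_fraction = region_fraction, alpha = alpha,
                 verbose = verbose), class = "pipeline_config")
}

#' Run the full calibration pipeline
#'
#' @param config a [pipeline_config()] (or a YAML path parseable into one
#'   via [read_pipeline_config()]).
#' @return invisibly, a list with the stage outputs (`summaries`,
#'   `retention`, `dataset`, `models`, `composites`, `observed`,
#'   `agreement`, `equivalence`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (isTRUE(config$verbose)) {
      message(sprintf("[yapcal:%s] %s", stage, sprintf(...)))
    }
  }
  cfg_hash <- substr(paste(
    config$seed, config$encoding, config$region_fraction, config$alpha,
    config$rules$min_valid_fraction, config$rules$min_valid_periods,
    config$rules$mode, collapse = "|"), 1, 64)
  meta <- output_metadata(seed = config$seed, config_hash = cfg_hash)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      audit <- file.path(config$out_dir, "pipeline_error.txt")
      writeLines(c(paste("stage:", name), conditionMessage(e)), audit)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (audit: ", audit, ")", call. = FALSE)
    })
  }

  instrument <- default_instrument()
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$rng_seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(do.call(sim_config,
                                                        sim_args)))
    instrument <- cohort$config$instrument
    in_dir <- file.path(config$out_dir, "inputs")
    stage("simulate", write_cohort(cohort, in_dir))
    streams <- cohort$streams
    sched <- list(week_dates = cohort$week_dates,
                  schedules = cohort$schedules,
                  assignment = stats::setNames(
                    cohort$participants$age_group,
                    cohort$participants$participant_id))
    responses <- merge(cohort$participants[, c("participant_id",
                                               "age_years", "gender")],
                       cohort$responses, by = "participant_id")
    logs <- cohort$nonwear_log
    met_tab <- cohort$met_table
    say("simulate", "n=%d participants", nrow(cohort$participants))
  } else {
    streams <- stage("read", read_streams(config$streams))
    sched <- stage("read", read_schedule(config$schedule))
    responses <- stage("read", read_responses(config$responses))
    logs <- if (!is.null(config$nonwear_log))
      stage("read", read_nonwear_log(config$nonwear_log)) else NULL
    met_tab <- if (!is.null(config$met_table))
      stage("read", read_met_table(config$met_table)) else
        default_met_table()
  }
  check_columns(responses, c("participant_id", "age_years", "gender"),
                "responses")
  if (is.null(streams)) {
    stop("pipeline requires minute-level streams (simulate with ",
         "detail = 'stream')", call. = FALSE)
  }

  # segment
  part_sched <- stats::setNames(
    sched$schedules[sched$assignment[unique(streams$participant_id)]],
    unique(streams$participant_id))
  summaries <- stage("segment",
                     segment_cohort(streams, part_sched, sched$week_dates))
  write_window_summaries(summaries,
                         file.path(config$out_dir, "windows.csv"), meta)
  counts$windows <- nrow(summaries)
  say("segment", "%d window occurrences from %d participants",
      nrow(summaries), length(unique(summaries$participant_id)))

  # screen
  summaries <- stage("screen",
                     impute_nonwear(summaries, streams, logs, met_tab))
  summaries <- flag_valid_windows(summaries, config$rules)
  retention <- retain_participants(summaries, config$rules)
  write_window_summaries(summaries,
                         file.path(config$out_dir, "windows_screened.csv"),
                         meta)
  write_csv_meta(retention, file.path(config$out_dir, "retention.csv"),
                 meta)
  counts$valid_windows <- sum(summaries$valid)
  say("screen", "%d/%d occurrences valid; %d retained (participant,window) pairs",
      sum(summaries$valid), nrow(summaries), sum(retention$retained))

  # calibrate
  dataset <- stage("calibrate",
                   assemble_dataset(summaries, responses, responses,
                                    instrument, retention))
  write_csv_meta(dataset, file.path(config$out_dir,
                                    "calibration_data.csv"), meta)
  models <- stage("calibrate",
                  fit_all_items(dataset, instrument,
                                encoding = config$encoding,
                                min_n_per_coef = config$min_n_per_coef))
  write_models(models, file.path(config$out_dir, "models.json"), meta)
  say("calibrate", "%d item models fitted on %d rows", length(models),
      nrow(dataset))

  # score
  group_weights <- lapply(sched$schedules, function(s) {
    window_weekly_weights(build_weekly_windows(s, sched$week_dates))
  })
  ids <- responses$participant_id
  wlist <- stats::setNames(group_weights[sched$assignment[ids]], ids)
  composites <- stage("score",
                      predict_composites(models, responses, responses,
                                         wlist, instrument))
  write_csv_meta(composites, file.path(config$out_dir, "composites.csv"),
                 meta)
  say("score", "composites for %d participants", nrow(composites))

  # evaluate: predicted vs accelerometer weekly minutes on the
  # whole-week-retained set (every window type valid, so the observed
  # weekly estimate is complete)
  ww_rules <- config$rules; ww_rules$mode <- "whole_week"
  ww <- retain_participants(summaries, ww_rules)
  ww_ids <- unique(ww$participant_id[ww$retained])
  observed <- observed_weekly_minutes(
    summaries[summaries$participant_id %in% ww_ids, , drop = FALSE],
    wlist, strict = TRUE)
  mm <- merge(composites[, c("participant_id", "weekly_min_week")],
              observed[, c("participant_id", "weekly_min_week")],
              by = "participant_id", suffixes = c("_pred", "_obs"))
  agreement <- NULL; equivalence <- NULL
  if (nrow(mm) >= 3) {
    agreement <- agreement_report(mm$weekly_min_week_pred,
                                  mm$weekly_min_week_obs)
    equivalence <- tost_equivalence(mm$weekly_min_week_pred,
                                    mm$weekly_min_week_obs,
                                    region_fraction = config$region_fraction,
                                    alpha = config$alpha)
    write_csv_meta(
      data.frame(participant_id = mm$participant_id,
                 predicted_min_week = mm$weekly_min_week_pred,
                 observed_min_week = mm$weekly_min_week_obs,
                 error_pct = agreement$individual_error_pct),
      file.path(config$out_dir, "agreement.csv"), meta)
    jsonlite::write_json(
      list(metadata = as.list(meta),
           equivalence = unclass(equivalence),
           group_error_pct = agreement$group_error_pct,
           mean_abs_individual_error_pct = agreement$mean_abs),
      file.path(config$out_dir, "equivalence.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    say("evaluate", "n=%d pairs, group error %.2f%%, verdict %s",
        agreement$n, agreement$group_error_pct, equivalence$verdict)
  } else {
    say("evaluate", "skipped: only %d complete pairs", nrow(mm))
  }

  counts_df <- data.frame(stage = names(counts),
                          records = unlist(counts, use.names = FALSE))
  write_csv_meta(counts_df, file.path(config$out_dir, "pipeline_log.csv"),
                 meta)
  invisible(list(summaries = summaries, retention = retention,
                 dataset = dataset, models = models,
                 composites = composites, observed = observed,
                 agreement = agreement, equivalence = equivalence,
                 out_dir = config$out_dir))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; `rules` is a mapping with
#' `min_valid_fraction`, `min_valid_periods`, `mode`.
#'
#' @param path YAML path.
#' @param out_dir,seed optional overrides.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  rules <- do.call(screening_rules, cfg$rules %||% list())
  pipeline_config(
    out_dir = out_dir %||% cfg$out_dir %||% stop("out_dir required"),
    seed = seed %||% cfg$seed %||% 1L,
    simulate = cfg$simulate,
    streams = cfg$streams, schedule = cfg$schedule,
    responses = cfg$responses, nonwear_log = cfg$nonwear_log,
    met_table = cfg$met_table, rules = rules,
    encoding = cfg$encoding %||% "auto",
    min_n_per_coef = cfg$min_n_per_coef %||% 10,
    region_fraction = cfg$region_fraction %||% 0.10,
    alpha = cfg$alpha %||% 0.05,
    verbose = cfg$verbose %||% TRUE)
}
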