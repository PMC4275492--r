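#' Segmented-day questionnaire definitions
#'
#' A segmented-day instrument asks one question per discrete daily time
#' window (recess, lunch, evening, ...) so that each item can be linked to
#' the matching period of an accelerometer record. The bundled default is a
#' 15-item Youth Activity Profile (YAP) style instrument: 5 activity-at-school
#' items, 5 activity-out-of-school items (each linked to one of the 10
#' schedule window types) and 5 sedentary items with no window link.
#'
#' @name instrument
NULL

yap_sections <- c("activity_school", "activity_out_of_school", "sedentary")

#' Construct and validate an instrument definition
#'
#' @param items data.frame with columns `item_id`, `section`, `window_type`
#'   (`NA` for unlinked items) and `prompt`.
#' @param sections character vector of section labels.
#' @param scale_min,scale_max ordinal response bounds.
#' @return An object of class `yap_instrument`: a list with elements
#'   `items`, `sections`, `scale_min`, `scale_max`.
#' @export
yap_instrument <- function(items, sections = yap_sections,
                           scale_min = 1L, scale_max = 5L) {
  check_columns(items, c("item_id", "section", "window_type", "prompt"),
                "instrument items")
  items$item_id <- as.character(items$item_id)
  items$section <- as.character(items$section)
  items$window_type <- as.character(items$window_type)
  obj <- structure(
    list(items = items, sections = as.character(sections),
         scale_min = as.integer(scale_min), scale_max = as.integer(scale_max)),
    class = "yap_instrument")
  validate_instrument(obj)
  obj
}

validate_instrument <- function(x) {
  items <- x$items
  if (anyDuplicated(items$item_id)) {
    dup <- unique(items$item_id[duplicated(items$item_id)])
    stop("instrument validation: duplicate item id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_sec <- setdiff(unique(items$section), x$sections)
  if (length(bad_sec)) {
    stop("instrument validation: undeclared section(s): ",
         paste(bad_sec, collapse = ", "), call. = FALSE)
  }
  linked <- !is.na(items$window_type)
  bad_win <- setdiff(items$window_type[linked], window_types())
  if (length(bad_win)) {
    stop("instrument validation: unknown window type(s): ",
         paste(bad_win, collapse = ", "), " for item(s) ",
         paste(items$item_id[items$window_type %in% bad_win], collapse = ", "),
         call. = FALSE)
  }
  if (x$scale_min >= x$scale_max) {
    stop("instrument validation: scale_min must be < scale_max", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.yap_instrument <- function(x, ...) {
  cat(sprintf("Segmented-day instrument: %d items in %d sections (scale %d-%d)\n",
              nrow(x$items), length(x$sections), x$scale_min, x$scale_max))
  for (s in x$sections) {
    it <- x$items[x$items$section == s, ]
    cat(sprintf("  %s: %d items (%d window-linked)\n", s, nrow(it),
                sum(!is.na(it$window_type))))
  }
  invisible(x)
}

#' Load an instrument definition from a YAML config
#'
#' @param path path to a YAML file with keys `scale_min`, `scale_max`,
#'   `sections` and `items` (a list of item records with `item_id`,
#'   `section`, optional `window_type`, optional `prompt`).
#' @return A validated [yap_instrument()].
#' @export
load_instrument <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse instrument config '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  for (k in c("sections", "items")) {
    if (is.null(cfg[[k]])) {
      stop("instrument config '", path, "': missing key '", k, "'",
           call. = FALSE)
    }
  }
  items <- do.call(rbind, lapply(cfg$items, function(it) {
    if (is.null(it$item_id) || is.null(it$section)) {
      stop("instrument config '", path,
           "': every item needs item_id and section", call. = FALSE)
    }
    data.frame(item_id = it$item_id, section = it$section,
               window_type = if (is.null(it$window_type)) NA_character_
                             else it$window_type,
               prompt = if (is.null(it$prompt)) "" else it$prompt,
               stringsAsFactors = FALSE)
  }))
  yap_instrument(items, sections = cfg$sections,
                 scale_min = cfg$scale_min %||% 1L,
                 scale_max = cfg$scale_max %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The bundled 15-item YAP-style instrument
#'
#' Five school items (transport to school, PE, recess, lunch, transport from
#' school), five out-of-school items (after school, before school, evening,
#' Saturday, Sunday) and five sedentary items without a window link.
#' Prompts are placeholders, not the published item wording.
#'
#' @return A validated [yap_instrument()].
#' @export
default_instrument <- function() {
  load_instrument(system.file("extdata", "yap_instrument.yml",
                              package = "yapcal", mustWork = TRUE))
}

#' Items of an instrument that are linked to schedule windows
#' @param instrument a [yap_instrument()]
#' @return data.frame of the window-linked (activity) items
#' @export
activity_items <- function(instrument) {
  instrument$items[!is.na(instrument$items$window_type), , drop = FALSE]
}

#' Compute raw section composite scores for one respondent
#'
#' Each section score is the arithmetic mean of that section's non-missing
#' item responses (pairwise deletion). A section with no answered items gets
#' `NA`, never zero. A `low_coverage` flag marks sections where fewer than
#' half the items were answered.
#'
#' @param instrument a [yap_instrument()]
#' @param responses named numeric vector (or one-row data.frame) of item
#'   responses keyed by item id; `NA` marks a missing response.
#' @return data.frame with columns `section`, `score`, `n_answered`,
#'   `n_items`, `low_coverage`.
#' @export
score_sections <- function(instrument, responses) {
  if (is.data.frame(responses)) {
    stopifnot(nrow(responses) == 1)
    responses <- unlist(responses[1, , drop = TRUE])
  }
  responses <- responses[names(responses) %in% instrument$items$item_id]
  vals <- suppressWarnings(as.numeric(responses))
  names(vals) <- names(responses)
  ok <- !is.na(vals)
  if (any(vals[ok] < instrument$scale_min | vals[ok] > instrument$scale_max)) {
    bad <- names(vals)[ok & (vals < instrument$scale_min |
                             vals > instrument$scale_max)]
    stop("response(s) outside scale bounds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(instrument$sections, function(s) {
    ids <- instrument$items$item_id[instrument$items$section == s]
    v <- vals[ids]
    n_ans <- sum(!is.na(v))
    data.frame(section = s,
               score = if (n_ans > 0) mean(v, na.rm = TRUE) else NA_real_,
               n_answered = n_ans, n_items = length(ids),
               low_coverage = n_ans < length(ids) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
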