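# Internal helpers shared across modules.

#' Parse "HH:MM" clock strings to minutes since midnight
#' @param x character vector of clock times
#' @return integer vector of minutes since midnight
#' @keywords internal
#' @noRd
parse_clock <- function(x) {
  ok <- grepl("^[0-2]?[0-9]:[0-5][0-9]$", x)
  if (any(!ok)) {
    stop("malformed clock time(s): ", paste(x[!ok], collapse = ", "),
         " (expected HH:MM)", call. = FALSE)
  }
  parts <- strsplit(x, ":", fixed = TRUE)
  h <- vapply(parts, function(p) as.integer(p[[1]]), integer(1))
  m <- vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  if (any(h > 23)) stop("clock hour out of range: ", x[h > 23][1], call. = FALSE)
  h * 60L + m
}

#' Format minutes since midnight back to "HH:MM"
#' @noRd
format_clock <- function(m) {
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' Clip numeric vector to [lo, hi]
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible per-unit sub-seed from a master seed
#'
#' Keeps cohorts extendable: participant i's stream never changes when
#' n_participants grows, because each participant draws from an own stream
#' keyed by (master seed, index). Kept below 2^31 - 1.
#' @noRd
split_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + index * 9973) %% 2147483629
}

#' Run an expression under a temporary RNG seed, restoring prior RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

#' Stop unless required columns are present
#' @noRd
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
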