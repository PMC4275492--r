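# Shared fixtures: random schedules/streams and a brute-force segmentation
# oracle used to cross-check the vectorized minute-assignment path.

# naive per-minute double loop: for every stream minute, scan every window
naive_segment <- function(stream, windows) {
  windows$date <- as.Date(windows$date)
  stream$date <- as.Date(stream$date)
  n <- nrow(windows)
  worn <- integer(n); mvpa <- integer(n)
  assigned <- integer(nrow(stream))
  for (i in seq_len(nrow(stream))) {
    hits <- 0L
    for (j in seq_len(n)) {
      if (stream$date[i] == windows$date[j] &&
          stream$minute[i] >= windows$start_min[j] &&
          stream$minute[i] < windows$end_min[j]) {
        hits <- hits + 1L
        if (stream$wear[i]) {
          worn[j] <- worn[j] + 1L
          if (stream$mvpa[i]) mvpa[j] <- mvpa[j] + 1L
        }
      }
    }
    assigned[i] <- hits
  }
  list(worn = worn, mvpa = mvpa, assigned = assigned)
}

# random but internally consistent school schedule: recess/PE/lunch occupy
# disjoint slots inside the school day on random subsets of weekdays
random_schedule <- function(seed) {
  set.seed(seed)
  ss <- 8 * 60 + sample(0:45, 1)
  se <- 15 * 60 + sample(0:55, 1)
  slot <- function(offset, len) {
    c(format_clock_t(ss + offset), format_clock_t(ss + offset + len))
  }
  days <- function() sort(sample(1:5, sample(2:5, 1)))
  dates_of <- function(d) {
    stats::setNames(rep(list(NULL), 0), character(0))
  }
  wd <- as.Date("2025-09-15") + 0:6
  mk <- function(ds, times) {
    out <- list()
    for (d in ds) out[[format(wd[d], "%Y-%m-%d")]] <- times
    out
  }
  schedule_config(
    school_start = format_clock_t(ss), school_end = format_clock_t(se),
    recess = mk(days(), slot(90 + sample(0:10, 1), 10 + sample(0:10, 1))),
    physical_education = mk(days(), slot(150 + sample(0:10, 1),
                                         35 + sample(0:10, 1))),
    lunch = mk(days(), slot(230 + sample(0:15, 1), 25 + sample(0:10, 1))))
}

format_clock_t <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

# sparse random stream across the week with random wear/mvpa flags
random_stream <- function(seed, pid = "P1", n_min = 800) {
  set.seed(seed)
  wd <- as.Date("2025-09-15") + 0:6
  d <- sample(wd, n_min, replace = TRUE)
  m <- sample(300:1339, n_min, replace = TRUE)
  key <- paste(d, m)
  keep <- !duplicated(key)
  data.frame(participant_id = pid, date = d[keep], minute = m[keep],
             ee_mets = runif(sum(keep), 1, 8),
             wear = runif(sum(keep)) < 0.85,
             mvpa = runif(sum(keep)) < 0.4, stringsAsFactors = FALSE)
}

# small summary-detail cohort for screening/evaluation tests
quick_cohort <- function(n = 60, seed = 1, ...) {
  simulate_cohort(sim_config(n_participants = n, detail = "summary",
                             rng_seed = seed, ...))
}

# all-linear response links for the bundled instrument (overrides the
# preset's plateau PE item; used where exact linearity is required)
linear_links_for <- function(instrument, intercept_base = 15, slope = 8) {
  act <- activity_items(instrument)
  links <- list()
  for (k in seq_len(nrow(act))) {
    links[[act$item_id[k]]] <- make_linear_link(intercept_base + 2 * k,
                                                slope)
  }
  links
}
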