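# Shared fixtures and independent oracles for the test suite.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "hivstadhere")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", name)
  p
}

load_fixture_cohort <- function() {
  read_cohort(fixture_path("fixture_participants.csv"),
              fixture_path("fixture_events.csv"),
              as.Date(c("2017-07-01", "2018-06-30")))
}

load_fixture_answers <- function() {
  jsonlite::read_json(fixture_path("fixture_answers.json"),
                      simplifyVector = TRUE)
}

# ---- brute-force adherence oracle -----------------------------------------
# Recomputes every pairwise consecutive gap from scratch and re-evaluates both
# criteria literally; independent of classify_adherence's implementation.
oracle_classify <- function(dates, results, endpoint, threshold = 100) {
  dates <- as.Date(dates)
  c1 <- TRUE
  if (length(dates) > 1)
    for (i in 2:length(dates))
      if (as.integer(dates[i] - dates[i - 1]) > threshold) c1 <- FALSE
  c2 <- as.integer(as.Date(endpoint) - dates[length(dates)]) <= threshold
  waived <- results[length(results)] == "positive"
  if (c1 && (c2 || waived)) "adherent" else "nonadherent"
}

# random included-participant timeline: first test somewhere in the window,
# 1-8 further gaps of 1-400 days (truncated at the endpoint), possibly a
# terminal positive result
random_timeline <- function(window_start, window_end) {
  start <- window_start + sample.int(200, 1) - 1
  dates <- start
  for (i in seq_len(sample.int(8, 1))) {
    nxt <- dates[length(dates)] + sample.int(400, 1)
    if (nxt > window_end) break
    dates <- c(dates, nxt)
  }
  results <- rep("negative", length(dates))
  if (stats::runif(1) < 0.15) results[length(results)] <- "positive"
  list(dates = dates, results = results)
}

events_df <- function(dates, results,
                      condom = rep(NA_character_, length(dates)),
                      id = "X") {
  data.frame(participant_id = rep(id, length(dates)), date = as.Date(dates),
             result = results, condom_use = condom, stringsAsFactors = FALSE)
}

# ---- hand-rolled logrank test (two groups, no ties) ------------------------
# U = sum over event times of (observed - expected) in group 1; V = sum of
# hypergeometric variances; statistic U^2 / V.
oracle_logrank <- function(time, event, group) {
  stopifnot(!anyDuplicated(time[event == 1]))
  U <- 0; V <- 0
  for (t in sort(time[event == 1])) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# ---- independent timeline sampler for the distribution-level truth ---------
# Mirrors the configured gap distributions but is written from the stated
# distributions, not via simulate_timeline; used to derive the expected
# classified-adherent probability per archetype.
oracle_sample_timeline <- function(archetype, window_start, window_end,
                                   stop_prob, cfg) {
  span <- as.integer(window_end - window_start)
  dates <- window_start + sample.int(span + 1, 1) - 1
  repeat {
    if (stats::runif(1) < stop_prob) break
    gap <- if (archetype == "adherent") {
      sample(cfg$adherent_interval[1]:cfg$adherent_interval[2], 1)
    } else if (stats::runif(1) < cfg$nonadherent_p_short) {
      sample(cfg$nonadherent_short[1]:cfg$nonadherent_short[2], 1)
    } else {
      sample(cfg$nonadherent_long[1]:cfg$nonadherent_long[2], 1)
    }
    nxt <- dates[length(dates)] + gap
    if (nxt > window_end) break
    dates <- c(dates, nxt)
  }
  dates
}
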