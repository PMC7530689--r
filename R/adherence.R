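#' Eligibility cascade: exclusion statuses
#'
#' Applies the fixed-order exclusion cascade that defines the analyzed
#' cohort: (1) registered but never tested; (2) positive at the first test
#' (already infected at entry, adherence undefined); (3) exactly one
#' negative test lying within `threshold_days` of the study endpoint, so
#' adherence cannot yet be judged. Everyone else is included.
#'
#' @param cohort a `hivst_cohort`.
#' @param threshold_days adherence interval threshold (default 100).
#' @param inclusive_single_test if `TRUE` (default) the single-test window
#'   uses `endpoint - date <= threshold`; `FALSE` uses strict `<`. The
#'   inclusive form is the exact complement of the second adherence
#'   criterion.
#' @return data.frame: `participant_id`, `eligibility` (one of `included`,
#'   `excluded_no_test`, `excluded_baseline_positive`,
#'   `excluded_indeterminate_single_test`).
#' @export
apply_exclusions <- function(cohort, threshold_days = 100,
                             inclusive_single_test = TRUE) {
  stopifnot(inherits(cohort, "hivst_cohort"))
  ids <- cohort$participants$participant_id
  endpoint <- cohort$window[2]
  ev_by <- split(cohort$events, cohort$events$participant_id)
  status <- vapply(ids, function(id) {
    ev <- ev_by[[id]]
    if (is.null(ev) || nrow(ev) == 0) return("excluded_no_test")
    if (ev$result[1] == "positive") return("excluded_baseline_positive")
    if (nrow(ev) == 1) {
      gap <- as.integer(endpoint - ev$date[1])
      near <- if (inclusive_single_test) gap <= threshold_days
              else gap < threshold_days
      if (near) return("excluded_indeterminate_single_test")
    }
    "included"
  }, character(1), USE.NAMES = FALSE)
  data.frame(participant_id = ids, eligibility = status,
             stringsAsFactors = FALSE)
}

#' Classify one participant's adherence
#'
#' The two-criterion definition: (1) no gap between adjacent tests exceeds
#' `threshold_days` (inclusive: a gap of exactly the threshold still
#' qualifies); (2) the last test lies within `threshold_days` of the study
#' endpoint (also inclusive). Criterion 2 is waived when the last test is
#' positive — a confirmed seroconverter needs no further tests. Adherent
#' iff criterion 1 holds and criterion 2 holds or is waived.
#'
#' @param events ordered event data.frame for one included participant
#'   (columns `date`, `result`), at least one row.
#' @param window_end study endpoint date.
#' @param threshold_days interval threshold in days (default 100).
#' @return List of class `adherence_label`: `label`
#'   ("adherent"/"nonadherent"), `criterion1_met`, `criterion2_met`,
#'   `waived_for_seroconversion`.
#' @export
classify_adherence <- function(events, window_end, threshold_days = 100) {
  if (is.null(events) || nrow(events) == 0)
    stop("classify_adherence requires at least one test event")
  dates <- as.Date(events$date)
  if (is.unsorted(dates, strictly = TRUE)) stop("events must be strictly date-ordered")
  gaps <- as.integer(diff(dates))
  c1 <- all(gaps <= threshold_days)
  endpoint_gap <- as.integer(as.Date(window_end) - dates[length(dates)])
  c2 <- endpoint_gap <= threshold_days
  waived <- events$result[nrow(events)] == "positive"
  structure(list(
    label = if (c1 && (c2 || waived)) "adherent" else "nonadherent",
    criterion1_met = c1, criterion2_met = c2,
    waived_for_seroconversion = waived), class = "adherence_label")
}

#' Count adhering tests
#'
#' A test is "adhering" when its gap from the participant's previous test is
#' at most `threshold_days` (inclusive). First tests never count; each
#' participant contributes `n_tests - 1` eligible intervals.
#'
#' @param events ordered event data.frame (column `date`) for one
#'   participant.
#' @param threshold_days interval threshold in days (default 100).
#' @return Named integer vector `c(eligible_intervals, adhering)`.
#' @export
count_adhering_tests <- function(events, threshold_days = 100) {
  dates <- as.Date(events$date)
  if (length(dates) <= 1)
    return(c(eligible_intervals = 0L, adhering = 0L))
  gaps <- as.integer(diff(dates))
  c(eligible_intervals = length(gaps),
    adhering = sum(gaps <= threshold_days))
}

#' Per-participant eligibility and adherence labels
#'
#' Runs the exclusion cascade and, for included participants, the adherence
#' classification and adhering-test counting, returning one row per
#' registered participant.
#'
#' @inheritParams apply_exclusions
#' @return data.frame: `participant_id`, `eligibility`, `label` (`NA` for
#'   excluded), `criterion1`, `criterion2`, `waived`, `n_tests`,
#'   `n_adhering`.
#' @export
adherence_labels <- function(cohort, threshold_days = 100,
                             inclusive_single_test = TRUE) {
  elig <- apply_exclusions(cohort, threshold_days, inclusive_single_test)
  ev_by <- split(cohort$events, cohort$events$participant_id)
  out <- elig
  out$label <- NA_character_
  out$criterion1 <- NA
  out$criterion2 <- NA
  out$waived <- NA
  out$n_tests <- vapply(out$participant_id, function(id) {
    ev <- ev_by[[id]]; if (is.null(ev)) 0L else nrow(ev)
  }, integer(1), USE.NAMES = FALSE)
  out$n_adhering <- 0L
  inc <- which(out$eligibility == "included")
  for (i in inc) {
    ev <- ev_by[[out$participant_id[i]]]
    lab <- classify_adherence(ev, cohort$window[2], threshold_days)
    out$label[i] <- lab$label
    out$criterion1[i] <- lab$criterion1_met
    out$criterion2[i] <- lab$criterion2_met
    out$waived[i] <- lab$waived_for_seroconversion
    out$n_adhering[i] <- count_adhering_tests(ev, threshold_days)[["adhering"]]
  }
  out
}

#' Cohort-level adherence summary
#'
#' Aggregates the cascade and classification: counts of included, adherent
#' and nonadherent participants, the adherent proportion, and the
#' adhering-test proportion (adhering tests over all tests of included
#' participants excluding each participant's first).
#'
#' @inheritParams apply_exclusions
#' @param labels optionally, a precomputed [adherence_labels()] result.
#' @return List of class `adherence_summary` with fields `n_registered`,
#'   `n_excluded_no_test`, `n_excluded_baseline_positive`,
#'   `n_excluded_indeterminate`, `n_included`, `n_adherent`,
#'   `n_nonadherent`, `proportion_adherent`, `n_tests_total`,
#'   `n_eligible_intervals`, `n_adhering_tests`, `proportion_adhering_tests`.
#'   Proportions are `NaN` when their denominator is zero.
#' @export
summarize_adherence <- function(cohort, threshold_days = 100,
                                inclusive_single_test = TRUE, labels = NULL) {
  if (is.null(labels))
    labels <- adherence_labels(cohort, threshold_days, inclusive_single_test)
  inc <- labels[labels$eligibility == "included", , drop = FALSE]
  n_included <- nrow(inc)
  n_adherent <- sum(inc$label == "adherent")
  n_tests_total <- sum(inc$n_tests)
  n_eligible <- n_tests_total - n_included
  n_adhering <- sum(inc$n_adhering)
  structure(list(
    n_registered = nrow(labels),
    n_excluded_no_test = sum(labels$eligibility == "excluded_no_test"),
    n_excluded_baseline_positive =
      sum(labels$eligibility == "excluded_baseline_positive"),
    n_excluded_indeterminate =
      sum(labels$eligibility == "excluded_indeterminate_single_test"),
    n_included = n_included,
    n_adherent = n_adherent,
    n_nonadherent = n_included - n_adherent,
    proportion_adherent = if (n_included) n_adherent / n_included else NaN,
    n_tests_total = n_tests_total,
    n_eligible_intervals = n_eligible,
    n_adhering_tests = n_adhering,
    proportion_adhering_tests = if (n_eligible) n_adhering / n_eligible else NaN
  ), class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat("<adherence summary>\n")
  cat(sprintf("  registered %d = no-test %d + baseline-positive %d + indeterminate %d + included %d\n",
              x$n_registered, x$n_excluded_no_test,
              x$n_excluded_baseline_positive, x$n_excluded_indeterminate,
              x$n_included))
  cat(sprintf("  adherent %d / %d (%.2f%%)\n", x$n_adherent, x$n_included,
              100 * x$proportion_adherent))
  cat(sprintf("  adhering tests %d / %d intervals (%.2f%%)\n",
              x$n_adhering_tests, x$n_eligible_intervals,
              100 * x$proportion_adhering_tests))
  invisible(x)
}
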