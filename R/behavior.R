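#' Classify a condom-use behavior transition
#'
#' Maps an ordered pair of condom-use categories (baseline questionnaire at
#' the first test, follow-up questionnaire at a later test) to one of three
#' classes:
#'
#' * `Better` — moved to a more protective category (Never->Ever,
#'   Never->Consistent, Ever->Consistent), maintained Consistent, or was
#'   Uncertain at baseline but Consistent at follow-up.
#' * `Worse` — moved to a less safe category (Ever->Never,
#'   Consistent->Ever, Consistent->Never).
#' * `Other` — stayed in a less protective category (Never->Never,
#'   Ever->Ever) or any pair involving an Uncertain follow-up, or an
#'   Uncertain baseline not resolved to Consistent.
#'
#' The map is total over the 16 ordered pairs. Vectorized; missing values
#' are treated as `Uncertain`.
#'
#' @param baseline,followup condom categories (see [condom_levels()]).
#' @return Character vector over `{"Better", "Worse", "Other"}`.
#' @export
#' @examples
#' classify_transition("Never", "Consistent")   # Better
#' classify_transition("Consistent", "Ever")    # Worse
classify_transition <- function(baseline, followup) {
  baseline <- as.character(baseline); followup <- as.character(followup)
  baseline[is.na(baseline)] <- "Uncertain"
  followup[is.na(followup)] <- "Uncertain"
  ok <- condom_levels()
  bad <- c(baseline, followup)[!c(baseline, followup) %in% ok]
  if (length(bad)) stop("unknown condom-use category '", bad[1], "'")
  key <- paste(baseline, followup, sep = "->")
  better <- c("Never->Ever", "Never->Consistent", "Ever->Consistent",
              "Consistent->Consistent", "Uncertain->Consistent")
  worse <- c("Ever->Never", "Consistent->Ever", "Consistent->Never")
  ifelse(key %in% better, "Better", ifelse(key %in% worse, "Worse", "Other"))
}

#' Behavior-change table: kth test versus first test
#'
#' Restricts to included participants with at least `k` tests, classifies
#' each one's condom-use transition from the first to the kth test, and
#' tabulates the three classes against the adherence label, attaching the
#' uncorrected Pearson chi-square comparison. Rows (classes) with zero
#' margin are dropped before the test; if fewer than two classes or groups
#' remain the chi-square is marked degenerate (`NULL`).
#'
#' @param cohort a `hivst_cohort`.
#' @param labels an [adherence_labels()] result.
#' @param k test index to compare against the first test, `>= 2`.
#' @return List of class `behavior_change_table`: `k`, `n`, `table`
#'   (3 x 2 matrix, classes x adherent/nonadherent), `chi_square`
#'   ([pearson_chi_square()] result or `NULL`), `empty` (no eligible
#'   participants).
#' @export
behavior_change_table <- function(cohort, labels, k = 2) {
  stopifnot(k >= 2)
  keep <- labels$eligibility == "included" & labels$n_tests >= k
  ids <- labels$participant_id[keep]
  groups <- labels$label[keep]
  tab <- matrix(0L, 3, 2,
                dimnames = list(c("Better", "Worse", "Other"),
                                c("adherent", "nonadherent")))
  if (!length(ids))
    return(structure(list(k = k, n = 0L, table = tab, chi_square = NULL,
                          empty = TRUE), class = "behavior_change_table"))
  ev_by <- split(cohort$events, cohort$events$participant_id)
  cls <- vapply(ids, function(id) {
    ev <- ev_by[[id]]
    classify_transition(ev$condom_use[1], ev$condom_use[k])
  }, character(1), USE.NAMES = FALSE)
  for (i in seq_along(ids)) tab[cls[i], groups[i]] <- tab[cls[i], groups[i]] + 1L
  nz <- rowSums(tab) > 0
  chi <- NULL
  if (sum(nz) >= 2 && all(colSums(tab) > 0))
    chi <- pearson_chi_square(tab[nz, , drop = FALSE])
  structure(list(k = k, n = length(ids), table = tab, chi_square = chi,
                 empty = FALSE), class = "behavior_change_table")
}

#' @export
print.behavior_change_table <- function(x, ...) {
  cat("<behavior change> test", x$k, "vs first (n =", x$n, ")\n")
  print(x$table)
  if (!is.null(x$chi_square)) print(x$chi_square)
  else cat("  chi-square: degenerate/empty\n")
  invisible(x)
}
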