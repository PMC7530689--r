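#' Pipeline run configuration
#'
#' @param threshold_days adherence interval threshold in days.
#' @param inclusive_single_test see [apply_exclusions()].
#' @param ci_dialect incidence CI dialect, `"paper"` or `"garwood"`.
#' @param level confidence level for every interval.
#' @param ties Cox tie handling, `"breslow"` or `"efron"`.
#' @param m_imputations imputations for the missing-covariate sensitivity
#'   fit.
#' @param seed root seed; the imputation stage derives its seed from it so a
#'   fixed config gives a byte-identical report bundle.
#' @param adjustment_sets named list of covariate vectors for the adjusted
#'   logistic models; `NULL` = one set ("all") holding every dictionary
#'   covariate present plus the test-count category.
#' @param behavior_k test indices for the behavior-change tables.
#' @return List of class `run_config`.
#' @export
run_config <- function(threshold_days = 100, inclusive_single_test = TRUE,
                       ci_dialect = c("paper", "garwood"), level = 0.95,
                       ties = c("breslow", "efron"), m_imputations = 10,
                       seed = 1, adjustment_sets = NULL,
                       behavior_k = c(2, 3, 4)) {
  stopifnot(threshold_days > 0)
  structure(list(
    threshold_days = threshold_days,
    inclusive_single_test = inclusive_single_test,
    ci_dialect = match.arg(ci_dialect), level = level,
    ties = match.arg(ties), m_imputations = m_imputations,
    seed = seed, adjustment_sets = adjustment_sets,
    behavior_k = behavior_k), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Field names mirror [run_config()] arguments; absent fields keep their
#' defaults. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# test-count category used by the group-comparison tables
.n_test_group <- function(n) {
  ifelse(n <= 2, "2 times or below", ifelse(n == 3, "3 times", "4 times or above"))
}

# cross-tab a categorical vector against the adherence label; complete-case
.label_table <- function(value, label, levels) {
  keep <- !is.na(value) & !is.na(label)
  tab <- matrix(0L, length(levels), 2,
                dimnames = list(levels, c("adherent", "nonadherent")))
  for (i in which(keep)) tab[value[i], label[i]] <- tab[value[i], label[i]] + 1L
  tab
}

.try_chi <- function(tab) {
  nz <- rowSums(tab) > 0
  if (sum(nz) < 2 || any(colSums(tab) == 0)) return(NULL)
  tryCatch(pearson_chi_square(tab[nz, , drop = FALSE]), error = function(e) NULL)
}

#' Run the full analysis pipeline
#'
#' Executes validate -> exclusion cascade -> adherence classification ->
#' group-comparison table (counts + chi-square per covariate) -> effect
#' table (univariate odds ratios; adjusted logistic models per adjustment
#' set, complete-case and pooled over multiple imputations) -> follow-up
#' and incidence (rates per group with the configured CI dialect, rate
#' ratio, Cox hazard ratio) -> baseline condom table -> behavior-change
#' tables. Every table is returned with the counts that produced it; the
#' cascade counts satisfy `registered = no-test + baseline-positive +
#' indeterminate + included` and `included = adherent + nonadherent`.
#'
#' Stages whose estimates are undefined on the given data (e.g. a Cox fit
#' with no seroconversions) are recorded as `NULL` with a note in `$log`
#' rather than aborting the stages that can run; hard errors (unreadable
#' input, invalid config) abort naming the stage.
#'
#' @param cohort a `hivst_cohort`.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `labels.csv`,
#'   `table1.csv`, `table2.csv`, `rates.json`, `table4.csv`, `table5.csv`,
#'   `cascade.json` and `run.log.jsonl`.
#' @return List of class `hivst_report`: `validation`, `labels`, `summary`,
#'   `cascade`, `table1`, `table2`, `table3`, `table4`, `table5`, `config`,
#'   `log`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "hivst_cohort"), inherits(config, "run_config"))
  log <- list()
  note <- function(stage, msg) log[[length(log) + 1]] <<- list(stage = stage, note = msg)

  validation <- validate_cohort(cohort)
  labels <- adherence_labels(cohort, config$threshold_days,
                             config$inclusive_single_test)
  summary <- summarize_adherence(cohort, config$threshold_days,
                                 config$inclusive_single_test, labels = labels)
  cascade <- list(
    registered = summary$n_registered,
    excluded_no_test = summary$n_excluded_no_test,
    excluded_baseline_positive = summary$n_excluded_baseline_positive,
    excluded_indeterminate_single_test = summary$n_excluded_indeterminate,
    included = summary$n_included,
    adherent = summary$n_adherent,
    nonadherent = summary$n_nonadherent)

  inc_ids <- labels$participant_id[labels$eligibility == "included"]
  part <- cohort$participants[match(inc_ids, cohort$participants$participant_id), ,
                              drop = FALSE]
  lab <- labels$label[match(inc_ids, labels$participant_id)]
  ntests <- labels$n_tests[match(inc_ids, labels$participant_id)]
  ev_by <- split(cohort$events, cohort$events$participant_id)
  sero <- vapply(inc_ids, function(id)
    any(ev_by[[id]]$result == "positive"), logical(1), USE.NAMES = FALSE)

  # ---- group-comparison table (counts + chi-square per characteristic)
  dict <- covariate_dictionary()
  vars <- intersect(names(dict), names(part))
  t1_rows <- list()
  add_t1 <- function(variable, tab) {
    chi <- .try_chi(tab)
    for (i in seq_len(nrow(tab)))
      t1_rows[[length(t1_rows) + 1]] <<- data.frame(
        variable = variable, level = rownames(tab)[i],
        adherent = tab[i, 1], nonadherent = tab[i, 2],
        chi_square = if (is.null(chi)) NA_real_ else chi$statistic,
        df = if (is.null(chi)) NA_integer_ else chi$df,
        p = if (is.null(chi)) NA_real_ else chi$p,
        stringsAsFactors = FALSE)
  }
  for (v in vars) add_t1(v, .label_table(part[[v]], lab, dict[[v]]))
  add_t1("hiv_seroconversion",
         .label_table(ifelse(sero, "Yes", "No"), lab, c("No", "Yes")))
  n_test_grp <- .n_test_group(ntests)
  add_t1("n_hivsts", .label_table(n_test_grp, lab,
         c("2 times or below", "3 times", "4 times or above")))
  table1 <- do.call(rbind, t1_rows)

  # ---- effect table: univariate ORs + adjusted logistic models
  part2 <- part
  part2$n_hivsts <- factor(n_test_grp, levels = c("2 times or below", "3 times",
                                                  "4 times or above"))
  model_vars <- c(vars, "n_hivsts")
  dict2 <- c(dict, list(n_hivsts = c("2 times or below", "3 times",
                                     "4 times or above")))
  outcome <- lab == "adherent"
  t2_rows <- list()
  for (v in model_vars) {
    levs <- dict2[[v]]
    val <- part2[[v]]
    ref <- levs[1]
    a_ref <- sum(val == ref & outcome, na.rm = TRUE)
    b_ref <- sum(val == ref & !outcome, na.rm = TRUE)
    for (lv in levs) {
      if (lv == ref) {
        t2_rows[[length(t2_rows) + 1]] <- data.frame(
          variable = v, level = lv, or = 1, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      a <- sum(val == lv & outcome, na.rm = TRUE)
      b <- sum(val == lv & !outcome, na.rm = TRUE)
      est <- tryCatch(odds_ratio_wald(a, b, a_ref, b_ref, level = config$level),
                      error = function(e) NULL)
      t2_rows[[length(t2_rows) + 1]] <- data.frame(
        variable = v, level = lv,
        or = if (is.null(est)) NA_real_ else est$or,
        ci_low = if (is.null(est)) NA_real_ else est$ci_low,
        ci_high = if (is.null(est)) NA_real_ else est$ci_high,
        p = if (is.null(est)) NA_real_ else est$p, stringsAsFactors = FALSE)
      if (is.null(est)) note("table2", paste0("univariate OR undefined for ",
                                              v, " = ", lv))
    }
  }
  univariate <- do.call(rbind, t2_rows)

  sets <- config$adjustment_sets
  if (is.null(sets)) sets <- list(all = model_vars)
  adjusted <- list()
  for (snm in names(sets)) {
    sv <- intersect(sets[[snm]], model_vars)
    cc <- tryCatch(
      logistic_fit(part2, outcome, sv, level = config$level)$coefficients,
      error = function(e) { note("table2", paste0("adjusted (", snm,
        ", complete-case) not fitted: ", conditionMessage(e))); NULL })
    pooled <- NULL
    if (any(vapply(part2[sv], anyNA, logical(1)))) {
      pooled <- tryCatch({
        imp_cohort <- new_cohort(part2, cohort$events[
          cohort$events$participant_id %in% inc_ids, , drop = FALSE],
          cohort$window, check = FALSE)
        completed <- impute_missing(imp_cohort, labels, m = config$m_imputations,
                                    seed = config$seed + 1L)
        fits <- lapply(completed, function(d)
          logistic_fit(d, outcome, sv, level = config$level)$coefficients)
        pool_rubin(fits, level = config$level)
      }, error = function(e) { note("table2", paste0("adjusted (", snm,
        ", imputed) not fitted: ", conditionMessage(e))); NULL })
    }
    adjusted[[snm]] <- list(complete_case = cc, imputed = pooled)
  }
  table2 <- list(univariate = univariate, adjusted = adjusted)

  # ---- follow-up and incidence
  fu <- build_followups(cohort, labels)
  table3 <- NULL
  if (nrow(fu)) {
    grp <- function(g) fu[fu$label == g, , drop = FALSE]
    mk <- function(d) incidence_rate(sum(d$event), sum(d$person_years),
                                     config$ci_dialect, config$level)
    rate_total <- mk(fu)
    rate_adh <- if (nrow(grp("adherent"))) mk(grp("adherent")) else NULL
    rate_non <- if (nrow(grp("nonadherent"))) mk(grp("nonadherent")) else NULL
    rr <- if (!is.null(rate_adh) && !is.null(rate_non))
      rate_ratio(rate_adh, rate_non, config$level) else NULL
    hr <- tryCatch(
      cox_fit(fu, data.frame(adherence = factor(fu$label,
                                                c("nonadherent", "adherent"))),
              ties = config$ties, level = config$level),
      error = function(e) { note("table3", paste0("Cox fit not run: ",
                                                  conditionMessage(e))); NULL })
    table3 <- list(n = nrow(fu), total = rate_total, adherent = rate_adh,
                   nonadherent = rate_non, rate_ratio = rr, cox = hr)
  } else note("table3", "no participants with >= 2 tests")

  # ---- baseline condom-use table (among the >= 2 test analysis set)
  table4 <- NULL
  if (nrow(fu)) {
    base_condom <- vapply(fu$participant_id, function(id) {
      v <- ev_by[[id]]$condom_use[1]
      if (is.na(v)) "Uncertain" else v
    }, character(1), USE.NAMES = FALSE)
    tab4 <- .label_table(base_condom, fu$label, condom_levels())
    table4 <- list(table = tab4, chi_square = .try_chi(tab4))
  }

  # ---- behavior-change tables
  table5 <- lapply(config$behavior_k, function(k)
    behavior_change_table(cohort, labels, k))
  names(table5) <- paste0("k", config$behavior_k)

  report <- structure(list(
    validation = validation, labels = labels, summary = summary,
    cascade = cascade, table1 = table1, table2 = table2, table3 = table3,
    table4 = table4, table5 = table5, config = config, log = log),
    class = "hivst_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "hivst_report"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  paths <- character()
  w <- function(name) { p <- file.path(out_dir, name); paths <<- c(paths, p); p }

  utils::write.csv(report$labels, w("labels.csv"), row.names = FALSE, na = "")
  utils::write.csv(report$table1, w("table1.csv"), row.names = FALSE, na = "")

  t2 <- report$table2$univariate
  t2$model <- "univariate"
  for (snm in names(report$table2$adjusted)) {
    for (kind in c("complete_case", "imputed")) {
      cf <- report$table2$adjusted[[snm]][[kind]]
      if (is.null(cf)) next
      cf <- cf[c("variable", "level", "or", "ci_low", "ci_high", "p")]
      cf$model <- paste0("adjusted:", snm, ":", kind)
      t2 <- rbind(t2, cf)
    }
  }
  utils::write.csv(t2, w("table2.csv"), row.names = FALSE, na = "")

  rates <- NULL
  if (!is.null(report$table3)) {
    as_rate <- function(r) if (is.null(r)) NULL else
      list(k = r$k, person_years = r$T, rate = r$rate,
           ci_low = r$ci_low, ci_high = r$ci_high, dialect = r$dialect)
    rates <- list(
      n = report$table3$n,
      total = as_rate(report$table3$total),
      adherent = as_rate(report$table3$adherent),
      nonadherent = as_rate(report$table3$nonadherent))
    if (!is.null(report$table3$rate_ratio))
      rates$rate_ratio <- report$table3$rate_ratio[c("ratio", "ci_low", "ci_high")]
    if (!is.null(report$table3$cox)) {
      cf <- report$table3$cox$coefficients
      rates$hazard_ratio <- list(term = cf$term[1], hr = cf$hr[1],
                                 ci_low = cf$ci_low[1], ci_high = cf$ci_high[1],
                                 p = cf$p[1], ties = report$table3$cox$ties)
    }
  }
  jsonlite::write_json(rates, w("rates.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  if (!is.null(report$table4)) {
    t4 <- as.data.frame(report$table4$table)
    t4 <- cbind(condom_use = rownames(report$table4$table), t4)
    if (!is.null(report$table4$chi_square)) {
      t4$chi_square <- report$table4$chi_square$statistic
      t4$df <- report$table4$chi_square$df
      t4$p <- report$table4$chi_square$p
    }
    utils::write.csv(t4, w("table4.csv"), row.names = FALSE, na = "")
  }

  t5_rows <- list()
  for (nm in names(report$table5)) {
    b <- report$table5[[nm]]
    for (i in seq_len(nrow(b$table)))
      t5_rows[[length(t5_rows) + 1]] <- data.frame(
        comparison = nm, class = rownames(b$table)[i],
        adherent = b$table[i, 1], nonadherent = b$table[i, 2],
        chi_square = if (is.null(b$chi_square)) NA_real_ else b$chi_square$statistic,
        df = if (is.null(b$chi_square)) NA_integer_ else b$chi_square$df,
        p = if (is.null(b$chi_square)) NA_real_ else b$chi_square$p,
        stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, t5_rows), w("table5.csv"),
                   row.names = FALSE, na = "")

  jsonlite::write_json(report$cascade, w("cascade.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  lines <- c(
    jsonlite::toJSON(list(stage = "config",
                          config = unclass(report$config)), auto_unbox = TRUE,
                     null = "null", digits = NA),
    jsonlite::toJSON(list(stage = "cascade", counts = report$cascade),
                     auto_unbox = TRUE, digits = NA),
    vapply(report$log, function(x)
      as.character(jsonlite::toJSON(x, auto_unbox = TRUE)), character(1)))
  writeLines(lines, w("run.log.jsonl"))
  invisible(paths)
}

#' @export
print.hivst_report <- function(x, ...) {
  cat("<hivst report>\n")
  print(x$summary)
  if (!is.null(x$table3)) {
    cat("  incidence (", x$table3$total$dialect, " dialect):\n", sep = "")
    cat("    total:       "); print(x$table3$total)
    if (!is.null(x$table3$adherent)) { cat("    adherent:    "); print(x$table3$adherent) }
    if (!is.null(x$table3$nonadherent)) { cat("    nonadherent: "); print(x$table3$nonadherent) }
  }
  invisible(x)
}
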