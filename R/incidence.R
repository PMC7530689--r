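#' Midpoint seroconversion date
#'
#' The seroconversion date is the midway point between the last negative and
#' first positive test dates; on an odd day span the half day is floored so
#' the result stays a calendar date.
#'
#' @param last_negative,first_positive Dates, `last_negative < first_positive`.
#' @return A Date.
#' @export
#' @examples
#' seroconversion_date(as.Date("2017-10-01"), as.Date("2017-12-01"))
seroconversion_date <- function(last_negative, first_positive) {
  last_negative <- as.Date(last_negative)
  first_positive <- as.Date(first_positive)
  if (any(last_negative >= first_positive))
    stop("last negative test must precede the first positive test")
  last_negative + floor(as.integer(first_positive - last_negative) / 2)
}

#' Build follow-up records for incidence analysis
#'
#' Restricts to included participants with at least two tests. Entry is the
#' first test date. For seroconverters (a positive test preceded by a
#' negative one) the exit is the midpoint seroconversion date and the event
#' flag is set; otherwise the exit is the last test date (censoring at the
#' last observation, not at the study endpoint).
#'
#' @param cohort a `hivst_cohort`.
#' @param labels an [adherence_labels()] result for the cohort.
#' @return data.frame: `participant_id`, `label`, `entry`, `exit`, `event`
#'   (logical), `person_years` (`(exit - entry) / 365.25`).
#' @export
build_followups <- function(cohort, labels) {
  keep <- labels$eligibility == "included" & labels$n_tests >= 2
  ids <- labels$participant_id[keep]
  ev_by <- split(cohort$events, cohort$events$participant_id)
  rows <- lapply(ids, function(id) {
    ev <- ev_by[[id]]
    entry <- ev$date[1]
    pos <- which(ev$result == "positive")
    if (length(pos)) {
      exit <- seroconversion_date(ev$date[pos[1] - 1], ev$date[pos[1]])
      event <- TRUE
    } else {
      exit <- ev$date[nrow(ev)]
      event <- FALSE
    }
    data.frame(participant_id = id, entry = entry, exit = exit,
               event = event, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), entry = as.Date(character()),
               exit = as.Date(character()), event = logical())
  out$label <- labels$label[match(out$participant_id, labels$participant_id)]
  out$person_years <- as.integer(out$exit - out$entry) / 365.25
  out[c("participant_id", "label", "entry", "exit", "event", "person_years")]
}

#' Incidence rate per 100 person-years with exact Poisson CI
#'
#' `rate = 100 k / T`. Two chi-square quantile dialects for the exact
#' interval on the event scale (then divided by `T` and scaled by 100):
#'
#' * `garwood` — the textbook exact interval,
#'   lower `= chi2(alpha/2, 2k) / 2`, upper `= chi2(1 - alpha/2, 2k + 2) / 2`
#'   (lower bound 0 when `k = 0`).
#' * `paper` — the same quantiles with the degrees of freedom swapped
#'   (lower uses `2k + 2`, upper uses `2k`), the dialect that reproduces the
#'   source study's printed intervals. It is narrower than Garwood on both
#'   sides; see the methods vignette.
#'
#' @param k event count, `>= 0`.
#' @param T person-years, `> 0`.
#' @param dialect `"paper"` or `"garwood"`.
#' @param level confidence level (default 0.95).
#' @return List of class `rate_estimate`: `k`, `T`, `rate`, `ci_low`,
#'   `ci_high` (per 100 person-years), `dialect`, `level`.
#' @export
incidence_rate <- function(k, T, dialect = c("paper", "garwood"), level = 0.95) {
  dialect <- match.arg(dialect)
  if (T <= 0) stop("person-years must be positive")
  if (k < 0 || k != round(k)) stop("event count must be a nonnegative integer")
  alpha <- 1 - level
  if (dialect == "garwood") {
    lo <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
    hi <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  } else {
    lo <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k + 2) / 2
    hi <- stats::qchisq(1 - alpha / 2, 2 * k) / 2
  }
  structure(list(k = as.integer(k), T = T, rate = 100 * k / T,
                 ci_low = 100 * lo / T, ci_high = 100 * hi / T,
                 dialect = dialect, level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.2f per 100 PY (%.2f-%.2f) [k=%d, T=%.2f, %s]\n",
              x$rate, x$ci_low, x$ci_high, x$k, x$T, x$dialect))
  invisible(x)
}

#' Rate ratio with log-scale Wald CI
#'
#' `ratio = a$rate / b$rate`; CI
#' `exp(log ratio +- z sqrt(1/k_a + 1/k_b))`. With zero events in either
#' group the ratio or its CI is unbounded: the bounds degenerate to
#' 0 / `Inf` and `unbounded` is flagged rather than erroring.
#'
#' @param a,b [incidence_rate()] results (numerator, denominator).
#' @param level confidence level.
#' @return List of class `rate_ratio`: `ratio`, `ci_low`, `ci_high`,
#'   `unbounded`.
#' @export
rate_ratio <- function(a, b, level = 0.95) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (a$k == 0 || b$k == 0) {
    ratio <- if (b$rate > 0) a$rate / b$rate else NaN
    return(structure(list(ratio = ratio, ci_low = 0, ci_high = Inf,
                          unbounded = TRUE), class = "rate_ratio"))
  }
  ratio <- a$rate / b$rate
  se <- sqrt(1 / a$k + 1 / b$k)
  structure(list(ratio = ratio,
                 ci_low = exp(log(ratio) - z * se),
                 ci_high = exp(log(ratio) + z * se),
                 unbounded = FALSE), class = "rate_ratio")
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (via the `survival` engine) on the
#' follow-up records, with Breslow (default) or Efron tie handling, and
#' reports hazard ratios with Wald confidence intervals. Errors on
#' non-convergence and on apparent monotone-likelihood separation (a
#' coefficient running away) instead of emitting unusable estimates.
#'
#' @param followups a [build_followups()] result (or any data.frame with
#'   `person_years` and logical `event`).
#' @param design data.frame of covariates, one row per follow-up row;
#'   character columns are converted to factors with their first declared
#'   dictionary level (or first observed value) as reference.
#' @param ties `"breslow"` or `"efron"`.
#' @param level confidence level for the Wald intervals.
#' @return List of class `hazard_fit`: `coefficients` data.frame (`term`,
#'   `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p`), `ties`, `converged`,
#'   `iterations`, `loglik`, `score_test` (statistic, df, p at beta = 0).
#' @export
cox_fit <- function(followups, design, ties = c("breslow", "efron"),
                    level = 0.95) {
  ties <- match.arg(ties)
  if (!any(followups$event)) stop("cox_fit requires at least one event")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  dict <- covariate_dictionary()
  for (v in names(design)) {
    if (is.character(design[[v]])) {
      lev <- if (v %in% names(dict)) intersect(dict[[v]], unique(design[[v]]))
             else unique(design[[v]])
      design[[v]] <- factor(design[[v]], levels = lev)
    }
    vals <- design[[v]][!is.na(design[[v]])]
    if (length(unique(vals)) < 2)
      stop("covariate ", v, " is constant; cannot be fitted")
  }
  dat <- cbind(data.frame(.time = followups$person_years,
                          .event = as.integer(followups$event)), design)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(names(design), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        stop("monotone likelihood (separation) in covariate(s): ",
             paste(names(design), collapse = ", "), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("monotone likelihood (separation); a coefficient diverged")
  z <- stats::qnorm(1 - (1 - level) / 2)
  sct <- fit$score
  structure(list(
    coefficients = data.frame(
      term = names(beta), beta = unname(beta), se = unname(se),
      hr = exp(unname(beta)),
      ci_low = exp(unname(beta) - z * unname(se)),
      ci_high = exp(unname(beta) + z * unname(se)),
      p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
      stringsAsFactors = FALSE),
    ties = ties, converged = TRUE, iterations = fit$iter,
    loglik = fit$loglik,
    score_test = list(statistic = unname(sct), df = length(beta),
                      p = stats::pchisq(unname(sct), length(beta),
                                        lower.tail = FALSE))),
    class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("<Cox fit> ties =", x$ties, "\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-28s HR %.2f (%.2f-%.2f) p=%.3g\n", cf$term[i],
                cf$hr[i], cf$ci_low[i], cf$ci_high[i], cf$p[i]))
  invisible(x)
}
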