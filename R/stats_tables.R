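#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `E = row x col / N`, `df = (r - 1)(c - 1)`, upper-tail p-value. No
#' continuity correction by default (the convention the reproduced tables
#' follow); set `correct = TRUE` for the Yates-corrected 2x2 statistic.
#'
#' @param table numeric matrix of nonnegative observed counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return List of class `chi_square_result`: `statistic`, `df`, `p`,
#'   `expected`.
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("counts must be nonnegative")
  if (nrow(O) < 2 || ncol(O) < 2) stop("table must be at least 2x2")
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0))
    stop("degenerate table: zero margin in row ", which(rs == 0)[1])
  if (any(cs == 0))
    stop("degenerate table: zero margin in column ", which(cs == 0)[1])
  E <- outer(rs, cs) / N
  dev <- abs(O - E)
  if (correct) {
    if (!all(dim(O) == c(2, 2))) stop("Yates correction applies to 2x2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E), class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.3g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Wald odds ratio from a 2x2 table
#'
#' `OR = (a d) / (b c)` where `a`/`b` are the exposed group's outcome and
#' non-outcome counts and `c`/`d` the reference group's. The log-scale
#' standard error is `sqrt(1/a + 1/b + 1/c + 1/d)`; Wald CI and two-sided p
#' follow. A zero cell errors unless `haldane = TRUE`, which adds 0.5 to
#' every cell (Haldane-Anscombe) and flags the result.
#'
#' @param a,b exposed group: outcome, non-outcome counts.
#' @param c,d reference group: outcome, non-outcome counts.
#' @param level confidence level.
#' @param haldane apply the +0.5 correction when a cell is zero.
#' @return List of class `effect_estimate`: `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `corrected`.
#' @export
odds_ratio_wald <- function(a, b, c, d, level = 0.95, haldane = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be nonnegative")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell in 2x2 table; set haldane = TRUE for the +0.5 correction")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  beta <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(beta = beta, se = se, or = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 corrected = corrected), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), p = %.3g%s\n", x$or, x$ci_low, x$ci_high,
              x$p, if (isTRUE(x$corrected)) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' Logistic regression with dummy-coded categorical covariates
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' the `stats` GLM engine). Character covariates are dummy coded against
#' their first dictionary level (or first observed level); odds ratios are
#' `exp(beta)` with Wald intervals. Errors on non-convergence and on
#' apparent separation instead of returning runaway estimates. Rows with a
#' missing covariate are dropped (complete-case); combine with
#' [impute_missing()] and [pool_rubin()] for imputation-based fits.
#'
#' @param data data.frame holding the covariates.
#' @param outcome logical or 0/1 vector, one element per row of `data`.
#' @param covariates character vector of column names to include.
#' @param level confidence level.
#' @return List of class `logistic_fit`: `coefficients` data.frame
#'   (`variable`, `level`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`;
#'   reference levels carry `beta = 0`, `or = 1`, `NA` elsewhere),
#'   `n`, `converged`.
#' @export
logistic_fit <- function(data, outcome, covariates, level = 0.95) {
  stopifnot(length(outcome) == nrow(data))
  outcome <- as.integer(as.logical(outcome))
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop("outcome must contain both classes")
  dict <- covariate_dictionary()
  dd <- data[, covariates, drop = FALSE]
  for (v in covariates) {
    if (is.factor(dd[[v]])) {
      dd[[v]] <- droplevels(dd[[v]])
    } else if (is.character(dd[[v]])) {
      vals <- dd[[v]]
      lev <- if (v %in% names(dict)) intersect(dict[[v]], unique(vals[!is.na(vals)]))
             else unique(vals[!is.na(vals)])
      dd[[v]] <- factor(vals, levels = lev)
    }
  }
  keep <- stats::complete.cases(dd) & !is.na(outcome)
  dd <- dd[keep, , drop = FALSE]
  y <- outcome[keep]
  if (nrow(dd) <= sum(vapply(dd, function(x) max(1L, nlevels(x) - 1L), integer(1))))
    stop("fewer observations than parameters")
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, dd), family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      # extreme fitted values are diagnosed by the separation check below
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("logistic fit did not converge after ", fit$iter,
                           " IRLS iterations")
  cf0 <- summary(fit)$coefficients
  if (nrow(cf0) > 1 && any(abs(cf0[-1, 1]) > 15 | cf0[-1, 2] > 100)) {
    bad <- rownames(cf0)[-1][abs(cf0[-1, 1]) > 15 | cf0[-1, 2] > 100][1]
    stop("apparent separation in covariate term ", bad)
  }
  # polish to the exact MLE: Newton steps until max |score| < 1e-8, so the
  # information-based standard errors are evaluated at the maximizer itself
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  for (it in 1:25) {
    p <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X, X * (p * (1 - p)))
    if (max(abs(score)) < 1e-8) break
    beta <- beta + solve(info, score)
  }
  if (max(abs(score)) >= 1e-8)
    stop("logistic fit did not converge: max |score| = ",
         format(max(abs(score))))
  se <- sqrt(diag(solve(info)))
  names(se) <- names(beta)
  cf <- cbind(beta, se)
  rownames(cf) <- names(beta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (v in covariates) {
    levs <- levels(dd[[v]])
    if (is.null(levs)) levs <- v
    for (j in seq_along(levs)) {
      term <- paste0(v, levs[j])
      if (j == 1 && length(levs) > 1) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = levs[j], beta = 0, se = NA_real_, or = 1,
          ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
      } else if (term %in% rownames(cf)) {
        b <- beta[[term]]; s <- se[[term]]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = levs[j], beta = b, se = s, or = exp(b),
          ci_low = exp(b - z * s), ci_high = exp(b + z * s),
          p = 2 * stats::pnorm(-abs(b / s)), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(coefficients = do.call(rbind, rows), n = nrow(dd),
                 converged = TRUE), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic fit> n =", x$n, "\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    if (cf$or[i] == 1 && is.na(cf$p[i]))
      cat(sprintf("  %s = %-28s 1.00 (reference)\n", cf$variable[i], cf$level[i]))
    else
      cat(sprintf("  %s = %-28s OR %.2f (%.2f-%.2f) p=%.3g\n", cf$variable[i],
                  cf$level[i], cf$or[i], cf$ci_low[i], cf$ci_high[i], cf$p[i]))
  }
  invisible(x)
}

#' Multiple imputation of missing categorical covariates
#'
#' For each of `m` imputations, every missing value of an imputable
#' variable is drawn from the variable's observed empirical distribution
#' conditional on the participant's adherence label (two strata; excluded
#' participants, which carry no label, draw from the overall distribution).
#' A simple stratified hot-deck: it preserves the covariate-outcome
#' association the sensitivity analyses care about without a chained-
#' equations model; see the methods vignette.
#'
#' @param cohort a `hivst_cohort`.
#' @param labels an [adherence_labels()] result.
#' @param vars variables to impute (default: the three with configured
#'   missingness — age group, marital status, age of first anal sex).
#' @param m number of imputations, `>= 2`.
#' @param seed optional integer seed.
#' @return List of `m` completed participant data.frames.
#' @export
impute_missing <- function(cohort, labels,
                           vars = c("age_group", "marital_status",
                                    "first_anal_sex_age_group"),
                           m = 10, seed = NULL) {
  stopifnot(m >= 2)
  if (!is.null(seed)) set.seed(seed)
  part <- cohort$participants
  vars <- intersect(vars, names(part))
  lab <- labels$label[match(part$participant_id, labels$participant_id)]
  for (v in vars)
    if (all(is.na(part[[v]]))) stop("variable ", v, " is 100% missing")
  other <- setdiff(names(part)[colSums(is.na(part)) > 0],
                   c(vars, "participant_id"))
  if (length(other))
    stop("missingness outside the declared imputable variables: ",
         paste(other, collapse = ", "))
  lapply(seq_len(m), function(i) {
    out <- part
    for (v in vars) {
      miss <- which(is.na(out[[v]]))
      for (j in miss) {
        stratum <- lab[j]
        pool <- if (!is.na(stratum)) out[[v]][lab == stratum & !is.na(out[[v]])]
                else out[[v]][!is.na(out[[v]])]
        if (!length(pool)) pool <- out[[v]][!is.na(out[[v]])]
        out[[v]][j] <- sample(pool, 1)
      }
    }
    out
  })
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Given aligned per-imputation coefficient tables (e.g. the `coefficients`
#' element of [logistic_fit()] run on each completed dataset), pools each
#' parameter: `Qbar = mean(Q_i)`, within-variance `W = mean(U_i)`,
#' between-variance `B = var(Q_i)`, total `T = W + (1 + 1/m) B`, degrees of
#' freedom `(m - 1)(1 + W / ((1 + 1/m) B))^2`, p from the t reference.
#'
#' @param estimates list of data.frames with columns `variable`, `level`,
#'   `beta`, `se` in identical order.
#' @param level confidence level.
#' @return data.frame: `variable`, `level`, `beta` (pooled), `se` (sqrt of
#'   total variance), `or`, `ci_low`, `ci_high`, `p`, `df`, `between`,
#'   `within`. Reference rows (se `NA`) pass through with `or = 1`.
#' @export
pool_rubin <- function(estimates, level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 2)
  base <- estimates[[1]][c("variable", "level")]
  for (e in estimates[-1])
    if (!identical(e[c("variable", "level")], base))
      stop("per-imputation estimates are misaligned")
  Q <- sapply(estimates, function(e) e$beta)
  U <- sapply(estimates, function(e) e$se^2)
  if (is.null(dim(Q))) { Q <- matrix(Q, nrow = 1); U <- matrix(U, nrow = 1) }
  out <- base
  Qbar <- rowMeans(Q)
  W <- rowMeans(U)
  B <- apply(Q, 1, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  ref <- is.na(W)          # reference levels: no se
  se <- sqrt(Tv)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out$beta <- Qbar
  out$se <- se
  out$or <- exp(Qbar)
  out$ci_low <- ifelse(ref, NA, exp(Qbar - tq * se))
  out$ci_high <- ifelse(ref, NA, exp(Qbar + tq * se))
  out$p <- ifelse(ref, NA, 2 * stats::pt(-abs(Qbar / se), df))
  out$df <- df
  out$between <- B
  out$within <- W
  out
}
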