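test_that("chi-square reproduces the published group-comparison statistics", {
  sero <- pearson_chi_square(rbind(c(123, 1172), c(8, 12)))
  expect_equal(round(sero$statistic, 3), 20.429)
  expect_equal(sero$df, 1)
  expect_lt(sero$p, 0.001)

  hivst <- pearson_chi_square(rbind(c(55, 937), c(26, 129), c(50, 118)))
  expect_equal(round(hivst$statistic, 3), 103.031)
  expect_equal(hivst$df, 2)

  condom <- pearson_chi_square(rbind(c(4, 6), c(30, 132), c(56, 249), c(41, 162)))
  expect_equal(round(condom$statistic, 3), 3.096)
  expect_equal(condom$df, 3)
})

test_that("chi-square basics: O = E gives 0; zero margins error; Yates flag", {
  expect_equal(pearson_chi_square(matrix(5, 2, 2))$statistic, 0)
  expect_error(pearson_chi_square(rbind(c(0, 0), c(3, 4))), "zero margin in row 1")
  expect_error(pearson_chi_square(rbind(c(3, 0), c(4, 0))), "zero margin in column 2")
  t22 <- rbind(c(12, 5), c(7, 20))
  expect_lt(pearson_chi_square(t22, correct = TRUE)$statistic,
            pearson_chi_square(t22)$statistic)
})

test_that("chi-square matches the 2x2 closed form and is permutation-invariant", {
  set.seed(14)
  for (i in 1:200) {
    O <- matrix(sample(1:60, 4, TRUE), 2, 2)
    closed <- sum(O) * (O[1, 1] * O[2, 2] - O[1, 2] * O[2, 1])^2 /
      prod(rowSums(O)) / prod(colSums(O))
    expect_equal(pearson_chi_square(O)$statistic, closed, tolerance = 1e-10)
    expect_equal(pearson_chi_square(t(O))$statistic,
                 pearson_chi_square(O)$statistic)
  }
  O <- matrix(sample(1:40, 12), 3, 4)
  base <- pearson_chi_square(O)$statistic
  expect_equal(pearson_chi_square(O[c(3, 1, 2), c(2, 4, 1, 3)])$statistic, base)
  # cross-check against the stock implementation on one table
  expect_equal(base, unname(stats::chisq.test(O, correct = FALSE)$statistic),
               tolerance = 1e-10)
})

test_that("chi-square type-I error is nominal on null 2x2 tables", {
  set.seed(15)
  reps <- 10000
  n <- 120                    # per group; all margins >= 50 w.h.p.
  x1 <- stats::rbinom(reps, n, 0.5)
  x2 <- stats::rbinom(reps, n, 0.5)
  rej <- vapply(seq_len(reps), function(i) {
    O <- rbind(c(x1[i], n - x1[i]), c(x2[i], n - x2[i]))
    if (any(rowSums(O) == 0) || any(colSums(O) == 0)) return(NA)
    pearson_chi_square(O)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej, na.rm = TRUE), 0.04)
  expect_lte(mean(rej, na.rm = TRUE), 0.06)
})

test_that("Wald odds ratios reproduce the published effect estimates", {
  e3 <- odds_ratio_wald(26, 129, 55, 937)
  expect_equal(round(e3$or, 2), 3.43)
  expect_equal(round(e3$ci_low, 2), 2.08)
  expect_equal(round(e3$ci_high, 2), 5.67)
  e4 <- odds_ratio_wald(50, 118, 55, 937)
  expect_equal(round(c(e4$or, e4$ci_low, e4$ci_high), 2), c(7.22, 4.70, 11.08))
  em <- odds_ratio_wald(111, 927, 15, 207)
  expect_equal(round(em$or, 2), 1.65)
})

test_that("odds ratio edge cases: unit table, zero cells, Haldane flag", {
  u <- odds_ratio_wald(1, 1, 1, 1)
  expect_equal(u$or, 1)
  expect_equal(u$p, 1)
  expect_equal(u$ci_low * u$ci_high, 1, tolerance = 1e-12)  # symmetric CI
  expect_error(odds_ratio_wald(0, 5, 3, 7), "zero cell")
  h <- odds_ratio_wald(0, 5, 3, 7, haldane = TRUE)
  expect_true(h$corrected)
  expect_equal(h$or, (0.5 * 7.5) / (5.5 * 3.5))
})

test_that("univariate logistic fit equals closed-form odds ratios", {
  # the published 3-level test-count factor
  counts <- data.frame(level = c("2 times or below", "3 times", "4 times or above"),
                       yes = c(55, 26, 50), no = c(937, 129, 118))
  dat <- data.frame(n_hivsts = rep(counts$level, counts$yes + counts$no))
  out <- rep(rep(c(TRUE, FALSE), 3), c(rbind(counts$yes, counts$no)))
  fit <- logistic_fit(dat, out, "n_hivsts")
  cf <- fit$coefficients
  e3 <- odds_ratio_wald(26, 129, 55, 937)
  e4 <- odds_ratio_wald(50, 118, 55, 937)
  expect_equal(cf$beta[cf$level == "3 times"], e3$beta, tolerance = 1e-8)
  expect_equal(cf$se[cf$level == "3 times"], e3$se, tolerance = 1e-8)
  expect_equal(cf$beta[cf$level == "4 times or above"], e4$beta, tolerance = 1e-8)
  expect_equal(cf$or[cf$level == "2 times or below"], 1)

  # independence: identical class rates give beta = 0
  dat2 <- data.frame(g = rep(c("a", "b"), each = 100))
  out2 <- rep(rep(c(TRUE, FALSE), 2), c(30, 70, 30, 70))
  fit2 <- logistic_fit(dat2, out2, "g")
  expect_equal(fit2$coefficients$beta[2], 0, tolerance = 1e-10)
})

test_that("logistic fit error contracts", {
  dat <- data.frame(g = c("a", "a", "b", "b"))
  expect_error(logistic_fit(dat, c(TRUE, TRUE, TRUE, TRUE), "g"), "both classes")
  # perfectly separated covariate
  dat2 <- data.frame(g = rep(c("a", "b"), each = 30))
  out2 <- rep(c(TRUE, FALSE), each = 30)
  expect_error(logistic_fit(dat2, out2, "g"), "separation")
})

test_that("imputation draws from the stratum-conditional observed distribution", {
  win <- as.Date(c("2017-07-01", "2018-06-30"))
  d0 <- win[1]
  # 10 adherent-stratum donors with marital distribution (2, 7, 1)/10 and one
  # missing value in the same stratum
  n <- 11
  ids <- sprintf("A%02d", 1:n)
  p <- data.frame(participant_id = ids,
                  marital_status = c(rep("Married", 2), rep("Unmarried", 7),
                                     "Divorced or widowed", NA))
  ev <- do.call(rbind, lapply(ids, function(id)
    events_df(d0 + c(0, 90, 180, 270, 350), rep("negative", 5), id = id)))
  co <- new_cohort(p, ev, win)
  labels <- adherence_labels(co)
  expect_true(all(labels$label == "adherent"))

  m <- 6000
  imp <- impute_missing(co, labels, vars = "marital_status", m = m, seed = 9)
  draws <- vapply(imp, function(d) d$marital_status[n], character(1))
  freq <- table(factor(draws, levels = covariate_dictionary()$marital_status)) / m
  for (i in seq_along(freq)) {
    p0 <- c(0.2, 0.7, 0.1)[i]
    expect_lt(abs(freq[[i]] - p0), 3 * sqrt(p0 * (1 - p0) / m))
  }

  # determinism and the no-missing identity
  imp2 <- impute_missing(co, labels, vars = "marital_status", m = 5, seed = 4)
  imp3 <- impute_missing(co, labels, vars = "marital_status", m = 5, seed = 4)
  expect_identical(imp2, imp3)
  full <- co; full$participants$marital_status[n] <- "Married"
  imp4 <- impute_missing(full, labels, vars = "marital_status", m = 3, seed = 1)
  expect_true(all(vapply(imp4, identical, logical(1), full$participants)))

  co_allmiss <- co; co_allmiss$participants$marital_status <- NA_character_
  expect_error(impute_missing(co_allmiss, labels, vars = "marital_status", m = 2),
               "100% missing")
})

test_that("Rubin pooling follows the stated combining rules", {
  est <- function(b) data.frame(variable = "v", level = "x", beta = b,
                                se = sqrt(0.1), stringsAsFactors = FALSE)
  pooled <- pool_rubin(list(est(1), est(2)))
  expect_equal(pooled$beta, 1.5)
  expect_equal(pooled$between, 0.5)
  expect_equal(pooled$within, 0.1)
  expect_equal(pooled$se^2, 0.1 + 1.5 * 0.5)   # W + (1 + 1/m) B
  expect_equal(pooled$df, (2 - 1) * (1 + 0.1 / (1.5 * 0.5))^2)

  # identical estimate sets: B = 0, pooled equals the common value
  same <- pool_rubin(list(est(0.7), est(0.7), est(0.7)))
  expect_equal(same$beta, 0.7)
  expect_equal(same$between, 0)
  expect_equal(same$se^2, 0.1)
  expect_equal(same$df, Inf)

  bad <- est(1); bad$level <- "y"
  expect_error(pool_rubin(list(est(1), bad)), "misaligned")
})
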