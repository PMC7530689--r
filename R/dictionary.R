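#' Baseline covariate dictionary
#'
#' The declared categorical variables of the participant table and their
#' levels. The first level of each variable is the reference level used by
#' the effect-estimation helpers ([logistic_fit()], [odds_ratio_wald()]).
#' A CSV rendering of the same dictionary ships under
#' `inst/extdata/data_dictionary.csv`.
#'
#' @return Named list; one character vector of levels per covariate.
#' @export
#' @examples
#' names(covariate_dictionary())
covariate_dictionary <- function() {
  list(
    age_group                = c("<=25", "26-40", ">=41"),
    marital_status           = c("Married", "Unmarried", "Divorced or widowed"),
    education                = c("Junior high school or below", "High school",
                                 "University/college or above"),
    first_anal_sex_age_group = c("<=18", "19-25", "26-40", ">=41"),
    sex_role                 = c("Insertive only", "Receptive only", "Both"),
    partner_venue            = c("Offline venues", "Internet/software/app"),
    n_regular_partners       = c("0", "1", "2", "3 or above"),
    n_casual_partners        = c("0", "1", "2", "3 or above"),
    sex_with_msw             = c("No", "Yes"),
    sex_with_women           = c("No", "Yes"),
    drug_use                 = c("No", "Yes"),
    other_stds               = c("No", "Yes")
  )
}

#' Default covariate marginal distributions
#'
#' Category probabilities for the synthetic cohort generator, taken from the
#' marginal composition of the source study cohort (N = 1315). Each element
#' is a probability vector aligned with [covariate_dictionary()] levels.
#'
#' @return Named list of probability vectors.
#' @export
default_covariate_marginals <- function() {
  counts <- list(
    age_group                = c(362, 525, 428),
    marital_status           = c(222, 1038, 55),
    education                = c(188, 284, 843),
    first_anal_sex_age_group = c(373, 689, 203, 50),
    sex_role                 = c(475, 322, 518),
    partner_venue            = c(269, 1046),
    n_regular_partners       = c(543, 514, 174, 84),
    n_casual_partners        = c(735, 295, 165, 120),
    sex_with_msw             = c(1256, 59),
    sex_with_women           = c(1109, 206),
    drug_use                 = c(1004, 311),
    other_stds               = c(1180, 135)
  )
  lapply(counts, function(x) x / sum(x))
}

#' Condom-use response categories
#'
#' The four questionnaire categories, ordered from least to most protective
#' with "Uncertain" last. Missing responses are treated as "Uncertain" by the
#' behavior-change classifier.
#'
#' @return Character vector of length 4.
#' @export
condom_levels <- function() c("Never", "Ever", "Consistent", "Uncertain")

# internal: result enum
.results <- c("negative", "positive")
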