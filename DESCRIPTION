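Package: hivstadhere
Title: Adherence Classification and Incidence Analysis for Longitudinal
    HIV Self-Testing Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns longitudinal HIV self-testing (HIVST) event logs into
    adherence classifications and epidemiological summaries. Implements the
    100-day inter-test adherence criteria with a seroconverter waiver,
    adhering-test counting, midpoint seroconversion dating, person-time
    incidence rates with two exact Poisson confidence-interval dialects,
    contingency-table statistics and Wald odds ratios, logistic and Cox
    proportional-hazards effect estimation, multiple imputation of
    categorical covariates with Rubin pooling, and condom-use behavior
    transition classification. A synthetic cohort generator with known
    ground truth makes the whole pipeline testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
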