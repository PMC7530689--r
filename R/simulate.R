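#' Default condom-use transition matrix
#'
#' Row-stochastic 4x4 matrix over (Never, Ever, Consistent, Uncertain) used
#' by the synthetic generator to evolve the condom-use response from one
#' test questionnaire to the next. No published transition matrix exists;
#' this default is chosen so that the baseline mix drifts toward consistent
#' use, giving the "Better/Worse/Other" mix observed in real follow-up data
#' the classifier must handle. See the methods vignette.
#'
#' @return 4x4 numeric matrix, rows summing to 1.
#' @export
default_condom_transition <- function() {
  m <- rbind(
    Never      = c(0.20, 0.40, 0.30, 0.10),
    Ever       = c(0.05, 0.45, 0.35, 0.15),
    Consistent = c(0.02, 0.13, 0.65, 0.20),
    Uncertain  = c(0.05, 0.20, 0.35, 0.40))
  colnames(m) <- condom_levels()
  m
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the generator. Defaults emulate the study design
#' the analysis assumes: a one-year window, ~5% of registrants positive at
#' their first test, a 10% adherent archetype testing every 30-100 days,
#' a nonadherent archetype mixing short gaps (35%) with long 101-330 day
#' gaps (65%), archetype-specific constant seroconversion hazards of 0.171
#' and 0.048 per person-year, baseline covariates drawn from the study
#' marginals, a Markov chain for condom-use responses, and <10% missingness
#' in age, marital status and age of first anal sex.
#'
#' @param n_participants cohort size.
#' @param window length-2 Date vector (start, endpoint).
#' @param p_baseline_positive probability the first test is positive (the
#'   participant then stops testing; exercises the baseline-positive
#'   exclusion branch).
#' @param p_adherent_archetype probability of the adherent testing archetype.
#' @param adherent_interval integer day range (min, max) of adherent
#'   inter-test gaps (discrete uniform).
#' @param nonadherent_short,nonadherent_long day ranges of the nonadherent
#'   gap mixture; `nonadherent_p_short` is the short-component weight.
#' @param stop_probability_per_test probability, after each test, that the
#'   participant takes no further test.
#' @param hazard_adherent,hazard_nonadherent seroconversion hazards, events
#'   per person-year, by archetype (not by downstream label).
#' @param covariate_marginals per-variable category probabilities; default
#'   [default_covariate_marginals()].
#' @param archetype_tilt named numeric; per covariate, a log-odds increment
#'   applied (per level step) to adherent-archetype participants, creating a
#'   known covariate-archetype association for recovery tests. Default: no
#'   tilt (covariates independent of archetype).
#' @param condom_transition 4x4 row-stochastic matrix over
#'   [condom_levels()].
#' @param condom_initial initial condom-category probabilities; default =
#'   the study's baseline mix (10, 162, 305, 203)/680.
#' @param missingness named per-variable missing probability.
#' @param seed integer; `simulate_cohort` seeds the RNG with it, making the
#'   output a pure function of the config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 1500,
                       window = as.Date(c("2017-07-01", "2018-06-30")),
                       p_baseline_positive = 144 / 2702,
                       p_adherent_archetype = 0.10,
                       adherent_interval = c(30L, 100L),
                       nonadherent_short = c(30L, 100L),
                       nonadherent_long = c(101L, 330L),
                       nonadherent_p_short = 0.35,
                       stop_probability_per_test = 0.30,
                       hazard_adherent = 0.171,
                       hazard_nonadherent = 0.048,
                       covariate_marginals = default_covariate_marginals(),
                       archetype_tilt = NULL,
                       condom_transition = default_condom_transition(),
                       condom_initial = c(10, 162, 305, 203) / 680,
                       missingness = c(age_group = 0.05, marital_status = 0.05,
                                       first_anal_sex_age_group = 0.05),
                       seed = NULL) {
  window <- as.Date(window)
  probs <- c(p_baseline_positive, p_adherent_archetype,
             nonadherent_p_short, stop_probability_per_test,
             condom_initial, unlist(missingness))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (hazard_adherent < 0 || hazard_nonadherent < 0) stop("hazards must be >= 0")
  if (n_participants < 0 || n_participants != round(n_participants))
    stop("n_participants must be a nonnegative integer")
  if (window[1] >= window[2]) stop("window start must precede the endpoint")
  for (r in list(adherent_interval, nonadherent_short, nonadherent_long))
    if (length(r) != 2 || r[1] < 1 || r[1] > r[2])
      stop("interval ranges must be (min, max) with 1 <= min <= max")
  condom_transition <- as.matrix(condom_transition)
  if (!all(dim(condom_transition) == c(4, 4)) ||
      any(condom_transition < 0) ||
      any(abs(rowSums(condom_transition) - 1) > 1e-12))
    stop("condom_transition must be a 4x4 row-stochastic matrix")
  if (abs(sum(condom_initial) - 1) > 1e-12 || length(condom_initial) != 4)
    stop("condom_initial must be a length-4 probability vector")
  dict <- covariate_dictionary()
  if (!all(names(covariate_marginals) %in% names(dict)))
    stop("covariate_marginals names outside the data dictionary")
  for (v in names(covariate_marginals)) {
    p <- covariate_marginals[[v]]
    if (length(p) != length(dict[[v]]) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("invalid marginal for ", v)
  }
  if (!is.null(archetype_tilt) &&
      !all(names(archetype_tilt) %in% names(dict)))
    stop("archetype_tilt names outside the data dictionary")
  if (!all(names(missingness) %in% names(dict)))
    stop("missingness names outside the data dictionary")

  structure(list(
    n_participants = as.integer(n_participants), window = window,
    p_baseline_positive = p_baseline_positive,
    p_adherent_archetype = p_adherent_archetype,
    adherent_interval = as.integer(adherent_interval),
    nonadherent_short = as.integer(nonadherent_short),
    nonadherent_long = as.integer(nonadherent_long),
    nonadherent_p_short = nonadherent_p_short,
    stop_probability_per_test = stop_probability_per_test,
    hazard_adherent = hazard_adherent,
    hazard_nonadherent = hazard_nonadherent,
    covariate_marginals = covariate_marginals,
    archetype_tilt = archetype_tilt,
    condom_transition = condom_transition,
    condom_initial = condom_initial,
    missingness = missingness,
    seed = seed), class = "sim_config")
}

.draw_gap <- function(archetype, config) {
  if (archetype == "adherent") {
    r <- config$adherent_interval
  } else if (stats::runif(1) < config$nonadherent_p_short) {
    r <- config$nonadherent_short
  } else {
    r <- config$nonadherent_long
  }
  sample.int(r[2] - r[1] + 1L, 1L) + r[1] - 1L
}

#' Simulate one participant's test timeline
#'
#' First test at the entry date; each subsequent gap is drawn from the
#' archetype's inter-test interval distribution. Generation stops when a
#' stop-probability draw fires or the next test would fall after the window
#' endpoint. Uses the current RNG state.
#'
#' @param entry entry date (first test), `entry <= window_end`.
#' @param archetype `"adherent"` or `"nonadherent"`.
#' @param window_end study endpoint date.
#' @param config a [sim_config()].
#' @return Strictly increasing Date vector, first element `entry`.
#' @export
simulate_timeline <- function(entry, archetype, window_end, config) {
  entry <- as.Date(entry); window_end <- as.Date(window_end)
  stopifnot(entry <= window_end)
  archetype <- match.arg(archetype, c("adherent", "nonadherent"))
  dates <- entry
  repeat {
    if (stats::runif(1) < config$stop_probability_per_test) break
    nxt <- dates[length(dates)] + .draw_gap(archetype, config)
    if (nxt > window_end) break
    dates <- c(dates, nxt)
  }
  dates
}

#' Simulate seroconversion results along a timeline
#'
#' A latent seroconversion time is drawn exponentially with the given
#' per-person-year hazard, starting from the first test date. Tests strictly
#' before the latent time are negative; tests at or after it are positive.
#' Hazard 0 means no seroconversion.
#'
#' @param timeline nonempty increasing Date vector.
#' @param hazard events per person-year, `>= 0`.
#' @return List: `results` (character vector over the timeline) and
#'   `seroconversion_date` (latent date, `NA` if hazard is 0).
#' @export
simulate_seroconversion <- function(timeline, hazard) {
  stopifnot(length(timeline) >= 1, hazard >= 0)
  timeline <- as.Date(timeline)
  if (hazard == 0)
    return(list(results = rep("negative", length(timeline)),
                seroconversion_date = as.Date(NA)))
  latent_days <- stats::rexp(1, rate = hazard) * 365.25
  sero <- timeline[1] + ceiling(latent_days)
  list(results = ifelse(timeline >= sero, "positive", "negative"),
       seroconversion_date = sero)
}

.tilted_marginal <- function(p, tilt) {
  # multiply the odds of level j by exp(tilt * (j - 1)), then renormalise
  w <- p * exp(tilt * (seq_along(p) - 1))
  w / sum(w)
}

#' Simulate a cohort with known ground truth
#'
#' Each participant receives a uniform entry date over the window, a testing
#' archetype, a test timeline, archetype-hazard seroconversion results, a
#' condom-use response chain, covariates from the configured marginals
#' (optionally tilted by archetype), and covariate missingness. Participants
#' drawn baseline-positive get a single positive test at entry (no further
#' tests are taken once infection is confirmed). Timelines are truncated at
#' the first positive test for the same reason.
#'
#' The ground truth needed by recovery tests (archetype, latent
#' seroconversion date, covariates before missingness) is attached as
#' attribute `"truth"`, a data.frame keyed by `participant_id`; write it
#' with [write_truth()].
#'
#' @param config a [sim_config()]. If `config$seed` is set the RNG is seeded,
#'   making the result a pure function of the config.
#' @return A `hivst_cohort` with attribute `"truth"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  dict <- covariate_dictionary()
  window <- config$window
  span <- as.integer(window[2] - window[1])

  ids <- sprintf("S%05d", seq_len(n))
  entry <- window[1] + if (n) sample.int(span + 1L, n, replace = TRUE) - 1L else integer()
  archetype <- ifelse(stats::runif(n) < config$p_adherent_archetype,
                      "adherent", "nonadherent")
  baseline_pos <- stats::runif(n) < config$p_baseline_positive

  ev_list <- vector("list", n)
  sero_dates <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    if (baseline_pos[i]) {
      dates <- entry[i]
      results <- "positive"
      sero_dates[i] <- entry[i]
    } else {
      dates <- simulate_timeline(entry[i], archetype[i], window[2], config)
      hz <- if (archetype[i] == "adherent") config$hazard_adherent
            else config$hazard_nonadherent
      sc <- simulate_seroconversion(dates, hz)
      results <- sc$results
      sero_dates[i] <- sc$seroconversion_date
      firstpos <- which(results == "positive")
      if (length(firstpos)) {        # confirmed positive: no further tests
        keep <- seq_len(firstpos[1])
        dates <- dates[keep]; results <- results[keep]
      }
    }
    k <- length(dates)
    condom <- character(k)
    condom[1] <- sample(condom_levels(), 1, prob = config$condom_initial)
    if (k > 1) for (j in 2:k)
      condom[j] <- sample(condom_levels(), 1,
                          prob = config$condom_transition[condom[j - 1], ])
    ev_list[[i]] <- data.frame(participant_id = ids[i],
                               date = dates, result = results,
                               condom_use = condom, stringsAsFactors = FALSE)
  }
  events <- if (n) do.call(rbind, ev_list) else
    data.frame(participant_id = character(), date = as.Date(character()),
               result = character(), condom_use = character())

  participants <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (v in names(config$covariate_marginals)) {
    p0 <- config$covariate_marginals[[v]]
    tilt <- if (!is.null(config$archetype_tilt)) config$archetype_tilt[v] else NA
    draw <- character(n)
    for (i in seq_len(n)) {
      p <- if (!is.na(tilt) && archetype[i] == "adherent")
        .tilted_marginal(p0, tilt) else p0
      draw[i] <- sample(dict[[v]], 1, prob = p)
    }
    participants[[v]] <- draw
  }

  truth <- participants
  truth$archetype <- archetype
  truth$seroconversion_date <- sero_dates
  truth$entry_date <- entry
  truth$baseline_positive <- baseline_pos

  for (v in names(config$missingness)) {
    pm <- config$missingness[[v]]
    if (pm > 0 && v %in% names(participants)) {
      hit <- stats::runif(n) < pm
      participants[[v]][hit] <- NA_character_
    }
  }

  cohort <- new_cohort(participants, events, window, check = FALSE)
  attr(cohort, "truth") <- truth
  cohort
}

#' Write the simulation ground truth
#'
#' Writes the `"truth"` attribute of a simulated cohort (archetype, latent
#' seroconversion date, entry date, uncensored covariates) as `truth.csv`.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no truth record")
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}
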