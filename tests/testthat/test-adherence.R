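win <- as.Date(c("2017-07-01", "2018-06-30"))
d0 <- as.Date("2017-07-01")

test_that("exclusion cascade applies its rules in fixed order", {
  co <- load_fixture_cohort()
  elig <- apply_exclusions(co)
  ans <- load_fixture_answers()$eligibility
  for (id in names(ans))
    expect_equal(elig$eligibility[elig$participant_id == id], ans[[id]],
                 label = id)

  # baseline-positive outranks every later rule even with 4 tests
  co2 <- new_cohort(data.frame(participant_id = "A"),
    events_df(d0 + c(0, 50, 100, 150),
              c("positive", "negative", "negative", "negative"), id = "A"), win)
  expect_equal(apply_exclusions(co2)$eligibility, "excluded_baseline_positive")

  # one negative test 50 days before endpoint -> indeterminate;
  # 150 days before -> included (and nonadherent)
  one <- function(days_before) new_cohort(
    data.frame(participant_id = "A"),
    events_df(win[2] - days_before, "negative", id = "A"), win)
  expect_equal(apply_exclusions(one(50))$eligibility,
               "excluded_indeterminate_single_test")
  expect_equal(apply_exclusions(one(150))$eligibility, "included")
  lab <- classify_adherence(one(150)$events, win[2])
  expect_equal(lab$label, "nonadherent")

  # the strict-window flag moves the 100-day boundary case
  expect_equal(apply_exclusions(one(100))$eligibility,
               "excluded_indeterminate_single_test")
  expect_equal(apply_exclusions(one(100),
                                inclusive_single_test = FALSE)$eligibility,
               "included")
})

test_that("two-criterion classification with inclusive thresholds and waiver", {
  # gaps 90, 90 <= 100; endpoint gap 60 <= 100 -> adherent
  ev <- events_df(d0 + c(0, 90, 180), rep("negative", 3))
  lab <- classify_adherence(ev, d0 + 240)
  expect_equal(lab$label, "adherent")
  expect_true(lab$criterion1_met && lab$criterion2_met)

  # gap 101 breaks criterion 1
  lab <- classify_adherence(events_df(d0 + c(0, 101), rep("negative", 2)),
                            d0 + 150)
  expect_equal(lab$label, "nonadherent")
  expect_false(lab$criterion1_met)

  # a gap of exactly 100 still qualifies
  lab <- classify_adherence(events_df(d0 + c(0, 100), rep("negative", 2)),
                            d0 + 150)
  expect_true(lab$criterion1_met)

  # terminal positive waives criterion 2
  lab <- classify_adherence(events_df(d0 + c(0, 95),
                                      c("negative", "positive")), d0 + 300)
  expect_equal(lab$label, "adherent")
  expect_false(lab$criterion2_met)
  expect_true(lab$waived_for_seroconversion)

  expect_error(classify_adherence(events_df(as.Date(character()), character()),
                                  win[2]), "at least one test")
})

test_that("adhering-test counting: inclusive gaps, first test never counts", {
  ev <- events_df(d0 + c(0, 90, 210, 310), rep("negative", 4))  # gaps 90,120,100
  expect_equal(count_adhering_tests(ev),
               c(eligible_intervals = 3L, adhering = 2L))
  expect_equal(count_adhering_tests(events_df(d0, "negative")),
               c(eligible_intervals = 0L, adhering = 0L))
  ev5 <- events_df(d0 + seq(0, 120, by = 30), rep("negative", 5))
  expect_equal(count_adhering_tests(ev5),
               c(eligible_intervals = 4L, adhering = 4L))
})

test_that("classifier agrees with the brute-force oracle on random timelines", {
  set.seed(101)
  for (i in 1:1000) {
    tl <- random_timeline(win[1], win[2])
    ev <- events_df(tl$dates, tl$results)
    got <- classify_adherence(ev, win[2])$label
    expect_identical(got, oracle_classify(tl$dates, tl$results, win[2]),
                     label = paste("timeline", i))
  }
})

test_that("raising the threshold never flips adherent to nonadherent", {
  set.seed(102)
  for (i in 1:300) {
    tl <- random_timeline(win[1], win[2])
    ev <- events_df(tl$dates, tl$results)
    labels <- vapply(c(60, 100, 140, 200), function(th)
      classify_adherence(ev, win[2], th)$label, character(1))
    adherent <- labels == "adherent"
    expect_true(all(adherent == cummax(adherent)),
                label = paste("monotone at timeline", i))
  }
})

test_that("appending a within-threshold test never breaks criterion 1", {
  set.seed(103)
  for (i in 1:200) {
    tl <- random_timeline(win[1], win[2])
    ev <- events_df(tl$dates, rep("negative", length(tl$dates)))
    before <- classify_adherence(ev, win[2])
    ev2 <- rbind(ev, events_df(tl$dates[length(tl$dates)] + sample.int(100, 1),
                               "negative"))
    after <- classify_adherence(ev2, win[2])
    if (before$criterion1_met) expect_true(after$criterion1_met)
  }
})

test_that("every participant gets exactly one status; included get one label", {
  co <- simulate_cohort(sim_config(n_participants = 400, seed = 55))
  labels <- adherence_labels(co)
  expect_setequal(labels$participant_id, co$participants$participant_id)
  expect_false(anyDuplicated(labels$participant_id) > 0)
  expect_true(all(labels$eligibility %in% c(
    "included", "excluded_no_test", "excluded_baseline_positive",
    "excluded_indeterminate_single_test")))
  inc <- labels$eligibility == "included"
  expect_true(all(labels$label[inc] %in% c("adherent", "nonadherent")))
  expect_true(all(is.na(labels$label[!inc])))
})

test_that("summary on the worked fixture matches the hand-computed answers", {
  co <- load_fixture_cohort()
  ans <- load_fixture_answers()
  s <- summarize_adherence(co)
  expect_equal(s$n_included, ans$cascade$included)
  expect_equal(s$n_adherent, ans$cascade$adherent)
  expect_equal(s$n_nonadherent, ans$cascade$nonadherent)
  expect_equal(s$n_tests_total, ans$summary$n_tests_total)
  expect_equal(s$n_eligible_intervals, ans$summary$n_eligible_intervals)
  expect_equal(s$n_adhering_tests, ans$summary$n_adhering_tests)
  expect_equal(s$proportion_adherent, ans$summary$proportion_adherent)
  expect_equal(s$proportion_adhering_tests, ans$summary$proportion_adhering_tests)

  # all-stale-single-test cohort: zero adherent
  stale <- new_cohort(
    data.frame(participant_id = c("A", "B")),
    rbind(events_df(d0 + c(0, 120), rep("negative", 2), id = "A"),
          events_df(d0 + c(5, 140), rep("negative", 2), id = "B")), win)
  s2 <- summarize_adherence(stale)
  expect_equal(s2$n_adherent, 0)
  expect_equal(s2$proportion_adherent, 0)

  # empty: undefined proportions, zero counts, not an error
  empty <- new_cohort(data.frame(participant_id = "Z"),
                      events_df(as.Date(character()), character()), win)
  s3 <- summarize_adherence(empty)
  expect_equal(s3$n_included, 0)
  expect_true(is.nan(s3$proportion_adherent))
})
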