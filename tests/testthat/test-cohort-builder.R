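d0 <- fixture_day0

test_that("distinct loss events follow the 90-day greedy anchor scan", {
  expect_equal(distinct_loss_events(d0 + c(0, 89)), d0)
  expect_equal(distinct_loss_events(d0 + c(0, 90)), d0 + c(0, 90))
  # hand enumeration: 0 anchors; 50 within 90; 95 accepted; 200 >= 95+90
  expect_equal(distinct_loss_events(d0 + c(0, 50, 95, 200)), d0 + c(0, 95, 200))
  expect_error(distinct_loss_events(d0 + c(10, 0)), "sorted")
  expect_length(distinct_loss_events(as.Date(character(0))), 0)
})

test_that("lowering the gap never decreases the distinct-event count", {
  set.seed(21)
  for (i in 1:50) {
    dates <- sort(d0 + sample.int(600, sample(2:12, 1)))
    n_prev <- 0
    for (gap in c(120, 90, 60, 30, 0)) {
      n <- length(distinct_loss_events(dates, gap))
      expect_gte(n, n_prev)
      n_prev <- n
    }
    expect_length(distinct_loss_events(dates, 0), length(dates))
  }
})

test_that("RPL selection honours all three qualifying routes and takes the earliest", {
  bundle <- fixture_bundle_25()
  cs <- default_concept_sets()
  rpl <- select_rpl(bundle, cs)

  expect_setequal(rpl$person_id, fixture25_expected$rpl_pre)
  # history-of-loss day 100 -> loss day 300 qualifies with the loss date
  expect_equal(rpl$index_date[rpl$person_id == "p06"], d0 + 300)
  # same-day history + loss does not qualify; single loss fails criterion (c)
  expect_false("p07" %in% rpl$person_id)
  expect_false("p08" %in% rpl$person_id)
  # explicit RPL diagnosis earlier than the second loss wins: min(50, 90)
  expect_equal(rpl$index_date[rpl$person_id == "p05"], d0 + 50)
  # second distinct event dates
  expect_equal(rpl$index_date[rpl$person_id == "p02"], d0 + 90)
  expect_equal(rpl$index_date[rpl$person_id == "p04"], d0 + 95)
  expect_equal(rpl$n_distinct_losses[rpl$person_id == "p04"], 3)
})

test_that("control selection requires a live birth and a clean history", {
  bundle <- fixture_bundle_25()
  ctl <- select_controls(bundle, default_concept_sets())
  expect_setequal(ctl$person_id, fixture25_expected$control_pre)
  expect_equal(attr(ctl, "n_excluded_by_concept"),
               fixture25_expected$control_removed_by_concept)
  # earliest of two births is the index
  expect_equal(ctl$index_date[ctl$person_id == "c02"], d0 + 400)
})

test_that("the exclusion cascade removes each fixture patient in its designed arm", {
  bundle <- fixture_bundle_25()
  cs <- default_concept_sets()
  built <- build_cohort(bundle, cs)
  exp <- fixture25_expected

  expect_setequal(built$cohort$person_id[built$cohort$group == "rpl"],
                  exp$rpl_final)
  expect_setequal(built$cohort$person_id[built$cohort$group == "control"],
                  exp$control_final)

  rep_rpl <- built$report[built$report$group == "rpl", ]
  expect_equal(stats::setNames(rep_rpl$n_removed, rep_rpl$criterion),
               exp$rpl_arms)
  rep_ctl <- built$report[built$report$group == "control" &
                          built$report$criterion != "exclusion_concept_in_history", ]
  expect_equal(stats::setNames(rep_ctl$n_removed, rep_ctl$criterion),
               exp$control_arms)

  idx <- stats::setNames(as.numeric(built$cohort$index_date - d0),
                         built$cohort$person_id)
  expect_equal(idx[names(exp$index_days)], exp$index_days)

  # age uses 365.25-day years: c07 born 16071 days before index -> exactly 44
  expect_equal(built$cohort$age_at_index[built$cohort$person_id == "c07"], 44)
  # visit count in window: 5 of c10's 7 visits fall on or before index + 365
  expect_equal(built$cohort$n_visits_in_window[built$cohort$person_id == "c10"], 5)
})

test_that("age derivation matches the day-count arithmetic", {
  bundle <- new_bundle(
    data.frame(person_id = "a", birth_date = as.Date("1988-01-01"),
               gender = "female", race = "r", ethnicity = "e"),
    data.frame(person_id = "a",
               concept_id = c("OMOP:LOSS_MISCARRIAGE", "OMOP:LOSS_MISCARRIAGE", "Z00.00"),
               condition_start_date = as.Date(c("2022-06-01", "2023-01-01", "2022-12-01")))
  )
  built <- build_cohort(bundle, default_concept_sets())
  # 12784 days from 1988-01-01 to 2023-01-01
  expect_equal(built$cohort$age_at_index, 12784 / 365.25)
  expect_equal(built$cohort$age_at_index, 35, tolerance = 1e-4)
})

test_that("severe-RPL selection needs three distinct events and indexes the third", {
  bundle <- fixture_bundle_25()
  cs <- default_concept_sets()
  severe <- build_cohort(bundle, cs, variant = "severe")
  sev_rpl <- severe$cohort[severe$cohort$group == "rpl", ]
  expect_equal(sev_rpl$person_id, "p04")
  expect_equal(sev_rpl$index_date, d0 + 200)
  # p15's third record is 80 days after its second event: not severe
  expect_false("p15" %in% sev_rpl$person_id)
  # controls identical to the main analysis
  expect_setequal(severe$cohort$person_id[severe$cohort$group == "control"],
                  fixture25_expected$control_final)
  # direct hand traces of the rule
  sel3 <- select_rpl(bundle, cs, min_events = 3L)
  expect_equal(sel3$person_id, "p04")
})

test_that("main RPL and control groups are disjoint and order-independent", {
  bundle <- fixture_bundle_25()
  cs <- default_concept_sets()
  a <- build_cohort(bundle, cs)
  set.seed(5)
  shuffled <- new_bundle(bundle$persons[sample(nrow(bundle$persons)), ],
                         bundle$conditions[sample(nrow(bundle$conditions)), ],
                         bundle$visits, bundle$center)
  b <- build_cohort(shuffled, cs)
  key <- function(x) x$cohort[order(x$cohort$person_id), ]
  ka <- key(a); kb <- key(b)
  rownames(ka) <- rownames(kb) <- NULL
  expect_equal(ka, kb)
  expect_length(intersect(a$cohort$person_id[a$cohort$group == "rpl"],
                          a$cohort$person_id[a$cohort$group == "control"]), 0)
})

test_that("ten-year subgroup keeps only patients with long pre-index records", {
  persons <- data.frame(person_id = c("long", "short"),
                        birth_date = as.Date("1985-06-01"),
                        gender = "female", race = "r", ethnicity = "e")
  idx <- as.Date("2020-01-01")
  conditions <- rbind(
    data.frame(person_id = "long", concept_id = "Z00.00",
               condition_start_date = idx - round(11 * 365.25)),
    data.frame(person_id = "short", concept_id = "Z00.00",
               condition_start_date = idx - round(9.9 * 365.25)),
    data.frame(person_id = c("long", "short"), concept_id = "OMOP:BIRTH_FULLTERM",
               condition_start_date = idx)
  )
  bundle <- new_bundle(persons, conditions)
  built <- build_cohort(bundle, default_concept_sets())
  sub <- select_ten_year_subgroup(built$cohort, bundle)
  expect_equal(sub$person_id, "long")
  expect_true(all(sub$person_id %in% built$cohort$person_id))
})

test_that("next-outcome lookup takes the earliest outcome at least 30 days out", {
  cs <- default_concept_sets()
  loss <- cs$pregnancy_loss[1]; birth <- cs$live_birth[1]
  mk <- function(extra) {
    persons <- data.frame(person_id = "a", birth_date = as.Date("1990-01-01"),
                          gender = "female", race = "r", ethnicity = "e")
    base <- data.frame(person_id = "a", concept_id = c(loss, loss, "Z00.00"),
                       condition_start_date = fixture_day0 + c(0, 90, 10))
    new_bundle(persons, rbind(base, extra))
  }
  cohort <- data.frame(person_id = "a", group = "rpl",
                       index_date = fixture_day0 + 90, stringsAsFactors = FALSE)

  b <- mk(data.frame(person_id = "a", concept_id = c(loss, birth),
                     condition_start_date = fixture_day0 + 90 + c(40, 400)))
  out <- find_next_outcome(cohort, b, cs)
  expect_equal(out$outcome, "loss")
  expect_equal(out$outcome_date, fixture_day0 + 130)

  # a record only 29 days out is not a next outcome
  b <- mk(data.frame(person_id = "a", concept_id = birth,
                     condition_start_date = fixture_day0 + 90 + 29))
  expect_equal(nrow(find_next_outcome(cohort, b, cs)), 0)
  # exactly 30 days qualifies
  b <- mk(data.frame(person_id = "a", concept_id = birth,
                     condition_start_date = fixture_day0 + 90 + 30))
  expect_equal(find_next_outcome(cohort, b, cs)$outcome, "birth")

  # same-day birth + loss resolves to loss, flagged ambiguous
  b <- mk(data.frame(person_id = "a", concept_id = c(birth, loss),
                     condition_start_date = fixture_day0 + 150))
  out <- find_next_outcome(cohort, b, cs)
  expect_equal(out$outcome, "loss")
  expect_true(out$ambiguous)
})
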