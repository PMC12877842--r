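test_that("generation is byte-identical under the same seed", {
  cfg <- synth_config(seed = 31, n_rpl = 80, n_control = 320)
  a <- generate_center(cfg)
  b <- generate_center(cfg)
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$truth$patients, b$truth$patients)
  c2 <- generate_center(synth_config(seed = 32, n_rpl = 80, n_control = 320))
  expect_false(identical(a$bundle$conditions, c2$bundle$conditions))
})

test_that("config invariants are validated before any sampling", {
  expect_error(synth_config(n_rpl = 0), "positive")
  expect_error(synth_config(race_probs = c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(synth_config(visit_case_multiplier = 0), "multiplier")
  bad <- default_diagnosis_panel(0)
  bad$planted_or[1] <- -1
  expect_error(synth_config(diagnoses = bad), "planted_or")
  expect_error(diagnosis_spec("X", "1", "x", baseline_prevalence = 1.2))
})

test_that("generated records respect the case/control contracts", {
  cfg <- synth_config(seed = 33, n_rpl = 120, n_control = 300)
  ctr <- generate_center(cfg)
  cs <- default_concept_sets()
  cond <- ctr$bundle$conditions
  truth <- ctr$truth$patients

  for (pid in truth$person_id[truth$case == 1][1:40]) {
    losses <- sort(cond$condition_start_date[cond$person_id == pid &
                     cond$concept_id %in% cs$pregnancy_loss])
    expect_gte(length(distinct_loss_events(losses)), 2)
  }
  ctl_ids <- truth$person_id[truth$case == 0]
  ctl_cond <- cond[cond$person_id %in% ctl_ids, ]
  expect_false(any(ctl_cond$concept_id %in% cs$control_exclusion))
  expect_true(all(vapply(split(ctl_cond$concept_id, ctl_cond$person_id),
                         function(x) any(x %in% cs$live_birth), logical(1))))
})

test_that("control prevalence tracks baseline within Monte-Carlo error", {
  panel <- rbind(
    diagnosis_spec("N92.6", "626.8", "Irregular menses", "genitourinary", 0.08, 2.0),
    diagnosis_spec("R01.9", "901.0", "Null A", "symptoms", 0.05, 1.0),
    diagnosis_spec("R02.9", "902.0", "Null B", "symptoms", 0.20, 1.0)
  )
  cfg <- synth_config(seed = 34, n_rpl = 500, n_control = 5000,
                      diagnoses = panel, utilization_link_strength = 0)
  ctr <- generate_center(cfg)
  ctl <- ctr$truth$patients$case == 0
  for (j in seq_len(nrow(panel))) {
    p_hat <- mean(ctr$truth$presence[ctl, j])
    p0 <- panel$baseline_prevalence[j]
    se <- sqrt(p0 * (1 - p0) / sum(ctl))
    expect_lt(abs(p_hat - p0), 3 * se + 0.005)
  }
})

test_that("a planted 2x2 odds ratio is recovered from the crude table", {
  panel <- rbind(diagnosis_spec("N92.6", "626.8", "Irregular menses",
                                "genitourinary", 0.10, 2.0))
  cfg <- synth_config(seed = 35, n_rpl = 2000, n_control = 8000,
                      diagnoses = panel)
  ctr <- generate_center(cfg)
  case <- ctr$truth$patients$case
  dx <- ctr$truth$presence[, 1]
  or_hat <- (sum(dx & case) * sum(!dx & !case)) /
    (sum(dx & !case) * sum(!dx & case))
  expect_gt(or_hat, 1.7)
  expect_lt(or_hat, 2.3)

  # null diagnosis at the same scale stays near 1
  panel0 <- rbind(diagnosis_spec("R01.9", "901.0", "Null", "symptoms", 0.10, 1.0))
  ctr0 <- generate_center(synth_config(seed = 36, n_rpl = 2000, n_control = 8000,
                                       diagnoses = panel0))
  dx0 <- ctr0$truth$presence[, 1]; case0 <- ctr0$truth$patients$case
  or0 <- (sum(dx0 & case0) * sum(!dx0 & !case0)) /
    (sum(dx0 & !case0) * sum(!dx0 & case0))
  expect_lt(abs(log(or0)), log(1.25))
})

test_that("cases are older than controls by about the configured shift", {
  cfg <- synth_config(seed = 37, n_rpl = 1500, n_control = 1500,
                      age_case_shift_years = 3.2)
  ctr <- generate_center(cfg)
  age <- ctr$truth$patients$age
  case <- ctr$truth$patients$case
  tt <- t.test(age[case == 1], age[case == 0])
  expect_lt(tt$p.value, 1e-10)
  expect_equal(mean(age[case == 1]) - mean(age[case == 0]), 3.2, tolerance = 0.5)
})

test_that("visit counts carry the center's case multiplier and the link is off by default", {
  cfg <- synth_config(seed = 38, n_rpl = 2000, n_control = 2000,
                      visit_mean_control = 14, visit_case_multiplier = 2.2,
                      utilization_link_strength = 0)
  ctr <- generate_center(cfg)
  tr <- ctr$truth$patients
  expect_equal(mean(tr$n_visits[tr$case == 0]), 14, tolerance = 1)
  expect_equal(mean(tr$n_visits[tr$case == 1]) / mean(tr$n_visits[tr$case == 0]),
               2.2, tolerance = 0.25)
  # with zero link, diagnosis presence is independent of visits given case:
  # logistic of presence on log-visits within controls is null
  ctl <- tr$case == 0
  dx <- ctr$truth$presence[ctl, 1]
  fit <- glm(dx ~ log1p(tr$n_visits[ctl]), family = binomial())
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)
})

test_that("injected edge cases land in their designed cohort arms", {
  cfg <- synth_config(seed = 39, n_rpl = 30, n_control = 60)
  ctr <- generate_center(cfg)
  bundle <- inject_edge_cases(ctr$bundle)
  cs <- default_concept_sets()
  built <- build_cohort(bundle, cs)
  ids <- built$cohort$person_id

  expect_false("edge_gap89" %in% ids)  # one distinct loss only
  expect_true(all(c("edge_gap90", "edge_gap91") %in% ids))
  expect_false("edge_under15" %in% ids)
  expect_false("edge_over44" %in% ids)
  expect_false("edge_span101y" %in% ids)
  expect_false("edge_nodx" %in% ids)
  expect_false("edge_preterm_ctrl" %in% ids)

  rpl <- select_rpl(bundle, cs)
  expect_equal(rpl$n_distinct_losses[rpl$person_id == "edge_gap90"], 2)
  expect_false("edge_gap89" %in% rpl$person_id)
})
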