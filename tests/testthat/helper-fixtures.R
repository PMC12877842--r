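# Fixtures built in code. fixture_bundle_25() is a hand-enumerated
# 25-patient bundle exercising every cohort-selection and exclusion arm;
# the expected memberships/index dates are derived by hand in the tests.

fixture_day0 <- as.Date("2015-01-01")

fixture_bundle_25 <- function() {
  d0 <- fixture_day0
  cs <- default_concept_sets()
  loss <- cs$pregnancy_loss[1]
  birth <- cs$live_birth[1]
  rpl_dx <- cs$rpl_diagnosis[1]
  hx <- cs$history_of_loss[1]
  exam <- "Z00.00"   # mapped ICD filler

  default_birth <- d0 - 10958  # ~age 30 at early index dates

  P <- function(id, birth_date = default_birth, gender = "female") {
    data.frame(person_id = id, birth_date = birth_date, gender = gender,
               race = "White", ethnicity = "Not Hispanic or Latino",
               stringsAsFactors = FALSE)
  }
  C <- function(id, code, days) {
    data.frame(person_id = id, concept_id = code,
               condition_start_date = d0 + days, stringsAsFactors = FALSE)
  }

  persons <- rbind(
    P("p01"), P("p02"), P("p03"), P("p04"), P("p05"), P("p06"), P("p07"),
    P("p08"),
    P("p09", birth_date = d0 + 90 - 5443),   # age 14.90 at day-90 index
    P("p10", birth_date = d0 + 90 - 16253),  # age 44.50 at day-90 index
    P("p11", gender = "male"),
    P("p12", gender = "other"),
    P("p13"), P("p14"), P("p15"),
    P("c01"), P("c02"), P("c03"), P("c04"), P("c05"),
    P("c06", birth_date = d0 + 500 - 5479),  # age 15.0006 at day-500 index
    P("c07", birth_date = d0 + 500 - 16071), # age 44.00 exactly
    P("c08"), P("c09"), P("c10")
  )

  conditions <- rbind(
    C("p01", loss, c(0, 89)), C("p01", exam, 10),
    C("p02", loss, c(0, 90)), C("p02", exam, 10),
    C("p03", loss, c(0, 91)), C("p03", exam, 10),
    C("p04", loss, c(0, 50, 95, 200)), C("p04", exam, 10),
    C("p05", rpl_dx, 50), C("p05", loss, c(0, 90)), C("p05", exam, 10),
    C("p06", hx, 100), C("p06", loss, 300), C("p06", exam, 10),
    C("p07", hx, 100), C("p07", loss, 100), C("p07", exam, 10),
    C("p08", loss, 0), C("p08", exam, 10),
    C("p09", loss, c(0, 90)), C("p09", exam, 10),
    C("p10", loss, c(0, 90)), C("p10", exam, 10),
    C("p11", rpl_dx, 50), C("p11", exam, 10),
    C("p12", loss, c(0, 90)), C("p12", exam, 10),
    C("p13", loss, c(0, 90)), C("p13", exam, c(-36900, 10)),
    C("p14", loss, c(0, 90)),
    C("p15", loss, c(0, 90, 170)), C("p15", exam, 10),
    C("c01", birth, 500), C("c01", exam, 520),
    C("c02", birth, c(400, 800)), C("c02", exam, 410),
    C("c03", birth, 500), C("c03", "OMOP:PRETERM_BIRTH", 900), C("c03", exam, 510),
    C("c04", birth, 500), C("c04", loss, 100), C("c04", exam, 510),
    C("c05", birth, 500), C("c05", "OMOP:MOLAR_PREGNANCY", 100), C("c05", exam, 510),
    C("c06", birth, 500), C("c06", exam, 510),
    C("c07", birth, 500), C("c07", exam, 510),
    C("c08", birth, 500), C("c08", exam, 500 + 366),
    C("c09", birth, 500), C("c09", exam, 500 + 365),
    C("c10", birth, 500), C("c10", exam, 510)
  )

  visits <- data.frame(
    person_id = "c10",
    visit_start_date = d0 + c(100, 200, 300, 400, 860, 900, 1000),
    stringsAsFactors = FALSE
  )

  new_bundle(persons, conditions, visits, "fixture25")
}

# Expected final memberships, by hand.
fixture25_expected <- list(
  rpl_pre = c("p02", "p03", "p04", "p05", "p06", "p09", "p10", "p11", "p12",
              "p13", "p14", "p15"),
  control_pre = c("c01", "c02", "c06", "c07", "c08", "c09", "c10"),
  control_removed_by_concept = 3L,  # c03 preterm, c04 loss, c05 molar
  rpl_final = c("p02", "p03", "p04", "p05", "p06", "p12", "p15"),
  control_final = c("c01", "c02", "c06", "c07", "c09", "c10"),
  index_days = c(p02 = 90, p03 = 91, p04 = 95, p05 = 50, p06 = 300,
                 p12 = 90, p15 = 90,
                 c01 = 500, c02 = 400, c06 = 500, c07 = 500, c09 = 500,
                 c10 = 500),
  rpl_arms = c(age_outside_15_44 = 2L,                 # p09, p10
               not_female_no_incident_pregnancy = 1L,  # p11
               record_span_100y_or_more = 1L,          # p13
               no_diagnoses_in_study_window = 1L),     # p14
  control_arms = c(age_outside_15_44 = 0L,
                   not_female_no_incident_pregnancy = 0L,
                   record_span_100y_or_more = 0L,
                   no_diagnoses_in_study_window = 1L)  # c08
)

fixture_phecode_map <- function() {
  read_phecode_map(system.file("extdata", "phecode_map_v1_2_synthetic.csv",
                               package = "rplphewas"))
}

# Design-level simulated phenome matrix: covariates, case status with a
# nonlinear age effect, and one presence column per planted odds ratio.
sim_phewas_matrix <- function(n, or = rep(1, 20), prevalence = 0.05,
                              case_rate = 0.2, age_confounding = TRUE,
                              visit_link = 0, visit_case_multiplier = 1) {
  age <- pmin(pmax(stats::rnorm(n, 33, 5), 15), 44)
  race <- sample(c("White", "Asian", "Other Race"), n, TRUE, c(0.5, 0.25, 0.25))
  eth <- sample(c("Not Hispanic or Latino", "Hispanic or Latino"), n, TRUE,
                c(0.8, 0.2))
  lp_case <- if (age_confounding) {
    v <- 0.04 * (age - 30) + 0.12 * pmax(age - 35, 0)
    v - mean(v) + stats::qlogis(case_rate)
  } else rep(stats::qlogis(case_rate), n)
  y <- as.integer(stats::runif(n) < stats::plogis(lp_case))
  visits <- 1L + stats::rnbinom(n, size = 1.5,
                                mu = 20 * ifelse(y == 1, visit_case_multiplier, 1))
  vz <- scale(log1p(visits))[, 1]
  presence <- sapply(seq_along(or), function(j) {
    lp <- stats::qlogis(prevalence) + log(or[j]) * y +
      (if (age_confounding) 0.05 * (age - 33) else 0) + visit_link * vz
    as.integer(stats::runif(n) < stats::plogis(lp))
  })
  patients <- data.frame(
    person_id = sprintf("s%05d", seq_len(n)),
    group = ifelse(y == 1, "rpl", "control"),
    age_at_index = age, race = race, ethnicity = eth,
    n_visits_in_window = visits, stringsAsFactors = FALSE
  )
  diagnoses <- data.frame(
    phecode = sprintf("d%03d", seq_along(or)),
    phecode_string = sprintf("Simulated diagnosis %d", seq_along(or)),
    category = "synthetic", stringsAsFactors = FALSE
  )
  new_phenome_matrix(presence, patients, diagnoses)
}

# Textbook step-up BH, written from the definition (oracle).
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Mean silhouette width for two labelled groups in 2-D (euclidean).
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
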