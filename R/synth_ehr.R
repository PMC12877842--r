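# Two-center synthetic EHR generator with known ground truth. Case status is
# generated first, then records consistent with it: the generator plants
# marginal structure (prevalence, odds ratios, visit-count links) rather than
# simulating pregnancy biology, because the testing surface is parameter
# recovery by the downstream pipeline.

#' Curated pregnancy-outcome concept sets used by the generator and fixtures
#'
#' Mirrors the structure of published OMOP concept lists for pregnancy
#' outcomes: loss, RPL diagnosis, history-of-loss, live birth, and the
#' control-exclusion set (which contains the loss concepts plus preterm,
#' molar and extrauterine pregnancy). Loss and birth concepts double as
#' evidence of incident pregnancy.
#'
#' @return named list of concept id vectors (class `concept_sets`).
#' @export
default_concept_sets <- function() {
  loss <- c("OMOP:LOSS_MISCARRIAGE", "OMOP:LOSS_FETAL_DEATH", "OMOP:LOSS_STILLBIRTH")
  birth <- c("OMOP:BIRTH_FULLTERM", "OMOP:BIRTH_NORMAL_DELIVERY")
  structure(list(
    rpl_diagnosis = c("OMOP:RPL_DX"),
    pregnancy_loss = loss,
    history_of_loss = c("OMOP:HX_PREGNANCY_LOSS"),
    live_birth = birth,
    control_exclusion = sort(c(loss, "OMOP:PRETERM_BIRTH", "OMOP:PRETERM_LABOR",
                               "OMOP:PROM", "OMOP:MULTI_GESTATION_LOSS",
                               "OMOP:MOLAR_PREGNANCY", "OMOP:EXTRAUTERINE_PREGNANCY")),
    incident_pregnancy = sort(c(loss, birth))
  ), class = "concept_sets")
}

#' Specify one planted diagnosis
#'
#' @param icd_code ICD-10-CM style code carried by condition records.
#' @param phecode phecode the fixture crosswalk maps the code to.
#' @param phecode_string human-readable phenotype name.
#' @param category phecode category label.
#' @param baseline_prevalence probability of the diagnosis in controls,
#'   in (0, 1).
#' @param planted_or odds ratio for case status (> 0); 1 plants a null.
#' @param age_modifier `"none"`, `"linear"` (log-odds increase with age) or
#'   `"post35"` (effect switches on after age 35) — used to exercise the
#'   age smooth in adjusted models.
#' @return one-row data frame (a `diagnosis_spec`).
#' @export
diagnosis_spec <- function(icd_code, phecode, phecode_string,
                           category = "other", baseline_prevalence = 0.05,
                           planted_or = 1.0, age_modifier = "none") {
  stopifnot(baseline_prevalence > 0, baseline_prevalence < 1, planted_or > 0,
            age_modifier %in% c("none", "linear", "post35"))
  data.frame(icd_code = icd_code, phecode = phecode,
             phecode_string = phecode_string, category = category,
             baseline_prevalence = baseline_prevalence,
             planted_or = planted_or, age_modifier = age_modifier,
             stringsAsFactors = FALSE)
}

#' Default planted-diagnosis panel
#'
#' A compact panel echoing the kinds of phenotypes the RPL literature
#' reports: menstrual and infertility-associated diagnoses with elevated
#' odds, delivery-related diagnoses with reduced odds, and null filler
#' diagnoses. Phecode strings and categories use phecode v1.2 vocabulary.
#'
#' @param n_null number of additional null (OR = 1) diagnoses to append.
#' @return data frame of `diagnosis_spec` rows.
#' @export
default_diagnosis_panel <- function(n_null = 10) {
  panel <- rbind(
    diagnosis_spec("N92.6", "626.8", "Irregular menstrual cycle/bleeding",
                   "genitourinary", 0.06, 2.7, "none"),
    diagnosis_spec("N91.2", "626.1", "Absent or infrequent menstruation",
                   "genitourinary", 0.05, 1.7, "none"),
    diagnosis_spec("N92.0", "626.2", "Excessive or frequent menstruation",
                   "genitourinary", 0.05, 1.9, "none"),
    diagnosis_spec("N97.9", "628", "Infertility, female",
                   "genitourinary", 0.04, 5.0, "post35"),
    diagnosis_spec("N80.9", "615", "Endometriosis",
                   "genitourinary", 0.04, 3.1, "linear"),
    diagnosis_spec("E28.2", "256.4", "Polycystic ovaries",
                   "endocrine/metabolic", 0.05, 2.2, "none"),
    diagnosis_spec("E28.8", "256", "Ovarian dysfunction",
                   "endocrine/metabolic", 0.03, 3.2, "none"),
    diagnosis_spec("D68.59", "286.81", "Primary hypercoagulable state",
                   "hematopoietic", 0.02, 4.2, "none"),
    diagnosis_spec("E88.81", "277.7", "Dysmetabolic syndrome X",
                   "endocrine/metabolic", 0.02, 5.0, "linear"),
    diagnosis_spec("O20.0", "640", "Hemorrhage in early pregnancy",
                   "pregnancy complications", 0.03, 5.2, "none"),
    diagnosis_spec("O80", "650", "Normal delivery",
                   "pregnancy complications", 0.30, 0.14, "none"),
    diagnosis_spec("O14.90", "642.1", "Preeclampsia and eclampsia",
                   "pregnancy complications", 0.06, 0.25, "none"),
    diagnosis_spec("O99.01", "648.8", "Anemia during pregnancy",
                   "pregnancy complications", 0.08, 0.29, "none"),
    diagnosis_spec("F41.9", "300.1", "Anxiety disorder",
                   "mental disorders", 0.10, 0.75, "none"),
    diagnosis_spec("E11.9", "250.2", "Type 2 diabetes",
                   "endocrine/metabolic", 0.05, 1.0, "linear")
  )
  if (n_null > 0) {
    nulls <- do.call(rbind, lapply(seq_len(n_null), function(i) {
      diagnosis_spec(sprintf("R%02d.9", i), sprintf("9%02d.0", i),
                     sprintf("Null filler diagnosis %d", i),
                     "symptoms", 0.04 + 0.004 * i, 1.0, "none")
    }))
    panel <- rbind(panel, nulls)
  }
  rownames(panel) <- NULL
  panel
}

#' Fixture ICD->Phecode crosswalk matching a diagnosis panel
#'
#' Builds a `phecode_map` whose rows cover the panel's ICD codes (flavor 10)
#' plus the guaranteed background examination code, so that every generated
#' condition record that should aggregate does.
#'
#' @param panel data frame of `diagnosis_spec` rows.
#' @return `phecode_map`.
#' @export
panel_phecode_map <- function(panel = default_diagnosis_panel()) {
  df <- data.frame(
    icd_code = c(panel$icd_code, "Z00.00"),
    icd_flavor = "10",
    phecode = c(panel$phecode, "1010"),
    phecode_string = c(panel$phecode_string, "Other tests"),
    category = c(panel$category, "other tests"),
    stringsAsFactors = FALSE
  )
  new_phecode_map(df)
}

#' Configure one synthetic center
#'
#' Defaults emulate the published two-center study structure: cases a few
#' years older than controls with the excess risk accelerating after age 35,
#' the reported race/ethnicity mixes, overdispersed (negative-binomial)
#' visit counts with a center-specific case/control visit gap, and planted
#' per-diagnosis odds ratios.
#'
#' @param seed integer RNG seed; the whole center is reproducible from it.
#' @param n_rpl,n_control group sizes.
#' @param center_label center name written into the bundle.
#' @param age_case_shift_years mean age excess of cases over controls.
#' @param age_range permissible age range at index.
#' @param race_probs,ethnicity_probs named probability vectors (must sum
#'   to 1).
#' @param visit_mean_control negative-binomial mean visit count in controls.
#' @param visit_case_multiplier multiplicative case/control visit gap
#'   (e.g. ~1.04 for a center where cases and controls have similar
#'   utilization, ~2.2 for a center with a large gap).
#' @param visit_dispersion negative-binomial size parameter.
#' @param diagnoses data frame of `diagnosis_spec` rows.
#' @param utilization_link_strength log-odds of diagnosis presence added per
#'   standard deviation of (log) visit count; 0 makes diagnosis presence
#'   conditionally independent of visits given case status.
#' @param record_span_years maximum pre-index record history length.
#' @param dup_loss_prob probability an RPL patient carries an extra loss
#'   record < 90 days after a true loss (a duplicate record for the same
#'   loss).
#' @param history_loss_prob probability of a history-of-loss record.
#' @param rpl_dx_prob probability an RPL patient also carries an explicit
#'   RPL diagnosis record on the index date.
#' @return validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_rpl = 500L,
                         n_control = 2000L,
                         center_label = "center_A",
                         age_case_shift_years = 3.2,
                         age_range = c(15, 44),
                         race_probs = c("White" = 0.459, "Asian" = 0.223,
                                        "Other Race" = 0.188, "Black or African American" = 0.050,
                                        "Unknown" = 0.067, "American Indian or Alaska Native" = 0.006,
                                        "Native Hawaiian or Other Pacific Islander" = 0.007),
                         ethnicity_probs = c("Not Hispanic or Latino" = 0.772,
                                             "Hispanic or Latino" = 0.157,
                                             "Unknown" = 0.071),
                         visit_mean_control = 41,
                         visit_case_multiplier = 1.04,
                         visit_dispersion = 1.2,
                         diagnoses = default_diagnosis_panel(),
                         utilization_link_strength = 0,
                         record_span_years = 12,
                         dup_loss_prob = 0.3,
                         history_loss_prob = 0.2,
                         rpl_dx_prob = 0.15) {
  cfg <- list(seed = as.integer(seed), n_rpl = as.integer(n_rpl),
              n_control = as.integer(n_control), center_label = center_label,
              age_case_shift_years = age_case_shift_years, age_range = age_range,
              race_probs = race_probs, ethnicity_probs = ethnicity_probs,
              visit_mean_control = visit_mean_control,
              visit_case_multiplier = visit_case_multiplier,
              visit_dispersion = visit_dispersion, diagnoses = diagnoses,
              utilization_link_strength = utilization_link_strength,
              record_span_years = record_span_years,
              dup_loss_prob = dup_loss_prob,
              history_loss_prob = history_loss_prob,
              rpl_dx_prob = rpl_dx_prob)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_rpl <= 0 || cfg$n_control <= 0) {
    stop("group sizes must be positive", call. = FALSE)
  }
  if (abs(sum(cfg$race_probs) - 1) > 1e-6 || abs(sum(cfg$ethnicity_probs) - 1) > 1e-6) {
    stop("race_probs and ethnicity_probs must each sum to 1", call. = FALSE)
  }
  if (cfg$visit_case_multiplier <= 0) stop("visit_case_multiplier must be > 0", call. = FALSE)
  if (cfg$utilization_link_strength < 0) stop("utilization_link_strength must be >= 0", call. = FALSE)
  with(cfg$diagnoses, {
    if (any(baseline_prevalence <= 0 | baseline_prevalence >= 1)) {
      stop("baseline_prevalence must lie in (0, 1)", call. = FALSE)
    }
    if (any(planted_or <= 0)) stop("planted_or must be > 0", call. = FALSE)
  })
  invisible(cfg)
}

# Piecewise-smooth nonlinear age effect on case propensity: slow rise to 35,
# accelerating afterwards (log-odds scale).
case_age_logodds <- function(age) {
  0.04 * (age - 30) + 0.12 * pmax(age - 35, 0)
}

age_modifier_term <- function(tag, age) {
  switch(tag,
         none = rep(0, length(age)),
         linear = 0.06 * (age - 32),
         post35 = 0.10 * pmax(age - 35, 0),
         stop("unknown age_modifier tag: ", tag, call. = FALSE))
}

# Truncated-normal ages with case/control densities tilted by the nonlinear
# case propensity (rejection sampling).
sample_ages <- function(n, case, cfg) {
  lo <- cfg$age_range[1]
  hi <- cfg$age_range[2]
  mu <- if (case) 32 + cfg$age_case_shift_years else 32
  w_max <- max(stats::plogis(case_age_logodds(seq(lo, hi, by = 0.5))))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean = mu, sd = 5)
    draw <- draw[draw >= lo & draw <= hi]
    w <- stats::plogis(case_age_logodds(draw))
    keep <- if (case) stats::runif(length(draw)) < w / w_max
            else stats::runif(length(draw)) < (1 - w)
    out <- c(out, draw[keep])
  }
  out[seq_len(n)]
}

#' Generate one synthetic center
#'
#' Produces an `ehr_bundle` plus its ground truth. Every RPL patient carries
#' at least two pregnancy-loss records >= 90 days apart (the second loss is
#' the planted index date); configured fractions additionally carry
#' duplicate loss records < 90 days after a true loss, history-of-loss
#' records, and explicit RPL diagnosis records. Every control carries a
#' live-birth record (the index) and no loss or exclusion records. Exposure
#' diagnoses are sampled from a logistic model with the planted log odds
#' ratio on case status; visit counts are negative-binomial with the
#' center's case multiplier. Every patient carries a background examination
#' record inside the study window. Fully reproducible from `config$seed`.
#'
#' @param config a `synth_config`.
#' @return list with elements `bundle` (an `ehr_bundle`) and `truth`
#'   (planted parameters and per-patient latent data).
#' @export
generate_center <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  cs <- default_concept_sets()
  n <- config$n_rpl + config$n_control
  case <- c(rep(1L, config$n_rpl), rep(0L, config$n_control))
  ids <- sprintf("%s_p%05d", config$center_label, seq_len(n))

  age <- numeric(n)
  age[case == 1L] <- sample_ages(config$n_rpl, TRUE, config)
  age[case == 0L] <- sample_ages(config$n_control, FALSE, config)
  race <- sample(names(config$race_probs), n, replace = TRUE, prob = config$race_probs)
  ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                      prob = config$ethnicity_probs)

  visits <- 1L + stats::rnbinom(n, size = config$visit_dispersion,
                                mu = config$visit_mean_control *
                                  ifelse(case == 1L, config$visit_case_multiplier, 1) - 1)
  lvis <- log1p(visits)
  lvis_z <- (lvis - mean(lvis)) / max(stats::sd(lvis), 1e-8)

  # index dates and record spans
  index_date <- as.Date("2012-01-01") + sample.int(3300L, n, replace = TRUE)
  pre_days <- round(stats::runif(n, min = 200,
                                 max = config$record_span_years * 365.25))
  first_record <- index_date - pre_days
  birth_date <- index_date - round(age * 365.25)

  # diagnosis presence: logit = logit(prev) + log(OR)*case + age term +
  # utilization link, with the extra terms centered on controls so control
  # prevalence stays close to baseline_prevalence
  dx <- config$diagnoses
  present <- matrix(FALSE, n, nrow(dx))
  ctrl <- case == 0L
  for (j in seq_len(nrow(dx))) {
    extra <- age_modifier_term(dx$age_modifier[j], age) +
      config$utilization_link_strength * lvis_z
    lp <- stats::qlogis(dx$baseline_prevalence[j]) +
      log(dx$planted_or[j]) * case + extra - mean(extra[ctrl])
    present[, j] <- stats::runif(n) < stats::plogis(lp)
  }

  # assemble condition rows
  cond_pid <- character(0); cond_code <- character(0); cond_date <- integer(0)
  add_rows <- function(pid, code, date) {
    cond_pid <<- c(cond_pid, pid)
    cond_code <<- c(cond_code, code)
    cond_date <<- c(cond_date, as.integer(date))
  }

  loss_codes <- cs$pregnancy_loss
  birth_codes <- cs$live_birth
  for (i in seq_len(n)) {
    idx <- index_date[i]
    start <- first_record[i]
    if (case[i] == 1L) {
      # second distinct loss event = index date
      gap <- round(stats::runif(1, 90, min(720, max(91, pre_days[i] - 30))))
      ev1 <- idx - gap
      if (ev1 < start) start <- ev1 - 10
      add_rows(rep(ids[i], 2), sample(loss_codes, 2, replace = TRUE), c(ev1, idx))
      if (stats::runif(1) < config$dup_loss_prob) {
        add_rows(ids[i], sample(loss_codes, 1), ev1 + sample.int(89L, 1))
      }
      if (stats::runif(1) < config$history_loss_prob) {
        add_rows(ids[i], cs$history_of_loss[1], ev1 - sample.int(200L, 1))
      }
      if (stats::runif(1) < config$rpl_dx_prob) {
        add_rows(ids[i], cs$rpl_diagnosis[1], idx)
      }
    } else {
      add_rows(ids[i], sample(birth_codes, 1), idx)
      if (stats::runif(1) < 0.15) {
        add_rows(ids[i], sample(birth_codes, 1), idx + 360 + sample.int(400L, 1))
      }
    }
    # background exam record guaranteed inside the study window
    add_rows(ids[i], "Z00.00", start + sample.int(max(1L, as.integer(idx - start)), 1))
    # exposure diagnosis records, anywhere from record start to index + 365
    pj <- which(present[i, ])
    if (length(pj) > 0) {
      span <- as.integer(idx + 365 - start)
      add_rows(rep(ids[i], length(pj)), dx$icd_code[pj],
               start + sample.int(span, length(pj), replace = TRUE))
    }
    first_record[i] <- start
  }

  conditions <- data.frame(person_id = cond_pid, concept_id = cond_code,
                           condition_start_date = as.Date(cond_date, origin = "1970-01-01"),
                           stringsAsFactors = FALSE)

  # visit rows: n visits uniform over [record start, index + 365]
  vis_pid <- rep(ids, visits)
  vis_start <- rep(as.integer(first_record), visits)
  vis_span <- rep(as.integer(index_date + 365 - first_record), visits)
  vis_date <- vis_start + floor(stats::runif(length(vis_pid)) * vis_span)
  visit_df <- data.frame(person_id = vis_pid,
                         visit_start_date = as.Date(vis_date, origin = "1970-01-01"),
                         stringsAsFactors = FALSE)

  persons <- data.frame(person_id = ids, birth_date = birth_date,
                        gender = "female", race = race, ethnicity = ethnicity,
                        stringsAsFactors = FALSE)
  bundle <- new_bundle(persons, conditions, visit_df, config$center_label)

  truth <- list(
    config = config,
    planted = dx,
    center = list(label = config$center_label,
                  visit_mean_control = config$visit_mean_control,
                  visit_case_multiplier = config$visit_case_multiplier,
                  utilization_link_strength = config$utilization_link_strength),
    patients = data.frame(person_id = ids, case = case, age = age,
                          n_visits = visits, index_date = index_date,
                          stringsAsFactors = FALSE),
    presence = present
  )
  list(bundle = bundle, truth = truth)
}

#' Append hand-designed edge-case patients to a bundle
#'
#' Adds named fixture patients that exercise each arm of the cohort
#' exclusion cascade: loss-record pairs at day gaps 89/90/91, under-15 and
#' over-44 ages at index, a >100-year record span, a patient with no ICD
#' diagnoses in the study window, and a would-be control carrying a
#' preterm-birth record.
#'
#' @param bundle `ehr_bundle` from [generate_center()].
#' @return augmented `ehr_bundle`.
#' @export
inject_edge_cases <- function(bundle) {
  cs <- default_concept_sets()
  d0 <- as.Date("2015-01-01")
  loss <- cs$pregnancy_loss[1]
  birth <- cs$live_birth[1]

  p <- function(id, birth_date, gender = "female") {
    data.frame(person_id = id, birth_date = birth_date, gender = gender,
               race = "Unknown", ethnicity = "Unknown", stringsAsFactors = FALSE)
  }
  cond <- function(id, code, days) {
    data.frame(person_id = id, concept_id = code,
               condition_start_date = d0 + days, stringsAsFactors = FALSE)
  }

  persons <- rbind(
    p("edge_gap89", d0 - round(30 * 365.25)),
    p("edge_gap90", d0 - round(30 * 365.25)),
    p("edge_gap91", d0 - round(30 * 365.25)),
    p("edge_under15", d0 + 90 - 5443),      # age 14.90 at day-90 index
    p("edge_over44", d0 + 90 - 16253),      # age 44.50 at day-90 index
    p("edge_span101y", d0 - round(30 * 365.25)),
    p("edge_nodx", d0 - round(30 * 365.25)),
    p("edge_preterm_ctrl", d0 - round(30 * 365.25))
  )
  conditions <- rbind(
    cond("edge_gap89", loss, c(0, 89)),
    cond("edge_gap89", "Z00.00", 10),
    cond("edge_gap90", loss, c(0, 90)),
    cond("edge_gap90", "Z00.00", 10),
    cond("edge_gap91", loss, c(0, 91)),
    cond("edge_gap91", "Z00.00", 10),
    cond("edge_under15", loss, c(0, 90)),
    cond("edge_under15", "Z00.00", 10),
    cond("edge_over44", loss, c(0, 90)),
    cond("edge_over44", "Z00.00", 10),
    cond("edge_span101y", loss, c(0, 90)),
    cond("edge_span101y", "Z00.00", -36900),  # first record > 100 years before last
    cond("edge_span101y", "Z00.00", 10),
    cond("edge_nodx", loss, c(0, 90)),
    cond("edge_preterm_ctrl", birth, 0),
    cond("edge_preterm_ctrl", "OMOP:PRETERM_BIRTH", 400),
    cond("edge_preterm_ctrl", "Z00.00", 10)
  )
  new_bundle(rbind(bundle$persons, persons),
             rbind(bundle$conditions, conditions),
             bundle$visits, bundle$center)
}

#' Simulate a single-diagnosis association design
#'
#' A lightweight design-level simulator (no record assembly) for studying
#' estimator behavior: covariates, case status with an optional nonlinear
#' age effect, and diagnosis presence with a planted conditional odds
#' ratio. The planted OR is conditional on the covariates in the model, so
#' an adjusted fit recovers `or` and, when `age_confounding = FALSE`, the
#' marginal 2x2 OR equals it too.
#'
#' @param n number of patients.
#' @param prevalence baseline diagnosis prevalence (at case = 0, mean age).
#' @param or planted odds ratio for case status.
#' @param case_rate approximate case fraction.
#' @param age_confounding logical; if `TRUE`, age raises both case odds
#'   (accelerating after 35) and diagnosis odds, confounding the crude OR.
#' @return data frame with columns `y`, `dx`, `age`, `race`, `ethnicity`,
#'   `n_visits`.
#' @export
simulate_association_data <- function(n, prevalence = 0.10, or = 2.0,
                                      case_rate = 0.2, age_confounding = FALSE) {
  age <- pmin(pmax(stats::rnorm(n, 33, 5), 15), 44)
  race <- sample(c("White", "Asian", "Other Race", "Black or African American"),
                 n, replace = TRUE, prob = c(0.5, 0.22, 0.2, 0.08))
  ethnicity <- sample(c("Not Hispanic or Latino", "Hispanic or Latino", "Unknown"),
                      n, replace = TRUE, prob = c(0.77, 0.16, 0.07))
  if (age_confounding) {
    lp_case <- case_age_logodds(age)
    lp_case <- lp_case - mean(lp_case) + stats::qlogis(case_rate)
  } else {
    lp_case <- rep(stats::qlogis(case_rate), n)
  }
  y <- as.integer(stats::runif(n) < stats::plogis(lp_case))
  age_term <- if (age_confounding) 0.08 * (age - 33) else rep(0, n)
  lp_dx <- stats::qlogis(prevalence) + log(or) * y + age_term
  dx <- as.integer(stats::runif(n) < stats::plogis(lp_dx))
  visits <- 1L + stats::rpois(n, 20)
  data.frame(y = y, dx = dx, age = age, race = race, ethnicity = ethnicity,
             n_visits = visits, stringsAsFactors = FALSE)
}

#' Write a generated center to disk in the interchange layout
#'
#' Writes the three EHR CSVs, the concept sets, the fixture crosswalk for
#' the planted panel, and `ground_truth.json`.
#'
#' @param center list from [generate_center()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_center <- function(center, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bundle(center$bundle, dir)
  write_concept_sets(default_concept_sets(), file.path(dir, "concept_sets.csv"))
  map <- panel_phecode_map(center$truth$planted)
  utils::write.csv(as.data.frame(map)[, c("icd_code", "icd_flavor", "phecode",
                                          "phecode_string", "category")],
                   file.path(dir, "phecode_map_v1_2.csv"), row.names = FALSE)
  gt <- center$truth
  gt$patients$index_date <- as.character(gt$patients$index_date)
  gt$presence <- NULL
  gt$config$diagnoses <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
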