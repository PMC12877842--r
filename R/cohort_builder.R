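# Patient selection: RPL case and live-birth control definitions, index
# dates, the exclusion cascade, subgroup variants, and next-pregnancy
# outcome lookup.
#
# Conventions (documented because the source phrasing leaves them open):
#  * the 90-day distinct-loss comparison is inclusive (>= 90 days);
#  * gaps are measured from the START of the previous accepted loss event
#    (greedy anchor scan), for both the two-loss and three-loss rules;
#  * a history-of-loss record must be strictly before the qualifying loss;
#  * ages use 365.25-day years.

DAYS_PER_YEAR <- 365.25

#' Collapse loss records into distinct loss events
#'
#' Greedy left-to-right scan: the first date starts event 1; each later
#' date starts a new event iff it is at least `min_gap_days` after the
#' start date of the previous accepted event. Records closer than the gap
#' are treated as duplicate records of the same loss.
#'
#' @param loss_dates `Date` vector sorted ascending.
#' @param min_gap_days minimum day gap between event starts (default 90).
#' @return `Date` vector of accepted event start dates.
#' @export
distinct_loss_events <- function(loss_dates, min_gap_days = 90) {
  if (length(loss_dates) == 0L) return(loss_dates)
  stopifnot(min_gap_days >= 0)
  if (is.unsorted(loss_dates)) {
    stop("loss_dates must be sorted ascending", call. = FALSE)
  }
  keep <- logical(length(loss_dates))
  keep[1] <- TRUE
  anchor <- loss_dates[1]
  for (i in seq_along(loss_dates)[-1]) {
    if (as.numeric(loss_dates[i] - anchor) >= min_gap_days) {
      keep[i] <- TRUE
      anchor <- loss_dates[i]
    }
  }
  loss_dates[keep]
}

# Split condition rows by person once; returns list keyed by person_id.
conditions_by_person <- function(bundle) {
  split(bundle$conditions[, c("concept_id", "condition_start_date")],
        bundle$conditions$person_id)
}

#' Select RPL (case) candidates with index dates
#'
#' A patient qualifies through any of: (a) an explicit RPL diagnosis record
#' (qualifying date: that record's date); (b) a pregnancy loss dated
#' strictly after a history-of-pregnancy-loss record (qualifying date: the
#' loss date); (c) at least `min_events` distinct loss events under the
#' 90-day rule (qualifying date: the date of the event that completes the
#' count). The index date is the earliest qualifying date.
#'
#' @param bundle `ehr_bundle`.
#' @param concept_sets `concept_sets` with `rpl_diagnosis`, `pregnancy_loss`
#'   and `history_of_loss`.
#' @param min_gap_days distinct-event gap (default 90).
#' @param min_events number of distinct loss events required by criterion
#'   (c); 2 for the main analysis, 3 for the severe-RPL subgroup (which
#'   drops criteria (a) and (b)).
#' @return data frame of pre-exclusion cohort members (`group = "rpl"`).
#' @export
select_rpl <- function(bundle, concept_sets, min_gap_days = 90, min_events = 2L) {
  by_person <- conditions_by_person(bundle)
  severe <- min_events > 2L
  rows <- lapply(names(by_person), function(pid) {
    rec <- by_person[[pid]]
    loss_dates <- sort(rec$condition_start_date[rec$concept_id %in% concept_sets$pregnancy_loss])
    events <- distinct_loss_events(loss_dates, min_gap_days)
    qualifying <- as.Date(character(0))
    if (!severe) {
      qualifying <- c(qualifying,
        rec$condition_start_date[rec$concept_id %in% concept_sets$rpl_diagnosis])
      hx <- rec$condition_start_date[rec$concept_id %in% concept_sets$history_of_loss]
      if (length(hx) > 0 && length(loss_dates) > 0) {
        after_hx <- loss_dates[loss_dates > min(hx)]
        if (length(after_hx) > 0) qualifying <- c(qualifying, min(after_hx))
      }
    }
    if (length(events) >= min_events) {
      qualifying <- c(qualifying, events[min_events])
    }
    if (length(qualifying) == 0L) return(NULL)
    data.frame(person_id = pid, group = "rpl",
               index_date = min(as.Date(qualifying, origin = "1970-01-01")),
               n_distinct_losses = length(events), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), group = character(0),
                      index_date = as.Date(character(0)),
                      n_distinct_losses = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Select live-birth control candidates with index dates
#'
#' Controls have at least one live-birth record and no control-exclusion
#' record (pregnancy loss, preterm birth/labor, premature rupture of
#' membranes, multiple gestation with loss, molar or extrauterine
#' pregnancy) anywhere in their history. Index date is the first live
#' birth.
#'
#' @param bundle `ehr_bundle`.
#' @param concept_sets `concept_sets` with `live_birth` and
#'   `control_exclusion`.
#' @return data frame of pre-exclusion members (`group = "control"`) with
#'   attribute `n_excluded_by_concept`: candidates with a live birth that
#'   were removed for carrying an exclusion concept.
#' @export
select_controls <- function(bundle, concept_sets) {
  by_person <- conditions_by_person(bundle)
  n_removed <- 0L
  rows <- lapply(names(by_person), function(pid) {
    rec <- by_person[[pid]]
    births <- rec$condition_start_date[rec$concept_id %in% concept_sets$live_birth]
    if (length(births) == 0L) return(NULL)
    if (any(rec$concept_id %in% concept_sets$control_exclusion)) {
      n_removed <<- n_removed + 1L
      return(NULL)
    }
    data.frame(person_id = pid, group = "control", index_date = min(births),
               n_distinct_losses = 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), group = character(0),
                      index_date = as.Date(character(0)),
                      n_distinct_losses = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "n_excluded_by_concept") <- n_removed
  out
}

#' Apply the post-selection exclusion cascade
#'
#' In flowchart order: (1) age at index outside [15, 44] years
#' (age = days from birth date to index / 365.25); (2) neither recorded
#' female gender nor any incident-pregnancy record; (3) total record span
#' of 100 or more years; (4) no ICD diagnosis inside the study window
#' (unbounded past through index + `window_days`; outcome concepts do not
#' count as ICD diagnoses). Also attaches the covariates used downstream:
#' age, race, ethnicity, visit count and record-years inside the window.
#'
#' @param members pre-exclusion members from [select_rpl()] /
#'   [select_controls()].
#' @param bundle `ehr_bundle`.
#' @param concept_sets `concept_sets` (for the incident-pregnancy rule and
#'   for identifying non-ICD outcome concepts).
#' @param window_days study window end offset after index (default 365).
#' @return list with `cohort` (data frame of retained members with
#'   covariates) and `report` (data frame of per-arm removal counts).
#' @export
apply_exclusions <- function(members, bundle, concept_sets, window_days = 365) {
  persons <- bundle$persons
  pi <- match(members$person_id, persons$person_id)
  if (anyNA(pi)) stop("cohort member absent from person table", call. = FALSE)
  members$age_at_index <-
    as.numeric(members$index_date - persons$birth_date[pi]) / DAYS_PER_YEAR
  members$race <- persons$race[pi]
  members$ethnicity <- persons$ethnicity[pi]
  gender <- persons$gender[pi]

  outcome_concepts <- unique(unlist(concept_sets))
  by_person <- conditions_by_person(bundle)
  n0 <- nrow(members)
  report <- data.frame(criterion = character(0), n_removed = integer(0))
  note <- function(criterion, removed) {
    report <<- rbind(report, data.frame(criterion = criterion,
                                        n_removed = sum(removed)))
  }

  # (1) age bounds
  keep <- members$age_at_index >= 15 & members$age_at_index <= 44
  note("age_outside_15_44", !keep)
  members <- members[keep, ]; gender <- gender[keep]

  # (2) gender / incident pregnancy
  has_incident <- vapply(members$person_id, function(pid) {
    rec <- by_person[[pid]]
    !is.null(rec) && any(rec$concept_id %in% concept_sets$incident_pregnancy)
  }, logical(1))
  keep <- gender == "female" | has_incident
  note("not_female_no_incident_pregnancy", !keep)
  members <- members[keep, ]

  # (3) record span >= 100 years
  span_years <- vapply(members$person_id, function(pid) {
    d <- by_person[[pid]]$condition_start_date
    v <- bundle$visits$visit_start_date[bundle$visits$person_id == pid]
    d <- c(d, v)
    if (length(d) == 0L) return(0)
    as.numeric(max(d) - min(d)) / DAYS_PER_YEAR
  }, numeric(1))
  keep <- span_years < 100
  note("record_span_100y_or_more", !keep)
  members <- members[keep, ]

  # (4) at least one ICD diagnosis inside the study window
  window_end <- members$index_date + window_days
  icd_in_window <- vapply(seq_len(nrow(members)), function(i) {
    rec <- by_person[[members$person_id[i]]]
    icd <- rec[!(rec$concept_id %in% outcome_concepts), , drop = FALSE]
    any(icd$condition_start_date <= window_end[i])
  }, logical(1))
  note("no_diagnoses_in_study_window", !icd_in_window)
  members <- members[icd_in_window, ]

  # covariates measured inside the study window
  window_end <- members$index_date + window_days
  members$n_visits_in_window <- vapply(seq_len(nrow(members)), function(i) {
    v <- bundle$visits$visit_start_date[bundle$visits$person_id == members$person_id[i]]
    sum(v <= window_end[i])
  }, numeric(1))
  members$ehr_years_in_window <- vapply(seq_len(nrow(members)), function(i) {
    rec <- by_person[[members$person_id[i]]]
    d <- c(rec$condition_start_date,
           bundle$visits$visit_start_date[bundle$visits$person_id == members$person_id[i]])
    d <- d[d <= window_end[i]]
    if (length(d) == 0L) return(0)
    as.numeric(max(d) - min(d)) / DAYS_PER_YEAR
  }, numeric(1))

  stopifnot(n0 - sum(report$n_removed) == nrow(members))
  rownames(members) <- NULL
  list(cohort = members, report = report)
}

#' Build a full case-control cohort from a bundle
#'
#' Runs selection and the exclusion cascade for both groups and asserts
#' case/control disjointness (guaranteed structurally, since controls
#' exclude all loss records).
#'
#' @param bundle `ehr_bundle`.
#' @param concept_sets `concept_sets`.
#' @param variant `"main"` (RPL diagnosis / history+loss / >= 2 losses) or
#'   `"severe"` (>= 3 distinct losses only; same controls).
#' @param min_gap_days distinct-loss gap (default 90).
#' @param window_days study window end offset (default 365).
#' @return list with `cohort` (data frame), `report` (per-group exclusion
#'   arms, including the control exclusion-concept arm).
#' @export
build_cohort <- function(bundle, concept_sets, variant = c("main", "severe"),
                         min_gap_days = 90, window_days = 365) {
  variant <- match.arg(variant)
  min_events <- if (variant == "severe") 3L else 2L
  rpl <- select_rpl(bundle, concept_sets, min_gap_days, min_events)
  ctl <- select_controls(bundle, concept_sets)
  if (length(intersect(rpl$person_id, ctl$person_id)) > 0L) {
    stop("case and control groups overlap", call. = FALSE)
  }
  ex_rpl <- apply_exclusions(rpl, bundle, concept_sets, window_days)
  ex_ctl <- apply_exclusions(ctl, bundle, concept_sets, window_days)
  report <- rbind(
    data.frame(group = "control", criterion = "exclusion_concept_in_history",
               n_removed = attr(ctl, "n_excluded_by_concept")),
    cbind(group = "rpl", ex_rpl$report),
    cbind(group = "control", ex_ctl$report)
  )
  cohort <- rbind(ex_rpl$cohort, ex_ctl$cohort)
  rownames(cohort) <- NULL
  list(cohort = cohort, report = report)
}

#' Restrict a cohort to patients with >= 10 years of pre-index records
#'
#' @param cohort cohort data frame.
#' @param bundle `ehr_bundle`.
#' @param min_years required pre-index record history (default 10 years =
#'   3652 days).
#' @return subset of `cohort`.
#' @export
select_ten_year_subgroup <- function(cohort, bundle, min_years = 10) {
  by_person <- conditions_by_person(bundle)
  first_rec <- vapply(cohort$person_id, function(pid) {
    d <- c(by_person[[pid]]$condition_start_date,
           bundle$visits$visit_start_date[bundle$visits$person_id == pid])
    as.numeric(min(d))
  }, numeric(1))
  keep <- first_rec <= as.numeric(cohort$index_date) - floor(min_years * DAYS_PER_YEAR)
  out <- cohort[keep, ]
  rownames(out) <- NULL
  out
}

#' Find each RPL patient's next recorded pregnancy outcome
#'
#' The earliest birth-or-loss record dated at least `min_days` after the
#' patient's index date; patients with no such record are omitted. A birth
#' and a loss recorded on the same (earliest) date are classified as a
#' loss and flagged ambiguous.
#'
#' @param rpl_cohort cohort rows with `group == "rpl"`.
#' @param bundle `ehr_bundle`.
#' @param concept_sets `concept_sets`.
#' @param min_days minimum days after index (default 30).
#' @return data frame with `person_id`, `outcome` (`"birth"`/`"loss"`),
#'   `outcome_date`, `ambiguous`.
#' @export
find_next_outcome <- function(rpl_cohort, bundle, concept_sets, min_days = 30) {
  rpl_cohort <- rpl_cohort[rpl_cohort$group == "rpl", ]
  by_person <- conditions_by_person(bundle)
  rows <- lapply(seq_len(nrow(rpl_cohort)), function(i) {
    pid <- rpl_cohort$person_id[i]
    cutoff <- rpl_cohort$index_date[i] + min_days
    rec <- by_person[[pid]]
    births <- rec$condition_start_date[rec$concept_id %in% concept_sets$live_birth]
    losses <- rec$condition_start_date[rec$concept_id %in% concept_sets$pregnancy_loss]
    births <- births[births >= cutoff]
    losses <- losses[losses >= cutoff]
    if (length(births) == 0L && length(losses) == 0L) return(NULL)
    d_birth <- if (length(births) > 0) min(births) else as.Date(Inf, origin = "1970-01-01")
    d_loss <- if (length(losses) > 0) min(losses) else as.Date(Inf, origin = "1970-01-01")
    ambiguous <- is.finite(d_birth) && is.finite(d_loss) && d_birth == d_loss
    outcome <- if (d_loss <= d_birth) "loss" else "birth"
    data.frame(person_id = pid, outcome = outcome,
               outcome_date = min(d_birth, d_loss), ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), outcome = character(0),
                      outcome_date = as.Date(character(0)), ambiguous = logical(0))
  }
  rownames(out) <- NULL
  out
}
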