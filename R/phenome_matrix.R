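# Windowed ICD extraction, Phecode aggregation, and the patients x
# diagnoses presence matrix. The study window runs from the unbounded past
# through index_date + window_days (inclusive); presence is any-occurrence
# (one-hot), and a candidate diagnosis is any phecode carried by at least
# one cohort patient inside the window.

#' Extract a patient's in-window ICD codes
#'
#' Codes with `condition_start_date <= index_date + window_days`; records
#' carrying pregnancy-outcome concepts (anything in the concept sets) are
#' not ICD diagnoses and are ignored.
#'
#' @param conditions condition rows for one patient (data frame with
#'   `concept_id`, `condition_start_date`).
#' @param index_date the patient's index date.
#' @param outcome_concepts character vector of non-ICD concept ids.
#' @param window_days window end offset (default 365).
#' @return character vector of distinct ICD codes.
#' @export
extract_window_codes <- function(conditions, index_date, outcome_concepts = character(0),
                                 window_days = 365) {
  in_window <- conditions$condition_start_date <= index_date + window_days
  codes <- conditions$concept_id[in_window]
  sort(unique(codes[!(codes %in% outcome_concepts)]))
}

#' Build the patients x Phecode presence matrix
#'
#' Maps each patient's in-window ICD codes through the crosswalk
#' (dot-insensitively), unions the mapped phecodes per patient, and keeps
#' as candidate columns every phecode present in at least one patient.
#' ICD codes with no crosswalk entry are tallied in a coverage report
#' rather than silently dropped.
#'
#' @param cohort cohort data frame (from [build_cohort()]).
#' @param bundle `ehr_bundle`.
#' @param phecode_map `phecode_map`.
#' @param concept_sets `concept_sets`; outcome concepts are excluded from
#'   ICD extraction.
#' @param window_days study window end offset (default 365).
#' @return object of class `phenome_matrix`: list with `presence` (binary
#'   integer matrix, patients x phecodes), `patients` (cohort rows, matrix
#'   row order), `diagnoses` (phecode, phecode_string, category,
#'   n_rpl_with, n_control_with), `coverage` (unmapped code tallies).
#' @export
build_matrix <- function(cohort, bundle, phecode_map, concept_sets,
                         window_days = 365) {
  if (!all(cohort$person_id %in% bundle$persons$person_id)) {
    stop("cohort contains person_ids absent from the bundle", call. = FALSE)
  }
  outcome_concepts <- unique(unlist(concept_sets))
  by_person <- conditions_by_person(bundle)
  lookup <- split(phecode_map$phecode, phecode_map$icd_norm)

  unmapped <- list()
  per_patient <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- by_person[[cohort$person_id[i]]]
    if (is.null(rec)) return(character(0))
    codes <- extract_window_codes(rec, cohort$index_date[i], outcome_concepts,
                                  window_days)
    norm <- normalize_icd(codes)
    hits <- lookup[norm]
    miss <- codes[vapply(hits, is.null, logical(1))]
    if (length(miss) > 0) unmapped[[length(unmapped) + 1L]] <<- miss
    sort(unique(unlist(hits)))
  })

  phecodes <- sort(unique(unlist(per_patient)))
  presence <- matrix(0L, nrow = nrow(cohort), ncol = length(phecodes),
                     dimnames = list(cohort$person_id, phecodes))
  for (i in seq_along(per_patient)) {
    presence[i, per_patient[[i]]] <- 1L
  }

  ann <- phecode_annotation(phecode_map)
  ann <- ann[match(phecodes, ann$phecode), ]
  is_rpl <- cohort$group == "rpl"
  diagnoses <- data.frame(
    phecode = phecodes,
    phecode_string = ann$phecode_string,
    category = ann$category,
    n_rpl_with = as.integer(colSums(presence[is_rpl, , drop = FALSE])),
    n_control_with = as.integer(colSums(presence[!is_rpl, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
  unmapped <- unlist(unmapped)
  coverage <- if (length(unmapped) > 0) {
    as.data.frame(table(code = unmapped), stringsAsFactors = FALSE)
  } else {
    data.frame(code = character(0), Freq = integer(0))
  }
  names(coverage) <- c("code", "n_records")

  structure(list(presence = presence, patients = cohort,
                 diagnoses = diagnoses, coverage = coverage),
            class = "phenome_matrix")
}

#' Construct a `phenome_matrix` from pre-built components
#'
#' Used by simulation studies that plant presence indicators directly
#' without assembling condition records.
#'
#' @param presence binary matrix, patients x phecodes (dimnames set).
#' @param patients data frame with at least `person_id`, `group`,
#'   `age_at_index`, `race`, `ethnicity` (and `n_visits_in_window` if
#'   visit-adjusted models will be fit).
#' @param diagnoses data frame with `phecode`, `phecode_string`,
#'   `category`; carrier counts are recomputed.
#' @return `phenome_matrix`.
#' @export
new_phenome_matrix <- function(presence, patients, diagnoses) {
  stopifnot(nrow(presence) == nrow(patients), ncol(presence) == nrow(diagnoses))
  is_rpl <- patients$group == "rpl"
  diagnoses$n_rpl_with <- as.integer(colSums(presence[is_rpl, , drop = FALSE]))
  diagnoses$n_control_with <- as.integer(colSums(presence[!is_rpl, , drop = FALSE]))
  dimnames(presence) <- list(patients$person_id, diagnoses$phecode)
  structure(list(presence = presence, patients = patients,
                 diagnoses = diagnoses,
                 coverage = data.frame(code = character(0), n_records = integer(0))),
            class = "phenome_matrix")
}

#' @export
print.phenome_matrix <- function(x, ...) {
  cat(sprintf("<phenome_matrix>: %d patients (%d RPL / %d control) x %d candidate diagnoses\n",
              nrow(x$presence), sum(x$patients$group == "rpl"),
              sum(x$patients$group != "rpl"), ncol(x$presence)))
  if (nrow(x$coverage) > 0) {
    cat(sprintf("  %d distinct unmapped ICD codes (see $coverage)\n", nrow(x$coverage)))
  }
  invisible(x)
}

#' Subset a phenome matrix by patient rows
#'
#' @param pm `phenome_matrix`.
#' @param keep logical or integer row index.
#' @param drop_empty drop diagnosis columns with no remaining carriers.
#' @return `phenome_matrix`.
#' @export
subset_patients <- function(pm, keep, drop_empty = TRUE) {
  presence <- pm$presence[keep, , drop = FALSE]
  patients <- pm$patients[keep, ]
  diagnoses <- pm$diagnoses
  if (drop_empty) {
    nonzero <- colSums(presence) > 0
    presence <- presence[, nonzero, drop = FALSE]
    diagnoses <- diagnoses[nonzero, ]
  }
  rownames(patients) <- NULL
  rownames(diagnoses) <- NULL
  new_phenome_matrix(presence, patients, diagnoses)
}

#' Drop all diagnosis columns of one phecode category
#'
#' Used before embedding so the two-dimensional layout reflects diagnoses
#' leading to the outcome rather than diagnoses indicating it. Patient
#' rows are retained even if all their diagnoses are removed.
#'
#' @param pm `phenome_matrix`.
#' @param category category label to remove (default
#'   `"pregnancy complications"`).
#' @return `phenome_matrix` without the category's columns.
#' @export
drop_category <- function(pm, category = "pregnancy complications") {
  keep <- !(tolower(pm$diagnoses$category) %in% tolower(category))
  out <- pm
  out$presence <- pm$presence[, keep, drop = FALSE]
  out$diagnoses <- pm$diagnoses[keep, ]
  rownames(out$diagnoses) <- NULL
  out
}

#' Write the matrix and per-diagnosis counts as CSV
#'
#' @param pm `phenome_matrix`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_matrix <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- data.frame(person_id = pm$patients$person_id,
                     group = pm$patients$group, pm$presence,
                     check.names = FALSE)
  p1 <- file.path(dir, "phenome_matrix.csv")
  p2 <- file.path(dir, "diagnosis_counts.csv")
  utils::write.csv(wide, p1, row.names = FALSE)
  utils::write.csv(pm$diagnoses, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
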