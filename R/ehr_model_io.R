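# OMOP-lite data model: flat person / condition_occurrence / visit_occurrence
# tables, curated pregnancy-outcome concept sets, and the ICD->Phecode
# crosswalk. All interchange is headered CSV; dates are ISO-8601 calendar
# dates (day resolution).

CONCEPT_SET_NAMES <- c(
  "rpl_diagnosis", "pregnancy_loss", "history_of_loss",
  "live_birth", "control_exclusion", "incident_pregnancy"
)

#' Parse a character vector of ISO-8601 dates, reporting bad rows
#'
#' @param x character vector.
#' @param what column name used in error messages.
#' @return `Date` vector.
#' @noRd
parse_iso_dates <- function(x, what) {
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unparseable date in column '%s' at data row(s): %s",
      what, paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "file '%s' is missing required column(s): %s",
      file, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

#' Read one center's EHR extract into a validated bundle
#'
#' Reads the three OMOP-style tables and returns an `ehr_bundle`. Condition
#' and visit rows whose `person_id` is absent from the person table are
#' dropped and counted in the bundle's load report (`attr(x, "load_report")`).
#'
#' @param person_path CSV with columns `person_id`, `birth_date`, `gender`,
#'   `race`, `ethnicity`.
#' @param condition_path CSV with columns `person_id`, `concept_id`,
#'   `condition_start_date`.
#' @param visit_path CSV with columns `person_id`, `visit_start_date`, or
#'   `NULL` for a center with no visit extract.
#' @param center_label short label for the source center (e.g. `"center_A"`).
#' @return An object of class `ehr_bundle`: a list with elements `center`,
#'   `persons`, `conditions`, `visits`.
#' @export
read_bundle <- function(person_path, condition_path, visit_path = NULL,
                        center_label = "center") {
  persons <- utils::read.csv(person_path, colClasses = "character")
  require_columns(persons, c("person_id", "birth_date", "gender", "race", "ethnicity"),
                  person_path)
  persons$birth_date <- parse_iso_dates(persons$birth_date, "birth_date")

  conditions <- utils::read.csv(condition_path, colClasses = "character")
  require_columns(conditions, c("person_id", "concept_id", "condition_start_date"),
                  condition_path)
  conditions$condition_start_date <-
    parse_iso_dates(conditions$condition_start_date, "condition_start_date")

  if (!is.null(visit_path) && file.exists(visit_path)) {
    visits <- utils::read.csv(visit_path, colClasses = "character")
    require_columns(visits, c("person_id", "visit_start_date"), visit_path)
    visits$visit_start_date <- parse_iso_dates(visits$visit_start_date, "visit_start_date")
  } else {
    visits <- data.frame(person_id = character(0),
                         visit_start_date = as.Date(character(0)))
  }

  new_bundle(persons, conditions, visits, center_label)
}

#' Construct an `ehr_bundle` from in-memory tables
#'
#' Orphan condition/visit rows (person_id not in the person table) are
#' dropped; their counts are stored in the `load_report` attribute.
#'
#' @param persons,conditions,visits data frames in the documented layouts.
#' @param center_label center label string.
#' @return `ehr_bundle` object.
#' @export
new_bundle <- function(persons, conditions, visits = NULL, center_label = "center") {
  stopifnot(is.data.frame(persons), is.data.frame(conditions))
  if (is.null(visits)) {
    visits <- data.frame(person_id = character(0),
                         visit_start_date = as.Date(character(0)))
  }
  if (anyDuplicated(persons$person_id)) {
    stop("duplicate person_id in person table", call. = FALSE)
  }
  if (any(!nzchar(as.character(conditions$concept_id)))) {
    stop("empty concept_id in condition table", call. = FALSE)
  }
  known <- persons$person_id
  orphan_cond <- !(conditions$person_id %in% known)
  orphan_vis <- !(visits$person_id %in% known)
  bundle <- structure(
    list(
      center = center_label,
      persons = persons[, c("person_id", "birth_date", "gender", "race", "ethnicity")],
      conditions = conditions[!orphan_cond,
                              c("person_id", "concept_id", "condition_start_date")],
      visits = visits[!orphan_vis, c("person_id", "visit_start_date")]
    ),
    class = "ehr_bundle"
  )
  rownames(bundle$conditions) <- NULL
  rownames(bundle$visits) <- NULL
  attr(bundle, "load_report") <- list(
    n_persons = nrow(persons),
    n_conditions = sum(!orphan_cond),
    n_visits = sum(!orphan_vis),
    orphan_conditions = sum(orphan_cond),
    orphan_visits = sum(orphan_vis)
  )
  bundle
}

#' @export
print.ehr_bundle <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf(
    "<ehr_bundle '%s'>: %d persons, %d condition rows, %d visit rows\n",
    x$center, nrow(x$persons), nrow(x$conditions), nrow(x$visits)
  ))
  if (!is.null(rep) && (rep$orphan_conditions > 0 || rep$orphan_visits > 0)) {
    cat(sprintf("  dropped orphans: %d condition, %d visit\n",
                rep$orphan_conditions, rep$orphan_visits))
  }
  invisible(x)
}

#' Write a bundle back to the three-table CSV layout
#'
#' @param bundle `ehr_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("person.csv", "condition_occurrence.csv",
                            "visit_occurrence.csv"))
  utils::write.csv(bundle$persons, paths[1], row.names = FALSE)
  utils::write.csv(bundle$conditions, paths[2], row.names = FALSE)
  utils::write.csv(bundle$visits, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read curated pregnancy-outcome concept sets
#'
#' The file mirrors the layout of published OMOP concept lists: one row per
#' (set, concept) with columns `set_name`, `concept_id`, `concept_name`.
#' Duplicate concept ids within a set are collapsed.
#'
#' @param path CSV path.
#' @return named list of character vectors (class `concept_sets`), one per
#'   distinct `set_name`.
#' @export
read_concept_sets <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("set_name", "concept_id", "concept_name"), path)
  if (nrow(df) == 0L) {
    warning("concept set file is empty: ", path, call. = FALSE)
    return(structure(list(), class = "concept_sets"))
  }
  unknown <- setdiff(unique(df$set_name), CONCEPT_SET_NAMES)
  if (length(unknown) > 0L) {
    stop(sprintf(
      "unknown concept set name(s): %s; allowed names are: %s",
      paste(unknown, collapse = ", "),
      paste(CONCEPT_SET_NAMES, collapse = ", ")
    ), call. = FALSE)
  }
  sets <- lapply(split(df$concept_id, df$set_name), function(x) sort(unique(x)))
  structure(sets, class = "concept_sets")
}

#' Write concept sets in the interchange layout
#'
#' @param sets named list of concept id vectors.
#' @param path output CSV path.
#' @export
write_concept_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(names(sets), function(nm) {
    data.frame(set_name = nm, concept_id = sets[[nm]],
               concept_name = sets[[nm]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Strip punctuation from ICD codes so dotted and undotted dialects match
#'
#' @param code character vector of ICD codes.
#' @return normalized codes (uppercased, dots removed).
#' @export
normalize_icd <- function(code) {
  toupper(gsub("[.]", "", trimws(as.character(code))))
}

#' Read an ICD->Phecode crosswalk (Phecode map v1.2 column layout)
#'
#' Columns: `icd_code`, `icd_flavor` (9 or 10), `phecode`, `phecode_string`,
#' `category`. Identical duplicate rows are silently deduplicated; two rows
#' assigning different categories to the same phecode are an error. Codes are
#' matched dot-insensitively.
#'
#' @param path CSV path.
#' @return data frame of class `phecode_map` with an added `icd_norm` column.
#' @export
read_phecode_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  require_columns(df, c("icd_code", "icd_flavor", "phecode", "phecode_string",
                        "category"), path)
  new_phecode_map(df)
}

#' Construct a phecode map from a data frame
#'
#' @param df data frame with the v1.2-layout columns.
#' @return `phecode_map` object.
#' @export
new_phecode_map <- function(df) {
  df <- df[, c("icd_code", "icd_flavor", "phecode", "phecode_string", "category")]
  df <- unique(df)
  if (any(!nzchar(df$category) & nzchar(df$phecode))) {
    stop("phecode map has mapped rows with empty category", call. = FALSE)
  }
  cat_per_code <- tapply(df$category, df$phecode, function(x) length(unique(x)))
  if (any(cat_per_code > 1L)) {
    stop(sprintf("conflicting category for phecode(s): %s",
                 paste(names(cat_per_code)[cat_per_code > 1L], collapse = ", ")),
         call. = FALSE)
  }
  df$icd_norm <- normalize_icd(df$icd_code)
  structure(df, class = c("phecode_map", "data.frame"))
}

#' Look up the phecodes mapped to an ICD code
#'
#' @param map `phecode_map`.
#' @param code ICD code (dotted or undotted).
#' @param flavor ICD flavor, 9 or 10; `NULL` matches either.
#' @return character vector of phecodes (possibly empty).
#' @export
phecode_lookup <- function(map, code, flavor = NULL) {
  hit <- map$icd_norm == normalize_icd(code)
  if (!is.null(flavor)) hit <- hit & map$icd_flavor == as.character(flavor)
  sort(unique(map$phecode[hit]))
}

#' Per-phecode annotation table (one row per distinct phecode)
#' @param map `phecode_map`.
#' @return data frame with `phecode`, `phecode_string`, `category`.
#' @export
phecode_annotation <- function(map) {
  ann <- unique(as.data.frame(map)[, c("phecode", "phecode_string", "category")])
  ann <- ann[order(ann$phecode), ]
  rownames(ann) <- NULL
  ann
}
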