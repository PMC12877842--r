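# Association between previously validated diagnoses and the outcome
# (loss vs live birth) of RPL patients' next recorded pregnancy.

#' Next-pregnancy outcome analysis
#'
#' For each diagnosis in the supplied validated set, tests its association
#' with the outcome of RPL patients' next pregnancy (loss = 1 vs
#' birth = 0) using the same confounder-adjusted additive model as the
#' main analysis. A diagnosis counts as present if the patient has any
#' mapped record strictly before their outcome date. BH adjustment is
#' applied within this family; redaction follows the shared small-cell
#' policy.
#'
#' @param rpl_cohort cohort rows (`group == "rpl"`) with covariates.
#' @param outcomes table from [find_next_outcome()].
#' @param bundle `ehr_bundle`.
#' @param phecode_map `phecode_map`.
#' @param validated data frame with `phecode` and `direction` (the main
#'   analysis direction, `"positive"`/`"negative"`), i.e. the validated
#'   diagnosis set this analysis is restricted to.
#' @param concept_sets `concept_sets` (outcome concepts are not ICD codes).
#' @param spec `model_spec`.
#' @return data frame: per-diagnosis OR for loss, CI, p, `p_adj`,
#'   `concordant_with_main` (sign agreement with the supplied main
#'   direction), convergence and redaction flags.
#' @export
run_next_pregnancy <- function(rpl_cohort, outcomes, bundle, phecode_map,
                               validated, concept_sets, spec = model_spec()) {
  if (nrow(validated) == 0L) stop("validated diagnosis set is empty", call. = FALSE)
  rpl_cohort <- rpl_cohort[rpl_cohort$group == "rpl", ]
  design <- merge(outcomes, rpl_cohort, by = "person_id")
  stopifnot(nrow(design) == nrow(outcomes))

  outcome_concepts <- unique(unlist(concept_sets))
  by_person <- conditions_by_person(bundle)
  lookup <- split(phecode_map$phecode, phecode_map$icd_norm)

  presence <- matrix(0L, nrow(design), nrow(validated),
                     dimnames = list(design$person_id, validated$phecode))
  for (i in seq_len(nrow(design))) {
    rec <- by_person[[design$person_id[i]]]
    before <- rec$condition_start_date < design$outcome_date[i]
    codes <- rec$concept_id[before]
    codes <- codes[!(codes %in% outcome_concepts)]
    phe <- unique(unlist(lookup[normalize_icd(codes)]))
    presence[i, validated$phecode %in% phe] <- 1L
  }

  y <- as.integer(design$outcome == "loss")
  n_loss <- sum(y); n_birth <- sum(1 - y)
  rows <- lapply(seq_len(nrow(validated)), function(j) {
    adj <- fit_adjusted(y, presence[, j], design$age_at_index, design$race,
                        design$ethnicity, spec = spec)
    n_with_loss <- sum(presence[y == 1, j])
    n_with_birth <- sum(presence[y == 0, j])
    cbind(data.frame(phecode = validated$phecode[j],
                     main_direction = validated$direction[j],
                     n_loss_with = n_with_loss, n_birth_with = n_with_birth),
          adj)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res$direction <- ifelse(!is.na(res$p_adj) & res$p_adj < spec$alpha,
                          ifelse(res$or_value > 1, "positive", "negative"),
                          "null")
  # OR here is for subsequent loss; a positive main (RPL risk) association
  # is concordant when the diagnosis also raises the odds of loss
  res$concordant_with_main <- ifelse(
    is.na(res$or_value), NA,
    (res$or_value > 1) == (res$main_direction == "positive")
  )
  res$redacted <- pmin(res$n_loss_with, res$n_birth_with,
                       n_loss - res$n_loss_with,
                       n_birth - res$n_birth_with) < spec$redaction_threshold
  attr(res, "n_loss") <- n_loss
  attr(res, "n_birth") <- n_birth
  res
}
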