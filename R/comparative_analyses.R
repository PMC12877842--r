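# Age-stratified analysis with effect-heterogeneity z-tests, the
# healthcare-utilization sensitivity analysis (odds-ratio percent change),
# within-center union comparisons, and cross-center concordance.

#' Age-stratified association analysis with coefficient z-tests
#'
#' Splits the cohort at `cutoff` years of age at index, runs an
#' independent association sweep in each stratum (restricted to candidate
#' diagnoses carried by at least one patient in BOTH strata), and tests
#' effect heterogeneity per diagnosis with a two-sided z-test on the
#' diagnosis coefficients:
#' `z = (beta_young - beta_old) / sqrt(se_young^2 + se_old^2)`.
#' The z-test p-values are BH-adjusted as their own family.
#'
#' @param pm `phenome_matrix`.
#' @param spec `model_spec`.
#' @param cutoff age cutoff in years (default 35; strata are `<cutoff` and
#'   `>=cutoff`).
#' @return list with `results_young`, `results_old` (association tables)
#'   and `comparison` (per-diagnosis z-test table).
#' @export
stratify_and_test <- function(pm, spec = model_spec(), cutoff = 35) {
  young <- pm$patients$age_at_index < cutoff
  if (sum(pm$patients$group[young] == "rpl") == 0 ||
      sum(pm$patients$group[!young] == "rpl") == 0) {
    stop("each age stratum must contain at least one case", call. = FALSE)
  }
  testable <- colSums(pm$presence[young, , drop = FALSE]) > 0 &
    colSums(pm$presence[!young, , drop = FALSE]) > 0
  pm_y <- subset_patients(pm, young, drop_empty = FALSE)
  pm_o <- subset_patients(pm, !young, drop_empty = FALSE)
  pm_y <- subset_diagnoses(pm_y, testable)
  pm_o <- subset_diagnoses(pm_o, testable)

  res_y <- run_phewas(pm_y, spec)
  res_o <- run_phewas(pm_o, spec)

  z <- (res_y$beta - res_o$beta) / sqrt(res_y$se^2 + res_o$se^2)
  comparison <- data.frame(
    phecode = res_y$phecode,
    phecode_string = res_y$phecode_string,
    beta_young = res_y$beta, se_young = res_y$se,
    beta_old = res_o$beta, se_old = res_o$se,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  comparison$p_adj <- bh_adjust(comparison$p)
  comparison$higher_stratum <- ifelse(
    is.na(z) | z == 0, "tie",
    ifelse(z > 0, sprintf("under%d", cutoff), sprintf("over%d", cutoff))
  )
  list(results_young = res_y, results_old = res_o, comparison = comparison)
}

# Restrict a phenome matrix to a logical column mask.
subset_diagnoses <- function(pm, keep) {
  out <- pm
  out$presence <- pm$presence[, keep, drop = FALSE]
  out$diagnoses <- pm$diagnoses[keep, ]
  rownames(out$diagnoses) <- NULL
  out
}

#' Healthcare-utilization sensitivity analysis
#'
#' Re-runs the association sweep with the in-window visit count added as a
#' covariate and summarizes how adjusted odds ratios change:
#' `pct_change = 100 * (or_with_visits - or_without) / or_without` per
#' diagnosis (negative values = attenuation toward the null), with the
#' median taken over the union of diagnoses significant in either fit.
#' Non-converged fits are excluded from the median and counted in the
#' diagnostics.
#'
#' @param pm `phenome_matrix` (patients must carry `n_visits_in_window`).
#' @param spec `model_spec` for the base fit; the visit-adjusted fit uses
#'   the same spec with `use_visits = TRUE`.
#' @return list with `per_diagnosis` (paired ORs and percent changes),
#'   `median_pct_change`, `union_significant` (phecodes), `results_without`,
#'   `results_with`, `n_nonconverged`.
#' @export
utilization_sensitivity <- function(pm, spec = model_spec()) {
  spec_v <- spec
  spec_v$use_visits <- TRUE
  res0 <- run_phewas(pm, spec)
  res1 <- run_phewas(pm, spec_v)
  stopifnot(identical(res0$phecode, res1$phecode))

  ok <- res0$converged & res1$converged
  pct <- 100 * (res1$or_value - res0$or_value) / res0$or_value
  sig0 <- !is.na(res0$p_adj) & res0$p_adj < spec$alpha
  sig1 <- !is.na(res1$p_adj) & res1$p_adj < spec$alpha
  union_sig <- res0$phecode[(sig0 | sig1) & ok]

  per <- data.frame(
    phecode = res0$phecode, phecode_string = res0$phecode_string,
    or_without = res0$or_value, or_with = res1$or_value,
    pct_change = pct,
    significant_without = sig0, significant_with = sig1,
    converged_both = ok,
    stringsAsFactors = FALSE
  )
  in_union <- per$phecode %in% union_sig
  list(
    per_diagnosis = per,
    median_pct_change = if (any(in_union)) stats::median(per$pct_change[in_union]) else NA_real_,
    union_significant = union_sig,
    results_without = res0,
    results_with = res1,
    n_nonconverged = sum(!ok)
  )
}

#' Cross-center concordance of association results
#'
#' Classifies each candidate diagnosis shared between two centers'
#' analyses: `validated_positive` / `validated_negative` (significant at
#' both with the same direction), `discordant` (significant at both,
#' opposite directions), `single_center_only` (significant at exactly
#' one), `neither`. Computes the Spearman rank correlation of odds ratios
#' over the both-significant set and flags diagnoses passing the
#' >= 10-patients-in-either-group-at-both-centers plot filter.
#'
#' @param results_a,results_b association tables from [run_phewas()] for
#'   the two centers.
#' @param alpha significance threshold on adjusted p-values.
#' @param min_count plot-filter count (default 10).
#' @return list with `table` (per-diagnosis classes), `spearman_r`,
#'   `spearman_p`, `n_shared`, `class_counts`.
#' @export
compare_centers <- function(results_a, results_b, alpha = 0.05, min_count = 10) {
  shared <- intersect(results_a$phecode, results_b$phecode)
  if (length(shared) == 0L) stop("no shared candidate diagnoses", call. = FALSE)
  a <- results_a[match(shared, results_a$phecode), ]
  b <- results_b[match(shared, results_b$phecode), ]

  sig_a <- !is.na(a$p_adj) & a$p_adj < alpha & a$converged
  sig_b <- !is.na(b$p_adj) & b$p_adj < alpha & b$converged
  pos_a <- a$or_value > 1
  pos_b <- b$or_value > 1

  class <- rep("neither", length(shared))
  class[xor(sig_a, sig_b)] <- "single_center_only"
  both <- sig_a & sig_b
  class[both & pos_a == pos_b & pos_a] <- "validated_positive"
  class[both & pos_a == pos_b & !pos_a] <- "validated_negative"
  class[both & pos_a != pos_b] <- "discordant"

  tab <- data.frame(
    phecode = shared, phecode_string = a$phecode_string,
    or_a = a$or_value, p_adj_a = a$p_adj,
    or_b = b$or_value, p_adj_b = b$p_adj,
    class = class,
    plot_filter = (pmax(a$n_rpl_with, a$n_control_with) >= min_count) &
      (pmax(b$n_rpl_with, b$n_control_with) >= min_count),
    stringsAsFactors = FALSE
  )

  if (sum(both) >= 3) {
    ct <- suppressWarnings(stats::cor.test(a$or_value[both], b$or_value[both],
                                           method = "spearman"))
    sp_r <- unname(ct$estimate)
    sp_p <- ct$p.value
  } else {
    sp_r <- NA_real_
    sp_p <- NA_real_
  }
  list(table = tab, spearman_r = sp_r, spearman_p = sp_p,
       n_shared = length(shared),
       class_counts = table(factor(class, levels = c(
         "validated_positive", "validated_negative", "discordant",
         "single_center_only", "neither"))))
}

#' Union comparison of a main analysis with a variant analysis
#'
#' Takes the union of diagnoses significant in either analysis, pairs
#' their odds ratios, computes Spearman correlation over the union, and
#' returns a log-log plot table with the >= 10-patient filter flag.
#'
#' @param results_main,results_variant association tables sharing a
#'   candidate set.
#' @param alpha significance threshold.
#' @param min_count plot-filter count.
#' @return list with `table`, `union_phecodes`, `spearman_r`, `spearman_p`.
#' @export
compare_within <- function(results_main, results_variant, alpha = 0.05,
                           min_count = 10) {
  shared <- intersect(results_main$phecode, results_variant$phecode)
  m <- results_main[match(shared, results_main$phecode), ]
  v <- results_variant[match(shared, results_variant$phecode), ]
  sig_m <- !is.na(m$p_adj) & m$p_adj < alpha & m$converged
  sig_v <- !is.na(v$p_adj) & v$p_adj < alpha & v$converged
  in_union <- sig_m | sig_v
  tab <- data.frame(
    phecode = shared[in_union],
    phecode_string = m$phecode_string[in_union],
    or_main = m$or_value[in_union], or_variant = v$or_value[in_union],
    significant_main = sig_m[in_union], significant_variant = sig_v[in_union],
    plot_filter = (pmax(m$n_rpl_with, m$n_control_with)[in_union] >= min_count) &
      (pmax(v$n_rpl_with, v$n_control_with)[in_union] >= min_count),
    stringsAsFactors = FALSE
  )
  if (nrow(tab) >= 3) {
    ct <- suppressWarnings(stats::cor.test(tab$or_main, tab$or_variant,
                                           method = "spearman"))
    sp_r <- unname(ct$estimate); sp_p <- ct$p.value
  } else {
    sp_r <- NA_real_; sp_p <- NA_real_
  }
  list(table = tab, union_phecodes = tab$phecode,
       spearman_r = sp_r, spearman_p = sp_p)
}
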