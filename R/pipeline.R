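# Study orchestration: run every enabled analysis for one or two centers
# from a single configuration, writing CSV result tables and a run
# manifest. All randomness flows from one root seed. The package's R
# functions (plus scripts/acceptance.R in the repository) are the
# command-line surface; each stage below is also callable on its own.

#' Demo two-center study configuration
#'
#' Two synthetic centers sharing the planted diagnosis panel but differing
#' in their case/control visit-count gap: center A has nearly equal
#' utilization between groups (like a center where cases and controls both
#' average ~41-42 visits), center B a large gap (like ~31 vs ~14). Center
#' B also carries a positive utilization link so visit-driven diagnosis
#' intensity is present where the gap is.
#'
#' @param seed root seed; per-center seeds are derived from it.
#' @param n_rpl,n_control per-center group sizes.
#' @param utilization_link_strength link strength used at both centers.
#' @return list of two `synth_config` objects.
#' @export
demo_center_configs <- function(seed = 1L, n_rpl = 600L, n_control = 2400L,
                                utilization_link_strength = 0.6) {
  list(
    center_A = synth_config(
      seed = seed * 1000L + 1L, n_rpl = n_rpl, n_control = n_control,
      center_label = "center_A", visit_mean_control = 41,
      visit_case_multiplier = 1.04,
      utilization_link_strength = utilization_link_strength
    ),
    center_B = synth_config(
      seed = seed * 1000L + 2L, n_rpl = n_rpl, n_control = n_control,
      center_label = "center_B", visit_mean_control = 14,
      visit_case_multiplier = 2.2,
      utilization_link_strength = utilization_link_strength
    )
  )
}

run_step <- function(manifest, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  manifest$steps[[name]] <- if (res$ok) "ok" else paste("failed:", res$value)
  list(manifest = manifest, value = if (res$ok) res$value else NULL)
}

#' Run the full study on one or two centers
#'
#' For each center: generate (or accept pre-built) data, build the main
#' cohort, assemble the phenome matrix, and run the enabled analyses
#' (main association sweep, age-stratified z-tests, utilization
#' sensitivity, severe-RPL and 10-year subgroups, UMAP embedding). With
#' two centers, cross-center concordance is computed; the next-pregnancy
#' analysis runs on the first center's validated set. A failing analysis
#' is recorded in the manifest and does not abort the others.
#'
#' @param configs list of `synth_config` objects (or lists with elements
#'   `bundle`/`truth` from [generate_center()]), named by center.
#' @param out_dir output directory for CSV tables and the manifest; `NULL`
#'   to skip writing.
#' @param spec `model_spec` shared by all analyses.
#' @param analyses character vector of toggles among `"main"`, `"strata"`,
#'   `"sensitivity"`, `"severe"`, `"ten_year"`, `"embedding"`,
#'   `"next_pregnancy"`, `"concordance"`.
#' @param embed_seed seed for the UMAP stage.
#' @return list with per-center results, cross-center comparison, and the
#'   run manifest.
#' @export
run_rpl_study <- function(configs, out_dir = NULL, spec = model_spec(),
                          analyses = c("main", "strata", "sensitivity",
                                       "severe", "ten_year", "embedding",
                                       "next_pregnancy", "concordance"),
                          embed_seed = 42) {
  manifest <- list(package_version = as.character(utils::packageVersion("rplphewas")),
                   analyses = analyses, steps = list(), counts = list())
  cs <- default_concept_sets()
  centers <- list()

  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    center <- if (inherits(cfg, "synth_config")) generate_center(cfg) else cfg
    bundle <- center$bundle
    map <- panel_phecode_map(if (!is.null(center$truth)) center$truth$planted
                             else default_diagnosis_panel())
    built <- build_cohort(bundle, cs, variant = "main")
    pm <- build_matrix(built$cohort, bundle, map, cs)
    res <- list(bundle = bundle, truth = center$truth, cohort = built$cohort,
                exclusions = built$report, matrix = pm)
    manifest$counts[[nm]] <- list(
      n_rpl = sum(built$cohort$group == "rpl"),
      n_control = sum(built$cohort$group == "control"),
      n_candidates = ncol(pm$presence)
    )

    if ("main" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":main"), run_phewas(pm, spec))
      manifest <- st$manifest; res$main <- st$value
    }
    if ("strata" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":strata"),
                     stratify_and_test(pm, spec))
      manifest <- st$manifest; res$strata <- st$value
    }
    if ("sensitivity" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":sensitivity"),
                     utilization_sensitivity(pm, spec))
      manifest <- st$manifest; res$sensitivity <- st$value
    }
    if ("severe" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":severe"), {
        sev <- build_cohort(bundle, cs, variant = "severe")
        pm_sev <- build_matrix(sev$cohort, bundle, map, cs)
        list(cohort = sev$cohort, results = run_phewas(pm_sev, spec))
      })
      manifest <- st$manifest; res$severe <- st$value
    }
    if ("ten_year" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":ten_year"), {
        sub <- select_ten_year_subgroup(built$cohort, bundle)
        if (sum(sub$group == "rpl") > 0 && sum(sub$group == "control") > 0) {
          pm_sub <- build_matrix(sub, bundle, map, cs)
          list(cohort = sub, results = run_phewas(pm_sub, spec))
        } else {
          list(cohort = sub, results = NULL)
        }
      })
      manifest <- st$manifest; res$ten_year <- st$value
    }
    if ("embedding" %in% analyses) {
      st <- run_step(manifest, paste0(nm, ":embedding"), {
        emb <- embed_patients(drop_category(pm), seed = embed_seed)
        tests <- rbind(
          cbind(comparison = "rpl_vs_control",
                ranksum_by_group(emb, emb$group)),
          cbind(comparison = "under35_vs_over35",
                ranksum_by_group(emb, emb$stratum))
        )
        list(embedding = emb, tests = tests)
      })
      manifest <- st$manifest; res$embedding <- st$value
    }
    centers[[nm]] <- res
  }

  study <- list(centers = centers)

  if ("concordance" %in% analyses && length(centers) >= 2 &&
      !is.null(centers[[1]]$main) && !is.null(centers[[2]]$main)) {
    st <- run_step(manifest, "concordance",
                   compare_centers(centers[[1]]$main, centers[[2]]$main,
                                   alpha = spec$alpha))
    manifest <- st$manifest; study$concordance <- st$value
  }

  if ("next_pregnancy" %in% analyses && !is.null(centers[[1]]$main)) {
    st <- run_step(manifest, "next_pregnancy", {
      first <- centers[[1]]
      main <- first$main
      validated <- if (!is.null(study$concordance)) {
        tab <- study$concordance$table
        keep <- tab$class %in% c("validated_positive", "validated_negative")
        data.frame(phecode = tab$phecode[keep],
                   direction = ifelse(tab$class[keep] == "validated_positive",
                                      "positive", "negative"))
      } else {
        keep <- main$direction != "null"
        data.frame(phecode = main$phecode[keep], direction = main$direction[keep])
      }
      if (nrow(validated) == 0) stop("no validated diagnoses to carry forward")
      rpl <- first$cohort[first$cohort$group == "rpl", ]
      outcomes <- find_next_outcome(rpl, first$bundle, cs)
      map <- panel_phecode_map(if (!is.null(first$truth)) first$truth$planted
                               else default_diagnosis_panel())
      list(outcomes = outcomes,
           results = run_next_pregnancy(rpl, outcomes, first$bundle, map,
                                        validated, cs, spec))
    })
    manifest <- st$manifest; study$next_pregnancy <- st$value
  }

  study$manifest <- manifest
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write study result tables and the manifest
#'
#' Association tables are exported through [format_results()] so the
#' small-cell redaction policy applies to everything that leaves the
#' package.
#'
#' @param study result of [run_rpl_study()].
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  for (nm in names(study$centers)) {
    ctr <- study$centers[[nm]]
    wr(ctr$exclusions, sprintf("exclusion_report_%s.csv", nm))
    wr(ctr$matrix$diagnoses, sprintf("diagnosis_counts_%s.csv", nm))
    if (!is.null(ctr$main)) {
      wr(format_results(ctr$main), sprintf("associations_main_%s.csv", nm))
      wr(plot_table(ctr$main), sprintf("plot_main_%s.csv", nm))
    }
    if (!is.null(ctr$strata)) {
      wr(ctr$strata$comparison, sprintf("strata_comparison_%s.csv", nm))
    }
    if (!is.null(ctr$sensitivity)) {
      wr(ctr$sensitivity$per_diagnosis, sprintf("sensitivity_%s.csv", nm))
    }
    if (!is.null(ctr$severe)) {
      wr(format_results(ctr$severe$results), sprintf("associations_severe_%s.csv", nm))
    }
    if (!is.null(ctr$ten_year) && !is.null(ctr$ten_year$results)) {
      wr(format_results(ctr$ten_year$results), sprintf("associations_ten_year_%s.csv", nm))
    }
    if (!is.null(ctr$embedding)) {
      wr(ctr$embedding$embedding, sprintf("embedding_%s.csv", nm))
      wr(ctr$embedding$tests, sprintf("embedding_tests_%s.csv", nm))
    }
  }
  if (!is.null(study$concordance)) wr(study$concordance$table, "concordance.csv")
  if (!is.null(study$next_pregnancy)) {
    wr(study$next_pregnancy$results, "next_pregnancy_results.csv")
  }
  jsonlite::write_json(study$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
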