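# rplphewas

A case-control phenome-wide association (PheWAS) pipeline for discovering
diagnoses associated with **recurrent pregnancy loss (RPL)** — two or more
pregnancy losses — in observational electronic health records.

RPL affects roughly 5–6% of ever-pregnant individuals and about half of
cases have no identified cause. This package provides, as tested and
reusable R code, the full analytic chain needed to screen a health
system's diagnosis histories for RPL-associated conditions:

* **Cohort phenotyping** from OMOP-style flat tables (person,
  condition_occurrence, visit_occurrence): RPL cases via an explicit RPL
  diagnosis, a loss after a recorded history of loss, or ≥ 2 *distinct*
  loss events (loss records ≥ 90 days apart, measured from the start of
  the previous accepted event); live-birth controls with a clean outcome
  history; index dating; and the exclusion cascade (age 15–44 at index,
  female or incident-pregnancy evidence, record span < 100 years, ≥ 1
  in-window ICD diagnosis).
* **Phecode aggregation**: all ICD-9/10(-CM) diagnoses from the unbounded
  past through one year after the index date, mapped dot-insensitively
  through a Phecode v1.2-layout crosswalk and one-hot encoded.
* **Association testing**: for each candidate diagnosis *d*, the crude
  2×2 odds ratio and the confounder-adjusted additive logistic model

  ```
  logit P(case) = β_d · x_d + s(age) + race + ethnicity [+ log(1+visits)]
  ```

  fit with `mgcv::gam` (cubic regression spline on age, df = 4 by
  default), Wald 95% CIs, Benjamini–Hochberg FDR within each analysis
  family, and small-cell redaction (< 10 patients ⇒ only directional
  bounds such as `">1"`, `"<0.05"` are exported).
* **Comparative analyses**: age-stratified sweeps (< 35 vs 35+) with
  two-sided z-tests on the diagnosis coefficients; a healthcare
  utilization sensitivity analysis (median % change in ORs after adding
  the visit-count covariate); union comparisons; and cross-center
  concordance (validated positive / validated negative / discordant,
  Spearman correlation of odds ratios).
* **UMAP embedding** of non-pregnancy diagnosis profiles with Wilcoxon
  rank-sum tests on the coordinates.
* **Next-pregnancy analysis**: association of previously validated
  diagnoses with loss vs birth in RPL patients' next recorded pregnancy.
* **A two-center synthetic EHR generator** with planted odds ratios,
  configurable case/control visit-count gaps, a nonlinear maternal-age
  effect, duplicate loss records, and exclusion-triggering edge cases —
  so the entire pipeline is testable without access to protected data.

## Worked example

Generate one synthetic center, build its cohort, and run the main
association sweep:

```r
library(rplphewas)

cfg    <- synth_config(seed = 20, n_rpl = 400, n_control = 1600,
                       center_label = "demo")
center <- generate_center(cfg)
cs     <- default_concept_sets()

built <- build_cohort(center$bundle, cs)
pm    <- build_matrix(built$cohort, center$bundle,
                      panel_phecode_map(cfg$diagnoses), cs)
pm
#> <phenome_matrix>: 2000 patients (400 RPL / 1600 control) x 26 candidate diagnoses

res <- run_phewas(pm)
head(res[order(res$p_adj),
         c("phecode", "phecode_string", "or_value", "ci_low", "ci_high",
           "p_adj", "direction")], 6)
#>    phecode                phecode_string or_value ci_low ci_high    p_adj direction
#> 16     650               Normal delivery    0.172  0.114   0.261 2.83e-15  negative
#> 5    277.7       Dysmetabolic syndrome X    7.405  4.517  12.141 1.79e-14  positive
#> 12     628           Infertility, female    5.146  3.436   7.705 1.79e-14  positive
#> 13     640 Hemorrhage in early pregnancy    6.430  4.002  10.332 9.42e-14  positive
#> 8      615                 Endometriosis    2.921  1.974   4.323 4.25e-07  positive
#> 6   286.81 Primary hypercoagulable state    4.287  2.348   7.826 9.27e-06  positive
```

Each row is one candidate diagnosis: `or_value` is the adjusted odds
ratio for RPL (here the generator planted, e.g., OR 5.0 for
"Dysmetabolic syndrome X" and 0.14 for "Normal delivery", so the sweep
is recovering the planted structure), `p_adj` is the BH-adjusted
p-value, and `direction` is the significance classification at
`p_adj < 0.05`. `format_results(res)` produces the export view with the
small-cell redaction policy applied.

A full two-center study — both centers, sensitivity analysis,
cross-center concordance, and the next-pregnancy analysis, with all CSV
tables and a run manifest written to `out/`:

```r
study <- run_rpl_study(demo_center_configs(seed = 1), out_dir = "out")
study$concordance$spearman_r
study$centers$center_B$sensitivity$median_pct_change
```

## Data formats

| file | required columns |
|---|---|
| `person.csv` | `person_id`, `birth_date`, `gender`, `race`, `ethnicity` |
| `condition_occurrence.csv` | `person_id`, `concept_id`, `condition_start_date` |
| `visit_occurrence.csv` | `person_id`, `visit_start_date` |
| `concept_sets.csv` | `set_name`, `concept_id`, `concept_name` |
| `phecode_map_v1_2.csv` | `icd_code`, `icd_flavor`, `phecode`, `phecode_string`, `category` |

Dates are ISO-8601 (`YYYY-MM-DD`). A small synthetic fixture crosswalk
and concept-set file ship under `inst/extdata/`. See
`vignettes/rpl-phewas-methods.Rmd` for the model, its assumptions, the
conventions adopted where the design was open, and known limitations.
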