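---
title: "Methods: case-control PheWAS of recurrent pregnancy loss from EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control PheWAS of recurrent pregnancy loss from EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design

`rplphewas` implements a retrospective case-control comparison of diagnosis
histories between patients with recurrent pregnancy loss (RPL, two or more
pregnancy losses) and patients with a live birth, from OMOP-style electronic
health record extracts. The unit of analysis is a (patient, diagnosis) pair:
every candidate diagnosis — an ICD code aggregated to a Phecode — is tested
for association with case status, one model per diagnosis, with
Benjamini-Hochberg control of the false discovery rate across the family.

The pipeline has five stages, each an independently callable module:

1. **Cohort phenotyping** (`build_cohort`): RPL cases qualify through an
   explicit RPL diagnosis record, a pregnancy loss dated after a recorded
   history of pregnancy loss, or at least two *distinct* loss events.
   Controls need a live-birth record and a history free of loss, preterm
   birth/labor, premature rupture of membranes, multiple gestation with
   loss, and molar or extrauterine pregnancy. Each patient is anchored at
   an index date (earliest qualifying date for cases, first live birth for
   controls), then an exclusion cascade removes patients aged outside
   15-44 years at index, patients neither recorded female nor carrying
   evidence of an incident pregnancy, patients with a biologically
   implausible record span of 100+ years, and patients with no ICD
   diagnosis in the study window.
2. **Phenome matrix** (`build_matrix`): all ICD diagnoses from the
   unbounded past through one year after the index date are mapped through
   the Phecode v1.2-layout crosswalk and one-hot encoded; any phecode
   carried by at least one cohort patient is a candidate.
3. **Association testing** (`run_phewas`): crude 2x2 odds ratios plus a
   confounder-adjusted additive logistic model per candidate.
4. **Comparative analyses**: age stratification with coefficient z-tests,
   the healthcare-utilization sensitivity analysis, and cross-center
   concordance.
5. **Synthetic data** (`generate_center`): a two-center generator with
   known planted effects, so that every stage above is testable without
   access to protected patient data.

# The adjusted model

For diagnosis $d$ with presence indicator $x_d$, the adjusted model is the
additive logistic regression

$$\operatorname{logit} P(\text{case}) = \beta_d x_d + s(\text{age}) +
\text{race} + \text{ethnicity} \;[+ \log(1+\text{visits})]$$

fit with `mgcv::gam`. The reported odds ratio is $e^{\hat\beta_d}$ with a
Wald 95% interval $e^{\hat\beta_d \pm 1.96\,\widehat{se}}$ and a two-sided
normal p-value.

Choices that the design left open, and how this package resolves them:

* **Age smooth.** Maternal age affects pregnancy-loss risk nonlinearly,
  with the slope steepening around age 35, so age always enters through a
  cubic regression spline. The default is a *fixed* 4 degrees of freedom
  (`mgcv` basis `"cr"`, `k = 5`, `fx = TRUE`), which captures one or two
  curvature changes while keeping fits fast and portable;
  `model_spec(penalized = TRUE)` switches to a penalized spline with
  smoothness chosen by generalized cross-validation. With
  `model_spec(age_smooth = "linear")` the model collapses to ordinary
  logistic regression — the test suite uses this to verify the GAM path
  against `glm()` to coefficient precision.
* **Reference levels.** Race and ethnicity use the largest category in
  the analysis sample as reference, which stabilizes fits in strata;
  missing values become an explicit `"Unknown"` level rather than being
  dropped.
* **Separation and degenerate cells.** Diagnoses present in (almost) only
  one group produce diverging coefficients. The package reports such fits
  as non-converged with direction preserved rather than applying a Firth
  or Bayesian correction by default, because penalization would silently
  shrink exactly the extreme, outcome-adjacent diagnoses (loss and
  delivery codes) whose extremity is informative. Flags propagate; the
  sweep never aborts.
* **Multiplicity.** BH is applied within each analysis family (main
  sweep, each age stratum, the z-test family, next-pregnancy) separately,
  via `stats::p.adjust(method = "BH")`; the test suite pins it against a
  brute-force step-up implementation written from the definition. All
  finite p-values enter the adjustment, including those from fits later
  flagged non-converged.
* **Redaction.** Any displayed count below 10 (carriers or non-carriers,
  in either group) marks the row as redacted; exported tables then show
  only directional bounds (`">1"`, `"<0.05"`) in place of exact values.
  Redaction is a display policy: classification is computed before
  masking and is never altered by it.

# Cohort conventions

* The 90-day duplicate-loss rule is inclusive (`>= 90` days) and greedy:
  gaps are measured from the *start* of the previous accepted loss event,
  for both the two-loss and the severe (three-loss) rule. This unifies
  the two phrasings of the rule and makes the event count monotone in the
  gap parameter (a property test).
* Criterion (b) requires the history-of-loss record strictly before the
  qualifying loss; a same-day pair does not qualify.
* For the two-loss criterion the index is the date of the *second*
  distinct event — the day the criterion is met. (The alternative reading,
  dating the index at the first loss, is a one-line change in
  `select_rpl`; it shifts index dates earlier but not membership.)
* Ages use 365.25-day years, the standard epidemiologic convention; the
  bounds 15 and 44 are inclusive.
* The study window end is index + 365 days, inclusive. The source design
  said "a year afterwards" without a day count; 365 is documented and
  configurable (`window_days`).
* Incident-pregnancy evidence (for retaining patients not recorded
  female) is the union of the loss and live-birth concept sets. An
  explicit RPL diagnosis alone is deliberately *not* treated as such
  evidence, so the gender rule retains a screen against miscoded records.
* A same-day birth + loss in the next-pregnancy lookup classifies as loss
  and is flagged ambiguous — conservative for an analysis whose outcome
  of interest is subsequent loss.

# The synthetic-data generator

`generate_center` plants marginal structure rather than simulating
obstetric biology: case status is drawn first, then records consistent
with it. It emulates the features of the two real study centers that
matter for the statistics:

* **Ages 15-44**, cases on average 3.2 years older, with the case
  propensity accelerating after age 35 (piecewise-smooth log-odds) — this
  is what the age spline must absorb.
* **Race/ethnicity mixes** matching the published demographics tables of
  a large academic center.
* **Overdispersed visit counts**: negative-binomial with a per-center
  case/control multiplier. The two demo centers use means 41 vs 14 and
  multipliers 1.04 vs 2.2, reproducing the pattern of one center where
  cases and controls have nearly equal utilization and one with a large
  gap.
* **Planted per-diagnosis odds ratios** on the logit scale (conditional
  on the covariates in the model), with baseline control prevalence
  calibrated by centering the extra age/utilization terms on controls.
* **Record realism**: duplicate loss records under 90 days apart,
  history-of-loss records, explicit RPL diagnosis records, and
  (via `inject_edge_cases`) patients designed to land in each exclusion
  arm.

What it does **not** emulate: ICD code frequency distributions, pregnancy
episodes and gestational age, correlated comorbidity structure, coding
drift over calendar time, or informative missingness. Passing tests on
generated data therefore demonstrate that the estimators recover known
effects under the stated confounding structure — not that any specific
clinical finding would replicate on real records.

`simulate_association_data` is the design-level shortcut used in the
estimator studies: it produces the covariates and a single planted
diagnosis without assembling records, which keeps replicate studies
(hundreds of GAM fits) fast.

# Comparative analyses

* **Age stratification** splits at 35 years at index, restricts to
  candidates carried in both strata, runs two independent sweeps, and
  tests heterogeneity with $z = (\hat\beta_{<35} - \hat\beta_{35+}) /
  \sqrt{se_{<35}^2 + se_{35+}^2}$, two-sided normal, BH-adjusted.
* **Utilization sensitivity** refits each candidate with
  $\log(1+\text{visits})$ added and summarizes
  $100\,(OR_{with} - OR_{without})/OR_{without}$; the median is taken
  over the union of diagnoses significant in either fit (negative =
  attenuation toward the null). Note that adding a covariate to a
  logistic model changes the estimand even absent confounding
  (noncollapsibility), so small positive medians at a no-gap center are
  expected behavior, not error.
* **Cross-center concordance** classifies each shared candidate as
  validated positive / validated negative / discordant / single-center /
  neither — the five classes partition the shared set — and reports the
  Spearman correlation of odds ratios over the both-significant set.
  Plot tables flag diagnoses with at least 10 carriers in either group
  at both centers.

# Embedding

UMAP (via `uwot`, single-threaded for determinism) embeds the one-hot
matrix after removal of the "pregnancy complications" category — the
module refuses matrices still containing it, since those diagnoses encode
the outcome itself. Coordinates are compared between groups with
two-sided Wilcoxon rank-sum tests on each dimension separately (the
design phrase "coordinate distributions" names no dimension; testing both
and reporting both is the conservative reading). Hyperparameters are the
common defaults (15 neighbors, min_dist 0.1, Euclidean) and are recorded
in the result metadata. Degenerate inputs (identical rows) fall back to
random initialization.

# Numerical and scale choices

Simulation sizes in the shipped tests and the acceptance script were
chosen as the smallest sizes at which the target property is cleanly
separated from Monte-Carlo noise on a single CPU:

* oracle equivalence (adjusted vs 2x2 OR, no confounding): 100 datasets
  of n = 5,000 — at this size nuisance-coefficient noise keeps the
  adjusted estimate within the 2% oracle band across all replicates;
* parameter recovery: 200 replicates of n = 10,000 at prevalence 0.10,
  planted OR 2.0;
* error control: 200 replicates of a 50-null-diagnosis sweep at n = 600,
  with the empirical FDR compared to the nominal level within two
  Monte-Carlo standard errors; z-test type-I error from 1,000
  equal-effect stratum pairs;
* sensitivity sweep: generated centers of 2,800 patients at utilization
  link strengths {0, 0.6, 1.2};
* demo study: two centers of 3,000 patients and ~26 candidate diagnoses.

# Known limitations

* The generator's planted odds ratios are conditional; marginal 2x2
  checks are only valid for diagnoses without age or utilization terms.
* Delivery detection relies on live-birth condition concepts alone; the
  original design additionally linked to a clinical data warehouse for
  deliveries, so next-pregnancy birth capture here is structurally more
  conservative.
* Candidate diagnoses are treated exchangeably; the Phecode hierarchy is
  not rolled up beyond the direct crosswalk, and temporal ordering inside
  the window is ignored (presence is any-occurrence).
* No mediation, interaction, or causal-effect machinery: the outputs are
  screened associations intended for hypothesis generation.
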