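# Per-diagnosis association models: crude 2x2 logistic odds ratios,
# confounder-adjusted additive (GAM) fits with maternal age entered as a
# cubic regression spline plus race and ethnicity, Benjamini-Hochberg FDR,
# direction classification, and small-cell redaction.

#' Specify the adjusted association model
#'
#' The additive logistic model is
#' `logit P(case) = beta * dx + s(age) + race + ethnicity [+ visits]`.
#' The age smooth is a cubic regression spline; by default it uses a fixed
#' 4 degrees of freedom, optionally penalized with smoothing chosen by
#' generalized cross-validation. Race/ethnicity reference levels are the
#' largest category in the analysis sample; missing values are kept as an
#' explicit `"Unknown"` level.
#'
#' @param age_smooth `"cr"` (cubic regression spline) or `"linear"` (age as
#'   a plain linear term — used mainly for validation against ordinary
#'   logistic regression).
#' @param age_df degrees of freedom of the fixed spline (default 4).
#' @param penalized if `TRUE`, the spline is penalized and its smoothness
#'   chosen by GCV instead of being fixed at `age_df`.
#' @param use_visits include the in-window visit count as a covariate
#'   (the healthcare-utilization sensitivity model).
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @param redaction_threshold counts below this are masked in exported
#'   result displays (default 10).
#' @return `model_spec` list.
#' @export
model_spec <- function(age_smooth = c("cr", "linear"), age_df = 4,
                       penalized = FALSE, use_visits = FALSE, alpha = 0.05,
                       redaction_threshold = 10) {
  structure(list(age_smooth = match.arg(age_smooth), age_df = age_df,
                 penalized = penalized, use_visits = use_visits,
                 alpha = alpha, redaction_threshold = redaction_threshold),
            class = "model_spec")
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (n11 * n00) / (n10 * n01)` with a Wald 95% confidence interval on
#' the log scale (equivalent to an intercept-plus-exposure logistic
#' regression). A zero cell makes the estimate degenerate: the result is
#' flagged non-converged, with the direction preserved.
#'
#' @param n11 exposed cases; @param n10 exposed controls;
#' @param n01 unexposed cases; @param n00 unexposed controls.
#' @return one-row data frame: `or_value`, `ci_low`, `ci_high`, `p`,
#'   `converged`.
#' @export
crude_or <- function(n11, n10, n01, n00) {
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  if (any(c(n11, n10, n01, n00) == 0)) {
    num <- n11 * n00; den <- n10 * n01
    or <- if (num == 0 && den == 0) NA_real_ else if (den == 0) Inf else 0
    return(data.frame(or_value = or, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, converged = FALSE))
  }
  log_or <- log(n11) + log(n00) - log(n10) - log(n01)
  se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  z <- log_or / se
  data.frame(or_value = exp(log_or),
             ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)),
             converged = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order. NA p-values (non-converged fits) stay NA and do
#' not count toward the number of tests.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Largest-category reference level, Unknown kept as explicit level.
as_covariate_factor <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "Unknown"
  tab <- sort(table(x), decreasing = TRUE)
  factor(x, levels = names(tab))
}

# Build the model formula for a given spec and data availability.
build_formula <- function(spec, data) {
  terms <- "dx"
  if (length(unique(data$age)) >= spec$age_df + 2 && spec$age_smooth == "cr") {
    fx <- if (spec$penalized) "" else ", fx = TRUE"
    terms <- c(terms, sprintf("s(age, bs = \"cr\", k = %d%s)", spec$age_df + 1, fx))
  } else {
    terms <- c(terms, "age")
  }
  if (nlevels(data$race) > 1) terms <- c(terms, "race")
  if (nlevels(data$ethnicity) > 1) terms <- c(terms, "ethnicity")
  if (spec$use_visits) terms <- c(terms, "log1p(n_visits)")
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Fit the confounder-adjusted association model for one diagnosis
#'
#' @param y 0/1 case indicator.
#' @param dx 0/1 diagnosis presence.
#' @param age numeric age at index.
#' @param race,ethnicity category vectors.
#' @param visits in-window visit counts (required when
#'   `spec$use_visits = TRUE`; entered as `log1p(visits)`).
#' @param spec `model_spec`.
#' @return one-row data frame: `beta`, `se`, `or_value`, `ci_low`,
#'   `ci_high`, `p`, `converged`.
#' @export
fit_adjusted <- function(y, dx, age, race, ethnicity, visits = NULL,
                         spec = model_spec()) {
  if (sum(y) == 0 || sum(1 - y) == 0) {
    stop("need at least one case and one control", call. = FALSE)
  }
  bad <- data.frame(
    beta = NA_real_, se = NA_real_, or_value = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p = NA_real_, converged = FALSE
  )
  if (length(unique(dx)) < 2) return(bad)
  data <- data.frame(y = y, dx = dx, age = age,
                     race = as_covariate_factor(race),
                     ethnicity = as_covariate_factor(ethnicity))
  if (spec$use_visits) {
    if (is.null(visits)) stop("spec requires visit counts", call. = FALSE)
    data$n_visits <- visits
  }
  form <- build_formula(spec, data)
  method <- if (spec$penalized) "GCV.Cp" else "REML"
  fit <- tryCatch(
    mgcv::gam(form, family = stats::binomial(), data = data, method = method),
    error = function(e) NULL
  )
  if (is.null(fit)) return(bad)
  beta <- unname(fit$coefficients["dx"])
  se <- unname(sqrt(diag(stats::vcov(fit))["dx"]))
  converged <- isTRUE(fit$converged) && is.finite(beta) && is.finite(se) &&
    se < 50 && abs(beta) < 15
  data.frame(
    beta = beta, se = se, or_value = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged
  )
}

#' Run the full association sweep over a phenome matrix
#'
#' Fits the crude 2x2 and confounder-adjusted models for every candidate
#' diagnosis column, applies Benjamini-Hochberg within this analysis
#' family, classifies directions at `spec$alpha`, and flags rows for
#' redaction wherever any displayed group count (carriers or
#' non-carriers, in either group) falls below the redaction threshold.
#' Per-diagnosis non-convergence is flagged, never fatal.
#'
#' @param pm `phenome_matrix`.
#' @param spec `model_spec`.
#' @return data frame of association results, one row per candidate.
#' @export
run_phewas <- function(pm, spec = model_spec()) {
  pat <- pm$patients
  y <- as.integer(pat$group == "rpl")
  n_rpl <- sum(y)
  n_ctl <- sum(1 - y)
  visits <- if (spec$use_visits) pat$n_visits_in_window else NULL

  rows <- lapply(seq_len(ncol(pm$presence)), function(j) {
    dxv <- pm$presence[, j]
    adj <- fit_adjusted(y, dxv, pat$age_at_index, pat$race, pat$ethnicity,
                        visits, spec)
    n11 <- sum(dxv[y == 1]); n10 <- sum(dxv[y == 0])
    cr <- crude_or(n11, n10, n_rpl - n11, n_ctl - n10)
    cbind(pm$diagnoses[j, c("phecode", "phecode_string", "category",
                            "n_rpl_with", "n_control_with")],
          adj,
          data.frame(crude_or_value = cr$or_value, crude_p = cr$p))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res$direction <- ifelse(
    !is.na(res$p_adj) & res$p_adj < spec$alpha,
    ifelse(res$or_value > 1, "positive", "negative"),
    "null"
  )
  thr <- spec$redaction_threshold
  res$redacted <- pmin(res$n_rpl_with, res$n_control_with,
                       n_rpl - res$n_rpl_with,
                       n_ctl - res$n_control_with) < thr
  attr(res, "n_rpl") <- n_rpl
  attr(res, "n_control") <- n_ctl
  attr(res, "alpha") <- spec$alpha
  res
}

#' Format association results for export, applying redaction
#'
#' Redacted rows are emitted only as directional bounds — the odds ratio
#' as `">1"` / `"<1"`, the p-value as `"<0.05"` / `">=0.05"` — and their
#' exact counts, CIs and p-values are masked. Significance classification
#' (`direction`) is unchanged by redaction.
#'
#' @param res result table from [run_phewas()].
#' @param alpha display threshold used in the p-value bound (default from
#'   the result's attribute, else 0.05).
#' @return data frame safe for export.
#' @export
format_results <- function(res, alpha = NULL) {
  if (is.null(alpha)) alpha <- attr(res, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  num <- function(x) ifelse(res$redacted, NA, x)
  sig <- !is.na(res$p_adj) & res$p_adj < alpha
  out <- data.frame(
    phecode = res$phecode, phecode_string = res$phecode_string,
    category = res$category,
    n_rpl_with = num(res$n_rpl_with), n_control_with = num(res$n_control_with),
    or_value = ifelse(res$redacted,
                      ifelse(is.na(res$or_value) | res$or_value > 1, ">1", "<1"),
                      as.character(res$or_value)),
    ci_low = num(res$ci_low), ci_high = num(res$ci_high),
    p = ifelse(res$redacted,
               ifelse(sig, sprintf("<%s", alpha), sprintf(">=%s", alpha)),
               as.character(res$p)),
    p_adj = ifelse(res$redacted,
                   ifelse(sig, sprintf("<%s", alpha), sprintf(">=%s", alpha)),
                   as.character(res$p_adj)),
    converged = res$converged, redacted = res$redacted,
    direction = res$direction,
    stringsAsFactors = FALSE
  )
  out
}

#' Plot-ready Manhattan/volcano table
#'
#' @param res result table from [run_phewas()].
#' @return data frame with `phecode`, `category`, `log10_or`,
#'   `neg_log10_p_adj`, `direction` (non-converged rows dropped).
#' @export
plot_table <- function(res) {
  ok <- res$converged & !res$redacted
  data.frame(
    phecode = res$phecode[ok], category = res$category[ok],
    log10_or = log10(res$or_value[ok]),
    neg_log10_p_adj = -log10(pmax(res$p_adj[ok], .Machine$double.xmin)),
    direction = res$direction[ok],
    stringsAsFactors = FALSE
  )
}
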