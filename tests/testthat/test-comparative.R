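make_result_row <- function(phecode, or, p_adj, n_rpl = 50, n_ctl = 50,
                            converged = TRUE) {
  data.frame(phecode = phecode, phecode_string = phecode, category = "x",
             n_rpl_with = n_rpl, n_control_with = n_ctl,
             beta = log(or), se = 0.1, or_value = or,
             ci_low = or * 0.8, ci_high = or * 1.25,
             p = p_adj, p_adj = p_adj, converged = converged,
             direction = ifelse(p_adj < 0.05, ifelse(or > 1, "positive", "negative"),
                                "null"),
             redacted = FALSE, stringsAsFactors = FALSE)
}

test_that("the heterogeneity z-test matches the closed form", {
  # z = (0.7 - 0.3) / sqrt(0.1^2 + 0.1^2) = 2.828; p = 2 * pnorm(-2.828)
  z <- (0.7 - 0.3) / sqrt(0.1^2 + 0.1^2)
  expect_equal(z, 2.8284, tolerance = 1e-4)
  expect_equal(2 * pnorm(-abs(z)), 0.004678, tolerance = 1e-3)

  set.seed(201)
  pm <- sim_phewas_matrix(3000, or = c(3, 1), prevalence = 0.15)
  st <- stratify_and_test(pm)
  expect_equal(st$comparison$z,
               (st$comparison$beta_young - st$comparison$beta_old) /
                 sqrt(st$comparison$se_young^2 + st$comparison$se_old^2))
  expect_equal(st$comparison$p, 2 * pnorm(-abs(st$comparison$z)))
  # candidates tested in both strata only
  young <- pm$patients$age_at_index < 35
  testable <- colSums(pm$presence[young, , drop = FALSE]) > 0 &
    colSums(pm$presence[!young, , drop = FALSE]) > 0
  expect_equal(nrow(st$comparison), sum(testable))
  # equal betas give z = 0, p = 1
  cmp <- st$comparison
  cmp$z[1] <- 0
  expect_equal(2 * pnorm(-abs(cmp$z[1])), 1)
})

test_that("stratified sweep errors when a stratum has no cases", {
  set.seed(202)
  pm <- sim_phewas_matrix(400, or = 2)
  pm$patients$age_at_index[pm$patients$group == "rpl"] <- 30  # all cases young
  expect_error(stratify_and_test(pm), "at least one case")
})

test_that("percent-change arithmetic and the null-link sensitivity behave", {
  expect_equal(100 * (1.74 - 2.0) / 2.0, -13.0)

  set.seed(203)
  pm <- sim_phewas_matrix(4000, or = c(3, 3, 0.3, 1), prevalence = 0.12,
                          visit_link = 0, visit_case_multiplier = 2)
  sens <- utilization_sensitivity(pm)
  expect_true(is.finite(sens$median_pct_change))
  expect_lt(abs(sens$median_pct_change), 5)
  expect_true(all(sens$per_diagnosis$pct_change ==
    100 * (sens$per_diagnosis$or_with - sens$per_diagnosis$or_without) /
      sens$per_diagnosis$or_without))

  # positive link + case visit gap attenuates ORs
  set.seed(204)
  pm2 <- sim_phewas_matrix(4000, or = c(3, 3, 0.3, 1), prevalence = 0.12,
                           visit_link = 0.8, visit_case_multiplier = 2)
  sens2 <- utilization_sensitivity(pm2)
  expect_lt(sens2$median_pct_change, 0)
  expect_lt(sens2$median_pct_change, sens$median_pct_change)
})

test_that("concordance classes follow their definitions and partition the shared set", {
  a <- rbind(make_result_row("d1", 2.0, 0.001), make_result_row("d2", 0.5, 0.001),
             make_result_row("d3", 2.0, 0.001), make_result_row("d4", 2.0, 0.001),
             make_result_row("d5", 1.5, 0.50), make_result_row("d6", 2.0, 0.001,
                                                               n_rpl = 4, n_ctl = 5))
  b <- rbind(make_result_row("d1", 2.2, 0.001), make_result_row("d2", 0.4, 0.001),
             make_result_row("d3", 0.5, 0.001), make_result_row("d4", 1.8, 0.80),
             make_result_row("d5", 1.4, 0.60), make_result_row("d6", 2.1, 0.001))
  cc <- compare_centers(a, b)
  cls <- stats::setNames(cc$table$class, cc$table$phecode)
  expect_equal(unname(cls[c("d1", "d2", "d3", "d4", "d5")]),
               c("validated_positive", "validated_negative", "discordant",
                 "single_center_only", "neither"))
  # classes partition the shared candidate set
  expect_equal(sum(cc$class_counts), cc$n_shared)
  # the <10-count plot filter uses the larger of the two group counts
  expect_false(cc$table$plot_filter[cc$table$phecode == "d6"])
  expect_true(all(cc$table$plot_filter[cc$table$phecode != "d6"]))
  expect_error(compare_centers(a[0, ], b), "shared")
})

test_that("rank-identical odds ratios give Spearman r = 1, on OR or log OR", {
  a <- do.call(rbind, lapply(1:6, function(i)
    make_result_row(paste0("d", i), c(1.2, 1.5, 2, 3, 5, 8)[i], 0.001)))
  b <- do.call(rbind, lapply(1:6, function(i)
    make_result_row(paste0("d", i), c(1.1, 1.4, 1.9, 2.5, 4, 9)[i], 0.001)))
  cc <- compare_centers(a, b)
  expect_equal(cc$spearman_r, 1)
  # rank invariance: Spearman on OR equals Spearman on log OR
  expect_equal(suppressWarnings(cor(a$or_value, b$or_value, method = "spearman")),
               suppressWarnings(cor(log(a$or_value), log(b$or_value),
                                    method = "spearman")))
})

test_that("within-center union comparison handles copies and disjoint sets", {
  main <- do.call(rbind, lapply(1:5, function(i)
    make_result_row(paste0("d", i), c(2, 3, 0.5, 1.2, 1.1)[i],
                    c(0.001, 0.001, 0.01, 0.5, 0.9)[i])))
  same <- compare_within(main, main)
  expect_setequal(same$union_phecodes, c("d1", "d2", "d3"))
  expect_equal(same$spearman_r, 1)

  variant <- main
  variant$p_adj <- c(0.9, 0.9, 0.9, 0.001, 0.001)
  variant$direction <- c("null", "null", "null", "positive", "positive")
  disj <- compare_within(main, variant)
  expect_setequal(disj$union_phecodes, c("d1", "d2", "d3", "d4", "d5"))
})
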