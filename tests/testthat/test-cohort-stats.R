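toy_table <- function(csa, gta, ifrom, group = NULL) {
  n <- length(csa)
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    group = group %||% rep(c("RCT", "CONTROL"), length.out = n),
    csa_deg = csa, gta_deg = gta, if_rom_deg = ifrom)
}

test_that("cohort table validation", {
  tb <- toy_table(c(40, 38, 36, 35), c(70, 72, 68, 66), c(50, 40, 120, 90))
  out <- cohort_table(tb)
  expect_equal(out$sum_deg, out$csa_deg + out$gta_deg)
  expect_error(cohort_table(tb[, -3]), "lacks column")
  bad <- tb; bad$group[1] <- "CASE"
  expect_error(cohort_table(bad), "RCT")
  bad2 <- tb; bad2$if_rom_deg[1] <- 150
  expect_error(cohort_table(bad2), "0, 120")
})

test_that("identical groups give t = 0, p = 1", {
  tb <- toy_table(rep(c(40, 38, 36), 2), rep(c(70, 72, 68), 2),
                  rep(c(50, 40, 90), 2),
                  group = rep(c("RCT", "CONTROL"), each = 3))
  gc <- group_compare(tb)
  expect_true(all(abs(gc$t_statistic) < 1e-12))
  expect_true(all(abs(gc$p_value - 1) < 1e-12))
})

test_that("the t statistic equals the hand-computed pooled formula on a 3+3 table", {
  x <- c(41, 44, 39); y <- c(36, 35, 38)
  tb <- toy_table(c(x, y), rep(70, 6), rep(60, 6),
                  group = rep(c("RCT", "CONTROL"), each = 3))
  gc <- group_compare(tb, vars = "csa_deg")
  sp2 <- ((3 - 1) * var(x) + (3 - 1) * var(y)) / (3 + 3 - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(gc$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(gc$df, 4)
  expect_equal(gc$mean_rct, mean(x))
  expect_equal(gc$sd_control, sd(y))
  # Welch option reported as such
  expect_equal(group_compare(tb, vars = "csa_deg", welch = TRUE)$test, "welch_t")
})

test_that("chi-square of proportions matches the closed-form statistic in both variants", {
  hand_chi2 <- function(M, yates) {
    E <- outer(rowSums(M), colSums(M)) / sum(M)
    adj <- if (yates) pmax(abs(M - E) - 0.5, 0) else abs(M - E)
    x2 <- sum(adj^2 / E)
    c(x2, pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # identical proportions
  r0 <- chi2_proportions(rbind(c(20, 20), c(10, 10)))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  # the two published contingency tables, each under its matching variant
  gender <- rbind(c(26, 18), c(11, 6))
  side <- rbind(c(25, 19), c(10, 7))
  rg <- chi2_proportions(gender, correction = TRUE)
  hg <- hand_chi2(gender, yates = TRUE)
  expect_equal(rg$chi2, hg[1], tolerance = 1e-12)
  expect_equal(rg$p_value, hg[2], tolerance = 1e-12)
  expect_equal(round(rg$p_value, 2), 0.91)
  rs <- chi2_proportions(side, correction = FALSE)
  hs <- hand_chi2(side, yates = FALSE)
  expect_equal(rs$chi2, hs[1], tolerance = 1e-12)
  expect_equal(round(rs$p_value, 2), 0.89)
  expect_error(chi2_proportions(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(chi2_proportions(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("correlation battery: analytic limits and rank identity", {
  x <- c(1, 2, 3, 4, 5, 6)
  tb <- toy_table(x, 2 * x + 1, 120 - 10 * x)
  cr <- correlation_battery(tb)
  pick <- function(v1, v2) cr[cr$var1 == v1 & cr$var2 == v2, ]
  expect_equal(pick("csa_deg", "gta_deg")$estimate, 1)           # y = 2x + 1
  expect_equal(pick("csa_deg", "if_rom_deg")$estimate, -1)       # strictly decreasing
  # monotone nonlinearity: Spearman 1, Pearson < 1
  tb2 <- toy_table(x, exp(x), 120 - 2^x)
  cr2 <- correlation_battery(tb2)
  expect_equal(cr2[cr2$var1 == "gta_deg", ]$estimate, -1)
  expect_lt(cr2[cr2$var1 == "csa_deg" & cr2$var2 == "gta_deg", ]$estimate, 1)
  expect_gt(cr2[cr2$var1 == "csa_deg" & cr2$var2 == "gta_deg", ]$estimate, 0.8)
  # Spearman equals Pearson on average ranks, exactly, including ties
  withr::with_seed(53, {
    xs <- sample(1:8, 30, replace = TRUE)
    ys <- sample(1:8, 30, replace = TRUE)
    expect_equal(cor(xs, ys, method = "spearman"),
                 cor(rank(xs), rank(ys)), tolerance = 1e-12)
  })
  cst <- toy_table(rep(40, 6), 2 * x, 120 - x)
  expect_error(correlation_battery(cst), "csa_deg")
})

test_that("a miniature end-to-end cohort completes with every report field", {
  res <- suppressWarnings(end_to_end_cohort(
    cohort_params(n_rct = 3, n_control = 3, edge_length = 2.5, seed = 2),
    simulation_config(step = 2)))
  expect_s3_class(res, "cohort_analysis")
  expect_equal(nrow(res$table), 6L)
  expect_equal(nrow(res$correlations), 4L)
  expect_true(all(c("csa_deg", "gta_deg", "sum_deg", "if_rom_deg") %in%
                    res$group_comparison$variable))
  expect_true(all(res$correlations$estimate >= -1 & res$correlations$estimate <= 1))
  expect_true(all(res$correlations$p_value >= 0 & res$correlations$p_value <= 1))
  g <- glance(res)
  expect_true(all(c("pearson_csa_gta", "spearman_sum_ifrom") %in% names(g)))
  expect_equal(nrow(tidy(res)), 6L)
  # measured angles track the generator targets
  expect_lt(max(abs(res$table$csa_deg - res$table$csa_target_deg)), 1)
  expect_lt(max(abs(res$table$gta_deg - res$table$gta_target_deg)), 1)
})

test_that("end-to-end runs are byte-identical under the same seed", {
  cp <- cohort_params(n_rct = 2, n_control = 2, edge_length = 3, seed = 9)
  r1 <- suppressWarnings(end_to_end_cohort(cp, simulation_config(step = 4)))
  r2 <- suppressWarnings(end_to_end_cohort(cp, simulation_config(step = 4)))
  expect_identical(r1$table, r2$table)
})
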