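test_that("covariate-adjusted t reduces to the plain pooled t", {
  set.seed(60)
  x <- rnorm(23); y <- rnorm(15, mean = 0.5)
  grp <- factor(rep(c("control", "patient"), c(23, 15)),
                levels = c("control", "patient"))
  fit <- covariate_adjusted_ttest(c(x, y), grp)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(fit$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(fit$p_raw, ref$p.value, tolerance = 1e-12)
  expect_equal(fit$direction,
               unname(ifelse(ref$statistic >= 0, "control_higher",
                             "patient_higher")))
})

test_that("regressing out a covariate removes its effect", {
  set.seed(61)
  grp <- factor(rep(c("control", "patient"), c(10, 10)),
                levels = c("control", "patient"))
  cov <- data.frame(age = rnorm(20, 25, 4))
  # values are exactly a linear function of the covariate
  fit <- covariate_adjusted_ttest(3 + 0.5 * cov$age, grp, cov)
  expect_lt(abs(fit$t_stat), 1e-8)
  # collinearity with group is rejected
  bad <- data.frame(ind = as.numeric(grp == "patient"))
  expect_error(covariate_adjusted_ttest(rnorm(20), grp, bad), "collinear")
})

test_that("adjusted t-test p-values are uniform under the null", {
  set.seed(62)
  grp <- factor(rep(c("control", "patient"), c(12, 10)),
                levels = c("control", "patient"))
  ps <- replicate(400, {
    cov <- data.frame(age = rnorm(22, 25, 5))
    covariate_adjusted_ttest(rnorm(22), grp, cov)$p_raw
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("power at a 1-SD shift matches the noncentral-t value", {
  set.seed(63)
  n1 <- 23; n2 <- 15
  tcrit <- qt(0.975, n1 + n2 - 2)
  ncp <- 1 / sqrt(1 / n1 + 1 / n2)
  power_theory <- 1 - pt(tcrit, n1 + n2 - 2, ncp) +
    pt(-tcrit, n1 + n2 - 2, ncp)
  grp <- factor(rep(c("control", "patient"), c(n1, n2)),
                levels = c("control", "patient"))
  rej <- replicate(1000, {
    vals <- c(rnorm(n1, 1), rnorm(n2, 0))
    covariate_adjusted_ttest(vals, grp)$p_raw < 0.05
  })
  expect_lt(abs(mean(rej) - power_theory), 0.05)
})

test_that("BH correction matches a hand-evaluated step-up walk", {
  # all-null and all-signal corner cases
  expect_false(any(fdr_bh(rep(1, 21))$reject))
  expect_true(all(fdr_bh(rep(0.001, 21))$reject))

  p <- c(0.01, 0.02, 0.04, rep(0.9, 18))
  res <- fdr_bh(p, alpha = 0.05)
  # manual step-up: largest k with p_(k) <= k/21 * 0.05; here none qualifies
  m <- length(p)
  ord <- order(p)
  crit <- (seq_len(m) / m) * 0.05
  k_max <- max(c(0, which(p[ord] <= crit)))
  expect_equal(k_max, 0)
  expect_false(any(res$reject))
  # adjusted p by the cumulative-minimum formula
  adj_manual <- rev(cummin(rev(p[ord] * m / seq_len(m))))[order(ord)]
  expect_equal(res$p_fdr, pmin(adj_manual, 1))
  expect_true(all(res$p_fdr >= res$p_raw))

  # raising alpha never removes a rejection
  set.seed(64)
  pr <- runif(21)^2
  r1 <- fdr_bh(pr, alpha = 0.02)$reject
  r2 <- fdr_bh(pr, alpha = 0.10)$reject
  expect_true(all(r2[r1]))
})

test_that("rank-sum z matches hand enumeration and the reference test", {
  # identical samples: fully tied, degenerate
  expect_warning(res <- wilcoxon_ranksum(rep(2, 5), rep(2, 5)), "tied")
  expect_equal(res$z_stat, 0)
  expect_equal(res$p, 1)

  # complete separation, n = 5 vs 5: W = 15, mu = 27.5, var = 275/12
  res <- wilcoxon_ranksum(1:5, 11:15)
  expect_equal(res$z_stat, (15 - 27.5) / sqrt(275 / 12), tolerance = 1e-12)

  # shift much larger than spread
  set.seed(65)
  x <- rnorm(12); y <- rnorm(12) + 50
  expect_lt(wilcoxon_ranksum(x, y)$p, 0.01)

  # tie correction agrees with wilcox.test's normal approximation
  x <- c(1, 2, 2, 3, 5, 5, 5)
  y <- c(2, 3, 3, 4, 5, 6)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(wilcoxon_ranksum(x, y)$p, ref$p.value, tolerance = 1e-12)
})

test_that("Fisher's exact test reproduces the printed sex-table p", {
  res <- fisher_exact_2x2(matrix(c(11, 12, 7, 8), 2, byrow = TRUE))
  expect_equal(round(res$p, 3), 1.000)

  # perfectly discordant table: two-sided p = 2 / choose(20, 10)
  res2 <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_lt(res2$p, 0.001)
  expect_equal(res2$p, 2 / choose(20, 10), tolerance = 1e-12)

  # invariance under transposition and row swap
  tab <- matrix(c(9, 4, 3, 8), 2)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(t(tab))$p)
  expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(tab[2:1, ])$p)

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 8), 2, byrow = TRUE)),
               "margin")
})

test_that("Spearman correlation handles monotone data and ties", {
  expect_equal(spearman_clinical(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_clinical(1:8, -(1:8)^3)$rho, -1)

  # 6 pairs with one tie: rho equals Pearson on mid-ranks
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.5, 3.5, 5.0, 4.2, 7.3)
  res <- spearman_clinical(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)

  expect_error(spearman_clinical(rep(1, 5), 1:5), "constant")
  expect_error(spearman_clinical(1:2, 1:2), "3 paired")
})

test_that("metric and nodal comparison tables are tidy and FDR-corrected", {
  spec <- cohort_spec(n_patients = 6, n_controls = 5, n_timepoints = 120)
  cohort <- cohort_connectivity(condition_cohort(simulate_cohort(spec,
                                                                 seed = 66)))
  metrics <- cohort_graph_metrics(cohort, mode = "both", n_nulls = 8,
                                  seed = 2)
  metrics <- dplyr::left_join(
    metrics, cohort[, c("subject_id", "age", "sex")], by = "subject_id"
  )
  cmp <- compare_global_metrics(metrics, covariates = c("age", "sex",
                                                        "mean_fd"))
  expect_equal(nrow(cmp), 14)   # 7 metrics x 2 modes
  expect_true(all(cmp$p_raw > 0 & cmp$p_raw <= 1))

  nodal <- cohort_nodal_degree(cohort, mode = "binary")
  nodal <- dplyr::left_join(
    nodal, cohort[, c("subject_id", "age", "sex", "mean_fd")],
    by = "subject_id"
  )
  nc <- compare_nodal_degree(nodal, covariates = c("age", "sex", "mean_fd"))
  expect_equal(nrow(nc), 21)
  expect_true(all(nc$p_fdr >= nc$p_raw - 1e-12))
  # FDR is applied within the 21-node family
  expect_equal(nc$p_fdr, fdr_bh(nc$p_raw)$p_fdr)

  cors <- correlate_clinical(
    dplyr::left_join(metrics,
                     cohort[, c("subject_id", "onset_age", "duration")],
                     by = "subject_id")
  )
  expect_equal(nrow(cors), 7 * 2 * 2)
  expect_true(all(abs(cors$rho) <= 1))
})
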