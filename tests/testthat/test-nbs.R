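test_that("edgewise contrast carries the control-minus-patient sign", {
  set.seed(40)
  n <- 24
  group <- rep(c("patient", "control"), each = n / 2)
  rs <- lapply(seq_len(n), function(i) {
    r <- random_r_matrix(6, sd = 0.05, base = 0.2)
    # connectivity increased in patients on edge 1-2
    if (group[i] == "patient") r[1, 2] <- r[2, 1] <- r[1, 2] + 0.4
    r
  })
  cohort <- cohort_from_r(rs, group,
                          labels = c("L-DN", "L-Th", "a", "b", "c", "d"))
  ec <- edgewise_contrast(cohort, covariates = NULL)
  row <- ec[ec$roi_i == "L-DN" & ec$roi_j == "L-Th", ]
  expect_lt(row$t, 0)         # increased in patients => negative t
  expect_lt(row$p, 0.01)
  tm <- attr(ec, "t_matrix")
  expect_true(isSymmetric(tm))
  expect_equal(tm["L-DN", "L-Th"], row$t)
})

test_that("null cohorts give near-null edge statistics", {
  set.seed(41)
  rs <- lapply(1:20, function(i) random_r_matrix(8, sd = 0.1))
  cohort <- cohort_from_r(rs, rep(c("patient", "control"), 10))
  ec <- edgewise_contrast(cohort, covariates = NULL)
  # |t| below the 99.9% null quantile at nearly all edges
  q999 <- qt(1 - 0.001 / 2, 18)
  expect_gte(mean(abs(ec$t) < q999), 0.95)
})

test_that("collinear covariates are rejected", {
  set.seed(42)
  rs <- lapply(1:10, function(i) random_r_matrix(5))
  cohort <- cohort_from_r(rs, rep(c("patient", "control"), each = 5))
  cohort$bad <- as.numeric(cohort$group == "patient")
  expect_error(edgewise_contrast(cohort, covariates = "bad"), "collinear")
  cohort$dup <- cohort$age
  expect_error(edgewise_contrast(cohort, covariates = c("age", "dup")),
               "rank deficient")
})

test_that("component extraction matches hand-worked unions", {
  labs <- paste0("n", 1:6)
  tmat <- matrix(0, 6, 6, dimnames = list(labs, labs))
  pmat <- matrix(1, 6, 6, dimnames = list(labs, labs))
  put <- function(i, j, t, p) {
    tmat[i, j] <<- tmat[j, i] <<- t
    pmat[i, j] <<- pmat[j, i] <<- p
  }
  put(1, 2, 3.5, 0.001); put(2, 3, -3.0, 0.004); put(5, 6, 2.9, 0.006)
  put(1, 4, 1.0, 0.5)   # sub-threshold
  comps <- extract_components(tmat, pmat, primary_alpha = 0.01)
  expect_equal(nrow(comps), 2)
  expect_equal(comps$statistic, c(2, 1))        # extents 2 and 1
  expect_setequal(comps$nodes[[1]], c("n1", "n2", "n3"))
  expect_setequal(comps$nodes[[2]], c("n5", "n6"))
  # intensity statistic sums |t| over component edges
  ci <- extract_components(tmat, pmat, primary_alpha = 0.01,
                           statistic = "intensity")
  expect_equal(ci$statistic[1], 3.5 + 3.0)

  none <- extract_components(tmat, pmat, primary_alpha = 1e-6)
  expect_equal(nrow(none), 0)

  # fully suprathreshold graph: a single component with all edges
  pall <- matrix(1e-9, 6, 6, dimnames = list(labs, labs))
  tall <- matrix(5, 6, 6, dimnames = list(labs, labs)); diag(tall) <- 0
  call <- extract_components(tall, pall, primary_alpha = 0.01)
  expect_equal(nrow(call), 1)
  expect_equal(call$statistic, 15)
  expect_equal(call$n_nodes, 6)
})

test_that("enumerated permutation p equals the brute-force oracle", {
  set.seed(43)
  n <- 6
  rs <- lapply(1:n, function(i) random_r_matrix(5, sd = 0.15))
  # plant a visible difference on edges (1,2) and (2,3)
  for (i in 1:3) {
    rs[[i]][1, 2] <- rs[[i]][2, 1] <- rs[[i]][1, 2] + 0.8
    rs[[i]][2, 3] <- rs[[i]][3, 2] <- rs[[i]][2, 3] + 0.8
  }
  cohort <- cohort_from_r(rs, rep(c("patient", "control"), each = 3))
  fit <- nbs(cohort, covariates = NULL, primary_alpha = 0.05, n_perm = 100,
             enumerate = "auto", seed = 1)
  expect_true(fit$config$enumerated)
  expect_equal(fit$config$n_perm, choose(6, 3))

  x <- do.call(rbind, lapply(rs, function(r) r[upper.tri(r)]))
  x <- sweep(x, 2, colMeans(x))   # intercept-only residualization
  ei <- which(upper.tri(diag(5)), arr.ind = TRUE)
  null_max <- slow_nbs_enumerate(x, 3, qt(1 - 0.05 / 2, 4),
                                 ei[, 1], ei[, 2], 5)
  expect_equal(sort(fit$null_max_stats), sort(null_max))
  comps <- tidy(fit)
  expect_gt(nrow(comps), 0)
  expect_equal(comps$fwer_p[1], mean(null_max >= comps$statistic[1]))

  # Monte-Carlo mode converges to the enumerated p within binomial error
  mc <- nbs(cohort, covariates = NULL, primary_alpha = 0.05, n_perm = 4000,
            enumerate = "never", seed = 2)
  p_exact <- comps$fwer_p[1]
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(tidy(mc)$fwer_p[1] - p_exact), 4 * se + 2 / 4000)
})

test_that("permutation p-values respect the add-one lower bound", {
  set.seed(44)
  rs <- lapply(1:16, function(i) random_r_matrix(6, sd = 0.02))
  for (i in 1:8) {   # overwhelming effect on a 3-edge chain
    for (e in list(c(1, 2), c(2, 3), c(3, 4))) {
      rs[[i]][e[1], e[2]] <- rs[[i]][e[2], e[1]] <- 0.9
    }
  }
  cohort <- cohort_from_r(rs, rep(c("patient", "control"), each = 8))
  fit <- nbs(cohort, covariates = NULL, n_perm = 200, enumerate = "never",
             seed = 3)
  comps <- tidy(fit)
  expect_gt(nrow(comps), 0)
  expect_gte(min(comps$fwer_p), 1 / 201)
  expect_lte(max(comps$fwer_p), 1)
  # the reported p follows the add-one formula exactly
  expect_equal(comps$fwer_p[1],
               (1 + sum(fit$null_max_stats >= comps$statistic[1])) / 201)
})

test_that("NBS is deterministic under a fixed seed", {
  set.seed(45)
  rs <- lapply(1:12, function(i) random_r_matrix(6, sd = 0.1))
  cohort <- cohort_from_r(rs, rep(c("patient", "control"), each = 6))
  f1 <- nbs(cohort, covariates = "age", n_perm = 300, seed = 7)
  f2 <- nbs(cohort, covariates = "age", n_perm = 300, seed = 7)
  expect_identical(f1$null_max_stats, f2$null_max_stats)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- nbs(cohort, covariates = "age", n_perm = 300, seed = 8)
  expect_false(identical(f1$null_max_stats, f3$null_max_stats))
})

test_that("growing a planted effect never shrinks the detected component", {
  set.seed(46)
  base <- lapply(1:20, function(i) random_r_matrix(7, sd = 0.08))
  group <- rep(c("patient", "control"), each = 10)
  edges <- list(c(1, 2), c(2, 3), c(3, 4))
  extent_at <- function(delta) {
    rs <- lapply(seq_along(base), function(i) {
      r <- base[[i]]
      if (group[i] == "patient") {
        for (e in edges) r[e[1], e[2]] <- r[e[2], e[1]] <- r[e[1], e[2]] + delta
      }
      r
    })
    fit <- nbs(cohort_from_r(rs, group), covariates = NULL, n_perm = 50,
               seed = 9)
    comps <- tidy(fit)
    if (nrow(comps) == 0) 0 else max(comps$statistic)
  }
  exts <- vapply(c(0.05, 0.15, 0.3, 0.5), extent_at, numeric(1))
  expect_true(all(diff(exts) >= 0))
})

test_that("glance summarizes the fit", {
  set.seed(47)
  rs <- lapply(1:10, function(i) random_r_matrix(5, sd = 0.1))
  fit <- nbs(cohort_from_r(rs, rep(c("patient", "control"), each = 5)),
             covariates = NULL, n_perm = 100, seed = 1)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("n_components", "n_significant", "min_fwer_p", "n_perm")
                  %in% names(gl)))
})
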