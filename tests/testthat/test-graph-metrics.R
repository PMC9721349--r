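k5 <- matrix(1, 5, 5) - diag(5)
p3 <- adj_from_edges(3, rbind(c(1, 2), c(2, 3)))
star4 <- adj_from_edges(5, cbind(1, 2:5))

test_that("clustering coefficient matches hand-counted triangles", {
  expect_equal(clustering_coefficient(k5, "binary")$mean, 1)
  expect_equal(clustering_coefficient(p3, "binary")$mean, 0)
  # 4-node graph with edges 1-2, 1-3, 2-3, 3-4: one triangle
  g4 <- adj_from_edges(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))
  cc <- clustering_coefficient(g4, "binary")
  expect_equal(cc$node, c(1, 1, 1 / 3, 0))
  expect_equal(cc$mean, mean(c(1, 1, 1 / 3, 0)))
  expect_error(clustering_coefficient(matrix(c(0, 1, 0, 0), 2, 2), "binary"),
               "symmetric")
})

test_that("path length, efficiencies and degree match hand enumeration", {
  expect_equal(characteristic_path_length(k5, "binary")$lp, 1)
  expect_equal(characteristic_path_length(p3, "binary")$lp, 4 / 3)
  # two disconnected dyads: finite distances are the 4 within-dyad pairs
  dyads <- adj_from_edges(4, rbind(c(1, 2), c(3, 4)))
  pl <- characteristic_path_length(dyads, "binary")
  expect_equal(pl$lp, 1)
  expect_equal(pl$n_unreachable_pairs, 8)
  expect_error(characteristic_path_length(matrix(0, 3, 3), "binary"),
               "edgeless")

  expect_equal(global_efficiency(k5, "binary"), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4), "binary"), 0)
  expect_equal(global_efficiency(p3, "binary"), 5 / 6)

  expect_equal(local_efficiency(k5, "binary"), 1)
  expect_equal(local_efficiency(star4, "binary"), 0)

  expect_equal(unname(nodal_degree(star4, "binary")), c(4, 1, 1, 1, 1))
  w <- star4 * 0.3
  expect_equal(unname(nodal_degree(w, "weighted")), c(4 * 0.3, rep(0.3, 4)))
  set.seed(20)
  g <- random_graph(10, 0.4)
  expect_equal(sum(nodal_degree(g, "binary")), sum(g > 0))
})

test_that("metrics equal brute-force oracles on random small graphs", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    weighted <- rep %% 2 == 0
    g <- random_graph(n, runif(1, 0.25, 0.8), weighted = weighted)
    if (sum(g) == 0) next
    mode <- if (weighted) "weighted" else "binary"
    expect_equal(clustering_coefficient(g, mode)$node,
                 bf_clustering(g, mode)$node, tolerance = 1e-12)
    if (sum(g > 0) > 0) {
      expect_equal(characteristic_path_length(g, mode)$lp,
                   bf_lp(g, mode)$lp, tolerance = 1e-12)
    }
    expect_equal(global_efficiency(g, mode), bf_eg(g, mode),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(g, mode), bf_eloc(g, mode),
                 tolerance = 1e-12)
  }
})

test_that("weighted metrics with unit weights equal binary metrics", {
  set.seed(22)
  g <- random_graph(12, 0.3)
  expect_identical(clustering_coefficient(g, "weighted")$node,
                   clustering_coefficient(g, "binary")$node)
  expect_identical(characteristic_path_length(g, "weighted")$lp,
                   characteristic_path_length(g, "binary")$lp)
  expect_identical(global_efficiency(g, "weighted"),
                   global_efficiency(g, "binary"))
  expect_identical(local_efficiency(g, "weighted"),
                   local_efficiency(g, "binary"))
})

test_that("relabeling nodes permutes nodal vectors, fixes global metrics", {
  set.seed(23)
  g <- random_graph(9, 0.45, weighted = TRUE)
  perm <- sample(9)
  gp <- g[perm, perm]
  for (mode in c("binary", "weighted")) {
    expect_equal(clustering_coefficient(gp, mode)$node,
                 clustering_coefficient(g, mode)$node[perm])
    expect_equal(nodal_degree(gp, mode), nodal_degree(g, mode)[perm])
    expect_equal(characteristic_path_length(gp, mode)$lp,
                 characteristic_path_length(g, mode)$lp)
    expect_equal(global_efficiency(gp, mode), global_efficiency(g, mode))
    expect_equal(local_efficiency(gp, mode), local_efficiency(g, mode))
  }
})

test_that("rewired nulls preserve the degree sequence exactly", {
  set.seed(24)
  g <- random_graph(21, 0.3)
  nulls <- rewire_null(g, n_nulls = 20)
  for (nu in nulls) {
    expect_identical(sort(rowSums(nu > 0)), sort(rowSums(g > 0)))
    expect_true(isSymmetric(nu))
    expect_true(all(diag(nu) == 0))
  }
  # at least some nulls differ from the source
  expect_true(any(vapply(nulls, function(nu) any(nu != g), logical(1))))

  # a complete graph admits no swap: nulls are copies
  expect_true(all(vapply(rewire_null(k5, 5), identical, logical(1), k5)))

  # weighted source: weight multiset is preserved
  gw <- random_graph(10, 0.4, weighted = TRUE)
  nw <- rewire_null(gw, 5)
  for (nu in nw) {
    expect_equal(sort(nu[upper.tri(nu)][nu[upper.tri(nu)] > 0]),
                 sort(gw[upper.tri(gw)][gw[upper.tri(gw)] > 0]))
    expect_identical(sort(rowSums(nu > 0)), sort(rowSums(gw > 0)))
  }

  set.seed(99); a <- rewire_null(g, 3)
  set.seed(99); b <- rewire_null(g, 3)
  expect_identical(a, b)
})

test_that("small-world normalization behaves as expected", {
  set.seed(25)
  g <- random_graph(12, 0.4)
  sw <- normalized_small_world(g, list(g, g, g), "binary")
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # ring lattice (21 nodes, degree 4): clustered, so gamma > 1
  n <- 21
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in 1:2) {
      j <- ((i - 1 + s) %% n) + 1
      ring[i, j] <- ring[j, i] <- 1
    }
  }
  set.seed(26)
  nulls <- rewire_null(ring, 50)
  sw <- normalized_small_world(ring, nulls, "binary")
  expect_gt(sw$gamma, 1)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)

  # an ER graph against its own rewired nulls: gamma and lambda near 1
  set.seed(27)
  er <- random_graph(21, 0.35)
  nulls <- rewire_null(er, 100)
  cp_null <- vapply(nulls, function(x) clustering_coefficient(x, "binary")$mean,
                    numeric(1))
  lp_null <- vapply(nulls,
                    function(x) characteristic_path_length(x, "binary")$lp,
                    numeric(1))
  sw <- normalized_small_world(er, nulls, "binary")
  # ER clustering is what rewiring produces, up to sampling error of the
  # graph itself (of order sd of the null ensemble, not its mean)
  expect_lt(abs(sw$gamma - 1), 3 * sd(cp_null) / mean(cp_null))
  expect_lt(abs(sw$lambda - 1), 3 * sd(lp_null) / mean(lp_null))
})

test_that("cohort metric tables are tidy and deterministic", {
  spec <- cohort_spec(n_patients = 3, n_controls = 2, n_timepoints = 120)
  cohort <- cohort_connectivity(simulate_cohort(spec, seed = 30))
  m1 <- cohort_graph_metrics(cohort, mode = "both", n_nulls = 10, seed = 4)
  m2 <- cohort_graph_metrics(cohort, mode = "both", n_nulls = 10, seed = 4)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 10)
  expect_setequal(unique(m1$graph_mode), c("binary", "weighted"))
  expect_true(all(c("cp", "lp", "gamma", "lambda", "sigma", "eg", "eloc")
                  %in% names(m1)))
  expect_equal(m1$sigma, m1$gamma / m1$lambda)

  nd <- cohort_nodal_degree(cohort, mode = "binary")
  expect_equal(nrow(nd), 5 * 21)
  bin <- cohort$connectivity[[1]]$binary
  expect_equal(nd$degree[nd$subject_id == "sub-01"],
               unname(rowSums(bin)))
})
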