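# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. Deliberately slow and literal: exhaustive triangle
# enumeration, Floyd-Warshall distances, explicit subgraph construction.

bf_distances <- function(g, mode) {
  n <- nrow(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && g[i, j] > 0) {
        d[i, j] <- if (mode == "binary") 1 else 1 / g[i, j]
      }
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_clustering <- function(g, mode) {
  n <- nrow(g)
  b <- (g > 0) + 0
  w <- if (mode == "binary") b else (g / max(g))^(1 / 3)
  cn <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(b[i, ])
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + w[i, j] * w[i, h] * w[j, h]
        }
      }
    }
    cn[i] <- acc / (k * (k - 1))
  }
  list(node = cn, mean = mean(cn))
}

bf_lp <- function(g, mode) {
  d <- bf_distances(g, mode)
  off <- d[row(d) != col(d)]
  list(lp = mean(off[is.finite(off)]), n_unreachable_pairs = sum(!is.finite(off)))
}

bf_eg <- function(g, mode) {
  n <- nrow(g)
  if (n < 2) return(0)
  d <- bf_distances(g, mode)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_eloc <- function(g, mode) {
  n <- nrow(g)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(g[i, ] > 0)
    if (length(nb) >= 2) vals[i] <- bf_eg(g[nb, nb, drop = FALSE], mode)
  }
  mean(vals)
}

random_graph <- function(n, p = 0.4, weighted = FALSE) {
  g <- matrix(0, n, n)
  up <- which(upper.tri(g))
  on <- runif(length(up)) < p
  g[up[on]] <- if (weighted) runif(sum(on), 0.1, 1) else 1
  g + t(g)
}

adj_from_edges <- function(n, edges, w = 1) {
  g <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    g[edges[k, 1], edges[k, 2]] <- w
    g[edges[k, 2], edges[k, 1]] <- w
  }
  g
}

# Build a minimal cohort tibble straight from per-subject r matrices, for
# NBS tests that need exact control over the edge values.
cohort_from_r <- function(r_list, group, labels = NULL, n_timepoints = 100) {
  labels <- labels %||% paste0("n", seq_len(ncol(r_list[[1]])))
  conn <- lapply(r_list, function(r) {
    dimnames(r) <- list(labels, labels)
    structure(list(r = r, n_timepoints = n_timepoints, labels = labels),
              class = "connectivity")
  })
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(r_list)),
    group = factor(group, levels = c("patient", "control")),
    age = seq(20, 30, length.out = length(r_list)),
    sex = factor(rep_len(c("female", "male"), length(r_list)),
                 levels = c("female", "male")),
    mean_fd = seq(0.05, 0.15, length.out = length(r_list)),
    connectivity = conn
  )
}

# Random symmetric r matrices with unit diagonal (not necessarily PD; fine
# for contrast tests that treat entries as data).
random_r_matrix <- function(n, sd = 0.1, base = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- base + rnorm(n * (n - 1) / 2, sd = sd)
  m <- m + t(m)
  diag(m) <- 1
  m
}

# Slow independent NBS for tiny cohorts: t.test per edge per labeling,
# components via igraph, exhaustive enumeration of label arrangements.
slow_nbs_enumerate <- function(x_edges, g1_size, tcrit, ei, ej, n_nodes) {
  n <- nrow(x_edges)
  sets <- combn(n, g1_size, simplify = FALSE)
  vapply(sets, function(s) {
    g1 <- rep(FALSE, n); g1[s] <- TRUE
    tt <- vapply(seq_len(ncol(x_edges)), function(e) {
      unname(stats::t.test(x_edges[g1, e], x_edges[!g1, e],
                           var.equal = TRUE)$statistic)
    }, numeric(1))
    sel <- which(abs(tt) > tcrit)
    if (length(sel) == 0) return(0)
    gr <- igraph::graph_from_edgelist(
      cbind(ei[sel], ej[sel]), directed = FALSE
    )
    comp <- igraph::components(gr)
    memb <- comp$membership
    max(vapply(seq_len(comp$no), function(ci) {
      sum(memb[ei[sel]] == ci)
    }, numeric(1)))
  }, numeric(1))
}
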