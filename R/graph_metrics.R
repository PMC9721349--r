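# Binary and weighted graph metrics with degree-preserving null
# normalization. Adjacency matrices are symmetric, nonnegative, with zero
# diagonal; "weighted" mode interprets entries as connection strengths in
# (0, 1] and maps them to distances as 1/weight.

check_adjacency_ <- function(g) {
  g <- as.matrix(g)
  if (!isSymmetric(unname(g), tol = 1e-12)) {
    rlang::abort("adjacency matrix must be symmetric")
  }
  if (any(diag(g) != 0)) rlang::abort("adjacency diagonal must be zero")
  if (any(g < 0)) rlang::abort("adjacency entries must be nonnegative")
  g
}

graph_from_adj_ <- function(g, mode) {
  gr <- igraph::graph_from_adjacency_matrix(
    g > 0, mode = "undirected", diag = FALSE
  )
  if (mode == "weighted") {
    ends <- igraph::as_edgelist(gr, names = FALSE)
    igraph::E(gr)$length <- 1 / g[ends]
  }
  gr
}

dist_matrix_ <- function(g, mode) {
  gr <- graph_from_adj_(g, mode)
  if (mode == "weighted") {
    igraph::distances(gr, weights = igraph::E(gr)$length)
  } else {
    igraph::distances(gr, weights = NA)
  }
}

#' Clustering coefficient
#'
#' Binary mode: `c_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of
#' triangles at node i; nodes with fewer than 2 neighbors contribute 0.
#' Weighted mode uses the Onnela geometric-mean generalization on weights
#' normalized by the graph maximum.
#'
#' @param g Adjacency matrix (symmetric, zero diagonal, nonnegative).
#' @param mode `"binary"` or `"weighted"`.
#' @return A list with `node` (per-node coefficients) and `mean` (Cp).
#' @export
clustering_coefficient <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  b <- (g > 0) + 0
  k <- rowSums(b)
  s <- if (mode == "binary") b else (g / max(g))^(1 / 3)
  tri <- diag(s %*% s %*% s) / 2
  cnode <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(node = unname(cnode), mean = mean(cnode))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs with a finite
#' distance (binary: hop count; weighted: sum of 1/weight edge lengths).
#' Unreachable pairs are excluded from the mean and counted in
#' `n_unreachable_pairs`.
#'
#' @inheritParams clustering_coefficient
#' @return A list with `lp` and `n_unreachable_pairs` (ordered pairs).
#' @export
characteristic_path_length <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  d <- dist_matrix_(g, mode)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) {
    rlang::abort("edgeless graph: no finite node pair distances")
  }
  list(lp = mean(off[finite]), n_unreachable_pairs = sum(!finite))
}

#' Global efficiency
#'
#' `Eg = (1 / (N (N - 1))) * sum over i != j of 1 / d_ij`, with 1/Inf = 0.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar efficiency (in `[0, 1]` for binary graphs).
#' @export
global_efficiency <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  n <- nrow(g)
  if (n < 2) return(0)
  d <- dist_matrix_(g, mode)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  vals <- vapply(seq_len(nrow(g)), function(i) {
    nb <- which(g[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(g[nb, nb, drop = FALSE], mode)
  }, numeric(1))
  mean(vals)
}

#' Nodal degree or strength
#'
#' Binary mode counts incident edges; weighted mode sums incident edge
#' weights (nodal strength).
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector, one value per node.
#' @export
nodal_degree <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  if (mode == "binary") rowSums(g > 0) else rowSums(g)
}

#' Degree-preserving random null ensemble
#'
#' Generates matched random graphs by Maslov-Sneppen double-edge swaps
#' (rejecting self-loops and multi-edges), preserving the exact degree
#' sequence of the source. For weighted sources the binary topology is
#' rewired and the multiset of observed weights is randomly reassigned to the
#' rewired edges. Uses the R RNG; seed with [set.seed()] for reproducibility.
#'
#' @param g Source adjacency matrix.
#' @param n_nulls Ensemble size (default 100, matching the convention of 100
#'   matched random networks).
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return A list of adjacency matrices with attribute `degenerate = TRUE`
#'   (plus a warning) when the source admits no valid swap.
#' @export
rewire_null <- function(g, n_nulls = 100, swaps_per_edge = 10) {
  g <- check_adjacency_(g)
  weighted <- any(g > 0 & g != 1)
  b <- (g > 0) + 0
  gr <- igraph::graph_from_adjacency_matrix(b > 0, mode = "undirected",
                                            diag = FALSE)
  m <- igraph::ecount(gr)
  degenerate <- m < 2
  if (degenerate) {
    rlang::warn("graph admits no degree-preserving swap; returning copies")
  }
  src_deg <- sort(rowSums(b))
  wts <- g[upper.tri(g)][g[upper.tri(g)] > 0]
  nulls <- purrr::map(seq_len(n_nulls), function(i) {
    if (degenerate) return(g)
    rg <- igraph::rewire(gr, igraph::keeping_degseq(niter = swaps_per_edge * m))
    adj <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
    stopifnot(identical(sort(rowSums(adj)), src_deg))
    if (weighted) {
      w <- sample(wts)
      out <- matrix(0, nrow(adj), ncol(adj), dimnames = dimnames(g))
      idx <- which(upper.tri(adj) & adj > 0)
      out[idx] <- w
      out <- out + t(out)
      out
    } else {
      dimnames(adj) <- dimnames(g)
      adj
    }
  })
  structure(nulls, degenerate = degenerate)
}

#' Normalized small-world coefficients
#'
#' `gamma = Cp / mean(Cp over nulls)`, `lambda = Lp / mean(Lp over nulls)`,
#' `sigma = gamma / lambda`.
#'
#' @param g Adjacency matrix.
#' @param nulls Null ensemble from [rewire_null()].
#' @inheritParams clustering_coefficient
#' @return A list with `gamma`, `lambda`, `sigma`.
#' @export
normalized_small_world <- function(g, nulls, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  cp <- clustering_coefficient(g, mode)$mean
  lp <- characteristic_path_length(g, mode)$lp
  null_cp <- mean(purrr::map_dbl(nulls,
                                 ~clustering_coefficient(.x, mode)$mean))
  null_lp <- mean(purrr::map_dbl(nulls,
                                 ~characteristic_path_length(.x, mode)$lp))
  if (null_cp == 0 || null_lp == 0) {
    rlang::abort("null ensemble has zero mean clustering or path length")
  }
  gamma <- cp / null_cp
  lambda <- lp / null_lp
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All global graph metrics for one graph
#'
#' @param g Adjacency matrix.
#' @param mode `"binary"` or `"weighted"`.
#' @param n_nulls Size of the rewired null ensemble used for gamma/lambda/
#'   sigma; 0 skips normalization (NA values).
#' @param swaps_per_edge Swaps per edge for [rewire_null()].
#' @return One-row tibble: `cp`, `lp`, `n_unreachable`, `gamma`, `lambda`,
#'   `sigma`, `eg`, `eloc`.
#' @export
graph_metrics <- function(g, mode = c("binary", "weighted"), n_nulls = 100,
                          swaps_per_edge = 10) {
  mode <- match.arg(mode)
  g <- check_adjacency_(g)
  if (sum(g > 0) == 0) {
    rlang::warn("empty graph: metrics undefined")
    return(tibble::tibble(cp = NA_real_, lp = NA_real_, n_unreachable = NA,
                          gamma = NA_real_, lambda = NA_real_,
                          sigma = NA_real_, eg = 0, eloc = 0))
  }
  cp <- clustering_coefficient(g, mode)$mean
  pl <- characteristic_path_length(g, mode)
  if (n_nulls > 0) {
    nulls <- rewire_null(g, n_nulls, swaps_per_edge)
    sw <- normalized_small_world(g, nulls, mode)
  } else {
    sw <- list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
  }
  tibble::tibble(
    cp = cp, lp = pl$lp, n_unreachable = pl$n_unreachable_pairs,
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
    eg = global_efficiency(g, mode), eloc = local_efficiency(g, mode)
  )
}

#' Per-subject graph metrics for a cohort
#'
#' Computes the global metric set for every subject's thresholded graph, in
#' binary and/or weighted mode, each normalized against its own rewired null
#' ensemble.
#'
#' @param cohort A cohort tibble with a `connectivity` list-column (see
#'   [cohort_connectivity()]).
#' @param mode `"binary"`, `"weighted"`, or `"both"` (default).
#' @param n_nulls Null ensemble size per subject (default 100).
#' @param seed RNG seed for the null ensembles.
#' @return A tidy tibble: one row per subject x mode with `subject_id`,
#'   `group`, `graph_mode`, the global metrics, and `mean_fd` when available.
#' @export
cohort_graph_metrics <- function(cohort, mode = c("both", "binary",
                                                  "weighted"),
                                 n_nulls = 100, seed = 1L) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("binary", "weighted") else mode
  with_seed_(seed, {
    rows <- purrr::imap(cohort$connectivity, function(cm, i) {
      purrr::map(modes, function(md) {
        g <- if (md == "binary") cm$binary else cm$weighted
        res <- graph_metrics(g, md, n_nulls = n_nulls)
        dplyr::bind_cols(
          tibble::tibble(subject_id = cohort$subject_id[i],
                         group = cohort$group[i], graph_mode = md),
          res
        )
      })
    })
    out <- dplyr::bind_rows(purrr::map(rows, dplyr::bind_rows))
    if ("mean_fd" %in% names(cohort)) {
      out <- dplyr::left_join(
        out, cohort[, c("subject_id", "mean_fd")], by = "subject_id"
      )
    }
    out
  })
}

#' Per-subject nodal degree / strength table
#'
#' @inheritParams cohort_graph_metrics
#' @return Long tibble: `subject_id`, `group`, `graph_mode`, `label`,
#'   `degree`.
#' @export
cohort_nodal_degree <- function(cohort, mode = c("both", "binary",
                                                 "weighted")) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("binary", "weighted") else mode
  rows <- purrr::imap(cohort$connectivity, function(cm, i) {
    purrr::map(modes, function(md) {
      g <- if (md == "binary") cm$binary else cm$weighted
      deg <- nodal_degree(g, md)
      tibble::tibble(subject_id = cohort$subject_id[i],
                     group = cohort$group[i], graph_mode = md,
                     label = cm$labels, degree = unname(deg))
    })
  })
  dplyr::bind_rows(purrr::map(rows, dplyr::bind_rows))
}
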