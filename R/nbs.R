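# Network-based statistic: covariate-adjusted edge-wise contrasts, primary
# thresholding, connected-component extraction and max-component permutation
# FWER p-values. The permutation loop is vectorized across edges.

edge_index_ <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Stack per-subject connectivity into a subject-by-edge matrix
#'
#' @param cohort A cohort tibble with a `connectivity` list-column.
#' @param fisher_z Apply the Fisher z-transform `atanh(r)` to the edge values.
#' @return An n_subjects x n_edges matrix with attributes `edge_i`, `edge_j`,
#'   `labels`.
#' @export
fc_edge_matrix <- function(cohort, fisher_z = FALSE) {
  rs <- purrr::map(cohort$connectivity, "r")
  n_roi <- ncol(rs[[1]])
  ei <- edge_index_(n_roi)
  x <- do.call(rbind, purrr::map(rs, ~.x[upper.tri(.x)]))
  if (fisher_z) x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  attr(x, "edge_i") <- ei$i
  attr(x, "edge_j") <- ei$j
  attr(x, "labels") <- cohort$connectivity[[1]]$labels
  x
}

# Residualize columns of x against [intercept + covariates]; errors on a
# rank-deficient design or a covariate collinear with group.
residualize_ <- function(x, covariates_df, group = NULL) {
  if (is.null(covariates_df) || ncol(covariates_df) == 0) {
    d <- matrix(1, nrow(x), 1)
  } else {
    d <- stats::model.matrix(~., data = as.data.frame(covariates_df))
  }
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    rlang::abort("covariate design is rank deficient")
  }
  if (!is.null(group)) {
    g01 <- as.numeric(group == levels(factor(group))[1])
    if (qr(cbind(d, g01))$rank <= qd$rank) {
      rlang::abort("a covariate is collinear with the group factor")
    }
  }
  x - qr.fitted(qd, x)
}

# Pooled-variance two-sample t for every column of r_mat, group1 minus
# group0; g1 is a logical vector selecting group1.
col_ttest_ <- function(r_mat, g1) {
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  m1 <- colMeans(r_mat[g1, , drop = FALSE])
  m0 <- colMeans(r_mat[!g1, , drop = FALSE])
  ss1 <- colSums(r_mat[g1, , drop = FALSE]^2) - n1 * m1^2
  ss0 <- colSums(r_mat[!g1, , drop = FALSE]^2) - n0 * m0^2
  s2 <- (ss1 + ss0) / (n - 2)
  tt <- (m1 - m0) / sqrt(s2 * (1 / n1 + 1 / n0))
  tt[s2 == 0] <- NA_real_
  tt
}

#' Covariate-adjusted edge-wise group contrast
#'
#' For every unordered ROI pair, residualizes the edge value across subjects
#' against an intercept plus the covariates, then computes a pooled-variance
#' two-sample t statistic on the residuals with the sign convention
#' control minus patient (a positive t means lower connectivity in patients;
#' an edge increased in patients carries a negative t).
#'
#' @param cohort A cohort tibble with `connectivity`, `group`, and covariate
#'   columns.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "sex", "mean_fd")`); `NULL` for none.
#' @param fisher_z Contrast Fisher-z transformed correlations.
#' @return A tibble with one row per edge: `roi_i`, `roi_j`, `t`, `p`
#'   (two-sided, df = n - 2), plus attribute `t_matrix` (signed 21 x 21).
#' @export
edgewise_contrast <- function(cohort, covariates = c("age", "sex", "mean_fd"),
                              fisher_z = FALSE) {
  x <- fc_edge_matrix(cohort, fisher_z = fisher_z)
  covs <- if (is.null(covariates)) NULL else
    cohort[, covariates, drop = FALSE]
  res <- residualize_(x, covs, group = cohort$group)
  g1 <- cohort$group == "control"
  tt <- col_ttest_(res, g1)
  df <- nrow(x) - 2
  pp <- 2 * pt(-abs(tt), df)
  labs <- attr(x, "labels")
  tm <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  tm[cbind(attr(x, "edge_i"), attr(x, "edge_j"))] <- tt
  tm <- tm + t(tm)
  out <- tibble::tibble(
    roi_i = labs[attr(x, "edge_i")], roi_j = labs[attr(x, "edge_j")],
    t = tt, p = pp
  )
  attr(out, "t_matrix") <- tm
  attr(out, "df") <- df
  out
}

# Max-component statistic over a set of suprathreshold edges (union-find).
max_component_stat_ <- function(sel, tabs, ei, ej, statistic) {
  if (length(sel) == 0) return(0)
  nodes <- unique(c(ei[sel], ej[sel]))
  parent <- seq_along(nodes)
  id <- match(c(ei[sel], ej[sel]), nodes)
  a <- id[seq_along(sel)]
  b <- id[-seq_along(sel)]
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(sel)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp_of_edge <- roots[a]
  if (statistic == "extent") {
    max(tabulate(comp_of_edge))
  } else {
    max(vapply(split(tabs[sel], comp_of_edge), sum, numeric(1)))
  }
}

#' Connected components of the suprathreshold edge set
#'
#' @param edge_t Signed symmetric t-statistic matrix (ROI labels as
#'   dimnames).
#' @param edge_p Matching matrix of two-sided p-values.
#' @param primary_alpha Edge-level threshold; edges with `p < primary_alpha`
#'   (strict) enter the component graph.
#' @param statistic `"extent"` (edge count) or `"intensity"` (sum of |t|).
#' @return A tibble with one row per component: `component`, `n_nodes`,
#'   `n_edges`, `statistic`, and list-columns `nodes` and `edges`.
#' @export
extract_components <- function(edge_t, edge_p, primary_alpha = 0.01,
                               statistic = c("extent", "intensity")) {
  statistic <- match.arg(statistic)
  labs <- rownames(edge_t) %||% paste0("node_", seq_len(nrow(edge_t)))
  supra <- !is.na(edge_p) & edge_p < primary_alpha
  supra[lower.tri(supra, diag = TRUE)] <- FALSE
  idx <- which(supra, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(component = integer(), n_nodes = integer(),
                          n_edges = integer(), statistic = numeric(),
                          nodes = list(), edges = list()))
  }
  gr <- igraph::graph_from_edgelist(
    cbind(labs[idx[, 1]], labs[idx[, 2]]), directed = FALSE
  )
  comp <- igraph::components(gr)
  member <- comp$membership
  rows <- purrr::map(seq_len(comp$no), function(ci) {
    cn <- names(member)[member == ci]
    in_comp <- labs[idx[, 1]] %in% cn
    edges <- tibble::tibble(
      roi_i = labs[idx[in_comp, 1]], roi_j = labs[idx[in_comp, 2]],
      t = edge_t[idx[in_comp, , drop = FALSE]]
    )
    stat <- if (statistic == "extent") nrow(edges) else sum(abs(edges$t))
    tibble::tibble(component = ci, n_nodes = length(cn),
                   n_edges = nrow(edges), statistic = stat,
                   nodes = list(cn), edges = list(edges))
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$statistic)) |>
    dplyr::mutate(component = dplyr::row_number())
}

#' Network-based statistic with permutation FWER control
#'
#' Runs the NBS procedure on a cohort: covariate-adjusted edge-wise two-sample
#' contrasts, primary thresholding at `primary_alpha`, connected-component
#' extraction, and a max-component permutation null. Covariates are
#' residualized out once and group labels are then permuted over the
#' residuals. Monte-Carlo FWER p-values use the add-one formula
#' `(1 + #\{null max >= observed\}) / (1 + n_perm)`; when the number of
#' distinct label arrangements does not exceed `n_perm` (and
#' `enumerate != "never"`) all arrangements are enumerated and the p-value is
#' the exact proportion.
#'
#' @inheritParams edgewise_contrast
#' @param primary_alpha Edge-level primary threshold (default 0.01).
#' @param n_perm Number of permutations (default 5000).
#' @param component_alpha FWER significance level recorded in the result
#'   (default 0.05).
#' @param statistic Component statistic: `"extent"` or `"intensity"`.
#' @param enumerate `"auto"` (default), `"never"`, or `"always"` (errors when
#'   enumeration is infeasible above `n_perm` arrangements).
#' @param seed RNG seed for the permutation draw.
#' @return An `nbs_result` object; see [tidy.nbs_result()] and
#'   [glance.nbs_result()].
#' @export
nbs <- function(cohort, covariates = c("age", "sex", "mean_fd"),
                primary_alpha = 0.01, n_perm = 5000, component_alpha = 0.05,
                statistic = c("extent", "intensity"), fisher_z = FALSE,
                enumerate = c("auto", "never", "always"), seed = 1L) {
  statistic <- match.arg(statistic)
  enumerate <- match.arg(enumerate)
  stopifnot(primary_alpha > 0, primary_alpha < 1, n_perm >= 1,
            component_alpha > 0, component_alpha < 1)
  x <- fc_edge_matrix(cohort, fisher_z = fisher_z)
  covs <- if (is.null(covariates)) NULL else
    cohort[, covariates, drop = FALSE]
  res <- residualize_(x, covs, group = cohort$group)
  g1 <- cohort$group == "control"
  n <- nrow(res); n1 <- sum(g1); n0 <- n - n1
  if (n1 < 2 || n0 < 2) rlang::abort("need at least 2 subjects per group")
  df <- n - 2
  tcrit <- qt(1 - primary_alpha / 2, df)
  ei <- attr(x, "edge_i"); ej <- attr(x, "edge_j")
  labs <- attr(x, "labels")

  tt <- col_ttest_(res, g1)
  pp <- 2 * pt(-abs(tt), df)
  tm <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  pm <- matrix(NA_real_, length(labs), length(labs),
               dimnames = list(labs, labs))
  tm[cbind(ei, ej)] <- tt; tm <- tm + t(tm)
  pm[cbind(ei, ej)] <- pp; pm[cbind(ej, ei)] <- pp
  comps <- extract_components(tm, pm, primary_alpha, statistic)

  n_arrangements <- choose(n, n1)
  do_enum <- (enumerate == "always") ||
    (enumerate == "auto" && n_arrangements <= n_perm)
  if (enumerate == "always" && n_arrangements > n_perm) {
    rlang::abort(sprintf(
      "exact enumeration needs %d arrangements but n_perm is %d",
      n_arrangements, n_perm
    ))
  }
  perm_sets <- with_seed_(seed, {
    if (do_enum) {
      combn(n, n1, simplify = FALSE)
    } else {
      purrr::map(seq_len(n_perm), ~sample.int(n, n1))
    }
  })
  # vectorized pooled t across all permutations at once
  p_mat <- matrix(0, n, length(perm_sets))
  for (b in seq_along(perm_sets)) p_mat[perm_sets[[b]], b] <- 1
  tot <- colSums(res); tot2 <- colSums(res^2)
  s1 <- crossprod(p_mat, res)                     # B x E group-1 sums
  q1 <- crossprod(p_mat, res^2)
  m1 <- s1 / n1
  m0 <- sweep(-s1, 2, tot, "+") / n0
  ss1 <- q1 - n1 * m1^2
  ss0 <- sweep(-q1, 2, tot2, "+") - n0 * m0^2
  tmat <- (m1 - m0) / sqrt((ss1 + ss0) / df * (1 / n1 + 1 / n0))
  supra <- abs(tmat) > tcrit
  null_max <- vapply(seq_len(nrow(tmat)), function(b) {
    sel <- which(supra[b, ])
    max_component_stat_(sel, abs(tmat[b, ]), ei, ej, statistic)
  }, numeric(1))

  if (nrow(comps) > 0) {
    comps$fwer_p <- vapply(comps$statistic, function(s) {
      if (do_enum) mean(null_max >= s) else
        (1 + sum(null_max >= s)) / (1 + length(null_max))
    }, numeric(1))
  } else {
    comps$fwer_p <- numeric(0)
  }
  structure(
    list(edge_t = tm, edge_p = pm, components = comps,
         null_max_stats = null_max,
         config = list(covariates = covariates,
                       primary_alpha = primary_alpha,
                       n_perm = length(perm_sets),
                       component_alpha = component_alpha,
                       statistic = statistic, fisher_z = fisher_z,
                       enumerated = do_enum, seed = seed, df = df)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<nbs_result> primary p < %g, %d %s, statistic = %s\n",
    cfg$primary_alpha, cfg$n_perm,
    if (cfg$enumerated) "enumerated arrangements" else "permutations",
    cfg$statistic
  ))
  if (nrow(x$components) == 0) {
    cat("  no suprathreshold components\n")
  } else {
    sig <- x$components$fwer_p < cfg$component_alpha
    cat(sprintf("  %d component(s), %d significant at FWER %g\n",
                nrow(x$components), sum(sig), cfg$component_alpha))
    top <- x$components[1, ]
    cat(sprintf("  largest: %d edges / %d nodes, corrected p = %.4g\n",
                top$n_edges, top$n_nodes, top$fwer_p))
  }
  invisible(x)
}

#' Tidy an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return The component tibble (one row per connected component, with
#'   `statistic` and `fwer_p`).
#' @method tidy nbs_result
#' @export
tidy.nbs_result <- function(x, ...) x$components

#' One-row summary of an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of components, edges in the largest
#'   component, minimal corrected p, permutation count.
#' @method glance nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    n_significant = sum(x$components$fwer_p < x$config$component_alpha),
    max_statistic = if (nrow(x$components)) max(x$components$statistic) else 0,
    min_fwer_p = if (nrow(x$components)) min(x$components$fwer_p) else
      NA_real_,
    n_perm = x$config$n_perm,
    enumerated = x$config$enumerated
  )
}
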