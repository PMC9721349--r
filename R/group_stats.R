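# Group-level statistics: covariate-adjusted two-sample t-tests with FDR
# across nodes, Wilcoxon rank-sum, Fisher's exact test, and Spearman
# correlations with clinical variables.

#' Covariate-adjusted two-sample t-test
#'
#' Residualizes the values against an intercept plus the covariates (fit on
#' all subjects), then performs a pooled-variance two-sample t-test on the
#' residuals. With no covariates this reduces exactly to the plain pooled
#' two-sample t-test. `welch = TRUE` switches to the Welch statistic.
#'
#' @param values Numeric vector, one value per subject.
#' @param group Two-level factor (first level minus second level sign
#'   convention; the pipeline uses control minus patient).
#' @param covariates Optional data frame of covariates.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return One-row tibble: `t_stat`, `df`, `p_raw`, `direction`.
#' @export
covariate_adjusted_ttest <- function(values, group, covariates = NULL,
                                     welch = FALSE) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2 || any(table(group) < 2)) {
    rlang::abort("need two groups with at least 2 subjects each")
  }
  res <- drop(residualize_(cbind(values), covariates, group = group))
  x <- res[group == levels(group)[1]]
  y <- res[group == levels(group)[2]]
  if (welch) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  tibble::tibble(
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_raw = tt$p.value,
    direction = ifelse(unname(tt$statistic) >= 0,
                       paste0(levels(group)[1], "_higher"),
                       paste0(levels(group)[2], "_higher"))
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param p_values Vector of raw p-values.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with `p_raw`, `p_fdr` (BH-adjusted), and `reject`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_fdr = adj, reject = adj <= alpha)
}

#' Wilcoxon rank-sum test (normal approximation with tie correction)
#'
#' Computes the rank-sum z statistic
#' `z = (W - n1 (N + 1) / 2) / sd`, where W is the rank sum of `x` and the
#' variance carries the standard tie correction, with a two-sided normal
#' p-value. When every value is tied across both samples the test is
#' degenerate and returns `z = 0`, `p = 1` with a warning.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `z_stat`, `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("both samples must be nonempty")
  }
  all_v <- c(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(all_v)
  w <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    rlang::warn("all values tied across both samples; test is degenerate")
    return(tibble::tibble(z_stat = 0, p = 1))
  }
  z <- (w - mu) / sqrt(v)
  tibble::tibble(z_stat = z, p = 2 * pnorm(-abs(z)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summation of hypergeometric probabilities no larger than
#' that of the observed table (via [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return One-row tibble: `p`, `odds_ratio`.
#' @examples
#' fisher_exact_2x2(matrix(c(11, 12, 7, 8), 2, byrow = TRUE))  # p = 1.000
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::abort("2x2 table has an empty margin")
  }
  ft <- fisher.test(table)
  tibble::tibble(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Spearman correlation between a network metric and a clinical variable
#'
#' Rank correlation with tie handling (t-approximation p-value), intended for
#' patient-only metric vs onset-age / illness-duration analyses.
#'
#' @param metric,clinical Numeric vectors of equal length (>= 3 pairs).
#' @return One-row tibble: `rho`, `p`.
#' @export
spearman_clinical <- function(metric, clinical) {
  if (length(metric) != length(clinical) || length(metric) < 3) {
    rlang::abort("need at least 3 paired observations")
  }
  if (sd(metric) == 0 || sd(clinical) == 0) {
    rlang::abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(
    cor.test(metric, clinical, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value)
}

#' Group comparison of global graph metrics
#'
#' Covariate-adjusted two-sample t-tests (control minus patient) for each
#' global metric within each graph mode.
#'
#' @param metrics Tidy metrics tibble from [cohort_graph_metrics()], joined
#'   with the covariate columns (`age`, `sex`, `mean_fd`) per subject.
#' @param covariates Character vector of covariate column names; `NULL` for
#'   unadjusted tests.
#' @param metric_names Metrics to test.
#' @return Tidy tibble: `graph_mode`, `metric`, `t_stat`, `df`, `p_raw`,
#'   `direction`.
#' @export
compare_global_metrics <- function(metrics,
                                   covariates = c("age", "sex", "mean_fd"),
                                   metric_names = c("cp", "lp", "gamma",
                                                    "lambda", "sigma", "eg",
                                                    "eloc")) {
  grp <- factor(metrics$group, levels = c("control", "patient"))
  purrr::map(unique(metrics$graph_mode), function(md) {
    sub <- metrics[metrics$graph_mode == md, ]
    gsub <- grp[metrics$graph_mode == md]
    covs <- if (is.null(covariates)) NULL else
      as.data.frame(sub[, covariates, drop = FALSE])
    purrr::map(metric_names, function(mn) {
      dplyr::bind_cols(
        tibble::tibble(graph_mode = md, metric = mn),
        covariate_adjusted_ttest(sub[[mn]], gsub, covs)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Group comparison of nodal degree with FDR across nodes
#'
#' Covariate-adjusted t-tests per node, BH-corrected across the 21 nodes
#' separately within each graph mode (binary and weighted families are
#' corrected independently).
#'
#' @param nodal Long tibble from [cohort_nodal_degree()] joined with the
#'   covariate columns per subject.
#' @param covariates Covariate column names; `NULL` for unadjusted.
#' @param alpha FDR level (default 0.05).
#' @return Tidy tibble: `graph_mode`, `label`, `t_stat`, `p_raw`, `p_fdr`,
#'   `reject`, `direction`.
#' @export
compare_nodal_degree <- function(nodal,
                                 covariates = c("age", "sex", "mean_fd"),
                                 alpha = 0.05) {
  purrr::map(unique(nodal$graph_mode), function(md) {
    sub <- nodal[nodal$graph_mode == md, ]
    grp <- factor(sub$group, levels = c("control", "patient"))
    rows <- purrr::map(unique(sub$label), function(lb) {
      s2 <- sub[sub$label == lb, ]
      covs <- if (is.null(covariates)) NULL else
        as.data.frame(s2[, covariates, drop = FALSE])
      g2 <- factor(s2$group, levels = c("control", "patient"))
      dplyr::bind_cols(
        tibble::tibble(graph_mode = md, label = lb),
        covariate_adjusted_ttest(s2$degree, g2, covs)
      )
    }) |> dplyr::bind_rows()
    fdr <- fdr_bh(rows$p_raw, alpha)
    rows$p_fdr <- fdr$p_fdr
    rows$reject <- fdr$reject
    rows
  }) |> dplyr::bind_rows()
}

#' Spearman correlations between patient metrics and clinical variables
#'
#' @param metrics Tidy metrics tibble (one row per subject x mode) joined
#'   with `onset_age` and `duration` columns; only patients are used.
#' @param metric_names Metrics to correlate.
#' @param clinical_names Clinical variable column names.
#' @return Tidy tibble: `graph_mode`, `metric`, `clinical`, `rho`, `p`.
#' @export
correlate_clinical <- function(metrics,
                               metric_names = c("cp", "lp", "gamma", "lambda",
                                                "sigma", "eg", "eloc"),
                               clinical_names = c("onset_age", "duration")) {
  pats <- metrics[metrics$group == "patient", ]
  combos <- expand.grid(graph_mode = unique(pats$graph_mode),
                        metric = metric_names, clinical = clinical_names,
                        stringsAsFactors = FALSE)
  purrr::pmap(combos, function(graph_mode, metric, clinical) {
    sub <- pats[pats$graph_mode == graph_mode, ]
    dplyr::bind_cols(
      tibble::tibble(graph_mode = graph_mode, metric = metric,
                     clinical = clinical),
      spearman_clinical(sub[[metric]], sub[[clinical]])
    )
  }) |> dplyr::bind_rows()
}
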