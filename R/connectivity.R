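# Per-subject connectivity: Pearson correlation matrices and
# significance-thresholded binary / weighted views.

#' Pearson connectivity matrix from ROI time series
#'
#' @param ts T x R numeric matrix (T time points, R ROIs). Column names are
#'   kept as ROI labels.
#' @return A `connectivity` object holding the symmetric correlation matrix
#'   `r` (unit diagonal) and `n_timepoints`.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' correlation_matrix(ts)$r
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) {
    rlang::abort("Pearson correlation needs at least 3 time points")
  }
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    rlang::abort(sprintf("zero-variance ROI series: %s",
                         paste(bad, collapse = ", ")))
  }
  r <- cor(ts)
  structure(
    list(r = r, n_timepoints = nrow(ts),
         labels = colnames(ts) %||% paste0("roi_", seq_len(ncol(ts)))),
    class = "connectivity"
  )
}

#' Critical correlation for a Bonferroni-corrected significance threshold
#'
#' Inverts the exact Student-t null distribution of the Pearson coefficient
#' (t = r * sqrt(df / (1 - r^2)), df = T - 2) at a two-sided per-edge level of
#' `alpha / n_comparisons`.
#'
#' @param n_timepoints Number of time points T.
#' @param alpha Family significance level.
#' @param n_comparisons Number of edges tested (210 for 21 nodes).
#' @return The critical |r| above which an edge is significant.
#' @export
critical_r <- function(n_timepoints, alpha = 0.05, n_comparisons = 210) {
  df <- n_timepoints - 2
  tcrit <- qt(1 - alpha / n_comparisons / 2, df)
  tcrit / sqrt(df + tcrit^2)
}

#' Threshold a connectivity matrix
#'
#' Retains edges whose correlation is significant at `alpha` after Bonferroni
#' correction over all node pairs, using the exact t-transform of the Pearson
#' null at df = T - 2. By default only positive correlations are eligible
#' (`edge_sign = "positive"`); `edge_sign = "abs"` admits edges by absolute
#' value. The result carries a `binary` adjacency (a_ij = 1 for surviving
#' edges) and a `weighted` matrix holding the surviving correlations.
#'
#' @param cm A `connectivity` object from [correlation_matrix()].
#' @param alpha Family significance level (default 0.05).
#' @param edge_sign `"positive"` (default) or `"abs"`.
#' @return The `connectivity` object with `binary`, `weighted`, and
#'   `threshold_rule` (alpha, n_comparisons, critical_r, edge_sign) added.
#' @export
threshold_connectivity <- function(cm, alpha = 0.05,
                                   edge_sign = c("positive", "abs")) {
  edge_sign <- match.arg(edge_sign)
  stopifnot(inherits(cm, "connectivity"))
  if (cm$n_timepoints <= 3) {
    rlang::abort("thresholding needs more than 3 time points (df = T - 2)")
  }
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  n <- ncol(cm$r)
  m <- n * (n - 1) / 2
  rc <- critical_r(cm$n_timepoints, alpha, m)
  eligible <- if (edge_sign == "positive") cm$r > 0 else cm$r != 0
  keep <- eligible & abs(cm$r) > rc
  diag(keep) <- FALSE
  binary <- keep + 0
  weighted <- ifelse(keep, if (edge_sign == "positive") cm$r else abs(cm$r), 0)
  dimnames(binary) <- dimnames(weighted) <- dimnames(cm$r)
  cm$binary <- binary
  cm$weighted <- weighted
  cm$threshold_rule <- list(alpha = alpha, n_comparisons = m, critical_r = rc,
                            edge_sign = edge_sign)
  cm
}

#' @export
print.connectivity <- function(x, ...) {
  n <- ncol(x$r)
  cat(sprintf("<connectivity> %d nodes, T = %d", n, x$n_timepoints))
  if (!is.null(x$binary)) {
    cat(sprintf(", %d/%d edges retained (critical r %.3f, %s)",
                sum(x$binary[upper.tri(x$binary)]),
                n * (n - 1) / 2, x$threshold_rule$critical_r,
                x$threshold_rule$edge_sign))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a connectivity object into an edge table
#'
#' @param x A `connectivity` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `roi_i`, `roi_j`,
#'   `r`, and (when thresholded) `retained` and `weight`.
#' @method tidy connectivity
#' @export
tidy.connectivity <- function(x, ...) {
  labs <- x$labels
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- tibble::tibble(
    roi_i = labs[idx[, 1]], roi_j = labs[idx[, 2]],
    r = x$r[idx]
  )
  if (!is.null(x$binary)) {
    out$retained <- x$binary[idx] > 0
    out$weight <- x$weighted[idx]
  }
  out
}

#' Build thresholded connectivity for every subject of a cohort
#'
#' @param cohort A cohort tibble; uses the `conditioned` list-column when
#'   present, otherwise `timeseries`.
#' @param alpha,edge_sign Passed to [threshold_connectivity()].
#' @return The cohort with a `connectivity` list-column added.
#' @export
cohort_connectivity <- function(cohort, alpha = 0.05,
                                edge_sign = c("positive", "abs")) {
  edge_sign <- match.arg(edge_sign)
  src <- if ("conditioned" %in% names(cohort)) cohort$conditioned else
    cohort$timeseries
  cohort$connectivity <- purrr::map(src, function(ts) {
    threshold_connectivity(correlation_matrix(ts), alpha, edge_sign)
  })
  cohort
}
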