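# Signal conditioning: framewise displacement, Friston-24 expansion,
# nuisance/spike regression and band-pass filtering of ROI time series.

#' Conditioning configuration
#'
#' @param band_low,band_high Band-pass edges in Hz (defaults 0.01 and 0.08).
#' @param tr Repetition time in seconds.
#' @param spike_fd_threshold FD (mm) above which a volume receives a spike
#'   regressor (default 0.5).
#' @param detrend_order Polynomial detrend order (1 = linear).
#' @param use_friston24,use_tissue Include the Friston-24 motion expansion /
#'   the white-matter and CSF surrogate signals in the nuisance design.
#' @param order `"regress_then_filter"` (default) regresses all nuisance terms
#'   and spikes in one design and band-passes the residuals;
#'   `"filter_then_regress"` band-passes first and regresses afterwards.
#' @param head_radius Sphere radius (mm) converting rotations to displacement
#'   in the FD computation (default 50).
#' @return A `conditioning_config` list.
#' @export
conditioning_config <- function(band_low = 0.01, band_high = 0.08, tr = 2,
                                spike_fd_threshold = 0.5, detrend_order = 1,
                                use_friston24 = TRUE, use_tissue = TRUE,
                                order = c("regress_then_filter",
                                          "filter_then_regress"),
                                head_radius = 50) {
  nyquist <- 1 / (2 * tr)
  if (!(band_low > 0 && band_low < band_high && band_high < nyquist)) {
    rlang::abort(sprintf(
      "band must satisfy 0 < low < high < Nyquist (%.3g Hz)", nyquist
    ))
  }
  structure(
    list(band_low = band_low, band_high = band_high, tr = tr,
         spike_fd_threshold = spike_fd_threshold,
         detrend_order = detrend_order, use_friston24 = use_friston24,
         use_tissue = use_tissue, order = match.arg(order),
         head_radius = head_radius),
    class = "conditioning_config"
  )
}

#' Framewise displacement from realignment parameters
#'
#' FD at volume t is the sum of absolute volume-to-volume changes of the six
#' realignment parameters, with the three rotations (radians) converted to arc
#' displacement on a sphere of `head_radius` mm:
#' `fd[t] = sum(|d trans|) + head_radius * sum(|d rot|)`, and `fd[1] = 0` by
#' convention.
#'
#' @param params T x 6 matrix: 3 translations (mm) then 3 rotations (radians).
#' @param head_radius Sphere radius in mm (default 50).
#' @param spike_threshold FD threshold (mm) defining motion spikes.
#' @return A `motion_trace` list with `fd`, `mean_fd`, `spike_mask`, `params`.
#' @examples
#' p <- matrix(0, 20, 6); p[5:20, 1] <- 1   # a single 1-mm step
#' compute_fd(p)$fd[5]
#' @export
compute_fd <- function(params, head_radius = 50, spike_threshold = 0.5) {
  params <- as.matrix(params)
  if (nrow(params) < 2) {
    rlang::abort("FD needs at least 2 time points")
  }
  if (ncol(params) != 6) {
    rlang::abort("motion parameters must have 6 columns")
  }
  d <- abs(diff(params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  structure(
    list(fd = fd, mean_fd = mean(fd), spike_mask = fd > spike_threshold,
         params = params, head_radius = head_radius,
         spike_threshold = spike_threshold),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d volumes, mean FD %.4f mm, %d spike(s)\n",
              length(x$fd), x$mean_fd, sum(x$spike_mask)))
  invisible(x)
}

#' Friston-24 motion regressor expansion
#'
#' Expands the six realignment parameters into 24 regressors: for each
#' parameter p, the columns p, p^2, p lagged by one volume, and the square of
#' the lagged parameter. Lagged columns are zero-padded at the first row.
#'
#' @param params T x 6 motion-parameter matrix.
#' @return A T x 24 matrix.
#' @export
friston24_expand <- function(params) {
  params <- as.matrix(params)
  if (nrow(params) < 2) {
    rlang::abort("Friston-24 expansion needs at least 2 time points")
  }
  if (ncol(params) != 6) {
    rlang::abort("motion parameters must have 6 columns")
  }
  lag1 <- rbind(0, params[-nrow(params), , drop = FALSE])
  out <- cbind(params, params^2, lag1, lag1^2)
  nm <- colnames(params) %||% paste0("p", 1:6)
  colnames(out) <- c(nm, paste0(nm, "_sq"), paste0(nm, "_lag"),
                     paste0(nm, "_lag_sq"))
  out
}

# Zero-phase Butterworth band-pass, column-wise.
bandpass_ <- function(x, band_low, band_high, tr) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(2, c(band_low, band_high) / nyq, type = "pass")
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Condition ROI time series
#'
#' Removes nuisance structure from each ROI series by ordinary least squares
#' against a design holding an intercept, polynomial trend, the Friston-24
#' motion expansion, optional tissue (white-matter/CSF) signals, and one
#' indicator column per FD spike, then band-pass filters the residuals
#' (zero-phase Butterworth) and re-centers each column to zero mean. With
#' `cfg$order = "filter_then_regress"` the band-pass is applied first.
#'
#' @param ts T x R numeric matrix of ROI signals.
#' @param motion A [compute_fd()] `motion_trace`, a T x 6 parameter matrix
#'   (converted internally), or `NULL` for no motion regressors.
#' @param cfg A [conditioning_config()].
#' @param tissue Optional T x 2 matrix of tissue nuisance signals.
#' @param filter Apply the band-pass stage (default `TRUE`); `FALSE` runs
#'   the nuisance regression alone.
#' @return A T x R matrix of conditioned signals (zero-mean columns).
#' @export
condition_timeseries <- function(ts, motion = NULL,
                                 cfg = conditioning_config(),
                                 tissue = NULL, filter = TRUE) {
  ts <- as.matrix(ts)
  n_t <- nrow(ts)
  if (!is.null(motion) && !inherits(motion, "motion_trace")) {
    motion <- compute_fd(motion, head_radius = cfg$head_radius,
                         spike_threshold = cfg$spike_fd_threshold)
  }
  if (!is.null(motion) && length(motion$fd) != n_t) {
    rlang::abort("motion trace and time series lengths differ")
  }
  if (!is.null(tissue) && nrow(tissue) != n_t) {
    rlang::abort("tissue signals and time series lengths differ")
  }
  design <- cbind(intercept = rep(1, n_t),
                  stats::poly(seq_len(n_t), cfg$detrend_order, raw = FALSE))
  if (!is.null(motion) && cfg$use_friston24) {
    design <- cbind(design, friston24_expand(motion$params))
  }
  if (!is.null(tissue) && cfg$use_tissue) {
    design <- cbind(design, as.matrix(tissue))
  }
  if (!is.null(motion) && any(motion$spike_mask)) {
    spikes <- which(motion$spike_mask)
    ind <- matrix(0, n_t, length(spikes))
    ind[cbind(spikes, seq_along(spikes))] <- 1
    colnames(ind) <- paste0("spike_", spikes)
    design <- cbind(design, ind)
  }
  # constant regressors (e.g. zero motion) carry no nuisance beyond the
  # intercept and would only make the design singular
  keep <- c(TRUE, apply(design[, -1, drop = FALSE], 2, stats::var) > 0)
  design <- design[, keep, drop = FALSE]
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    rlang::abort(sprintf(
      "nuisance design is rank deficient (%d columns, rank %d)",
      ncol(design), qr_d$rank
    ))
  }
  if (ncol(design) >= n_t) {
    rlang::abort("more nuisance regressors than time points")
  }
  regress <- function(y) y - qr.fitted(qr_d, y)
  bp <- if (filter) {
    function(y) bandpass_(y, cfg$band_low, cfg$band_high, cfg$tr)
  } else {
    identity
  }
  out <- switch(cfg$order,
    regress_then_filter = bp(regress(ts)),
    filter_then_regress = regress(bp(ts))
  )
  out <- sweep(out, 2, colMeans(out))
  dimnames(out) <- dimnames(ts)
  out
}

#' Condition every subject of a cohort
#'
#' Applies [compute_fd()] and [condition_timeseries()] to each subject and
#' records per-subject quality-control summaries.
#'
#' @param cohort A `motor_cohort` tibble from [simulate_cohort()] (or any
#'   tibble with `timeseries`, `motion`, `tissue` list-columns).
#' @param cfg A [conditioning_config()].
#' @return The cohort with added columns `conditioned` (list of T x R
#'   matrices), `mean_fd`, and `n_spikes`.
#' @export
condition_cohort <- function(cohort, cfg = conditioning_config()) {
  traces <- purrr::map(cohort$motion, compute_fd,
                       head_radius = cfg$head_radius,
                       spike_threshold = cfg$spike_fd_threshold)
  tissue <- if ("tissue" %in% names(cohort)) cohort$tissue else
    rep(list(NULL), nrow(cohort))
  cohort$conditioned <- purrr::pmap(
    list(cohort$timeseries, traces, tissue),
    function(ts, tr, ti) condition_timeseries(ts, tr, cfg, ti)
  )
  cohort$mean_fd <- purrr::map_dbl(traces, "mean_fd")
  cohort$n_spikes <- purrr::map_dbl(traces, ~sum(.x$spike_mask))
  cohort
}
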