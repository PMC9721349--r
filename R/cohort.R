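# Synthetic two-group cohort generator.
#
# The generator emulates the study design the rest of the pipeline expects:
# 23 patients + 15 controls, 175 retained volumes at TR = 2 s, 21 ROIs with a
# block-structured inter-regional correlation target, group effects planted on
# specific edges, and head-motion traces small enough to pass the usual
# < 2 mm / < 2 degree inclusion criteria.

#' Default planted group-difference edges
#'
#' The default perturbation pattern mirrors the cerebello-thalamo-striato-
#' cortical circuit reported in patients: one increased edge (left dentate
#' nucleus to left thalamus) and nine decreased cortico-cortical,
#' cortico-subcortical and cortico-cerebellar edges. Deltas are expressed on
#' the correlation (r) scale and applied to the patient group only.
#'
#' @param delta_increase Correlation increase on L-DN to L-Th (default +0.25).
#' @param delta_decrease Correlation change on the nine decreased edges
#'   (default -0.20).
#' @return A tibble with columns `roi_i`, `roi_j`, `delta_r`.
#' @export
default_planted_edges <- function(delta_increase = 0.25,
                                  delta_decrease = -0.20) {
  dec <- tibble::tribble(
    ~roi_i, ~roi_j,
    "L-SPL", "R-BG",
    "L-SMA", "L-M1",
    "L-Th",  "L-M1",
    "L-SCb", "R-M1",
    "R-SCb", "R-M1",
    "L-SMA", "R-M1",
    "L-SMA", "L-PMd",
    "R-SMA", "L-PMd",
    "R-SMA", "L-SCb"
  )
  dplyr::bind_rows(
    tibble::tibble(roi_i = "L-DN", roi_j = "L-Th", delta_r = delta_increase),
    dplyr::mutate(dec, delta_r = delta_decrease)
  )
}

#' Block-structured correlation target for the motor network
#'
#' Builds a symmetric positive-definite correlation matrix in which ROI pairs
#' within the same subsystem (cerebellar, subcortical, cortical) share a
#' common correlation and pairs in different subsystems a weaker one.
#'
#' @param atlas Atlas tibble from [motor_atlas()].
#' @param within,between Target Pearson correlations within and between
#'   subsystems (defaults 0.5 and 0.1).
#' @return A 21 x 21 correlation matrix with ROI labels as dimnames.
#' @export
block_covariance <- function(atlas = motor_atlas(), within = 0.5,
                             between = 0.1) {
  b <- atlas$subsystem
  m <- outer(b, b, function(a, c) ifelse(a == c, within, between))
  diag(m) <- 1
  dimnames(m) <- list(atlas$label, atlas$label)
  m
}

#' Specify a synthetic cohort
#'
#' Bundles the design constants of a simulated two-group resting-state study.
#' The defaults reproduce the study conditions this pipeline targets:
#' 23 patients and 15 controls, 185 acquired volumes with the first 10
#' discarded (175 retained), TR = 2 s, 21 ROIs, block-structured correlations
#' (within-subsystem r = 0.5, between 0.1), and the [default_planted_edges()]
#' pattern applied to patients.
#'
#' The patient-group correlation target (base plus planted deltas) is checked
#' for positive definiteness; when `repair_covariance = TRUE` (default) it is
#' repaired by clipping eigenvalues at `1e-6` and rescaling to unit diagonal,
#' otherwise construction fails naming the offending eigenvalue.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Retained volumes per subject (post-discard).
#' @param tr Repetition time in seconds.
#' @param atlas Atlas tibble; fixes `n_rois` and ROI labels.
#' @param base_covariance Target correlation matrix (default block-structured).
#' @param planted_edges Tibble (`roi_i`, `roi_j`, `delta_r`) of patient-group
#'   correlation perturbations; `NULL` for none.
#' @param ar_coefficient Lag-1 autocorrelation of the simulated signals,
#'   in `[0, 1)`.
#' @param motion_scale Standard deviation (mm) of the per-volume head-motion
#'   random-walk steps; rotations use `motion_scale / head_radius` rad.
#' @param head_radius Sphere radius (mm) linking rotations to displacement.
#' @param seed Integer RNG seed used by [simulate_cohort()].
#' @param repair_covariance Repair a non-positive-definite patient target by
#'   eigenvalue clipping instead of failing.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' spec$n_patients + spec$n_controls  # 38
#' @export
cohort_spec <- function(n_patients = 23, n_controls = 15, n_timepoints = 175,
                        tr = 2, atlas = motor_atlas(), base_covariance = NULL,
                        planted_edges = default_planted_edges(),
                        ar_coefficient = 0.3, motion_scale = 0.02,
                        head_radius = 50, seed = 1L,
                        repair_covariance = TRUE) {
  if (n_timepoints < 3) {
    rlang::abort("n_timepoints must be at least 3 (Pearson df = T - 2 > 0)")
  }
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    rlang::abort("ar_coefficient must lie in [0, 1)")
  }
  base_covariance <- base_covariance %||% block_covariance(atlas)
  check_correlation_target(base_covariance, "base_covariance")
  patient_cov <- apply_planted_edges(base_covariance, planted_edges,
                                     repair = repair_covariance)
  structure(
    list(
      n_patients = n_patients, n_controls = n_controls,
      n_timepoints = n_timepoints, tr = tr, atlas = atlas,
      n_rois = nrow(atlas), base_covariance = base_covariance,
      patient_covariance = patient_cov, planted_edges = planted_edges,
      ar_coefficient = ar_coefficient, motion_scale = motion_scale,
      head_radius = head_radius, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d patients + %d controls, %d x %d time series (TR %g s)\n",
              x$n_patients, x$n_controls, x$n_timepoints, x$n_rois, x$tr))
  n_pl <- if (is.null(x$planted_edges)) 0L else nrow(x$planted_edges)
  cat(sprintf("  ar(1) = %g, motion scale %g mm, %d planted edge(s), seed %d\n",
              x$ar_coefficient, x$motion_scale, n_pl, x$seed))
  invisible(x)
}

check_correlation_target <- function(m, name) {
  if (!isSymmetric(m, tol = 1e-10)) {
    rlang::abort(sprintf("%s must be symmetric", name))
  }
  if (max(abs(diag(m) - 1)) > 1e-10) {
    rlang::abort(sprintf("%s must have unit diagonal", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    rlang::abort(sprintf(
      "%s is not positive definite (smallest eigenvalue %.3e)", name, min(ev)
    ))
  }
  invisible(ev)
}

# Apply patient-group deltas to the correlation target; repair positive
# definiteness by eigenvalue clipping at 1e-6 (then rescale to unit diagonal)
# or fail naming the offending eigenvalue.
apply_planted_edges <- function(base, planted_edges, repair = TRUE) {
  m <- base
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    labs <- rownames(base)
    for (k in seq_len(nrow(planted_edges))) {
      i <- match(planted_edges$roi_i[k], labs)
      j <- match(planted_edges$roi_j[k], labs)
      if (is.na(i) || is.na(j)) {
        rlang::abort(sprintf(
          "planted edge %s--%s names an ROI absent from the atlas",
          planted_edges$roi_i[k], planted_edges$roi_j[k]
        ))
      }
      m[i, j] <- m[i, j] + planted_edges$delta_r[k]
      m[j, i] <- m[i, j]
    }
    if (max(abs(m[upper.tri(m)])) >= 1) {
      rlang::abort("planted deltas push a correlation outside (-1, 1)")
    }
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) <= 0) {
    if (!repair) {
      rlang::abort(sprintf(
        "perturbed covariance is not positive definite (eigenvalue %.3e)",
        min(e$values)
      ))
    }
    v <- pmax(e$values, 1e-6)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- stats::cov2cor(m)
    dimnames(m) <- dimnames(base)
  }
  m
}

# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed_ <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal sampling by inverse-CDF; exact and vectorized.
rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  stats::qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# Stationary AR(1) series with unit marginal variance, T x k.
ar1_noise_ <- function(n_t, k, phi) {
  e <- matrix(rnorm(n_t * k), n_t, k)
  if (phi == 0) return(e)
  z <- e
  z[-1, ] <- z[-1, ] * sqrt(1 - phi^2)
  for (t in 2:n_t) z[t, ] <- phi * z[t - 1, ] + z[t, ]
  z
}

# Fold a random walk back into [-b, b] (reflecting bounds).
reflect_ <- function(x, b) {
  b - abs((x + b) %% (4 * b) - 2 * b)
}

#' Simulate one subject
#'
#' Draws a stationary Gaussian AR(1) ROI time-series matrix whose population
#' Pearson correlation structure equals the spec's target for the given group
#' (base for controls, base plus planted deltas for patients), a bounded
#' random-walk motion trace, and two surrogate tissue (white-matter / CSF)
#' nuisance series.
#'
#' @param spec A [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param seed Integer seed for this subject's substream.
#' @return A list with elements `timeseries` (T x R), `motion_params` (T x 6),
#'   `tissue` (T x 2), and `group`.
#' @export
simulate_subject <- function(spec, group = c("control", "patient"),
                             seed = spec$seed) {
  group <- match.arg(group)
  sigma <- if (group == "patient") spec$patient_covariance else
    spec$base_covariance
  with_seed_(seed, {
    z <- ar1_noise_(spec$n_timepoints, spec$n_rois, spec$ar_coefficient)
    x <- z %*% chol(sigma)
    colnames(x) <- spec$atlas$label
    # head motion: reflected Gaussian random walks, translations in mm and
    # rotations in radians scaled so both contribute equally to FD
    steps <- cbind(
      matrix(rnorm(spec$n_timepoints * 3, 0, spec$motion_scale),
             spec$n_timepoints, 3),
      matrix(rnorm(spec$n_timepoints * 3, 0, spec$motion_scale /
                     spec$head_radius), spec$n_timepoints, 3)
    )
    walk <- apply(steps, 2, cumsum)
    if (spec$motion_scale > 0) {
      walk[, 1:3] <- reflect_(walk[, 1:3], 2)
      walk[, 4:6] <- reflect_(walk[, 4:6], 2 * pi / 180)
    }
    colnames(walk) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
    tissue <- ar1_noise_(spec$n_timepoints, 2, spec$ar_coefficient)
    colnames(tissue) <- c("white_matter", "csf")
    list(timeseries = x, motion_params = walk, tissue = tissue, group = group)
  })
}

#' Simulate a full cohort
#'
#' Generates `n_patients + n_controls` subjects with demographics anchored to
#' the study population (patient age 22.30 +/- 5.49 years, control age
#' 24.67 +/- 5.21, both truncated to the 15-36 range; sex counts 11/12 female/
#' male in patients and 7/8 in controls at the default sizes; patient onset
#' age 13.48 +/- 4.57 and illness duration 8.83 +/- 5.10 years). Each subject
#' is drawn from its own RNG substream derived from the master seed, so the
#' cohort is reproducible subject-by-subject.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master seed; defaults to `spec$seed`.
#' @return A `motor_cohort` tibble with one row per subject: `subject_id`,
#'   `group`, `age`, `sex`, `onset_age`, `duration`, and list-columns
#'   `timeseries` (T x R matrix), `motion` (T x 6), `tissue` (T x 2).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 3, n_controls = 2,
#'                                       n_timepoints = 40))
#' nrow(cohort)
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  n_p <- spec$n_patients
  n_c <- spec$n_controls
  n <- n_p + n_c
  with_seed_(seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    group <- c(rep("patient", n_p), rep("control", n_c))
    age <- c(rtruncnorm_(n_p, 22.30, 5.49, 15, 36),
             rtruncnorm_(n_c, 24.67, 5.21, 15, 36))
    n_f_p <- round(n_p * 11 / 23)
    n_f_c <- round(n_c * 7 / 15)
    sex <- c(rep(c("female", "male"), c(n_f_p, n_p - n_f_p)),
             rep(c("female", "male"), c(n_f_c, n_c - n_f_c)))
    onset <- rep(NA_real_, n)
    duration <- rep(NA_real_, n)
    onset[1:n_p] <- pmin(rtruncnorm_(n_p, 13.48, 4.57, 2, 30), age[1:n_p] - 1)
    duration[1:n_p] <- pmin(rtruncnorm_(n_p, 8.83, 5.10, 0.5, 30),
                            age[1:n_p] - onset[1:n_p])
    subjects <- purrr::map2(group, subject_seeds,
                            function(g, s) simulate_subject(spec, g, s))
    out <- tibble::tibble(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      group = factor(group, levels = c("patient", "control")),
      age = round(age, 1),
      sex = factor(sex, levels = c("female", "male")),
      onset_age = round(onset, 1),
      duration = round(duration, 1),
      motion = purrr::map(subjects, "motion_params"),
      tissue = purrr::map(subjects, "tissue"),
      timeseries = purrr::map(subjects, "timeseries")
    )
    class(out) <- c("motor_cohort", class(out))
    attr(out, "spec") <- spec
    out
  })
}
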