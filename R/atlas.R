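#' The 21-node motor execution network atlas
#'
#' Returns the 21 spherical regions of interest (ROIs) that define the motor
#' execution network: bilateral anterior inferior cerebellum (AICb), basal
#' ganglia (BG), dentate nucleus (DN), supplementary motor area (SMA),
#' superior parietal lobule (SPL), primary motor cortex (M1), dorsolateral and
#' ventrolateral premotor cortex (PMd, PMv), superior cerebellum (SCb),
#' thalamus (Th), and the right postcentral gyrus (PCG). Centers are MNI
#' coordinates in mm; each node is a sphere of `sphere_diameter` mm.
#'
#' The constructor validates that labels are unique and that no two spheres
#' overlap (all pairwise center distances are at least `sphere_diameter`).
#' Each ROI is also tagged with the subsystem it belongs to (`cerebellar`,
#' `subcortical`, `cortical`), which the synthetic cohort generator uses to
#' build its block-structured correlation target.
#'
#' @param sphere_diameter Sphere diameter in mm (default 10).
#' @return A tibble with columns `label`, `region`, `hemisphere`, `subsystem`,
#'   `x`, `y`, `z`, and attribute `sphere_diameter`.
#' @examples
#' atlas <- motor_atlas()
#' nrow(atlas)  # 21
#' @export
motor_atlas <- function(sphere_diameter = 10) {
  entries <- tibble::tribble(
    ~region, ~hemisphere, ~x, ~y, ~z, ~subsystem,
    "AICb", "L", -22, -45, -49, "cerebellar",
    "AICb", "R",  16, -45, -49, "cerebellar",
    "BG",   "L", -25, -14,   8, "subcortical",
    "BG",   "R",  22,  -2,  12, "subcortical",
    "DN",   "L", -28, -55, -43, "cerebellar",
    "DN",   "R",  19, -55, -39, "cerebellar",
    "SMA",  "L",  -5,  -4,  57, "cortical",
    "SMA",  "R",   5,  -4,  57, "cortical",
    "SPL",  "L", -22, -62,  54, "cortical",
    "SPL",  "R",  16, -66,  57, "cortical",
    "M1",   "L", -38, -22,  56, "cortical",
    "M1",   "R",  38, -22,  56, "cortical",
    "PMd",  "L", -22, -13,  57, "cortical",
    "PMd",  "R",  28, -10,  54, "cortical",
    "PMv",  "L", -49,  -1,  38, "cortical",
    "PMv",  "R",  53,   0,  25, "cortical",
    "SCb",  "L", -25, -56, -21, "cerebellar",
    "SCb",  "R",  16, -59, -21, "cerebellar",
    "Th",   "L", -10, -20,  11, "subcortical",
    "Th",   "R",   7, -20,  11, "subcortical",
    "PCG",  "R",  37, -34,  53, "cortical"
  )
  atlas <- dplyr::mutate(entries,
    label = paste(.data$hemisphere, .data$region, sep = "-"),
    .before = 1
  )
  if (anyDuplicated(atlas$label) > 0) {
    rlang::abort("atlas labels must be unique")
  }
  d <- as.matrix(stats::dist(atlas[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (min(d) < sphere_diameter) {
    bad <- which(d == min(d), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "spheres of diameter %g mm overlap: %s and %s are %.2f mm apart",
      sphere_diameter, atlas$label[bad[1]], atlas$label[bad[2]], min(d)
    ))
  }
  attr(atlas, "sphere_diameter") <- sphere_diameter
  atlas
}

#' Minimum pairwise center distance of an atlas
#'
#' @param atlas An atlas tibble from [motor_atlas()].
#' @return Minimum Euclidean distance (mm) between any two ROI centers.
#' @export
atlas_min_distance <- function(atlas) {
  d <- as.matrix(stats::dist(atlas[, c("x", "y", "z")]))
  diag(d) <- Inf
  min(d)
}

#' Extract mean sphere-ROI time series from a 4D volume
#'
#' Averages the signal across all voxels whose centers fall strictly within
#' `sphere_diameter / 2` mm of each ROI center (half-open ball, world
#' coordinates via the image affine). This is the volumetric entry point of
#' the pipeline; most workflows instead start from ROI time-series tables.
#'
#' @param volume A 4D array (X x Y x Z x T) or an `RNifti` image. For a plain
#'   array, `affine` must be supplied.
#' @param atlas Atlas tibble from [motor_atlas()].
#' @param affine 4x4 voxel-index (0-based) to world-mm affine matrix; taken
#'   from the NIfTI header when `volume` is an `RNifti` image.
#' @return A T x 21 matrix with ROI labels as column names.
#' @export
extract_roi_timeseries <- function(volume, atlas, affine = NULL) {
  if (inherits(volume, "niftiImage")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      rlang::abort("reading NIfTI volumes requires the RNifti package")
    }
    affine <- RNifti::xform(volume)
    volume <- as.array(volume)
  }
  if (is.null(affine)) {
    rlang::abort("an affine matrix is required for plain-array input")
  }
  stopifnot(length(dim(volume)) == 4, all(dim(affine) == c(4, 4)))
  dims <- dim(volume)
  radius <- attr(atlas, "sphere_diameter") / 2
  # world coordinates of every voxel center (0-based indices)
  grid <- as.matrix(expand.grid(
    i = seq_len(dims[1]) - 1, j = seq_len(dims[2]) - 1, k = seq_len(dims[3]) - 1
  ))
  world <- grid %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(grid), 3, byrow = TRUE)
  vol_mat <- matrix(volume, prod(dims[1:3]), dims[4])
  out <- matrix(NA_real_, dims[4], nrow(atlas),
                dimnames = list(NULL, atlas$label))
  for (n in seq_len(nrow(atlas))) {
    ctr <- c(atlas$x[n], atlas$y[n], atlas$z[n])
    d2 <- (world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 +
      (world[, 3] - ctr[3])^2
    inside <- d2 < radius^2
    if (!any(inside)) {
      rlang::abort(sprintf(
        "ROI %s contains no voxel centers (grid too coarse or out of field)",
        atlas$label[n]
      ))
    }
    out[, n] <- colMeans(vol_mat[inside, , drop = FALSE])
  }
  out
}
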