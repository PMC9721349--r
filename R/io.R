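# Plain-text interchange: per-subject time-series TSVs, SPM-style rp_*.txt
# motion files, covariate tables, connectivity matrices, and a miniature
# synthetic NIfTI emitter for end-to-end tests of sphere extraction.

write_tsv_ <- function(x, path, rownames = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = TRUE)
}

#' Write a cohort to disk
#'
#' Emits one time-series TSV per subject (columns = ROI labels), one
#' whitespace-delimited 6-column motion file per subject (`rp_<id>.txt`,
#' SPM dialect: 3 translations in mm then 3 rotations in radians), one tissue
#' TSV per subject, and a cohort covariate table `participants.tsv`.
#'
#' @param cohort A `motor_cohort` tibble.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    write_tsv_(cohort$timeseries[[i]],
               file.path(dir, paste0(id, "_timeseries.tsv")))
    utils::write.table(cohort$motion[[i]],
                       file.path(dir, paste0("rp_", id, ".txt")),
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    if ("tissue" %in% names(cohort)) {
      write_tsv_(cohort$tissue[[i]],
                 file.path(dir, paste0(id, "_tissue.tsv")))
    }
  }
  covs <- cohort[, intersect(
    c("subject_id", "group", "age", "sex", "onset_age", "duration"),
    names(cohort)
  )]
  write_tsv_(as.data.frame(covs), file.path(dir, "participants.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `participants.tsv` and per-subject files.
#' @return A `motor_cohort` tibble with `timeseries`, `motion` (and `tissue`
#'   when present) list-columns.
#' @export
read_cohort <- function(dir) {
  covs <- utils::read.table(file.path(dir, "participants.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(covs)
  out$group <- factor(out$group, levels = c("patient", "control"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out$motion <- purrr::map(out$subject_id, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0("rp_", id, ".txt"))))
  })
  out$timeseries <- purrr::map(out$subject_id, function(id) {
    as.matrix(utils::read.table(
      file.path(dir, paste0(id, "_timeseries.tsv")),
      sep = "\t", header = TRUE, check.names = FALSE
    ))
  })
  tissue_files <- file.path(dir, paste0(out$subject_id, "_tissue.tsv"))
  if (all(file.exists(tissue_files))) {
    out$tissue <- purrr::map(tissue_files, function(f) {
      as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                  check.names = FALSE))
    })
  }
  class(out) <- c("motor_cohort", class(out))
  out
}

#' Write a subject's connectivity matrices
#'
#' Writes the correlation, binary, and weighted matrices as three labeled
#' 21 x 21 TSVs.
#'
#' @param cm A thresholded `connectivity` object.
#' @param dir Output directory.
#' @param subject_id Filename prefix.
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(cm, dir, subject_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_(cm$r, file.path(dir, paste0(subject_id, "_r.tsv")),
             rownames = TRUE)
  if (!is.null(cm$binary)) {
    write_tsv_(cm$binary, file.path(dir, paste0(subject_id, "_binary.tsv")),
               rownames = TRUE)
    write_tsv_(cm$weighted,
               file.path(dir, paste0(subject_id, "_weighted.tsv")),
               rownames = TRUE)
  }
  invisible(dir)
}

#' Render a subject's ROI series as a miniature 4D volume
#'
#' Builds a small 4D array on an isotropic grid covering the atlas bounding
#' box in which every voxel inside ROI j's sphere carries that ROI's time
#' series (plus optional voxel noise) and all other voxels carry noise. Used
#' to exercise the volumetric extraction path without real scanner data.
#'
#' @param ts T x R ROI time-series matrix (columns ordered as `atlas`).
#' @param atlas Atlas tibble.
#' @param voxel_mm Isotropic voxel size in mm (default 3).
#' @param noise_sd Standard deviation of added voxel noise (default 0).
#' @param margin Margin (mm) around the atlas bounding box.
#' @return A list with `volume` (X x Y x Z x T array) and `affine` (4 x 4,
#'   0-based voxel indices to MNI mm).
#' @export
roi_volume <- function(ts, atlas, voxel_mm = 3, noise_sd = 0, margin = 6) {
  ts <- as.matrix(ts)
  radius <- attr(atlas, "sphere_diameter") / 2
  lo <- c(min(atlas$x), min(atlas$y), min(atlas$z)) - margin
  hi <- c(max(atlas$x), max(atlas$y), max(atlas$z)) + margin
  dims <- ceiling((hi - lo) / voxel_mm) + 1
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- lo
  n_t <- nrow(ts)
  vol <- array(rnorm(prod(dims) * n_t, sd = noise_sd),
               dim = c(dims, n_t))
  grid <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                                j = seq_len(dims[2]) - 1,
                                k = seq_len(dims[3]) - 1))
  world <- grid * voxel_mm + matrix(lo, nrow(grid), 3, byrow = TRUE)
  vol_mat <- matrix(vol, prod(dims), n_t)
  for (n in seq_len(nrow(atlas))) {
    ctr <- c(atlas$x[n], atlas$y[n], atlas$z[n])
    d2 <- (world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 +
      (world[, 3] - ctr[3])^2
    inside <- d2 < radius^2
    vol_mat[inside, ] <- vol_mat[inside, , drop = FALSE] +
      matrix(ts[, n], sum(inside), n_t, byrow = TRUE)
  }
  list(volume = array(vol_mat, c(dims, n_t)), affine = affine)
}

#' Write a miniature synthetic 4D NIfTI volume
#'
#' Renders [roi_volume()] output to a `.nii` file (requires RNifti). The
#' emitted volume is synthetic: a block rendering of ROI series on a coarse
#' grid, not a simulated scan.
#'
#' @inheritParams roi_volume
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_roi_nifti <- function(ts, atlas, path, voxel_mm = 3, noise_sd = 0) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    rlang::abort("writing NIfTI requires the RNifti package")
  }
  rv <- roi_volume(ts, atlas, voxel_mm = voxel_mm, noise_sd = noise_sd)
  img <- RNifti::asNifti(rv$volume)
  img <- RNifti::`sform<-`(img, structure(rv$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
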