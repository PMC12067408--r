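#' Save a volume as NIfTI
#'
#' Writes `.nii`/`.nii.gz` with an axis-aligned affine encoding the voxel
#' spacing and origin. Label volumes round-trip bit-exactly (integer
#' storage); spacing is preserved to NIfTI float precision.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# extract (spacing, origin, flip) from an axis-aligned NIfTI affine
affine_to_grid <- function(img, tol = 1e-3) {
  aff <- RNifti::xform(img)
  m <- aff[1:3, 1:3]
  offdiag <- m - diag(diag(m))
  if (max(abs(offdiag)) > tol)
    stop("NIfTI affine is not axis-aligned (tolerance 1e-3)")
  list(spacing = abs(diag(m)), origin = aff[1:3, 4], step = diag(m))
}

#' Load a grey-scale NIfTI volume
#'
#' Slice order is normalized to base-to-apex at load: if the affine's z
#' step is negative the slice axis is flipped (and the origin adjusted) so
#' that the stored z always increases with slice index.
#'
#' @param path NIfTI file path.
#' @return An [image_volume()].
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  gr <- affine_to_grid(img)
  raw <- as.array(img)
  vals <- array(as.vector(raw), dim(raw)[1:3])  # drop NIfTI attributes
  origin <- gr$origin
  if (gr$step[3] < 0) {
    vals <- vals[, , rev(seq_len(dim(vals)[3])), drop = FALSE]
    origin[3] <- gr$origin[3] + (dim(vals)[3] - 1) * gr$step[3]
  }
  image_volume(vals, gr$spacing, origin)
}

#' Load a 5-class label NIfTI volume
#'
#' As [load_volume()], with label validation: any voxel outside 0..4 raises
#' an error naming the voxel.
#'
#' @param path NIfTI file path.
#' @return A [label_volume()].
#' @export
load_labels <- function(path) {
  v <- load_volume(path)
  label_volume(array(as.integer(round(v$values)), dim(v$values)),
               v$spacing, v$origin)
}

#' Load a cine study from per-frame NIfTI files
#'
#' @param paths Character vector of frame paths, ordered; frame 1 is ED.
#' @param heart_rate,body_weight Subject metadata (bpm, g).
#' @param subject_id,timepoint Identifiers stored in the study.
#' @return A [cine_study()].
#' @export
load_study <- function(paths, heart_rate, body_weight,
                       subject_id = "subject", timepoint = "control") {
  frames <- lapply(paths, load_volume)
  cine_study(frames, heart_rate, body_weight, subject_id, timepoint)
}

#' Check that an image and a label map share a grid
#'
#' @param img An [image_volume()].
#' @param lab A [label_volume()].
#' @param tol Metadata tolerance (mm).
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_paired_grid <- function(img, lab, tol = 1e-6) {
  if (!same_grid(img, lab, tol))
    stop("image and label grids do not match (dimensions/spacing/origin)")
  invisible(TRUE)
}
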