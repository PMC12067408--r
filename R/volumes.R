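#' @useDynLib ratcine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile median sd cor var prcomp setNames
#' @importFrom utils head tail write.csv read.csv
#' @importFrom dplyr .data
NULL

#' Five-class bi-ventricular label dictionary
#'
#' Integer codes used throughout the package: 0 background, 1 LV cavity
#' (blood pool, trabeculae and papillary muscles included), 2 LV wall
#' (interventricular septum included), 3 RV cavity, 4 RV wall.
#'
#' @format Named integer vector of length 5.
#' @export
heart_labels <- c(
  background = 0L, lv_cavity = 1L, lv_wall = 2L,
  rv_cavity = 3L, rv_wall = 4L
)

#' Construct a grey-scale image volume
#'
#' A minimal 3-D scalar grid with voxel spacing and origin. The physical
#' coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + (i - 1, j - 1, k - 1) * spacing` (voxel centres). The slice
#' axis (third index) runs base to apex.
#'
#' @param values 3-D numeric array.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all positive.
#' @param origin Physical coordinate (mm) of the centre of voxel (1,1,1).
#' @return An `image_volume` object.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a 5-class label volume
#'
#' Like [image_volume()] but holding integer anatomical labels from
#' [heart_labels]. Values outside 0..4 are rejected, naming the first
#' offending voxel.
#'
#' @inheritParams image_volume
#' @return A `label_volume` object.
#' @export
label_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3,
            all(spacing > 0), length(origin) == 3)
  storage.mode(values) <- "integer"
  bad <- which(!(values %in% 0:4))
  if (length(bad) > 0) {
    ijk <- arrayInd(bad[1], dim(values))
    stop(sprintf("unknown label value %d at voxel (%d, %d, %d)",
                 values[bad[1]], ijk[1], ijk[2], ijk[3]))
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("label_volume", "image_volume"))
}

#' Bundle cine frames with subject metadata
#'
#' @param frames List of [image_volume()] objects sharing one grid; frame 1
#'   is end-diastole.
#' @param heart_rate Heart rate in beats per minute.
#' @param body_weight Body weight in grams.
#' @param subject_id Subject identifier.
#' @param timepoint Cohort/timepoint tag (e.g. `"control"`).
#' @return A `cine_study` object.
#' @export
cine_study <- function(frames, heart_rate, body_weight,
                       subject_id = "subject", timepoint = "control") {
  stopifnot(length(frames) >= 1, heart_rate > 0, body_weight > 0)
  d0 <- dim(frames[[1]]$values)
  for (f in frames) {
    if (!identical(dim(f$values), d0) ||
        max(abs(f$spacing - frames[[1]]$spacing)) > 1e-9)
      stop("all cine frames must share one grid")
  }
  structure(list(frames = frames, heart_rate = heart_rate,
                 body_weight = body_weight, subject_id = subject_id,
                 timepoint = timepoint),
            class = "cine_study")
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing (%s) mm\n", kind,
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf("<cine_study> %s: %d frames, HR %g bpm, BW %g g (%s)\n",
              x$subject_id, length(x$frames), x$heart_rate, x$body_weight,
              x$timepoint))
  invisible(x)
}

#' Voxel volume in microlitres
#'
#' 1 mm^3 equals 1 uL, so this is simply the product of spacings.
#' @param vol An [image_volume()].
#' @return Scalar voxel volume in uL.
#' @export
voxel_volume_ul <- function(vol) prod(vol$spacing)

# physical centre coordinates of every voxel, as an n x 3 matrix ordered
# like the flattened array (x fastest)
grid_points <- function(vol) {
  d <- dim(vol$values)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

# binary mask (numeric cube) for a label subset
label_mask <- function(lab, labels) {
  m <- array(0, dim(lab$values))
  m[lab$values %in% labels] <- 1
  m
}

# signed Euclidean distance (mm), negative inside the mask; a small
# Gaussian (voxel units) removes the half-voxel corrugation of the digital
# distance field so isosurfaces are smooth at the sub-voxel level
signed_distance <- function(mask, spacing, smooth_vox = 0.7) {
  din <- sqrt(cpp_sqedt(mask, spacing))
  dout <- sqrt(cpp_sqedt(1 - mask, spacing))
  phi <- din - dout
  if (smooth_vox > 0) phi <- cpp_gauss_smooth(phi, rep(smooth_vox, 3))
  phi
}

# mean-pool downsample of a cube by factor 2 (trims odd trailing samples)
downsample2 <- function(a) {
  d <- dim(a)
  d2 <- d %/% 2
  a <- a[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3]),
         drop = FALSE]
  # average 2x2x2 blocks
  a <- (a[seq(1, 2 * d2[1], 2), , , drop = FALSE] +
        a[seq(2, 2 * d2[1], 2), , , drop = FALSE]) / 2
  a <- (a[, seq(1, 2 * d2[2], 2), , drop = FALSE] +
        a[, seq(2, 2 * d2[2], 2), , drop = FALSE]) / 2
  (a[, , seq(1, 2 * d2[3], 2), drop = FALSE] +
    a[, , seq(2, 2 * d2[3], 2), drop = FALSE]) / 2
}

# run code under a local, restored RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
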