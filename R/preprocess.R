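#' Augmentation parameters
#'
#' On-the-fly training augmentation: random intensity rescaling (default
#' +/-10%), in-plane rotations (default +/-10 degrees) and a spatial shift
#' along exactly one randomly chosen image axis (default +/-10 pixels),
#' drawn independently per call from a seeded stream.
#'
#' @param intensity_scale_range Fractional intensity scale half-range.
#' @param rotation_range Rotation half-range (degrees, about z).
#' @param shift_range Shift half-range (pixels).
#' @param seed Integer seed for the augmentation stream.
#' @return An `augment_spec` object.
#' @export
augment_spec <- function(intensity_scale_range = 0.10, rotation_range = 10,
                         shift_range = 10, seed = 1L) {
  stopifnot(intensity_scale_range >= 0, rotation_range >= 0, shift_range >= 0)
  structure(list(intensity_scale_range = intensity_scale_range,
                 rotation_range = rotation_range, shift_range = shift_range,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Percentile intensity normalization
#'
#' Clips intensities to the per-scan 1st and 99th percentiles (computed over
#' the whole 3-D stack) and rescales the result linearly to `[0, 1]`. A
#' constant image maps to all zeros. Idempotent on its own output once the
#' tails are saturated.
#'
#' @param img An [image_volume()].
#' @return A normalized [image_volume()].
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "image_volume"), length(img$values) > 0)
  p <- quantile(img$values, c(0.01, 0.99), names = FALSE, type = 7)
  v <- img$values
  if (p[2] <= p[1]) {
    img$values <- array(0, dim(v))
    return(img)
  }
  v[v < p[1]] <- p[1]
  v[v > p[2]] <- p[2]
  img$values <- (v - p[1]) / (p[2] - p[1])
  img
}

# bilinear in-plane resample of a 3-D stack at (source row, col) grids;
# src_i/src_j are matrices of (possibly fractional) 1-based source indices
resample_inplane <- function(vals, src_i, src_j, nearest) {
  d <- dim(vals)
  out <- array(0, d)
  inside <- src_i >= 1 & src_i <= d[1] & src_j >= 1 & src_j <= d[2]
  if (nearest) {
    ii <- round(src_i[inside]); jj <- round(src_j[inside])
    for (k in seq_len(d[3])) {
      sl <- vals[, , k]
      ok <- array(0, d[1:2])
      ok[inside] <- sl[cbind(ii, jj)]
      out[, , k] <- ok
    }
  } else {
    i0 <- floor(src_i[inside]); j0 <- floor(src_j[inside])
    fi <- src_i[inside] - i0; fj <- src_j[inside] - j0
    i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2])
    for (k in seq_len(d[3])) {
      sl <- vals[, , k]
      v <- sl[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
           sl[cbind(i1, j0)] * fi * (1 - fj) +
           sl[cbind(i0, j1)] * (1 - fi) * fj +
           sl[cbind(i1, j1)] * fi * fj
      ok <- array(0, d[1:2])
      ok[inside] <- v
      out[, , k] <- ok
    }
  }
  out
}

# shift a stack along z by a (fractional) number of slices
shift_z <- function(vals, dz, nearest) {
  d <- dim(vals)
  out <- array(0, d)
  src <- seq_len(d[3]) - dz
  if (nearest) src <- round(src)
  for (k in seq_len(d[3])) {
    s <- src[k]
    if (nearest) {
      if (s >= 1 && s <= d[3]) out[, , k] <- vals[, , s]
    } else {
      s0 <- floor(s); f <- s - s0
      if (s0 >= 1 && s0 <= d[3]) out[, , k] <- out[, , k] + (1 - f) * vals[, , s0]
      if (s0 + 1 >= 1 && s0 + 1 <= d[3])
        out[, , k] <- out[, , k] + f * vals[, , s0 + 1]
    }
  }
  out
}

#' Randomly augment a paired image and label map
#'
#' Draws one (intensity scale, in-plane rotation, single-axis shift) triple
#' and applies the identical spatial transform to both inputs: linear
#' interpolation for the image, nearest-neighbour for the label. Intensity
#' scaling affects the image only. The RNG state advances per call, so a
#' fresh draw is made for every batch; seed the stream with `set.seed` (or
#' the training loop's seed) for reproducibility.
#'
#' @param img An [image_volume()].
#' @param lab The paired [label_volume()].
#' @param spec An [augment_spec()].
#' @return List with augmented `image`, `label` and the `draw` used.
#' @export
augment_pair <- function(img, lab, spec) {
  check_paired_grid(img, lab)
  scale <- 1 + runif(1, -1, 1) * spec$intensity_scale_range
  ang <- runif(1, -1, 1) * spec$rotation_range * pi / 180
  axis <- sample.int(3, 1)
  shift <- runif(1, -1, 1) * spec$shift_range
  iv <- img$values * scale
  lv <- lab$values
  if (ang != 0) {
    d <- dim(iv)
    ci <- (d[1] + 1) / 2; cj <- (d[2] + 1) / 2
    ti <- matrix(seq_len(d[1]) - ci, d[1], d[2])
    tj <- matrix(rep(seq_len(d[2]) - cj, each = d[1]), d[1], d[2])
    # inverse rotation of target coords gives source coords
    src_i <- cos(ang) * ti + sin(ang) * tj + ci
    src_j <- -sin(ang) * ti + cos(ang) * tj + cj
    iv <- resample_inplane(iv, src_i, src_j, nearest = FALSE)
    lv <- resample_inplane(lv, src_i, src_j, nearest = TRUE)
  }
  if (shift != 0) {
    if (axis == 3) {
      iv <- shift_z(iv, shift, nearest = FALSE)
      lv <- shift_z(lv, shift, nearest = TRUE)
    } else {
      d <- dim(iv)
      if (axis == 1) {
        si <- matrix(seq_len(d[1]) - shift, d[1], d[2])
        sj <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
      } else {
        si <- matrix(seq_len(d[1]), d[1], d[2])
        sj <- matrix(rep(seq_len(d[2]) - shift, each = d[1]), d[1], d[2])
      }
      iv <- resample_inplane(iv, si, sj, nearest = FALSE)
      lv <- resample_inplane(lv, si, sj, nearest = TRUE)
    }
  }
  iv[iv < 0] <- 0
  out_img <- img; out_img$values <- iv
  out_lab <- lab
  out_lab$values <- array(as.integer(lv), dim(lv))
  list(image = out_img, label = out_lab,
       draw = list(scale = scale, angle_deg = ang * 180 / pi, axis = axis,
                   shift_px = shift))
}

#' Select the end-systolic frame
#'
#' ES is the frame with the smallest LV blood-pool size at the
#' mid-ventricular level; the mid-ventricular slice is the middle slice
#' (floor of half) among slices containing any LV cavity in the ED frame.
#' Ties go to the earliest frame. Frame 1 is ED by convention.
#'
#' @param labels_per_frame List of per-frame [label_volume()] objects.
#' @return Integer frame index (1-based).
#' @export
select_es_frame <- function(labels_per_frame) {
  stopifnot(length(labels_per_frame) >= 2)
  has_lv <- vapply(labels_per_frame,
                   function(l) any(l$values == heart_labels["lv_cavity"]),
                   logical(1))
  if (!any(has_lv)) stop("no LV cavity found in any frame")
  ed <- labels_per_frame[[1]]
  lv_slices <- which(apply(ed$values == 1L, 3, any))
  if (length(lv_slices) == 0) lv_slices <- seq_len(dim(ed$values)[3])
  mid <- lv_slices[max(1L, ceiling(length(lv_slices) / 2))]
  counts <- vapply(labels_per_frame,
                   function(l) sum(l$values[, , mid] == 1L), numeric(1))
  which.min(counts)  # which.min returns the earliest on ties
}
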