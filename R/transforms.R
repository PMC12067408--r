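#' Spatial transforms
#'
#' Transforms map physical points (mm) of a fixed/reference space into a
#' moving space; resampling a moving volume onto a fixed grid samples the
#' moving image at the transformed fixed voxel centres.
#'
#' @param rotation 3 x 3 rotation matrix (orthogonal, det +1).
#' @param translation Length-3 translation (mm).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop("rotation must be orthogonal with det +1")
  structure(list(A = rotation, t = as.numeric(translation)),
            class = c("rigid_transform", "affine_transform", "spatial_transform"))
}

#' @rdname rigid_transform
#' @param matrix 3 x 3 linear part.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  structure(list(A = matrix, t = as.numeric(translation)),
            class = c("affine_transform", "spatial_transform"))
}

#' Free-form deformation transform
#'
#' `T(x) = A x + t + D(x)` where `D` is a cubic B-spline interpolation of a
#' lattice of control-point displacements and `(A, t)` is the affine (or
#' rigid-affine composition) the FFD was initialized from. The composition
#' order rigid -> affine -> FFD is recorded by construction.
#'
#' @param disp 4-D array `(ncx, ncy, ncz, 3)` of control displacements (mm).
#' @param lat_origin Physical position of control point (1,1,1).
#' @param lat_spacing Control-point spacing per axis (mm).
#' @param init An `affine_transform` (includes rigid) applied before the
#'   displacement field.
#' @return An `ffd_transform`.
#' @export
ffd_transform <- function(disp, lat_origin, lat_spacing,
                          init = affine_transform()) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3,
            inherits(init, "affine_transform"))
  structure(list(disp = disp, lat_origin = as.numeric(lat_origin),
                 lat_spacing = as.numeric(lat_spacing), init = init),
            class = c("ffd_transform", "spatial_transform"))
}

#' Apply a transform to points
#'
#' @param tf A `spatial_transform`.
#' @param pts n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(tf, pts) {
  UseMethod("apply_transform")
}

#' @export
apply_transform.affine_transform <- function(tf, pts) {
  sweep(pts %*% t(tf$A), 2, tf$t, "+")
}

#' @export
apply_transform.ffd_transform <- function(tf, pts) {
  base <- apply_transform(tf$init, pts)
  base + cpp_bspline_disp(pts, tf$disp, tf$lat_origin, tf$lat_spacing)
}

#' Compose two affine-class transforms
#'
#' Returns the transform equivalent to applying `first` then `second`.
#'
#' @param second,first Affine or rigid transforms.
#' @return An `affine_transform` (a `rigid_transform` if both inputs are).
#' @export
compose_affine <- function(second, first) {
  A <- second$A %*% first$A
  t <- as.vector(second$A %*% first$t) + second$t
  if (inherits(second, "rigid_transform") && inherits(first, "rigid_transform"))
    rigid_transform(A, t)
  else affine_transform(A, t)
}

#' Invert a rigid or affine transform
#' @param tf An `affine_transform`.
#' @return The inverse transform.
#' @export
invert_affine <- function(tf) {
  Ai <- solve(tf$A)
  out <- affine_transform(Ai, -as.vector(Ai %*% tf$t))
  if (inherits(tf, "rigid_transform")) class(out) <- class(tf)
  out
}

#' Resample a label volume through a transform
#'
#' Nearest-neighbour sampling of `moving` at `T(x)` for every voxel centre
#' `x` of `fixed_grid`; points mapped outside the moving grid become
#' background.
#'
#' @param moving A [label_volume()].
#' @param tf A `spatial_transform` mapping fixed space to moving space.
#' @param fixed_grid A volume defining the output grid.
#' @return A [label_volume()] on the fixed grid.
#' @export
warp_labels <- function(moving, tf, fixed_grid) {
  pts <- apply_transform(tf, grid_points(fixed_grid))
  v <- cpp_nearest(array(as.numeric(moving$values), dim(moving$values)),
                   moving$spacing, moving$origin, pts, 0)
  label_volume(array(as.integer(round(v)), dim(fixed_grid$values)),
               fixed_grid$spacing, fixed_grid$origin)
}

#' Serialize / deserialize transforms as JSON-compatible lists
#'
#' A documented plain-text form (matrix rows, control lattice) for storing
#' fitted transforms alongside pipeline artifacts.
#'
#' @param tf A `spatial_transform`.
#' @return A plain list (`transform_to_list`) or a transform
#'   (`transform_from_list`).
#' @export
transform_to_list <- function(tf) {
  if (inherits(tf, "ffd_transform")) {
    list(type = "ffd", disp = as.vector(tf$disp), dim = dim(tf$disp),
         lat_origin = tf$lat_origin, lat_spacing = tf$lat_spacing,
         init = transform_to_list(tf$init))
  } else {
    list(type = if (inherits(tf, "rigid_transform")) "rigid" else "affine",
         A = as.vector(t(tf$A)), t = tf$t)
  }
}

#' @rdname transform_to_list
#' @param x A list produced by `transform_to_list`.
#' @export
transform_from_list <- function(x) {
  if (x$type == "ffd") {
    ffd_transform(array(x$disp, x$dim), x$lat_origin, x$lat_spacing,
                  transform_from_list(x$init))
  } else {
    A <- matrix(x$A, 3, 3, byrow = TRUE)
    if (x$type == "rigid") rigid_transform(A, x$t)
    else affine_transform(A, x$t)
  }
}
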