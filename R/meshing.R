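#' Long-axis centreline
#'
#' @param point A point on the axis (mm).
#' @param direction Unit direction, oriented apex to base.
#' @return A `centre_axis` object.
#' @export
centre_axis <- function(point, direction) {
  n <- sqrt(sum(direction^2))
  stopifnot(n > 0)
  structure(list(point = as.numeric(point),
                 direction = as.numeric(direction) / n),
            class = "centre_axis")
}

# structure tag -> label subset
structure_labels <- function(structure) {
  switch(structure,
         lv_endo = 1L, lv_epi = c(1L, 2L),
         rv_endo = 3L, rv_epi = c(3L, 4L),
         stop("unknown structure tag: ", structure))
}

#' Triangulated surface mesh
#'
#' @param vertices n x 3 matrix of positions (mm).
#' @param faces m x 3 integer matrix (1-based vertex indices).
#' @param tag Structure tag (`lv_endo`, `lv_epi`, `rv_endo`, `rv_epi`).
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, tag = "surface") {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  structure(list(vertices = vertices, faces = faces, tag = tag),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d vertices, %d faces\n", x$tag,
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract an isosurface mesh from a label volume
#'
#' The structure's binary mask is converted to a signed Euclidean distance
#' field (negative inside; its zero level is the mask's 0.5 level with
#' sub-voxel accuracy) and triangulated by marching tetrahedra on a 6-tet
#' cube decomposition -- a case-table-free member of the marching-cubes
#' family producing closed, consistently oriented (outward) 2-manifold
#' surfaces. Endocardial surfaces use the cavity mask; epicardial surfaces
#' use cavity + wall.
#'
#' @param lab A [label_volume()].
#' @param structure One of `"lv_endo"`, `"lv_epi"`, `"rv_endo"`,
#'   `"rv_epi"`.
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(lab, structure) {
  mask <- label_mask(lab, structure_labels(structure))
  if (sum(mask) == 0) stop("structure ", structure, " has no voxels")
  phi <- signed_distance(mask, lab$spacing)
  mc <- cpp_marching_tetra(phi, 0, lab$spacing, lab$origin)
  surface_mesh(mc$vertices, mc$faces, structure)
}

#' Surface area of a mesh (mm^2)
#' @param mesh A [surface_mesh()].
#' @return Total triangle area.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3, divergence theorem)
#' @param mesh A closed, outward-oriented [surface_mesh()].
#' @return Enclosed volume.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v0 <- v[f[, 1], ]; v1 <- v[f[, 2], ]; v2 <- v[f[, 3], ]
  det3 <- v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
          v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
          v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  abs(sum(det3)) / 6
}

#' Connected components and Euler characteristics of a mesh
#'
#' Splits the face set into vertex-connected components and reports
#' `V - E + F` per component (2 for each closed sphere-like surface).
#'
#' @param mesh A [surface_mesh()].
#' @return Tibble: component, n_vertices, n_edges, n_faces, euler.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  g <- igraph::graph_from_edgelist(
    rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  fcomp <- comp[f[, 1]]
  edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  keys <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]),
            edge_key(f[, 1], f[, 3]))
  ekcomp <- rep(fcomp, 3)
  rows <- lapply(sort(unique(fcomp)), function(cc) {
    vs <- unique(as.vector(f[fcomp == cc, ]))
    es <- unique(keys[ekcomp == cc])
    tibble::tibble(component = cc, n_vertices = length(vs),
                   n_edges = length(es), n_faces = sum(fcomp == cc),
                   euler = length(vs) - length(es) + sum(fcomp == cc))
  })
  dplyr::bind_rows(rows)
}

#' Fit the septal centreline
#'
#' Septal voxels are LV-wall voxels within 2 voxels of the RV cavity; a
#' total-least-squares 3-D line is fitted through their per-slice centroids
#' at ED and held fixed for both phases. The direction is normalized apex
#' to base. If no septal voxels exist the line falls back to per-slice LV
#' cavity centroids (flagged via the `fallback` attribute).
#'
#' @param lab_ed The ED [label_volume()].
#' @return A [centre_axis()].
#' @export
fit_centreline <- function(lab_ed) {
  rv <- label_mask(lab_ed, heart_labels[["rv_cavity"]])
  fallback <- FALSE
  if (sum(rv) > 0) {
    dvox <- sqrt(cpp_sqedt(rv, c(1, 1, 1)))
    sept <- (lab_ed$values == heart_labels[["lv_wall"]]) & (dvox <= 2)
  } else sept <- array(FALSE, dim(lab_ed$values))
  if (!any(sept)) {
    sept <- lab_ed$values == heart_labels[["lv_cavity"]]
    fallback <- TRUE
    if (!any(sept)) stop("no septal or LV cavity voxels for the centreline")
  }
  d <- dim(lab_ed$values)
  cents <- lapply(seq_len(d[3]), function(k) {
    sl <- which(sept[, , k], arr.ind = TRUE)
    if (nrow(sl) == 0) return(NULL)
    c(lab_ed$origin[1] + (mean(sl[, 1]) - 1) * lab_ed$spacing[1],
      lab_ed$origin[2] + (mean(sl[, 2]) - 1) * lab_ed$spacing[2],
      lab_ed$origin[3] + (k - 1) * lab_ed$spacing[3])
  })
  cents <- do.call(rbind, cents[!vapply(cents, is.null, TRUE)])
  if (nrow(cents) < 2) stop("too few slices to fit a centreline")
  ctr <- colMeans(cents)
  dir <- prcomp(cents, center = TRUE, scale. = FALSE)$rotation[, 1]
  # slices run base -> apex (z increasing); apex->base must point down z
  if (dir[3] > 0) dir <- -dir
  ax <- centre_axis(ctr, dir)
  attr(ax, "fallback") <- fallback
  attr(ax, "slice_centroids") <- cents
  ax
}

#' Build a template surface mesh at a vertex budget
#'
#' Extracts the template's isosurface on a uniformly rescaled sampling grid
#' whose scale is bisected until the vertex count is within `tol` of
#' `target_vertices`. The fixed template mesh indexing is what makes ED/ES
#' and inter-subject vertices correspond.
#'
#' @param lab The template [label_volume()].
#' @param structure Structure tag (see [extract_surface()]).
#' @param target_vertices Vertex budget (defaults: 14440 for LV surfaces,
#'   18312 for RV surfaces).
#' @param tol Relative vertex-count tolerance.
#' @return A [surface_mesh()].
#' @export
build_template_mesh <- function(lab, structure, target_vertices = NULL,
                                tol = 0.05) {
  if (is.null(target_vertices))
    target_vertices <- if (grepl("^lv", structure)) 14440L else 18312L
  mask <- label_mask(lab, structure_labels(structure))
  if (sum(mask) == 0) stop("structure ", structure, " has no voxels")
  phi <- signed_distance(mask, lab$spacing)
  d <- dim(phi)
  mesh_at <- function(s) {
    sp <- lab$spacing * s
    nd <- pmax(4L, ceiling((d - 1) / s) + 1L)
    grid <- image_volume(array(0, nd), sp, lab$origin)
    vals <- cpp_trilinear(phi, lab$spacing, lab$origin, grid_points(grid),
                          max(phi))
    mc <- cpp_marching_tetra(array(vals, nd), 0, sp, lab$origin)
    surface_mesh(mc$vertices, mc$faces, structure)
  }
  lo <- 0.4; hi <- 4
  for (it in 1:12) {
    s <- sqrt(lo * hi)
    m <- mesh_at(s)
    ratio <- nrow(m$vertices) / target_vertices
    if (abs(ratio - 1) < tol) break
    if (ratio > 1) lo <- s else hi <- s
  }
  m
}

apply_tf_any <- function(tf, pts) {
  if (is.function(tf)) tf(pts) else apply_transform(tf, pts)
}

#' Establish ED/ES vertex correspondence by template propagation
#'
#' The fixed template mesh is warped by the phase-specific fitted
#' transforms onto each phase and the warped vertices are projected to the
#' nearest point of that phase's isosurface, so vertex `i` denotes the same
#' material point at ED and ES. If more than `max_fail_frac` of projections
#' exceed `cap` mm, the result carries a quality-failure flag (such
#' subjects are screened out downstream).
#'
#' @param template A [surface_mesh()] (fixed indexing).
#' @param subject_ed,subject_es The subject's phase [label_volume()]s.
#' @param transforms List with `ed` and `es` transforms mapping template
#'   space to the respective phase space (spatial transforms or functions
#'   of an n x 3 matrix).
#' @param centreline Optional [centre_axis()]; fitted from `subject_ed`
#'   when missing.
#' @param cap Projection-distance cap (mm).
#' @param max_fail_frac QC threshold on the fraction of far projections.
#' @return A `corresponded_meshes` object: template, `ed_vertices`,
#'   `es_vertices`, `centreline`, `qc`.
#' @export
correspond <- function(template, subject_ed, subject_es, transforms,
                       centreline = NULL, cap = 1, max_fail_frac = 0.05) {
  stopifnot(inherits(template, "surface_mesh"),
            all(c("ed", "es") %in% names(transforms)))
  if (is.null(centreline)) centreline <- fit_centreline(subject_ed)
  project_phase <- function(lab, tf) {
    surf <- extract_surface(lab, template$tag)
    moved <- apply_tf_any(tf, template$vertices)
    pr <- cpp_project_points(moved, surf$vertices, surf$faces)
    list(v = pr$points, dist = pr$distance)
  }
  ed <- project_phase(subject_ed, transforms$ed)
  es <- project_phase(subject_es, transforms$es)
  frac <- max(mean(ed$dist > cap), mean(es$dist > cap))
  structure(list(template = template, ed_vertices = ed$v,
                 es_vertices = es$v, centreline = centreline,
                 tag = template$tag,
                 qc = list(flag = frac > max_fail_frac, frac_over = frac,
                           cap = cap, max_fail_frac = max_fail_frac)),
            class = "corresponded_meshes")
}

#' @export
print.corresponded_meshes <- function(x, ...) {
  cat(sprintf("<corresponded_meshes> %s: %d vertices, QC %s (%.1f%% > %g mm)\n",
              x$tag, nrow(x$ed_vertices),
              if (x$qc$flag) "FAIL" else "ok", 100 * x$qc$frac_over,
              x$qc$cap))
  invisible(x)
}
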