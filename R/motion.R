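# orthonormal frame (e1, e2) perpendicular to a unit axis direction,
# chosen deterministically
axis_frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# cylindrical coordinates of points about a centre_axis
cylindrical <- function(pts, axis) {
  u <- axis$direction
  fr <- axis_frame(u)
  w <- sweep(pts, 2, axis$point)
  z <- as.vector(w %*% u)
  x1 <- as.vector(w %*% fr$e1)
  x2 <- as.vector(w %*% fr$e2)
  list(z = z, r = sqrt(x1^2 + x2^2), theta = atan2(x2, x1))
}

#' Decompose ED to ES wall motion into cylindrical components
#'
#' Each corresponded vertex pair (ED position `p`, ES position `q`) is
#' expressed in the cylindrical frame of the centreline (axial coordinate
#' along the apex-to-base direction, radius, angle). Components:
#' longitudinal `z(p) - z(q)` (positive = systolic descent toward the
#' apex), radial `r(p) - r(q)` (positive = inward contraction),
#' circumferential `r(p) * dtheta` with the signed angular change wrapped
#' to (-pi, pi] and the radius taken at ED. The motion magnitude is the
#' root sum of squares of the three orthogonal components (config
#' `magnitude = "rms"` divides by sqrt(3) for the literal
#' root-mean-square reading). A vertex on the axis has zero
#' circumferential motion by definition.
#'
#' @param meshes A `corresponded_meshes` object (see [correspond()]).
#' @param ventricle Tag stored in the output (defaults from the mesh tag).
#' @param magnitude `"norm"` (Euclidean norm, default) or `"rms"`.
#' @return A `motion_field` tibble: vertex, longitudinal, radial,
#'   circumferential, magnitude (mm), with ventricle/phase metadata.
#' @export
decompose_motion <- function(meshes, ventricle = NULL,
                             magnitude = c("norm", "rms")) {
  magnitude <- match.arg(magnitude)
  stopifnot(inherits(meshes, "corresponded_meshes"))
  if (is.null(ventricle))
    ventricle <- if (grepl("^rv", meshes$tag)) "RV" else "LV"
  p <- cylindrical(meshes$ed_vertices, meshes$centreline)
  q <- cylindrical(meshes$es_vertices, meshes$centreline)
  dtheta <- q$theta - p$theta
  dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))  # wrap to [-pi, pi]
  dtheta[dtheta <= -pi] <- dtheta[dtheta <= -pi] + 2 * pi  # half-open
  l <- p$z - q$z
  r <- p$r - q$r
  circ <- p$r * dtheta
  circ[p$r < 1e-12] <- 0
  mag <- sqrt(l^2 + r^2 + circ^2)
  if (magnitude == "rms") mag <- mag / sqrt(3)
  out <- tibble::tibble(vertex = seq_along(l), longitudinal = l, radial = r,
                        circumferential = circ, magnitude = mag)
  attr(out, "ventricle") <- ventricle
  attr(out, "phase_pair") <- "ED->ES"
  attr(out, "magnitude_mode") <- magnitude
  class(out) <- c("motion_field", class(out))
  out
}

#' Point-wise percentage change against a control mean field
#'
#' Per-vertex `100 (m_subj - m_ctrl) / m_ctrl` for each component and the
#' magnitude, summarized as the arithmetic mean over vertices. Vertices
#' whose control value is below `floor` (in absolute value) are excluded
#' from that component's mean and counted, since near-zero baselines yield
#' excessively large percentages.
#'
#' @param subject,control_mean `motion_field`s on the same template
#'   indexing (control typically a vertex-wise mean across control
#'   subjects, see [average_motion_fields()]).
#' @param floor Baseline floor (mm).
#' @return List: `per_vertex` tibble and `summary` tibble (component,
#'   mean_pct, n_excluded).
#' @export
pointwise_percent_change <- function(subject, control_mean, floor = 0.01) {
  if (nrow(subject) != nrow(control_mean))
    stop("vertex indexing mismatch between subject and control fields")
  comps <- c("longitudinal", "radial", "circumferential", "magnitude")
  pv <- tibble::tibble(vertex = subject$vertex)
  rows <- lapply(comps, function(cc) {
    s <- subject[[cc]]
    m <- control_mean[[cc]]
    pct <- 100 * (s - m) / m
    keep <- abs(m) >= floor
    pv[[paste0(cc, "_pct")]] <<- ifelse(keep, pct, NA_real_)
    tibble::tibble(component = cc, mean_pct = mean(pct[keep]),
                   n_excluded = sum(!keep))
  })
  list(per_vertex = pv, summary = dplyr::bind_rows(rows))
}

#' Vertex-wise mean of motion fields
#'
#' @param fields List of `motion_field`s sharing one template indexing.
#' @return A `motion_field` of vertex-wise means.
#' @export
average_motion_fields <- function(fields) {
  stopifnot(length(fields) >= 1)
  n <- nrow(fields[[1]])
  for (f in fields) if (nrow(f) != n) stop("vertex indexing mismatch")
  out <- fields[[1]]
  for (cc in c("longitudinal", "radial", "circumferential", "magnitude"))
    out[[cc]] <- rowMeans(do.call(cbind, lapply(fields, `[[`, cc)))
  out
}

#' Group percentage difference from a baseline group
#'
#' `100 (mean(group) - mean(baseline)) / mean(baseline)`, with the group
#' spread propagated to the percentage scale: `sd_pct` is the SD of the
#' per-subject percentages against the baseline mean, and `se_pct` the
#' delta-method standard error including baseline-mean uncertainty.
#'
#' @param group_values,baseline_values Per-subject summary values (e.g.
#'   mean RV motion magnitude per subject).
#' @return Tibble: pct_diff, sd_pct, se_pct, n_group, n_baseline.
#' @export
group_percent_difference <- function(group_values, baseline_values) {
  stopifnot(length(baseline_values) >= 1, length(group_values) >= 1)
  mb <- mean(baseline_values)
  mg <- mean(group_values)
  if (mb == 0) stop("baseline mean is zero")
  pct <- 100 * (mg - mb) / mb
  sd_pct <- 100 * sd(group_values) / abs(mb)
  ng <- length(group_values)
  nb <- length(baseline_values)
  vg <- if (ng > 1) var(group_values) / ng else 0
  vb <- if (nb > 1) var(baseline_values) / nb else 0
  se <- 100 * sqrt(vg / mb^2 + mg^2 * vb / mb^4)
  tibble::tibble(pct_diff = pct, sd_pct = sd_pct, se_pct = se,
                 n_group = ng, n_baseline = nb)
}

#' Export a motion field as tidy CSV
#'
#' @param field A `motion_field`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(field, path) {
  df <- tibble::as_tibble(field)
  df$ventricle <- attr(field, "ventricle")
  utils::write.csv(df[, c("vertex", "ventricle", "longitudinal", "radial",
                          "circumferential", "magnitude")],
                   path, row.names = FALSE)
  invisible(path)
}
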