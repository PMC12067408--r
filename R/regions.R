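# canonical sector names, counterclockwise from the anterior insertion
lv_sector_names <- c("anterior", "anterolateral", "inferolateral",
                     "inferior", "inferoseptal", "anteroseptal")
rv_sector_names <- c("anterior", "anterolateral", "inferolateral",
                     "inferior")

#' Detect the anterior RV insertion angle
#'
#' The RV insertion points are the ends of the RV cavity's angular span
#' about the centreline, evaluated at the mid-slice of the basal third.
#' The anterior insertion is the counterclockwise end of the span (sector
#' numbering proceeds from it through the RV free wall).
#'
#' @param lab An ED [label_volume()].
#' @param axis The [centre_axis()] used for motion analysis.
#' @return Insertion angle (radians) in the axis frame, with the RV span
#'   (degrees) as attribute `span_deg`.
#' @export
find_insertion_angle <- function(lab, axis) {
  rv_idx <- which(lab$values == heart_labels[["rv_cavity"]], arr.ind = TRUE)
  if (nrow(rv_idx) == 0)
    stop("no RV cavity voxels: insertion point undetectable")
  pts <- cbind(lab$origin[1] + (rv_idx[, 1] - 1) * lab$spacing[1],
               lab$origin[2] + (rv_idx[, 2] - 1) * lab$spacing[2],
               lab$origin[3] + (rv_idx[, 3] - 1) * lab$spacing[3])
  cyl <- cylindrical(pts, axis)
  # basal third mid-slice: upper (large-z) third of the RV's axial span
  zr <- range(cyl$z)
  zmid_basal <- zr[2] - (zr[2] - zr[1]) / 6
  tol <- max(lab$spacing)
  sel <- abs(cyl$z - zmid_basal) <= tol
  if (!any(sel)) sel <- rep(TRUE, length(cyl$z))
  th <- sort(cyl$theta[sel])
  if (length(th) < 3)
    stop("too few RV voxels at the basal level: insertion undetectable")
  # largest angular gap -> span endpoints
  gaps <- diff(c(th, th[1] + 2 * pi))
  gi <- which.max(gaps)
  ccw_end <- th[gi]                  # counterclockwise end of the span
  span <- 2 * pi - max(gaps)
  structure(ccw_end, span_deg = span * 180 / pi)
}

#' Assign LV (17) and RV (11) segments to corresponded mesh vertices
#'
#' The apical cap (most apical 5% of the axial extent) forms the apex
#' segment (LV 17, RV 11). The remaining axial extent is split into equal
#' basal/mid/apical thirds. Angles are measured clockwise from the anterior
#' insertion point in 60-degree sectors (anterior, anterolateral,
#' inferolateral, inferior, then inferoseptal and anteroseptal for the LV
#' only). LV: 6 sectors at basal (1-6) and mid (7-12), 4 merged 90-degree
#' sectors at apical (13-16), apex 17. RV: the 4 non-septal sectors at
#' basal (1-4) and mid (5-8), 2 merged sectors at apical (9-10), apex 11;
#' the rare vertex falling into a septal sector joins its nearest free-wall
#' sector.
#'
#' @param meshes A `corresponded_meshes` object (ED vertices are used).
#' @param ventricle `"LV"` or `"RV"`; defaults from the mesh tag.
#' @param insertion_angle Anterior insertion angle (radians, axis frame),
#'   e.g. from [find_insertion_angle()].
#' @param apex_frac Apical-cap fraction of the axial extent.
#' @return A `segment_model` tibble: vertex, segment id, level, sector
#'   name.
#' @export
assign_segments <- function(meshes, insertion_angle, ventricle = NULL,
                            apex_frac = 0.05) {
  stopifnot(inherits(meshes, "corresponded_meshes"))
  if (is.null(ventricle))
    ventricle <- if (grepl("^rv", meshes$tag)) "RV" else "LV"
  cyl <- cylindrical(meshes$ed_vertices, meshes$centreline)
  zr <- range(cyl$z)
  # axial coordinate runs apex->base: apex = min z
  apex_cut <- zr[1] + apex_frac * (zr[2] - zr[1])
  rest <- zr[2] - apex_cut
  level <- ifelse(cyl$z <= apex_cut, "apex",
           ifelse(cyl$z <= apex_cut + rest / 3, "apical",
           ifelse(cyl$z <= apex_cut + 2 * rest / 3, "mid", "basal")))
  # clockwise angle from the anterior insertion, in [0, 360)
  delta <- (insertion_angle - cyl$theta) * 180 / pi
  delta <- delta %% 360
  sector6 <- pmin(floor(delta / 60) + 1L, 6L)
  if (ventricle == "LV") {
    sector4 <- pmin(floor(delta / 90) + 1L, 4L)
    id <- integer(length(level))
    id[level == "basal"] <- sector6[level == "basal"]
    id[level == "mid"] <- 6L + sector6[level == "mid"]
    id[level == "apical"] <- 12L + sector4[level == "apical"]
    id[level == "apex"] <- 17L
    name <- character(length(id))
    name[level == "basal"] <- lv_sector_names[sector6[level == "basal"]]
    name[level == "mid"] <- lv_sector_names[sector6[level == "mid"]]
    apical_names <- c("anterior", "lateral", "inferior", "septal")
    name[level == "apical"] <- apical_names[sector4[level == "apical"]]
    name[level == "apex"] <- "apex"
  } else {
    sec <- pmin(sector6, 4L)   # clamp septal sectors to the free wall
    id <- integer(length(level))
    id[level == "basal"] <- sec[level == "basal"]
    id[level == "mid"] <- 4L + sec[level == "mid"]
    id[level == "apical"] <- 8L + ifelse(sec[level == "apical"] <= 2, 1L, 2L)
    id[level == "apex"] <- 11L
    name <- character(length(id))
    name[level != "apex"] <- rv_sector_names[sec[level != "apex"]]
    name[level == "apical"] <-
      c("anterior", "inferior")[ifelse(sec[level == "apical"] <= 2, 1, 2)]
    name[level == "apex"] <- "apex"
  }
  out <- tibble::tibble(vertex = seq_along(id), segment = id,
                        level = level, sector = name)
  attr(out, "ventricle") <- ventricle
  attr(out, "insertion_angle") <- insertion_angle
  class(out) <- c("segment_model", class(out))
  out
}

#' Segment layout table for one ventricle
#'
#' The fixed segment numbering used by [assign_segments()], ordered basal
#' to apical.
#'
#' @param ventricle `"LV"` or `"RV"`.
#' @return Tibble: segment, level, sector.
#' @export
segment_layout <- function(ventricle = c("LV", "RV")) {
  ventricle <- match.arg(ventricle)
  if (ventricle == "LV") {
    tibble::tibble(
      segment = 1:17,
      level = c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex"),
      sector = c(lv_sector_names, lv_sector_names,
                 c("anterior", "lateral", "inferior", "septal"), "apex"))
  } else {
    tibble::tibble(
      segment = 1:11,
      level = c(rep("basal", 4), rep("mid", 4), rep("apical", 2), "apex"),
      sector = c(rv_sector_names, rv_sector_names,
                 c("anterior", "inferior"), "apex"))
  }
}

#' Per-segment motion summary for one subject
#'
#' The per-subject statistic is the median over the vertices of each
#' segment, for each motion component and the magnitude. The apical cap can
#' be excluded (as in regional line-graph summaries).
#'
#' @param field A `motion_field` (see [decompose_motion()]).
#' @param segs The matching `segment_model`.
#' @param exclude_apex Drop the apex segment from the output.
#' @return Tibble: ventricle, segment, level, sector, component, median,
#'   n_vertices.
#' @export
regional_summary <- function(field, segs, exclude_apex = FALSE) {
  if (nrow(field) != nrow(segs)) stop("field and segments do not align")
  vent <- attr(segs, "ventricle")
  comps <- c("longitudinal", "radial", "circumferential", "magnitude")
  lay <- segment_layout(vent)
  if (exclude_apex) lay <- lay[lay$level != "apex", ]
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    sel <- segs$segment == lay$segment[i]
    tibble::tibble(ventricle = vent, segment = lay$segment[i],
                   level = lay$level[i], sector = lay$sector[i],
                   component = comps,
                   median = vapply(comps, function(cc)
                     if (any(sel)) median(field[[cc]][sel]) else NA_real_,
                     0),
                   n_vertices = sum(sel))
  })
  dplyr::bind_rows(rows)
}

#' Group-level regional statistics
#'
#' Mean and SD, across subjects, of the per-subject segment medians.
#'
#' @param summaries List of [regional_summary()] tibbles (one per subject).
#' @return Tibble: ventricle, segment, level, sector, component, mean, sd,
#'   n_subjects.
#' @export
group_regional_summary <- function(summaries) {
  all <- dplyr::bind_rows(summaries)
  dplyr::summarise(
    dplyr::group_by(all, .data$ventricle, .data$segment, .data$level,
                    .data$sector, .data$component),
    mean = mean(.data$median), sd = sd(.data$median),
    n_subjects = dplyr::n(), .groups = "drop")
}

#' 28-segment bi-ventricular table
#'
#' Combines LV (17 segments) and RV (11 segments) summaries into the fixed
#' 28-row order (LV basal to apex, then RV basal to apex) for one motion
#' component.
#'
#' @param lv_summary,rv_summary Outputs of [regional_summary()] or
#'   [group_regional_summary()].
#' @param component Motion component to tabulate.
#' @return 28-row tibble, basal-to-apical within each ventricle.
#' @export
bullseye_table <- function(lv_summary, rv_summary,
                           component = "magnitude") {
  pick <- function(s, vent) {
    s <- s[s$component == component & s$ventricle == vent, ]
    val_col <- if ("median" %in% names(s)) "median" else "mean"
    lay <- segment_layout(vent)
    out <- dplyr::left_join(lay, s,
                            by = c("segment", "level", "sector"))
    tibble::tibble(ventricle = vent, segment = lay$segment,
                   level = lay$level, sector = lay$sector,
                   value = out[[val_col]])
  }
  out <- dplyr::bind_rows(pick(lv_summary, "LV"), pick(rv_summary, "RV"))
  attr(out, "component") <- component
  out
}
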