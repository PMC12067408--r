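#' Analytic end-systolic deformation parameters
#'
#' The end-diastole to end-systole map composes three closed-form motions in
#' the cylindrical frame of the long axis, each mapping onto exactly one of
#' the reported wall-motion components: base-toward-apex longitudinal
#' shortening (apex fixed), radial contraction toward the axis, and a twist
#' about the axis whose angle grows linearly with height above the apex
#' (right-handed about the apex-to-base direction).
#'
#' @param long_shorten_frac Fractional longitudinal shortening in `[0, 0.6]`;
#'   a point at height `h` above the apex moves to height `(1 - f) * h`.
#' @param radial_contract_frac Fractional radial contraction in `[0, 0.6]`.
#' @param twist_deg_per_mm Twist in degrees per mm of height above the apex.
#' @param apex_fixed Kept for interface completeness; the map always fixes
#'   the apex.
#' @return A `deformation_spec` object.
#' @export
deformation_spec <- function(long_shorten_frac = 0.15,
                             radial_contract_frac = 0.2,
                             twist_deg_per_mm = 1,
                             apex_fixed = TRUE) {
  stopifnot(long_shorten_frac >= 0, long_shorten_frac <= 0.6,
            radial_contract_frac >= 0, radial_contract_frac <= 0.6)
  structure(list(long_shorten_frac = long_shorten_frac,
                 radial_contract_frac = radial_contract_frac,
                 twist_deg_per_mm = twist_deg_per_mm,
                 apex_fixed = isTRUE(apex_fixed)),
            class = "deformation_spec")
}

# multiply the amplitude of a deformation (used for cine interpolation)
scale_deformation <- function(d, amp) {
  deformation_spec(d$long_shorten_frac * amp,
                   d$radial_contract_frac * amp,
                   d$twist_deg_per_mm * amp,
                   d$apex_fixed)
}

#' Synthetic rat-heart phantom parameters
#'
#' The phantom models the two ventricles as implicit surfaces: the LV as two
#' coaxial truncated prolate ellipsoids (endocardium and epicardium, with
#' the septum carrying the LV-wall label), and the RV cavity as the crescent
#' between the LV epicardial shell and a copy of it offset along +x,
#' restricted to an angular sector, with its own thin free wall. The base is
#' truncated by a plane perpendicular to the long axis; slices are ordered
#' base to apex (apex at the largest z). In-plane resolution and the
#' high-resolution slice thickness follow small-animal cine/3-D protocols
#' (0.2 mm in-plane, 0.34 mm HR slices, thick cine slices at 4x the HR
#' spacing). Anatomical defaults (3 mm endocardial radius, 1.5 mm wall,
#' 12 mm long axis) are plausible for an adult rat but are not measured
#' values; phantom volumes are not physiological claims.
#'
#' @param long_axis_len Full LV endocardial long-axis diameter (mm).
#' @param lv_endo_radius LV endocardial equatorial radius (mm).
#' @param lv_wall_thick LV wall thickness (mm), must be `< lv_endo_radius`.
#' @param rv_wall_thick RV free-wall thickness (mm).
#' @param rv_crescent_extent Angular extent of the RV crescent (degrees).
#' @param rv_offset Offset of the RV shells along +x (mm); sets the maximal
#'   crescent thickness.
#' @param base_truncation_frac Fraction in `[0, 0.5)` controlling where the
#'   basal plane truncates the ellipsoids.
#' @param systole A [deformation_spec()] describing the ED to ES map.
#' @param intensity_means Named class-mean intensities in `[0, 1]` (bright
#'   blood, mid-grey myocardium).
#' @param noise_sigma Additive Gaussian noise SD (image intensity units).
#' @param inplane_spacing In-plane voxel size (mm).
#' @param lr_slice_thick Cine (low-resolution) slice thickness (mm); must be
#'   an integer multiple of `hr_slice_thick`.
#' @param hr_slice_thick High-resolution slice thickness (mm).
#' @param n_frames Number of cine frames (cosine ED-ES-ED profile).
#' @param heart_rate Heart rate (bpm).
#' @param body_weight Body weight (g).
#' @param seed Integer seed making every generated output reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(long_axis_len = 12, lv_endo_radius = 3,
                         lv_wall_thick = 1.5, rv_wall_thick = 0.8,
                         rv_crescent_extent = 150, rv_offset = 2,
                         base_truncation_frac = 0.15,
                         systole = deformation_spec(),
                         intensity_means = c(background = 0.10,
                                             lv_cavity = 0.85,
                                             lv_wall = 0.50,
                                             rv_cavity = 0.75,
                                             rv_wall = 0.42),
                         noise_sigma = 0.04, inplane_spacing = 0.2,
                         lr_slice_thick = 1.36, hr_slice_thick = 0.34,
                         n_frames = 8, heart_rate = 350, body_weight = 250,
                         seed = 1L) {
  lens <- c(long_axis_len, lv_endo_radius, lv_wall_thick, rv_wall_thick,
            rv_offset, inplane_spacing, lr_slice_thick, hr_slice_thick)
  if (any(lens <= 0)) stop("invalid phantom spec: all lengths must be > 0")
  if (lv_wall_thick >= lv_endo_radius)
    stop("invalid phantom spec: wall thickness must be < endocardial radius")
  if (rv_wall_thick >= lv_endo_radius + lv_wall_thick)
    stop("invalid phantom spec: RV wall too thick for the epicardial shell")
  if (lr_slice_thick <= hr_slice_thick)
    stop("invalid phantom spec: cine slices must be thicker than HR slices")
  k <- lr_slice_thick / hr_slice_thick
  if (abs(k - round(k)) > 1e-6)
    stop("lr_slice_thick must be an integer multiple of hr_slice_thick")
  if (base_truncation_frac < 0 || base_truncation_frac >= 0.5)
    stop("base_truncation_frac must be in [0, 0.5)")
  if (rv_crescent_extent < 0 || rv_crescent_extent > 360)
    stop("rv_crescent_extent must be in [0, 360] degrees")
  stopifnot(inherits(systole, "deformation_spec"),
            all(intensity_means >= 0), all(intensity_means <= 1),
            noise_sigma >= 0, n_frames >= 2, heart_rate > 0, body_weight > 0)
  structure(list(long_axis_len = long_axis_len,
                 lv_endo_radius = lv_endo_radius,
                 lv_wall_thick = lv_wall_thick,
                 rv_wall_thick = rv_wall_thick,
                 rv_crescent_extent = rv_crescent_extent,
                 rv_offset = rv_offset,
                 base_truncation_frac = base_truncation_frac,
                 systole = systole, intensity_means = intensity_means,
                 noise_sigma = noise_sigma,
                 inplane_spacing = inplane_spacing,
                 lr_slice_thick = lr_slice_thick,
                 hr_slice_thick = hr_slice_thick,
                 n_frames = as.integer(n_frames), heart_rate = heart_rate,
                 body_weight = body_weight, seed = as.integer(seed)),
            class = "phantom_spec")
}

# derived geometry shared by the generators
phantom_geometry <- function(spec) {
  cz <- spec$long_axis_len / 2          # endocardial semi-axis along z
  a <- spec$lv_endo_radius
  w <- spec$lv_wall_thick
  wr <- spec$rv_wall_thick
  d <- spec$rv_offset
  z_base <- -cz * (1 - 2 * spec$base_truncation_frac)
  z_apex <- cz + w                      # LV epicardial apex (fixed point)
  margin <- 1.0
  half_xy <- max(a + w + wr + d, a + w + wr) + margin
  np <- ceiling(2 * half_xy / spec$inplane_spacing)
  np <- as.integer(ceiling(np / 32) * 32)   # FCN-friendly in-plane size
  k <- as.integer(round(spec$lr_slice_thick / spec$hr_slice_thick))
  z_lo <- z_base - margin
  z_hi <- z_apex + margin
  nz <- ceiling((z_hi - z_lo) / spec$hr_slice_thick)
  nz <- as.integer(ceiling(nz / k) * k)
  list(cz = cz, a = a, w = w, wr = wr, d = d, z_base = z_base,
       z_apex = z_apex, np = np, nz = nz, k = k,
       origin = c(-(np - 1) / 2 * spec$inplane_spacing,
                  -(np - 1) / 2 * spec$inplane_spacing,
                  z_lo + spec$hr_slice_thick / 2),
       spacing_hr = c(spec$inplane_spacing, spec$inplane_spacing,
                      spec$hr_slice_thick))
}

#' Long-axis centreline of a phantom
#'
#' The analytic axis of the phantom: through the LV epicardial apex, with
#' unit direction pointing apex to base.
#'
#' @param spec A [phantom_spec()].
#' @return A `centre_axis` object (point, direction).
#' @export
phantom_axis <- function(spec) {
  g <- phantom_geometry(spec)
  centre_axis(point = c(0, 0, g$z_apex), direction = c(0, 0, -1))
}

# keep each RV class 6-connected: stray rasterization slivers of the
# cavity join the wall, stray wall slivers clear to background
tidy_rv_components <- function(values) {
  for (cls in c(3L, 4L)) {
    m <- array(0, dim(values))
    m[values == cls] <- 1
    if (sum(m) == 0) next
    comp <- cpp_label_components(m)
    tab <- tabulate(comp[comp > 0])
    main <- which.max(tab)
    stray <- comp > 0 & comp != main
    if (any(stray)) values[stray] <- if (cls == 3L) 4L else 0L
  }
  values
}

# label a matrix of physical points according to the implicit anatomy
classify_points <- function(spec, pts) {
  g <- phantom_geometry(spec)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  lab <- integer(length(x))
  ok <- z >= g$z_base
  r2 <- x^2 + y^2
  r2d <- (x - g$d)^2 + y^2
  zc2 <- z^2
  in_endo <- ok & (r2 / g$a^2 + zc2 / g$cz^2 < 1)
  in_epi <- ok & (r2 / (g$a + g$w)^2 + zc2 / (g$cz + g$w)^2 < 1)
  half <- spec$rv_crescent_extent / 2 * pi / 180
  in_sector <- abs(atan2(y, x)) <= half
  in_rv_endo <- ok & in_sector & (r2d / (g$a + g$w)^2 + zc2 / g$cz^2 < 1)
  in_rv_epi <- ok & in_sector &
    (r2d / (g$a + g$w + g$wr)^2 + zc2 / (g$cz + g$wr)^2 < 1)
  lab[in_rv_epi & !in_epi] <- 4L
  lab[in_rv_endo & !in_epi] <- 3L
  lab[in_epi] <- 2L
  lab[in_endo] <- 1L
  lab
}

#' Generate the end-diastolic high-resolution label volume
#'
#' Rasterizes the implicit two-ventricle anatomy onto the high-resolution
#' grid. The interventricular septum carries the LV-wall label and the
#' blood-pool labels stand in for cavities with trabeculae included.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] on the HR grid.
#' @export
generate_ed_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  dims <- c(g$np, g$np, g$nz)
  vol <- label_volume(array(0L, dims), g$spacing_hr, g$origin)
  pts <- grid_points(vol)
  vol$values <- tidy_rv_components(array(classify_points(spec, pts), dims))
  vol
}

# forward ED -> ES map (h = height above apex, twist right-handed about the
# apex->base direction, which is -z on the grid)
forward_map <- function(pts, d, z_apex) {
  h <- z_apex - pts[, 3]
  h2 <- (1 - d$long_shorten_frac) * h
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1])
  tau <- d$twist_deg_per_mm * pi / 180
  th2 <- th - tau * h       # -z axis frame: +twist about apex->base = -theta
  r2 <- (1 - d$radial_contract_frac) * r
  cbind(r2 * cos(th2), r2 * sin(th2), z_apex - h2)
}

# inverse of forward_map
inverse_map <- function(pts, d, z_apex) {
  h2 <- z_apex - pts[, 3]
  h <- h2 / (1 - d$long_shorten_frac)
  r2 <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  r <- r2 / (1 - d$radial_contract_frac)
  th2 <- atan2(pts[, 2], pts[, 1])
  tau <- d$twist_deg_per_mm * pi / 180
  th <- th2 + tau * h
  cbind(r * cos(th), r * sin(th), z_apex - h)
}

#' Deform end-diastolic labels to end-systole
#'
#' Resamples the ED label grid through the inverse of the analytic
#' deformation (nearest-neighbour), so cavity volumes shrink for any
#' nonzero contraction. The map's Jacobian is checked numerically on a
#' coarse grid and must be positive (invertibility).
#'
#' @param labels_ed ED [label_volume()] from [generate_ed_labels()].
#' @param d A [deformation_spec()].
#' @param spec The generating [phantom_spec()] (supplies the fixed apex).
#' @return ES [label_volume()] on the same grid.
#' @export
deform_to_es <- function(labels_ed, d, spec) {
  stopifnot(inherits(labels_ed, "label_volume"),
            inherits(d, "deformation_spec"))
  g <- phantom_geometry(spec)
  jac <- (1 - d$long_shorten_frac) * (1 - d$radial_contract_frac)^2
  if (jac <= 0) stop("deformation is not invertible")
  # numerical spot-check of invertibility on a coarse grid
  chk <- as.matrix(expand.grid(x = seq(-g$a, g$a, length.out = 4),
                               y = seq(-g$a, g$a, length.out = 4),
                               z = seq(g$z_base, g$z_apex, length.out = 4)))
  back <- inverse_map(forward_map(chk, d, g$z_apex), d, g$z_apex)
  if (max(abs(back - chk)) > 1e-8) stop("deformation failed inversion check")
  pts <- grid_points(labels_ed)
  src <- inverse_map(pts, d, g$z_apex)
  v <- cpp_nearest(array(as.numeric(labels_ed$values), dim(labels_ed$values)),
                   labels_ed$spacing, labels_ed$origin, src, 0)
  out <- labels_ed
  out$values <- tidy_rv_components(array(as.integer(round(v)),
                                         dim(labels_ed$values)))
  out
}

#' Closed-form ED to ES displacement components
#'
#' Evaluates the analytic deformation at ED points and returns the motion
#' components in the cylindrical frame of the long axis: longitudinal
#' (positive toward the apex), radial (positive inward), and circumferential
#' (arc length at the ED radius, signed by the angular change about the
#' apex-to-base direction).
#'
#' @param points n x 3 matrix of ED positions (mm).
#' @param d A [deformation_spec()].
#' @param axis A `centre_axis` (see [phantom_axis()]); its point must be the
#'   deformation's fixed apex.
#' @return n x 3 matrix with columns `longitudinal`, `radial`,
#'   `circumferential` (mm).
#' @export
analytic_displacement <- function(points, d, axis) {
  stopifnot(is.matrix(points), ncol(points) == 3,
            inherits(d, "deformation_spec"))
  u <- axis$direction
  w <- sweep(points, 2, axis$point)
  h <- as.vector(w %*% u)               # height above apex along apex->base
  rad <- w - outer(h, u)
  r <- sqrt(rowSums(rad^2))
  tau <- d$twist_deg_per_mm * pi / 180
  cbind(longitudinal = d$long_shorten_frac * h,
        radial = d$radial_contract_frac * r,
        circumferential = r * tau * h)
}

#' Rasterize a label volume into a grey-scale image
#'
#' Assigns each class its mean intensity and, for the thick-slice cine mode,
#' averages the HR sub-slices spanned by each thick voxel (partial-volume
#' effect), then adds seeded Gaussian noise and clips to `[0, 1]`.
#'
#' @param labels HR [label_volume()].
#' @param spec The generating [phantom_spec()].
#' @param mode `"cine_lr"` (thick slices) or `"hr"`.
#' @param seed Noise seed; defaults to `spec$seed`.
#' @return An [image_volume()].
#' @export
rasterize <- function(labels, spec, mode = c("cine_lr", "hr"),
                      seed = spec$seed) {
  mode <- match.arg(mode)
  mu <- spec$intensity_means[labels$values + 1L]
  img <- array(mu, dim(labels$values))
  spacing <- labels$spacing
  origin <- labels$origin
  if (mode == "cine_lr") {
    k <- as.integer(round(spec$lr_slice_thick / spec$hr_slice_thick))
    d <- dim(img)
    if (d[3] %% k != 0) stop("HR slice count not divisible by the LR factor")
    dim(img) <- c(d[1] * d[2], k, d[3] %/% k)
    img <- colMeans(aperm(img, c(2, 1, 3)))   # slab average over k sub-slices
    dim(img) <- c(d[1], d[2], d[3] %/% k)
    spacing[3] <- spec$lr_slice_thick
    origin[3] <- origin[3] + (k - 1) / 2 * spec$hr_slice_thick
  }
  if (spec$noise_sigma > 0) {
    img <- img + with_seed(seed, array(rnorm(length(img), 0, spec$noise_sigma),
                                       dim(img)))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  image_volume(img, spacing, origin)
}

# thick-slice label volume: nearest HR sub-slice to each LR slice centre
downsample_labels <- function(labels_hr, k) {
  d <- dim(labels_hr$values)
  stopifnot(d[3] %% k == 0)
  centre <- ceiling((k + 1) / 2)
  idx <- seq(centre, d[3], by = k)
  label_volume(labels_hr$values[, , idx, drop = FALSE],
               c(labels_hr$spacing[1:2], labels_hr$spacing[3] * k),
               c(labels_hr$origin[1:2],
                 labels_hr$origin[3] + (k - 1) / 2 * labels_hr$spacing[3]))
}

# uniform jitter of the geometric parameters of a spec
jitter_spec <- function(base, jitter, seed) {
  with_seed(seed, {
    f <- function(x) x * runif(1, 1 - jitter, 1 + jitter)
    phantom_spec(long_axis_len = f(base$long_axis_len),
                 lv_endo_radius = f(base$lv_endo_radius),
                 lv_wall_thick = f(base$lv_wall_thick),
                 rv_wall_thick = f(base$rv_wall_thick),
                 rv_crescent_extent = f(base$rv_crescent_extent),
                 rv_offset = f(base$rv_offset),
                 base_truncation_frac = base$base_truncation_frac,
                 systole = base$systole,
                 intensity_means = base$intensity_means,
                 noise_sigma = base$noise_sigma,
                 inplane_spacing = base$inplane_spacing,
                 lr_slice_thick = base$lr_slice_thick,
                 hr_slice_thick = base$hr_slice_thick,
                 n_frames = base$n_frames,
                 heart_rate = f(base$heart_rate),
                 body_weight = f(base$body_weight),
                 seed = seed)
  })
}

#' Generate a phantom cohort
#'
#' Produces `n_subjects` phantoms with geometric parameters perturbed
#' uniformly by `+/- jitter`, each with a cine study whose frames follow a
#' cosine ED-ES-ED contraction profile (frame 1 is ED), thick-slice ED/ES
#' label maps, HR ED/ES label maps, and the ground-truth deformation.
#'
#' @param n_subjects Number of subjects.
#' @param base_spec A [phantom_spec()] giving the cohort's centre.
#' @param jitter Relative jitter in `[0, 0.3]`.
#' @param seed Cohort seed (subject seeds are derived from it).
#' @param timepoint Tag stored in each study.
#' @param cine_frames If `FALSE`, only ED and ES cine frames are rendered
#'   (positions 1 and ES) to save time; frame count metadata is kept.
#' @return List of subjects, each a list with elements `study`, `labels_lr`
#'   (ED/ES), `labels_hr` (ED/ES), `deformation`, `spec`, `id`.
#' @export
generate_cohort <- function(n_subjects, base_spec = phantom_spec(),
                            jitter = 0.1, seed = 1L, timepoint = "control",
                            cine_frames = TRUE) {
  stopifnot(jitter >= 0, jitter <= 0.3)
  lapply(seq_len(n_subjects), function(i) {
    sp <- if (jitter > 0) jitter_spec(base_spec, jitter, seed * 1000L + i)
          else { s <- base_spec; s$seed <- seed * 1000L + i; s }
    ed_hr <- generate_ed_labels(sp)
    es_hr <- deform_to_es(ed_hr, sp$systole, sp)
    g <- phantom_geometry(sp)
    n <- sp$n_frames
    es_idx <- which.min(cos(2 * pi * (seq_len(n) - 1) / n))
    frame_ids <- if (cine_frames) seq_len(n) else c(1L, es_idx)
    frames <- lapply(frame_ids, function(t) {
      amp <- (1 - cos(2 * pi * (t - 1) / n)) / 2
      lab_t <- if (amp == 0) ed_hr
               else deform_to_es(ed_hr, scale_deformation(sp$systole, amp), sp)
      rasterize(lab_t, sp, "cine_lr", seed = sp$seed * 100L + t)
    })
    study <- cine_study(frames, sp$heart_rate, sp$body_weight,
                        subject_id = sprintf("phantom%03d", i),
                        timepoint = timepoint)
    list(study = study,
         labels_lr = list(ed = downsample_labels(ed_hr, g$k),
                          es = downsample_labels(es_hr, g$k)),
         labels_hr = list(ed = ed_hr, es = es_hr),
         deformation = sp$systole, spec = sp,
         es_frame = if (cine_frames) es_idx else 2L,
         id = sprintf("phantom%03d", i))
  })
}

#' Write a cohort to disk with a manifest
#'
#' Saves NIfTI images/labels per subject plus a CSV manifest of subject id,
#' seed, body weight, heart rate and deformation parameters.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest as a tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    base <- file.path(dir, s$id)
    for (ph in c("ed", "es")) {
      save_volume(s$labels_hr[[ph]], paste0(base, "_hr_", ph, ".nii.gz"))
      save_volume(s$labels_lr[[ph]], paste0(base, "_lr_", ph, ".nii.gz"))
    }
    for (t in seq_along(s$study$frames))
      save_volume(s$study$frames[[t]],
                  sprintf("%s_cine_f%02d.nii.gz", base, t))
    tibble::tibble(subject = s$id, seed = s$spec$seed,
                   body_weight_g = s$spec$body_weight,
                   heart_rate_bpm = s$study$heart_rate,
                   timepoint = s$study$timepoint,
                   long_shorten_frac = s$deformation$long_shorten_frac,
                   radial_contract_frac = s$deformation$radial_contract_frac,
                   twist_deg_per_mm = s$deformation$twist_deg_per_mm)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
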