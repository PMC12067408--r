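test_that("label generation is deterministic and validates its spec", {
  sp <- tiny_spec(seed = 7)
  a <- generate_ed_labels(sp)
  b <- generate_ed_labels(sp)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% 0:4))
  expect_error(phantom_spec(lv_wall_thick = 4, lv_endo_radius = 3),
               "invalid phantom spec")
  expect_error(phantom_spec(lr_slice_thick = 0.3, hr_slice_thick = 0.34),
               "thicker")
})

test_that("a zero-extent crescent yields no RV voxels", {
  sp <- tiny_spec(rv_crescent_extent = 0)
  lab <- generate_ed_labels(sp)
  expect_equal(sum(lab$values %in% c(3L, 4L)), 0)
})

test_that("LV cavity volume matches fine-grid integration of the shape", {
  sp <- tiny_spec(seed = 3)
  lab <- generate_ed_labels(sp)
  g <- ratcine:::phantom_geometry(sp)
  vol_label <- sum(lab$values == 1L) * voxel_volume_ul(lab)
  zs <- seq(g$z_base, g$cz, length.out = 4000)
  dz <- zs[2] - zs[1]
  vol_true <- sum(pi * g$a^2 * pmax(0, 1 - zs^2 / g$cz^2) * dz)
  expect_lt(abs(vol_label - vol_true) / vol_true, 0.05)
})

test_that("label-volume error shrinks as the grid is refined", {
  err_at <- function(inplane, hr) {
    sp <- tiny_spec(inplane_spacing = inplane, hr_slice_thick = hr,
                    lr_slice_thick = 4 * hr)
    lab <- generate_ed_labels(sp)
    g <- ratcine:::phantom_geometry(sp)
    zs <- seq(g$z_base, g$cz, length.out = 4000)
    vol_true <- sum(pi * g$a^2 * pmax(0, 1 - zs^2 / g$cz^2) * (zs[2] - zs[1]))
    abs(sum(lab$values == 1L) * voxel_volume_ul(lab) - vol_true) / vol_true
  }
  expect_lt(err_at(0.35, 0.68), err_at(0.8, 1.36) + 1e-9)
})

test_that("identity deformation is a no-op and contraction shrinks cavities", {
  sp <- tiny_spec(seed = 5)
  ed <- tiny_ed()
  es_id <- deform_to_es(ed, deformation_spec(0, 0, 0), tiny_spec(seed = 9))
  expect_identical(es_id$values, ed$values)
  es <- tiny_es()
  edv <- sum(ed$values %in% c(1L, 3L))
  esv <- sum(es$values %in% c(1L, 3L))
  expect_lt(esv, edv)                      # EF > 0
})

test_that("pure radial contraction reduces the mid-slice cavity radius by
           the prescribed fraction", {
  sp <- tiny_spec(seed = 2)
  ed <- generate_ed_labels(sp)
  d <- deformation_spec(0, 0.2, 0)
  es <- deform_to_es(ed, d, sp)
  g <- ratcine:::phantom_geometry(sp)
  mid <- which.min(abs(ratcine:::grid_points(ed)[
    seq(1, prod(dim(ed$values)), by = prod(dim(ed$values)[1:2])), 3]))
  eq_radius <- function(lab, k) {
    n <- sum(lab$values[, , k] == 1L)
    sqrt(n * prod(lab$spacing[1:2]) / pi)
  }
  r_ed <- eq_radius(ed, mid)
  r_es <- eq_radius(es, mid)
  expect_lt(abs(r_es - 0.8 * r_ed), max(sp$inplane_spacing, 0.02 * r_ed))
})

test_that("deformation preserves cavity topology (single 6-connected
           components)", {
  for (lab in list(tiny_ed(), tiny_es())) {
    for (cls in c(1L, 3L)) {
      comp <- ratcine:::cpp_label_components(
        ratcine:::label_mask(lab, cls))
      expect_equal(max(comp), 1)
    }
  }
})

test_that("analytic displacement has the closed-form components", {
  ax <- centre_axis(c(0, 0, 10), c(0, 0, -1))
  d <- deformation_spec(0.1, 0.15, 2)
  # on-axis point with twist only: zero circumferential
  on_axis <- analytic_displacement(matrix(c(0, 0, 4), 1),
                                   deformation_spec(0, 0, 2), ax)
  expect_equal(unname(on_axis[1, "circumferential"]), 0)
  # apex point: all zero
  apex <- analytic_displacement(matrix(c(0, 0, 10), 1), d, ax)
  expect_equal(unname(apex[1, ]), c(0, 0, 0))
  # r = 3 mm, twist 2 deg/mm, height 4 mm -> arc = 3 * 8 deg
  p <- matrix(c(3, 0, 6), 1)   # height above apex = 4
  twist_only <- analytic_displacement(p, deformation_spec(0, 0, 2), ax)
  expect_equal(unname(twist_only[1, "circumferential"]), 3 * (8 * pi / 180),
               tolerance = 1e-12)
  # longitudinal/radial fractions
  mixed <- analytic_displacement(p, d, ax)
  expect_equal(unname(mixed[1, "longitudinal"]), 0.1 * 4)
  expect_equal(unname(mixed[1, "radial"]), 0.15 * 3)
})

test_that("rasterization applies partial-volume slab averaging and is
           seeded", {
  sp <- tiny_spec(noise_sigma = 0)
  # synthetic 50/50 slab: half cavity (0.85), half wall (0.50)
  k <- as.integer(round(sp$lr_slice_thick / sp$hr_slice_thick))
  vals <- array(1L, c(4, 4, 2 * k))
  vals[, , seq_len(k)] <- 1L
  vals[, , k + seq_len(k)] <- 2L
  vals[, , k + seq_len(k / 2)] <- 1L  # second slab: k/2 cavity, k/2 wall
  lab <- label_volume(vals, c(sp$inplane_spacing, sp$inplane_spacing,
                              sp$hr_slice_thick))
  img <- rasterize(lab, sp, "cine_lr")
  mu <- sp$intensity_means
  expect_equal(img$values[1, 1, 1], unname(mu["lv_cavity"]))
  expect_equal(img$values[1, 1, 2],
               unname((mu["lv_cavity"] + mu["lv_wall"]) / 2))
  # seeded noise reproducibility
  spn <- tiny_spec(noise_sigma = 0.05, seed = 4)
  i1 <- rasterize(tiny_ed(), spn, "cine_lr")
  i2 <- rasterize(tiny_ed(), spn, "cine_lr")
  expect_identical(i1$values, i2$values)
  expect_true(all(i1$values >= 0 & i1$values <= 1))
})

test_that("cohorts are reproducible, jitter-controlled, and EF tracks the
           prescribed contraction", {
  c1 <- generate_cohort(3, tiny_spec(), jitter = 0.1, seed = 11,
                        cine_frames = FALSE)
  c2 <- generate_cohort(3, tiny_spec(), jitter = 0.1, seed = 11,
                        cine_frames = FALSE)
  expect_identical(c1[[2]]$labels_hr$ed$values, c2[[2]]$labels_hr$ed$values)
  specs <- lapply(c1, `[[`, "spec")
  expect_true(length(unique(vapply(specs, `[[`, 0, "lv_endo_radius"))) == 3)
  c0 <- generate_cohort(2, tiny_spec(), jitter = 0, seed = 11,
                        cine_frames = FALSE)
  expect_equal(c0[[1]]$spec$lv_endo_radius, tiny_spec()$lv_endo_radius)
  # EF strictly increasing with prescribed contraction
  efs <- vapply(c(0.08, 0.16, 0.28), function(f) {
    sp <- tiny_spec(systole = deformation_spec(f, f, 0.5), seed = 3)
    ed <- generate_ed_labels(sp)
    es <- deform_to_es(ed, sp$systole, sp)
    1 - sum(es$values == 1L) / sum(ed$values == 1L)
  }, 0)
  expect_true(all(diff(efs) > 0))
})

test_that("frame 1 of the cine is ED and the ES frame tracks peak
           contraction", {
  co <- generate_cohort(1, tiny_spec(n_frames = 8), jitter = 0, seed = 13,
                        cine_frames = TRUE)[[1]]
  expect_equal(length(co$study$frames), 8)
  expect_equal(co$es_frame, 5)  # argmin of cos(2 pi t/n) at t = n/2
})
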