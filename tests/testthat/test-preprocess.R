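test_that("percentile normalization matches a direct computation", {
  v <- array(rep(0:100, length.out = 4000), c(20, 20, 10))
  img <- image_volume(v, c(1, 1, 1))
  out <- normalize_intensity(img)
  p <- quantile(v, c(0.01, 0.99), names = FALSE)
  expected <- pmin(pmax(v, p[1]), p[2])
  expected <- (expected - p[1]) / (p[2] - p[1])
  expect_equal(out$values, expected, tolerance = 1e-12)
  expect_equal(min(out$values), 0)
  expect_equal(max(out$values), 1)
})

test_that("constant images map to zero and normalization is idempotent", {
  flat <- image_volume(array(3.7, c(5, 5, 2)), c(1, 1, 1))
  expect_true(all(normalize_intensity(flat)$values == 0))
  img <- image_volume(array(rnorm(8000), c(20, 20, 20)), c(1, 1, 1))
  once <- normalize_intensity(img)
  twice <- normalize_intensity(once)
  # idempotent up to the interpolation of the saturated tail percentiles
  expect_equal(twice$values, once$values, tolerance = 1e-3)
})

test_that("augmentation with zero ranges is the identity", {
  sp <- tiny_spec(seed = 9)
  img <- rasterize(tiny_ed(), sp, "hr")
  set.seed(1)
  a <- augment_pair(img, tiny_ed(),
                    augment_spec(0, 0, 0))
  expect_equal(a$image$values, img$values, tolerance = 1e-12)
  expect_identical(a$label$values, tiny_ed()$values)
})

test_that("an integer x-shift translates label columns exactly", {
  vals <- array(0L, c(8, 8, 2))
  vals[3, 4, 1] <- 2L
  lab <- label_volume(vals, c(1, 1, 1))
  img <- image_volume(array(0, c(8, 8, 2)), c(1, 1, 1))
  shifted <- ratcine:::resample_inplane(lab$values,
    matrix(seq_len(8) - 3, 8, 8),
    matrix(rep(seq_len(8), each = 8), 8, 8), nearest = TRUE)
  expect_equal(shifted[6, 4, 1], 2)
  expect_equal(sum(shifted != 0), 1)
})

test_that("augmentation is deterministic under a seed and preserves the
           label set and grid", {
  sp <- tiny_spec(seed = 9)
  img <- rasterize(tiny_ed(), sp, "hr")
  aspec <- augment_spec(0.1, 10, 5)
  set.seed(42)
  a1 <- augment_pair(img, tiny_ed(), aspec)
  set.seed(42)
  a2 <- augment_pair(img, tiny_ed(), aspec)
  expect_identical(a1$image$values, a2$image$values)
  expect_identical(a1$label$values, a2$label$values)
  expect_identical(dim(a1$image$values), dim(img$values))
  expect_true(all(a1$label$values %in% 0:4))
  # a later draw differs (fresh parameters per call)
  a3 <- augment_pair(img, tiny_ed(), aspec)
  expect_false(identical(a2$label$values, a3$label$values) &&
               identical(a2$image$values, a3$image$values))
})

test_that("ES selection follows the mid-ventricular LV count with the tie
           rule", {
  mk <- function(n_cavity) {
    vals <- array(0L, c(10, 10, 5))
    vals[seq_len(n_cavity), 1, 3] <- 1L
    # make slice 3 the mid LV slice by adding cavity to slices 2..4
    vals[1, 2, 2] <- 1L
    vals[1, 2, 4] <- 1L
    label_volume(vals, c(1, 1, 1))
  }
  labs <- lapply(c(5, 4, 2, 3), mk)
  expect_equal(select_es_frame(labs), 3)
  ties <- lapply(c(3, 3), mk)
  expect_equal(select_es_frame(ties), 1)
  empty <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(select_es_frame(list(empty, empty)), "no LV cavity")
})

test_that("the selected ES frame matches the analytic contraction peak on
           a phantom cine", {
  co <- generate_cohort(1, tiny_spec(n_frames = 8), jitter = 0, seed = 17,
                        cine_frames = TRUE)[[1]]
  sp <- co$spec
  g <- ratcine:::phantom_geometry(sp)
  labs <- lapply(seq_len(8), function(t) {
    amp <- (1 - cos(2 * pi * (t - 1) / 8)) / 2
    if (amp == 0) co$labels_hr$ed
    else deform_to_es(co$labels_hr$ed,
                      ratcine:::scale_deformation(sp$systole, amp), sp)
  })
  expect_lte(abs(select_es_frame(labs) - 5), 1)
})
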