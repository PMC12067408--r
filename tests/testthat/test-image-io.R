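test_that("NIfTI round-trips preserve values and grid metadata", {
  lab <- tiny_ed()
  f <- tempfile(fileext = ".nii.gz")
  save_volume(lab, f)
  back <- load_labels(f)
  expect_identical(back$values, lab$values)
  expect_lt(max(abs(back$spacing - lab$spacing)), 1e-6)
  expect_lt(max(abs(back$origin - lab$origin)), 1e-4)
  # grey-scale with anisotropic spacing
  img <- image_volume(array(runif(24), c(2, 3, 4)), c(0.2, 0.2, 1.2),
                      c(-1, 2, 0.5))
  f2 <- tempfile(fileext = ".nii.gz")
  save_volume(img, f2)
  back2 <- load_volume(f2)
  expect_equal(back2$values, img$values, tolerance = 1e-12)
  expect_equal(back2$spacing, c(0.2, 0.2, 1.2), tolerance = 1e-6)
})

test_that("label validation names the offending voxel", {
  vals <- array(0L, c(3, 3, 3))
  vals[2, 3, 1] <- 5L
  expect_error(label_volume(vals, c(1, 1, 1)), "5 at voxel \\(2, 3, 1\\)")
  f <- tempfile(fileext = ".nii.gz")
  save_volume(image_volume(array(5, c(2, 2, 2)), c(1, 1, 1)), f)
  expect_error(load_labels(f), "unknown label")
})

test_that("apex-first slice order is normalized to base-to-apex at load", {
  vals <- array(as.numeric(1:24), c(2, 3, 4))
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- c(1, 1, 2)
  aff <- diag(c(1, 1, -2, 1))          # negative z step: apex-first
  aff[1:3, 4] <- c(0, 0, 6)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, f)
  back <- load_volume(f)
  expect_equal(back$values[, , 1], vals[, , 4], tolerance = 1e-12)
  expect_equal(back$origin[3], 0)      # flipped origin at the low-z slice
  expect_equal(back$spacing[3], 2)
})

test_that("paired grids are enforced and studies validate metadata", {
  img <- image_volume(array(0, c(4, 4, 2)), c(1, 1, 1))
  lab <- label_volume(array(0L, c(4, 4, 3)), c(1, 1, 1))
  expect_error(check_paired_grid(img, lab), "do not match")
  expect_error(cine_study(list(img), heart_rate = -1, body_weight = 200))
  st <- cine_study(list(img, img), 350, 250, "s1", "control")
  expect_s3_class(st, "cine_study")
})
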