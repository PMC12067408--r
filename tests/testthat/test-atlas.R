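test_that("landmarks sit on the axis of a cylindrical cavity and are
           translation-equivariant", {
  vals <- array(0L, c(21, 21, 9))
  for (k in 2:8) {
    x <- (1:21) - 11
    vals[, , k] <- ((outer(x^2, x^2, "+") <= 16) * 1L) +
      ((outer(x^2, x^2, "+") <= 36 & outer(x^2, x^2, "+") > 16) * 2L)
  }
  # add a small RV cavity so detection succeeds
  vals[18:20, 10:12, 3:7] <- 3L
  lab <- label_volume(vals, c(1, 1, 1))
  lm <- detect_landmarks(lab)
  expect_equal(unname(lm["LV_basal", 1:2]), c(10, 10))
  expect_equal(unname(lm["LV_mid", 1:2]), c(10, 10))
  expect_equal(unname(lm["LV_apical", 1:2]), c(10, 10))
  lab2 <- lab
  lab2$origin <- lab$origin + c(5, -3, 2)
  lm2 <- detect_landmarks(lab2)
  expect_equal(lm2, lm + rep(c(5, -3, 2), each = 6))
  thin <- label_volume(array(1L, c(4, 4, 2)), c(1, 1, 1))
  expect_error(detect_landmarks(thin), "fewer than 3 slices")
})

test_that("phantom landmarks match brute-force slice centroids", {
  lab <- tiny_ed()
  lm <- detect_landmarks(lab)
  lv_slices <- which(apply(lab$values == 1L, 3, any))
  k <- lv_slices[ceiling(length(lv_slices) / 2)]
  idx <- which(lab$values[, , k] == 1L, arr.ind = TRUE)
  oracle <- c(lab$origin[1] + (mean(idx[, 1]) - 1) * lab$spacing[1],
              lab$origin[2] + (mean(idx[, 2]) - 1) * lab$spacing[2],
              lab$origin[3] + (k - 1) * lab$spacing[3])
  expect_lt(max(abs(lm["LV_mid", ] - oracle)), max(lab$spacing))
})

test_that("the landmark rigid solver recovers exact transforms", {
  set.seed(10)
  src <- matrix(rnorm(18, sd = 4), 6, 3)
  expect_equal(rigid_from_landmarks(src, src)$A, diag(3), tolerance = 1e-9)
  expect_equal(attr(rigid_from_landmarks(src, src), "rms_residual"), 0,
               tolerance = 1e-9)
  shifted <- src + rep(c(2, 0, 0), each = 6)
  tf <- rigid_from_landmarks(src, shifted)
  expect_equal(tf$t, c(2, 0, 0), tolerance = 1e-9)
  expect_equal(tf$A, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  tf2 <- rigid_from_landmarks(src, t(R %*% t(src)))
  expect_lt(max(abs(tf2$A - R)), 1e-6)
  line <- cbind(1:6, 2 * (1:6), 3 * (1:6))
  expect_error(rigid_from_landmarks(line, line), "collinear")
})

test_that("majority-vote fusion follows the vote and rank tie rules", {
  mk <- function(v) label_volume(array(as.integer(v), c(1, 1, 1)),
                                 c(1, 1, 1))
  expect_equal(fuse_labels(list(mk(2)))$values[1], 2L)          # single atlas
  expect_equal(fuse_labels(list(mk(1), mk(1), mk(3)))$values[1], 1L)
  expect_equal(fuse_labels(list(mk(3), mk(1)))$values[1], 3L)   # best rank
  expect_error(fuse_labels(list()), "no atlases")
  # fusion label set within the union of inputs
  set.seed(2)
  atls <- lapply(1:3, function(i)
    label_volume(array(sample(c(0L, 2L, 4L), 27, TRUE), c(3, 3, 3)),
                 c(1, 1, 1)))
  expect_true(all(fuse_labels(atls)$values %in% c(0L, 2L, 4L)))
})

test_that("atlas ranking puts the subject itself first and is stable on
           ties", {
  labs <- list(tiny_ed(), tiny_es(), tiny_ed())
  lib <- atlas_library(labs, c("ED", "ED", "ED"))
  rk <- rank_atlases(tiny_ed(), lib, "ED")
  expect_equal(rk$atlas[1], 1)        # identical atlas ranked first ...
  expect_equal(rk$score[1], 1.0)
  expect_equal(rk$atlas[2], 3)        # ... its duplicate next (tie rule)
  expect_equal(nrow(rk), 3)           # k capped at the library size
})

test_that("affine and FFD stages improve overlap monotonically on a
           deformed pair", {
  spA <- tiny_spec(seed = 51)
  spB <- ratcine:::jitter_spec(tiny_spec(), 0.12, 52)
  A <- generate_ed_labels(spA)
  B <- generate_ed_labels(spB)
  tf0 <- rigid_from_landmarks(detect_landmarks(A), detect_landmarks(B))
  d0 <- mean_dice(warp_labels(B, tf0, A), A)
  tfa <- register_affine(B, A, init = tf0, max_iter = 30)
  da <- mean_dice(warp_labels(B, tfa, A), A)
  tff <- register_ffd(B, A, init = tfa, max_iter = 20)
  df <- mean_dice(warp_labels(B, tff, A), A)
  expect_gte(da, d0 - 1e-3)
  expect_gte(df, da - 1e-3)
  # objective trace non-increasing
  tr <- attr(tff, "objective_trace")
  for (t in tr) expect_true(all(diff(t) <= 1e-12))
})

test_that("registering a volume to itself stays near the identity", {
  A <- tiny_ed()
  tfa <- register_affine(A, A, init = rigid_transform(), max_iter = 20)
  expect_lt(max(abs(tfa$A - diag(3))), 0.05)
  expect_lt(max(abs(tfa$t)), 0.2)
  tff <- register_ffd(A, A, init = tfa, max_iter = 10)
  expect_lt(mean(abs(tff$disp)), 0.1)
})

test_that("the template equals its inputs for a degenerate library and
           stays inside the volume envelope otherwise", {
  lib1 <- atlas_library(list(tiny_ed()), "ED")
  t1 <- build_template(lib1)
  expect_identical(t1$label$values, tiny_ed()$values)
  lib2 <- atlas_library(list(tiny_ed(), tiny_ed()), c("ED", "ES"))
  t2 <- build_template(lib2)
  expect_identical(t2$label$values, tiny_ed()$values)
  spB <- ratcine:::jitter_spec(tiny_spec(), 0.1, 53)
  B <- generate_ed_labels(spB)
  lib3 <- atlas_library(list(tiny_ed(), B, tiny_es()),
                        c("ED", "ED", "ES"))
  t3 <- build_template(lib3)
  vols <- vapply(lib3$atlases, function(a)
    sum(a$label$values == 1L) * voxel_volume_ul(a$label), 0)
  tvol <- sum(t3$label$values == 1L) * voxel_volume_ul(t3$label)
  expect_gte(tvol, min(vols) * 0.9)
  expect_lte(tvol, max(vols) * 1.1)
})

test_that("template alignment is rigid (no shape distortion)", {
  spB <- ratcine:::jitter_spec(tiny_spec(), 0.08, 54)
  B <- generate_ed_labels(spB)
  lib <- atlas_library(list(tiny_ed(), B), c("ED", "ED"))
  tmpl <- build_template(lib)
  al <- align_to_template(B, tmpl, refine = FALSE)
  expect_s3_class(al$transform, "rigid_transform")
  expect_lt(max(abs(crossprod(al$transform$A) - diag(3))), 1e-9)
  expect_true(ratcine:::same_grid(al$label, tmpl$label))
})

test_that("transforms serialize to plain lists and back", {
  tf <- rigid_transform(random_rotation(), c(1, -2, 0.5))
  back <- transform_from_list(transform_to_list(tf))
  expect_equal(back$A, tf$A)
  expect_equal(back$t, tf$t)
  ffd <- ffd_transform(array(rnorm(2 * 2 * 2 * 3, sd = 0.1), c(2, 2, 2, 3)),
                       c(0, 0, 0), c(5, 5, 5), init = tf)
  back2 <- transform_from_list(transform_to_list(ffd))
  pts <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(back2, pts), apply_transform(ffd, pts))
})
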