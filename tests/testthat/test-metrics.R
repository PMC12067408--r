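mkvol <- function(v, dims = c(2, 2, 2), spacing = c(1, 1, 1)) {
  label_volume(array(as.integer(v), dims), spacing)
}

test_that("Dice follows its formula, symmetry, and the empty-empty flag", {
  a <- mkvol(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(as.numeric(dice(a, a, 1)), 1)
  b <- mkvol(c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(as.numeric(dice(a, b, 1)), 0)
  # |A| = 4, |B| = 4, |A intersect B| = 2 -> 0.5
  c2 <- mkvol(c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(as.numeric(dice(a, c2, 1)), 0.5)
  expect_equal(as.numeric(dice(c2, a, 1)), 0.5)   # symmetric
  ee <- dice(a, a, 3)                             # both masks empty
  expect_equal(as.numeric(ee), 1)
  expect_true(attr(ee, "empty"))
  wrong <- mkvol(0, dims = c(2, 2, 1))
  expect_error(dice(a, wrong, 1), "identical grids")
})

test_that("slicewise Dice enumerates shifted cylinders correctly", {
  mk <- function(z0, z1) {
    v <- array(0L, c(5, 5, 6))
    v[2:4, 2:4, z0:z1] <- 1L
    label_volume(v, c(1, 1, 1))
  }
  a <- mk(1, 4)
  b <- mk(2, 5)
  sw <- slicewise_dice(a, b, 1)
  expect_equal(sw$slice, 1:5)
  expect_equal(sw$dice, c(0, 1, 1, 1, 0))
  expect_equal(attr(sw, "n_empty"), 1)            # slice 6 empty in both
  same <- slicewise_dice(a, a, 1)
  expect_true(all(same$dice == 1))
})

test_that("cardiac indices match hand computations", {
  # EDV 500 uL (500 voxels at 1 uL), ESV 200 uL, wall 600 uL
  ed <- array(0L, c(20, 20, 5))
  ed[seq_len(500)] <- 1L
  ed[500 + seq_len(600)] <- 2L
  ed[1200 + seq_len(100)] <- 3L
  ed[1300 + seq_len(100)] <- 4L
  es <- array(0L, c(20, 20, 5))
  es[seq_len(200)] <- 1L
  es[500 + seq_len(600)] <- 2L
  es[1200 + seq_len(50)] <- 3L
  es[1300 + seq_len(100)] <- 4L
  ci <- cardiac_indices(label_volume(ed, c(1, 1, 1)),
                        label_volume(es, c(1, 1, 1)),
                        heart_rate = 350, body_weight = 200)
  lv <- ci[ci$ventricle == "LV", ]
  expect_equal(lv$edv_ul, 500)
  expect_equal(lv$sv_ul, 300)
  expect_equal(lv$ef_pct, 60)
  expect_equal(lv$co, 350 * 300 / 1000)           # formula units
  expect_equal(lv$mass_mg, 1.05 * 600)
  expect_equal(lv$bsa_m2, 10 * 200^(2 / 3) / 10000)
  expect_equal(lv$bsa_m2, 0.03420, tolerance = 1e-3)
  expect_equal(lv$sv_i, 300 / lv$bsa_m2)
  # volumes scale with voxel volume (spacing s -> s^3)
  ci2 <- cardiac_indices(label_volume(ed, c(2, 2, 2)),
                         label_volume(es, c(2, 2, 2)), 350, 200)
  expect_equal(ci2$edv_ul, ci$edv_ul * 8)
  expect_equal(ci2$ef_pct, ci$ef_pct)             # EF is scale-free
  # zero EDV errors out
  empty <- label_volume(array(0L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(cardiac_indices(empty, empty, 350, 200), "EF undefined")
})

test_that("Bland-Altman agreement matches hand computations and is
           antisymmetric", {
  x <- c(1, 2, 3)
  same <- agreement(x, x)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))
  expect_equal(same$r, 1)
  off <- agreement(x + 5, x)
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  # pairs (manual, auto): (1,2), (2,4), (3,6) -> diffs 1, 2, 3
  ag <- agreement(c(2, 4, 6), c(1, 2, 3))
  expect_equal(ag$bias, 2)
  expect_equal(ag$sd_diff, 1)
  expect_equal(ag$loa_lower, 2 - 1.96)
  expect_equal(ag$loa_upper, 2 + 1.96)
  expect_equal(ag$r, 1)
  rev <- agreement(c(1, 2, 3), c(2, 4, 6))
  expect_equal(rev$bias, -ag$bias)
  p <- plot_bland_altman(c(2, 4, 6), c(1, 2, 3))
  expect_s3_class(p, "ggplot")
})

test_that("mean Dice averages the four foreground labels", {
  a <- mkvol(c(1, 2, 3, 4, 0, 0, 0, 0))
  b <- mkvol(c(1, 2, 0, 0, 0, 0, 3, 4))
  # labels 1, 2 overlap fully; labels 3, 4 are disjoint
  expect_equal(mean_dice(a, b), mean(c(1, 1, 0, 0)))
  tab <- evaluate_labels(a, b, "s1")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$dice, c(1, 1, 0, 0))
})
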