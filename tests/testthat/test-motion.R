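# hand-built corresponded meshes for closed-form checks
mock_meshes <- function(ed, es, axis) {
  tmpl <- surface_mesh(ed, matrix(1L, 1, 3), tag = "rv_endo")
  structure(list(template = tmpl, ed_vertices = ed, es_vertices = es,
                 centreline = axis, tag = "rv_endo",
                 qc = list(flag = FALSE, frac_over = 0, cap = 1,
                           max_fail_frac = 0.05)),
            class = "corresponded_meshes")
}

zaxis <- centre_axis(c(0, 0, 10), c(0, 0, -1))   # apex at z = 10

test_that("motion components follow the cylindrical closed forms", {
  ed <- rbind(c(3, 0, 4), c(0, 2, 6), c(1, 1, 8))
  # no motion
  mf0 <- decompose_motion(mock_meshes(ed, ed, zaxis))
  expect_equal(max(abs(as.matrix(mf0[, 2:5]))), 0)
  # pure 2 mm axial translation toward the apex (apex at high z)
  es_ax <- ed + rep(c(0, 0, 2), each = 3)
  mf1 <- decompose_motion(mock_meshes(ed, es_ax, zaxis))
  expect_equal(mf1$longitudinal, rep(2, 3))
  expect_equal(mf1$radial, rep(0, 3))
  expect_equal(mf1$circumferential, rep(0, 3))
  # 0.5 rad rotation about the axis at r = 3: circumferential = 1.5 mm
  p <- matrix(c(3, 0, 4), 1)
  th <- -0.5   # right-handed about apex->base = -z means -0.5 about +z
  q <- matrix(c(3 * cos(th), 3 * sin(th), 4), 1)
  mf2 <- decompose_motion(mock_meshes(p, q, zaxis))
  expect_equal(mf2$circumferential, 1.5, tolerance = 1e-12)
  expect_equal(mf2$longitudinal, 0)
  expect_equal(mf2$radial, 0, tolerance = 1e-12)
  # components (3, 4, 0) -> magnitude 5 (Euclidean norm)
  p3 <- matrix(c(5, 0, 7), 1)   # height 3, radius 5
  q3 <- matrix(c(1, 0, 10), 1)  # descends 3 to the apex, contracts 4
  mf3 <- decompose_motion(mock_meshes(p3, q3, zaxis))
  expect_equal(mf3$longitudinal, 3)
  expect_equal(mf3$radial, 4)
  expect_equal(mf3$magnitude, 5)
  # literal root-mean-square reading rescales by sqrt(3)
  mf3r <- decompose_motion(mock_meshes(p3, q3, zaxis), magnitude = "rms")
  expect_equal(mf3r$magnitude, 5 / sqrt(3))
})

test_that("a vertex on the axis has zero circumferential motion", {
  p <- matrix(c(0, 0, 5), 1)
  q <- matrix(c(0, 0, 5), 1)
  mf <- decompose_motion(mock_meshes(p, q, zaxis))
  expect_equal(mf$circumferential, 0)
})

test_that("magnitude properties hold on random fields", {
  set.seed(12)
  ed <- matrix(rnorm(60, sd = 3), 20, 3)
  es <- ed + matrix(rnorm(60, sd = 0.5), 20, 3)
  mf <- decompose_motion(mock_meshes(ed, es, zaxis))
  expect_true(all(mf$magnitude >= 0))
  expect_equal(mf$magnitude,
               sqrt(mf$longitudinal^2 + mf$radial^2 + mf$circumferential^2))
  # negated field has the same magnitude; zero iff all components zero
  mneg <- decompose_motion(mock_meshes(es, 2 * es - ed, zaxis))
  expect_equal(sum(mf$magnitude < 1e-12),
               sum(abs(mf$longitudinal) + abs(mf$radial) +
                     abs(mf$circumferential) < 1e-12))
})

test_that("motion is invariant under a shared rigid transform of both
           phases and the axis", {
  set.seed(13)
  ed <- matrix(rnorm(60, sd = 3), 20, 3)
  es <- ed + matrix(rnorm(60, sd = 0.4), 20, 3)
  mf <- decompose_motion(mock_meshes(ed, es, zaxis))
  R <- random_rotation()
  t <- c(4, -2, 1)
  rot <- function(p) t(R %*% t(p)) + rep(t, each = nrow(p))
  ax2 <- centre_axis(as.vector(R %*% zaxis$point) + t,
                     as.vector(R %*% zaxis$direction))
  mf2 <- decompose_motion(mock_meshes(rot(ed), rot(es), ax2))
  for (cc in c("longitudinal", "radial", "circumferential", "magnitude"))
    expect_equal(mf2[[cc]], mf[[cc]], tolerance = 1e-6)
})

test_that("point-wise percentage change applies the floor-exclusion rule", {
  set.seed(14)
  ed <- matrix(rnorm(30, sd = 3), 10, 3)
  es <- ed + matrix(rnorm(30, sd = 0.5), 10, 3)
  ctl <- decompose_motion(mock_meshes(ed, es, zaxis))
  same <- pointwise_percent_change(ctl, ctl)
  expect_equal(same$summary$mean_pct, rep(0, 4))
  half <- ctl
  for (cc in c("longitudinal", "radial", "circumferential", "magnitude"))
    half[[cc]] <- ctl[[cc]] / 2
  pc <- pointwise_percent_change(half, ctl)
  expect_equal(pc$summary$mean_pct, rep(-50, 4))
  low <- ctl
  low$magnitude[1] <- 0.001      # below the 0.01 mm floor
  pc2 <- pointwise_percent_change(ctl, low)
  expect_equal(pc2$summary$n_excluded[pc2$summary$component == "magnitude"],
               1)
  bad <- ctl[1:5, ]
  expect_error(pointwise_percent_change(bad, ctl), "mismatch")
})

test_that("group percentage difference matches the arithmetic and its
           degenerate cases", {
  expect_equal(group_percent_difference(c(10, 10), c(10, 10))$pct_diff, 0)
  expect_equal(group_percent_difference(rep(6.2, 3), rep(10, 3))$pct_diff,
               -38)
  g <- group_percent_difference(c(5, 7), c(9, 11))
  expect_equal(g$pct_diff, 100 * (6 - 10) / 10)
  expect_equal(g$sd_pct, 100 * sd(c(5, 7)) / 10)
})
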