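test_that("sphere meshes match closed-form area and volume within 3%,
           improving with resolution", {
  m1 <- extract_surface(sphere_labels(10, 1), "lv_endo")
  a_true <- 4 * pi * 100
  v_true <- 4 / 3 * pi * 1000
  err_a1 <- abs(mesh_area(m1) - a_true) / a_true
  err_v1 <- abs(mesh_volume(m1) - v_true) / v_true
  expect_lt(err_a1, 0.03)
  expect_lt(err_v1, 0.03)
  m2 <- extract_surface(sphere_labels(10, 0.5), "lv_endo")
  expect_lt(abs(mesh_area(m2) - a_true) / a_true, err_a1)
  expect_lt(abs(mesh_volume(m2) - v_true) / v_true, err_v1)
})

test_that("closed components have Euler characteristic 2, also for two
           disconnected blobs", {
  m <- extract_surface(sphere_labels(8, 1), "lv_endo")
  comp <- mesh_components(m)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$euler, 2)
  two <- sphere_labels(5, 1, margin = 14)
  d <- dim(two$values)
  shift <- two$values * 0L
  shift[1:14, , ] <- two$values[(d[1] - 13):d[1], , ]
  two$values <- two$values + 0L
  two$values[, , ] <- 0L
  ctr <- (d + 1) / 2
  x <- (1:d[1]) - ctr[1]
  s2 <- outer(x^2, x^2, "+")
  for (k in 1:d[3]) {
    z2 <- ((k - ctr[3]))^2
    blob1 <- (outer((x + 8)^2, x^2, "+") + z2 <= 25)
    blob2 <- (outer((x - 8)^2, x^2, "+") + z2 <= 25)
    two$values[, , k] <- (blob1 | blob2) * 1L
  }
  m2 <- extract_surface(two, "lv_endo")
  comp2 <- mesh_components(m2)
  expect_equal(nrow(comp2), 2)
  expect_equal(comp2$euler, c(2, 2))
  expect_error(extract_surface(label_volume(array(0L, c(4, 4, 4)),
                                            c(1, 1, 1)), "lv_endo"),
               "no voxels")
})

test_that("no mesh triangle is degenerate", {
  m <- extract_surface(tiny_ed(), "lv_endo")
  v <- m$vertices
  f <- m$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  expect_gt(min(areas), 1e-9)
})

test_that("the septal centreline is near-axial for the symmetric phantom,
           equivariant, and optimal among random lines", {
  ax <- fit_centreline(tiny_ed())
  expect_lt(acos(abs(ax$direction[3])) * 180 / pi, 3)   # near-axial
  expect_lt(ax$direction[3], 0)                         # apex->base = -z
  # rigid equivariance: translate the label grid
  lab2 <- tiny_ed()
  lab2$origin <- lab2$origin + c(3, -1, 2)
  ax2 <- fit_centreline(lab2)
  expect_equal(ax2$direction, ax$direction, tolerance = 1e-9)
  expect_equal(ax2$point, ax$point + c(3, -1, 2), tolerance = 1e-9)
  # TLS optimality against random candidate lines
  cents <- attr(ax, "slice_centroids")
  line_cost <- function(p0, u) {
    w <- sweep(cents, 2, p0)
    proj <- w - outer(as.vector(w %*% u), u)
    mean(sqrt(rowSums(proj^2)))
  }
  best <- line_cost(ax$point, ax$direction)
  set.seed(8)
  for (i in 1:100) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    p0 <- colMeans(cents) + rnorm(3, sd = 0.3)
    expect_gte(line_cost(p0, u), best - 1e-9)
  }
})

test_that("the centreline falls back to LV centroids without a septum", {
  sp <- tiny_spec(rv_crescent_extent = 0)
  lab <- generate_ed_labels(sp)
  ax <- fit_centreline(lab)
  expect_true(attr(ax, "fallback"))
})

test_that("template meshes hit the requested vertex budget", {
  m <- build_template_mesh(tiny_ed(), "lv_endo", target_vertices = 800)
  expect_lt(abs(nrow(m$vertices) / 800 - 1), 0.15)
})

test_that("correspondence is identity-consistent and preserves vertex
           count and indexing", {
  ed <- tiny_ed()
  tmpl <- extract_surface(ed, "lv_endo")
  cm <- correspond(tmpl, ed, ed,
                   list(ed = function(p) p, es = function(p) p))
  expect_equal(nrow(cm$ed_vertices), nrow(tmpl$vertices))
  expect_equal(nrow(cm$es_vertices), nrow(tmpl$vertices))
  expect_lt(max(sqrt(rowSums((cm$ed_vertices - cm$es_vertices)^2))),
            max(ed$spacing))
  expect_false(cm$qc$flag)
})

test_that("a tight projection cap flags quality failure", {
  ed <- tiny_ed()
  es <- tiny_es()
  tmpl <- extract_surface(ed, "lv_endo")
  cm <- correspond(tmpl, ed, es,
                   list(ed = function(p) p, es = function(p) p),
                   cap = 1e-6)
  expect_true(cm$qc$flag)
})

test_that("meshes round-trip through OFF and PLY carries attributes", {
  m <- extract_surface(sphere_labels(5, 1), "lv_endo")
  f_off <- tempfile(fileext = ".off")
  write_mesh(m, f_off)
  back <- read_mesh_off(f_off)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-5)
  expect_identical(back$faces, m$faces)
  f_ply <- tempfile(fileext = ".ply")
  write_mesh(m, f_ply, attributes = list(mag = seq_len(nrow(m$vertices))))
  hdr <- readLines(f_ply, n = 12)
  expect_true(any(grepl("property float mag", hdr)))
})
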