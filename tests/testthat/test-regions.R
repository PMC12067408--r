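# shared fixture: corresponded phantom meshes with analytic ES mapping
region_fix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sp <- tiny_spec(seed = 61)
    ed <- generate_ed_labels(sp)
    es <- deform_to_es(ed, sp$systole, sp)
    g <- ratcine:::phantom_geometry(sp)
    ax <- phantom_axis(sp)
    fwd <- function(p) ratcine:::forward_map(p, sp$systole, g$z_apex)
    cms <- lapply(c("lv_endo", "rv_endo"), function(st)
      correspond(extract_surface(ed, st), ed, es,
                 list(ed = function(p) p, es = fwd), centreline = ax))
    names(cms) <- c("lv_endo", "rv_endo")
    ins <- find_insertion_angle(ed, ax)
    cache <<- list(sp = sp, ed = ed, es = es, ax = ax, cms = cms, ins = ins)
    cache
  }
})

test_that("segment ids partition each ventricle with the stated layout", {
  fx <- region_fix()
  lv <- assign_segments(fx$cms$lv_endo, fx$ins)
  expect_true(all(lv$segment %in% 1:17))
  expect_true(all(table(factor(lv$segment, levels = 1:17)) > 0))
  expect_true(all(lv$level[lv$segment %in% 1:6] == "basal"))
  expect_true(all(lv$level[lv$segment %in% 7:12] == "mid"))
  expect_true(all(lv$level[lv$segment %in% 13:16] == "apical"))
  expect_gt(sum(lv$segment == 17), 0)            # apex non-empty
  rv <- assign_segments(fx$cms$rv_endo, fx$ins)
  expect_true(all(rv$segment %in% 1:11))
  expect_gt(sum(rv$segment == 11), 0)
  # exhaustive and disjoint by construction: one id per vertex
  expect_equal(nrow(lv), nrow(fx$cms$lv_endo$ed_vertices))
})

test_that("a vertex 30 degrees clockwise of the insertion in the basal
           third lands in segment 1 (anterior basal)", {
  fx <- region_fix()
  cm <- fx$cms$lv_endo
  cyl <- ratcine:::cylindrical(cm$ed_vertices, cm$centreline)
  segs <- assign_segments(cm, fx$ins)
  delta <- ((as.numeric(fx$ins) - cyl$theta) * 180 / pi) %% 360
  sel <- abs(delta - 30) < 10 & segs$level == "basal"
  expect_gt(sum(sel), 0)
  expect_true(all(segs$segment[sel] == 1L))
})

test_that("segment assignment is equivariant under a shared rigid motion", {
  fx <- region_fix()
  cm <- fx$cms$lv_endo
  segs <- assign_segments(cm, fx$ins)
  R <- diag(3)  # rotation about the long axis keeps the angular origin rule
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- function(p) t(R %*% t(p)) + rep(c(1, 2, -3), each = nrow(p))
  cm2 <- cm
  cm2$ed_vertices <- rot(cm$ed_vertices)
  cm2$es_vertices <- rot(cm$es_vertices)
  cm2$centreline <- centre_axis(
    as.vector(R %*% cm$centreline$point) + c(1, 2, -3),
    as.vector(R %*% cm$centreline$direction))
  # rotating everything, including the insertion landmark, changes nothing
  cyl_old <- ratcine:::cylindrical(cm$ed_vertices, cm$centreline)
  cyl_new <- ratcine:::cylindrical(cm2$ed_vertices, cm2$centreline)
  shift <- (cyl_new$theta - cyl_old$theta)[1]
  segs2 <- assign_segments(cm2, as.numeric(fx$ins) + shift)
  expect_equal(segs2$segment, segs$segment)
})

test_that("regional summaries are medians: uniform fields and outlier
           robustness", {
  fx <- region_fix()
  cm <- fx$cms$lv_endo
  segs <- assign_segments(cm, fx$ins)
  mf <- decompose_motion(cm)
  uniform <- mf
  for (cc in c("longitudinal", "radial", "circumferential", "magnitude"))
    uniform[[cc]] <- rep(1.5, nrow(mf))
  rs <- regional_summary(uniform, segs)
  expect_true(all(abs(rs$median - 1.5) < 1e-12))
  spiked <- mf
  big <- which.max(tabulate(segs$segment))
  vsel <- which(segs$segment == big)
  before <- regional_summary(mf, segs)
  spiked$magnitude[vsel[1]] <- 1e6
  after <- regional_summary(spiked, segs)
  pick <- before$segment == big & before$component == "magnitude"
  expect_equal(after$median[pick], before$median[pick], tolerance = 1e-6)
})

test_that("per-segment counts are stable across phases and weighted means
           aggregate exactly", {
  fx <- region_fix()
  cm <- fx$cms$rv_endo
  segs <- assign_segments(cm, fx$ins)
  mf <- decompose_motion(cm)
  rs <- regional_summary(mf, segs)
  expect_equal(sum(rs$n_vertices[rs$component == "magnitude"]), nrow(mf))
  # weighted-mean conservation over occupied segments
  occ <- sort(unique(segs$segment))
  means <- vapply(occ, function(s) mean(mf$magnitude[segs$segment == s]), 0)
  counts <- vapply(occ, function(s) sum(segs$segment == s), 0)
  expect_equal(sum(means * counts), sum(mf$magnitude), tolerance = 1e-9)
})

test_that("the bullseye table has the fixed 28-row layout and survives a
           plot round-trip", {
  fx <- region_fix()
  lv <- regional_summary(decompose_motion(fx$cms$lv_endo),
                         assign_segments(fx$cms$lv_endo, fx$ins))
  rv <- regional_summary(decompose_motion(fx$cms$rv_endo),
                         assign_segments(fx$cms$rv_endo, fx$ins))
  bt <- bullseye_table(lv, rv)
  expect_equal(nrow(bt), 28)
  expect_equal(sum(bt$ventricle == "LV"), 17)
  expect_equal(sum(bt$ventricle == "RV"), 11)
  expect_equal(bt$segment[bt$ventricle == "LV"], 1:17)  # basal -> apical
  expect_equal(bt$segment[bt$ventricle == "RV"], 1:11)
  p <- plot_bullseye(bt)
  expect_s3_class(p, "ggplot")
  expect_equal(sort(unique(p$data$value[p$data$ventricle == "LV"])),
               sort(unique(bt$value[bt$ventricle == "LV"])))
})

test_that("graded contraction orders the per-segment group means", {
  specs <- lapply(c(0.08, 0.2), function(f)
    tiny_spec(systole = deformation_spec(f, f, 0.5), seed = 62))
  mags <- vapply(specs, function(sp) {
    ed <- generate_ed_labels(sp)
    es <- deform_to_es(ed, sp$systole, sp)
    g <- ratcine:::phantom_geometry(sp)
    fwd <- function(p) ratcine:::forward_map(p, sp$systole, g$z_apex)
    cm <- correspond(extract_surface(ed, "rv_endo"), ed, es,
                     list(ed = function(p) p, es = fwd),
                     centreline = phantom_axis(sp))
    mean(decompose_motion(cm)$magnitude)
  }, 0)
  expect_true(all(diff(mags) > 0))
})
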