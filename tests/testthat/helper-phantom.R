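# Shared fixtures. Unit tests use a coarse phantom (0.4 mm in-plane,
# 0.68 mm HR slices) so each file stays fast; acceptance tests build
# full-resolution phantoms themselves.

tiny_spec <- function(...) {
  defaults <- list(long_axis_len = 8, lv_endo_radius = 2.2,
                   lv_wall_thick = 1, rv_wall_thick = 0.6, rv_offset = 1.4,
                   inplane_spacing = 0.4, hr_slice_thick = 0.68,
                   lr_slice_thick = 2.72, noise_sigma = 0.03)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# memoized tiny ED/ES labels shared across tests
.fix <- new.env(parent = emptyenv())

tiny_ed <- function() {
  if (is.null(.fix$ed)) .fix$ed <- generate_ed_labels(tiny_spec(seed = 9))
  .fix$ed
}

tiny_es <- function() {
  if (is.null(.fix$es)) {
    sp <- tiny_spec(seed = 9)
    .fix$es <- deform_to_es(tiny_ed(), sp$systole, sp)
  }
  .fix$es
}

# digital sphere label volume (radius vox, spacing mm)
sphere_labels <- function(radius = 10, spacing = 1, margin = 3) {
  half <- radius + margin
  n <- round(2 * half / spacing) + 1
  x <- ((1:n) - (n + 1) / 2) * spacing
  vals <- array(0L, c(n, n, n))
  s2 <- outer(x^2, x^2, "+")
  for (k in 1:n) vals[, , k] <- (s2 + x[k]^2 <= radius^2) * 1L
  label_volume(vals, rep(spacing, 3))
}

random_rotation <- function() {
  w <- rnorm(3)
  th <- runif(1, 0.1, 2.5)
  k <- w / sqrt(sum(w^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
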