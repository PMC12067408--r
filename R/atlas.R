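#' Detect the six bi-ventricular landmarks
#'
#' For each cavity (LV, RV) the basal, mid-ventricular and apical slices
#' are the first, middle and last slices containing that cavity (slices run
#' base to apex); each landmark is the physical centroid of the cavity's
#' voxels in that slice.
#'
#' @param lab A [label_volume()] with LV and RV cavities spanning at least
#'   3 slices each.
#' @return 6 x 3 matrix (mm), rows `LV_basal`, `LV_mid`, `LV_apical`,
#'   `RV_basal`, `RV_mid`, `RV_apical`.
#' @export
detect_landmarks <- function(lab) {
  one <- function(cav, tag) {
    slices <- which(apply(lab$values == cav, 3, any))
    if (length(slices) < 3)
      stop(sprintf("%s cavity spans fewer than 3 slices", tag))
    picks <- c(basal = slices[1],
               mid = slices[ceiling(length(slices) / 2)],
               apical = slices[length(slices)])
    t(vapply(names(picks), function(p) {
      k <- picks[[p]]
      idx <- which(lab$values[, , k] == cav, arr.ind = TRUE)
      c(lab$origin[1] + (mean(idx[, 1]) - 1) * lab$spacing[1],
        lab$origin[2] + (mean(idx[, 2]) - 1) * lab$spacing[2],
        lab$origin[3] + (k - 1) * lab$spacing[3])
    }, numeric(3)))
  }
  lv <- one(heart_labels[["lv_cavity"]], "LV")
  rv <- one(heart_labels[["rv_cavity"]], "RV")
  out <- rbind(lv, rv)
  rownames(out) <- c("LV_basal", "LV_mid", "LV_apical",
                     "RV_basal", "RV_mid", "RV_apical")
  out
}

#' Least-squares rigid transform between landmark sets
#'
#' Orthogonal-Procrustes (Kabsch) solution minimizing
#' `sum || T(src) - dst ||^2` over rotations and translations; the RMS
#' residual is attached as an attribute.
#'
#' @param src,dst Paired n x 3 point matrices (n >= 3, not all collinear).
#' @return A [rigid_transform()] mapping `src` points onto `dst`.
#' @export
rigid_from_landmarks <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), nrow(src) >= 3)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2)
    stop("degenerate (collinear) landmark configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cd - as.vector(R %*% cs)
  tf <- rigid_transform(R, t)
  res <- apply_transform(tf, src) - dst
  attr(tf, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  tf
}

# smoothed one-hot channel images of a label volume (channel 1 = background)
label_channels <- function(lab, sigma_vox = 1) {
  lapply(0:4, function(l) {
    m <- array(0, dim(lab$values))
    m[lab$values == l] <- 1
    cpp_gauss_smooth(m, rep(sigma_vox, 3))
  })
}

ds_channels <- function(ch, spacing, origin) {
  list(ch = lapply(ch, downsample2), spacing = spacing * 2,
       origin = origin + spacing / 2)
}

# generic gradient descent with backtracking line search; obj_grad(par,
# want_grad) returns list(obj, grad); take_step(par, grad, step) proposes
gd_backtrack <- function(par, obj_grad, take_step, step0, max_iter, tol) {
  og <- obj_grad(par, TRUE)
  obj <- og$obj
  step <- step0
  trace <- obj
  for (it in seq_len(max_iter)) {
    accepted <- FALSE
    for (try in 1:15) {
      cand <- take_step(par, og$grad, step)
      o2 <- obj_grad(cand, FALSE)$obj
      if (o2 < obj) {
        accepted <- TRUE
        break
      }
      step <- step * 0.4
      if (step < 1e-12) break
    }
    if (!accepted) break
    rel <- (obj - o2) / max(obj, 1e-12)
    par <- cand
    obj <- o2
    trace <- c(trace, obj)
    if (rel < tol) break
    og <- obj_grad(par, TRUE)
    step <- step * 1.5
  }
  list(par = par, obj = obj, trace = trace, converged = TRUE)
}

# shared setup: multi-resolution channel pyramids in centre-shifted
# coordinates (both grids shifted by -centre so rotations/linear terms are
# well-conditioned)
reg_setup <- function(moving, fixed, sigma_vox) {
  fch <- label_channels(fixed, sigma_vox)
  mch <- label_channels(moving, sigma_vox)
  centre <- fixed$origin + (dim(fixed$values) - 1) / 2 * fixed$spacing
  list(fch = fch, mch = mch, centre = centre,
       fsp = fixed$spacing, forg = fixed$origin - centre,
       msp = moving$spacing, morg = moving$origin - centre)
}

# convert a centred-coordinates (A, t') into a raw-coordinates transform
uncentre <- function(A, t, centre, rigid = FALSE) {
  t_raw <- as.vector(t) + centre - as.vector(A %*% centre)
  if (rigid) rigid_transform(A, t_raw) else affine_transform(A, t_raw)
}

centre_affine <- function(tf, centre) {
  # T(x) = A x + t  ->  centred: y = x - c, T'(y) = A y + (A c + t - c)
  list(A = tf$A, t = as.vector(tf$A %*% centre) + tf$t - centre)
}

#' Affine registration of label volumes
#'
#' Optimizes the label-consistency objective (mean squared difference of
#' Gaussian-smoothed one-hot label channels, a soft multi-class overlap)
#' over the 12 affine parameters by gradient descent with backtracking line
#' search, over two resolution levels (half, then full with strided
#' sampling). The objective is non-increasing across accepted iterations.
#'
#' @param moving,fixed [label_volume()] objects; the transform maps fixed
#'   space into moving space (resampling convention).
#' @param init A rigid or affine initialization (e.g. from
#'   [rigid_from_landmarks()]).
#' @param max_iter Iterations per level.
#' @param tol Relative objective-change tolerance.
#' @param sigma_vox Gaussian smoothing of the one-hot channels (voxels).
#' @return An `affine_transform` with attribute `objective_trace`.
#' @export
register_affine <- function(moving, fixed, init = rigid_transform(),
                            max_iter = 200, tol = 1e-6, sigma_vox = 1) {
  su <- reg_setup(moving, fixed, sigma_vox)
  ct <- centre_affine(init, su$centre)
  par <- list(A = ct$A, t = ct$t)
  sig2 <- max(su$fsp * dim(su$fch[[1]]))^2 / 16  # ~ (domain/4)^2 mm^2
  lv1 <- ds_channels(su$fch, su$fsp, su$forg)
  lv1m <- ds_channels(su$mch, su$msp, su$morg)
  traces <- NULL
  for (level in 1:2) {
    if (level == 1) {
      fch <- lv1$ch; fsp <- lv1$spacing; forg <- lv1$origin
      mch <- lv1m$ch; msp <- lv1m$spacing; morg <- lv1m$origin
      stride <- 1L
    } else {
      fch <- su$fch; fsp <- su$fsp; forg <- su$forg
      mch <- su$mch; msp <- su$msp; morg <- su$morg
      stride <- 2L
    }
    og <- function(p, want) {
      r <- cpp_affine_obj_grad(fch, fsp, forg, mch, msp, morg, p$A, p$t,
                               stride, want)
      list(obj = r$obj, grad = list(A = r$gA, t = r$gt))
    }
    st <- function(p, g, step) {
      list(A = p$A - step / sig2 * g$A, t = p$t - step * g$t)
    }
    fit <- gd_backtrack(par, og, st, step0 = 20, max_iter = max_iter,
                        tol = tol)
    par <- fit$par
    traces <- c(traces, list(fit$trace))
  }
  out <- uncentre(par$A, par$t, su$centre)
  attr(out, "objective_trace") <- traces
  out
}

#' Rigid refinement by label overlap
#'
#' As [register_affine()] but constrained to rotations + translation
#' (rotation updated on the manifold via Rodrigues' formula).
#'
#' @inheritParams register_affine
#' @return A `rigid_transform`.
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform(),
                           max_iter = 60, tol = 1e-6, sigma_vox = 1) {
  su <- reg_setup(moving, fixed, sigma_vox)
  ct <- centre_affine(init, su$centre)
  par <- list(R = ct$A, t = ct$t)
  sig2 <- max(su$fsp * dim(su$fch[[1]]))^2 / 16
  lv1 <- ds_channels(su$fch, su$fsp, su$forg)
  lv1m <- ds_channels(su$mch, su$msp, su$morg)
  rodrigues <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-14) return(diag(3))
    k <- w / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  gens <- list(matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),
               matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3, 3),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3))
  for (level in 1:2) {
    if (level == 1) {
      fch <- lv1$ch; fsp <- lv1$spacing; forg <- lv1$origin
      mch <- lv1m$ch; msp <- lv1m$spacing; morg <- lv1m$origin
      stride <- 1L
    } else {
      fch <- su$fch; fsp <- su$fsp; forg <- su$forg
      mch <- su$mch; msp <- su$msp; morg <- su$morg
      stride <- 2L
    }
    og <- function(p, want) {
      r <- cpp_affine_obj_grad(fch, fsp, forg, mch, msp, morg, p$R, p$t,
                               stride, want)
      gw <- if (want) vapply(gens, function(G)
        sum(r$gA * (G %*% p$R)), 0) else NULL
      list(obj = r$obj, grad = list(w = gw, t = r$gt))
    }
    st <- function(p, g, step) {
      list(R = rodrigues(-step / sig2 * g$w) %*% p$R,
           t = p$t - step * g$t)
    }
    fit <- gd_backtrack(par, og, st, step0 = 10, max_iter = max_iter,
                        tol = tol)
    par <- fit$par
  }
  # re-orthogonalize against numerical drift
  sv <- svd(par$R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  uncentre(R, par$t, su$centre, rigid = TRUE)
}

#' B-spline free-form deformation registration
#'
#' Starting from an affine initialization, optimizes a lattice of cubic
#' B-spline control-point displacements (default spacing 8 HR voxels per
#' axis, displacements capped at twice the spacing) against the same
#' smoothed label-consistency objective, multi-resolution, gradient descent
#' with backtracking. Composition order rigid/affine then FFD is recorded
#' in the returned transform.
#'
#' @inheritParams register_affine
#' @param init The affine (or rigid) stage output.
#' @param lattice_vox Control-point spacing in fixed-grid voxels.
#' @param max_iter Iterations per level.
#' @return An `ffd_transform` with attribute `objective_trace`.
#' @export
register_ffd <- function(moving, fixed, init = affine_transform(),
                         lattice_vox = 8, max_iter = 100, tol = 1e-6,
                         sigma_vox = 1) {
  su <- reg_setup(moving, fixed, sigma_vox)
  ct <- centre_affine(init, su$centre)
  d <- dim(fixed$values)
  lat_spacing <- su$fsp * lattice_vox
  lat_origin <- su$forg - lat_spacing
  nc <- ceiling((d - 1) * su$fsp / lat_spacing) + 4L
  disp <- array(0, c(nc, 3))
  cap <- 2 * max(lat_spacing)
  lv1 <- ds_channels(su$fch, su$fsp, su$forg)
  lv1m <- ds_channels(su$mch, su$msp, su$morg)
  traces <- NULL
  for (level in 1:2) {
    if (level == 1) {
      fch <- lv1$ch; fsp <- lv1$spacing; forg <- lv1$origin
      mch <- lv1m$ch; msp <- lv1m$spacing; morg <- lv1m$origin
      stride <- 1L
    } else {
      fch <- su$fch; fsp <- su$fsp; forg <- su$forg
      mch <- su$mch; msp <- su$msp; morg <- su$morg
      stride <- 2L
    }
    og <- function(p, want) {
      r <- cpp_ffd_obj_grad(fch, fsp, forg, mch, msp, morg, ct$A, ct$t, p,
                            lat_origin, lat_spacing, stride, want)
      list(obj = r$obj, grad = r$grad)
    }
    st <- function(p, g, step) {
      out <- p - step * g
      out[out > cap] <- cap
      out[out < -cap] <- -cap
      out
    }
    fit <- gd_backtrack(disp, og, st, step0 = 50, max_iter = max_iter,
                        tol = tol)
    disp <- fit$par
    traces <- c(traces, list(fit$trace))
  }
  out <- ffd_transform(disp, lat_origin + su$centre, lat_spacing,
                       uncentre(ct$A, ct$t, su$centre))
  attr(out, "objective_trace") <- traces
  out
}

#' Assemble an atlas library
#'
#' @param labels List of HR [label_volume()] objects.
#' @param phases Character vector (`"ED"`/`"ES"`) per atlas.
#' @param ids Optional atlas identifiers.
#' @return An `atlas_library` (atlases with cached landmarks).
#' @export
atlas_library <- function(labels, phases, ids = NULL) {
  stopifnot(length(labels) == length(phases),
            all(phases %in% c("ED", "ES")))
  if (is.null(ids)) ids <- sprintf("atlas%02d", seq_along(labels))
  atl <- Map(function(l, p, id)
    list(label = l, phase = p, id = id, landmarks = detect_landmarks(l)),
    labels, phases, ids)
  structure(list(atlases = atl), class = "atlas_library")
}

#' Rank atlases by label consistency
#'
#' Each same-phase atlas is rigidly registered to the subject (initialized
#' by the six landmarks), resampled onto the subject grid, and scored by
#' mean foreground Dice ("label consistency"); atlases are returned in
#' descending score order (stable in library order on ties), truncated to
#' the phase's default selection size (5 for ED, 3 for ES), capped at the
#' library size.
#'
#' @param subject A subject [label_volume()] (typically the FCN prediction
#'   resampled to HR).
#' @param lib An [atlas_library()].
#' @param phase `"ED"` or `"ES"`.
#' @param k Number of atlases kept; default 5 (ED) / 3 (ES).
#' @return Tibble: atlas index, id, score, in rank order, with the rigid
#'   transforms in the `transform` list-column.
#' @export
rank_atlases <- function(subject, lib, phase = c("ED", "ES"), k = NULL) {
  phase <- match.arg(phase)
  cand <- which(vapply(lib$atlases, function(a) a$phase == phase, TRUE))
  if (length(cand) == 0) stop("no atlases for phase ", phase)
  if (is.null(k)) k <- if (phase == "ED") 5L else 3L
  k <- min(k, length(cand))
  sub_lm <- detect_landmarks(subject)
  rows <- lapply(cand, function(i) {
    a <- lib$atlases[[i]]
    tf <- rigid_from_landmarks(sub_lm, a$landmarks)
    warped <- warp_labels(a$label, tf, subject)
    tibble::tibble(atlas = i, id = a$id, score = mean_dice(warped, subject),
                   transform = list(tf))
  })
  tab <- dplyr::bind_rows(rows)
  tab <- tab[order(-tab$score, tab$atlas), , drop = FALSE]
  tab[seq_len(k), , drop = FALSE]
}

#' Fuse warped atlas labels by majority vote
#'
#' Per-voxel majority vote; ties are broken in favour of the label voted by
#' the highest-ranked atlas (implemented as a rank-decreasing epsilon
#' weight that cannot overturn a strict majority).
#'
#' @param warped List of [label_volume()] objects on one grid, ordered best
#'   rank first.
#' @return The fused [label_volume()].
#' @export
fuse_labels <- function(warped) {
  if (length(warped) == 0) stop("no atlases to fuse")
  grid <- warped[[1]]
  for (w in warped) if (!same_grid(w, grid)) stop("grids differ in fusion")
  K <- length(warped)
  eps <- 1 / (2 * K + 1)
  wts <- 1 + eps * (K - seq_len(K) + 1) / K
  score <- array(0, c(dim(grid$values), 5))
  for (i in seq_len(K)) {
    for (l in 0:4) {
      sel <- warped[[i]]$values == l
      if (any(sel)) {
        sl <- score[, , , l + 1]
        sl[sel] <- sl[sel] + wts[i]
        score[, , , l + 1] <- sl
      }
    }
  }
  flat <- matrix(score, ncol = 5)
  out <- grid
  out$values <- array(max.col(flat, ties.method = "first") - 1L,
                      dim(grid$values))
  out
}

#' Fit a high-resolution label to a subject via multi-atlas fusion
#'
#' The full refinement stage: rank the library against the subject's
#' thick-slice segmentation (resampled to the HR grid), register the top
#' atlases with affine + FFD on top of the landmark rigid initialization,
#' resample them onto the subject HR grid, and fuse by majority vote.
#'
#' @param subject_lr The subject's (thick-slice) [label_volume()].
#' @param lib An [atlas_library()].
#' @param phase `"ED"` or `"ES"`.
#' @param k Atlas count (default per phase).
#' @param hr_spacing_z Target slice spacing; defaults to the library's.
#' @param ffd_iter,affine_iter Optimizer iterations.
#' @return List: `label` (fused HR label), `ranking`, `transforms`.
#' @export
atlas_fit <- function(subject_lr, lib, phase = c("ED", "ES"), k = NULL,
                      hr_spacing_z = NULL, affine_iter = 60, ffd_iter = 40) {
  phase <- match.arg(phase)
  if (is.null(hr_spacing_z))
    hr_spacing_z <- lib$atlases[[1]]$label$spacing[3]
  subject_hr <- upsample_z_nn(subject_lr, hr_spacing_z)
  ranking <- rank_atlases(subject_hr, lib, phase, k)
  warped <- list()
  tfs <- list()
  for (r in seq_len(nrow(ranking))) {
    a <- lib$atlases[[ranking$atlas[r]]]
    tf0 <- ranking$transform[[r]]
    tfa <- register_affine(a$label, subject_hr, init = tf0,
                           max_iter = affine_iter)
    tff <- register_ffd(a$label, subject_hr, init = tfa,
                        max_iter = ffd_iter)
    tfs[[r]] <- tff
    warped[[r]] <- warp_labels(a$label, tff, subject_hr)
  }
  list(label = fuse_labels(warped), ranking = ranking, transforms = tfs)
}

#' Nearest-neighbour z-upsampling of a thick-slice label map
#'
#' The super-resolution baseline: replicate thick slices onto a finer z
#' grid covering the same slab extent.
#'
#' @param lab A [label_volume()].
#' @param new_dz Target slice spacing (mm), finer than the current one.
#' @return A [label_volume()] on the finer grid.
#' @export
upsample_z_nn <- function(lab, new_dz) {
  d <- dim(lab$values)
  dz <- lab$spacing[3]
  z0 <- lab$origin[3] - dz / 2          # slab lower edge
  nz <- round(d[3] * dz / new_dz)
  zc <- z0 + (seq_len(nz) - 0.5) * new_dz
  src <- pmin(pmax(ceiling((zc - z0) / dz), 1L), d[3])
  label_volume(lab$values[, , src, drop = FALSE],
               c(lab$spacing[1:2], new_dz),
               c(lab$origin[1:2], zc[1]))
}

#' Build the average bi-ventricular template
#'
#' Iterative scheme: rigidly co-register every atlas (landmark-initialized)
#' to a reference (the first atlas in library order), fuse by majority
#' vote, then re-register to the fused average; two iterations.
#' Deterministic given library order. ED and ES atlases all contribute.
#'
#' @param lib An [atlas_library()].
#' @param iterations Re-registration iterations (default 2).
#' @return List: `label` (template), `landmarks`.
#' @export
build_template <- function(lib, iterations = 2) {
  stopifnot(length(lib$atlases) >= 1)
  ref <- lib$atlases[[1]]$label
  ref_lm <- lib$atlases[[1]]$landmarks
  for (it in seq_len(iterations)) {
    warped <- lapply(lib$atlases, function(a) {
      tf <- rigid_from_landmarks(ref_lm, a$landmarks)
      warp_labels(a$label, tf, ref)
    })
    ref <- fuse_labels(warped)
    ref_lm <- detect_landmarks(ref)
  }
  list(label = ref, landmarks = ref_lm)
}

#' Rigidly align a subject's HR label to the template
#'
#' Landmark-initialized, overlap-refined rigid registration (rigid only: no
#' shape distortion), so motion analyses are comparable across subjects.
#' The transform maps template space to subject space and is kept for mesh
#' transport.
#'
#' @param subject_hr The subject's fused HR [label_volume()].
#' @param template Output of [build_template()] (or a list with `label`,
#'   `landmarks`).
#' @param refine Run the overlap refinement after landmark initialization.
#' @return List: `label` (subject resampled on the template grid),
#'   `transform` (template -> subject `rigid_transform`).
#' @export
align_to_template <- function(subject_hr, template, refine = TRUE) {
  tf <- rigid_from_landmarks(template$landmarks,
                             detect_landmarks(subject_hr))
  if (refine)
    tf <- register_rigid(subject_hr, template$label, init = tf,
                         max_iter = 30)
  list(label = warp_labels(subject_hr, tf, template$label), transform = tf)
}
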