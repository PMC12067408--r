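# Training and inference for the per-slice segmentation network.

# centre pad/crop a 2-D slice to (H, W); pad with the slice minimum
fit_slice <- function(sl, H, W, pad_value = min(sl)) {
  d <- dim(sl)
  out <- matrix(pad_value, H, W)
  si <- seq_len(min(d[1], H)); sj <- seq_len(min(d[2], W))
  oi <- (H - length(si)) %/% 2L; oj <- (W - length(sj)) %/% 2L
  ii <- (d[1] - length(si)) %/% 2L; jj <- (d[2] - length(sj)) %/% 2L
  out[oi + si, oj + sj] <- sl[ii + si, jj + sj]
  out
}

# cohort -> list of training slices: normalized ED/ES cine slices paired
# with thick-slice labels
cohort_slices <- function(cohort) {
  slices <- list()
  for (s in cohort) {
    es <- s$es_frame
    for (ph in c("ed", "es")) {
      frame <- if (ph == "ed") s$study$frames[[1]]
               else s$study$frames[[es]]
      img <- normalize_intensity(frame)
      lab <- s$labels_lr[[ph]]
      for (k in seq_len(dim(img$values)[3])) {
        slices[[length(slices) + 1]] <-
          list(x = img$values[, , k], y = lab$values[, , k],
               subject = s$id, phase = ph, slice = k)
      }
    }
  }
  slices
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  model$adam$t <- model$adam$t + 1L
  for (nm in names(model$par))
    cpp_adam(model$par[[nm]], model$adam$m[[nm]], model$adam$v[[nm]],
             grads[[nm]], lr, beta1, beta2, eps, model$adam$t)
  invisible(model)
}

batch_loss <- function(model, batch, training) {
  H <- model$input_size[1]; W <- model$input_size[2]
  N <- length(batch)
  X <- matrix(0, N * H * W, 1)
  y <- integer(N * H * W)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * H * W + 1):(n * H * W)
    X[rows, 1] <- as.vector(fit_slice(batch[[n]]$x, H, W))
    y[rows] <- as.vector(fit_slice(batch[[n]]$y, H, W, pad_value = 0L))
  }
  fw <- segnet_forward(model, X, N, training = training)
  sm <- nn_softmax_ce(fw$logits, y)
  list(fw = fw, sm = sm, y = y, N = N)
}

#' Train the segmentation network
#'
#' Mini-batch Adam on mean per-pixel cross-entropy over all ED/ES slices of
#' the training subjects, with fresh augmentation drawn per batch. Subjects
#' must be split subject-wise upstream (every rat's images belong to exactly
#' one of train/validation/test).
#'
#' @param model A `segnet` from [build_segnet()].
#' @param cohort Training subjects (as produced by [generate_cohort()]).
#' @param cfg The [net_config()] (epochs, batch size, learning rate, seed).
#' @param aug An [augment_spec()], or `NULL` to disable augmentation.
#' @param val_cohort Optional validation subjects for a per-epoch loss.
#' @param verbose Print per-epoch losses.
#' @return The model, with `loss_history` (tibble: epoch, train, val).
#' @export
train_segnet <- function(model, cohort, cfg = model$cfg, aug = NULL,
                         val_cohort = NULL, verbose = FALSE) {
  stopifnot(length(cohort) >= 2)
  slices <- cohort_slices(cohort)
  val_slices <- if (!is.null(val_cohort)) cohort_slices(val_cohort)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(length(slices))
    losses <- numeric(0)
    b0 <- 1
    while (b0 <= length(perm)) {
      ids <- perm[b0:min(b0 + cfg$batch_size - 1, length(perm))]
      batch <- slices[ids]
      if (!is.null(aug)) {
        batch <- lapply(batch, function(sl) {
          d <- c(dim(sl$x), 1L)
          a <- augment_pair(image_volume(array(sl$x, d), c(1, 1, 1)),
                            label_volume(array(sl$y, d), c(1, 1, 1)),
                            aug)
          list(x = a$image$values[, , 1], y = a$label$values[, , 1])
        })
      }
      bl <- batch_loss(model, batch, training = TRUE)
      if (!is.finite(bl$sm$loss))
        stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d); %s",
                     epoch, b0, "try a lower learning rate"))
      if (cfg$learning_rate > 0) {
        grads <- segnet_backward(model, bl$fw$caches, bl$sm$dlogits, bl$N)
        adam_step(model, grads, cfg$learning_rate)
      }
      losses <- c(losses, bl$sm$loss)
      b0 <- b0 + cfg$batch_size
    }
    hist_train <- c(hist_train, mean(losses))
    if (!is.null(val_slices)) {
      vb <- batch_loss(model, val_slices, training = FALSE)
      hist_val <- c(hist_val, vb$sm$loss)
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f%s", epoch, mean(losses),
                      if (length(hist_val)) sprintf("  val %.4f",
                                                    tail(hist_val, 1)) else ""))
  }
  model$loss_history <- tibble::tibble(
    epoch = seq_along(hist_train), train = hist_train,
    val = if (length(hist_val)) hist_val else NA_real_)
  model
}

#' Predict a label volume for a cine frame
#'
#' Runs the network slice-by-slice (inference mode, running batch-norm
#' statistics) and restacks the per-pixel argmax into a [label_volume()] on
#' the cine grid. Argmax ties break to the lowest class index. Slices are
#' centre-padded/cropped to the network's input size and the prediction
#' mapped back.
#'
#' @param model A trained `segnet`.
#' @param img A normalized [image_volume()] (one cine frame).
#' @return A [label_volume()] on the same grid.
#' @export
predict_segnet <- function(model, img) {
  stopifnot(inherits(img, "image_volume"))
  H <- model$input_size[1]; W <- model$input_size[2]
  d <- dim(img$values)
  nz <- d[3]
  out <- array(0L, d)
  chunk <- 4L
  k0 <- 1L
  while (k0 <= nz) {
    ks <- k0:min(k0 + chunk - 1L, nz)
    N <- length(ks)
    X <- matrix(0, N * H * W, 1)
    for (n in seq_len(N))
      X[((n - 1) * H * W + 1):(n * H * W), 1] <-
        as.vector(fit_slice(img$values[, , ks[n]], H, W))
    fw <- segnet_forward(model, X, N, training = FALSE)
    pr <- fw$logits
    lab <- max.col(pr, ties.method = "first") - 1L
    for (n in seq_len(N)) {
      sl <- matrix(lab[((n - 1) * H * W + 1):(n * H * W)], H, W)
      # undo centre pad/crop
      si <- seq_len(min(d[1], H)); sj <- seq_len(min(d[2], W))
      oi <- (H - length(si)) %/% 2L; oj <- (W - length(sj)) %/% 2L
      ii <- (d[1] - length(si)) %/% 2L; jj <- (d[2] - length(sj)) %/% 2L
      full <- matrix(0L, d[1], d[2])
      full[ii + si, jj + sj] <- sl[oi + si, oj + sj]
      out[, , ks[n]] <- full
    }
    k0 <- k0 + chunk
  }
  label_volume(out, img$spacing, img$origin)
}

#' Predict ED and ES segmentations for a study
#'
#' Normalizes the study's ED frame (frame 1) and a chosen ES frame and
#' predicts both.
#'
#' @param model A trained `segnet`.
#' @param study A [cine_study()].
#' @param es_frame ES frame index; if `NULL`, every frame is predicted and
#'   the ES frame chosen by [select_es_frame()].
#' @return List with `ed`, `es` label volumes and `es_frame`.
#' @export
predict_study <- function(model, study, es_frame = NULL) {
  norm_frames <- lapply(study$frames, normalize_intensity)
  if (is.null(es_frame)) {
    labs <- lapply(norm_frames, function(f) predict_segnet(model, f))
    es_frame <- select_es_frame(labs)
    list(ed = labs[[1]], es = labs[[es_frame]], es_frame = es_frame)
  } else {
    list(ed = predict_segnet(model, norm_frames[[1]]),
         es = predict_segnet(model, norm_frames[[es_frame]]),
         es_frame = es_frame)
  }
}
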