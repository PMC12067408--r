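# Layer primitives for the 2-D segmentation network.
#
# Activations are (N*H*W) x C matrices: pixel p = i + H*(j-1) (column-major
# within a slice), samples stacked sample-major. The heavy gather/scatter
# and GEMM work happens in compiled code; per-sample index tables are cached
# here by (H, W, stride / factor).

.nn_cache <- new.env(parent = emptyenv())

# source pixel ids (0 = zero pad) for each output pixel x kernel position
conv_idx <- function(H, W, stride) {
  key <- sprintf("c%d_%d_%d", H, W, stride)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- (H + stride - 1L) %/% stride
  Wo <- (W + stride - 1L) %/% stride
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  ic <- stride * (io - 1L) + 1L
  jc <- stride * (jo - 1L) + 1L
  idx <- matrix(0L, Ho * Wo, 9L)
  k <- 0L
  for (kj in -1:1) for (ki in -1:1) {
    k <- k + 1L
    si <- ic + ki
    sj <- jc + kj
    ok <- si >= 1L & si <= H & sj >= 1L & sj <= W
    col <- integer(Ho * Wo)
    col[ok] <- si[ok] + H * (sj[ok] - 1L)
    idx[, k] <- col
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .nn_cache[[key]] <- out
  out
}

# transposed conv 2x2 stride 2: 1-based target pixel (within the 4*H*W
# output block of one sample) per kernel position
convt_maps <- function(H, W) {
  key <- sprintf("t%d_%d", H, W)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- 2L * H
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  maps <- matrix(0L, H * W, 4L)
  q <- 0L
  for (dj in 0:1) for (di in 0:1) {
    q <- q + 1L
    maps[, q] <- (2L * (i - 1L) + 1L + di) + Ho * (2L * (j - 1L) + dj)
  }
  .nn_cache[[key]] <- maps
  maps
}

# nearest-neighbour upsample source ids (per sample)
upsample_src <- function(H, W, f) {
  key <- sprintf("u%d_%d_%d", H, W, f)
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- H * f; Wo <- W * f
  ti <- rep(seq_len(Ho), times = Wo)
  tj <- rep(seq_len(Wo), each = Ho)
  src <- ((ti - 1L) %/% f + 1L) + H * ((tj - 1L) %/% f)
  .nn_cache[[key]] <- src
  src
}

nn_conv_fwd <- function(X, N, H, W, stride, Wm, keep_col = FALSE) {
  ci <- conv_idx(H, W, stride)
  cpp_conv3_fwd(X, ci$idx, N, H * W, Wm, keep_col, H, W, stride)
}

nn_conv_bwd <- function(col, dY, N, H, W, stride, Wm, Cin) {
  ci <- conv_idx(H, W, stride)
  cpp_conv3_bwd(col, dY, ci$idx, N, H * W, Wm, Cin, H, W, stride)
}

nn_convt_fwd <- function(X, N, H, W, Wm, Cout) {
  cpp_convt_fwd(X, convt_maps(H, W), N, Wm, Cout)
}

nn_convt_bwd <- function(dY, X, N, H, W, Wm, Cout) {
  cpp_convt_bwd(X, dY, convt_maps(H, W), N, Wm, Cout)
}

nn_upsample <- function(X, N, H, W, f) {
  cpp_gather_rows(X, upsample_src(H, W, f), N, H * W)
}

nn_upsample_bwd <- function(dY, N, H, W, f) {
  cpp_scatter_add_rows(dY, upsample_src(H, W, f), N, H * W)
}

nn_softmax_ce <- function(logits, labels, want_probs = FALSE) {
  cpp_softmax_ce(logits, as.integer(labels), want_probs)
}
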