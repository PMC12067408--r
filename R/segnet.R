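#' Segmentation network configuration
#'
#' A 2-D encoder-decoder fully convolutional network for per-slice 5-class
#' segmentation. The encoder holds 14 3x3 convolutional layers, each
#' followed by batch normalization and a rectified linear unit, of which 5
#' are stride-2 downsampling convolutions doubling the feature width; the
#' decoder upsamples with 2x2 stride-2 transposed convolutions (with
#' encoder skip concatenation), and the decoder features of every scale are
#' upsampled to full resolution and concatenated before a final 1x1
#' classification layer. Training minimizes mean per-pixel cross-entropy
#' with Adam.
#'
#' @param n_classes Number of classes; must be 5.
#' @param base_features Feature width at full resolution (doubles at each
#'   downsample).
#' @param n_conv_layers Total 3x3 encoder convolutions (default 14).
#' @param n_downsamples Stride-2 encoder convolutions (default 5).
#' @param epochs Training epochs (default 200).
#' @param batch_size Slices per training batch (default 2).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param seed Seed for initialization and batch shuffling.
#' @return A `net_config` object.
#' @export
net_config <- function(n_classes = 5, base_features = 16, n_conv_layers = 14,
                       n_downsamples = 5, epochs = 200, batch_size = 2,
                       learning_rate = 0.001, seed = 1L) {
  if (n_classes != 5) stop("the bi-ventricular model uses exactly 5 classes")
  extra <- n_conv_layers - 2L - 2L * n_downsamples
  if (extra < 0)
    stop("n_conv_layers must be at least 2 + 2 * n_downsamples")
  structure(list(n_classes = as.integer(n_classes),
                 base_features = as.integer(base_features),
                 n_conv_layers = as.integer(n_conv_layers),
                 n_downsamples = as.integer(n_downsamples),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "net_config")
}

# architecture description: list of layers with types conv3 / convt / head
segnet_layers <- function(cfg) {
  bf <- cfg$base_features
  nd <- cfg$n_downsamples
  extra <- cfg$n_conv_layers - 2L - 2L * nd
  layers <- list(
    list(name = "stem1", type = "conv3", cin = 1L, cout = bf, stride = 1L),
    list(name = "stem2", type = "conv3", cin = bf, cout = bf, stride = 1L))
  for (l in seq_len(nd)) {
    wprev <- bf * 2^(l - 1)
    wl <- bf * 2^l
    layers <- c(layers, list(
      list(name = sprintf("down%d", l), type = "conv3", cin = wprev,
           cout = wl, stride = 2L),
      list(name = sprintf("ref%d", l), type = "conv3", cin = wl, cout = wl,
           stride = 1L)))
  }
  for (i in seq_len(extra)) {
    w <- bf * 2^nd
    layers <- c(layers, list(
      list(name = sprintf("bott%d", i), type = "conv3", cin = w, cout = w,
           stride = 1L)))
  }
  # decoder: deepest -> full resolution, concatenating the encoder skip
  for (l in nd:1) {
    cin <- if (l == nd) bf * 2^nd else 2L * bf * 2^l
    layers <- c(layers, list(
      list(name = sprintf("up%d", l), type = "convt", cin = cin,
           cout = bf * 2^(l - 1), stride = 2L)))
  }
  cat_ch <- bf * (2^nd - 1L)
  layers <- c(layers, list(
    list(name = "head", type = "head", cin = cat_ch, cout = cfg$n_classes)))
  layers
}

#' Build a segmentation network
#'
#' Initializes parameters (He initialization, seeded) for a given in-plane
#' input size, which must be divisible by `2^n_downsamples`.
#'
#' @param cfg A [net_config()].
#' @param input_size Integer `(H, W)` of the training slices.
#' @return A `segnet` model object (environment).
#' @export
build_segnet <- function(cfg, input_size) {
  stopifnot(inherits(cfg, "net_config"), length(input_size) == 2)
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  div <- 2^cfg$n_downsamples
  if (H %% div != 0 || W %% div != 0)
    stop(sprintf("input size %dx%d is not divisible by 2^%d", H, W,
                 cfg$n_downsamples))
  if (cfg$n_downsamples > floor(log2(min(H, W))))
    stop("too many downsamples for this input size")
  layers <- segnet_layers(cfg)
  par <- list()
  with_seed(cfg$seed, {
    for (ly in layers) {
      if (ly$type == "conv3") {
        par[[paste0(ly$name, "_W")]] <-
          matrix(rnorm(9L * ly$cin * ly$cout, 0, sqrt(2 / (9 * ly$cin))),
                 9L * ly$cin, ly$cout)
      } else if (ly$type == "convt") {
        par[[paste0(ly$name, "_W")]] <-
          matrix(rnorm(ly$cin * 4L * ly$cout, 0, sqrt(2 / ly$cin)),
                 ly$cin, 4L * ly$cout)
      } else {
        par[["head_W"]] <-
          matrix(rnorm(ly$cin * ly$cout, 0, sqrt(2 / ly$cin)),
                 ly$cin, ly$cout)
        par[["head_bias"]] <- matrix(0, 1L, ly$cout)
      }
      if (ly$type %in% c("conv3", "convt")) {
        par[[paste0(ly$name, "_g")]] <- matrix(1, 1L, ly$cout)
        par[[paste0(ly$name, "_b")]] <- matrix(0, 1L, ly$cout)
      }
    }
  })
  bn_stats <- list()
  for (ly in layers) {
    if (ly$type %in% c("conv3", "convt"))
      bn_stats[[ly$name]] <- list(mean = numeric(ly$cout),
                                  var = rep(1, ly$cout), n = 0L)
  }
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$layers <- layers
  model$par <- par
  model$bn_stats <- bn_stats
  model$input_size <- c(H, W)
  model$adam <- list(m = lapply(par, function(p) array(0, dim(p))),
                     v = lapply(par, function(p) array(0, dim(p))),
                     t = 0L)
  model$loss_history <- NULL
  class(model) <- "segnet"
  model
}

get_par <- function(model, name) model$par[[name]]

#' Number of trainable parameters of a model
#' @param model A `segnet`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$par, length, 0L))
}

#' Count the 3x3 convolutional layers of a model
#'
#' Introspects the architecture and counts non-transposed, non-1x1
#' convolutional layers (and how many are stride-2 downsamples).
#'
#' @param model A `segnet`.
#' @return Named integer vector `conv3` and `downsampling`.
#' @export
count_conv_layers <- function(model) {
  types <- vapply(model$layers, `[[`, "", "type")
  strides <- vapply(model$layers, function(l)
    if (!is.null(l$stride)) l$stride else 0L, 0L)
  c(conv3 = sum(types == "conv3"),
    downsampling = sum(types == "conv3" & strides == 2L))
}

# batch-norm + ReLU block shared by conv and convT layers
bn_relu_block <- function(model, name, z, training) {
  st <- model$bn_stats[[name]]
  bn <- cpp_bn_relu_fwd(z, as.numeric(get_par(model, paste0(name, "_g"))),
                        as.numeric(get_par(model, paste0(name, "_b"))),
                        training, st$mean, st$var, 1e-5)
  if (training) {
    mom <- 0.1
    st$mean <- (1 - mom) * st$mean + mom * as.numeric(bn$mean)
    st$var <- (1 - mom) * st$var + mom * as.numeric(bn$var)
    model$bn_stats[[name]] <- st
  }
  bn
}

# forward pass; X is (N*H*W) x 1, returns logits and (optionally) caches
segnet_forward <- function(model, X, N, training = FALSE) {
  H <- model$input_size[1]; W <- model$input_size[2]
  nd <- model$cfg$n_downsamples
  bf <- model$cfg$base_features
  caches <- if (training) list() else NULL
  act <- X
  curH <- H; curW <- W
  skips <- list()          # encoder outputs per scale 0..nd
  for (ly in model$layers) {
    if (ly$type == "conv3") {
      cf <- nn_conv_fwd(act, N, curH, curW, ly$stride,
                        get_par(model, paste0(ly$name, "_W")),
                        keep_col = training)
      bn <- bn_relu_block(model, ly$name, cf$y, training)
      if (training)
        caches[[ly$name]] <- list(col = cf$col, xhat = bn$xhat,
                                  ivar = bn$ivar, relu = bn$y,
                                  H = curH, W = curW)
      act <- bn$y
      if (ly$stride == 2L) { curH <- curH %/% 2L; curW <- curW %/% 2L }
      # record encoder skip at the end of each scale
      if (ly$name == "stem2") skips[["s0"]] <- act
      if (grepl("^ref", ly$name))
        skips[[paste0("s", sub("ref", "", ly$name))]] <- act
      if (grepl("^bott", ly$name))
        skips[[paste0("s", nd)]] <- act   # deepest = last bottleneck output
    } else if (ly$type == "convt") {
      l <- as.integer(sub("up", "", ly$name))
      inp <- if (l == nd) skips[[paste0("s", nd)]]
             else cbind(act, skips[[paste0("s", l)]])
      z <- nn_convt_fwd(inp, N, curH, curW,
                        get_par(model, paste0(ly$name, "_W")), ly$cout)
      bn <- bn_relu_block(model, ly$name, z, training)
      if (training)
        caches[[ly$name]] <- list(inp = inp, xhat = bn$xhat, ivar = bn$ivar,
                                  relu = bn$y, H = curH, W = curW, l = l)
      act <- bn$y
      curH <- curH * 2L; curW <- curW * 2L
      skips[[paste0("d", l - 1)]] <- act   # decoder features per scale
    } else {
      # multi-scale 1x1 classifier over the concatenated decoder features;
      # computed per scale before upsampling (a nearest upsample is a row
      # gather, so up(d) %*% W == up(d %*% W)) -- identical result, cheaper
      headW <- get_par(model, "head_W")
      off <- 0L
      logits <- NULL
      for (l in 0:(nd - 1)) {
        ch <- bf * 2^l
        dl <- skips[[paste0("d", l)]]
        proj <- dl %*% headW[(off + 1L):(off + ch), , drop = FALSE]
        off <- off + ch
        if (l > 0) proj <- nn_upsample(proj, N, H %/% 2^l, W %/% 2^l, 2^l)
        logits <- if (is.null(logits)) proj else logits + proj
      }
      logits <- logits + rep(get_par(model, "head_bias"), each = nrow(logits))
      if (training) caches[["head"]] <- list(dec = skips[paste0("d", 0:(nd - 1))])
      return(list(logits = logits, caches = caches))
    }
  }
  stop("network has no head layer")
}

# backward pass: returns a named list of gradients aligned with model$par
segnet_backward <- function(model, caches, dlogits, N) {
  H <- model$input_size[1]; W <- model$input_size[2]
  nd <- model$cfg$n_downsamples
  bf <- model$cfg$base_features
  grads <- vector("list", length(model$par))
  names(grads) <- names(model$par)
  put <- function(name, g) grads[[name]] <<- g
  # head: per-scale adjoint of the shared 1x1 classifier
  dec <- caches[["head"]]$dec
  headW <- get_par(model, "head_W")
  dheadW <- matrix(0, nrow(headW), ncol(headW))
  put("head_bias", colSums(dlogits))
  ddec <- list()
  off <- 0L
  for (l in 0:(nd - 1)) {
    ch <- bf * 2^l
    ds <- if (l == 0) dlogits
          else nn_upsample_bwd(dlogits, N, H %/% 2^l, W %/% 2^l, 2^l)
    dl <- dec[[paste0("d", l)]]
    dheadW[(off + 1L):(off + ch), ] <- crossprod(dl, ds)
    ddec[[paste0("d", l)]] <-
      tcrossprod(ds, headW[(off + 1L):(off + ch), , drop = FALSE])
    off <- off + ch
  }
  put("head_W", dheadW)
  # decoder convT layers, shallowest first in backprop order (up1 ... upnd)
  dskip <- list()   # gradients flowing into encoder skips
  for (l in seq_len(nd)) {
    ly_name <- sprintf("up%d", l)
    ca <- caches[[ly_name]]
    ly <- NULL
    for (cand in model$layers) if (cand$name == ly_name) ly <- cand
    dy <- ddec[[paste0("d", l - 1)]]
    if (!is.null(dskip[[paste0("d", l - 1)]]))
      dy <- dy + dskip[[paste0("d", l - 1)]]
    bnb <- cpp_bn_relu_bwd(dy, ca$relu, ca$xhat, as.numeric(ca$ivar),
                           as.numeric(get_par(model, paste0(ly_name, "_g"))))
    put(paste0(ly_name, "_g"), bnb$dgamma)
    put(paste0(ly_name, "_b"), bnb$dbeta)
    tb <- nn_convt_bwd(bnb$dx, ca$inp, N, ca$H, ca$W,
                       get_par(model, paste0(ly_name, "_W")), ly$cout)
    put(paste0(ly_name, "_W"), tb$dW)
    if (l == nd) {
      dskip[[paste0("s", nd)]] <- tb$dX
    } else {
      ch_dec <- bf * 2^l
      ddec_next <- tb$dX[, seq_len(ch_dec), drop = FALSE]
      dskip_part <- tb$dX[, (ch_dec + 1L):(2L * ch_dec), drop = FALSE]
      dskip[[paste0("d", l)]] <- ddec_next
      dskip[[paste0("s", l)]] <- dskip_part
    }
  }
  # encoder, deepest first
  enc_layers <- Filter(function(l) l$type == "conv3", model$layers)
  dact <- NULL
  for (ly in rev(enc_layers)) {
    ca <- caches[[ly$name]]
    dy <- if (is.null(dact)) matrix(0, nrow(ca$relu), ncol(ca$relu)) else dact
    # add skip gradient entering at this layer's output
    skip_name <- if (ly$name == "stem2") "s0"
                 else if (grepl("^ref", ly$name))
                   paste0("s", sub("ref", "", ly$name))
                 else if (grepl("^bott", ly$name) &&
                          ly$name == sprintf("bott%d",
                            model$cfg$n_conv_layers - 2L - 2L * nd)) paste0("s", nd)
                 else NA_character_
    if (!is.na(skip_name) && !is.null(dskip[[skip_name]])) {
      dy <- dy + dskip[[skip_name]]
      dskip[[skip_name]] <- NULL
    }
    bnb <- cpp_bn_relu_bwd(dy, ca$relu, ca$xhat, as.numeric(ca$ivar),
                           as.numeric(get_par(model, paste0(ly$name, "_g"))))
    cb <- nn_conv_bwd(ca$col, bnb$dx, N, ca$H, ca$W, ly$stride,
                      get_par(model, paste0(ly$name, "_W")), ly$cin)
    put(paste0(ly$name, "_g"), bnb$dgamma)
    put(paste0(ly$name, "_b"), bnb$dbeta)
    put(paste0(ly$name, "_W"), cb$dW)
    dact <- cb$dX
  }
  grads
}
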