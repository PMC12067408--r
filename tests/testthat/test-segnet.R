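test_that("the encoder counts 14 3x3 convolutions, 5 of them strided", {
  m <- build_segnet(net_config(base_features = 4), c(64, 64))
  counts <- count_conv_layers(m)
  expect_equal(unname(counts["conv3"]), 14)
  expect_equal(unname(counts["downsampling"]), 5)
  expect_error(net_config(n_classes = 4), "5 classes")
  expect_error(build_segnet(net_config(), c(60, 60)), "not divisible")
})

test_that("forward probabilities normalize and argmax labels are unique
           and deterministic", {
  cfg <- net_config(base_features = 2, seed = 5)
  m <- build_segnet(cfg, c(32, 32))
  set.seed(1)
  X <- matrix(rnorm(32 * 32), ncol = 1)
  fw <- ratcine:::segnet_forward(m, X, 1, training = FALSE)
  p <- exp(fw$logits - apply(fw$logits, 1, max))
  p <- p / rowSums(p)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-5)
  img <- image_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), c(1, 1, 1))
  l1 <- predict_segnet(m, img)
  l2 <- predict_segnet(m, img)
  expect_identical(l1$values, l2$values)
  expect_true(all(l1$values %in% 0:4))
})

test_that("seeded initialization reproduces the initial loss exactly", {
  cfg <- net_config(base_features = 2, seed = 77)
  m1 <- build_segnet(cfg, c(32, 32))
  m2 <- build_segnet(cfg, c(32, 32))
  set.seed(3)
  X <- matrix(rnorm(2 * 32 * 32), ncol = 1)
  y <- sample(0:4, 2 * 32 * 32, replace = TRUE)
  l1 <- ratcine:::nn_softmax_ce(
    ratcine:::segnet_forward(m1, X, 2, TRUE)$logits, y)$loss
  l2 <- ratcine:::nn_softmax_ce(
    ratcine:::segnet_forward(m2, X, 2, TRUE)$logits, y)$loss
  expect_identical(l1, l2)
})

test_that("the analytic gradient matches finite differences", {
  cfg <- net_config(base_features = 2, n_conv_layers = 8,
                    n_downsamples = 3, seed = 11)
  m <- build_segnet(cfg, c(16, 16))
  set.seed(4)
  X <- matrix(rnorm(2 * 16 * 16), ncol = 1)
  y <- sample(0:4, 2 * 16 * 16, replace = TRUE)
  fw <- ratcine:::segnet_forward(m, X, 2, training = TRUE)
  sm <- ratcine:::nn_softmax_ce(fw$logits, y)
  g <- ratcine:::segnet_backward(m, fw$caches, sm$dlogits, 2)
  loss_at <- function() ratcine:::nn_softmax_ce(
    ratcine:::segnet_forward(m, X, 2, training = TRUE)$logits, y)$loss
  set.seed(5)
  for (rep in 1:6) {
    nm <- sample(names(m$par), 1)
    i <- sample(length(m$par[[nm]]), 1)
    e <- 1e-6
    th0 <- m$par[[nm]][i]
    m$par[[nm]][i] <- th0 + e
    l1 <- loss_at()
    m$par[[nm]][i] <- th0 - e
    l2 <- loss_at()
    m$par[[nm]][i] <- th0
    expect_equal((l1 - l2) / (2 * e), g[[nm]][i], tolerance = 1e-3)
  }
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  co <- generate_cohort(2, tiny_spec(), jitter = 0, seed = 23,
                        cine_frames = FALSE)
  cfg <- net_config(base_features = 2, epochs = 2, learning_rate = 0,
                    seed = 2)
  d <- dim(co[[1]]$study$frames[[1]]$values)
  m <- build_segnet(cfg, d[1:2])
  before <- lapply(m$par, function(p) p + 0)
  sl <- ratcine:::cohort_slices(co)[1:2]
  # batch-statistics mode: depends only on the (frozen) parameters
  eval_loss <- function(mod) ratcine:::batch_loss(mod, sl, TRUE)$sm$loss
  l_before <- eval_loss(m)
  m <- train_segnet(m, co, cfg)
  expect_equal(m$par, before, tolerance = 0)
  expect_identical(eval_loss(m), l_before)   # flat: nothing moved
})

test_that("a short training run reduces the loss and reproduces under the
           same seeds", {
  co <- generate_cohort(3, tiny_spec(), jitter = 0.05, seed = 29,
                        cine_frames = FALSE)
  cfg <- net_config(base_features = 4, epochs = 3, seed = 6)
  d <- dim(co[[1]]$study$frames[[1]]$values)
  m <- train_segnet(build_segnet(cfg, d[1:2]), co, cfg)
  h <- m$loss_history$train
  expect_lt(h[length(h)], h[1])
  m2 <- train_segnet(build_segnet(cfg, d[1:2]), co, cfg)
  expect_equal(m$loss_history$train, m2$loss_history$train,
               tolerance = 1e-12)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- net_config(base_features = 2, seed = 8)
  m <- build_segnet(cfg, c(32, 32))
  f <- tempfile(fileext = ".rds")
  save_segnet(m, f)
  m2 <- load_segnet(f)
  expect_equal(m$par, m2$par)
  img <- image_volume(array(runif(32 * 32 * 2), c(32, 32, 2)), c(1, 1, 1))
  expect_identical(predict_segnet(m, img)$values,
                   predict_segnet(m2, img)$values)
})
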