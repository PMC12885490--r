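test_that("analytic gradients match finite differences everywhere", {
  set.seed(42)
  cfg <- tiny_config(dropout = 0)
  dims <- mispeed:::.conformer_dims(cfg, C = 3, T = 50)
  p <- mispeed:::.conformer_init(cfg, dims)
  x <- matrix(rnorm(3 * 50), 3, 50)
  y <- 2L
  lossfn <- function(p) {
    sc <- mispeed:::.conformer_forward(p, cfg, dims, x)$scores
    -log(mispeed:::.softmax(sc)[y])
  }
  fw <- mispeed:::.conformer_forward(p, cfg, dims, x)
  pr <- mispeed:::.softmax(fw$scores)
  dsc <- pr
  dsc[y] <- dsc[y] - 1
  bw <- mispeed:::.conformer_backward(p, cfg, dims, fw$cache, dsc)
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-5 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("forward output obeys the shape and determinism contracts", {
  cfg <- tiny_config()
  m <- untrained_model(cfg, C = 3, T = 50, fs = 50)
  set.seed(1)
  dat <- array(rnorm(5 * 3 * 50), c(5, 3, 50))
  dat[2, , ] <- dat[1, , ]  # duplicated trial
  dat[5, , ] <- 0           # zero trial
  e <- manual_epochs(dat, fs = 50, channels = m$channel_names)
  sc <- conformer_forward(m, e)
  expect_equal(dim(sc), c(5, 4))
  expect_identical(sc[1, ], sc[2, ])
  expect_true(all(is.finite(sc)))
  bad <- manual_epochs(array(0, c(2, 4, 50)), fs = 50)
  expect_error(conformer_forward(m, bad), "does not match")
})

test_that("prediction is argmax with ties toward the lower class index", {
  cfg <- tiny_config()
  m <- untrained_model(cfg, C = 3, T = 50, fs = 50)
  # zero all parameters: every class score is equal -> tie -> class 0
  m$params <- lapply(m$params, function(x) x * 0)
  e <- manual_epochs(array(rnorm(3 * 3 * 50), c(3, 3, 50)), fs = 50,
                     channels = m$channel_names)
  idx <- predict_classes(m, e)
  expect_equal(unname(idx), rep(0L, 3))
  expect_equal(names(idx), rep("rest", 3))
  # non-degenerate model: predictions equal argmax of the score rows
  m2 <- untrained_model(cfg, C = 3, T = 50, fs = 50, seed = 4)
  sc <- conformer_forward(m2, e)
  expect_equal(unname(predict_classes(m2, e)),
               unname(apply(sc, 1, which.max) - 1L))
  expect_length(predict_classes(m2, e), 3)
})

test_that("permuting trials permutes predictions identically", {
  cfg <- tiny_config()
  m <- untrained_model(cfg, C = 3, T = 50, fs = 50, seed = 2)
  set.seed(8)
  e <- manual_epochs(array(rnorm(6 * 3 * 50), c(6, 3, 50)), fs = 50,
                     channels = m$channel_names)
  perm <- c(4, 1, 6, 2, 5, 3)
  ep <- epoch_subset(e, perm)
  expect_equal(unname(predict_classes(m, ep)),
               unname(predict_classes(m, e))[perm])
})

test_that("consistent channel permutation leaves the forward pass unchanged", {
  cfg <- tiny_config()
  m <- untrained_model(cfg, C = 4, T = 50, fs = 50, seed = 3,
                       channels = paste0("ch", 1:4))
  set.seed(9)
  e <- manual_epochs(array(rnorm(2 * 4 * 50), c(2, 4, 50)), fs = 50,
                     channels = m$channel_names)
  perm <- c(3, 1, 4, 2)
  m2 <- m
  m2$params$W <- m$params$W[, perm]
  e2 <- e
  e2$data <- e$data[, perm, , drop = FALSE]
  expect_equal(conformer_forward(m2, e2), conformer_forward(m, e),
               tolerance = 1e-12)
})

test_that("training is seed-reproducible and validates inputs", {
  set.seed(5)
  cfg <- tiny_config(dropout = 0.25)
  n <- 16
  dat <- array(rnorm(n * 3 * 50), c(n, 3, 50))
  labs <- rep(c("rest", "slow", "medium", "fast"), each = 4)
  e <- manual_epochs(dat, fs = 50, labels = labs)
  m1 <- train_conformer(cfg, e, e, seed = 11, max_passes = 3, batch_size = 8)
  m2 <- train_conformer(cfg, e, e, seed = 11, max_passes = 3, batch_size = 8)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
  m3 <- train_conformer(cfg, e, e, seed = 12, max_passes = 3, batch_size = 8)
  expect_false(identical(m3$training_log$train_loss, m1$training_log$train_loss))
  missing_class <- epoch_subset(e, 1:12)  # no "fast"
  expect_error(train_conformer(cfg, missing_class, e, seed = 1),
               "every class")
})

test_that("a small model overfits a tiny separable problem", {
  # two classes of trials carrying tones at different frequencies
  set.seed(6)
  fs <- 50
  n_per <- 8
  t <- (0:99) / fs
  mk <- function(f) {
    t(vapply(seq_len(n_per), function(i) {
      sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + 0.1 * rnorm(100)
    }, numeric(100)))
  }
  dat <- array(0, c(4 * n_per, 2, 100))
  freqs <- c(3, 6, 12, 18)
  for (k in 1:4) {
    block <- mk(freqs[k])
    dat[(k - 1) * n_per + seq_len(n_per), 1, ] <- block
    dat[(k - 1) * n_per + seq_len(n_per), 2, ] <- block
  }
  labs <- rep(c("rest", "slow", "medium", "fast"), each = n_per)
  e <- manual_epochs(dat, fs = fs, labels = labs)
  cfg <- conformer_config(n_temporal_filters = 8, temporal_kernel_len = 15,
                          pool_len = 20, pool_stride = 10, embed_dim = 8,
                          n_attention_layers = 1, n_heads = 2, dropout = 0.1)
  m <- train_conformer(cfg, e, e, seed = 21, max_passes = 40, patience = 40,
                       batch_size = 8)
  expect_gt(max(m$training_log$val_acc), 0.9)
})
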