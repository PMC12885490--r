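test_that("kernel spectra: delta is flat, boxcar matches the Dirichlet oracle", {
  K <- rbind(c(1, rep(0, 24)),        # delta
             rep(1, 25))              # boxcar
  ks <- kernel_frequency_response(K, fs = 250)
  expect_gte(length(ks$freq), 256)
  expect_equal(max(ks$freq), 125)
  delta_mag <- ks$magnitude[1, ]
  expect_lt(max(delta_mag) - min(delta_mag), 1e-9)
  # brute-force DFT oracle for the boxcar: |sum_n exp(-i 2 pi f n / fs)|
  oracle <- vapply(ks$freq, function(f) {
    Mod(sum(exp(-2i * pi * f * (0:24) / 250)))
  }, 0)
  expect_equal(ks$magnitude[2, ], oracle, tolerance = 1e-9)
  expect_equal(ks$magnitude[2, 1], 25 * ks$magnitude[1, 1])
})

test_that("kernel spectra are reversal-invariant and validate smoothing", {
  set.seed(2)
  k <- rnorm(25)
  m1 <- kernel_frequency_response(rbind(k), fs = 250)
  m2 <- kernel_frequency_response(rbind(rev(k)), fs = 250)
  expect_equal(m1$magnitude, m2$magnitude, tolerance = 1e-10)
  expect_error(kernel_frequency_response(rbind(k), smooth = c(4, 3), fs = 250),
               "odd")
  expect_error(kernel_frequency_response(rbind(k), smooth = c(3, 3), fs = 250),
               "greater than the order")
})

test_that("spatial patterns invert W with the stated fallbacks", {
  I4 <- diag(4)
  sp <- spatial_pattern(I4)
  expect_equal(sp$pattern_matrix, I4)
  expect_equal(sp$normalized_abs, I4)
  # orthonormal W: inverse equals transpose
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(spatial_pattern(Q)$pattern_matrix, t(Q), tolerance = 1e-9)
  # scale invariance of the normalized form
  expect_equal(spatial_pattern(2 * I4)$normalized_abs, I4)
  # non-square W: Moore-Penrose pseudo-inverse
  W <- matrix(rnorm(12), 3, 4)
  expect_equal(spatial_pattern(W)$pattern_matrix, MASS::ginv(W),
               tolerance = 1e-9)
  # ill-conditioned square W falls back with a warning
  bad <- diag(c(1, 1, 1, 1e-12))
  expect_warning(spatial_pattern(bad), "ill-conditioned")
})

test_that("the CAM combination rule is the signed weighted sum", {
  A <- matrix(seq(-3, 4), 1, 8)
  expect_equal(mispeed:::.cam_combine(A, matrix(1, 1, 8)), as.vector(A))
  A2 <- rbind(as.vector(A), as.vector(A))
  G <- rbind(rep(1, 8), rep(-1, 8))
  expect_equal(mispeed:::.cam_combine(A2, G), rep(0, 8))
  # linear in the feature maps for fixed gradients
  set.seed(5)
  B1 <- matrix(rnorm(24), 3, 8)
  B2 <- matrix(rnorm(24), 3, 8)
  Gr <- matrix(rnorm(24), 3, 8)
  expect_equal(mispeed:::.cam_combine(2 * B1 + B2, Gr),
               2 * mispeed:::.cam_combine(B1, Gr) +
                 mispeed:::.cam_combine(B2, Gr),
               tolerance = 1e-12)
})

test_that("gradcam bins a [-1, 5] s epoch into 12 half-second bins", {
  cfg <- conformer_config(n_temporal_filters = 6, temporal_kernel_len = 11,
                          pool_len = 20, pool_stride = 10, embed_dim = 6,
                          n_attention_layers = 1, n_heads = 2, dropout = 0)
  fs <- 100
  m <- untrained_model(cfg, C = 3, T = 6 * fs, fs = fs, seed = 7, t0 = -1)
  set.seed(10)
  e <- manual_epochs(array(rnorm(4 * 3 * 600), c(4, 3, 600)), fs = fs, t0 = -1,
                     labels = c("medium", "medium", "fast", "rest"),
                     channels = m$channel_names)
  cam <- gradcam(m, e, "medium")
  expect_length(cam$binned, 12)
  expect_equal(cam$bin_starts, seq(-1, 4.5, by = 0.5))
  expect_length(cam$cam, 600)
  # bin partition conservation: binned mean equals unbinned mean
  expect_equal(mean(cam$binned), mean(cam$cam), tolerance = 1e-12)
  expect_error(gradcam(m, e, "slow"), "no epochs")
  expect_error(gradcam(m, e, "walk"), "unknown class")
})

test_that("CAT reduces to the stated degenerate forms", {
  fs <- 100
  set.seed(11)
  dat <- array(rnorm(3 * 4 * 200), c(3, 4, 200))
  e <- normalize_epochs(manual_epochs(dat, fs = fs, t0 = -1,
                                      labels = rep("fast", 3)))
  cam1 <- structure(list(class_label = "fast", time = e$time_axis,
                         cam = rep(1, 200), bin_starts = numeric(0), bin_s = 0.5,
                         binned = numeric(0), n_trials = 3, fs = fs),
                    class = "cam_result")
  ct <- cat_topography(cam1, e)
  # CAM == 1: CAT is the time-mean of normalized signals, i.e. ~0
  expect_lt(max(abs(ct$values)), 1e-12)
  cam0 <- cam1
  cam0$cam <- rep(0, 200)
  expect_equal(unname(cat_topography(cam0, e)$values), rep(0, 4))
  cam_bad <- cam1
  cam_bad$cam <- rep(1, 100)
  cam_bad$time <- e$time_axis[1:100]
  expect_error(cat_topography(cam_bad, e), "misaligned")
})

test_that("CAT recovers a channel-localized discriminative source", {
  # class structure (class-specific tone frequencies) lives only on
  # channels 1-2; channels 3-6 carry pure noise
  set.seed(12)
  fs <- 100
  n <- 8
  t <- (0:199) / fs
  # tone frequencies sit away from the average-pooling sinc nulls
  # (multiples of fs / pool_len = 5 Hz), which would erase the pooled
  # phase-locked ripple the topography relies on
  freqs <- c(rest = 7, slow = 12, medium = 17, fast = 23)
  dat <- array(rnorm(4 * n * 6 * 200, sd = 0.3), c(4 * n, 6, 200))
  labs <- rep(names(freqs), each = n)
  for (i in seq_len(4 * n)) {
    tone <- sin(2 * pi * freqs[labs[i]] * t + runif(1, 0, 2 * pi))
    dat[i, 1, ] <- dat[i, 1, ] + 2 * tone
    dat[i, 2, ] <- dat[i, 2, ] + 1.5 * tone
  }
  e <- normalize_epochs(manual_epochs(dat, fs = fs, labels = labs))
  cfg <- conformer_config(n_temporal_filters = 8, temporal_kernel_len = 15,
                          pool_len = 20, pool_stride = 10, embed_dim = 8,
                          n_attention_layers = 1, n_heads = 2, dropout = 0.1)
  m <- train_conformer(cfg, e, NULL, seed = 13, max_passes = 80,
                       batch_size = 8, patience = 80)
  mass_on_source <- vapply(names(freqs), function(cl) {
    ct <- cat_topography(gradcam(m, e, cl), e, cl)
    mass <- abs(ct$values) / sum(abs(ct$values))
    sum(mass[1:2])
  }, 0)
  expect_true(all(mass_on_source > 0.4))  # uniform spread would give 1/3
  expect_gt(mean(mass_on_source), 0.5)
})
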