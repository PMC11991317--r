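test_that("adaptive ECA kernel size follows the channel-count formula", {
  expect_equal(eca_kernel_size(2), 1L)
  expect_equal(eca_kernel_size(64), 3L)
  expect_equal(eca_kernel_size(256), 5L)
  expect_equal(eca_kernel_size(1152), 5L)
  expect_equal(eca_kernel_size(1), 1L)
  expect_error(eca_kernel_size(0), ">= 1")
  ks <- eca_kernel_size(1:4096)
  expect_true(all(ks %% 2 == 1))
  expect_true(all(diff(ks) >= 0))      # nondecreasing in C
  ## direct evaluation of the formula, independently of the vectorized path
  for (C in c(1:20, 100, 500, 1000, 4096)) {
    k <- floor(abs(log2(C) / 2 + 1 / 2))
    if (k %% 2 == 0) k <- k + 1
    expect_equal(eca_kernel_size(C), max(k, 1))
  }
})

test_that("ECA rescales channels by sigmoid-activated pooled descriptors", {
  set.seed(12)
  ## zero conv weights: every channel weight is sigmoid(0) = 0.5
  x <- array(rnorm(3 * 3 * 64), c(3, 3, 64))
  expect_equal(eca(x, numeric(eca_kernel_size(64))), 0.5 * x)
  ## zero input stays zero
  expect_equal(eca(array(0, c(2, 2, 3)), rnorm(1)), array(0, c(2, 2, 3)))
  ## toy maps match the explicit-loop oracle (k = 1 and k = 3 regimes)
  x3 <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  w1 <- rnorm(eca_kernel_size(3))
  expect_equal(eca(x3, w1), oracle_eca(x3, w1), tolerance = 1e-12)
  x64 <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  w3 <- rnorm(eca_kernel_size(64))
  expect_equal(eca(x64, w3), oracle_eca(x64, w3), tolerance = 1e-12)
  ## attention preserves shape and shrinks magnitudes (weights in (0,1))
  y <- eca(x64, w3)
  expect_equal(dim(y), dim(x64))
  expect_true(all(abs(y) <= abs(x64) + 1e-12))
  ## mismatched kernel length is rejected
  expect_error(eca(x64, rnorm(5)), "kernel size")
})

test_that("CBAM fusion matches an explicit-loop oracle and bounds its attention", {
  set.seed(13)
  for (kernel in c(3, 7)) {
    C <- 4; Cr <- 2
    x <- array(rnorm(2 * 2 * C), c(2, 2, C))
    cam <- list(W1 = matrix(rnorm(Cr * C), Cr), b1 = rnorm(Cr),
                W2 = matrix(rnorm(C * Cr), C), b2 = rnorm(C))
    sam <- list(W = array(rnorm(kernel * kernel * 2), c(kernel, kernel, 2, 1)),
                b = rnorm(1))
    out <- cbam_fuse(x, cam, sam, kernel)
    expect_equal(out, oracle_cbam(x, cam, sam, kernel), tolerance = 1e-12)
    expect_equal(dim(out), dim(x))
    expect_true(all(abs(out) <= abs(x) + 1e-12))   # two (0,1) attention stages
  }
  ## zero MLP weights: channel attention is exactly 0.5 everywhere
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  cam0 <- list(W1 = matrix(0, 2, 4), b1 = numeric(2),
               W2 = matrix(0, 4, 2), b2 = numeric(4))
  sam0 <- list(W = array(0, c(7, 7, 2, 1)), b = 0)
  expect_equal(cbam_fuse(x, cam0, sam0), 0.25 * x)  # 0.5 (channel) * 0.5 (spatial)
})

test_that("MSARB reduces to the stem pathway when the multi-scale path is zeroed", {
  samples <- tiny_dataset()
  model <- tiny_model(samples)
  for (blk in c("ms7", "ms5", "ms3", "fuse"))
    model$params$msarb[[blk]][c("W", "b")] <-
      zero_params(model$params$msarb[[blk]][c("W", "b")])
  g <- samples$grid[, , , 1]
  out <- msarb(model, g)
  ## stem path computed through the same conv+BN+ReLU builder
  tape <- msdsanet:::ad_tape()
  h0 <- msdsanet:::bld_cbr(tape, msdsanet:::ad_leaf(array(g, c(dim(g), 1))),
                           msdsanet:::wrap_leaves(model$params$msarb$stem),
                           c(1, 1, 1, 1), "msarb.stem", FALSE, model$state)
  expect_equal(out, array(h0$value, dim(h0$value)[1:3]), tolerance = 1e-12)
  ## repeated inference-mode calls are identical
  expect_identical(msarb(model, g), msarb(model, g))
})

test_that("MSARB preserves the spatial plane and emits f0 feature channels", {
  cfg <- model_config(seed = 1)   # published sizes: f0 = 64
  model <- msdsanet_model(cfg, n_eeg = 32, n_periph = 2, n_time = 128)
  g <- array(rnorm(9 * 9 * 128), c(9, 9, 128))
  out <- msarb(model, g)
  expect_equal(dim(out), c(9, 9, 64))
  expect_true(all(is.finite(out)))
})

test_that("the raw-EEG stream ends in 32 feature maps and validates its input", {
  cfg <- model_config(seed = 1)
  model <- msdsanet_model(cfg, n_eeg = 32, n_periph = 2, n_time = 128)
  eeg <- matrix(rnorm(32 * 128), 32)
  out <- eeg_temporal_stream(model, eeg)
  expect_equal(dim(out), c(1, 128, 32))   # electrodes collapsed, 32 maps
  expect_error(eeg_temporal_stream(model, eeg[, 1:3]), "temporal kernel")
  ## zero weights (with identity-initialized BN) give a zero feature map
  model$params$stream1 <- lapply(model$params$stream1, function(blk) {
    blk$W <- blk$W * 0; blk$b <- blk$b * 0; blk
  })
  expect_true(all(eeg_temporal_stream(model, eeg) == 0))
})

test_that("the peripheral extractor concatenates its branch LSTM states", {
  cfg <- model_config(seed = 1)   # published sizes: LSTM 768 + 384
  model <- msdsanet_model(cfg, n_eeg = 32, n_periph = 2, n_time = 128)
  periph <- matrix(rnorm(2 * 128), 2)
  expect_length(dsanet(model, periph), 1152)

  long_only <- msdsanet_model(ablation_config("Model5", cfg), 32, 2, 128)
  expect_length(dsanet(long_only, periph), 768)
  short_only <- msdsanet_model(ablation_config("Model6", cfg), 32, 2, 128)
  expect_length(dsanet(short_only, periph), 384)

  expect_error(dsanet(model, periph[, 1:40, drop = FALSE]), "at least 50")
  ## zero weights give a zero feature vector
  zm <- model
  zm$params$dsanet <- zero_params(zm$params$dsanet)
  expect_true(all(dsanet(zm, periph) == 0))
})

test_that("the classifier outputs a normalized probability vector", {
  samples <- tiny_dataset()
  model <- tiny_model(samples)
  p <- msdsanet_forward(model, samples$eeg[, , 1], samples$grid[, , , 1],
                        samples$periph[, , 1])
  expect_length(p, 2)
  expect_true(all(p > 0))
  expect_lt(abs(sum(p) - 1), 1e-6)
  ## zero head weights: logits 0 -> uniform probabilities
  model$params$head <- zero_params(model$params$head)
  p0 <- msdsanet_forward(model, samples$eeg[, , 1], samples$grid[, , , 1],
                         samples$periph[, , 1])
  expect_equal(unname(p0), c(0.5, 0.5))
})

test_that("inference is deterministic and the full-size model accepts benchmark shapes", {
  samples <- tiny_dataset()
  model <- tiny_model(samples)
  p1 <- msdsanet_forward(model, samples$eeg[, , 1], samples$grid[, , , 1],
                         samples$periph[, , 1])
  p2 <- msdsanet_forward(model, samples$eeg[, , 1], samples$grid[, , , 1],
                         samples$periph[, , 1])
  expect_identical(p1, p2)

  cfg <- model_config(seed = 1)
  full <- msdsanet_model(cfg, n_eeg = 32, n_periph = 2, n_time = 128)
  set.seed(2)
  p <- msdsanet_forward(full, matrix(rnorm(32 * 128), 32),
                        array(rnorm(9 * 9 * 128), c(9, 9, 128)),
                        matrix(rnorm(2 * 128), 2))
  expect_lt(abs(sum(p) - 1), 1e-6)
  expect_true(all(is.finite(p)))
})

test_that("cross-entropy follows its closed form and an explicit-loop oracle", {
  ## perfect one-hot predictions give zero loss
  y <- diag(2)
  expect_equal(cross_entropy(y, y), 0, tolerance = 1e-10)
  ## single sample at probability 0.5 gives ln 2
  expect_equal(cross_entropy(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               log(2), tolerance = 1e-12)
  ## batch of 3 against a per-sample loop
  set.seed(14)
  p <- matrix(runif(6, 0.05, 0.95), 3); p <- p / rowSums(p)
  yt <- matrix(0, 3, 2); yt[cbind(1:3, sample(1:2, 3, TRUE))] <- 1
  ref <- 0
  for (i in 1:3) ref <- ref - log(p[i, which(yt[i, ] == 1)])
  expect_equal(cross_entropy(yt, p), ref / 3, tolerance = 1e-12)
  expect_error(cross_entropy(yt, p[1:2, ]), "mismatch")
})

test_that("model checkpoints round-trip with identical predictions", {
  samples <- tiny_dataset()
  model <- tiny_model(samples)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  m2 <- load_model(path)
  expect_identical(predict_proba(model, subset_samples(samples, 1:4)),
                   predict_proba(m2, subset_samples(samples, 1:4)))
  unlink(path)
})
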