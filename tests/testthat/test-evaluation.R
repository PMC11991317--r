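test_that("confusion counts match the explicit-loop oracle", {
  expect_equal(unclass(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))[c("TP", "TN", "FP", "FN")],
               list(TP = 2, TN = 2, FP = 0, FN = 0))
  y <- c(1, 0, 1, 0)
  flipped <- confusion(y, 1 - y)
  expect_equal(flipped$TP + flipped$TN, 0)
  set.seed(15)
  for (i in 1:200) {
    yt <- rbinom(20, 1, 0.5)
    yp <- rbinom(20, 1, 0.5)
    expect_equal(unclass(confusion(yt, yp))[c("TP", "FN", "FP", "TN")],
                 oracle_counts(yt, yp)[c("TP", "FN", "FP", "TN")])
  }
  expect_error(confusion(c(1, 0), c(1)), "mismatch")
})

test_that("metrics follow their defining ratios", {
  m <- metrics_from_counts(confusion(rep(c(1, 0), c(50, 50)),
                                     rep(c(1, 0, 1, 0), c(45, 5, 10, 40))))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sn, 0.90)
  expect_equal(m$sp, 0.80)
  expect_equal(m$precision, 45 / 55, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9), tolerance = 1e-12)

  perfect <- metrics_from_counts(list(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_true(all(unlist(perfect) == 1))

  expect_warning(
    expect_warning(deg <- metrics_from_counts(list(TP = 0, FN = 3, FP = 0, TN = 3)),
                   "precision undefined"),
    "F1 undefined")
  expect_true(is.nan(deg$precision))
  expect_true(is.nan(deg$f1))
  expect_error(metrics_from_counts(list(TP = 0, FN = 0, FP = 0, TN = 0)), "zero")
})

test_that("metrics agree with a per-sample loop oracle on random tables", {
  set.seed(16)
  for (i in 1:1000) {
    yt <- rbinom(30, 1, runif(1, 0.2, 0.8))
    yp <- rbinom(30, 1, runif(1, 0.2, 0.8))
    cts <- oracle_counts(yt, yp)
    m <- suppressWarnings(metrics_from_counts(confusion(yt, yp)))
    expect_equal(m$acc, mean(yt == yp))
    if (cts$TP + cts$FN > 0) expect_equal(m$sn, cts$TP / (cts$TP + cts$FN))
    if (cts$TN + cts$FP > 0) expect_equal(m$sp, cts$TN / (cts$TN + cts$FP))
  }
})

test_that("kappa coefficients match both chance models", {
  expect_equal(kappa_uniform(0.75, 2), 0.5)
  expect_equal(kappa_uniform(0.5, 2), 0)
  ## two-class uniform-chance identity: kappa = 2p - 1
  p <- seq(0, 1, by = 0.05)
  expect_equal(kappa_uniform(p, 2), 2 * p - 1)
  ## balanced table: both forms agree (0.6)
  bal <- list(TP = 40, FN = 10, FP = 10, TN = 40)
  expect_equal(kappa_marginal(bal), 0.6)
  expect_equal(kappa_uniform(0.8, 2), 0.6)
  expect_error(kappa_uniform(1.2), "\\[0, 1\\]")
  expect_error(kappa_uniform(0.5, 1), "N")
})

test_that("fold construction partitions samples reproducibly", {
  samples <- tiny_dataset()
  n <- n_samples(samples)
  f1 <- msdsanet:::stratified_folds(samples$label, 5, seed = 3)
  f2 <- msdsanet:::stratified_folds(samples$label, 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_length(f1, n)                      # disjoint folds covering all samples
  ## stratification: each fold is close to class-balanced
  for (k in 1:5) expect_lte(abs(sum(samples$label[f1 == k]) -
                                sum(f1 == k) / 2), 1)
  ## grouped folds never split a trial
  fg <- msdsanet:::grouped_folds(samples$meta, samples$label, 4, seed = 3)
  split_count <- tapply(fg, paste(samples$meta$subject_id, samples$meta$trial_id),
                        function(v) length(unique(v)))
  expect_true(all(split_count == 1))
})

test_that("SGD training is seeded, monotone on easy data, and inert at lr 0", {
  samples <- tiny_dataset()
  hyper <- hyper_config(lr = 0.05, batch_size = 8, epochs = 3, momentum = 0.9,
                        seed = 4)
  m1 <- train_model(tiny_model(samples), samples, hyper)
  m2 <- train_model(tiny_model(samples), samples, hyper)
  expect_identical(m1$model$params, m2$model$params)
  expect_lt(m1$loss[3], m1$loss[1])

  ## frozen optimizer: full-batch, dropout off, so the loss is a constant
  frozen <- train_model(tiny_model(samples, dropout = 0), samples,
                        hyper_config(lr = 0, batch_size = n_samples(samples),
                                     epochs = 2, seed = 4))
  expect_identical(frozen$model$params, tiny_model(samples, dropout = 0)$params)
  expect_equal(frozen$loss[1], frozen$loss[2], tolerance = 1e-9)
  expect_error(train_model(tiny_model(samples), subset_samples(samples, integer(0))),
               "empty")
})

test_that("cross-validation reports per-fold metrics with coherent aggregates", {
  samples <- tiny_dataset()
  rep <- run_subject_cv(samples, k = 2, cfg = model_config(preset = "tiny", dropout = 0),
                        hyper = hyper_config(lr = 0.05, batch_size = 8, epochs = 2,
                                             momentum = 0.9, seed = 1),
                        seed = 6)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_fold), 2)
  agg <- rep$aggregate$acc
  expect_gte(agg["mean"], min(rep$per_fold$acc))
  expect_lte(agg["mean"], max(rep$per_fold$acc))
  expect_error(run_subject_cv(samples, k = 1000), "per class")
})

test_that("ablation variants disable exactly the declared streams", {
  base <- model_config(preset = "tiny", seed = 2)
  expect_error(ablation_config("Model7", base), "Model1.*Model6.*full")

  full <- ablation_config("full", base)
  expect_true(full$use_stream1 && full$use_stream2 && full$use_periph)
  expect_equal(full$periph_branches, "both")

  samples <- tiny_dataset()
  idx <- 1:4
  nan_eeg <- samples; nan_eeg$eeg[] <- NaN; nan_eeg$grid[] <- NaN
  nan_per <- samples; nan_per$periph[] <- NaN

  ## Model2 (peripheral only) never touches EEG inputs
  m2 <- msdsanet_model(ablation_config("Model2", base), 6, 2, 64, 3, 3)
  expect_identical(predict_proba(m2, subset_samples(samples, idx)),
                   predict_proba(m2, subset_samples(nan_eeg, idx)))
  ## Model1 (EEG only) never touches peripheral inputs
  m1 <- msdsanet_model(ablation_config("Model1", base), 6, 2, 64, 3, 3)
  expect_identical(predict_proba(m1, subset_samples(samples, idx)),
                   predict_proba(m1, subset_samples(nan_per, idx)))
})

test_that("a noise sweep includes a bit-identical no-noise reference", {
  samples <- tiny_dataset()
  cfg <- model_config(preset = "tiny", seed = 2)
  hyper <- hyper_config(lr = 0.05, batch_size = 8, epochs = 2, momentum = 0.9,
                        seed = 1)
  reps <- noise_sweep(samples, snr_list = c(0), cfg = cfg, hyper = hyper,
                      seed = 6, test_frac = 0.25)
  expect_length(reps, 2)                     # requested levels + Inf reference
  expect_equal(names(reps)[1], "Inf")
  ref <- holdout_eval(samples, cfg, hyper, test_frac = 0.25, seed = 6)
  expect_identical(reps[["Inf"]]$per_fold$acc, ref$metrics$acc)
  expect_identical(reps[["Inf"]]$per_fold$f1, ref$metrics$f1)
})

test_that("feature embedding preserves separated clusters deterministically", {
  set.seed(17)
  feats <- rbind(matrix(rnorm(40 * 5, mean = 0), 40),
                 matrix(rnorm(40 * 5, mean = 8), 40))
  labels <- rep(0:1, each = 40)
  y1 <- embed_features(feats, perplexity = 10, seed = 2)
  y2 <- embed_features(feats, perplexity = 10, seed = 2)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(80, 2))
  ## 1-nearest-neighbour label agreement in the embedded space
  d <- as.matrix(dist(y1))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(labels[nn] == labels), 0.95)
  expect_error(embed_features(feats[1:3, ]), "at least 5")
})

test_that("evaluation reports serialize to CSV and JSON", {
  samples <- tiny_dataset()
  rep <- msdsanet:::eval_report(
    data.frame(fold = 1:2, acc = c(0.8, 0.9), kappa = c(0.6, 0.8),
               kappa_uniform = c(0.6, 0.8), f1 = c(0.8, 0.9),
               sn = c(0.8, 0.9), sp = c(0.8, 0.9)),
    dimension = "valence", seed = 1, config = model_config(preset = "tiny"))
  stem <- tempfile()
  write_report(rep, stem)
  expect_true(file.exists(paste0(stem, ".json")))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$aggregate$acc$mean, 0.85)
  folds <- read.csv(paste0(stem, "_folds.csv"))
  expect_equal(nrow(folds), 2)
  unlink(paste0(stem, c(".json", "_folds.csv")))
})
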