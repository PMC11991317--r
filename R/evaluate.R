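#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred 0/1 vectors of equal length (positive class = 1).
#' @return a `confusion_counts` list with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("length mismatch: %d true vs %d predicted labels",
          length(y_true), length(y_pred))
  if (length(y_true) < 1) stopf("empty label vectors")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 `2*P*SN/(P+SN)`. A metric
#' whose denominator is zero is reported as `NaN` with a warning.
#'
#' @param counts a [confusion()] result.
#' @return named list `acc`, `sn`, `sp`, `precision`, `f1`.
#' @export
metrics_from_counts <- function(counts) {
  total <- counts$TP + counts$FN + counts$FP + counts$TN
  if (total == 0) stopf("all confusion counts are zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NaN", what))
      return(NaN)
    }
    num / den
  }
  acc <- (counts$TP + counts$TN) / total
  sn <- safe_div(counts$TP, counts$TP + counts$FN, "sensitivity")
  sp <- safe_div(counts$TN, counts$TN + counts$FP, "specificity")
  p <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  f1 <- if (is.nan(p) || is.nan(sn) || (p + sn) == 0) {
    warning("F1 undefined; reported as NaN")
    NaN
  } else 2 * p * sn / (p + sn)
  list(acc = acc, sn = sn, sp = sp, precision = p, f1 = f1)
}

#' Kappa coefficients
#'
#' `kappa_uniform()` is the uniform-chance form `(N*p - 1)/(N - 1)` for `N`
#' classes at accuracy `p` (for two classes it reduces to `2p - 1`).
#' `kappa_marginal()` is Cohen's kappa with the chance agreement taken from
#' the row/column marginals of the confusion table; this is the default
#' reported column since printed kappas in the literature typically follow the
#' marginal form.
#'
#' @param p overall accuracy in `[0, 1]`.
#' @param N number of classes (>= 2).
#' @return kappa value in `[-1, 1]`.
#' @export
kappa_uniform <- function(p, N = 2) {
  if (any(p < 0 | p > 1)) stopf("accuracy p must lie in [0, 1]")
  if (N < 2) stopf("N must be >= 2")
  (N * p - 1) / (N - 1)
}

#' @rdname kappa_uniform
#' @param counts a [confusion()] result.
#' @export
kappa_marginal <- function(counts) {
  total <- counts$TP + counts$FN + counts$FP + counts$TN
  po <- (counts$TP + counts$TN) / total
  pe <- ((counts$TP + counts$FN) * (counts$TP + counts$FP) +
         (counts$FP + counts$TN) * (counts$FN + counts$TN)) / total^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

## all metrics for a fitted model on an evaluation set
evaluate_model <- function(model, samples) {
  pred <- predict_labels(model, samples)
  cts <- confusion(samples$label, pred)
  m <- suppressWarnings(metrics_from_counts(cts))
  c(m, list(kappa = kappa_marginal(cts),
            kappa_uniform = kappa_uniform(m$acc, model$cfg$n_classes),
            counts = cts))
}

## short config fingerprint for reports
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 4294967291
  sprintf("%05x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## stratified fold assignment (seeded): within each class, shuffled samples
## are dealt round-robin over the k folds
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

## trial-grouped fold assignment: whole trials go to one fold (avoids window
## leakage between train and test at the cost of fewer, coarser units);
## stratified over the per-trial labels
grouped_folds <- function(meta, labels, k, seed) {
  key <- paste(meta$subject_id, meta$trial_id)
  trials <- unique(key)
  trial_label <- labels[match(trials, key)]
  with_seed(seed, {
    tf <- integer(length(trials))
    for (cl in unique(trial_label)) {
      idx <- sample(which(trial_label == cl))
      tf[idx] <- rep_len(seq_len(k), length(idx))
    }
    tf[match(key, trials)]
  })
}

#' Single stratified train/test split evaluation
#'
#' Trains a fresh model on a stratified random subset and evaluates every
#' metric on the held-out remainder.
#'
#' @param samples a `sample_set`.
#' @param cfg a [model_config()].
#' @param hyper a [hyper_config()].
#' @param test_frac held-out fraction.
#' @param seed seed for the split and the model initialization.
#' @param grouped split at trial level (whole trials held out) instead of
#'   window level; avoids same-trial windows appearing on both sides of the
#'   split, so it measures generalization to unseen trials.
#' @return list with `metrics`, the trained `model`, the `loss` trace and the
#'   held-out indices `test_idx`.
#' @export
holdout_eval <- function(samples, cfg, hyper = hyper_config(preset = "reduced"),
                         test_frac = 0.3, seed = 1L, grouped = FALSE) {
  n <- n_samples(samples)
  k <- round(1 / test_frac)
  fold <- if (grouped) grouped_folds(samples$meta, samples$label, k, seed)
          else stratified_folds(samples$label, k, seed)
  test_idx <- which(fold == 1)
  train <- subset_samples(samples, setdiff(seq_len(n), test_idx))
  test <- subset_samples(samples, test_idx)
  cfg$seed <- as.integer(child_seed(seed, 1))
  model <- msdsanet_model(cfg, n_eeg = dim(samples$eeg)[1],
                          n_periph = dim(samples$periph)[1],
                          n_time = dim(samples$eeg)[2],
                          grid_h = samples$layout$grid_h,
                          grid_w = samples$layout$grid_w)
  hyper$seed <- as.integer(child_seed(seed, 2))
  fit <- train_model(model, train, hyper)
  list(metrics = evaluate_model(fit$model, test), model = fit$model,
       loss = fit$loss, test_idx = test_idx)
}

#' Subject-level k-fold cross-validation
#'
#' Window-level stratified random k-fold split (the published protocol); a
#' trial-grouped mode is available via `grouped = TRUE` — note that window
#' level splitting places windows of the same trial in train and test folds,
#' which inflates accuracy relative to trial-grouped splitting.
#'
#' @param samples one subject's `sample_set` (>= k samples per class).
#' @param k number of folds.
#' @param cfg a [model_config()].
#' @param hyper a [hyper_config()].
#' @param seed split/init seed.
#' @param grouped use trial-grouped folds.
#' @return an `eval_report`: per-fold metric data frame plus mean/sd
#'   aggregates, the affect dimension, seed, and a config fingerprint.
#' @export
run_subject_cv <- function(samples, k = 10, cfg = model_config(),
                           hyper = hyper_config(), seed = 1L,
                           grouped = FALSE) {
  if (min(table(samples$label)) < k)
    stopf("need at least k = %d samples per class", k)
  fold <- if (grouped) grouped_folds(samples$meta, samples$label, k, seed)
          else stratified_folds(samples$label, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_samples(samples, which(fold != f))
    te <- subset_samples(samples, which(fold == f))
    if (length(unique(tr$label)) < 2)
      stopf("a class is absent from the training split of fold %d", f)
    cfg$seed <- as.integer(child_seed(seed, f))
    model <- msdsanet_model(cfg, n_eeg = dim(samples$eeg)[1],
                            n_periph = dim(samples$periph)[1],
                            n_time = dim(samples$eeg)[2],
                            grid_h = samples$layout$grid_h,
                            grid_w = samples$layout$grid_w)
    hyper$seed <- as.integer(child_seed(seed, 100 + f))
    fit <- train_model(model, tr, hyper)
    m <- evaluate_model(fit$model, te)
    rows[[f]] <- data.frame(fold = f, acc = m$acc, kappa = m$kappa,
                            kappa_uniform = m$kappa_uniform, f1 = m$f1,
                            sn = m$sn, sp = m$sp)
  }
  per_fold <- do.call(rbind, rows)
  eval_report(per_fold, dimension = samples$dimension, seed = seed,
              config = cfg)
}

eval_report <- function(per_fold, dimension, seed, config, extra = list()) {
  agg <- lapply(per_fold[-1], function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(c(list(per_fold = per_fold, aggregate = agg,
                   dimension = dimension, seed = seed,
                   config_hash = config_hash(config)), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d fold(s), seed %s, config %s\n",
              x$dimension, nrow(x$per_fold), x$seed, x$config_hash))
  agg <- vapply(x$aggregate, identity, numeric(2))
  cat(sprintf("  %s: %.4f +/- %.4f\n", colnames(agg), agg["mean", ],
              ifelse(is.na(agg["sd", ]), 0, agg["sd", ])), sep = "")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-fold metrics go to `<stem>_folds.csv`, the aggregates (plus seed and
#' config fingerprint) to `<stem>.json`.
#'
#' @param report an `eval_report`.
#' @param stem output path stem (no extension).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, stem) {
  utils::write.csv(report$per_fold, paste0(stem, "_folds.csv"),
                   row.names = FALSE)
  js <- list(dimension = report$dimension, seed = report$seed,
             config_hash = report$config_hash,
             aggregate = lapply(report$aggregate, as.list))
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' Ablation configurations
#'
#' Returns the model variant that disables exactly the streams the named
#' ablation removes: `Model1` EEG only (both EEG streams, no peripheral
#' branch); `Model2` peripheral only; `Model3` raw-EEG stream + peripheral (no
#' grid/MSARB); `Model4` grid stream + peripheral (no raw series); `Model5`
#' full EEG + long-kernel peripheral branch only; `Model6` full EEG +
#' short-kernel branch only; `full` everything.
#'
#' @param name one of `"Model1"`..`"Model6"`, `"full"`.
#' @param base base [model_config()] to modify.
#' @return a `model_config`.
#' @export
ablation_config <- function(name, base = model_config()) {
  valid <- c(paste0("Model", 1:6), "full")
  if (!name %in% valid)
    stopf("unknown ablation '%s'; valid names: %s", name,
          paste(valid, collapse = ", "))
  mods <- switch(name,
    Model1 = list(use_periph = FALSE),
    Model2 = list(use_stream1 = FALSE, use_stream2 = FALSE),
    Model3 = list(use_stream2 = FALSE),
    Model4 = list(use_stream1 = FALSE),
    Model5 = list(periph_branches = "long"),
    Model6 = list(periph_branches = "short"),
    full = list())
  cfg <- utils::modifyList(base, mods)
  class(cfg) <- "model_config"
  cfg
}

#' Noise-robustness sweep
#'
#' For each signal-to-noise ratio, Gaussian noise is injected into the EEG
#' channels of both the training and the held-out data (peripheral channels
#' optionally too), the standard protocol is run, and the report collected.
#' The first entry is always the no-noise (`Inf` dB) reference.
#'
#' @param samples a `sample_set`.
#' @param snr_list SNR levels in dB (default `c(10, 0, -5)`).
#' @param cfg a [model_config()].
#' @param hyper a [hyper_config()].
#' @param seed seed (split, init, noise).
#' @param test_frac held-out fraction.
#' @param include_periph also corrupt peripheral channels.
#' @param grouped trial-grouped train/test split (see [holdout_eval()]).
#' @return list of `eval_report`s named by SNR (`"Inf"` first); each carries
#'   an `snr_db` field.
#' @export
noise_sweep <- function(samples, snr_list = c(10, 0, -5),
                        cfg = model_config(preset = "reduced"),
                        hyper = hyper_config(preset = "reduced"), seed = 1L,
                        test_frac = 0.3, include_periph = FALSE,
                        grouped = FALSE) {
  levels <- c(Inf, snr_list)
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (i in seq_along(levels)) {
    snr <- levels[i]
    noisy <- noisy_samples(samples, snr, seed = as.integer(child_seed(seed, 300 + i)),
                           include_periph = include_periph)
    hh <- holdout_eval(noisy, cfg, hyper, test_frac = test_frac, seed = seed,
                       grouped = grouped)
    m <- hh$metrics
    per_fold <- data.frame(fold = 1, acc = m$acc, kappa = m$kappa,
                           kappa_uniform = m$kappa_uniform, f1 = m$f1,
                           sn = m$sn, sp = m$sp)
    out[[i]] <- eval_report(per_fold, dimension = samples$dimension,
                            seed = seed, config = cfg,
                            extra = list(snr_db = snr))
  }
  out
}
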