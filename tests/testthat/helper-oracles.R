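## Brute-force reference implementations used as independent oracles, plus
## small shared fixtures. Oracles are written as explicit loops, deliberately
## independent of the package's array kernels.

sigm <- function(z) 1 / (1 + exp(-z))

## ECA by explicit loops: GAP per channel, zero-padded 1-D conv, sigmoid, scale
oracle_eca <- function(x, w) {
  C <- dim(x)[3]
  k <- length(w)
  p <- (k - 1) / 2
  g <- apply(x, 3, mean)
  gp <- c(rep(0, p), g, rep(0, p))
  a <- numeric(C)
  for (c in seq_len(C)) a[c] <- sigm(sum(w * gp[c:(c + k - 1)]))
  out <- x
  for (c in seq_len(C)) out[, , c] <- x[, , c] * a[c]
  out
}

## CBAM by explicit loops (channel MLP attention then spatial conv attention)
oracle_cbam <- function(x, cam, sam, kernel) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  mlp <- function(v) as.vector(cam$W2 %*% pmax(cam$W1 %*% v + cam$b1, 0) + cam$b2)
  avg <- apply(x, 3, mean)
  mx <- apply(x, 3, max)
  fca <- sigm(mlp(avg) + mlp(mx))
  hca <- x
  for (c in seq_len(C)) hca[, , c] <- x[, , c] * fca[c]
  avgmap <- apply(hca, c(1, 2), mean)
  maxmap <- apply(hca, c(1, 2), max)
  p <- (kernel - 1) / 2
  padA <- matrix(0, H + 2 * p, W + 2 * p)
  padM <- padA
  padA[p + seq_len(H), p + seq_len(W)] <- avgmap
  padM[p + seq_len(H), p + seq_len(W)] <- maxmap
  smap <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- sam$b
    for (u in seq_len(kernel)) for (v in seq_len(kernel))
      s <- s + padA[i + u - 1, j + v - 1] * sam$W[u, v, 1, 1] +
               padM[i + u - 1, j + v - 1] * sam$W[u, v, 2, 1]
    smap[i, j] <- sigm(s)
  }
  out <- hca
  for (c in seq_len(C)) out[, , c] <- hca[, , c] * smap
  out
}

## confusion counts by an explicit per-sample loop
oracle_counts <- function(y_true, y_pred) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    else if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
    else if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    else tn <- tn + 1
  }
  list(TP = tp, FN = fn, FP = fp, TN = tn)
}

## valid 0-based window starts by direct enumeration
oracle_window_starts <- function(n_samples, w_samples, s_samples) {
  starts <- c()
  k <- 0
  repeat {
    st <- k * s_samples
    if (st + w_samples > n_samples) break
    starts <- c(starts, st)
    k <- k + 1
  }
  starts
}

## hand-built trial_recording (bypasses the generator)
manual_trial <- function(signal, baseline, fs, roles = NULL, ratings = c(valence = 7),
                         rating_scale = "1-9") {
  if (is.null(rownames(signal)))
    rownames(signal) <- paste0("CH", seq_len(nrow(signal)))
  structure(list(subject_id = 1, trial_id = 1, signal = signal,
                 baseline = baseline, fs = fs,
                 channel_names = rownames(signal),
                 channel_roles = roles %||% rep("EEG", nrow(signal)),
                 ratings = ratings, rating_scale = rating_scale, state = NA),
            class = "trial_recording")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## mean periodogram power of a signal within [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi & f <= fs / 2
  mean(p[sel])
}

## small multimodal dataset for fast end-to-end runs (fs 64 keeps the LSTM
## and grid-channel sizes down); memoized across test files
.fixture_cache <- new.env()
tiny_dataset <- function(delta = 1, n_trials = 8, trial_s = 5, seed = 11) {
  key <- paste("tiny", delta, n_trials, trial_s, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- synth_config(n_subjects = 1, n_trials = n_trials, trial_s = trial_s,
                      baseline_s = 2, fs = 64, n_eeg = 6, n_periph = 2,
                      periph_kind = "ECG", rating_scale = "1-5",
                      effect_size = delta, noise_sd = 0.5, seed = seed)
  .fixture_cache[[key]] <- make_samples(generate_dataset(cfg))
  .fixture_cache[[key]]
}

## reduced-scale dataset for the parameter-recovery runs (200 windows/class)
recovery_dataset <- function(delta, seed = 11) {
  key <- paste("recovery", delta, seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- synth_config(n_subjects = 1, n_trials = 20, trial_s = 20,
                      baseline_s = 3, fs = 128, n_eeg = 14, n_periph = 2,
                      periph_kind = "ECG", rating_scale = "1-5",
                      effect_size = delta, noise_sd = 0.5, seed = seed)
  .fixture_cache[[key]] <- make_samples(generate_dataset(cfg))
  .fixture_cache[[key]]
}

tiny_model <- function(samples, seed = 3, ...) {
  cfg <- model_config(preset = "tiny", seed = seed, ...)
  msdsanet_model(cfg, n_eeg = dim(samples$eeg)[1],
                 n_periph = dim(samples$periph)[1],
                 n_time = dim(samples$eeg)[2],
                 grid_h = samples$layout$grid_h, grid_w = samples$layout$grid_w)
}

## set every array in a parameter subtree to zero
zero_params <- function(p) {
  if (is.list(p)) return(lapply(p, zero_params))
  p * 0
}

## max relative error between analytic and central-difference gradients,
## probed at a randomly perturbed parameter point (biases at exactly zero sit
## on ReLU kinks where finite differences straddle the non-differentiability)
fd_gradient_check <- function(model, batch, labels, n_each = 1, h = 1e-5,
                              seed = 42) {
  y <- matrix(0, model$cfg$n_classes, length(labels))
  y[cbind(labels + 1L, seq_along(labels))] <- 1
  set.seed(seed)
  nudge <- function(x) if (is.list(x)) lapply(x, nudge)
                       else x + stats::rnorm(length(x), sd = 0.05)
  model$params <- nudge(model$params)
  loss_at <- function(m) {
    m$state <- new.env()
    fw <- msdsanet:::forward_batch(m, batch, training = TRUE)
    msdsanet:::ad_softmax_ce(fw$tape, fw$logits, y)$value
  }
  m1 <- model
  m1$state <- new.env()
  fw <- msdsanet:::forward_batch(m1, batch, training = TRUE)
  loss <- msdsanet:::ad_softmax_ce(fw$tape, fw$logits, y)
  msdsanet:::ad_backward(fw$tape, loss)
  grads <- msdsanet:::collect_grads(fw$leaves)

  paths <- function(x, pre = character()) {
    if (!is.list(x)) return(list(pre))
    do.call(c, lapply(names(x), function(nm) {
      if (is.null(x[[nm]])) list() else paths(x[[nm]], c(pre, nm))
    }))
  }
  getp <- function(x, pth) { for (p in pth) x <- x[[p]]; x }
  setp <- function(x, pth, val) {
    if (length(pth) == 1) { x[[pth]] <- val; return(x) }
    x[[pth[1]]] <- setp(x[[pth[1]]], pth[-1], val)
    x
  }
  worst <- 0
  for (pth in paths(model$params)) {
    arr <- getp(model$params, pth)
    for (r in seq_len(n_each)) {
      j <- sample.int(length(arr), 1)
      g_an <- getp(grads, pth)[j]
      mp <- model; ap <- arr; ap[j] <- arr[j] + h
      mp$params <- setp(mp$params, pth, ap)
      mm <- model; am <- arr; am[j] <- arr[j] - h
      mm$params <- setp(mm$params, pth, am)
      g_fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      if (max(abs(g_an), abs(g_fd)) < 1e-7) next
      worst <- max(worst, abs(g_an - g_fd) / max(abs(g_an), abs(g_fd)))
    }
  }
  worst
}
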