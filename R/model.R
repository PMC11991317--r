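#' Adaptive ECA kernel size
#'
#' Efficient Channel Attention chooses the 1-D convolution kernel length from
#' the channel count: `k = floor(|log2(C)/t0 + b1/t0|)`, incremented to the
#' next integer if even, so the result is always odd and at least 1. With the
#' defaults `t0 = 2`, `b1 = 1`: C = 64 gives 3, C = 256 gives 5, C = 1152
#' gives 5.
#'
#' @param C number of channels (>= 1).
#' @param t0,b1 formula constants.
#' @return odd positive integer kernel length.
#' @export
eca_kernel_size <- function(C, t0 = 2, b1 = 1) {
  if (any(C < 1)) stopf("channel count must be >= 1")
  k <- floor(abs(log2(C) / t0 + b1 / t0))
  k <- ifelse(k %% 2 == 0, k + 1, k)
  as.integer(pmax(k, 1))
}

#' Model configuration
#'
#' All architectural hyperparameters of the network, with the published
#' values as defaults and switches that enable the ablation variants. Streams:
#' stream 1 processes the raw EEG channel x time matrix (temporal convolution
#' per electrode, a cross-channel convolution, then two 3x3 convolutions with
#' 64 and 32 feature maps); stream 2 is the multi-scale attention residual
#' block (MSARB) over the electrode-grid tensor; the peripheral branch is the
#' dual-scale conv-LSTM extractor (DSANet) with a 1x50/1x10 long-kernel branch
#' (768 LSTM units) and a 1x5/1x3 short-kernel branch (384 units), fused by
#' ECA. CBAM fuses whatever streams are enabled.
#'
#' @param f0 MSARB stem feature maps.
#' @param f_ms feature maps per multi-scale path.
#' @param kt stream-1 temporal kernel length (odd).
#' @param stream1_filters feature maps of stream 1's four convolutions
#'   (temporal, cross-channel, then the two 3x3 stages).
#' @param dsanet_filters feature maps of the two convolutions in each DSANet
#'   branch.
#' @param lstm_units `c(long, short)` LSTM cell counts.
#' @param dropout dropout probability.
#' @param fe fusion projection channels for the peripheral feature vector.
#' @param cbam_r CBAM MLP reduction ratio.
#' @param cbam_kernel CBAM spatial-attention kernel size (7 per the design).
#' @param eca_t0,eca_b1 ECA kernel-size constants.
#' @param n_classes output classes.
#' @param use_stream1,use_stream2,use_periph stream switches (ablations).
#' @param periph_branches `"both"`, `"long"` or `"short"`.
#' @param preset `"full"` (published sizes), `"reduced"` (small sizes for
#'   synthetic-data experiments) or `"tiny"` (gradient-check sizes); explicit
#'   arguments override the preset.
#' @param seed seed for weight initialization.
#' @return a `model_config` list.
#' @export
model_config <- function(f0 = 64, f_ms = 64, kt = 5,
                         stream1_filters = c(64, 64, 64, 32),
                         dsanet_filters = c(32, 64),
                         lstm_units = c(768, 384),
                         dropout = 0.5, fe = 16, cbam_r = 8, cbam_kernel = 7,
                         eca_t0 = 2, eca_b1 = 1, n_classes = 2,
                         use_stream1 = TRUE, use_stream2 = TRUE,
                         use_periph = TRUE,
                         periph_branches = c("both", "long", "short"),
                         preset = NULL, seed = 1L) {
  periph_branches <- match.arg(periph_branches)
  cfg <- as.list(environment())
  cfg$preset <- NULL
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "reduced", "tiny"))
    override <- switch(preset,
      full = list(),
      reduced = list(f0 = 8, f_ms = 8, stream1_filters = c(8, 8, 8, 8),
                    dsanet_filters = c(8, 8), lstm_units = c(32, 16),
                    fe = 4, cbam_r = 4),
      tiny = list(f0 = 4, f_ms = 3, stream1_filters = c(3, 3, 3, 3),
                  dsanet_filters = c(2, 2), lstm_units = c(8, 4),
                  fe = 2, cbam_r = 2))
    called <- names(match.call())[-1]
    override <- override[setdiff(names(override), called)]
    cfg <- utils::modifyList(cfg, override)
  }
  if (cfg$kt %% 2 != 1) stopf("kt must be odd for a centred receptive field")
  if (any(cfg$lstm_units < 1) || any(cfg$dsanet_filters < 1))
    stopf("unit counts must be positive")
  structure(cfg, class = "model_config")
}

## ---- parameter initialization ----------------------------------------------

## seeded uniform fan-in initialization
w_init <- function(dims, fan_in) {
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

conv_block <- function(kh, kw, cin, f, bn = TRUE) {
  p <- list(W = w_init(c(kh, kw, cin, f), kh * kw * cin), b = numeric(f))
  if (bn) { p$gamma <- rep(1, f); p$beta <- numeric(f) }
  p
}

lstm_block <- function(f, u) {
  p <- list(Wx = w_init(c(4 * u, f), f), Wh = w_init(c(4 * u, u), u),
            b = numeric(4 * u))
  p$b[(u + 1):(2 * u)] <- 1    # forget-gate bias
  p
}

#' Construct an untrained model
#'
#' Initializes all weights (seeded uniform fan-in scheme) for the given input
#' geometry and returns the model object used by [train_model()],
#' [predict_labels()] and the block-level forward functions.
#'
#' @param cfg a [model_config()].
#' @param n_eeg EEG channel count.
#' @param n_periph peripheral channel count.
#' @param n_time samples per window (e.g. 128 for 1 s at 128 Hz).
#' @param grid_h,grid_w electrode-grid dimensions.
#' @return a `msdsanet_model` object (config, params, BN running-stat state).
#' @export
msdsanet_model <- function(cfg, n_eeg = 32, n_periph = 2, n_time = 128,
                           grid_h = 9, grid_w = 9) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$use_periph && n_periph < 1)
    stopf("peripheral stream enabled but n_periph = %d", n_periph)
  with_seed(cfg$seed, {
    params <- list()
    if (cfg$use_stream2) {
      params$msarb <- list(
        stem = conv_block(3, 3, n_time, cfg$f0),
        ms7 = conv_block(7, 7, cfg$f0, cfg$f_ms),
        ms5 = conv_block(5, 5, cfg$f0, cfg$f_ms),
        ms3 = conv_block(3, 3, cfg$f0, cfg$f_ms),
        fuse = conv_block(1, 1, 3 * cfg$f_ms, cfg$f0),
        eca_w = w_init(eca_kernel_size(cfg$f0, cfg$eca_t0, cfg$eca_b1),
                       cfg$f0))
    }
    if (cfg$use_stream1) {
      fl <- cfg$stream1_filters
      params$stream1 <- list(
        conv_t = conv_block(1, cfg$kt, 1, fl[1]),
        conv_c = conv_block(n_eeg, 1, fl[1], fl[2]),
        conv1 = conv_block(3, 3, fl[2], fl[3]),
        conv2 = conv_block(3, 3, fl[3], fl[4]))
    }
    if (cfg$use_periph) {
      df <- cfg$dsanet_filters
      ds <- list()
      if (cfg$periph_branches %in% c("both", "long"))
        ds$long <- c(list(conv1 = conv_block(1, 50, n_periph, df[1], bn = FALSE),
                          conv2 = conv_block(1, 10, df[1], df[2], bn = FALSE)),
                     lstm_block(df[2], cfg$lstm_units[1]))
      if (cfg$periph_branches %in% c("both", "short"))
        ds$short <- c(list(conv1 = conv_block(1, 5, n_periph, df[1], bn = FALSE),
                           conv2 = conv_block(1, 3, df[1], df[2], bn = FALSE)),
                      lstm_block(df[2], cfg$lstm_units[2]))
      d_eog <- sum(cfg$lstm_units[
        switch(cfg$periph_branches, both = 1:2, long = 1, short = 2)])
      ds$eca_w <- w_init(eca_kernel_size(d_eog, cfg$eca_t0, cfg$eca_b1), d_eog)
      params$dsanet <- ds
    }
    c_all <- 0L
    if (cfg$use_stream1) c_all <- c_all + cfg$stream1_filters[4]
    if (cfg$use_stream2) c_all <- c_all + cfg$f0
    if (cfg$use_periph) c_all <- c_all + cfg$fe
    cr <- max(1L, c_all %/% cfg$cbam_r)
    d_eog <- if (cfg$use_periph) sum(cfg$lstm_units[
      switch(cfg$periph_branches, both = 1:2, long = 1, short = 2)]) else 0L
    params$fusion <- list(
      proj = if (cfg$use_periph)
        list(W = w_init(c(cfg$fe * grid_h * grid_w, d_eog), d_eog),
             b = numeric(cfg$fe * grid_h * grid_w)) else NULL,
      cam = list(W1 = w_init(c(cr, c_all), c_all), b1 = numeric(cr),
                 W2 = w_init(c(c_all, cr), cr), b2 = numeric(c_all)),
      sam = conv_block(cfg$cbam_kernel, cfg$cbam_kernel, 2, 1, bn = FALSE))
    params$head <- list(
      W = w_init(c(cfg$n_classes, c_all * grid_h * grid_w),
                 c_all * grid_h * grid_w),
      b = numeric(cfg$n_classes))

    structure(list(cfg = cfg, params = params, state = new.env(),
                   n_eeg = n_eeg, n_periph = n_periph, n_time = n_time,
                   grid_h = grid_h, grid_w = grid_w, c_all = c_all),
              class = "msdsanet_model")
  })
}

#' @export
print.msdsanet_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf("<msdsanet_model> %d EEG + %d peripheral channels, %d samples/window; %d fused channels on %dx%d grid; %d parameters\n",
              x$n_eeg, x$n_periph, x$n_time, x$c_all, x$grid_h, x$grid_w, np))
  cat("  streams:",
      paste(c(if (x$cfg$use_stream1) "EEG-raw", if (x$cfg$use_stream2) "EEG-grid",
              if (x$cfg$use_periph) paste0("peripheral(", x$cfg$periph_branches, ")")),
            collapse = " + "), "\n")
  invisible(x)
}

## convert params (nested list of arrays) into leaf nodes of the same shape
wrap_leaves <- function(params) {
  if (is.list(params)) return(lapply(params, wrap_leaves))
  if (is.null(params)) return(NULL)
  ad_leaf(params)
}

collect_grads <- function(leaves) {
  if (is.environment(leaves)) return(leaves$grad %||% array(0, dim(leaves$value) %||% length(leaves$value)))
  if (is.list(leaves)) return(lapply(leaves, collect_grads))
  NULL
}

## ---- forward builders -------------------------------------------------------

## move (1, L, F, N) spatial map into sequence form (F, L, N)
ad_spatial_to_seq <- function(tape, x) {
  d <- dim(x$value)
  y <- aperm(array(x$value, c(d[2], d[3], d[4])), c(2, 1, 3))
  ad_node(tape, y, list(x), function(nd) {
    g <- aperm(nd$grad, c(2, 1, 3))
    dim(g) <- d
    list(g)
  })
}

## conv + BN + ReLU
bld_cbr <- function(tape, x, blk, pad, key, training, state) {
  h <- ad_conv2d(tape, x, blk$W, blk$b, pad = pad)
  h <- ad_bn(tape, h, blk$gamma, blk$beta, state, key, training)
  ad_relu(tape, h)
}

## ECA over the channels of a spatial map
bld_eca_sp <- function(tape, x, w, t0, b1) {
  C <- dim(x$value)[3]
  k <- eca_kernel_size(C, t0, b1)
  if (length(w$value) != k)
    stopf("ECA weight length %d does not match adaptive kernel size %d for C = %d",
          length(w$value), k, C)
  g <- ad_gap_sp(tape, x)
  a <- ad_sigmoid(tape, ad_conv1d_channels(tape, g, w))
  ad_scale_ch(tape, x, a)
}

## ECA over a feature vector (each "channel" has length 1, so pooling is the
## identity and the 1-D convolution runs along the feature axis)
bld_eca_vec <- function(tape, x, w, t0, b1) {
  C <- nrow(x$value)
  k <- eca_kernel_size(C, t0, b1)
  if (length(w$value) != k)
    stopf("ECA weight length %d does not match adaptive kernel size %d for C = %d",
          length(w$value), k, C)
  a <- ad_sigmoid(tape, ad_conv1d_channels(tape, x, w))
  ad_mul(tape, x, a)
}

## multi-scale attention residual block over the grid tensor
bld_msarb <- function(tape, x, L, cfg, training, state) {
  h0 <- bld_cbr(tape, x, L$stem, c(1, 1, 1, 1), "msarb.stem", training, state)
  h7 <- bld_cbr(tape, h0, L$ms7, c(3, 3, 3, 3), "msarb.ms7", training, state)
  h5 <- bld_cbr(tape, h0, L$ms5, c(2, 2, 2, 2), "msarb.ms5", training, state)
  h3 <- bld_cbr(tape, h0, L$ms3, c(1, 1, 1, 1), "msarb.ms3", training, state)
  hcat <- ad_concat_ch(tape, list(h7, h5, h3))
  hcat1 <- bld_cbr(tape, hcat, L$fuse, c(0, 0, 0, 0), "msarb.fuse",
                   training, state)
  heca <- bld_eca_sp(tape, hcat1, L$eca_w, cfg$eca_t0, cfg$eca_b1)
  ad_add(tape, heca, h0)
}

## raw EEG stream: per-electrode temporal conv, cross-channel conv, two 3x3
## conv stages, dropout after the final activation
bld_stream1 <- function(tape, x, L, cfg, training, state) {
  ps <- pad_same(cfg$kt)
  h <- bld_cbr(tape, x, L$conv_t, c(0, 0, ps), "s1.t", training, state)
  h <- bld_cbr(tape, h, L$conv_c, c(0, 0, 0, 0), "s1.c", training, state)
  h <- bld_cbr(tape, h, L$conv1, c(1, 1, 1, 1), "s1.c1", training, state)
  h <- bld_cbr(tape, h, L$conv2, c(1, 1, 1, 1), "s1.c2", training, state)
  ad_dropout(tape, h, cfg$dropout, training)
}

## standard LSTM over a (F, L, N) sequence; returns the final hidden state
bld_lstm <- function(tape, x, Wx, Wh, b, U) {
  ad_lstm(tape, x, Wx, Wh, b, U)
}

bld_dsa_branch <- function(tape, x, L, k1, k2, U) {
  h <- ad_relu(tape, ad_conv2d(tape, x, L$conv1, L$conv1b,
                               pad = c(0, 0, pad_same(k1))))
  h <- ad_relu(tape, ad_conv2d(tape, h, L$conv2, L$conv2b,
                               pad = c(0, 0, pad_same(k2))))
  bld_lstm(tape, ad_spatial_to_seq(tape, h), L$Wx, L$Wh, L$b, U)
}

## dual-scale conv-LSTM peripheral extractor with ECA fusion
bld_dsanet <- function(tape, x, L, cfg, training, state) {
  Tn <- dim(x$value)[2]
  if (Tn < 50)
    stopf("peripheral window has %d samples; the 1x50 long-kernel branch needs at least 50", Tn)
  hs <- list()
  if (cfg$periph_branches %in% c("both", "long"))
    hs$long <- bld_dsa_branch(tape, x,
      list(conv1 = L$long$conv1$W, conv1b = L$long$conv1$b,
           conv2 = L$long$conv2$W, conv2b = L$long$conv2$b,
           Wx = L$long$Wx, Wh = L$long$Wh, b = L$long$b),
      50, 10, cfg$lstm_units[1])
  if (cfg$periph_branches %in% c("both", "short"))
    hs$short <- bld_dsa_branch(tape, x,
      list(conv1 = L$short$conv1$W, conv1b = L$short$conv1$b,
           conv2 = L$short$conv2$W, conv2b = L$short$conv2$b,
           Wx = L$short$Wx, Wh = L$short$Wh, b = L$short$b),
      5, 3, cfg$lstm_units[2])
  hcat <- if (length(hs) == 2) ad_concat_rows(tape, unname(hs)) else hs[[1]]
  bld_eca_vec(tape, hcat, L$eca_w, cfg$eca_t0, cfg$eca_b1)
}

## CBAM fusion over whichever streams are present
bld_fusion <- function(tape, parts, L, cfg, training, state, grid_h, grid_w) {
  maps <- list()
  if (!is.null(parts$stream1))
    maps$stream1 <- ad_adaptive_avgpool(tape, parts$stream1, grid_h, grid_w)
  if (!is.null(parts$stream2)) maps$stream2 <- parts$stream2
  if (!is.null(parts$periph)) {
    pr <- ad_dense(tape, parts$periph, L$proj$W, L$proj$b)
    maps$periph <- ad_reshape(tape, pr, c(grid_h, grid_w, cfg$fe,
                                          ncol(parts$periph$value)))
  }
  hall <- if (length(maps) > 1) ad_concat_ch(tape, unname(maps)) else maps[[1]]
  bld_cbam(tape, hall, L$cam, L$sam, cfg$cbam_kernel)
}

## CBAM: channel attention (shared 2-layer MLP over average- and max-pooled
## channel descriptors) followed by spatial attention (kxk conv over the
## [avg; max] channel-pooled maps); shape-preserving
bld_cbam <- function(tape, hall, Lcam, Lsam, kernel) {
  mlp <- function(v) ad_dense(tape, ad_relu(tape, ad_dense(tape, v, Lcam$W1, Lcam$b1)),
                              Lcam$W2, Lcam$b2)
  fca <- ad_sigmoid(tape, ad_add(tape, mlp(ad_gap_sp(tape, hall)),
                                 mlp(ad_gmp_sp(tape, hall))))
  hca <- ad_scale_ch(tape, hall, fca)
  pooled <- ad_concat_ch(tape, list(ad_chmean(tape, hca), ad_chmax(tape, hca)))
  ps <- pad_same(kernel)
  fsa <- ad_sigmoid(tape, ad_conv2d(tape, pooled, Lsam$W, Lsam$b,
                                    pad = c(ps, ps)))
  ad_scale_sp(tape, hca, fsa)
}

#' CBAM attention fusion on a single feature map
#'
#' Applies the convolutional block attention module (channel attention from a
#' shared MLP over average- and max-pooled descriptors, then spatial attention
#' from a convolution over the channel-pooled maps) to a spatial feature map,
#' using explicit weights. Output shape equals input shape.
#'
#' @param x array `H x W x C`.
#' @param cam list with `W1` (`Cr x C`), `b1`, `W2` (`C x Cr`), `b2`.
#' @param sam list with `W` (`k x k x 2 x 1`) and `b` (length 1).
#' @param kernel spatial-attention kernel size (default 7).
#' @return array of the same shape as `x`.
#' @export
cbam_fuse <- function(x, cam, sam, kernel = 7) {
  stopifnot(length(dim(x)) == 3)
  tape <- ad_tape()
  xn <- ad_leaf(array(x, c(dim(x), 1)))
  out <- bld_cbam(tape, xn, wrap_leaves(cam), wrap_leaves(sam), kernel)
  array(out$value, dim(x))
}

bld_head <- function(tape, x, L, cfg, training) {
  flat <- ad_reshape(tape, x, c(prod(dim(x$value)[1:3]), dim(x$value)[4]))
  flat <- ad_dropout(tape, flat, cfg$dropout, training)
  ad_dense(tape, flat, L$W, L$b)
}

## full forward pass on a batch; returns logits node plus the leaves used
forward_batch <- function(model, batch, training = FALSE, tape = NULL) {
  cfg <- model$cfg
  if (is.null(tape)) tape <- ad_tape()
  leaves <- wrap_leaves(model$params)
  parts <- list()
  if (cfg$use_stream1) {
    v <- batch$eeg
    dim(v) <- c(dim(batch$eeg)[1], dim(batch$eeg)[2], 1, dim(batch$eeg)[3])
    parts$stream1 <- bld_stream1(tape, ad_leaf(v), leaves$stream1, cfg,
                                 training, model$state)
  }
  if (cfg$use_stream2)
    parts$stream2 <- bld_msarb(tape, ad_leaf(batch$grid), leaves$msarb, cfg,
                               training, model$state)
  if (cfg$use_periph) {
    v <- aperm(batch$periph, c(2, 1, 3))
    dim(v) <- c(1, dim(v)[1], dim(v)[2], dim(v)[3])
    parts$periph <- bld_dsanet(tape, ad_leaf(v), leaves$dsanet, cfg,
                               training, model$state)
  }
  fused <- bld_fusion(tape, parts, leaves$fusion, cfg, training, model$state,
                      model$grid_h, model$grid_w)
  logits <- bld_head(tape, fused, leaves$head, cfg, training)
  list(tape = tape, leaves = leaves, logits = logits, fused = fused)
}

## assemble the arrays forward_batch() consumes from a sample_set
sample_batch <- function(samples, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_samples(samples))
  list(eeg = samples$eeg[, , idx, drop = FALSE],
       grid = samples$grid[, , , idx, drop = FALSE],
       periph = samples$periph[, , idx, drop = FALSE])
}

## ---- user-facing forward functions ------------------------------------------

#' Efficient channel attention on a feature map
#'
#' Applies ECA to a single spatial feature map: global average pooling per
#' channel, a 1-D convolution of adaptive kernel size across channels, a
#' sigmoid, and per-channel rescaling of the input. Output shape equals input
#' shape and all attention weights lie in (0, 1).
#'
#' @param x array `H x W x C`.
#' @param weights numeric vector of length [eca_kernel_size()]`(C)`.
#' @param t0,b1 kernel-size constants.
#' @return array of the same shape as `x`.
#' @export
eca <- function(x, weights, t0 = 2, b1 = 1) {
  stopifnot(length(dim(x)) == 3)
  tape <- ad_tape()
  xn <- ad_leaf(array(x, c(dim(x), 1)))
  out <- bld_eca_sp(tape, xn, ad_leaf(weights), t0, b1)
  array(out$value, dim(x))
}

#' Block-level forward passes (single sample, inference mode)
#'
#' Run one component of a model on a single sample: `msarb()` on a grid tensor
#' `H x W x T`, `eeg_temporal_stream()` on a `C x T` EEG matrix, `dsanet()` on
#' a `P x T` peripheral matrix, returning that block's feature output.
#'
#' @param model a [msdsanet_model()].
#' @param grid,eeg,periph single-sample inputs.
#' @return `msarb`: array `H x W x f0`; `eeg_temporal_stream`: array
#'   `1 x T x F`; `dsanet`: numeric feature vector (length = sum of active
#'   LSTM units).
#' @name blocks
NULL

#' @rdname blocks
#' @export
msarb <- function(model, grid) {
  stopifnot(inherits(model, "msdsanet_model"), !is.null(model$params$msarb))
  tape <- ad_tape()
  xn <- ad_leaf(array(grid, c(dim(grid), 1)))
  out <- bld_msarb(tape, xn, wrap_leaves(model$params$msarb), model$cfg,
                   FALSE, model$state)
  array(out$value, dim(out$value)[1:3])
}

#' @rdname blocks
#' @export
eeg_temporal_stream <- function(model, eeg) {
  stopifnot(inherits(model, "msdsanet_model"), !is.null(model$params$stream1))
  if (ncol(eeg) < model$cfg$kt)
    stopf("window of %d samples shorter than temporal kernel (%d)",
          ncol(eeg), model$cfg$kt)
  tape <- ad_tape()
  xn <- ad_leaf(array(eeg, c(dim(eeg), 1, 1)))
  out <- bld_stream1(tape, xn, wrap_leaves(model$params$stream1), model$cfg,
                     FALSE, model$state)
  array(out$value, dim(out$value)[1:3])
}

#' @rdname blocks
#' @export
dsanet <- function(model, periph) {
  stopifnot(inherits(model, "msdsanet_model"), !is.null(model$params$dsanet))
  tape <- ad_tape()
  v <- t(periph)
  dim(v) <- c(1, nrow(v), ncol(v), 1)
  out <- bld_dsanet(tape, ad_leaf(v), wrap_leaves(model$params$dsanet),
                    model$cfg, FALSE, model$state)
  drop(out$value)
}

#' Full forward pass on one sample
#'
#' @param model a [msdsanet_model()].
#' @param eeg `C x T` EEG matrix.
#' @param grid `H x W x T` grid tensor.
#' @param periph `P x T` peripheral matrix.
#' @return probability vector over the classes (sums to 1).
#' @export
msdsanet_forward <- function(model, eeg, grid, periph) {
  batch <- list(eeg = array(eeg, c(dim(eeg), 1)),
                grid = array(grid, c(dim(grid), 1)),
                periph = array(periph, c(dim(periph), 1)))
  fw <- forward_batch(model, batch, training = FALSE)
  drop(softmax_cols(fw$logits$value))
}

#' Class probabilities / labels for a sample set
#'
#' @param model a trained [msdsanet_model()].
#' @param samples a `sample_set`.
#' @param batch_size forward batch size.
#' @return `predict_proba`: `n x n_classes` matrix; `predict_labels`: 0/1
#'   vector (argmax class).
#' @export
predict_proba <- function(model, samples, batch_size = 64) {
  n <- n_samples(samples)
  out <- matrix(0, n, model$cfg$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    fw <- forward_batch(model, sample_batch(samples, idx), training = FALSE)
    out[idx, ] <- t(softmax_cols(fw$logits$value))
  }
  out
}

#' @rdname predict_proba
#' @export
predict_labels <- function(model, samples, batch_size = 64) {
  max.col(predict_proba(model, samples, batch_size)) - 1L
}

#' Fused feature vectors (CBAM output, pre-classifier)
#'
#' Extracts the flattened multimodal fusion features for each sample, e.g. for
#' t-SNE visualization with [embed_features()].
#'
#' @inheritParams predict_proba
#' @return `n x d` feature matrix.
#' @export
model_features <- function(model, samples, batch_size = 64) {
  n <- n_samples(samples)
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    fw <- forward_batch(model, sample_batch(samples, idx), training = FALSE)
    v <- fw$fused$value
    m <- t(matrix(v, prod(dim(v)[1:3]), dim(v)[4]))
    out <- rbind(out, m)
  }
  out
}

#' Save / load a model checkpoint (config embedded)
#' @param model a `msdsanet_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  model$state <- as.list(model$state)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  model$state <- list2env(model$state)
  model
}
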