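#' Electrode layout: mapping channels onto a 2-D scalp grid
#'
#' A layout assigns each electrode a cell of an `grid_h` x `grid_w` grid that
#' preserves the topological neighbour relations of the international 10-20
#' placement system, so 2-D convolutions over the grid span physically
#' adjacent electrodes. The placement must be injective (one electrode per
#' cell) and within bounds.
#'
#' @param placement data frame with columns `name`, `row`, `col` (1-based).
#' @param grid_h,grid_w grid dimensions.
#' @return an `electrode_layout` object.
#' @export
electrode_layout <- function(placement, grid_h = 9, grid_w = 9) {
  stopifnot(is.data.frame(placement),
            all(c("name", "row", "col") %in% names(placement)))
  if (any(placement$row < 1 | placement$row > grid_h |
          placement$col < 1 | placement$col > grid_w))
    stopf("placement contains cells outside the %dx%d grid", grid_h, grid_w)
  key <- paste(placement$row, placement$col)
  if (anyDuplicated(key))
    stopf("placement is not injective: cell(s) %s shared by several electrodes",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  if (anyDuplicated(placement$name))
    stopf("duplicate electrode name(s) in placement")
  structure(list(grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
                 placement = placement[, c("name", "row", "col")]),
            class = "electrode_layout")
}

#' Built-in 9x9 layouts for the 32-channel and 14-channel montages
#'
#' @param name `"deap32"` (32 electrodes) or `"dreamer14"` (14 electrodes), or
#'   `"auto"` to pick by channel count / fall back to a row-major packing for
#'   nonstandard montages.
#' @param channel_names channel names, required for `"auto"` fallback packing.
#' @return an `electrode_layout`.
#' @export
default_layout <- function(name = c("deap32", "dreamer14", "auto"),
                           channel_names = NULL) {
  name <- match.arg(name)
  if (name == "auto") {
    n <- length(channel_names)
    if (n == 32) return(default_layout("deap32"))
    if (n == 14) return(default_layout("dreamer14"))
    side <- ceiling(sqrt(n))
    placement <- data.frame(name = channel_names,
                            row = ((seq_len(n) - 1) %/% side) + 1L,
                            col = ((seq_len(n) - 1) %% side) + 1L)
    return(electrode_layout(placement, side, side))
  }
  file <- switch(name, deap32 = "layout_deap_9x9.csv",
                 dreamer14 = "layout_dreamer_9x9.csv")
  path <- system.file("extdata", file, package = "msdsanet")
  electrode_layout(utils::read.csv(path), 9, 9)
}

#' Baseline correction: subtract the mean of 1-s baseline segment means
#'
#' For every channel, the resting baseline is cut into consecutive full 1-s
#' segments; the mean of the segment means is subtracted from every stimulus
#' sample of that channel. Recordings without a baseline pass through
#' unchanged.
#'
#' @param trial a `trial_recording`.
#' @param strict if `TRUE`, a non-empty baseline shorter than one second is an
#'   error; otherwise the trial is returned unchanged with a warning.
#' @return the corrected `trial_recording`.
#' @export
subtract_baseline <- function(trial, strict = FALSE) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(trial$baseline)) return(trial)
  nb <- ncol(trial$baseline)
  if (nb == 0) return(trial)
  seg_len <- round(trial$fs)
  n_seg <- nb %/% seg_len
  if (n_seg < 1) {
    if (strict) stopf("baseline (%d samples) shorter than one 1-s segment (%d samples)",
                      nb, seg_len)
    warning("baseline shorter than one second; trial returned unchanged")
    return(trial)
  }
  seg_means <- vapply(seq_len(n_seg), function(k) {
    rowMeans(trial$baseline[, ((k - 1) * seg_len + 1):(k * seg_len), drop = FALSE])
  }, numeric(nrow(trial$baseline)))
  ref <- rowMeans(matrix(seg_means, nrow = nrow(trial$baseline)))
  trial$signal <- trial$signal - ref
  trial
}

#' Sliding-window segmentation of a trial
#'
#' Splits the stimulus signal into fixed-length windows. With the defaults
#' (1-s window, 1-s stride) the windows are non-overlapping, so a 60-s trial
#' yields 60 windows. Windows are half-open sample ranges
#' `[k*stride*fs, k*stride*fs + window*fs)` with 0-based start indices; a
#' trial shorter than one window yields an empty list.
#'
#' @param trial a `trial_recording`.
#' @param window_s,stride_s window length and stride in seconds.
#' @return list of channel x sample matrices, each with attributes
#'   `window_index` (0-based) and `fs`.
#' @export
segment_trial <- function(trial, window_s = 1, stride_s = 1) {
  stopifnot(inherits(trial, "trial_recording"))
  if (window_s <= 0 || stride_s <= 0) stopf("window_s and stride_s must be > 0")
  fs <- trial$fs
  w <- round(window_s * fs)
  s <- round(stride_s * fs)
  n <- ncol(trial$signal)
  n_win <- if (n < w) 0L else (n - w) %/% s + 1L
  lapply(seq_len(n_win), function(k) {
    x <- trial$signal[, ((k - 1) * s + 1):((k - 1) * s + w), drop = FALSE]
    attr(x, "window_index") <- k - 1L
    attr(x, "fs") <- fs
    x
  })
}

#' Default binarization threshold for a rating scale
#' @param rating_scale `"1-9"` or `"1-5"`.
#' @return the threshold (5 or 3).
#' @export
default_threshold <- function(rating_scale) {
  unname(rating_bounds(rating_scale)["threshold"])
}

#' Binarize a continuous affect rating
#'
#' A score strictly greater than the threshold maps to the high class (1);
#' a score equal to or below it maps to the low class (0). The conventional
#' thresholds are 5 on a 1-9 scale and 3 on a 1-5 scale.
#'
#' @param score numeric rating(s).
#' @param threshold decision threshold.
#' @param scale optional `c(lo, hi)` bounds; scores outside them are an error.
#' @return integer 0/1 vector.
#' @export
binarize_label <- function(score, threshold, scale = NULL) {
  if (!is.null(scale) && (any(score < scale[1]) || any(score > scale[2])))
    stopf("score outside the declared scale [%g, %g]", scale[1], scale[2])
  as.integer(score > threshold)
}

#' Map EEG channels onto the spatial grid
#'
#' Produces the 3-D spatiotemporal tensor (grid row x grid column x time) used
#' by the grid stream of the network: each placed channel's time series fills
#' its cell, every unplaced cell is exactly zero.
#'
#' @param eeg channel x time matrix with rownames naming the channels.
#' @param layout an [electrode_layout()] placing every EEG channel.
#' @return numeric array `grid_h x grid_w x T`.
#' @export
map_to_grid <- function(eeg, layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  ch <- rownames(eeg)
  if (is.null(ch)) stopf("eeg matrix must carry channel rownames")
  missing <- setdiff(ch, layout$placement$name)
  if (length(missing))
    stopf("channel(s) not placed in layout: %s", paste(missing, collapse = ", "))
  g <- array(0, c(layout$grid_h, layout$grid_w, ncol(eeg)))
  idx <- match(ch, layout$placement$name)
  for (i in seq_along(ch))
    g[layout$placement$row[idx[i]], layout$placement$col[idx[i]], ] <- eeg[i, ]
  g
}

#' Read placed grid cells back into a channel matrix (inverse of map_to_grid)
#' @param grid array `H x W x T`.
#' @param layout the layout used to build it.
#' @param channel_names channels to extract, defaults to all placed ones.
#' @return channel x time matrix.
#' @export
grid_to_channels <- function(grid, layout, channel_names = NULL) {
  pl <- layout$placement
  if (!is.null(channel_names)) pl <- pl[match(channel_names, pl$name), ]
  out <- t(vapply(seq_len(nrow(pl)),
                  function(i) grid[pl$row[i], pl$col[i], ],
                  numeric(dim(grid)[3])))
  rownames(out) <- pl$name
  out
}

#' Additive Gaussian noise at a prescribed signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise per channel with variance
#' `P / 10^(snr_db/10)`, where `P` is that channel's mean square. Used for
#' noise-robustness experiments at, e.g., 10, 0 and -5 dB. `snr_db = Inf`
#' returns the input unchanged (the no-noise reference).
#'
#' @param signal channel x time matrix (or plain vector).
#' @param snr_db target signal-to-noise ratio in decibels.
#' @param seed optional integer seed for reproducible noise.
#' @return matrix of the same shape.
#' @export
add_gaussian_noise <- function(signal, snr_db, seed = NULL) {
  if (!is.finite(snr_db)) {
    if (is.infinite(snr_db) && snr_db > 0) return(signal)
    stopf("snr_db must be finite or +Inf")
  }
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, nrow = 1) else signal
  if (length(x) == 0) stopf("signal is empty")
  p <- rowMeans(x^2)
  sd_n <- sqrt(p / 10^(snr_db / 10))
  noisy <- with_seed(seed, x + matrix(stats::rnorm(length(x)), nrow(x)) * sd_n)
  if (vec) drop(noisy) else noisy
}

#' Build model-ready samples from recordings
#'
#' Full preprocessing pipeline: baseline correction, 1-s sliding-window
#' segmentation, label binarization for the chosen affect dimension, spatial
#' grid mapping of the EEG channels, and separation of peripheral channels.
#' Every window inherits the label of its parent trial. Samples are returned
#' as batched arrays for efficiency.
#'
#' @param recordings list of `trial_recording` objects.
#' @param dimension affect dimension to label by.
#' @param layout an [electrode_layout()]; `NULL` picks [default_layout()]
#'   `"auto"` from the EEG channel names.
#' @param window_s,stride_s segmentation parameters (seconds).
#' @param threshold binarization threshold; `NULL` uses the scale default.
#' @param baseline `TRUE` to apply [subtract_baseline()].
#' @param zscore optional per-channel standardization of EEG and peripheral
#'   windows using statistics over the given samples (apply only to training
#'   folds and reuse the returned stats for held-out data).
#' @return a `sample_set`: list with `eeg` (C x T x n), `grid` (H x W x T x n),
#'   `periph` (P x T x n), `label` (0/1), `meta` data frame, `layout`, `fs`.
#' @export
make_samples <- function(recordings, dimension = "valence", layout = NULL,
                         window_s = 1, stride_s = 1, threshold = NULL,
                         baseline = TRUE, zscore = FALSE) {
  stopifnot(length(recordings) >= 1)
  r1 <- recordings[[1]]
  eeg_idx <- which(r1$channel_roles == "EEG")
  per_idx <- which(r1$channel_roles == "peripheral")
  if (is.null(layout))
    layout <- default_layout("auto", channel_names = r1$channel_names[eeg_idx])
  if (is.null(threshold)) threshold <- default_threshold(r1$rating_scale)
  bounds <- rating_bounds(r1$rating_scale)

  eeg_l <- list(); per_l <- list(); lab <- integer(); meta <- list()
  for (rec in recordings) {
    if (!dimension %in% names(rec$ratings))
      stopf("dimension '%s' absent from ratings (%s)", dimension,
            paste(names(rec$ratings), collapse = ", "))
    if (baseline) rec <- subtract_baseline(rec)
    wins <- segment_trial(rec, window_s, stride_s)
    y <- binarize_label(rec$ratings[[dimension]], threshold,
                        scale = bounds[c("lo", "hi")])
    for (w in wins) {
      eeg_l[[length(eeg_l) + 1L]] <- w[eeg_idx, , drop = FALSE]
      per_l[[length(per_l) + 1L]] <- w[per_idx, , drop = FALSE]
      lab <- c(lab, y)
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = rec$subject_id, trial_id = rec$trial_id,
        window_index = attr(w, "window_index"))
    }
  }
  n <- length(eeg_l)
  if (n == 0) stopf("no windows produced; trials shorter than the window?")
  Tn <- ncol(eeg_l[[1]])
  eeg <- array(unlist(eeg_l), c(length(eeg_idx), Tn, n))
  dimnames(eeg) <- list(r1$channel_names[eeg_idx], NULL, NULL)
  periph <- array(unlist(per_l), c(length(per_idx), Tn, n))

  stats <- NULL
  if (isTRUE(zscore)) {
    stats <- list(
      eeg_mu = apply(eeg, 1, mean), eeg_sd = pmax(apply(eeg, 1, stats::sd), 1e-8),
      per_mu = if (length(per_idx)) apply(periph, 1, mean) else numeric(),
      per_sd = if (length(per_idx)) pmax(apply(periph, 1, stats::sd), 1e-8) else numeric())
    eeg <- sweep(sweep(eeg, 1, stats$eeg_mu), 1, stats$eeg_sd, "/")
    if (length(per_idx))
      periph <- sweep(sweep(periph, 1, stats$per_mu), 1, stats$per_sd, "/")
  }

  grid <- array(0, c(layout$grid_h, layout$grid_w, Tn, n))
  for (i in seq_len(n)) grid[, , , i] <- map_to_grid(eeg[, , i], layout)

  structure(list(eeg = eeg, grid = grid, periph = periph,
                 label = lab, meta = do.call(rbind, meta), layout = layout,
                 fs = r1$fs, dimension = dimension, zscore_stats = stats),
            class = "sample_set")
}

#' Subset a sample set
#' @param x a `sample_set`.
#' @param idx sample indices to keep.
#' @return the subset `sample_set`.
#' @export
subset_samples <- function(x, idx) {
  x$eeg <- x$eeg[, , idx, drop = FALSE]
  x$grid <- x$grid[, , , idx, drop = FALSE]
  x$periph <- x$periph[, , idx, drop = FALSE]
  x$label <- x$label[idx]
  x$meta <- x$meta[idx, , drop = FALSE]
  x
}

#' Number of samples in a sample set
#' @param x a `sample_set`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$label)

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d windows: EEG %dx%d, grid %dx%dx%d, periph %dx%d; %s labels: %d high / %d low\n",
              n_samples(x), dim(x$eeg)[1], dim(x$eeg)[2],
              dim(x$grid)[1], dim(x$grid)[2], dim(x$grid)[3],
              dim(x$periph)[1], dim(x$periph)[2], x$dimension,
              sum(x$label == 1), sum(x$label == 0)))
  invisible(x)
}

#' Inject EEG noise into an existing sample set
#'
#' Applies [add_gaussian_noise()] to every EEG window (per channel) and
#' rebuilds the spatial grid from the noisy EEG. Peripheral channels are left
#' untouched unless `include_periph = TRUE`.
#'
#' @param samples a `sample_set`.
#' @param snr_db target SNR in dB (`Inf` = no-op).
#' @param seed integer seed.
#' @param include_periph also corrupt peripheral channels.
#' @return the noisy `sample_set`.
#' @export
noisy_samples <- function(samples, snr_db, seed = 1L, include_periph = FALSE) {
  if (is.infinite(snr_db) && snr_db > 0) return(samples)
  n <- n_samples(samples)
  with_seed(seed, {
    for (i in seq_len(n)) {
      samples$eeg[, , i] <- add_gaussian_noise(samples$eeg[, , i], snr_db)
      samples$grid[, , , i] <- map_to_grid(samples$eeg[, , i], samples$layout)
      if (include_periph)
        samples$periph[, , i] <- add_gaussian_noise(samples$periph[, , i], snr_db)
    }
  })
  samples
}
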