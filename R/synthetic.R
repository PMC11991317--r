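#' Configuration for the synthetic multimodal recording generator
#'
#' Builds the parameter bundle consumed by [generate_dataset()]. The generator
#' emulates the structure of benchmark affective datasets: per-trial stimulus
#' and resting-baseline segments sampled at `fs` Hz, multichannel EEG whose
#' band-limited oscillatory content is modulated by a latent binary affective
#' state, event-structured peripheral channels (ocular blinks or cardiac QRS
#' complexes), and continuous self-assessment ratings on a declared scale.
#'
#' The latent state of a trial scales the alpha-band amplitude on the first
#' `ceiling(n_eeg / 4)` EEG channels and the beta-band amplitude on the
#' remaining channels by `(1 + effect_size)`, and scales the peripheral event
#' rate by the same factor, so `effect_size = 0` yields class-indistinguishable
#' signals and larger values yield increasingly separable classes.
#'
#' @param n_subjects number of subjects to simulate.
#' @param n_trials trials per subject.
#' @param trial_s stimulus duration in seconds; either a single value or a
#'   length-2 range from which each trial's duration is drawn uniformly
#'   (DREAMER-like variable-length clips).
#' @param baseline_s resting baseline duration in seconds (0 disables it).
#' @param fs sampling rate in Hz.
#' @param n_eeg number of EEG channels.
#' @param n_periph number of peripheral channels.
#' @param periph_kind `"EOG"` (blink events over slow drift) or `"ECG"`
#'   (periodic QRS-like complexes).
#' @param rating_scale `"1-9"` (binarization threshold 5) or `"1-5"`
#'   (binarization threshold 3).
#' @param effect_size class-effect amplitude/rate factor, a dimensionless
#'   delta >= 0.
#' @param noise_sd standard deviation of the additive Gaussian background
#'   noise, in the same arbitrary microvolt-like units as the oscillations.
#' @param seed integer seed; identical configuration plus seed reproduces the
#'   dataset bit for bit.
#' @return an object of class `synth_config`.
#' @seealso [preset_deap_like()], [preset_dreamer_like()], [generate_dataset()]
#' @export
synth_config <- function(n_subjects = 1, n_trials = 40, trial_s = 60,
                         baseline_s = 3, fs = 128, n_eeg = 32, n_periph = 2,
                         periph_kind = c("EOG", "ECG"),
                         rating_scale = c("1-9", "1-5"),
                         effect_size = 1, noise_sd = 0.5, seed = 1L) {
  periph_kind <- match.arg(periph_kind)
  rating_scale <- match.arg(rating_scale)
  if (fs <= 0) stopf("fs must be positive, got %s", fs)
  if (any(trial_s < 1)) stopf("trial_s must be >= 1 second")
  if (length(trial_s) > 2) stopf("trial_s must be a scalar or a length-2 range")
  if (baseline_s < 0) stopf("baseline_s must be >= 0")
  if (n_eeg < 1) stopf("n_eeg must be >= 1")
  if (n_periph < 0) stopf("n_periph must be >= 0")
  if (effect_size < 0) stopf("effect_size (delta) must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    trial_s = trial_s, baseline_s = baseline_s, fs = fs,
    n_eeg = as.integer(n_eeg), n_periph = as.integer(n_periph),
    periph_kind = periph_kind, rating_scale = rating_scale,
    effect_size = effect_size, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

#' DEAP-like and DREAMER-like generator presets
#'
#' `preset_deap_like()` mirrors the structure of the DEAP benchmark: 32 EEG +
#' 2 EOG channels, 40 trials of 60 s stimulus after a 3 s baseline, sampled at
#' 128 Hz, ratings on a 1-9 scale. `preset_dreamer_like()` mirrors DREAMER:
#' 14 EEG + 2 ECG channels, 18 trials whose stimulus length varies per trial
#' (default uniform on 60-240 s), 128 Hz, ratings on a 1-5 scale.
#'
#' @param ... overrides passed on to [synth_config()].
#' @return a `synth_config`.
#' @export
preset_deap_like <- function(...) {
  args <- list(n_subjects = 1, n_trials = 40, trial_s = 60, baseline_s = 3,
               fs = 128, n_eeg = 32, n_periph = 2, periph_kind = "EOG",
               rating_scale = "1-9")
  do.call(synth_config, utils::modifyList(args, list(...)))
}

#' @rdname preset_deap_like
#' @export
preset_dreamer_like <- function(...) {
  args <- list(n_subjects = 1, n_trials = 18, trial_s = c(60, 240),
               baseline_s = 3, fs = 128, n_eeg = 14, n_periph = 2,
               periph_kind = "ECG", rating_scale = "1-5")
  do.call(synth_config, utils::modifyList(args, list(...)))
}

rating_bounds <- function(rating_scale) {
  switch(rating_scale,
    "1-9" = c(lo = 1, hi = 9, threshold = 5),
    "1-5" = c(lo = 1, hi = 5, threshold = 3),
    stopf("unknown rating scale '%s'", rating_scale))
}

rating_dimensions <- function(rating_scale) {
  if (rating_scale == "1-9") c("valence", "arousal", "dominance", "liking")
  else c("valence", "arousal", "dominance")
}

## canonical electrode name sets (10-20 system)
eeg_channel_names <- function(n_eeg) {
  deap32 <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
              "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4",
              "Fz", "F4", "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6",
              "CP2", "P4", "P8", "PO4", "O2")
  dreamer14 <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2", "P8",
                 "T8", "FC6", "F4", "F8", "AF4")
  if (n_eeg == 32) deap32
  else if (n_eeg == 14) dreamer14
  else paste0("EEG", seq_len(n_eeg))
}

## oscillation bands used for the synthetic EEG content (Hz)
synth_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

## band-limited oscillatory EEG content for one channel
synth_eeg_channel <- function(tt, amp) {
  bands <- synth_bands()
  out <- numeric(length(tt))
  for (b in names(bands)) {
    f <- stats::runif(1, bands[[b]][1], bands[[b]][2])
    ph <- stats::runif(1, 0, 2 * pi)
    out <- out + amp[b] * sin(2 * pi * f * tt + ph)
  }
  out
}

## biphasic 0.3-s blink template and 0.08-s triangular QRS template
blink_template <- function(fs) {
  n <- max(2L, round(0.3 * fs))
  3 * sin(2 * pi * seq(0, 1, length.out = n))
}

qrs_template <- function(fs) {
  n <- max(3L, round(0.08 * fs))
  half <- ceiling(n / 2)
  5 * c(seq(0, 1, length.out = half), seq(1, 0, length.out = n - half + 1)[-1])
}

add_events <- function(x, fs, times_s, template) {
  n <- length(x)
  for (t0 in times_s) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:min(n, i0 + length(template) - 1L)
    if (length(idx) >= 1 && idx[1] <= n)
      x[idx] <- x[idx] + template[seq_along(idx)]
  }
  x
}

## peripheral channel: drift + blink pulses (EOG) or QRS train (ECG);
## the event rate carries the class effect.
synth_periph_channel <- function(tt, fs, kind, rate_factor, noise_sd) {
  dur <- length(tt) / fs
  drift_f <- stats::runif(1, 0.05, 0.3)
  x <- 0.5 * sin(2 * pi * drift_f * tt + stats::runif(1, 0, 2 * pi))
  if (kind == "EOG") {
    rate <- 0.25 * rate_factor              # blinks per second
    n_ev <- stats::rpois(1, rate * dur)
    times <- sort(stats::runif(n_ev, 0, max(dur - 0.3, 0)))
    x <- add_events(x, fs, times, blink_template(fs))
  } else {
    bpm <- stats::runif(1, 60, 100) * rate_factor
    period <- 60 / bpm
    times <- seq(stats::runif(1, 0, period), dur - 0.1, by = period)
    x <- add_events(x, fs, times, qrs_template(fs))
  }
  x + stats::rnorm(length(tt), 0, noise_sd)
}

#' Generate a reproducible synthetic multimodal dataset
#'
#' Draws, for every subject and trial, a latent binary affective state
#' (balanced within subject), continuous ratings consistent with that state
#' (high state: uniform above the scale threshold; low state: uniform at or
#' below it, so binarizing at the threshold recovers the state exactly), EEG
#' as a sum of delta/theta/alpha/beta band oscillations plus Gaussian noise
#' with the class effect described in [synth_config()], and peripheral
#' channels with class-dependent event rates. Baseline segments contain
#' oscillations and noise only, with no class effect.
#'
#' @param cfg a [synth_config()].
#' @return a list of `trial_recording` objects, each holding `signal`
#'   (channels x samples), `baseline`, `fs`, `channel_names`, `channel_roles`
#'   (`"EEG"`/`"peripheral"`), `ratings`, `rating_scale`, and the latent
#'   `state` used to generate it.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  bounds <- rating_bounds(cfg$rating_scale)
  dims <- rating_dimensions(cfg$rating_scale)
  ch_names <- c(eeg_channel_names(cfg$n_eeg),
                if (cfg$n_periph > 0) paste0(cfg$periph_kind, seq_len(cfg$n_periph)))
  roles <- c(rep("EEG", cfg$n_eeg), rep("peripheral", cfg$n_periph))
  n_alpha <- ceiling(cfg$n_eeg / 4)          # alpha-boosted channel block

  with_seed(cfg$seed, {
    out <- vector("list", cfg$n_subjects * cfg$n_trials)
    k <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      states <- sample(rep(0:1, length.out = cfg$n_trials))
      for (tr in seq_len(cfg$n_trials)) {
        k <- k + 1L
        z <- states[tr]
        dur <- if (length(cfg$trial_s) == 2)
          stats::runif(1, cfg$trial_s[1], cfg$trial_s[2]) else cfg$trial_s
        n_samp <- round(dur * cfg$fs)
        n_base <- round(cfg$baseline_s * cfg$fs)
        tt <- seq_len(n_samp) / cfg$fs
        tb <- seq_len(n_base) / cfg$fs

        sig <- matrix(0, cfg$n_eeg + cfg$n_periph, n_samp)
        base <- matrix(0, cfg$n_eeg + cfg$n_periph, n_base)
        gain <- 1 + cfg$effect_size * z
        for (ch in seq_len(cfg$n_eeg)) {
          amp <- c(delta = 1, theta = 1, alpha = 1, beta = 1)
          if (ch <= n_alpha) amp["alpha"] <- gain else amp["beta"] <- gain
          sig[ch, ] <- synth_eeg_channel(tt, amp) +
            stats::rnorm(n_samp, 0, cfg$noise_sd)
          if (n_base > 0)
            base[ch, ] <- synth_eeg_channel(tb, c(delta = 1, theta = 1,
                                                  alpha = 1, beta = 1)) +
              stats::rnorm(n_base, 0, cfg$noise_sd)
        }
        for (p in seq_len(cfg$n_periph)) {
          ch <- cfg$n_eeg + p
          sig[ch, ] <- synth_periph_channel(tt, cfg$fs, cfg$periph_kind,
                                            gain, cfg$noise_sd)
          if (n_base > 0)
            base[ch, ] <- synth_periph_channel(tb, cfg$fs, cfg$periph_kind,
                                               1, cfg$noise_sd)
        }
        rownames(sig) <- rownames(base) <- ch_names

        ratings <- vapply(dims, function(d) {
          if (z == 1) stats::runif(1, bounds["threshold"] + 1e-9, bounds["hi"])
          else stats::runif(1, bounds["lo"], bounds["threshold"])
        }, numeric(1))

        out[[k]] <- structure(list(
          subject_id = s, trial_id = tr, signal = sig, baseline = base,
          fs = cfg$fs, channel_names = ch_names, channel_roles = roles,
          ratings = ratings, rating_scale = cfg$rating_scale, state = z
        ), class = "trial_recording")
      }
    }
    out
  })
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %s trial %s: %d channels x %d samples @ %g Hz (baseline %d samples)\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$baseline)))
  cat("  ratings:", paste(sprintf("%s=%.2f", names(x$ratings), x$ratings),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a dataset to a single container file
#'
#' Recordings are written with R's native serialization (`saveRDS`), which
#' round-trips the nested trial structure losslessly.
#'
#' @param recordings list of `trial_recording` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(recordings, path) {
  saveRDS(recordings, path)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  readRDS(path)
}
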