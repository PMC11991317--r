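---
title: "Multimodal emotion recognition with msdsanet: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal emotion recognition with msdsanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Affective state is commonly estimated from short windows of multichannel
physiological recordings: scalp EEG plus one or more peripheral channels
(electrooculogram, EOG, or electrocardiogram, ECG). In the benchmark protocol
this package follows, a subject watches an emotion-eliciting clip, a resting
baseline is recorded before each trial, and the subject reports continuous
ratings (valence, arousal, dominance, and sometimes liking) that are
binarized into high/low classes. Classification is subject-dependent: a model
is trained and evaluated within one subject's windows.

`msdsanet` implements MSDSANet, a multimodal network for this task, together
with everything needed to exercise it end to end without controlled-access
data: a synthetic recording generator, the windowing/labelling/grid
preprocessing, training and cross-validated evaluation with the field's five
metrics, ablation variants, a noise-robustness sweep, and a t-SNE feature
visualizer.

## The model

The network has three feature extractors fused by attention:

* **EEG raw-series stream** (`eeg_temporal_stream()`): a convolution along
  time applied per electrode (kernel `1 x kt`, default `kt = 5`), a
  convolution across the full electrode axis (kernel `C x 1`) that collapses
  electrodes, then two `3 x 3` convolutions with 64 and 32 feature maps. Every
  convolution is followed by batch normalization and ReLU, and dropout
  follows the final activation.
* **EEG grid stream — MSARB** (`msarb()`): the window's EEG is first mapped
  onto a 2-D scalp grid that preserves 10-20 electrode adjacency
  (`map_to_grid()`), giving a grid-row x grid-column x time tensor. Time
  samples act as input channels, so the spatial plane being convolved is the
  electrode layout. A `3 x 3` stem produces `F0` maps; three parallel
  convolutions (`7 x 7`, `5 x 5`, `3 x 3`, same-padded) capture neighbourhoods
  at three spatial scales; their concatenation is fused back to `F0` channels
  by a `1 x 1` convolution; efficient channel attention (ECA) reweights the
  fused maps; and a residual connection adds the stem output back.
* **Peripheral stream — DSANet** (`dsanet()`): two parallel conv-LSTM
  branches over the peripheral channels. The long-kernel branch (`1 x 50`
  then `1 x 10` convolutions, LSTM with 768 cells) targets slow structure;
  the short-kernel branch (`1 x 5` then `1 x 3`, LSTM with 384 cells) targets
  transients. The final hidden states are concatenated (length 1152) and
  reweighted by ECA applied across the feature axis.

**ECA** computes one weight per channel: global average pooling, a 1-D
convolution across the channel axis whose kernel length adapts to the channel
count as `k = floor(|log2(C)/t0 + b1/t0|)` (bumped to the next odd integer;
`t0 = 2`, `b1 = 1`), then a sigmoid. `eca_kernel_size()` exposes the rule:
C = 64 gives 3, C = 1152 gives 5.

**Fusion (CBAM)**: the raw-series stream output is adaptive-average-pooled to
the grid plane, the peripheral vector is linearly projected and reshaped to
`fe` grid-shaped channels, and the three maps are concatenated on the channel
axis. Channel attention applies a shared two-layer MLP (reduction ratio `r`)
to the average- and max-pooled channel descriptors; spatial attention applies
a `7 x 7` convolution to the average- and max-pooled channel maps. Both end
in sigmoids, so every attention weight lies in (0, 1) and neither stage
changes the tensor shape. The fused map is flattened, passed through dropout
and a dense softmax layer, and trained with mean cross-entropy.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `f0`, `f_ms` | 64, 64 | MSARB stem / per-scale feature maps |
| `kt` | 5 | temporal kernel length (odd), stream 1 |
| `stream1_filters` | 64, 64, 64, 32 | stream-1 conv widths; final 32 is the published width |
| `dsanet_filters` | 32, 64 | conv widths in each peripheral branch |
| `lstm_units` | 768, 384 | long / short branch LSTM cells |
| `dropout` | 0.5 | dropout probability (stream 1 and classifier head) |
| `fe` | 16 | grid channels the peripheral vector is projected to |
| `cbam_r`, `cbam_kernel` | 8, 7 | CBAM MLP reduction and spatial kernel |
| `eca_t0`, `eca_b1` | 2, 1 | ECA kernel-size constants |

`model_config(preset = "reduced")` (`f0 = 8`, LSTM 32/16, widths 8) is the
scale used for the synthetic-data experiments and the test suite;
`preset = "tiny"` (`f0 = 4`, LSTM 8/4) is used for gradient checks. Presets
change sizes only, never the architecture.

### Where the published description is silent

Several details are not stated by the architecture's published description;
this package fixes them as follows (all configurable where sensible):

* stream-1's temporal kernel length (`kt = 5`) and the widths of the first
  two stream-1 convolutions and the DSANet convolutions (matched to the
  64-filter scale of adjacent layers);
* batch normalization and ReLU after all four stream-1 convolutions, not only
  the two `3 x 3` stages; ReLU (no BN) after the DSANet convolutions;
* same-padding wherever a concatenation or residual connection requires shape
  agreement, with asymmetric zero padding for even kernel lengths (the
  `1 x 50` and `1 x 10` kernels), so the peripheral branch accepts any window
  of at least 50 samples; no pooling between the DSANet convolutions;
* the CBAM inputs have heterogeneous shapes; the raw-series map is adapted by
  adaptive average pooling and the peripheral vector by a learned projection,
  since spatial concatenation requires a common plane;
* the grid is 9 x 9 for the 32- and 14-channel montages (shipped as editable
  CSV files under `inst/extdata/`; any other montage is packed row-major);
* dropout rate 0.5; SGD without momentum or weight decay in the full-scale
  presets; seeded uniform fan-in weight initialization.

## The synthetic generator

`generate_dataset()` emulates the *structure* of the benchmark recordings:
per-trial baseline + stimulus segments at 128 Hz, EEG as a sum of band-limited
oscillations (delta/theta/alpha/beta, one random frequency and phase per band
per channel per trial) plus Gaussian noise, and event-structured peripheral
channels (0.3-s biphasic blinks at 0.25 Hz for EOG; 0.08-s triangular QRS
complexes at 60-100 bpm for ECG). A latent binary affective state per trial
scales alpha amplitude on the first quarter of EEG channels and beta
amplitude on the rest by `1 + effect_size`, and scales the peripheral event
rate by the same factor, so both modalities are informative. Ratings are
drawn uniformly on the matching side of the binarization threshold, making
label recovery exact by construction. One latent state drives all rating
dimensions; independent per-dimension states would make all but one dimension
unlearnable from a single signal.

What the generator does **not** emulate: volume conduction and electrode
cross-correlation, non-stationarity, artifacts other than blinks, realistic
1/f spectra, or any empirical estimate of how large real emotion effects are
— `effect_size` is a free knob, not an estimate of the benchmark datasets'
separability. Consequently, passing the synthetic parameter-recovery tests
shows the pipeline can learn the class signal it was given and that the
machinery is correct; it says nothing about accuracy on real recordings.

## Evaluation protocol and the leakage caveat

The published protocol shuffles 1-s windows and averages ten stratified
cross-validation folds; `run_subject_cv()` implements exactly that. Windows
of one trial then appear on both sides of a split. On synthetic data this
matters measurably: each trial has its own oscillation frequencies, so a
capable model can match a test window to training windows from the same trial
and inherit the label without using any class information. The package
therefore also provides trial-grouped splitting (`grouped = TRUE` in
`holdout_eval()`, `run_subject_cv()` and `noise_sweep()`), which holds out
whole trials. The synthetic recovery experiments use the grouped mode: at
`effect_size = 0` it keeps held-out accuracy at chance, as it must, while the
window-level mode drifts above chance through trial memorization. Real
recordings carry the same risk in milder form; grouped splitting is the
conservative choice when the goal is generalization to unseen trials.

Metrics: accuracy, sensitivity, specificity, precision, F1, and two kappa
forms — uniform-chance `(N p - 1)/(N - 1)` (equal to `2p - 1` for two
classes) and Cohen's marginal kappa from the confusion table. Published
kappa values in this literature are consistent with the marginal form rather
than the uniform-chance identity, so the marginal form is the default column
and the uniform form is reported alongside. Metrics with zero denominators
are reported as `NaN` with a warning rather than silently coerced to 0.

## Numerical choices

* Batch normalization uses population (biased) batch variance, `eps = 1e-5`,
  running-average momentum 0.1; inference uses the running statistics.
* Cross-entropy clips probabilities at `1e-12`. Softmax subtracts the column
  maximum before exponentiation.
* The LSTM is a single fused operation with hand-written backpropagation
  through time (per-step graph nodes made the backward pass quadratic in
  sequence length); its gradients are validated against central finite
  differences in the unit tests.
* Gradient checks probe a randomly perturbed parameter point. At the freshly
  initialized point all biases are exactly zero and flat stretches of the
  synthetic signals drive many pre-activations exactly onto the ReLU kink,
  where a central difference straddles the non-differentiability and disagrees
  with any one-sided subgradient by design; away from the kink the analytic
  and numeric gradients agree to ~1e-6 relative error or better.
* Ties in max-pooling attention take the first maximum; adaptive average
  pooling uses the floor/ceiling bin rule, which degenerates to replication
  when upsampling a singleton axis.
* `embed_features()` is an exact t-SNE (perplexity by per-point binary
  search, early exaggeration for 50 iterations, momentum gradient descent),
  quadratic in the number of points and intended for per-subject window
  counts, not whole datasets.
* Training hyperparameters: the full-scale presets follow the published
  protocol (SGD, learning rate 1e-5, batch 64, 40 or 30 epochs). The
  `"reduced"` preset used on synthetic data (learning rate 0.05, momentum
  0.9, batch 32, 8 epochs) was fixed once from the optimization behaviour on
  the generator's default conditions, where the loss converges within about
  three epochs.

## Problem sizes used by the tests and the acceptance script

Structural checks use a full DEAP-like subject (40 trials x 60 s at 128 Hz:
2400 windows of 32 x 128). Parameter-recovery runs use a 14-EEG + 2-ECG
montage, 20 trials of 20 s (200 windows per class), the reduced model, and a
trial-grouped one-third holdout; the noise sweep trains one model per SNR
level in {Inf, 10, 0, -5} dB with noise injected into the EEG of both split
sides. Gradient checks use the tiny model on 6-channel, 64-Hz windows. These
sizes are the package's default desk-scale experiment; all of them scale up
through the same public functions.

## Limitations

* The network is trained on CPU in plain R; it is suitable for the reduced
  synthetic experiments and for correctness work, not for full-scale
  benchmark training.
* Dataset adapters for the controlled-access benchmark releases are out of
  scope; the container the package reads and writes is its own RDS format.
* Binary classification only (high/low per rating dimension), matching the
  published protocol.
* The synthetic generator's simplifications listed above bound what synthetic
  results can claim about real data.
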