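---
title: "Decoding motor-imagery speed from EEG: models, simulator and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery speed from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mispeed)
```

## The problem

When a person imagines a repetitive movement (say, squeezing a hand) paced at
a fixed rate, the EEG carries at least three signatures of the imagined
*speed*:

1. **Steady-state movement-related potentials (SSMRP)** — narrowband peaks at
   the pacing fundamental $f_0$ and its harmonics $h f_0$ over sensorimotor
   cortex, typically strongest at the second harmonic.
2. **Steady-state visual evoked potentials (SSVEP)** — the same harmonic
   structure over occipito-parietal cortex, driven by the visual pacing
   stimulus, usually larger than the SSMRP.
3. **Event-related desynchronization (ERD)** — attenuation of ongoing alpha
   (8–12 Hz) and beta (12–30 Hz) rhythms over motor cortex during (and
   shortly before) motor imagery, with depth that varies with the imagined
   speed.

`mispeed` implements a full desk-scale analysis of this setting: a simulator
that generates sessions with these signatures and known ground truth, a
compact convolution + self-attention classifier over four classes
(rest / slow / medium / fast), the steady-state PSD/SNR analysis, and the
interpretation toolchain (kernel spectra, spatial patterns, signed Grad-CAM
and class activation topographies). Because no public recordings accompany
the study design this package emulates, every empirical claim the test suite
makes is a *recovery* claim on simulated data: the pipeline must find, in
data whose generating process is known, exactly the structure that was
injected.

## The session design and simulator

The emulated protocol is three runs of 35 trials (10 per motor-imagery speed,
5 rest), each trial being a 1-s visual cue, a 5-s paced MI period opened by a
beep, and a 2-s break. Pacing rates are 0.93, 2.12 and 2.56 Hz for
slow/medium/fast. The trial arithmetic gives 30 trials per MI class and 15
rest trials, so the majority-class chance level is $30/105 = 0.2857$.

```{r}
design <- session_design()          # 3 x 35 trials, 1/5/2 s, fs = 250 Hz
conds  <- default_conditions()      # f0 = 0 / 0.93 / 2.12 / 2.56 Hz
noise  <- noise_spec()
session <- generate_session(design, conds, noise, seed = 1)
```

Each trial is the sum of:

* **1/f background**: per-channel power-law noise (exponent 1, RMS 5 µV),
  mixed across channels with a Gaussian spatial correlation
  (length 0.8 rad) so that the background is spatially smooth, as volume
  conduction makes real EEG backgrounds smooth. Without this, the surface
  Laplacian would amplify spatially-white noise unrealistically.
* **Ongoing rhythms**: narrowband stochastic alpha (~10 Hz, RMS 4 µV) and
  beta (~20 Hz, RMS 2 µV) over a sensorimotor Gaussian topography,
  attenuated multiplicatively by $1-\mathrm{erd}$ from 1 s before MI onset
  (the anticipatory lead) through the end of MI, with 0.2-s raised-cosine
  ramps to avoid spectral splatter. Default ERD depths grow with imagined
  speed (alpha: 0/0.2/0.35/0.5).
* **SSMRP**: $\sum_h a_h \sin(2\pi h f_0 t + \varphi_h)$ during MI on the
  sensorimotor topography, with the harmonic profile
  $a = 2 \times (0.6, 1.0, 0.5, 0.25)$ µV — maximal at the second harmonic
  with gradual attenuation above, the qualitative shape reported for paced
  MI. Phases are drawn once per trial. Harmonics above Nyquist are dropped
  with a warning.
* **SSVEP**: the same profile scaled to a 1.5× amplitude on an
  occipito-parietal topography, reflecting that visual steady-state
  responses exceed the movement-related ones.

Topographies are Gaussian bumps (width 0.6 rad) centred on the named channel
sets of the montage — the simplest spatially smooth ground truth. The default
montage is 14 channels: the nine SSMRP channels (FC3, FCz, FC4, C3, Cz, C4,
CP3, CPz, CP4), the three SSVEP channels (Pz, O1, O2), plus Fz and T7.
Positions are idealized unit-sphere 10-10 coordinates, not a digitized head
model.

Two deliberate simplifications: no ocular/muscle artifacts and no realistic
volume-conduction forward model. Passing recovery tests therefore shows the
*pipeline machinery* is correct, not that the decoder would reach any
particular accuracy on human EEG.

The grid-aligned condition variant (`default_conditions(grid_aligned =
TRUE)`: 0.9/2.1/2.6 Hz) puts every harmonic exactly on the 0.2-Hz grid of a
5-s window; the spectral-recovery fixtures use it so that harmonic energy is
not split across adjacent bins.

Everything is seeded: the same (design, conditions, noise, seed) reproduce a
bit-identical session before the 16-bit EDF quantization. Sessions round-trip
through `write_session()` / `read_session()` (classic continuous EDF +
BIDS-style `events.tsv`).

## Preprocessing

`bandpass()` applies a 4th-order Butterworth forward-backward (zero phase),
default 4–40 Hz: the low edge removes sub-4-Hz content (as the emulated
analysis did, to avoid motion artifacts), the high edge keeps the input
compact. Note one consequence: the slow fundamental (0.93 Hz) and all its
harmonics fall below 4 Hz, so the slow class is identifiable mainly through
its ERD — mirroring the empirical finding that the slow condition shows no
detectable steady-state response.

`epoch_session()` cuts $[-1, 5)$ s windows around MI onset (covering the
anticipatory second), `normalize_epochs()` z-scores each channel of each
trial (zero-variance channels map to zero, and the operation is idempotent),
and `split_epochs()` provides leave-one-run-out (default; respects the run
structure) or seeded stratified k-fold splits.

## The decoder

The classifier is a compact conv-transformer in the EEGConformer family,
written natively in this package (forward pass, backpropagation and the Adam
loop), with correctness pinned by a finite-difference gradient check in the
test suite:

* **Convolution module** — a bank of temporal FIR kernels (default 40
  kernels of 25 samples) applied per channel, a spatial filter matrix
  $W$ (filters × channels) mixing channels per kernel, ELU, then average
  pooling (window 75, stride 15) into a token sequence. Because the temporal
  convolution and the per-filter spatial projection are both linear, they
  commute; the implementation projects spatially first, which is
  mathematically identical and much cheaper.
* **Self-attention module** — 2 post-norm transformer encoder layers
  (4 heads, embedding 40, feed-forward 2×, GELU).
* **Classification module** — flatten + linear head over the 4 classes;
  ties in the argmax resolve toward the lower class index.

Training minimizes softmax cross-entropy with Adam plus decoupled weight
decay on the weight matrices (default lr $10^{-3}$, batch 16, decay
$10^{-3}$), early-stops on validation loss (patience 20) and restores the
best parameters. Initialization, batch order and dropout masks all derive
from one seed, so the training log is exactly reproducible. These training
hyperparameters are this package's own choices — community defaults for the
architecture family.

Two details serve interpretability. The temporal kernels are kept
**zero-mean** during training: the input is high-pass filtered, so a
kernel's DC response is unidentifiable, and left unconstrained it drifts
under the optimizer and (with a 25-tap kernel's ~5-Hz spectral resolution)
leaks a spurious low-frequency bump into the kernel spectra. And the
kernels are initialized small (0.2× Glorot) so that, after training, the
filter bank's frequency response is dominated by what training grew rather
than by the random initialization — with full-scale random kernels the
model can solve separable desk-scale problems through downstream layers
while the kernels barely move, leaving near-flat, seed-dependent spectra.

## Interpretation

* `kernel_frequency_response()` — the DFT magnitude of each temporal kernel
  on ≥256 points up to Nyquist (magnitude is invariant to the time reversal
  implied by convolution); the mean across kernels is smoothed with a
  Savitzky–Golay filter (window 5, order 3).
* `spatial_pattern()` — columns of $W^{-1}$ (exact inverse only for a square,
  well-conditioned $W$; Moore–Penrose pseudo-inverse otherwise, with a
  condition-number threshold of $10^6$), reported as per-column normalized
  absolute values since the sign of an oscillatory pattern is arbitrary.
* `gradcam()` — gradient-weighted class activation over the feature maps at
  the convolution-module output (the pooled tokens): weights are spatial
  means of the score gradient, the map is the weighted sum **without
  rectification**, so negative values can be read as ERD and positive as
  ERS. Token-resolution maps are upsampled to the input axis by
  nearest-receptive-field-centre assignment (ties to the earlier token) and
  binned into 0.5-s bins; binning conserves the epoch mean.
* `cat_topography()` — per channel, the mean over time and trials of
  (normalized signal × CAM). Each trial is multiplied by its *own* CAM
  before averaging: a class-averaged CAM would cancel against the random
  per-trial phases of oscillatory sources, hiding exactly the localized
  structure the topography is meant to reveal. The class-averaged CAM
  remains the displayed temporal quantity.

## Steady-state analysis

`csd_transform()` implements the spherical-spline surface Laplacian
(stiffness $m = 4$, regularization $\lambda = 10^{-5}$, 50 Legendre terms,
output µV/m² for a 9-cm head radius). `welch_psd()` averages
Blackman-tapered segment periodograms over segments, channels of a set and
trials (default segments 2.5 s with 50 % overlap; `segment_s = NULL` gives
the full-window periodogram, 0.2-Hz resolution over a 5-s MI span).
`snr_spectrum()` divides each bin's power by the mean of its ±5 neighbors
(edges flagged undefined), and `harmonic_readout()` reads the SNR at the
nearest grid bin to each $h f_0$ (ties to the lower frequency) and marks the
global maximum over 1–8 Hz.

With the default generative amplitudes, 30 medium-condition epochs put the
global SNR maximum at 4.2 Hz (= 2 × 2.1 Hz) and fast-condition epochs at
5.2 Hz — the second harmonics, reproducing the qualitative finding the
simulator encodes.

## Numerical and design choices

* Default sampling rate 250 Hz; all default durations are sample-aligned.
  The `high_separability` recovery profile samples at 125 Hz, halving
  decoder cost while keeping the 4–40 Hz band comfortably below Nyquist.
* The recovery profile strengthens the injected structure (ERD depths up to
  0.9, 4× steady-state amplitudes, background RMS 2 µV) so that
  leave-one-run-out decoding is reliably learnable from 70 training trials;
  a simple band-power LDA solves this profile at ~93 %, so decoder success
  reflects feature recovery rather than luck. Its optimizer settings
  (lr 2 × 10⁻³, batch 8, ≤70 passes, patience 15, 25 % validation split)
  make training converge in about a minute per fold on one CPU.
* Per-trial z-normalization couples the frequency bands: attenuating alpha
  necessarily raises every other band's *share* of unit variance, so with a
  stationary 1/f background the low-frequency band carries a reliable
  complement of the alpha-ERD information, and trained kernels honestly
  develop low-frequency response. The kernel-attribution recovery fixture
  therefore removes the background and the steady-state components
  entirely, leaving classes that differ only in their alpha-versus-beta ERD
  balance — the one construction in which "the discriminative content lies
  in 8–30 Hz" is true after normalization. On that fixture the trained
  filter bank's mean response in 8–30 Hz exceeds the 4–8 Hz band
  (3-seed average). `noise_spec(background_jitter =)` optionally adds
  per-trial lognormal background-amplitude non-stationarity (a realistic
  property of EEG backgrounds that weakens the complement channel); the
  default keeps the background stationary.
* Problem sizes used by the test suite: 100-repetition Monte-Carlo checks for
  spectral properties; 60 seeded repetitions of 30 epochs for harmonic
  recovery; 3 seeds × 3 leave-one-run-out folds for end-to-end recovery.
* Welch PSD floors zero-power bins at −300 dB with a warning rather than
  producing −Inf.
* EDF output uses one continuous data record and per-channel 16-bit scaling
  over the observed range; round-trips are exact up to that quantization.
  Event markers live in `events.tsv`, not embedded EDF annotations.
* `eval = FALSE` throughout this vignette: the code shown is executed (and
  asserted on) by the test suite instead, keeping package builds fast.

## Known limitations

* The simulator's steady-state components have constant amplitude across the
  MI period and trials; real steady-state responses drift and habituate.
* The spatial model (Gaussian bumps on an idealized sphere) cannot test
  referencing or realistic source-leakage effects; CSD results on real data
  will differ quantitatively.
* The per-participant decoding accuracies of the emulated study depend on
  undeposited human recordings and are out of scope; this package reproduces
  the metric machinery and the qualitative interpretability findings on
  synthetic ground truth only.
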