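---
title: "Decoding and reconstructing visual stimuli from low-density EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and reconstructing visual stimuli from low-density EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vepdecode)
```

# The problem

A visually evoked potential (VEP) is the stereotyped EEG response that
follows a visual stimulus onset: an occipital negativity near 100 ms (N1)
followed by a positivity near 200 ms (P2). With a portable 8-channel
montage over occipito-parietal sites (PO8, O2, O1, PO7, PO3, POZ, PO4, Pz;
250 Hz), single 2-second trials carry enough class-discriminative
information that the category of the viewed image can be decoded well
above the 5% chance level of a 20-class problem, and a generative image
model conditioned on the EEG can reconstruct aspects of the stimulus.

`vepdecode` implements this entire pathway at desk scale, from raw-signal
simulation through quality control, CNN classification, embedding
extraction, and latent-diffusion reconstruction with an n-way top-1
evaluation and an inter-trial null control. Because the underlying human
recordings are not publicly downloadable, the package ships a synthetic
session generator whose statistical structure matches what the analysis
assumes; every downstream stage is exercised and tested against it.

# The synthetic session generator

`vep_model()` renders each class's evoked response as two Gaussian lobes
(negative N1, default 100 ms latency, 22 ms width; positive P2, 200 ms,
40 ms width) projected onto the 8 channels by a class-specific spatial
signature. Class identity is carried by deterministic per-class
perturbations: latency shifts (SD 12 ms around N1, 19 ms around P2),
log-normal amplitude factors (SD 0.25), and an independent positive
signature per class. Trial-to-trial variability adds latency jitter
(SD 4 ms) and multiplicative amplitude jitter (SD 0.1).

The background is the sum of three canonical EEG confounders: 1/f
("pink") noise made by spectral shaping of white noise (exponent 1, SD
4 uV), a white sensor floor (SD 2 uV), and a fixed-phase 60 Hz line
component (1 uV) — the targets of the 1 Hz/95 Hz/60 Hz filters. A single
`snr` knob sets the ratio of the template peak to the total noise SD;
`snr = 0` produces stimulus-free sessions, and the classification
recovery analyses use `snr = 3` as the "high-SNR subject" (any ratio of
2 or more is comfortably decodable). These values were fixed once as
typical of wet-electrode occipital recordings.

Inter-trial gray-screen periods contain noise only, which is what gives
the inter-trial null control its meaning. Stimuli are parametric colored
shapes (one shape and hue per class on a class-specific gray background),
chosen so a small from-scratch classifier can learn them quickly and so
that within-class mean luminance varies less than between-class
luminance, mirroring the low-level coherence of curated natural-image
classes.

What the generator does *not* emulate: volume-conduction correlations
between channels (channels are independent under the null), eye-blink and
muscle artifact physics, electrode drift, and the semantic structure of
natural images. Tests passing on this generator therefore demonstrate
that the pipeline's machinery is correct and sensitive, not that any
particular accuracy will be attained on human data.

# Preprocessing

The per-session pipeline is strictly ordered: (1) segment the *unfiltered*
signal into 500-sample stimulus-locked epochs and compute the bad-trial
mask there; (2) zero-phase filter the *continuous* signal (edge artifacts
stay outside the trials); (3) re-segment; (4) drop flagged trials;
(5) z-normalize per channel over the session's retained trials and clamp
at 20 SD.

Filters are Butterworth high/low-pass (order 4, realised as two cascaded
order-2 passes for coefficient stability at the 1 Hz corner) plus an IIR
notch biquad of quality factor 30 at 60 Hz, each applied
forward-backward. Reflection padding (up to 500 samples) suppresses
filtfilt edge transients that would otherwise leak into the first and
last trials. The bad-trial criteria are: any non-finite sample; any
channel peak-to-peak below 0.01 uV; any channel pair with |r| > 0.99
(bridged electrodes); mean pairwise |r| below 0.01. The last threshold
deliberately sits more than five null standard deviations below the
expectation of the mean absolute correlation of independent 500-sample
channels (~0.036), so statistically independent channels are never
rejected; all four thresholds are exposed in `bad_trial_criteria()`.

Normalization statistics are computed per session over retained trials
only, and a constant channel is a hard error rather than a silent NaN —
a flat channel should have been caught by the mask.

# The classifier and encoder

`build_eegnet()` is a compact depthwise-separable CNN: a temporal filter
bank shared across channels (F1 filters of kernel length 64 samples),
batch-norm, a depthwise spatial convolution spanning all 8 channels
(depth multiplier D), batch-norm + ELU + pooling + dropout, a separable
convolution (depthwise 16-sample temporal + 1x1 pointwise), a second
norm/activation/pool/dropout block, and a linear classifier.
Convolutions are bias-free (each is followed by batch-norm); the
classifier carries a bias. With the best configuration — F1 = 64, D = 2,
max pooling (4, 8) and dropout 0.25 — the network has exactly 62,612
trainable parameters, which the test suite checks against an independent
closed-form per-layer accounting. "64 temporal filters" is read as
F1 = 64 with kernel length 64; this is the only reading that lands at
about 62k parameters.

`build_eegnet_plus()` swaps the classifier head for two linear layers;
the 512-unit output of the first is the embedding `y` used to condition
the generative model, and dropping the second layer turns the model into
the EEG encoder.

Because no deep-learning framework is available to R in this toolchain,
the networks are implemented directly on BLAS matrix operations with
hand-written backward passes; analytic gradients of every layer are
verified against central finite differences in the test suite. For the
desk-scale training runs the suite uses a reduced filter bank (F1 = 8,
kernel 32, ~5.8k parameters): the 62k-parameter default is exercised for
construction, shape and counting, while recovery experiments train the
smaller variant, whose capacity is ample for the synthetic classes and
which keeps the full suite within a practical runtime. Problem sizes used
by the recovery analyses: 12 sessions x 600 trials for the high-SNR
subject (train 10 / validate 1 / test 1), trained 5 epochs at peak LR
1e-2; 3 sessions for the zero-SNR control, trained 2 epochs — training on
noise converges to chance regardless of budget.

Training uses AdamW (decoupled weight decay on weights only, not biases
or norm parameters) under a one-cycle schedule: cosine warm-up over the
first 30% of steps from max_lr/25, cosine annealing to max_lr/1e4. The
best-validation-epoch weights are retained. The hold-out split follows
the missing-trials rule: the session with the fewest dropped trials is
the test set (ties: lowest session index), the next-fewest is validation.
`grid_search()` retrains the winning configuration on train+validation
before the single test evaluation, and `cross_validate()` holds out each
non-test session once.

Model comparison uses the one-sided exact Wilcoxon signed-rank test
(exact null for n <= 25 without ties, tie-corrected normal approximation
otherwise; zero differences dropped — the classical treatment) with
Bonferroni correction of the family alpha. The point-biserial
correlation is implemented by its group-mean formula and is
algebraically identical to Pearson with 0/1 coding, which the tests
verify to 1e-12.

# The reconstruction pathway

The generative side is a deliberately small latent diffusion model:

* **Latent codec.** A plain convolutional autoencoder (two stride-2
  convolutions to a 4-channel latent at 1/4 resolution; 12x compression
  for 32x32 RGB inputs) trained on the stimulus set with MSE. A
  vector-quantized variant is out of scope at this scale; the plain
  codec is the default.
* **Denoiser.** A 2-level UNet with one cross-attention resolution:
  conv-in at full latent resolution, a stride-2 down block, additive
  time-step embedding (sinusoidal, MLP-projected), scaled-dot-product
  cross-attention with a residual connection at the low resolution,
  a mid convolution, nearest-neighbor upsampling with skip
  concatenation, and conv-out.
* **Conditioning.** The 512-d embedding is reshaped into M = 4 tokens of
  128 and mapped to token depth 32 by a 1x1 convolution (the projector
  `tau`); tokens feed the attention as keys and values. A second
  projector `sigma` maps the flattened tokens onto the time-embedding
  dimension and is *added* to the sinusoidal time embedding — the
  "double conditioning". A flag disables the `sigma` pathway to recover
  the single-conditioned objective.
* **Objective.** Standard noise prediction: draw t uniform on {1..T},
  eps standard normal, form `z_t = sqrt(ab_t) z + sqrt(1-ab_t) eps` and
  minimize `||eps - eps_theta(z_t, t, tau(y), sigma(tau(y)))||^2`. The
  schedule is linear beta from 1e-4 to 2e-2; `diffusion_schedule()`
  defaults to the customary T = 1000 steps, while the desk-scale
  analyses use T = 300 — a small un-normalized denoiser predicts noise
  far more faithfully per step on the compressed schedule, which is
  what the conditioning pathway needs to steer generation. Pretraining
  runs 1500 AdamW steps at peak LR 2e-3 with cosine decay to 10%; the
  decay matters, as the un-normalized net degrades late in training at
  a constant rate.
* **Sampler.** PLMS: deterministic DDIM-style transfer where the noise
  estimate is an Adams-Bashforth combination of buffered predictions
  (orders 1-4, warming up until four evaluations exist). For a denoiser
  whose output is independent of `z_t` and `t`, any number of steps
  collapses to the closed-form single-step solution, which the tests
  assert to 1e-10. The full-scale preset (250 steps, 256x256) exists in
  configuration; the desk-scale runs use 20-50 steps at 32x32.

Pretraining conditions the denoiser on fixed per-class anchor embeddings
(random 512-d vectors of norm sqrt(512)), standing in for the separate
conditioning context in which a full-scale model would have been
pretrained. Fine-tuning then swaps in EEG embeddings: only the EEG
encoder, the attention projections (W_Q, W_K, W_V and the output
projection) and the two projectors are updated; every other weight is
frozen and verified bit-identical afterwards. The encoder runs with
frozen batch-norm statistics during fine-tuning. The full-scale recipe
(LR 5e-6, 200 epochs) is kept in the documentation as configuration; the
desk-scale default is 150-300 steps at LR 1e-3.

## Evaluation

`n_way_top1()` implements the n-way top-1 protocol: per generated image
and Monte-Carlo trial, n-1 distractor classes are drawn uniformly
without replacement and the trial succeeds when the surrogate classifier
scores the true class above all distractors; chance is 1/n. The
best-of-5 statistic takes, per image, the sample with the highest n-way
accuracy among 5 generations with distinct seeds; mean-of-5 averages
them (best >= mean by construction). At desk scale the metric is 20-way
over the 20 synthetic classes (chance 5%), with the surrogate classifier
— a small CNN trained on the stimulus set with noise/brightness/blur
corruption so its scores stay informative on imperfect generations —
standing in for a pretrained vision transformer.

The null control extracts the 1-second inter-trial gray-screen windows
(which contain no evoked signal by construction), linearly upsamples
them from 250 to 500 samples (interpolation method is a flag), applies
channel-wise z-normalization, and runs the identical encoder-sampler-
metric pathway. Stimulus dependence of the reconstruction shows up as
the contrast between above-chance accuracy on real trials and
at-chance accuracy on the null.

One statistical point deserves care: when the comparison set size
equals the number of classes, the per-sample n-way accuracy reduces to
the top-1 indicator, and the best-of-5 statistic is a maximum — it has
positive selection bias even for a generator that carries no label
information (about `1 - (1 - 1/n)^5`, i.e. ~23% at n = 20). The
seen-class side of the contrast therefore uses best-of-5 as defined,
but the null control is compared to chance on the *mean*-over-samples
accuracy, whose expectation is exactly `1/n` whenever the pseudo-labels
are independent of the generations — which the gray-screen windows
guarantee by construction.

Desk-scale problem sizes for the reconstruction analyses: a 5-session
subject (3 train / 1 validation / 1 test), the encoder trained 8
epochs at peak LR 1e-2; denoiser pretraining 1500 steps; fine-tuning
400 steps at LR 2e-3 for the conditioning pathway (half that for the
encoder); 60 test trials (3 per class) and 20 inter-trial null windows,
each reconstructed 5 times with 20 PLMS sampling steps.

# Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; stage seeds are derived from one master seed.
  All generators and training loops are bit-reproducible.
* Pooling truncates a non-divisible time axis (125 -> 15 at pool 8),
  matching the parameter accounting.
* Zero-SD channels, empty splits, out-of-range trial indices, windows
  beyond the recording, and mismatched dimensions are hard errors with
  named messages; >50% dropped trials warns but returns.
* Softmax and cross-entropy are computed with max-subtraction and a
  1e-12 floor.
* Ties in `make_split` and `grid_search` resolve to the lowest index /
  smallest parameter count.

# Known limitations

The generator's class structure (distinct latencies, amplitudes,
topographies; hue-coded stimuli) is more separable than natural images
and real VEPs, so absolute accuracies here say nothing about human data.
Channels are independent under the null, so the inter-channel
correlation criteria are exercised mainly by crafted artifacts. The toy
denoiser has no normalization layers and a single attention resolution;
it is adequate for 4x8x8 latents but far from a production diffusion
backbone. Real-time (causal-filter) operation is explicitly out of
scope.
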