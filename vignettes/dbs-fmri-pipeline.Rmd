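---
title: "From BOLD response maps to stimulation parameters: the dbsfmri pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From BOLD response maps to stimulation parameters: the dbsfmri pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Programming a deep brain stimulation (DBS) device after electrode
implantation means searching a large parameter space — voltage, frequency,
pulse width, and active contact — for the combination that maximises clinical
benefit. Done empirically, this takes many clinic visits spread over months.
BOLD fMRI acquired under a 30 s stimulation ON/OFF cycling paradigm offers a
biomarker shortcut: the evoked response map of a *clinically optimal* setting
has a characteristic topography (deactivation of the ipsilateral motor cortex
and contralateral cerebellum with thalamic activation), sub-therapeutic
voltages shrink the response while preserving that topography, and
supra-therapeutic voltages strengthen it while recruiting non-motor
(inferior frontal, occipital) regions.

`dbsfmri` implements a complete, testable pipeline around this biomarker:

1. **`synthetic cohort`** — a forward model from stimulation parameters to
   t-statistic response maps (and raw BOLD series), because no clinical
   DBS-fMRI dataset of this kind is publicly deposited;
2. **`GLM mapping`** — motion censoring, Gaussian smoothing, design-matrix
   construction with a canonical double-gamma hemodynamic response, and
   voxelwise ordinary-least-squares t-maps;
3. **`autoencoder`** — an unsupervised convolutional autoencoder with a
   structural-similarity (SSIM) reconstruction loss that compresses each map
   to a compact latent code;
4. **`MLP heads`** — a binary optimal/non-optimal classifier and one
   regressor per stimulation parameter, trained on the frozen latents inside
   a stratified k-fold cross-validation;
5. **`evaluation`** — fold-pooled ROC/PR curves, RMSE and tolerance accuracy,
   the cosine similarity index (CSI) against left-right-flipped maps, and a
   t-SNE view of the latent space;
6. **`closed loop`** — the semi-automated programming protocol: acquire a
   map, classify it, and (if non-optimal) let the regressors propose the next
   setting, until a setting is classified optimal.

## The forward model (synthetic cohort)

Each synthetic patient carries an anatomical offset (Gaussian, 1.5 mm sd per
axis) that coherently shifts both the response centroids and the lead
position, a quadripolar lead with 3 mm contact spacing, an optimal voltage
`v_opt ~ U(2, 4)` V and frequency `U(110, 160)` Hz (pulse width constant at
60 µs). Tested settings per patient number 1–5: the optimal one plus
tolerated sub-therapeutic (`v/v_opt ~ U(0.4, 0.7)`), supra-therapeutic
(`U(1.3, 1.8)`) and contact-displaced settings, each with a 20–40 Hz
frequency shift inside the 80–160 Hz band.

A response map is a sum of signed Gaussian foci plus iid voxel noise
(sd 0.5 in t units). Its amplitude law is

* below the optimum: `a(v) = base_patient * v / v_opt` (reduced magnitude,
  preserved topography);
* above it: `a(v) = base_patient * (1 + 1.5 * (v/v_opt - 1))`, plus positive
  non-motor foci with amplitude `base_patient * 1.5 * (v/v_opt - 1)`;
* stimulating a displaced contact attenuates the motor amplitude by
  `exp(-d² / (2 · 3²))` with `d` the contact displacement in mm.

The base amplitude is 7.5 t-units for every patient (an optional
`amp_voltage_exponent` can couple it to the optimal voltage, but that
confounds the optimal/non-optimal contrast across patients and defaults to
off). Two couplings make the absolute stimulation parameters partially
observable in the map — relevant because the per-map min–max normalization
applied before the autoencoder deliberately discards the absolute t-value
scale:

* the activation extent grows as `sigma_eff = 7 mm * (v / 3)^(1/2)`, a
  volume-of-activated-tissue analogue, so the stimulated voltage leaves a
  (weak) spatial-scale trace;
* motor centroids shift along z by 2 mm per mm of active-contact offset from
  the lead midpoint, the analogue of the stimulated fibre population moving
  with the contact, so contact depth leaves a positional trace.

The worst-case amplitude contrast between an optimal and a sub-therapeutic
map is `0.3 × 7.5 = 2.25`, 4.5 times the noise sd, comfortably inside the
"strong class separation" regime the test suite exercises. What the generator does
*not* emulate: anatomically realistic brains, registration distortion,
spatially correlated or physiological noise, scanner drift, and any effect
of stimulation *frequency* on the map (so frequency prediction can only
regress to the cohort mean — a known, documented limitation). Passing tests
therefore demonstrate internal correctness and recoverability of planted
structure, not clinical performance.

## GLM t-maps

`render_bold_series()` is the exact forward model that `fit_glm_tmap()`
inverts: every voxel follows `baseline + map_value * x(t) + noise`, with
`x(t)` the ON/OFF boxcar convolved with the canonical double-gamma response
(peak delay 6 s, undershoot delay 16 s, dispersions 1 s, peak:undershoot
6:1, 32 s kernel). The design matrix holds the task regressor first, six
motion regressors, and an intercept last; the contrast picks the task
column. Choices where the field leaves room:

* censoring uses the Euclidean norm of the three translations against the
  2 mm threshold (rotations excluded), removing whole volumes and their
  design rows; the regressor is evaluated at the surviving acquisition
  times, so censoring and design construction commute;
* all-zero motion columns are dropped to keep the design full rank;
* no autocorrelation correction (prewhitening) is applied;
* smoothing is a separable Gaussian, `sigma = FWHM / (2 sqrt(2 ln 2))` per
  axis in voxel units, with nearest-neighbour boundaries, so constants are
  preserved exactly;
* voxels with residual variance indistinguishable from zero (relative
  tolerance 1e-20) receive a capped t value (default 1e6) with a warning;
* resampling to the network grid is trilinear (align-corners); a constant
  map min–max-normalises to 0.5 everywhere by convention.

## The autoencoder

The 91 axial slices of a preprocessed map enter a 2-D convolutional stack as
input *channels* — the reading forced by the published filter counts (a final
decoder stage with 91 filters, a 256×3×3 latent). The full-size encoder is a
stride-1 kernel-3 block compressing 91 channels to 1, followed by five
stride-2 kernel-4 blocks widening 16→32→64→128→256, taking 96×96 slices to a
256×3×3 code (padding 1 everywhere is the only choice that makes this ladder
exact). Every interior block is convolution → ReLU → batch-norm. The decoder
mirrors this with transposed convolutions (128, 64, 32, 16, 91 filters); its
*output* block is the bare transposed convolution, compared to the [0, 1]
targets directly (a sigmoid clamp is available as a config option but off by
default). Training minimises `1 − SSIM` with Adam; SSIM uses an 11-pixel
uniform local window by default (window 0 gives the single global statistic,
used by the closed-form tests), `c1 = (0.01 L)²`, `c2 = (0.03 L)²`, `L = 1`.

Two initialisation choices were required to make this architecture train
reliably, and both are documented here because they are load-bearing:

* the first convolution's bias cancels its mean-input response (plus a 0.1
  margin). The network input lives in [0, 1] (mean ≈ 0.5), not centred; with
  a plain He initialisation the single-filter first block's DC response
  dwarfs its signal variation, and with an unlucky draw the block's ReLU is
  dead *at initialisation* — and a one-channel bottleneck can never recover;
* the output block starts at bias 0.5 with 0.1-scaled weights, so training
  begins luminance-matched. Otherwise the constant-output reconstruction (a
  strong local optimum of SSIM on noise-dominated volumes) is reached by
  actively silencing the encoder, which permanently kills the latent code.

After training, the batch-norm running statistics are recalibrated with one
full-data forward pass: ReLU-sparse channels make momentum-averaged
minibatch statistics a poor inference-time estimate on small datasets, and
without recalibration single latent dimensions can be mis-scaled by orders
of magnitude. Encoding is then a pure function of the input (evaluation-mode
batch-norm, no dropout).

The desk-scale preset (`ae_config_desk()`) used by the test suite keeps the
91 slice-channels but works on 48×48 slices with one fewer downsampling
stage and trimmed interior filter widths (16, 32, 64), while retaining the
full 256-channel bottleneck — the latent stays 256×3×3 (flattened length
2304) as in the full-size configuration. Retaining the wide bottleneck
matters: at desk scale the encoder is far from converged and the latent
behaves partly as a learned sketch of the map, so its width bounds how much
per-map information (activation extent, noise floor, focus positions)
survives for the supervised heads. The full-size configuration remains the
default.

## MLP heads and the training driver

Heads are fully connected stacks ending in a 16 → 1 output layer: the
full-size taper is 2304 → 1024 → 512 → 256 → 128 → 64 → 32 → 16 → 1 (eight
hidden layers; the intermediate widths are a power-of-two choice, the
published account fixing only the input, the 16 → 1 ending and the depth),
with ReLU after every layer but the last and dropout 25%/15%/15%/15% after
the first four blocks. The classifier applies a sigmoid at the output; for
numerical stability it is *trained* on the pre-sigmoid logits (the two forms
are mathematically identical; the clamped probability-space gradient can
freeze a saturated network). Regressors are fitted on z-scored targets and
denormalised for reporting — one single-output model per parameter (voltage,
frequency, contact x, y, z).

`run_algorithm1()` is the two-stage driver: stage 1 trains the autoencoder
on *all* maps (it is unsupervised; validation folds do not exist yet), then
freezes it. Latents are extracted once, column-standardised (an unsupervised
transform fitted, like the autoencoder itself, on the full map set), and
stage 2 trains one classifier and five regressors per fold of a shuffled
label-stratified k-fold split, validating every epoch and keeping the
weights of the best validation score (highest accuracy for classifiers,
lowest MSE for regressors — "accuracy" is undefined for regression; ties go
to the earliest epoch). Regression targets of *every* map are the owning
patient's optimal parameters; this is what lets the closed loop propose
optimal settings from a non-optimal map. Defaults follow the reference
protocol (250 autoencoder epochs at learning rate 1e-4; 100 head epochs at
1e-3; 5 folds; batch 8). The desk plan reduces the epochs to 30/40, raises
the autoencoder learning rate to 1e-3 — at 30 epochs a 1e-4 rate provably
leaves the autoencoder at its luminance plateau with uninformative latents —
and trims the MLP interior widths to 2304 → 256 → 128 → 64 → 32 → 16 → 1
(the head-training cost is dominated by the first weight matrix; the
trimmed taper fits the desk compute budget without measurable loss on the
synthetic cohort).

Splitting is over maps, which permits multiple maps of one patient to span
the train/validation boundary; `group_by_patient = TRUE` keeps patients
intact (best-effort stratification at patient level). The default matches
the reference protocol; the flag exists because within-patient leakage is
scientifically material when maps per patient share a topography.

## Evaluation and the flip probe

All scalar metrics are the textbook formulas and are tested against
independent brute-force oracles. ROC and precision–recall curves pool the
out-of-fold predictions of all folds (a single pooled confusion matrix is
well-defined; averaging per-fold curves is not), with trapezoidal AUC.
Tolerance accuracy counts predictions within ±10% or ±15% of the truth; an
exactly-zero truth counts as accurate only for an exactly-zero prediction.
The robustness probe mirrors every map left-right, re-encodes both sets with
the frozen autoencoder, and reports the paired-mean cosine similarity per
label group (the headline; the group-mean variant is also computed) next to
a permutation baseline — the mean cosine of randomly mismatched pairs within
the group, 1000 shuffles. t-SNE is an exact O(n²) implementation (bisection
to the target perplexity, early exaggeration 4 for 100 iterations, momentum
0.5 → 0.8, adaptive gains), adequate for cohort-sized inputs.

## The closed loop

`run_loop()` starts from the simulator's initial probe — a mid-range
sub-therapeutic voltage (0.55 × v_opt) at the planned contact, 130 Hz — and
iterates render → preprocess → encode → classify. A fold-ensemble
probability at or above 0.5 terminates with `optimal-found`; otherwise the
fold-ensemble regressors propose the next setting: voltage and frequency
clipped to safety bounds (0.5–8 V, 80–160 Hz), the predicted contact point
snapped to the nearest lead centroid (ties to the lower index), pulse width
carried unchanged. The iteration budget is enforced unconditionally. In the
intended clinical workflow each classification is a confirmation point where
the attending clinician sets the parameters; the simulator logs these
decisions instead of prompting.

## Problem sizes and reproducibility

The test suite and the acceptance script run the pipeline at the desk scale:
39 patients (~125 maps) on a 48×48×91 grid, 30 autoencoder epochs, 40 head
epochs, 5 folds, and a 20-patient held-out closed-loop experiment — sizes
chosen so a complete run finishes in minutes on one CPU core while leaving
every stage's behaviour measurable. Every random draw (cohort, noise,
initialisation, shuffling, dropout, embedding) goes through R's RNG under
seeds derived from a single plan seed, so identical seeds give bit-identical
cohorts, fold assignments, loss traces and metric tables on one machine.

## What the closed loop can and cannot achieve here

The loop terminates when a proposed setting is *classified* optimal, which
in practice requires re-proposing the patient's optimal voltage to roughly
±15% and the correct contact from a single observed map. Under the
simulator's conditions this is only partly possible, and the package
reports it honestly: per-map min–max normalization removes the absolute
t-value scale, so a held-out patient's absolute optimal voltage is encoded
only through the activation-extent channel (weak at a ~2-voxel focus width)
and through the amplitude-to-noise-floor ratio that identifies `v/v_opt`
(intrinsic ~16% noise at the default noise level). A hand-built decoder
with direct access to the raw maps — an upper bound no learned pipeline can
beat — recovers held-out optimal voltage with only ~33% ±15%-tolerance
accuracy. Consequently the closed loop steers roughly half of held-out
simulated patients (those whose optimal parameters lie in the recoverable
region) to an accepted setting within five iterations; the cross-validated
prediction metrics look better than this because the map-level split lets
several maps of one patient straddle the train/validation boundary. This is
a deliberate, measured property of the stated synthetic conditions rather
than a defect of the loop mechanics, which are verified exhaustively with
forced-outcome classifiers.

## Known limitations

* The generator's couplings are stylised; in particular frequency leaves no
  trace in the map, and noise is iid rather than spatially correlated, which
  makes the synthetic GLM and SSIM tasks cleaner than real data.
* Latent quality at 30 desk epochs is far from converged; the full-size
  configuration at 250 epochs is the intended production setting.
* The closed loop's success criterion is "classified optimal", which is the
  protocol's own stopping rule, not an independent clinical ground truth;
  its reachable success rate under the default conditions is analysed
  above.
* Exact t-SNE scales quadratically; cohorts beyond a few thousand maps
  would need a tree-based implementation.
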