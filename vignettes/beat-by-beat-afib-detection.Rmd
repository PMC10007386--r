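---
title: "Beat-by-beat AFib detection: models, preprocessing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-by-beat AFib detection: models, preprocessing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Atrial fibrillation (AFib) alters the ECG in two ways: the RR-interval
sequence becomes irregular, and the waveform morphology changes — P-waves
disappear and a low-amplitude fibrillatory (f-) wave rides on the baseline.
Most automatic detectors use rhythm statistics computed over windows of many
beats, which costs latency. `beatae` instead classifies *individual
heartbeats* from a single ECG lead: each beat's fixed-length template is
compressed by an autoencoder into a small morphological code, optionally
joined by a single per-beat rhythm number (the LCSD), and classified by a
tiny feed-forward network with a few hundred trainable parameters.

## The models

All four network archetypes are dense feed-forward stacks built and trained
by the package itself (base matrix algebra, hand-derived backpropagation,
Adam optimisation):

* **AE** — undercomplete autoencoder, layers `input -> code -> input` with a
  tanh code layer and linear output, trained on mean squared error (MSE).
  The code width is 25% of the input width (75% compression), so a 150-sample
  template (600 ms at 250 Hz) maps to 38 features and a 180-sample template
  (300 Hz) to 45.
* **SAE** — the same architecture with an L1 activity penalty
  `lambda * mean(|code|)` on the code layer (default `lambda = 1e-4`),
  encouraging sparse codes.
* **SupAE** — supervised autoencoder: a sigmoid classifier head is attached
  to the code and the whole network minimises
  `w_rec * MSE + w_cls * BCE + lambda * mean(|code|)` jointly
  (defaults `w_rec = w_cls = 1`), so the code is shaped by both
  reconstruction and the NSR/AFib label.
* **MLP** — the classifier head on its own: `features -> 3 tanh units ->
  1 sigmoid unit`. In the two-stage pipeline it classifies the frozen SAE
  code; with zero hidden units it degenerates to logistic regression, used
  for the LCSD-only baseline.

The classifier head can receive *side features* appended to the code; the
package uses this for the LCSD column. The rationale for tanh/linear
activations is that inputs are standardized, so a linear reconstruction
output is natural and tanh keeps the code bounded. Weights start from a
seeded uniform distribution scaled by `1/sqrt(fan_in)`; biases start at 0.

### The LCSD rhythm feature

For R-peaks at times $R_1, \dots, R_N$ the Local Change of Successive
Differences of an interior beat $i$ is

$$\mathrm{LCSD}(R_i) = \frac{\left|(R_{i+1}-R_i) - (R_i-R_{i-1})\right|}
{\frac{1}{N-1}\sum_{j=1}^{N-1}(R_{j+1}-R_j)}, \qquad 1 < i < N.$$

It is dimensionless, non-negative, invariant under uniform time scaling and
defined per beat — the rhythm information it carries costs only the two
adjacent RR-intervals. Boundary beats are undefined and encoded as `NA`,
never as 0. The denominator always uses the *full detected R-peak series* of
the recording, not the set of templates that survive outlier rejection, so
removing a template never changes its neighbours' values. For long
multi-rhythm recordings the denominator scope is configurable
(`lcsd_scope`): `"portion"` (default for AFDB-like records; each same-label
interval is its own unit, matching the portion-wise evaluation protocol) or
`"record"` (natural for short single-label records). The definition leaves
this open; both are supported.

## Preprocessing chain

1. **High-pass FIR filter**, cutoff 0.5 Hz, windowed-sinc (Hamming) design,
   applied with group-delay compensation so R-peak times are unchanged.
   The kernel length is just under `5 * fs` taps: long enough that a
   0.2 Hz baseline drift is attenuated by more than 20 dB while a 5 s
   record can still be filtered; the taps are re-centred to put an exact
   null at DC. (A shorter, more conventional `3 * fs` kernel leaves ~18%
   of a 0.2 Hz drift in place, which is why the longer kernel is the
   default.)
2. **R-peak detection** in the Pan–Tompkins/Hamilton family: 8–20 Hz
   band-pass, differentiate, rectify, 80 ms moving average, adaptive
   signal/noise threshold with a 200 ms refractory period, followed by
   refinement of each detection to the absolute signal maximum within
   ±100 ms. Annotated R-peaks (when a database provides them) skip
   detection and are only refined (±50 ms), since provided annotations can
   be a few samples off the waveform maximum.
3. **Segmentation**: one template per R-peak, 200 ms before to 400 ms
   after (`pre = round(0.2 fs)`, `post = round(0.4 fs)` samples, R at
   0-based index `pre`). Beats whose window leaves the signal, straddles a
   rhythm boundary or lies in an `other`-labelled interval are dropped.
4. **Second-R-peak padding**: when the next RR-interval is shorter than
   the 400 ms post-window, the following beat's R-peak intrudes into the
   template; everything from 70 ms before that second peak (covering its
   Q-wave) to the end of the template is zeroed. The pad start uses
   round-half-even (`0.25 s * 250 Hz = 62.5 -> 62` samples after R); the
   operation is idempotent, and a pathological start before the beat's own
   R sample is clamped there with a warning. Only *trailing* intruders are
   padded; a leading intruder implies RR < 200 ms and such beats are left
   to the outlier filter.
5. **DMEAN outlier rejection**: per recording, a beat is discarded when its
   cosine distance to the recording's mean template exceeds a threshold
   (default 0.2). Zero-norm templates are always discarded. At most 30% of
   a recording's beats may be removed; beyond that only the worst are
   dropped. The multi-criterion rule the name originally refers to is
   deliberately reduced to its cosine-distance core, and the filter runs
   per recording (the natural unit for a template average).

## Training and evaluation protocol

* Standardization (templates and the LCSD column jointly) is fitted on
  training rows only; validation and test data reuse the training statistics.
  Constant features get their SD replaced by 1.
* Training data are balanced by undersampling the majority class down to the
  minority count (seeded, without replacement); test sets are never balanced.
* Splits are either **portion-wise** (a portion = a maximal same-label
  interval; for synthetic or short records, a record), stratified by class,
  80/20, or **patient-wise** (no patient on both sides; `round(0.8 * n)`
  patients train, e.g. 23 patients split 18/5).
* Optimisation: Adam (learning rate 1e-4, beta 0.9/0.999, eps 1e-8),
  mini-batches of 32, at most 2000 epochs with early stopping after 50
  epochs without a validation-loss decrease; the weights of the best
  validation epoch are kept. Cross-validation assigns the balanced training
  beats to seeded folds (10 by default); each fold serves once as the
  validation set and the fold run with the lowest validation loss is the
  selected model instance. Hyperparameters are not searched over folds;
  epochs are governed by early stopping within each fold.
* The operating threshold maximises Youden's J (sensitivity + specificity
  − 1) on the selected instance's validation fold — never on test data —
  with ties broken toward 0.5.
* Reported metrics: confusion counts, accuracy, precision, recall, F1 and
  AUC by the trapezoidal rule over the full ROC (exactly the pairwise
  concordance probability with ties counted 1/2). The LCSD statistic is
  validated by a Mann–Whitney U test (midrank ties, tie-corrected normal
  approximation with continuity correction) between the two classes'
  per-beat values; one test per dataset, no multiplicity correction.

## The synthetic generator

Every test runs on synthetic single-lead ECG built by the package: each
beat is a sum of Gaussian kernels for the P, Q, R, S and T waves
(Lead-I-like defaults: P 0.15 mV / −120 ms / 20 ms, Q −0.10 / −35 / 10,
R 1.0 / 0 / 12, S −0.20 / +30 / 10, T 0.30 / +250 / 50); AFib beats have
the P kernel removed and a 0.05 mV, 6 Hz sinusoidal f-wave added. RR models:
NSR ~ Normal(0.85 s, 0.02 s); AFib ~ Normal(0.65 s, 0.15 s) truncated to
[0.35, 1.4] s — overlapping rates but clearly different successive
differences. A short-RR AFib preset (floor 0.30 s) guarantees intruding
second R-peaks for the padding path. Noise defaults: 0.02 mV white noise
plus a 0.1 mV, 0.25 Hz baseline wander (below the 0.5 Hz cutoff, so the
filter removes it). Truncated-normal draws use the inverse-CDF so the
RNG stream length is input-independent and records are bit-reproducible
from their seed.

With `patients = k`, records of both rhythm classes are assigned round-robin
to one shared pool of `k` patients (as in paroxysmal-AFib Holter data, a
patient contributes both rhythms), and `patient_morph_sd > 0` draws an
independent log-normal scale *per wave and patient* (widths scale by the
square root). Per-wave scaling matters: a single per-patient gain is mostly
removed by standardization and produces no generalization gap, whereas
wave-shape differences — e.g. a patient with a congenitally small P-wave —
are exactly what makes unseen-patient morphology hard.

What the generator does **not** emulate: respiratory modulation, ectopic
beats, electrode artefacts, pathological QRS shapes, multi-lead geometry,
and within-record rhythm transitions (each synthetic record carries one
rhythm label). Passing tests therefore demonstrate the correctness of the
pipeline's mechanics and its behaviour under controlled rhythm/morphology
differences — not clinical performance on recorded data, where mislabelled
portions, noise bursts and pathological waveforms lower all scores
substantially.

## Problem sizes and numerical choices in the shipped tests

The test-suite benchmarks are deliberately desk-scale and fully seeded:

* The held-out-performance benchmark uses 30 records per class, 35 s each
  at 250 Hz (≈ 2300 beats after preprocessing, ≥ 1000 per class), 2-fold
  cross-validation, and training capped at 150 epochs (patience 25) — the
  networks are small enough that convergence on this separable problem
  happens well before the cap.
* The model/feature-ordering study runs a 2×2 grid (AE vs SupAE, with and
  without LCSD) over 3 fixed seeds at 10 records per class with 0.06 mV
  white noise. The added noise is the point: under the clean defaults every
  cell saturates at F1 ≈ 1 and orderings would be decided by single-beat
  flips. The patient-vs-portion comparison enables per-wave patient offsets
  (SD 0.4) and uses morphology-only models, because the rhythm feature
  transfers across patients and would mask the morphology generalization
  gap that the comparison is about. Conclusions are by majority vote over
  the 3 seeds.
* Gradient checks run in double precision against central differences
  (step 1e-5, max relative error 1e-4) for all four archetypes, including
  the L1 and joint-loss terms.
* Probabilities are clipped to [1e-12, 1 − 1e-12] inside the binary
  cross-entropy; the sigmoid + BCE gradient is fused analytically, so no
  clipping enters the backward pass.

## Known limitations

* The exact layer widths behind the reference models' reported parameter
  counts are not recoverable; the presets here land in the same
  low-hundreds range (e.g. 38-wide code for a 150-sample template) and all
  widths are configuration, not constants.
* The WFDB support is a minimal subset (format 16, single- or multi-channel
  signals, MIT annotation files with aux strings); it is sufficient for
  AFDB-style records and for the package's own exporter, not a general
  WFDB implementation.
* Training is plain R matrix algebra — ample for the desk-scale benchmarks
  and for the low-hundreds-of-parameters models the method targets, but not
  tuned for millions of beats.
* The classifier is strictly binary (NSR vs AFib); atrial flutter,
  junctional rhythms and noisy segments are mapped to `other` and excluded,
  so real-world deployment would need an upstream quality/rhythm gate.
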