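---
title: "Detecting tactile error-related potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tactile error-related potentials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(errpipe)
```

## The problem

A person wearing an actuated arm orthosis can feel, purely through touch and
proprioception, when the device briefly moves against their intended movement.
That percept elicits an error-related potential (ErrP): a stereotyped,
fronto-central EEG deflection. A classifier that detects single-trial ErrPs
gives a robotic device an implicit error signal from its user's brain.
`errpipe` implements the complete analysis for this setting — session
simulation, EEG synthesis, preprocessing, Riemannian tangent-space feature
extraction, class-weighted linear classification, cross-validated and
cross-scenario evaluation, and ERP averaging — so the pipeline can be
exercised and validated end-to-end on data with known ground truth.

## The experimental design being emulated

One *set* consists of 32 orthosis movements alternating flexion and
extension (16 each). Errors — 0.25 s counter-movements — are planted in
exactly 6 of the first 30 movements, drawn uniformly without replacement; the
two appended final movements are always error-free, so each set has 26
correct and 6 incorrect trials. Ten sets per simulated subject give 260
correct and 60 incorrect trials. Error events are marked `S96`; correct
trials receive an `S48` probe marker 0.5 s after movement onset (the probe
latency is not pinned down by the design, so it is a configurable constant).

The design states that errors occur "randomly with a probability of 20%"
*and* that each set contains exactly 6 errors in 30 eligible movements;
sampling exactly `round(0.2 * 30)` error slots uniformly honours both
statements. Flexion/extension ordering within a set is not specified beyond
the 16/16 count; strict alternation starting with a flexion is used (a
physically plausible flex/extend cycle) and is configurable. Trial durations
are drawn from a normal law with mean 6.857 s and SD 0.309 s (the reported
across-subject distribution of median trial durations), and inter-trial
intervals uniformly from 0.5–1 s, which puts a set's duration in the 4–5
minute band on average. The error onset within a movement is only
characterized by mean angular positions (−42° for flexion, −58° for
extension, with the fully extended arm at −10°); the onset is drawn uniformly
in the middle 60% of the movement and the angle from a normal law (SD 3°)
truncated to (−90°, −10°).

### Behaviour model

Three response scenarios are modelled:

* **ButtonPress** — the subject presses a button on error detection.
  Reaction times are log-normal with median 0.746 s (the reported mean of
  per-subject median RTs) and log-scale spread 0.25; log-normality is a
  modelling choice (RTs are positive and right-skewed; the family itself is
  not reported).
* **DelayedButtonPress** — the press is deliberately delayed; the log-normal
  is re-located so its *mean* is 4.54 s, the reported mean delayed RT.
* **NoButtonPress** — no motor response exists; trial labels come from the
  markers alone, so misses and false presses are undefined in this scenario.

Misses occur with probability 0.0188 per error trial and spurious presses
with probability 0.0083 per correct trial (the reported FN/FP percentages).
False-press timing within a trial is not reported and is drawn uniformly.

## The synthetic EEG

`synthesize_recording()` renders an additive forward model at 500 Hz:
background noise plus template × topography contributions at event times.

* **ErrP template** (at each `S96` onset): three Gaussian bumps — a
  negativity peaking at 250 ms (5 µV, SD 40 ms), a positivity at 400 ms
  (8 µV, SD 70 ms), a second negativity at 600 ms (4 µV, SD 50 ms) —
  reproducing the reported tri-phasic interaction-ErrP morphology.
* **ErrP topography**: fronto-central, maximal at FCz (gain 1.0) and Fz
  (0.9), smaller at Cz (0.6) and Pz (0.3), so averaged amplitudes are larger
  fronto-centrally than centro-parietally.
* **Motor template** (at each button press): a biphasic negative-then-
  positive bump (4 µV / 3 µV), right-central maximum at C4 — contralateral
  to the left (button) hand. Its exact shape is not reported; this is the
  package's own construction.
* **Noise**: per channel, Gaussian white noise (SD 3 µV) plus 1/f-shaped
  noise (6 µV) and an optional narrow-band oscillation. The ongoing-EEG
  characteristics of the original recordings are not reported; these
  amplitudes were calibrated once so that the full pipeline operates in the
  high-performance regime (pooled balanced accuracy ≈ 0.95–1.0 at the
  default 10-set, 8-channel configuration) and then frozen. The 1/f shaping
  runs in the frequency domain at the next 2-3-5-smooth length so synthesis
  stays O(n log n).

Two montages are built in: the full 64-name extended 10-20 layout and a
reduced 8-channel fronto-central montage (Fz, FCz, Cz, Pz, C3, C4, F3, F4)
for fast experimentation. Synthesized data represent recordings referenced at
FCz, but FCz is kept as a data channel so ERP re-referencing needs no channel
reconstruction.

What the generator deliberately does *not* emulate: ocular/muscle artifacts
(the corresponding ICA cleaning step is therefore omitted from ERP
averaging), inter-subject variability in ErrP morphology and topography,
non-stationarity across sets, and volume-conduction correlation structure in
the noise. Passing tests on this generator validate the pipeline's
correctness and its sensitivity/specificity mechanics — they do not certify
classification numbers on real human EEG.

## Preprocessing

Epochs span [−0.1, 1.0) s around each `S48`/`S96` marker (550 samples at
500 Hz; half-open windows everywhere, marker at relative time 0). Epochs with
behaviourally invalid responses (missed errors, spurious presses) are
excluded with a logged reason; in NoButtonPress the exclusion is an identity
pass since no responses exist to validate. Then, in this order: per-channel
zero-meaning, decimation to 50 Hz, 0.1–12 Hz band-pass.

Numerical choices: the anti-alias filter is a 4th-order Butterworth low-pass
at 0.4 × the target rate; the band-pass is a cascade of a 2nd-order high-pass
and 4th-order low-pass. All filters are applied forward-backward
(zero-phase), so ERP latencies shift by less than one sample — a property the
tests assert. The decimation grid is aligned so relative time 0 stays a
retained sample.

The stated epoch window is 1.1 s but the feature stage uses 50 samples per
channel; the package resolves this by keeping the [−0.1, 0) prefix for
baseline use and cropping features to the half-open [0, 1.0) s window, which
holds exactly 50 samples at 50 Hz. (An alternative reading — different
decimation phase — cannot be excluded; this choice is recorded here as an
assumption.)

## Feature extraction

The feature chain, fitted strictly on training data:

1. **xDAWN spatial filtering** to 7 pseudo channels. The epoch-based variant
   is implemented: filters are generalized eigenvectors maximizing the ratio
   of ErrP-evoked energy `P P' / T` (with `P` the ErrP-class mean epoch) to
   the average per-epoch covariance, solved by whitening followed by a
   symmetric eigendecomposition. The original continuous-signal least-squares
   construction is approximated by this standard epoch formulation for
   pre-cut epochs. Rank-deficient covariances receive a documented diagonal
   jitter with a warning.
2. **Extended epochs**: the filtered ErrP-class prototype (7 × 50) is stacked
   over each filtered epoch (7 × 50), giving 14 × 50 super-trials whose
   covariance captures epoch–prototype co-variation. The prototype uses the
   ErrP class only, matching the class whose SNR xDAWN maximizes.
3. **Ledoit–Wolf shrinkage covariance** (14 × 14 over the 50 samples):
   `C = (1−λ)S + λνI` with the analytic shrinkage intensity; guarantees
   positive-definite estimates despite 50 samples for 105 free parameters.
4. **Fréchet (geometric) mean** of the training covariances as tangent-space
   reference: fixed-point iteration `G ← G^{1/2} exp(mean log(G^{-1/2} C_i
   G^{-1/2})) G^{1/2}`, initialized at the arithmetic mean, tolerance 1e-8
   (Frobenius norm of the mean log), at most 50 iterations; non-convergence
   warns rather than errors. Matrix logs/exponentials use eigendecompositions
   with an eigenvalue floor of 1e-12.
5. **Tangent projection** `log(ref^{-1/2} C ref^{-1/2})` and **Mandel
   vectorization**: 14 diagonal entries plus 91 upper-triangle entries
   (row-major) scaled by √2 — 105 dimensions whose Euclidean norm equals the
   matrix Frobenius norm, hence the affine-invariant Riemannian distance to
   the reference.
6. **Per-dimension standardization** with training statistics.
   (Whether the original normalization was per-dimension standardization or
   vector-norm scaling is not stated; standardization is assumed.)
   Zero-variance dimensions keep scale 1 with a warning.

The fitted extractor records which cross-validation folds it may transform;
in strict mode (used throughout the tests) transforming any other fold is an
error. This is a mechanical guard against train/test leakage.

## Classification and evaluation

A linear SVM on the 105-dimensional features with class weights
NoErrP:ErrP = 1:2 (ErrP is the positive class), cost selected from
{10⁻⁶, …, 10⁻¹, 1} by an inner stratified 5-fold loop maximizing pooled
balanced accuracy; ties go to the smallest cost (strongest regularization —
the tie rule is not stated in the design and is fixed here). The outer loop
is a stratified 10-fold cross-validation; the whole feature extractor is
refitted inside every outer-training set (and inside every inner fold), so
no spatial filter, reference point or normalization statistic ever sees test
data. A `concat_first` flag reproduces the variant in which features are
fitted once on all concatenated data — the design text is ambiguous on this
point — but it is clearly labelled as leaky and not used in any reported
number. The inner selection metric (balanced accuracy) matches the headline
metric; it is likewise an assumption, not a stated fact.

Metrics: balanced accuracy (mean of TPR and TNR), TPR, TNR, precision and
the F1 measure of the positive class, per fold and pooled over the outer
confusion counts. Ratios with zero denominators are reported as `NA` with a
flag, never as 0.

**Transfer designs.** A pipeline fitted on ButtonPress data (extractor state
and classifier frozen) is evaluated on NoButtonPress or DelayedButtonPress
synthesis. In the delayed scenario the motor potential falls ~4.5 s after
the error, outside the [0, 1) s feature window, so a classifier that
exploits motor activity must lose sensitivity — the package's tests check
exactly this directional effect, not any numeric value, since the magnitudes
on real data depend on subject-specific factors the generator does not
model. Three design choices make the effect measurable: the synthesis for
this experiment emphasizes the motor potential (10/8 µV) so it actually
carries class information; the template scale is set to 0.5 of the
calibrated default so in-scenario sensitivity is off ceiling (at the default
scale the ErrP alone saturates the classifier and the motor contribution is
invisible in the metrics); and the two test scenarios are generated as a
matched pair — identical schedules and noise realizations, differing only in
response behaviour — so the comparison is within-noise rather than between
independent corpora. With the default reaction-time median of 0.746 s only
the early part of the motor potential falls inside the [0, 1) s feature
window, which bounds how much sensitivity the delayed scenario can remove.

## Problem sizes used in the shipped checks

The package's acceptance checks run a 10-set (320-trial) subject on the
8-channel montage for the headline cross-validation, a 10-set pure-noise
(template scale 0) subject for the chance-level guarantee, a 4-level
template-scale sweep at 5 sets per level for monotonicity, 6 + 3 + 3 sets
for the transfer comparison at scale 0.5, four 2-set subjects on the full
64-channel montage for grand-average morphology, and ~10⁴ trials for
behavioural-rate recovery. These sizes were chosen to keep the full
validation suite in the minutes range on a single CPU while leaving every
statistical check well-powered.

## Known limitations

* The synthetic generator's stereotypy means classification numbers here are
  upper bounds of mechanism, not predictions for human EEG.
* The xDAWN implementation is the epoch-based approximation, not the
  continuous-signal least-squares construction.
* Only the affine-invariant metric is implemented (no log-Euclidean/Bures
  alternatives), and no cross-session Riemannian alignment.
* File I/O implements one frozen BrainVision-style dialect (multiplexed
  little-endian float32, 1-based marker samples), not the full vendor header
  vocabulary, and no EDF/BDF.
* ERP averaging omits ICA artifact removal, which the original plotting
  pipeline used; synthetic data contains no artifacts to remove.
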