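# errpipe

Detection of **tactile error-related potentials (ErrPs)** — the stereotyped
fronto-central EEG deflection a person produces when they *feel* a wearable
robot misbehave — with a fully simulated, fully reproducible analysis
pipeline. The package is aimed at brain–computer-interface researchers who
want a tested, end-to-end reference implementation of the
xDAWN + Riemannian-tangent-space + weighted-linear-SVM classification chain,
exercised on synthetic EEG with known ground truth.

## What it implements

**The experiment being emulated.** A subject wears an actuated arm orthosis
that alternates flexion and extension movements, 32 movements per set.
In exactly 6 of the first 30 movements the orthosis briefly (0.25 s) moves
against the intended direction; the subject presses a button on detecting the
error (or withholds / delays the press in two control scenarios). Ten sets
per subject give 260 correct (`S48`) and 60 incorrect (`S96`) trials.

**The classification chain.** Epochs `[-0.1, 1)` s around each event marker
are zero-meaned per channel, decimated to 50 Hz and band-passed 0.1–12 Hz.
On training data only, the pipeline fits:

1. an **xDAWN** spatial filter bank (7 pseudo channels) maximizing the
   ErrP-class evoked signal-to-noise ratio;
2. **extended epochs** `[P; X] ∈ R^{14×50}` stacking the class prototype *P*
   over each filtered epoch *X*;
3. **Ledoit–Wolf** shrinkage covariance `C = (1−λ)S + λνI` per epoch
   (guaranteed SPD);
4. the **Fréchet (geometric) mean** `G = argmin_G Σ_i δ²(G, C_i)` of the
   training covariances under the affine-invariant metric
   `δ(A,B) = ‖log(A^{-1/2} B A^{-1/2})‖_F`;
5. the **tangent-space projection** `S_i = log(G^{-1/2} C_i G^{-1/2})`,
   **Mandel-vectorized** to 105 dimensions (off-diagonals × √2, so the
   Euclidean norm equals δ), then per-dimension standardization;
6. a **linear SVM** with class weights NoErrP:ErrP = 1:2, cost selected from
   `{10⁻⁶, …, 1}` by inner stratified 5-fold cross-validation.

Evaluation is a stratified 10-fold outer cross-validation with everything —
spatial filters, reference point, normalization, cost — refitted inside each
outer training fold, plus cross-scenario transfer designs (train on
ButtonPress, test on NoButtonPress / DelayedButtonPress). The headline metric
is the balanced accuracy `bACC = (TPR + TNR)/2` with ErrP as the positive
class.

## Worked example

```r
library(errpipe)

# one simulated subject: 10 sets, button-press scenario
schedule <- generate_subject_sessions(n_sets = 10, seed = 101)
outcomes <- simulate_behavior(schedule, behavior_model("ButtonPress", seed = 7))
summarize_behavior(outcomes)
#> # A tibble: 1 × 7
#>   n_error n_correct  n_fn  n_fp rt_median fn_pct fp_pct
#>     <int>     <int> <int> <int>     <dbl>  <dbl>  <dbl>
#> 1      60       260     2     5     0.814   3.33   1.92

# synthesize continuous EEG (8-channel montage), preprocess, cross-validate
recordings <- synthesize_session(outcomes, synth_config(), seed = 5)
epochs <- segment_epochs(recordings) |>
  exclude_behavioral_errors(outcomes) |>
  preprocess_epochs()
epochs
#> <errp_epochs> 313 epochs x 8 ch x 50 samples @ 50 Hz, window [0, 1);
#>   58 ErrP / 255 NoErrP; steps: segment -> exclude -> zero_mean ->
#>   decimate_50 -> bandpass_0.1_12 -> crop

cv <- nested_cv(epochs, cv_plan(seed = 42))
cv
#> <errp_cv> 10-fold nested CV, pooled bACC 0.991 (TPR 0.983, TNR 1.000)
#>   over 313 epochs
```

The behaviour summary shows the simulated subject missed 2 of 60 errors and
false-pressed on 5 of 260 correct trials, with a median reaction time of
0.81 s — one draw from the configured behaviour model (miss rate 1.88%,
false-alarm rate 0.83%, median RT 0.746 s). The cross-validation report pools
the outer-fold confusion counts: at the calibrated default signal-to-noise
ratio the pipeline recovers the planted ErrPs almost perfectly (bACC 0.99).
`tidy(cv)` gives per-fold metrics and the selected cost; `glance(cv)` the
pooled one-row summary; `autoplot()` methods plot CV metrics and averaged
ERPs.

A one-call driver runs the whole thing — simulation, synthesis, a write/read
round trip through the BrainVision-style file triad, preprocessing, and
evaluation — from one config and master seed:

```r
res <- run_experiment(experiment_config(scenarios = c(ButtonPress = 10), seed = 1))
```

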