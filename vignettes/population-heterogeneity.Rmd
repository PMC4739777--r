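---
title: "Population heterogeneity analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population heterogeneity analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

During a visual go/no-go detection task, the same weak grating sometimes is
and sometimes is not detected. Which aspect of the momentary cortical
population state distinguishes the two? The classical candidate — a higher
mean population rate on detected (hit) trials — turns out to be a weak
single-trial correlate. `hetpop` implements an alternative per-trial
statistic, *population heterogeneity*: the degree to which neurons in the
population are activated *dissimilarly* on one trial, together with the
comparator metrics, decoders and geometric analyses needed to test whether
heterogeneity carries detection-related information that the mean does not.

## The heterogeneity metric and its multidimensional twin

Trial responses are the mean dF/F0 per neuron over the stimulus analysis
interval, collected into an n-neurons-by-T-trials matrix R. Each neuron is
z-scored over all trials (sample SD):

$$Z_{i,t} = (R_{i,t} - \mu_i)/\sigma_i.$$

For trial $t$, the heterogeneity matrix holds absolute pairwise differences
$H_t = |z_t - z_t^\top|$, and the scalar heterogeneity is the mean over the
$n(n-1)/2$ unique pairs:

$$h_t = \frac{\sum_{i<j} H_{t,i,j}}{n(n-1)/2}.$$

High $h_t$ means the population was activated unevenly — some neurons far
above their personal average, others far below — regardless of the overall
level. The implementation uses the sorted-vector identity
$\sum_{i<j}|x_i-x_j| = \sum_j (2j-1-n)\,x_{(j)}$, which is exactly the pair
loop at $O(n\log n)$ cost; tests verify equality with the brute-force
double loop.

The multidimensional variant treats a trial's population vector as a point
in n-dimensional response space and measures its Euclidean distance to the
all-equal ("main") diagonal, $\sqrt{\sum_i (r_i - \bar r)^2}$. On z-scored
responses the two definitions correlate at $r > 0.9$ across trials (checked
by a test and recomputed by the acceptance script), so geometric analyses
(mirroring, removal) can work with the distance-to-diagonal form.

## The analysis pipeline

The stages, each an exported function family, are:

1. **Preprocessing** — sliding-baseline dF/F0 (per frame, baseline = mean
   of the lowest 50% of raw fluorescence in a centred 30-s window),
   optional neuropil regression `F - r·F_neuropil`, soma/neuropil
   discriminability QC (`D_r = F_soma/(F_soma+F_neuropil)`, flagged when
   below 0.5 for more than 1 s), trial extraction with a 150-ms fast-lick
   exclusion and miss-duration matching (each miss analysed over a duration
   drawn from the same-contrast hit reaction-time distribution, so hits and
   misses have equal signal-to-noise), z-scoring, and preferred-orientation
   assignment with a block-consistency filter (rejected when more than 1/3
   of repetition blocks disagree with the modal preference).
2. **Metrics** — heterogeneity (both forms), mean dF/F0, the per-trial
   Pearson-like correlation (mean and SD of pairwise z-score products),
   variance, sparseness (kurtosis), sliding-window correlations, and
   frame-resolved timecourses.
3. **Hit modulation** — each neuron's hit-trial response z-scored against
   same-orientation-and-contrast misses; the matrix decomposed into
   neuron-identity and trial-fluctuation approximations with R² against
   1000-iteration shuffle nulls.
4. **Detection statistics** — pooled-SD Cohen's d and rank-statistic ROC
   AUC per contrast, heterogeneity-vs-reaction-time regression, 10–90%
   rise times, pre-stimulus predictability (the leave-one-out δ statistic),
   inter-trial pattern consistency against per-neuron trial shuffles,
   orientation-averaged noise correlations, Clopper–Pearson behavioural
   intervals, Benjamini–Hochberg FDR.
5. **Decoding** — leave-one-out Gaussian naive-Bayes decoders (uniform
   priors, log-space likelihoods, SD floor 1e-6): stimulus presence from
   the preferred population (0% vs 100% models, so test contrasts are
   automatically cross-validated), 4-way orientation per contrast, 21-way
   stimulus type, and single-trial predictive decoding of the upcoming
   response type with the angular accuracy index.
6. **Geometry** — inter-trial distances, mirroring across the diagonal
   (`r' = 2\mu_r - r`), removal of mean and/or heterogeneity, and hit/miss
   decoding on each variant.

## The synthetic session generator

No recordings are distributed with the package, so `generate_session()`
emulates the study design well enough that every analysis runs and the
pipeline's detectors can be validated by parameter recovery:

* **Task structure**: 8 drifting-grating directions × 6 contrasts
  (0, 0.5, 2, 8, 32, 100%), each condition once per randomised 48-trial
  block (default 8 blocks), stimulus window up to 3 s, inter-trial interval
  uniform in 10–12 s, 80 neurons at 25.4 Hz.
* **Tuning**: von-Mises orientation tuning on the doubled angle
  (concentration 1.5) and Naka–Rushton contrast gain (c50 = 8%, exponent
  1.2) — the minimal standard forms reproducing orientation selectivity
  and contrast monotonicity.
* **Behaviour**: response probability is a logistic function of
  log2-contrast (threshold 2%, slope 1 per octave) with a 10% lapse and
  15% false-alarm rate, giving graded hit/miss mixtures at the test
  contrasts; reaction time = 1.6 s − 0.7 s × contrast drive − 0.25 s ×
  arousal + exponential jitter (mean 0.25 s), truncated to (0, 3] s.
* **Arousal**: a standardised AR(1) latent (coefficient 0.5) across trials
  that shortens reaction times and scales pre-stimulus per-neuron activity
  dispersion (log-scale gain 0.5 around a 0.15 dF/F offset SD), so
  pre-stimulus heterogeneity — but not the pre-stimulus mean — predicts
  fast responses.
* **Hit structure**: per-trial per-neuron multiplicative gains are
  log-normal with mean exactly 1; their log-scale spread is 0.5 on hits
  versus 0.15 on misses. Gains act on baseline-plus-evoked drive (a
  0.12 dF/F spontaneous baseline), so the gain-spread difference raises
  heterogeneity at every contrast while leaving the expected population
  mean unchanged. Hits additionally receive a small additive population
  boost (0.002 dF/F) and a fixed zero-mean hit-pattern vector (amplitude
  0.25), which makes hit activation patterns partially consistent across
  trials. A log-normal (rather than truncated-normal) gain is essential:
  a truncated gain has expectation above 1 and would leak a spurious hit
  effect into the population mean.
* **Shared variability**: a per-trial common multiplicative gain (SD 0.2)
  scales the whole population's evoked response independently of outcome,
  emulating global cortical rate fluctuations. This is what makes the
  population mean a *noisy* single-trial readout — without it, even a tiny
  additive hit boost would be detectable far beyond what cortical data
  support, and the dissociation between heterogeneity and mean dF/F would
  not be reproduced.
* **Observation model**: drive is convolved with a unit-gain single
  exponential (τ = 0.7 s, an OGB-like timescale; linear, no saturation,
  preserving trial-mean ordering), scaled onto per-neuron baselines around
  100 a.u., and observed with 3% additive noise. Neuropil annuli (dimmer
  than somata, so the discriminability QC behaves as in stable
  recordings) share a slow background plus a bleed of the mean population
  signal; each soma picks up the neuropil's fractional signal with a
  per-neuron contamination ratio uniform in [0.1, 0.6]. Deep pre-stimulus
  dips still push a handful of neurons per session below the
  discriminability threshold for more than a second, so the QC stage has
  realistic flags to report.

`synth_config_null()` removes every hit/arousal effect (equal gain
spreads, no boost, no pattern, no arousal coupling); the calibration suite
requires all detectors to sit at chance on such sessions.

What the generator does *not* emulate: stimulus-driven changes in
noise-correlation structure, indicator saturation and nonlinearity,
slow drift and z-motion, locomotion/licking artefacts, and any realistic
laminar or cell-type structure. Passing the recovery suite therefore shows
the *estimators* detect the effects they target at realistic effect sizes
and sample sizes — it does not validate the biological claims on real data.

## Numerical and design choices

* **Frame indexing** is 0-based with half-open intervals `[onset, offset)`;
  unambiguous interval arithmetic.
* **Sample SD (n−1)** in all z-scores and the hit-modulation denominators.
* **Baseline window truncation**: the sliding dF/F0 window is truncated at
  recording edges (never reflected), and "lowest 50%" uses
  `k = max(1, floor(m/2))` values of an m-frame window.
* **z-score scope**: global (over all trial types) by default; a
  per-contrast scope is implemented and tested because contrast-stratified
  hit/miss comparisons are also reported that way in the literature.
* **Argmax ties** in preferred-orientation assignment break toward the
  lowest orientation; fast/slow median ties assign the median trial to
  slow; presence-decoder likelihood ties decode "absent". All
  deterministic and conservative.
* **Kurtosis** is the raw fourth standardised moment (Gaussian → 3).
* **Sliding-window kernel**: a Gaussian with FWHM equal to the 1.0-s time
  scale, truncated and renormalised at trial edges — a transparent stand-in
  for wavelet-based sliding correlation at the same time scale.
* **Hit-modulation "both" approximation** is the literal sum of the two
  marginal-mean matrices even though this double-counts the grand mean; a
  grand-mean-corrected variant is available behind
  `center_grand_mean = TRUE`. The per-neuron modulation test is a
  two-sided one-sample t-test (neurons may be up- or down-regulated).
* **Shuffle nulls** permute neuron identities within trials, trial
  identities within neurons, or (for "both" and for the significant-neuron
  fraction) the full matrix; 2-SD exceedance of the shuffle distribution is
  the significance criterion.
* **Decoders** use uniform class priors and leave-one-out cross-validation
  everywhere, including the 0%/100% anchor trials of the presence decoder,
  to avoid training on the test trial.
* **Degenerate inputs**: zero-variance neurons are dropped from z-scoring
  with a warning; trials exactly on the response-space diagonal are dropped
  from heterogeneity removal; likelihood SDs are floored at 1e-6; δ is 0 by
  convention when both distances vanish.
* **RNG**: every stochastic analysis step (miss-duration matching, shuffle
  nulls) draws from a sub-stream derived from the analysis seed and
  restores the caller's RNG state, so stages are reproducible in isolation
  and full reports are deterministic given one seed.

Open points resolved as package choices: preferred-orientation argmax
pools all nonzero contrasts; block-consistency compares each block to the
*modal* block preference; hit-modulation miss statistics pool all blocks;
pattern-consistency group statistics pool the test contrasts; session-level
predictability points are per-repetition-block means (the replicate unit
available within one session); comparator metrics (variance, kurtosis) are
computed on z-scored responses by default with raw dF/F available.

## Problem sizes

The test suite and acceptance script run everything on synthetic data at
the study's native scale (80 neurons, 8 blocks, 384 trials, ≈ 84 minutes
of simulated recording) for single-session analyses, and at 40 neurons ×
4 blocks for the 20-seed null-calibration sweep; Monte-Carlo blocks use
20 seeds. These sizes give the recovery and calibration checks comfortable
statistical margins while keeping a full run in the minutes range on one
core.

## Known limitations

* Session-level (not animal-level) inference: the package analyses one
  session at a time; across-animal meta-statistics (t-tests over per-animal
  values with FDR/Holm correction) are provided as helpers
  (`holm_slope_test`, `fdr_correct`) but the repository's drivers
  demonstrate them on repetition blocks of a single synthetic session.
* The sliding-window correlation is a Gaussian-kernel approximation, not a
  wavelet construction.
* The hit-modulation decomposition's "both" R² inherits the grand-mean
  double count of its definition; use the centred variant for comparisons
  across matrices with large grand means.
* Heterogeneity estimates are sensitive to the analysis-interval duration
  through noise averaging; the miss-duration matching controls this
  between outcome groups but not between contrasts.
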