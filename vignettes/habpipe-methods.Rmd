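---
title: "Methods: spectral, time-frequency, coherence and source analysis of deep-brain LFP with cortical sensor arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral, time-frequency, coherence and source analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`habpipe` implements a complete analysis chain for experiments in which
local field potentials (LFPs) from deep-brain (DBS-electrode) contacts —
here, the habenula — are recorded simultaneously with a cortical
sensor array (MEG-like) while subjects view emotionally valenced
pictures. The scientific questions the chain answers are:

1. Which oscillations are present in the habenular LFP at rest, over and
   above the aperiodic 1/f-like background?
2. How does stimulus-locked band power change with the emotional valence
   of the stimulus, in the LFP and over the cortical sensors, and is that
   change phase-locked (evoked) or not (induced)?
3. Does cortico-habenular coupling (cross-trial coherence) change after
   stimulus onset, and where in the head does it localize?
4. Are the observed modulations explained by stimulus valence or by
   arousal, which co-varies with valence?

No public recordings exist for this paradigm, so the package ships a
calibrated synthetic-data generator that reproduces the design and the
statistical structure the analysis assumes. Every stage is tested against
that generator and against brute-force oracles.

# The synthetic generator

`sim_config()` fixes the study conditions:

* **Paradigm.** Epochs of −2.5 to 4.5 s around picture onset (1 s
  fixation, 2 s picture, 3–4 s blank), three valence conditions
  (neutral, positive, negative), 27 trials per condition per subject
  (the emulated design reports a mean of 27, range 18–30), 9 subjects,
  raw sampling 1000 Hz down-sampled to 250 Hz.
* **Background.** Every channel carries 1/f-like noise synthesized by
  spectral shaping of white noise: the target one-sided spectrum is
  `10^(offset − χ·log10 f)`, multiplied by Gaussian oscillatory peaks
  specified in log10-power units. Phases are random, so oscillations are
  non-phase-locked by construction. The default habenular peak sits at
  8.2 Hz (bandwidth 2.4 Hz, amplitude 0.5 log10 units), matching the
  average resting theta/alpha peak the design reports; sensors carry a
  weaker 9.5 Hz alpha peak. Monopolar rest recordings add a common-mode
  component per hemisphere (50 Hz line noise plus drift) that bipolar
  referencing and filtering must remove.
* **Condition effects.** Valence effects are injected as band-limited,
  random-phase bursts gated by a smooth window: inside the window the
  in-band signal amplitude is multiplied by the condition's gain. The
  defaults place a 5–10 Hz effect at 100–500 ms (LFP and frontal
  sensors) and a 4–7 Hz effect at 2700–3300 ms (LFP only), with gains
  negative 1.2, neutral 1.1, positive 1.0. Those gains were chosen once
  so that the negative-vs-positive percent-change contrast lands in the
  tens of percentage points, the magnitude typical of event-related
  synchronization in depth recordings; they are deliberately moderate so
  that group inference is non-trivial.
* **Coupling.** Cross-region coupling is realized by a shared narrowband
  component: within the coupling window the source channel's in-band
  activity is rebuilt as `√(1−m)·own + √m·shared` (power-neutral) and
  the targets receive a scaled, lagged copy of `shared`, so the expected
  cross-trial coherence equals the requested strength `m`. Defaults
  couple each habenular channel to the frontal sensors at 5–10 Hz,
  800–1300 ms, with strengths negative 0.45 / neutral 0.35 / positive
  0.25 and a 20 ms lag. Both hemispheres act as sources because the
  emulated design analyses every habenula–sensor combination (two
  habenulae per subject).
* **Valence/arousal structure.** Picture ratings are truncated normals
  on the 1–9 scale with means neutral (5.0, 3.3), positive (7.1, 6.3),
  negative (2.3, 6.0) for (valence, arousal). This preserves the two
  contractual orderings — valence: negative < neutral < positive;
  arousal: neutral < both — i.e. arousal is non-monotone in valence,
  which is exactly what lets a linear model separate the two predictors.
  Absolute rating calibration is unconstrained by the available
  information, so only the orderings are load-bearing.
* **Subject heterogeneity.** A per-subject log-normal gain on
  oscillation amplitude (SD 0.05 log10 units) and a per-subject ×
  condition latent factor that jointly nudges the 800–1300 ms coupling
  and the late theta gain (`coupling_theta_link`), giving the
  coherence→late-theta regression a true positive slope.
* **Sensor-space dependence.** Sensor background noise is mixed through
  a smooth spatial kernel over the 2-D layout, so sensor-level cluster
  tests face realistic spatial correlation rather than trivially
  independent sensors.

What the generator does **not** emulate: volume conduction physics and
anatomical geometry (the lead field is a smooth synthetic distance-decay
model on a regular grid), heavy-tailed artifacts, sensor-specific noise
spectra, and non-stationarities beyond the gated bursts. Passing tests
therefore demonstrate the correctness and calibration of the analysis
machinery under the assumed signal model, not robustness to every
property of real recordings.

# Preprocessing

Bipolar channels are differences of depth-adjacent monopolar contacts
(contact *i* − contact *i+1*; four contacts yield three bipolar
channels), removing the shared reference. The filter chain is a
zero-phase (forward–backward) 4th-order Butterworth high-pass at 0.3 Hz,
2 Hz-wide IIR band-stop notches at 50 Hz and harmonics below the
low-pass edge, a 4th-order low-pass at 100 Hz, then decimation to
250 Hz. The filter family and order are a package choice (the design
source does not state them); zero-phase filtering is essential because
latency claims (100–500 ms vs 2700–3300 ms windows) would otherwise be
biased. Artifact handling accepts externally marked time windows plus an
optional |z| > threshold auto-marker, since visual inspection is not
reproducible; rejection refuses to leave fewer than two trials per
condition because cross-trial coherence is undefined below that.

# Spectral parameterization

`welch_psd()` uses 2 s Hann segments with 50% overlap (0.5 Hz
resolution, enough points for a 2–40 Hz fit). `fit_spectral_model()`
separates the spectrum into an aperiodic component `b − χ·log10 f` and
Gaussian peaks, with the conventional settings: at most 4 peaks, peak
widths 1–15 Hz, detection threshold 2 SD of the flattened residual. The
aperiodic fit is made robust by refitting on the points whose residual
lies below the 2.5% quantile of positive residuals, which ignores
oscillatory mass above the fit. Peaks are extracted iteratively from the
flattened spectrum, refined jointly by bounded Levenberg–Marquardt, and
near-duplicates (centers closer than half the smaller bandwidth) are
merged so that duplicated Gaussians cannot exhaust the peak budget.
Reported bandwidth is two standard deviations of the Gaussian; amplitude
is height above the aperiodic fit in log10 units. No "knee" parameter is
fitted: over a 2–40 Hz range the knee is unidentifiable and the source
analysis did not use one. A channel may legitimately return an empty
peak list; the package reports it without interpretation.

# Time-frequency analysis

`morlet_tfr()` convolves each trial with complex Morlet wavelets of 6
cycles (σ_t = 6/(2πf)), by FFT. The amplitude convention is pinned so
that a unit-amplitude sinusoid at the wavelet's frequency yields power 1
at its frequency row, independent of frequency. Two consequences worth
stating: percent-change baselining cancels any such convention, and the
wavelet's equivalent noise bandwidth grows linearly with frequency, so
time-averaged wavelet power equals the Welch density only after dividing
by f (the test suite checks exactly that proportionality).

Epochs keep a 500 ms buffer at each edge: wavelet coefficients are
computed on the full epoch and the buffer is then trimmed, so retained
samples near the edge draw on real data rather than padding. For
frequencies whose 4σ_t support exceeds the buffer (below ≈ 8 Hz at 6
cycles) the outermost retained samples still see some zero padding —
attenuation, not contamination; this mirrors the buffered-epoch
convention of the emulated analysis.

Baseline normalization is percent change relative to the mean of
−2000…−200 ms, applied per channel and frequency **after** averaging
trials within a condition (a per-trial variant exists for robustness
checks). The ERP is the 0.3–30 Hz band-passed trial average;
`induced_only()` subtracts each condition's ERP from its trials so the
evoked/induced distinction can be tested explicitly.

# Cross-trial coherence

`cross_trial_coherence()` computes, per (frequency, time) point,
`|Σ_k X_k Ȳ_k| / √(Σ|X|² Σ|Y|²)` across trials, reported as magnitude
(not squared; a flag provides the square). The estimator's small-sample
bias is `E[coh²] = 1/n` on independent inputs, which the tests verify at
n ∈ {5, 27, 100}; because the bias depends on n, conditions compared on
coherence are first equalized in trial count by seeded random
subsampling. Stimulus-related change is expressed as percent change of
the coherence relative to the pre-stimulus baseline per frequency.
Short coupling windows are smeared by the wavelet's temporal support, so
calibration is read at the window core and the upper band rows; the
generator's coupling strength is recovered there within ±0.1.

# Cluster-based permutation inference

Per-bin paired t statistics are mapped through the t CDF to
standard-normal z-scores (the pinned construction behind "z-scores").
Bins beyond the two-sided p < 0.05 pre-cluster threshold form connected
clusters — 4-connectivity on the (frequency, time) grid, a distance
neighbor graph on sensor layouts (δ = 1.3 × median nearest-neighbor
distance, giving 4–8 neighbors on regular layouts), 6-connectivity on
source grids. Cluster mass is the sum of member z-scores; the null is
the distribution of the maximum |mass| over sign-flips of the pair
assignment. When 2ⁿ does not exceed the requested permutation count the
enumeration is exhaustive and p-values are exact proportions; otherwise
p = (1 + #{perm ≥ observed})/(n_perm + 1), which cannot return zero.
Both tails are computed for the main contrasts; the one-sided variant
exists because source-level contrasts in this design family use a
one-tailed dependent-sample t. The paired permutation t-test reports a
bootstrap percentile CI of the mean difference (a sign-flip resample is
centered at zero and cannot produce a CI around the estimate); the
permutation correlation permutes y, residualizes on covariates when
supplied, and enumerates all n! orderings when feasible.

# DICS-style beamforming

The cross-spectral density is averaged over trials and all
(frequency, time) points in the requested band/window. Filters are
`w = (lᵀC_r⁻¹l)⁻¹ lᵀC_r⁻¹` with `C_r = Re(CSD) + λI`, λ = 1% of the
mean diagonal — the regularization fraction the emulated analysis used —
and fixed (scalar) source orientation, since the synthetic lead field is
orientation-free. Power and coherence are evaluated with the full
complex CSD; filters stay real. Lead-field columns are normalized to
unit norm by default: the unit-gain beamformer's noise power scales as
1/‖l‖², so unnormalized distance-decay gains would bias power toward
weakly seen nodes. Coherence maps,
`|w·csd_ref| / √(node power × ref power)`, are scale-invariant and
therefore indifferent to that normalization. Source contrasts report
both the corrected cluster p and uncorrected per-node permutation p,
because practice in this design family mixes the two thresholds.

# Mixed-effects valence/arousal models

Each neural measure (early habenular theta/alpha, late habenular theta,
frontal-sensor theta/alpha, right-frontal–habenular coherence change) is
modeled as `measure ~ valence + arousal + (1 | subject)` on one
observation per subject × condition, the predictors being the
condition-mean ratings of the presented pictures (per-trial modeling
exists but is not the default, matching the condition-mean design).
Estimation is REML via `lme4`, p-values by Satterthwaite approximation
(`lmerTest`), CIs are Wald t intervals on the same Satterthwaite
denominator df (a plain z interval undercovers at nine subjects).
R² is reported as marginal (fixed effects
over total variance), with the conditional value alongside, since the
flavor is otherwise ambiguous. Degenerate fits (zero residual variance)
fall back to OLS, which the random-intercept model reduces to at zero
random-effect variance. The coherence→late-theta link is fitted at the
habenula level (one observation per habenula × condition, subject as
random effect), with a pooled permutation Pearson correlation as the
supplementary statistic, and a window-specificity control repeats the
correlation in four flanking windows.

# Numerical and design choices

* All randomness flows from one root seed split per stage
  (`stage_seed()`), so stages re-run independently reproduce exactly.
* The quick profile (`study_config(quick = TRUE)`) reduces sensors (24),
  permutations (200), rest duration (60 s) and the source grid (3³),
  and caps trials at 18 — the lower end of the emulated design's trial
  range — rather than below it, because coherence bias and variance
  scale with 1/n_trials and smaller counts would change the estimand.
* Test problem sizes: spectral recovery uses 200 synthetic spectra;
  type-I calibration uses 200 null simulations × 200 permutations on
  9-subject 12×20 maps; detection/localization uses 50 reduced studies
  at 9 subjects × 18 trials (125 Hz synthesis); LME coverage uses 500
  simulations. These sizes are the package's chosen compromise between
  the precision of a Monte-Carlo estimate and a test suite that runs in
  minutes.
* Serialization is plain text: CSV for data, trials, channels, ratings
  and summary tables; JSON for configs, fits and reports.

# Known limitations

* The aperiodic model is fixed-mode (no knee); spectra with a bend
  inside 2–40 Hz would bias the exponent.
* Coherence calibration is exact only up to wavelet temporal smearing;
  windows shorter than the wavelet support at the lowest band frequency
  are recovered diluted.
* The beamformer assumes the synthetic fixed-orientation lead field;
  nothing here validates against anatomical head models.
* The generator's bursts are amplitude modulations of Gaussian
  narrowband noise; rhythmic but non-sinusoidal (e.g. sawtooth-like)
  waveform shapes are out of scope.
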