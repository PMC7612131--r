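---
title: "Methods: generative models, estimators and calibration in erndim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative models, estimators and calibration in erndim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`erndim` implements the full analysis chain of a flanker-task study of the
error-related negativity (ERN) and dimensional psychopathology: ERP
amplitude quantification, reliability, exclusion screening, transdiagnostic
dimension scoring, a regression battery, correlation power analysis and the
two-step-task analysis of model-based learning — together with synthetic
generators for every data type, calibrated so that each estimator can be
validated against known ground truth. This vignette documents the models,
the estimators, the numerical conventions and the design decisions that
were genuinely open.

# ERP scoring

Response-locked epochs live on a fixed grid: −400…500 ms at 250 Hz (4 ms
step, inclusive endpoints, 226 samples). Scoring applies, in order:

1. **Baseline correction** — subtract each epoch's mean over the inclusive
   −400…−200 ms window (51 samples).
2. **Threshold rejection** — drop every epoch whose absolute amplitude
   *strictly exceeds* 50 μV at any sample. The boundary convention keeps an
   epoch touching exactly ±50.0 μV: rejection fires on "exceeds the
   criterion". Both the threshold and the convention are configurable
   (`scoring_config()`). Rejection follows baseline correction.
3. **Averaging** — pointwise mean across surviving epochs.
4. **Quantification** — one of four estimators:
   * *adaptive mean*: find the minimum sample in the inclusive −20…120 ms
     search window (36 samples) and average over peak ± 40 ms (21 samples).
     Ties at the minimum resolve to the earliest latency. On the standard
     grid the ± 40 ms window is always interior to the epoch; in the general
     case it is clipped to the epoch bounds.
   * *window mean*: mean over a fixed 0…100 ms window (26 samples).
   * *minimum amplitude*: the minimum sample in the search window.
   * *trough-to-peak*: minimum in the search window minus the maximum over
     the preceding window [−100 ms, peak latency], reported negative-signed.
     The preceding-window definition is not standardised in the literature;
     this choice is a documented package convention.

The correct-trial analogue (CRN) is scored identically on correct-response
epochs; ΔERN = ERN − CRN, and `residualise_ern()` provides the
across-subject OLS residualisation of ERN on CRN (residuals sum to zero and
are exactly uncorrelated with CRN in sample; a zero-variance CRN falls back
to centering with a warning).

**Split-half reliability** scores the even- and odd-indexed epoch averages
separately per subject, Pearson-correlates the two score vectors across
subjects and applies the Spearman–Brown correction 2r/(1+r). Indexing is
0-based, so the "even" half holds the 1st, 3rd, 5th… epochs and receives
the extra epoch at odd counts.

# The synthetic EEG generator and its calibration

The generator's purpose is parameter recovery: the adaptive-mean score of a
noiseless simulated subject must equal that subject's true amplitude
*exactly*, for negative (error-trial) and positive (correct-trial)
amplitudes alike. A component built as "amplitude × negative-going kernel"
cannot do this for positive amplitudes — scaling a negative bump by a
positive amplitude produces a waveform with no negative peak, and a
min-picking estimator returns garbage. The generator therefore composes
each noiseless epoch from two parts:

* a **carrier**: flat (= 1) across the component center ± 52 ms — so that
  the whole ± 40 ms scoring window sees exactly 1 even when the detected
  peak or the epoch latency is off by a few samples — and cosine-tapered to
  zero over the following 40 ms (zero throughout the baseline window);
* a **rider**: a fixed-depth (default 20 μV), smooth, Mexican-hat-like
  marker with its minimum at the component center, positive side lobes, and
  an *exactly zero* sum over the 21 scoring-window samples. Its support is
  kept inside ± 32 ms of the center so that scoring windows centered within
  2 samples of the true peak still cover it entirely.

An epoch with true amplitude $A$ is $A \cdot \mathrm{carrier} + \mathrm{rider}$:
the rider pins the detected minimum at the component latency for any
$A \in [-10, 10]$ μV without contributing to the windowed mean, so
score(generate($A$)) $= A$ to machine precision. `calibrate_kernel_gain()`
additionally provides the classical scalar calibration for negative-going
kernels (a delta-like kernel gives gain 21, the number of samples in the
window; a half-cosine gives the closed-form windowed mean).

The component center defaults to 37.61 ms post-response — a typical
grand-average error-trial peak latency — snapped to the nearest grid sample
(36 ms), since 37.61 ms is not representable at 250 Hz.

Noise and dispersion are layered on top:

* true amplitudes per subject: Normal(−3.11, 2.79²) μV for error trials and
  Normal(0.30, 1.89²) μV for correct trials by default, matching the
  population moments of a large (N = 196) flanker cohort;
* per-subject epoch counts: Normal(51.88, 33.09²) error epochs and
  Normal(404, 58.78²) correct epochs, rounded and floored at 9 (the
  smallest retained count in such cohorts);
* per-trial latency jitter: Normal(0, 10 ms), quantised to grid samples.
  The jitter magnitude is not identifiable from published summaries; 10 ms
  is a modelling choice, exposed in `eeg_gen_params()`;
* i.i.d. Gaussian sample noise, default SD 10 μV, chosen so the ±50 μV
  criterion rejects roughly 0.4 % of epochs — the rejection rate such
  cohorts actually show. No 1/f structure is simulated; this is a
  deliberate simplification sufficient for the estimator properties under
  test (see *Limitations*).

With latency jitter on, the adaptive mean acquires a small negative-going
bias (peak-picking on a smeared component); the carrier's ± 52 ms flat
margin bounds it to a few hundredths of a μV at the default jitter, and the
recovery tests bound it rather than asserting exact unbiasedness.

## Reliability calibration

`derive_noise_for_reliability()` inverts the reliability model
$r = \sigma_b^2 / (\sigma_b^2 + \sigma_{\mathrm{eff}}^2 / n)$ for the
per-sample noise SD, where $\sigma_{\mathrm{eff}}^2$ is the effective
per-epoch variance of the adaptive-mean score. Because peak picking is
nonlinear, $\sigma_{\mathrm{eff}}$ is estimated by a small internal
simulation that scores averages of $n/2$ epochs — the half-size the
even/odd split actually uses — and the noise SD is refined
multiplicatively over three rounds.

One structural point deserves emphasis. Matching the per-*score* noise
implied by a split-half reliability of 0.90 at 52 epochs and a 2.79 μV
between-subject SD requires a per-sample i.i.d. noise SD near 26 μV. Real
EEG noise of that score-level magnitude is strongly autocorrelated and
rarely crosses ±50 μV; i.i.d. noise of the same score variance has far
larger sample maxima and would be rejected wholesale by the ±50 μV
criterion (the probability that at least one of 226 independent draws
exceeds 50 μV is essentially 1). The reliability study therefore runs
without the rejection step and with zero latency jitter
(`split_half_reliability(..., apply_rejection = FALSE)` is the default),
while the recovery pipeline keeps rejection on at the default 10 μV noise.
This is a property of the i.i.d. noise simplification, not of the
estimators.

# Flanker behaviour

The task design is fixed: 480 trials in 2 blocks of 240, each block 80
congruent and 160 incongruent in uniformly shuffled order (the 2:1
incongruent ratio raises conflict frequency and error counts), 1050 ms
response deadline. Behaviour is generated per trial: congruency-dependent
error probabilities (defaults 3.61 % / 15.58 %), shifted log-normal RTs
(positive skew typical of RT data; means 283 ms correct / 212 ms error, a
61.6 ms congruency cost split −2/3 / +1/3 so the marginal mean is
preserved under the 1:2 trial ratio, trial SD 60 ms, shift 80 ms), ~20 ms
post-error slowing applied in expectation to trials following a non-missed
error within the same block, and misses from a base rate plus deadline
overflow. End-of-block feedback: "faster" when > 25 % missed or accuracy
> 90 % (speed message wins when both branches hold, mirroring the rule
order), else "more accurate" when accuracy < 75 %, else "great job".

Screening applies the exclusion cascade on a rolling basis — corrupted
EEG (an input flag, not detected from raw files), epoch survival < 95 %,
missed trials > 96, accuracy < 55 %, catch item ≠ "A little" — with strict
comparisons as printed, so a subject at exactly 96 missed trials, 55 %
accuracy and 95 % survival is retained. Post-error/post-correct strata
classify each trial by the correctness of the previous non-missed trial
within the same block; the first trial of a block follows nothing, and
trials after a miss are dropped from these strata.

# Questionnaire cohort and dimension projection

Nine instruments contribute 209 items (AUDIT 10, AES 18, SDS 20, EAT-26
26, BIS-11 30, OCI-R 18, SSMS 43, LSAS 24, STAI-T 20), plus one catch
item excluded from all scoring. The manifest is the single source of truth
for item order, response levels and (synthetic) reverse-keying; it does not
reproduce any instrument's item wording or true key.

The generative model draws three correlated factors — anxious-depression
(AD), compulsivity/intrusive thought (CIT), social withdrawal (SW) — with
inter-factor correlations 0.33–0.39, forms item propensities through fixed
loadings (each instrument loading on its dominant factor; reverse-keyed
items negatively), adds i.i.d. item noise (SD 0.8) and discretises at
equal-probability normal thresholds into each item's ordinal levels.

Scale totals flip reverse-keyed items within their own response range and
sum; the clinical flags use the instruments' printed comparators (OCI-R
total ≥ 21; STAI total > 41, strict). Dimension scores are weighted sums
of the *raw* item responses through a 209 × 3 weight matrix, then z-scored
across the analysed cohort. The canonical weight matrix from the large
factor-analytic reference study is not redistributable, so the packaged
default is synthetic — the generator's own loadings, labelled
non-canonical — and a loader accepts a user-supplied CSV aligned to the
manifest. Weighted sums (not regression-based factor scores) are the
implemented projection; this is the simplest rule consistent with applying
fixed external weights to raw responses.

# Regression battery and power

All models are OLS with intercept and conventional standard errors, the
predictors z-scored over the analysed subjects, so each reported beta is in
outcome units (μV) per predictor SD. The nine questionnaire models are
fitted separately (the instruments are too intercorrelated to enter
jointly); the three dimensions enter one joint model. Covariates (error
rate, demographics, medication) are extra spec fields, not separate code
paths. Both the exact Bonferroni threshold (0.05/9 ≈ 0.00556) and the
conventional rounded 0.005 are reported; with the observed p-value spread
the choice between them is immaterial, and the battery's type-I behaviour
is verified by simulation at α = 0.005.

Power for a correlation uses the Fisher-z approximation
$N = \lceil ((z_{1-\alpha/2} + z_{\mathrm{power}}) / \mathrm{atanh}\, r)^2 + 3 \rceil$
with a ceiling (not rounding) and the +3 small-sample correction; the
returned N is verified to achieve the nominal power by direct simulation.

# Two-step task

The agent is the standard hybrid: model-free SARSA(λ) first-stage values,
model-based values combining the known 70/30 transition matrix with the
max second-stage values, softmax choice with inverse temperatures β₁/β₂
and a first-stage stickiness bonus, and reward probabilities following
reflecting Gaussian walks in [0.25, 0.75] with step SD 0.025 (canonical
settings for this task; trials default to 200 per subject and are
configurable, as published variants differ).

The analysis drops each subject's first trial and effect-codes the
previous trial (reward ±1, transition ±1), so the reward × transition
coefficient of the stay logistic directly indexes model-based control:
positive for model-based agents (stay after rewarded-common and
unrewarded-rare), ~0 for model-free agents, whose signature is a reward
main effect. Without dimensions the pooled fit absorbs per-subject
baseline stay tendencies through subject fixed effects (per-subject
intercepts); with dimensions a single pooled model adds each z-scored
dimension and its interactions with the three base terms, the headline
term being dimension × reward × transition. A mixed-effects backend could
be swapped in behind the same record builder; the package's test surface
is deliberately sign- and recovery-based rather than coefficient-magnitude
based, since random-effect structure shifts magnitudes. Quasi-separation
is flagged with a warning rather than an error. Per-subject model-based
indices (`subject_mb_indices()`) come from independent per-subject fits of
the base model.

Cohort coupling sets each subject's model-based weight to
$w = \mathrm{logistic}(\mathrm{logit}(w_0) + \mathrm{slope} \cdot z_d)$,
recording ground truth, so dimension-coupling recovery can be tested with
known sign and size.

# Numerical conventions and degenerate inputs

* Windows are inclusive at both ends everywhere; all window arithmetic is
  exact integer indexing on the 4 ms grid.
* Ties at the negative peak resolve to the earliest latency.
* An epoch set whose every epoch is rejected raises an explicit error, to
  be handled by screening (epoch-survival rule) rather than silently.
* Zero-variance paired differences and zero-variance CRN regressors warn
  and fall back to the defined degenerate answers (p ∈ {0, 1} edge;
  centered ERN).
* A single-subject or zero-variance dimension z-scores to 0 in the
  two-step coupling rather than NaN.
* Seeds: every generator takes an explicit integer seed; constructors that
  draw fixed quantities (the latent model's loadings) use a private RNG
  stream and restore the caller's stream, so lazy evaluation can never
  perturb a seeded draw path.

# What the generators do and do not emulate

The synthetic layer reproduces the *structure* the estimators care about:
congruency-dependent error rates, post-error slowing, ERN/CRN components
with latency jitter and calibrated amplitudes, dispersed epoch counts, a
correlated three-factor item structure with ordinal discretisation and
catch failures, and hybrid two-step choice behaviour. It does not emulate:
continuous EEG or artifact classes (blinks, line noise — upstream cleaning
is out of scope), 1/f or spatially structured noise, multi-electrode
topography (a single virtual fronto-central channel is simulated),
item-level wording or true reverse-keys of the published instruments, or
RT dynamics on the two-step task. Passing tests therefore demonstrate
correctness of the estimators and pipelines under a faithful structural
model, not robustness to every property of recorded EEG.

# Problem sizes

The test and acceptance runs use the cohort scale the defaults describe
(196 subjects; ~52 error / ~404 correct epochs) with replicate counts
chosen to put Monte-Carlo error well inside each tolerance: 4–10 replicate
cohorts for amplitude-recovery grand means, 3–4 for reliability, 2000
score-level cohorts for type-I calibration of the battery, and 5 replicate
2000-subject cohorts for dimension-coupling sign recovery. Smaller
fixtures (8 subjects, ~20 epochs) cover schema and determinism checks.

# Limitations

* The i.i.d. noise model makes the ±50 μV rejection incompatible with
  score-noise levels matching low reliabilities (see *Reliability
  calibration*); colored noise would reconcile the two at the cost of a
  more complex calibration.
* The default dimension weights are synthetic; analyses of real data must
  supply the canonical weight matrix.
* The stay model's pooled fixed-effects formulation understates
  between-subject heterogeneity relative to a mixed model; only signs and
  recovery properties should be compared across formulations.
* The trough-to-peak preceding-window convention is package-defined;
  published variants differ.
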