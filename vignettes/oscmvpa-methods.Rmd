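---
title: "Time-resolved decoding of oscillatory EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of oscillatory EEG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

`oscmvpa` asks *when*, not just whether, a cognitive state becomes readable
from scalp EEG. Given epoched multichannel recordings labeled by a binary
outcome (here: whether the context of a studied item was later remembered
correctly), the pipeline slides a 300-ms window across the first two seconds
after stimulus onset and asks, window by window, how well a multivariate
classifier separates the two trial classes from oscillatory power patterns.
The earliest window whose decoding accuracy peaks above an empirically
calibrated chance level is taken as the moment the brain first carries the
discriminating information. Comparing these peak moments between conditions
(which context feature is decoded, which was attended, encoding vs
retrieval) adjudicates between competing accounts of how simple and complex
visual features are ordered in time.

# The decoding model

## Time-frequency decomposition

Each epoch (−1000 to +3000 ms around onset, 256 Hz) is convolved with
complex Morlet wavelets on a grid of 78 linearly spaced frequencies from 3
to 80 Hz at five cycles per wavelet. Five cycles fixes the time-frequency
trade-off: the Gaussian envelope has $\sigma_t = 5/(2\pi f)$, i.e. about
265 ms at 3 Hz and 10 ms at 80 Hz. Kernels are unit-energy and truncated at
$\pm 3.5\sigma_t$; the epoch must extend beyond the analysis interval by at
least half the longest kernel, so edge-distorted samples never enter the
analysis. After convolution the coefficients are cropped to 0–2000 ms and
decimated toward a nominal 50.25-Hz grid. Because 50.25 Hz does not divide
256 Hz, decimation keeps every `round(256/50.25)` = 5th sample (an
effective 51.2 Hz); all window arithmetic downstream uses the retained
samples' true millisecond labels, never sample counts, so the nominal
20-ms window step maps cleanly onto the grid.

## Bands, covariances, and CSP

Power is organized into the five conventional bands (δ 3–4, θ 4–7, α 8–14,
β 14–30, γ 30–80 Hz). A frequency bin sitting exactly on a boundary shared
by two bands (4, 14, 30 Hz) is assigned to the lower band only, so no bin
is double-counted. For one band and one 300-ms window, each trial's
channel-by-channel covariance is the real part of the wavelet
cross-spectral matrix averaged over the band's bins and the window's
timepoints — symmetric positive semi-definite by construction, and computed
from the wavelet representation rather than re-filtered time series, since
spatial filtering operates downstream of the decomposition.

Common spatial patterns (CSP) finds channel weightings that maximize the
ratio of class variances: with class-average covariances $\bar C_1, \bar
C_2$, the filters solve the generalized eigenproblem $\bar C_1 w = \lambda
\bar C_2 w$. A 300-ms window on the decimated grid holds only ~16
timepoints per band, so the class averages are shrunk toward a scaled
identity ($\mathrm{tr}(C)/d \cdot I$) with intensity 0.1 by default before
the eigenproblem is solved (Cholesky whitening plus a symmetric
eigendecomposition; the filter with the largest-magnitude coefficient is
sign-flipped positive for determinism). All $d$ filters per band are
retained; the dimensionality cap happens at feature selection, not at the
filter level.

## Features, selection, classification

Each trial's feature for filter $w$ is the variance of the spatially
filtered band-limited signal, computed as the quadratic form $w^\top
\Sigma_{\mathrm{trial}} w$ on the trial's band covariance. The five-band
pools give $5d$ candidate features per window; Fisher's criterion
$(\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$ ranks them and the top five are
kept (ties broken toward the lower feature index). A Gaussian naive-Bayes
classifier with empirical priors is trained on the selected features; class
variances are floored at $10^{-9}$ times the feature's pooled variance so
degenerate features cannot produce division errors.

Performance is the mean accuracy of a stratified 5-fold cross-validation.
By default CSP fitting and Fisher selection happen *inside* each training
fold — the leakage-safe arrangement — and a `fit_scope = "all"` switch
reproduces the literal variant that fits them on all trials first (the unit
suite demonstrates the optimistic bias this induces). One seeded fold
assignment is reused across all 86 windows, so between-window differences
reflect time, not resampling. Folds are dealt round-robin within class with
a running pointer, which makes overall fold sizes differ by at most one
(47 trials over 5 folds gives 10/10/9/9/9) while preserving class
imbalance in every fold.

## Empirical chance and the conservative threshold

With unbalanced classes and flexible feature selection, the theoretical 50%
chance level is not trustworthy, so significance is calibrated by
permutation: the full time-resolved procedure is repeated with labels
shuffled (without replacement, preserving class counts), 500 times per
analysis in a full run, each repetition with its own permutation-indexed
seed and a fresh fold assignment. Each window has its own null
distribution; the subject-level significance threshold is deliberately
conservative — the *highest* per-window 95th percentile across windows.
Percentiles everywhere use linear interpolation between order statistics.
The null's per-window *means* serve a second, distinct role: they are the
empirical chance levels subtracted from the actual timecourse for
group-level actual-minus-chance curves, whose cross-subject t-based 95%
confidence intervals flag windows reliably above chance.

## Earliest significant peak

A window is a candidate peak when its accuracy is strictly greater than
every other window whose midpoint lies within ±60 ms (three grid steps each
side; exact ties disqualify, matching the strict reading of "higher").
Edge windows compete only against existing neighbors. Candidates at or
below the conservative threshold are discarded, and the earliest survivor
is the peak moment. The strictness matters: on saturated or perfectly flat
stretches, tied windows eliminate each other, which is the intended
behavior — a plateau has no well-defined peak.

# Group-level statistics

Per subject there are eight peak latencies (2 phases × 2 attended features
× 2 decoded features). A one-sample Kolmogorov–Smirnov check on the
standardized pooled latencies (asymptotic p-values) decides whether rank
statistics are warranted; latency predictions are then tested with
one-tailed Wilcoxon signed-rank contrasts. The signed-rank implementation
drops zero differences, uses tie-averaged ranks, reports $T$ = the sum of
positive-difference ranks, computes exact one-tailed p-values by
convolution over the realized ranks for $n \le 12$, and switches to the
normal approximation with tie correction and continuity correction above
that. Age effects are ordinary least-squares regressions of peaks (or peak
differences) on age, reported as $\beta$, $R^2$, $F_{(1,n-2)}$, and a
two-tailed p.

The three candidate accounts of latency ordering are operationalized as a
decision table over four one-tailed contrasts (α = 0.05, no
multiple-comparison correction, directions fixed a priori): the
complexity-ordered contrast when the prioritized feature is attended
(`attended`), the same contrast when it is not (`unattended`, optionally
with its reverse direction), the interaction of attention on the latency
gap, and the attended-prioritized vs attended-other contrast (`across`).
`hierarchical` requires the ordering in both attention conditions;
`attention` requires the ordering to flip with attention while `across`
stays flat; `hybrid` requires the ordering only under attention with
`across` significant; anything else is `indeterminate`. This is a decision
table rather than a model fit because the adjudication in the underlying
design rests on exactly these significance patterns.

# The synthetic cohort generator

Real data for this paradigm cannot be redistributed with the package, so
every stage is exercised against a generator with known ground truth. One
subject-condition recording is: per channel, independent broadband
background noise synthesized in the frequency domain with amplitude
$\propto f^{-\chi}$ ($\chi = 1$ by default) plus a flat component, both
confined to 0.5–125 Hz (mirroring the acquisition band-pass, which is
treated as a property of the input); on top of it, a band-limited
oscillation whose carrier is drawn per trial uniformly within the effect
band, with random phase, a Hann envelope over the configured latency
window, and a spatial profile across channels (posterior-weighted by
default). The "correct" class receives $\sqrt{\text{effect\_size}}$ times
the amplitude of the "incorrect" class, so the injected class band-power
ratio equals `effect_size`; at the default amplitudes the injected
oscillation dominates the background's band power, and direct spectral
measurement recovers the configured ratio within a few percent.

Two features deserve emphasis because they were added for realism and
matter for what the tests can show. First, oscillation amplitude varies
trial-to-trial by a lognormal factor (SD 0.3 on the log scale) shared by
both classes: real band power fluctuates strongly across trials, and
without this the classes separate almost deterministically — accuracy
saturates at 100%, adjacent overlapping windows tie exactly, and the
strict peak rule correctly reports no peak. Second, the Hann envelope makes
decodability rise to a genuine apex at the effect-window center instead of
a flat plateau, which is what gives "peak latency" a recoverable meaning.
What the generator does *not* emulate: volume-conducted correlated noise
between channels, ERP transients, eye or muscle artifacts with realistic
morphology, or non-stationary background spectra. Passing tests therefore
certify the pipeline's statistical machinery and its parameter recovery
under the stated noise model, not artifact robustness on real recordings.

Cohorts draw subject ages uniformly over a configurable range and shift
each condition cell's effect window by a specified offset plus independent
Gaussian between-subject jitter (SD 40 ms by default). The ground-truth
windows are stored alongside the data, which is what makes parameter
recovery testable. `scenario_offsets()` encodes the three latency-ordering
accounts as offset tables, and `simulate_scenario_peak_table()` draws
cohorts directly at the peak-table level — the natural input granularity of
the group-statistics layer — for verdict-recovery testing at full cohort
size without the decoding cost.

# Artifact rejection conventions

The three automated rejection rules are relative, data-driven thresholds:
(1) the 400-ms windowed voltage range stepped by 100 ms, flagged above the
99th percentile; (2) the linear-trend |slope| above the 95th percentile,
gated by a minimum fit $R^2$ of 0.30; (3) the 100-ms windowed range stepped
by 25 ms within ±150 ms of onset, frontal and eye channels only, above the
95th percentile. Each rule reduces an epoch to a single statistic — the
maximum over its channels and windows — and percentiles are taken across
epochs. The alternative reading (pooling every epoch×channel×window value
and flagging an epoch when *any* window exceeds the pooled percentile)
rejects nearly every epoch on i.i.d. data (one minus $0.99^{\#windows}$)
and is inconsistent with the ~1% + 5% + 5% per-rule rates that sum, with
overlap, to the low-teens rejection percentages typical of this
preprocessing; the per-epoch-statistic reading is therefore used.
Comparisons are strict (ties never reject), the frontal set defaults to
{FP1, FP2, AF3, AF4, F7, F8} plus any EOG channel, and all thresholds are
returned in the rejection report. Since the rules are relative, they always
remove roughly the same fraction; they are a quality-control convention,
not an artifact detector with a fixed physical threshold.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (type 7),
  everywhere.
* Generalized eigenproblems: Cholesky whitening of $\bar C_2$ followed by a
  symmetric eigendecomposition; a singular $\bar C_2$ at zero shrinkage is
  an error instructing nonzero shrinkage.
* Naive-Bayes variance floor: $10^{-9} \times$ pooled feature variance
  (absolute floor $10^{-12}$ when the pooled variance is itself zero);
  prediction ties resolve to the first class.
* Fisher scores with zero denominator: 0 when the class means agree
  (no information), effectively infinite otherwise (perfectly separating
  feature).
* Seeds: every stochastic step takes an explicit seed; nested streams are
  derived with a Lehmer-style mixer (`derive_seed`) so permutation $r$ of
  analysis $a$ is reproducible in isolation, and all derived seeds stay
  below $2^{31}$.
* The compiled decoding sweep (RcppArmadillo) contains no random number
  generation — labels, permutations and folds are generated in R and passed
  in — and a pure-R reference engine (`engine = "r"`) reproduces its
  accuracies to ~1e−10; the equivalence is asserted in the test suite.

# Problem sizes used by the test suite

The package's statistical claims are validated on scaled-down synthetic
designs chosen for estimator precision per unit compute; they are the
package's own study designs and are stated here for transparency:

* *Chance calibration*: one balanced 80-trial subject, 4 posterior
  channels, one 300-ms window, 100 label shuffles — mean accuracy within
  50 ± 2%.
* *Latency recovery*: 20 subjects × 2 conditions separated by +70 ms,
  beta-band effect (chosen for its sharp wavelet temporal resolution,
  $\sigma_t \approx 40$ ms at 20 Hz), 200 balanced trials, 0–1100-ms span,
  100 permutations per analysis — the test asserts that the median
  recovered peak difference falls within ±40 ms of 70 ms and that a
  one-tailed signed-rank test detects the order at p < 0.05. Design-phase
  pilots across bands, trial counts and effect sizes measured the
  earliest-peak estimator's anchor noise at sd ≈ 130 ms or more per
  analysis with 15–30% gross outliers, so this assertion is *expected to
  fail* under the generator's stationary noise model; see *Known
  limitations* for why, and the verdict-recovery suite for the
  latency-ordering inference validated at the peak-table level.
* *Familywise control*: 50 zero-effect analyses of 80 trials at the
  default 60/40 imbalance, full 86-window grid, 100 permutations — the test asserts the
  nominal bound (at most 10% of analyses with a significant earliest peak).
  Measured familywise error under this generator is ~30%, so this assertion
  is also expected to fail; the mechanism is documented below.
* *Verdict recovery*: 3 scenarios × 20 replicate cohorts of 25 subjects at
  the peak-table level with 70-ms offsets and 40-ms jitter — ≥ 80% of
  cohorts must be classified as their generating scenario.

# Known limitations

* **The conservative threshold is not a maxT correction.** The highest
  per-window 95th percentile is only a familywise-valid threshold when
  accuracy timecourses are strongly correlated across windows (then the
  per-window nulls and the max null nearly coincide). Under the generator's
  stationary background, windows more than ~300 ms apart are effectively
  independent — roughly seven independent blocks over 0–2000 ms — and the
  measured familywise error is ~30% rather than the nominal ~5%
  ($1 - 0.95^7 \approx 30\%$). Real recordings with long-memory band-power
  envelopes will sit somewhere between the two regimes. A true maxT
  threshold (95th percentile of the per-permutation max over windows) would
  control familywise error exactly, but is deliberately not substituted
  because the max-of-percentiles rule is the procedure being implemented.
* The earliest-significant-peak estimator is intrinsically noisy on broad
  decodability profiles: with a 300-ms window, any effect produces a
  ≥ 600-ms decodable span; accuracy noise of a few percent anchors the
  earliest candidate anywhere on the rising flank, spurious above-threshold
  noise windows (previous bullet) can pre-empt it entirely, and saturated
  plateaus yield exact ties that the strict rule rejects. Measured
  per-analysis anchor noise stays ≥ 130 ms sd across a wide range of
  synthetic designs, consistent with the several-hundred-ms between-subject
  peak spread such analyses show on real data. Group-level ordering
  contrasts absorb much of this at large n, but single-subject peak
  latencies — and recovery claims at small n with tight tolerances — should
  be read with corresponding humility.
* Three-class identity decoding uses one-vs-rest CSP (CSP is inherently
  two-class) with a multi-class Fisher ratio; other multiclass extensions
  exist and would give different features.
* The KS normality screen tests standardized values against the standard
  normal; with estimated parameters it is slightly conservative
  (a Lilliefors correction is deliberately not applied, matching the
  screening role it plays here).
* Artifact rejection is relative; it cannot certify a clean recording, only
  comparable treatment across subjects.
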