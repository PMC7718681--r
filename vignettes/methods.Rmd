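---
title: "Methods: instrumented assessment of upper-limb cerebellar ataxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumented assessment of upper-limb cerebellar ataxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cerebellar ataxia disturbs the accuracy, timing, rhythmicity and stability
of voluntary movement. Clinicians grade it by watching standard bedside
tasks — finger chase (FCT), finger tapping (FTT), finger to nose (FNT) and
rapid alternating hand movements (DDKT) — and scoring them on ordinal scales
such as SARA, whose three upper-limb items sum to the 0–15 SARA-UL score.
Human scoring is coarse and observer-dependent. This package implements an
instrumented version of that assessment: raw motion recordings (a 30 Hz
2-D marker/target trace for FCT; 50 Hz tri-axial accelerometer and
gyroscope streams for the other three tests) are reduced to a fixed catalog
of 62 kinematic features, screened by resampled backward elimination,
and fed to leave-one-out-validated models that (a) discriminate ataxic from
control subjects and (b) regress a severity score `ps` that is bucketed
onto a 4-level scale anchored to SARA-UL.

Because no public recording set exists for this task family, the package
ships a synthetic cohort generator that emulates the study conditions; all
end-to-end guarantees are stated — and tested — on that generator.

## Feature catalog

`catalogFeatures()` enumerates the 62 features (FCT 14, FTT 8, FNT 20,
DDKT 20), each tagged with one STAR domain (Stability, Timing, Accuracy,
Rhythmicity). Names follow `{Feature}_{Test}_{Signal}{Axis}_{Hand}`, e.g.
`MR_FNT_AAcY_L`. FNT linear-acceleration features carry STAR tags by the
same axis-role rule as the angular accelerations (X/Z spectral features →
Stability; the Y-axis RF → Timing), since the published tag table lists
only the angular rows. One published figure refers to 64 features; the
62-item enumeration is internally consistent with the per-test recipes and
is taken as canonical.

### Finger chase (FCT)

* **DTW error** (`dtwError`): accumulated cost of the optimal monotone
  alignment between the demeaned marker and target traces per screen axis,
  with absolute-difference local cost. The defining recursion is
  `DS(i,j) = |S_m(i) − S_t(j)| + min(DS(i−1,j), DS(i−1,j−1), DS(i,j−1))`
  and the feature is `DS(n,n)`. A literal reading of "summing the values
  along the backtracked shortest path" would re-add cumulative entries and
  double-count; the standard accumulated cost is used instead. The
  dynamic program is in C++ (trajectories run to ~1500 samples); its test
  oracle is an independent exponential-time path enumeration in R.
* **Reaction time** (`reactionTime`): the non-negative lag maximising the
  cross-correlation between marker and target per axis, in ms. Lags span
  `[0, T)`; both series are demeaned first, and zero-variance input is an
  error (the correlation is undefined).
* **Kinematic delay** (`kinematicDelay`): Fitts'-law throughput. Per reach,
  `ID = log2(di/ra)` bits (di = distance between consecutive target
  centres, ra = disc radius) and `MT` = time from target onset to the
  marker's first entry into the disc. Where the marker never enters before
  the next jump, the inter-event interval caps MT (no reach is dropped);
  reaches with `di ≤ ra` contribute 0 bits. The feature is the mean
  `ID/MT` in bits/s, one value per hand (2-D distance), counted once per
  hand in the catalog.
* **Acceleration alterations** (`accelAlterations`): sign changes of the
  double-differenced marker position per reach. Raw 30 Hz pixel traces are
  noise-dominated under second differencing, so the position is smoothed
  with a 5-sample moving average first (window surfaced as an argument).
  The catalog stores the per-trial total (mean per reach × 20), matching
  the scale on which group means of ~20–35 are meaningful; the per-reach
  mean is the primitive, so either scaling is derivable.

### Finger tapping (FTT)

* **Tap detection** (`detectTaps`): the source assessment does not specify
  a detector, so one is defined: peaks of the absolute band-passed
  accelerometer Z channel above 3× its median absolute deviation, with a
  150 ms minimum separation. Fewer than 4 taps is an error.
* **CITI** (`citi`): sd/mean of the inter-tap intervals — rhythm
  variability relative to rate, invariant under uniform time rescaling.
* **Fuzzy entropy** (`fuzzyEntropy`, m = 3, r = 0.2·sd): templates are
  mean-centred (standard fuzzy-entropy practice, implied by the cited
  method though not restated in the assessment description), distances are
  Chebyshev, similarity is `exp(−(d/r)²)`, self-matches are excluded, and
  `FuEn = ln φ^m − ln φ^{m+1}`. Both φ averages use N−m templates so the
  pair counts match. FuEn is computed on the 0.3–20 Hz signal, not the
  2–5 Hz band: the complexity loss of disease lives in the broadband
  structure that the narrow band would delete.

### FNT and DDKT spectral features

* **RF/MR** (`rfMr`): the dominant bin of the single-sided amplitude
  spectrum (Hann window, zero-padded to the next power of two for stable
  peak location; the source names no window) and its amplitude. RF is
  constrained to (0, Nyquist); a published table value of 40.3 Hz at a
  25 Hz Nyquist is treated as an artefact and not reproduced. MR is
  reported in input units with no conversion (the published "mV" scale is
  a raw-sensor artefact).
* Signal derivations: angular acceleration is the central finite
  difference of the band-passed gyroscope; angle is its cumulative
  trapezoid with mean removal. Both are the lowest-order unbiased schemes;
  nothing in the source dictates otherwise.
* Filter order: the 2–5 Hz 6th-order band-pass is applied *on top of* the
  0.3–20 Hz conditioning filter (the source leaves the composition
  ambiguous; applying it to the conditioned signal keeps one code path for
  all features and changes in-band content negligibly).

## Preprocessing choices

All filters are zero-phase (forward–backward Butterworth, effective order
doubled). Features compare event timing across channels — a causal filter's
group delay would bias ReTi and MT — and the assessment is offline, so
non-causal filtering is free. Filters are applied per axis independently;
no orientation estimation or gravity separation is attempted (features are
defined on raw axis signals).

## Statistics

`groupCompare` gates on Shapiro–Wilk normality (α = 0.05 per group):
Student's t for two normal groups, Wilcoxon rank-sum otherwise. The effect
size is always Cohen's d with pooled SD — the convention under which the
design effect size of 0.88 for group sizes 14 and 41 at 80% power
reproduces (`minDetectableEffect(14, 41)`, solved by bisection on the
noncentral-t power function). No multiple-testing correction is applied,
mirroring the per-feature α = 0.05 presentation of the source tables.
A published side statement that a correlation effect size of r = 0.30 is
detectable at n = 55 with 80% power is not consistent with the Fisher-z
approximation; it is noted and not used.

## Feature selection

`fbeOnce` implements one elimination pass: draw 90% of subjects (stratified
by group so both classes are always present), fit a linear model of
SARA-UL on the current features, and repeatedly remove the feature with
the largest partial p-value above α until all survive at α. The
"conditional independence given the selected set" test is realised as the
nested-model partial F (coefficient t) test — the source describes a
regression-style test without naming one. SARA-UL (the continuous score)
is the response; a binary-label variant would discard the severity
gradient the flowchart's "predicted score" implies. When features outnumber
subsampled rows, a marginal-correlation prefilter cuts to rows − 2
candidates; exactly singular designs fall back to a ridge-stabilised
refit for their p-values (both logged). `selectionFrequency` repeats this
100 times (default) and ranks by survival frequency, ties broken by mean
partial F. Baseline rankers delegate where mature implementations exist:
random-forest permutation importance (`randomForest`), lasso activation
order along the `glmnet` path; ReliefF is implemented directly (no
installed package provides it). The default operating point keeps the top
k = 22 features.

## Models and validation

Everything is leave-one-out over subjects, with fold-internal
standardisation (mean/sd learned on the training fold only). Four
classifiers are exposed; hyperparameters the source omits are fixed as:
QDA with class covariances shrunk toward their diagonal by 10⁻³ (folds
have ~13–24 controls against up to 22 features; unregularised QDA is
singular there, which is also why QDA is implemented directly rather than
via `MASS::qda` — the latter serves as an independent cross-check on
well-conditioned data), KNN with k = 5, radial SVM with the median
pairwise-distance bandwidth heuristic. Class imbalance (41 vs 14 by
default) is left as-is; MCC is reported to expose it. AUC is the rank
statistic of the pooled held-out scores.

Severity uses ridge regression on SARA-UL with the penalty chosen per
outer fold by *exact* inner leave-one-out over λ ∈ {10⁻³ … 10³} via the
hat-matrix identity (closed form, so the inner loop costs one solve per
λ). Held-out predictions `ps` are bucketed as `ps < 4 → 0`,
`4 ≤ ps < 7 → 1`, `7 ≤ ps < 10 → 2`, `ps ≥ 10 → 3` — half-open intervals
exactly as printed in the source scale, on the SARA-UL *sum* (0–15) scale,
which is the only reading under which a threshold of 10 is reachable.
Agreement is tabulated against the bucketed observed SARA-UL.
`evaluateTestGroups` reruns selection + both models on the feature subsets
of the test combinations G1 = FCT+FTT … G6 = FCT+FTT+FNT.

## The synthetic cohort generator

`simulateCohortData` draws `round(n · 41/55)` ataxic subjects with latent
severity s ~ U(0.4, 3) and the rest as controls at s = 0, and maps
severity to SARA-UL as `clamp(round(3s + N(0, 0.5)), 0, 15)`. Every knob
is a linear function of s, monotone in the direction the clinical group
differences run:

* **FCT**: 20 target jumps on a 1920×1080 px field (radius 40 px). The
  marker waits a reaction delay (400 + 90s ms), then performs a
  minimum-jerk reach (duration 0.70 + 0.12s s) with an overshoot excursion
  of (0.02 + 0.12s)·di and settle-back, plus narrowband 2–5 Hz tremor of
  (1 + 8s) px and 1 px white noise. The next target appears when the
  settle completes. The delay/duration pair is calibrated so extracted
  reaction times land near 750 ms for controls and near 1100 ms at
  s = 2.5, the anchor means of the clinical tables; minimum-jerk bases
  were chosen because they are smooth, physiologic and closed-form (so
  the acceleration-alteration oracle is analytic).
* **FTT**: 15 s at 50 Hz; taps at mean ITI 0.4 s with cv = 0.05 + 0.07s;
  each contact is a ~50 ms band-limited Gaussian transient (amplitude ~8)
  on accelerometer Z. Background movement on all channels is a
  complexity-weighted mixture `w·white + (1−w)·slow oscillation` with
  w = 0.75 − 0.18s: ataxic movement is *less* complex, so fuzzy entropy
  falls with s (complexity-loss direction).
* **FNT/DDKT**: a primary-axis oscillation inside 2–5 Hz whose frequency
  (3.2 − 0.25s Hz) and amplitude (gyro 2.0 − 0.45s) decrease with s, with
  secondary-axis narrowband leakage (0.15 + 0.45s) increasing with s —
  proximal instability bleeding into non-primary axes. DDKT effects are
  deliberately milder (smaller slopes, more sensor noise), mirroring the
  clinical finding that FCT+FTT outperforms FCT+DDKT.

What the generator does **not** emulate: real contact dynamics and sensor
saturation, gravity components and orientation drift, fatigue and learning
across a trial, disease-subtype signatures, missing/corrupted recordings,
and between-subject kinematic idiosyncrasies beyond the severity axis.
Passing end-to-end tests therefore demonstrates that the pipeline recovers
a severity signal *of the stated shape* from plausibly structured raw
signals — not clinical performance. The published cohort-level values
(ACC 96.4%, AUC 0.97, ρ = 0.8) are properties of a clinical dataset that
is not publicly deposited and are deliberately not asserted anywhere.

## Numerical and scale choices

* Problem sizes: the test suite exercises the full pipeline on one
  100-subject generated cohort (seed 0) — large enough for stable
  selection frequencies and LOO metrics while keeping the suite quick —
  and smaller cohorts for I/O and determinism checks. Brute-force DTW
  oracle comparisons run exhaustively over all sequence pairs of length
  ≤ 3 on the {0,1,2} grid plus 200 seeded random pairs of lengths 4–6.
* Degenerate inputs: zero-variance series are errors for correlation-type
  operations; all-zero signals are errors for spectral peaks; MCC with a
  zero denominator is defined as 0 (logged); aliased design columns are
  handled by the ridge-stabilised refit.
* Ties: ranking ties break by mean partial F, then feature name, keeping
  reports byte-stable under a fixed seed.

## Limitations

Feature magnitudes that depend on unspecified hardware scaling (MR,
DTWEr, AcAlt) are only meaningful within a consistently recorded cohort.
The severity mapping assumes a monotone severity→kinematics link; floor
knobs clip at high s. FBE inherits the instability of stepwise selection;
the resampled frequency is the mitigation, not a cure. LOO estimates have
high variance at n = 55-scale cohorts; MCC and AUC are reported alongside
accuracy for that reason.
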