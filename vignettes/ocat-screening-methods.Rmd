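---
title: "Oculometric screening for possible MCI: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculometric screening for possible MCI: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocatscreen)
```

## The screening problem

A one-minute oculo-cognitive addition test (OCAT) presents sequences of
three numbers at different screen positions; the participant mentally
adds them and clicks to advance. Position within a sequence carries
increasing working-memory load (low/medium/high), and the spatial layout
forces saccades across horizontal, vertical and diagonal planes. The
hypothesis behind the test is that early cognitive decline shows up in
oculomotor control and response timing — longer saccadic latencies,
longer and more dispersed fixations, more blinks, noisier pupil dynamics,
slower completion — before it is obvious clinically.

The package implements the full analysis chain for this design:
simulation of raw 120 Hz gaze recordings, quality control, eye-movement
event classification, a 31-feature oculometric dictionary, leakage-safe
tabular preprocessing with minority oversampling, two-step feature
selection, and bootstrapped evaluation of thresholded logistic-regression
and k-nearest-neighbour screeners. The screening label is operational:
participants with a Mattis Dementia Rating Scale (DRS) score below 140
are labelled "possible MCI" (PMCI), everyone at or above 140
"cognitively normal" (CN).

No raw cohort is distributed with the package, so a first-class
synthetic-data generator stands in for acquisition. Everything downstream
of acquisition treats a simulated recording exactly as it would treat a
real one in the same CSV dialect.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `generate_cohort()` renders
them. Group sizes default to the studied composition (166 CN, 40 PMCI).
Per group, each participant draws latent parameters from truncated
normals:

| parameter | CN mean (SD) | truncation | units |
|---|---|---|---|
| age | 64.9 (8.9) | [21, 99] | years |
| DRS | 142.1 (1.5) | [140, 144] | points |
| saccadic latency | 200 (40) | [100, 400] | ms |
| fixation duration scale | 250 (50) | [120, 600] | ms |
| fixation jitter SD | 6 (1.5) | [2, 20] | px |
| blink rate | 15 (7) | [2, 40] | /min |
| blink duration | 160 (40) | [80, 450] | ms |
| pupil baseline | 3.5 (0.4) | [2, 6] | mm |
| pupil noise SD | 0.10 (0.04) | [0.02, 0.30] | mm |
| think time | 1800 (350) | [800, 4000] | ms |

PMCI DRS follows N(135.9, 3.2) truncated to [100, 139], so the DRS label
rule holds by construction; the truncation bounds were chosen to enforce
the rule and the instrument's 0–144 range. The PMCI oculomotor effects
default to +40 ms latency, ×1.3 fixation duration, ×1.4 jitter SD,
+4 blinks/min, ×1.5 pupil noise SD, ×1.25 think time and +3 years of
age. These magnitudes are the package's own working conditions — large
enough for stable pipeline recovery, not claims about effect sizes in
any clinical population. All of them scale with a single `effect_scale`
knob; `effect_scale = 0` produces a null cohort whose groups differ only
in DRS and label, which is what the calibration tests exercise.

The forward model renders, per stimulus: a dwell on the previous target
composed of sub-fixations (Gamma-distributed durations with mean equal
to the fixation scale, centres relocating 0.8–2° around the target,
white Gaussian jitter within each sub-fixation); a targeting saccade
after the participant's latency plus trial noise, with main-sequence
duration (21 ms + 2.2 ms/deg) and a smoothstep position profile; and a
click at onset + think time × workload multiplier (1 / 1.2 / 1.5 for
positions 1–3). Two behavioural constraints matter for measurement
fidelity: exploratory relocations stop at stimulus onset (gaze holds
until the targeting saccade — scanning belongs to the thinking phase),
and blinks are suppressed during target acquisition windows and
separated by a refractory gap, with durations drawn inside [100, 450] ms
so that a real blink is never lost at the detector's own 75/500 ms
boundaries. Pupil size is baseline plus a workload-dependent increment
(0.05/0.10/0.18 mm for positions 1–3) plus Gaussian noise. Isolated
invalid samples (0.4%) and rare valid-but-implausible spikes (0.1%)
exercise quality control.

What the generator deliberately does not emulate: calibration drift,
smooth pursuit, vergence, head motion, asymmetric saccade dynamics,
pupil light reflexes, or any dependence of oculomotor parameters on the
arithmetic content. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers what this signal model encodes —
not that the classifier performance transfers to clinical recordings.

## Quality control

The tracking ratio is the fraction of raw valid samples; recordings
below 80% are excluded, with "meets 80%" read inclusively (a ratio of
exactly 0.80 is kept). The ratio is always computed on the acquisition
flags — interpolation never improves it.

Spike correction invalidates samples whose angular velocity both into
and out exceeds 1000 deg/s (an out-and-back excursion no eye movement
produces; saccades peak well below that), then linearly interpolates
invalid gaps no longer than 75 ms between valid neighbours, one-sided at
recording edges. Longer gaps stay invalid: those are blinks (75–500 ms
runs, detected on the raw flags) or signal loss (longer). A running
median (window 3) optionally smooths single-sample noise. Despiking is
idempotent.

## Event classification and the feature dictionary

Fixations come from the classic dispersion-threshold algorithm (I-DT): a
window covering at least the minimum duration is opened and extended
while its dispersion — (max x − min x) + (max y − min y), converted to
visual degrees — stays at or below threshold. Defaults are 1.0° and
100 ms, the textbook operating point for 120 Hz data; invalid runs split
the data and no event ever spans a gap. The interval between two
consecutive fixations becomes a saccade when their centroids are more
than the dispersion threshold apart; each saccade carries its amplitude,
median inter-sample velocity, direction and plane (±22.5° bins around
the axes).

Two quantities needed definitions the source material leaves open, and
they are deliberately simple:

* **fixation size** — the largest pairwise distance among the fixation's
  samples, in millimetres on screen;
* **fixation area** — the convex-hull area of those samples, in mm².

Pixel-to-millimetre conversion assumes square pixels on the 14″
1920×1080 panel (0.1614 mm/px); degrees use the arctangent at 600 mm
viewing distance.

Saccadic latency per stimulus is the start time of the first saccade
after onset (and before the next onset) whose direction lies within ±45°
of the direction from the saccade's own start position to the new
target; stimuli with no qualifying saccade yield missing values that are
excluded from the latency mean/SD. The ±45° gate rejects intrusive
saccades away from the target.

`ocat_feature_dictionary()` enumerates the 31 features — 6 time-related
(total test time; mean response time per workload position; latency mean
and SD) and 25 eye-movement-related (per-position fixation time, size
and area, mean and SD; per-plane median saccadic velocities; blink rate
and median duration; pupil-size SD and coefficient of variation) — with
display names, category, and which features are designated for log
transformation (the latency pair and all per-position SDs). Age is
appended to every feature table and participates in all feature-set
modes.

Two aggregation choices worth knowing: latency statistics pool all
stimuli (including the first of each sequence), and fixations are
attributed to the stimulus whose onset interval contains the fixation
start, so the dwell that continues past the next onset stays with the
stimulus it was serving.

## Preprocessing, balancing, standardization

The order is fixed: log transform → stratified split → (training-only)
imputation → SMOTE → standardization. The default log policy transforms
the dictionary's designated set; a data-driven alternative applies the
|skewness| > 1 rule (adjusted Fisher–Pearson estimator) computed on
training rows only. Zero values are offset by 10⁻⁶ of the feature's
positive training median before the log; negative values are an error.

The stratified 80/20 split rounds per-class test counts with
largest-remainder reconciliation; 166/40 yields 33/8. Because externally
given partitions may not follow that rule, per-class test counts can be
overridden — that is how the 135/29 + 31/11 composition used in the
balancing checks is constructed.

SMOTE interpolates uniformly between a minority row and one of its k = 5
nearest minority neighbours (Euclidean, on raw — unstandardized —
features, matching the stated preprocessing order) until the minority
count equals the majority count; synthetic rows are flagged and the test
partition is never touched. Missing feature values (a session with no
blinks has no median blink duration; an empty saccadic plane has no
velocity median) are imputed with training medians before balancing.
Standardization is fitted on the (post-SMOTE) training table and applied
unchanged to the test table; zero-variance features get SD 1 with a
warning rather than NaNs.

## Two-step feature selection

Step one groups features as the connected components of the graph with
an edge wherever |Pearson r| > 0.8 on the training rows. Components
rather than cliques: the choice is deterministic, transitive, and the
common practice; a chain A–B, B–C lands in one group even if A–C is
weaker. One random forest (500 trees, fixed seed) fit on all features
ranks importance (mean Gini decrease), and each multi-feature group
keeps only its most important member; ties keep the earlier feature in
dictionary order.

Step two scores each surviving feature with a single-feature decision
tree and stratified 5-fold cross-validated ROC-AUC, dropping features at
or below 0.5. The tree is grown (maxdepth 3) and then cost-complexity
pruned with the one-standard-error rule on the internal cross-validated
error, with one refinement: the root row's relative error is taken as
identically 1, because a constant classifier needs no cross-validated
estimate of its own error. The refinement is what gives the ≤ 0.5 rule
its intended meaning. Held-out AUC of any always-splitting tree on a
label-independent feature is symmetric around 0.5 (label-flip
exchangeability), so such a filter would drop noise features only half
the time, like a coin flip; with honest pruning, a feature that cannot
beat chance by more than one standard error collapses to the root,
predicts a constant, scores exactly 0.5 and is excluded. On simulated
null features this drops ~70–75% of repeats while leaving informative
features (AUC 0.8–1.0) untouched. A resubstitution mode exists for
comparison.

Selection runs once, on the balanced training table (preprocessing
including SMOTE precedes selection in the workflow order), and both
balancing arms compare models over the same feature list. Age is treated
like any other feature during selection but is always restored to the
modeling feature set.

## Models and evaluation

**Logistic regression** is ridge-penalized (glmnet, alpha = 0) on
standardized features with an unpenalized intercept. The penalty applies
to the per-observation objective with a fixed lambda = 0.005, a weak
ridge comparable at a few hundred training rows to common solver
defaults. Fixing lambda per observation — rather than scaling it with
1/n — makes the fit a function of the empirical training distribution
only, so duplicating every row leaves the coefficients unchanged; that
invariance is asserted in the tests. Decisions use two a-priori
thresholds, 0.45 and 0.50, with ties called positive.

**KNN** uses Euclidean distance and uniform weights; k is chosen in
3–10 by mean stratified 5-fold cross-validated F1 on the training set
only (accuracy available as an alternative criterion), smallest k on
ties. Probabilities are the neighbour vote fractions, thresholded by the
package (not by the underlying vote winner) so tie handling is explicit.

Metrics are recall, precision, specificity, F1, accuracy — with
zero-denominator cases reported as 0 and flagged, never NaN — and the
area under the precision–recall curve computed as average precision
(stepwise sum of precision × recall increments, no interpolation).
Uncertainty comes from resampling the held-out test set with replacement
1000 times with the trained model fixed, sharing replicates across
metrics, redrawing (and logging) replicates that lack a positive or
negative case, and reporting replicate means with percentile 2.5/97.5
limits.

Two cautions about small test splits. First, average precision is biased
upward under the null for few positives (roughly p(1 + (1−p)/(P+1)) for
P positives at prevalence p), which is why the null-calibration checks
use test splits with 8 positives rather than 3–4. Second, rate-type
features are information-limited by session length: at the default
3-sequence session (~25 s) the Poisson counting noise of a blink-rate
estimate (SD ≈ 5.5/min) is comparable to the between-participant spread
(7/min), capping any attainable correlation near 0.8; the
parameter-recovery analyses therefore use 18-sequence (~2 min) sessions,
where all four latent parameter classes are identifiable (r > 0.9).

## Problem sizes used by the checks

The packaged verification suite simulates: 50 cohorts of 206 for DRS
calibration; one 200-participant cohort (18 sequences) for parameter
recovery; 20 null cohorts of 200 (zero effect) for AUPRC-vs-prevalence
calibration plus 50 null repeats (n = 2000) for the selection filter;
and 20 default-effect cohorts of 75 for the directional comparisons
(balancing raises recall; the combined feature set's AUPRC is at least
each single set's). These sizes were chosen so each check's Monte-Carlo
error is small against its acceptance band.

## Known limitations

* The generator's group differences are stylized, independent draws; it
  encodes no correlation structure between latent parameters (a real
  cohort's latency and completion time correlate through more than the
  label), so feature-correlation patterns are weaker than in real data.
* Event classification is dispersion-based only (no velocity-threshold
  variant, no microsaccades, no smooth pursuit), matching the intended
  method rather than the state of the art.
* The DRS-based binary label is itself a coarse screening construct;
  nothing here validates against clinical adjudication.
* Single 80/20 splits at n = 206 leave wide bootstrap intervals; the
  workflow reports them honestly rather than averaging over repeated
  splits, because that is the design being reproduced.
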