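---
title: "Model-based neurophysiological indices from EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based neurophysiological indices from EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegindex)
library(dplyr)
```

## The problem

A viewer's affective and cognitive response to a video clip varies second
by second, and verbal reports collected afterwards cannot resolve it in
time. `eegindex` implements a model-based alternative: for each subject,
short calibration recordings made under a known state (a neutral baseline
versus a happiness-, surprise-, or attention-inducing stimulus) are used
to train a two-class discriminant on spectral EEG features. Applying that
classifier to each quarter-second window of a novel recording — a TV
commercial, say — yields a posterior probability that the window expresses
the target state, which becomes an index time series on a [-1, 1] scale.
Clips can then be ranked by mean index across subjects, and the
group-average trajectory inspected for supra-threshold peaks that point at
specific scenes.

The pipeline assumes a 14-channel consumer montage (AF3, F7, F3, FC5, T7,
P7, O1, O2, P8, T8, FC6, F4, F8, AF4 in the 10/20 system) sampled at
128 Hz, but every stage takes the montage and rate from its input.

## Preprocessing

Recordings are band-pass filtered, re-referenced to a common average, and
split into contiguous quarter-second windows (32 samples at 128 Hz), with
a trailing partial window dropped.

The conventional analysis band for this montage is quoted as 0.5–100 Hz,
which cannot be realised at a 128 Hz sampling rate (Nyquist 64 Hz). The
filter therefore clamps the upper edge to 0.45 × rate (57.6 Hz) and warns.
Since every band feature lies below 50 Hz, the clamp does not affect the
features. The filter itself is a Butterworth design applied zero-phase
(forward–backward): a cascade of a 2nd-order high-pass at the low edge and
a 2nd-order low-pass at the high edge, giving a 4th-order magnitude
response in each direction. The cascade form was chosen over a single
band-pass polynomial because a band edge at 0.5 Hz against a 64 Hz Nyquist
puts a direct 8th-order polynomial filter near its numerical stability
limit, while the cascade is well conditioned. Filtering and re-referencing
are both linear and time-invariant, so their order is immaterial (this is
tested).

## Band-power features

Each window of each channel is Hann-tapered and zero-padded to 256 points,
placing the periodogram on a 0.5 Hz grid; a 32-sample window has a native
resolution of 4 Hz, and zero-padding is the only reading that reconciles a
quarter-second window with a 0.5 Hz analysis grid. The power spectral
density is averaged over the bins of six bands — delta [0.5, 4), theta
[4, 8), alpha [8, 12), low beta [12, 20), high beta [20, 30) and gamma
[30, 50] Hz, half-open so shared edges are not double-counted — giving
14 × 6 = 84 features per window. Features default to
`log10(power + 1e-12)`: the log stabilises variance for the downstream
ANOVA and the Gaussian posterior model; raw power is available via
`transform = "raw"`.

Two caveats are inherent to quarter-second windows and are left
uncorrected deliberately: the delta band is poorly resolved (less than one
period of a 2 Hz component fits in the window), and the Hann mainlobe
(~8 Hz at this window length) smears a planted narrow-band effect into
neighbouring bins. Consequently a band-power *ratio* measured through the
feature path is diluted relative to the generating ratio; calibration
checks of the synthetic generator therefore use a long-window periodogram
oracle, not the feature path.

## Feature selection

For each subject and index, neutral and target-condition windows are
pooled and labelled, and each of the 84 features is scored with a one-way
ANOVA F value (for two classes, exactly the squared pooled-variance t
statistic). The highest-F feature seeds a greedy forward search: at each
step the candidate that maximises tenfold cross-validated accuracy of the
augmented set is added, and the search stops at the first step whose best
achievable accuracy is strictly below the current one.

Three details the source procedure leaves open are fixed as follows, and
recorded in each result's metadata sidecar:

* **Plateaus.** A step whose best accuracy *equals* the current accuracy
  continues the search, but features added during a plateau are kept only
  if a later step strictly improves; otherwise the returned set is
  truncated at the last strict improvement. This honours "until accuracy
  begins to decrease" without letting plateaus grow the set unboundedly.
* **Ties.** Candidates tied on accuracy are resolved by higher F value,
  then lower feature index — consistent with the ANOVA seeding.
* **Folds.** One stratified fold assignment is drawn per subject/index
  from the configured seed and reused for every candidate evaluation;
  accuracies over a common denominator are compared exactly (tolerance 0).
  A hard cap at the full feature count guarantees termination.

A known limitation follows from the fixed folds: the greedy maximum over
~80 candidates can keep finding one-window improvements under a pure null,
so null chosen-set sizes average around five rather than collapsing to
one or two. This is selection overfitting, visible in the final CV
accuracy of null runs (~0.55–0.64), and is why reported CV accuracies
should be read as selection-optimised, not unbiased, estimates.

## The discriminant and its posterior

The classifier is Fisher's linear discriminant: the projection `w`
maximising J(w) = (wᵀS_B w)/(wᵀS_W w), with S_B the between-class scatter
of the two class means about the grand mean and S_W the within-class
scatter. For two classes the maximiser is `w ∝ (S_W + λI)⁻¹(μ₁ − μ₀)`;
a small ridge `λ = 1e-6 · tr(S_W)/d` guards against a singular S_W when
the window count is small relative to the selected dimension, and `w` is
normalised to unit length with its sign fixed so the target class projects
higher.

The source procedure reports posterior probabilities without stating how
they are produced. The package's contract is the minimal generative
completion of the Fisher projection: one-dimensional Gaussian
class-conditionals on z = wᵀx with the projected per-class means and
variances and **equal priors** (calibration sessions have arbitrary,
design-determined lengths that should not bias the index). A
pooled-variance option is available; a zero class variance falls back to
the pooled variance, and if that is also zero, to a hard threshold at the
projected midpoint. Ties at posterior 0.5 classify as the target class.

## Scoring, ranking, peaks

A clip's index series is `2p − 1` per window — the unique affine map of
[0, 1] posteriors onto the [-1, 1] index range. Subject means are averaged
into a group mean ± SD per clip and ranked (rank 1 = largest mean, ties by
clip label order). The group-average series (subjects truncated to the
shortest window grid) is scanned for maximal runs of windows whose value
exceeds a threshold (default 0.5); adjacent supra-threshold windows merge,
and isolated single windows are valid quarter-second peaks. No temporal
smoothing is applied before peak detection — quarter-second peak spans are
meaningful output — though averaging across subjects already suppresses
most single-subject noise.

Because the posterior-to-index map is affine, averaging posteriors and
then normalising equals normalising and then averaging; the package
normalises per window first.

## Behavioural scoring

Preference, short-term-memory and recall rankings of n clips convert to
points as `n + 1 − rank` (4/3/2/1 for four clips); purchase intention
stays on its 1–7 Likert scale. Group comparison is a one-way ANOVA across
clips followed by all pairwise paired t-tests with Holm adjustment,
flagged at α = 0.05 and 0.01. Points are treated as interval-scaled, as
their construction implies; a rank-based alternative (Friedman omnibus +
paired Wilcoxon) is available via `method = "rank"` for readers who
prefer not to make that assumption. The post-hoc procedure is a package
choice — the source reports pairwise significance without naming a test —
and Holm-adjusted paired t-tests were picked as conservative and
appropriate to the within-subject design.

## The synthetic generator

No recorded EEG ships with the package, so a generator produces sessions
with known ground truth:

* **Background**: stationary Gaussian 1/f^α noise per channel (α = 1 by
  default, spectral floor at 0.5 Hz, total SD 10 µV), realised by spectral
  shaping of white noise. This matches the broadband shape of resting EEG
  without modelling physiology. Channels are independent by default; a
  `shared_source` fraction mixes in a common source when inter-channel
  correlation matters.
* **Planted effects**: per condition, a list of (channel, band,
  multiplier ≥ 1) cells. Each effect adds an independent band-limited
  Gaussian oscillation whose variance is (multiplier − 1) times the
  background's analytic band variance, so the expected band power equals
  the neutral level times the multiplier — exactly, by construction.
* **Commercials**: a trajectory g(t) ∈ [0, 1] (function or
  piecewise-linear breakpoints) scales the planted effect's instantaneous
  power so band power interpolates linearly between neutral (0) and the
  full multiplier (1); the per-window trajectory values are returned as
  ground truth, one per 0.25 s.

Determinism: each (config seed, condition) pair maps to its own RNG
stream, so identical configurations regenerate bit-identical sessions and
different conditions are independent.

What the generator does **not** emulate — ocular/muscle artifacts, volume
conduction, nonstationary baselines, between-session impedance drift —
bounds what passing tests show: they demonstrate that the pipeline
recovers known spectral structure under realistic noise, not that it is
robust to artifact-laden recordings.

### Default study conditions

Validation studies use 60 s calibration sessions and 30 s clips (240 and
120 quarter-second windows), six subjects, four clips, and the
happiness-assigned cells FC5-gamma and T8-high-beta planted at multiplier
2.5 — channel/band choices that mirror where high-frequency happiness
features concentrate in real data, and an effect size at which per-window
classification is good but not saturated. The planted clip's trajectory is
a trapezoid (rise over 7.5 s, hold, fall), which exercises both
intermediate intensities and a sustained plateau. Null calibrations use
200 windows per class. These sizes are the package's standard validation
scale; they keep a full 20-seed recovery study to a few minutes on one
core.

## Numerical choices, in one place

* Band membership: bin centre in [low, high); gamma closed at 50 Hz.
* Log features offset: `+1e-12` before `log10`.
* Filter: zero-phase Butterworth cascade (2nd-order HP + 2nd-order LP);
  upper edge clamped at 0.45 × rate with a warning.
* Ridge: `1e-6 · tr(S_W)/d`, overridable.
* Accuracy comparisons in selection: exact (common denominator).
* Coincident class means: `w` falls back to the first coordinate axis
  with a warning rather than failing.
* EDF I/O quantises to 16 bits over the per-channel physical range;
  round-trips agree to one quantisation step.

## A worked miniature

```{r mini, eval = FALSE}
effects <- tibble::tibble(condition = "happiness", channel = "FC5",
                          band = "gamma", multiplier = 2.5)
cfg <- synth_config(effects = effects, session_length = 60, seed = 1)

lab <- label_features(
  band_power_features(eeg_preprocess(simulate_session(cfg, "neutral"))),
  band_power_features(eeg_preprocess(simulate_session(cfg, "happiness"))))
sel <- select_features(lab, seed = 1)
fit <- flda(lab, features = sel$chosen$feature)

clip_cfg <- synth_config(effects = effects, session_length = 30, seed = 1)
sim <- simulate_commercial(clip_cfg, trajectory_triangle(15, 30), "C1")
series <- score_clip(band_power_features(eeg_preprocess(sim$recording)),
                     fit, "S01", "happiness", "C1")
plot_index_series(series, detect_peaks(series))
```

## Known limitations

* Reported CV accuracies are maximised by the selection loop and carry
  optimistic bias; an unbiased estimate would need nested CV, which the
  procedure being implemented does not use.
* The posterior model is a design choice; differently calibrated
  posteriors (logistic, isotonic) would change index magnitudes, though
  not the ranking direction.
* Quarter-second windows limit spectral resolution; delta-band features
  are noisy by construction.
* The generator's effects are stationary within a window and confined to
  one band; real affective EEG is neither.
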