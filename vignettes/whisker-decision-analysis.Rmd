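---
title: "Methods: decoding pole location and choice from whisker mechanosensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding pole location and choice from whisker mechanosensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskertask)
```

## The task and the analysis problem

A head-fixed mouse uses a single whisker to locate a vertical pole
presented at one of three positions (posterior, middle, anterior) along its
anterior–posterior axis, and reports the position with one of three
responses. Choices are labelled by the location for which they are correct,
so locations and choices share one label set. High-speed imaging (1000
frames/s) yields, per trial, the whisker angle θ (degrees; 0° is the
anterior–posterior axis, nose to tail, so protraction increases θ), the
whisker curvature κ near the base (mm⁻¹; curvature change Δκ is
proportional to the bending moment of the contact), and the minimum
whisker–pole distance. The analysis turns those traces into a small set of
per-trial predictors, decodes pole location and mouse choice from them with
a probabilistic classifier, and quantifies how much of the behaviour —
especially errors — is driven by sensory evidence versus choice history.

## Feature extraction

**Frame quality.** Frames that fail tracking are flagged `dropped`. A
single dropped frame flanked by good frames is linearly interpolated in θ
and κ and reflagged; runs of two or more dropped frames are left flagged
and treated as unresolved (`fill_isolated_gaps()`).

**Touch episodes.** A touch episode is a maximal contiguous run of frames
with whisker–pole distance below a threshold (`detect_touch_episodes()`).
The threshold is a configuration parameter (default 0.5 mm against the
generator's 2 mm baseline / 0.1 mm contact distances) because in practice
it is tuned per recording setup. Dropped frames inside a candidate run
split the run, with a warning; detection is invariant to any monotone
rescaling of the distance channel that preserves the threshold crossing
set.

**Whisking phase and amplitude.** The whisker angle is mean-removed and
band-passed (2nd-order Butterworth, zero-phase forward–backward filtering)
over a configurable band, default 4–30 Hz, bracketing the whisking
fundamental of head-fixed mice (~5–25 Hz). The phase and magnitude of the
analytic signal (FFT construction) give the whisk phase and the
whisking-amplitude envelope. Conventions: phase in (−π, 0) means the angle
is rising — protraction; phase in (0, π) retraction; the measure-zero ties
at exactly 0 and ±π are assigned to retraction. These are arbitrary,
documented rules; all direction statistics inherit them.

**Touch type.** Each episode is labelled protraction or retraction from
the phase at its start frame (first good frame of the episode if the start
is dropped). The trial-level *touch type* is the direction of the first
episode, or `none`.

**Δκ95.** For the first touch episode, the baseline is the median κ over
the 6 frames immediately preceding touch onset (exclusive of the onset
frame; at 1 kHz, 6 ms). Δκ(f) = κ(f) − baseline over the episode's good
frames; Δκ95 is whichever of the 5th and 95th percentiles of those values
has the larger absolute value, with ties going to the 95th (consistent
with the protraction-positive sign convention). Percentiles use linear
interpolation between order statistics (`stats::quantile` type 7); the
test oracles implement the same convention independently. Δκ95 is zero by
definition on no-touch trials. If all six baseline frames are dropped the
trial is flagged unusable and excluded — mirroring the retrack-or-discard
rule applied to dropped frames during first touch in curated data — and
the pipeline reports the excluded count.

**Previous choice type.** A six-valued categorical predictor: the previous
trial's choice crossed with its correctness. It is undefined on the first
trial of each session, and those trials are excluded from every
previous-choice computation.

## The MAP classifier

`nb_map()` fits P(y = k | x₁…x_R) ∝ π(k)·∏ⱼ P(xⱼ|y = k) with class priors
equal to training relative frequencies, multinomial conditionals for
categorical predictors and Gaussian conditionals for continuous ones,
assuming conditional independence of predictors given the class. Numerical
choices:

* posteriors are computed in the log domain and normalized per trial;
* zero-frequency or unseen categories contribute a floor probability of
  1e−9 — this avoids −∞ log posteriors without materially affecting MAP
  decisions;
* Gaussian conditional standard deviations are floored at 1e−6 (predictor
  units), with a message when the floor binds;
* the predicted class is the posterior argmax; ties — including exact
  rational ties that floating-point rounding would otherwise break
  arbitrarily — go to the earlier class in the fixed order (posterior,
  middle, anterior), detected with a 1e−9 log-domain tolerance.

Gaussian conditionals are the canonical choice for Δκ95; within a class
they pool touch and no-touch trials (the zeros), which is deliberate — the
class-conditional distribution of the *predictor as defined* is what the
classifier should see.

Evaluation uses tenfold cross-validation: trials are randomly allocated to
folds of as-equal-as-possible size, each fold predicted by a model trained
on the rest, predictions concatenated in trial order. A partition that
leaves a class absent from some training split is resampled (bounded
retries). Two metrics: *classifier performance* (fraction of trials with
correctly predicted pole location) and *choice consistency* (fraction
where the classifier's implied choice, through the location→correct-choice
bijection, equals the mouse's). Chance levels repeat the whole
cross-validation on label-shuffled data, 50 iterations by default, and
report the mean and the 2.5/97.5 percentile interval. The "95% confidence
interval" is defined as that percentile interval throughout; the method is
stated here because percentile and Gaussian-approximation intervals differ
slightly at 50 iterations.

## Behavioural statistics

**Task performance** is the proportion of correct trials; its chance
distribution shuffles the pole-location sequence against the fixed choice
sequence 10,000 times. A session is above chance when performance exceeds
the 97.5th percentile. Learning is the first of three consecutive
above-chance sessions; asymptotic performance is the mean over the latest
window of eight consecutive above-chance sessions.

**Perseveration** is P(choice_t = choice_{t−1}) over selected trials
(t ≥ 2): all trials, current-correct only, or current-error only. The
shuffle null permutes the full choice sequence and recomputes the
statistic on the same subset positions — this preserves the subset
structure while breaking sequential dependence. The all-trials statistic
is exactly the subset-size-weighted average of the correct- and
error-subset statistics, which the tests assert. A further conditional
splits perseveration on error trials by whether the previous trial was
correct or an error.

**Double dissociation.** `dissociation_analysis()` predicts mouse choice
twice under one shared fold assignment — once from sensory predictors
(touch type + Δκ95), once from the previous choice type — then evaluates
accuracy separately on correct and error trials, each against a shuffle
null recomputed on the same subset positions. Training on all trials and
splitting only the evaluation follows the logic that the animal's policy,
not the classifier, differs between the subsets. The fold assignment is
shared so that the sensory/history comparison never reflects partition
luck. Results are invariant to session concatenation order once the folds
are fixed.

## The synthetic-session generator

The generator produces sessions with the statistical structure the
analysis assumes, with ground truth attached, so every stage can be tested
without animal data.

* **Trial sequencing.** Locations are drawn i.i.d. from the configured
  probabilities, resampling any draw that would create a run longer than
  `max_run` (default 3) — constrained randomization matching the task's
  pseudorandom presentation policy. A single-location configuration with
  `max_run < n_trials` is rejected as unsatisfiable.
* **Whisking.** θ(t) = setpoint + A(t)·cos(2πft + φ₀) + white noise, with
  A(t) stepping from `amp_pre` (2°) to `amp_post` (15°) over a 100 ms ramp
  after pole onset (500 ms into a 2000 ms trial), f = 12 Hz, setpoint
  100°, noise SD 0.5°. This emulates the stereotyped onset of whisking
  after pole presentation.
* **Contact.** Whether a trial has touches is Bernoulli with
  location-dependent probability (0.87 / 0.93 / 0.46 for posterior /
  middle / anterior — the reported touch rates). Touch count (1–4, with
  P(≤3) = 0.84) and direction persistence between consecutive touches
  (0.94, then 0.98) reproduce the reported touch-sequence statistics. The
  first touch is protraction with location-dependent probability (0.25 /
  0.85 / 0.80), encoding the strategy of whisking between the middle and
  posterior positions: the posterior pole is met during retraction, the
  middle/anterior poles during protraction. Each touch occupies a 21 ms
  window centred in the matching half of successive whisk cycles; the
  distance channel drops to 0.1 mm for exactly those frames (a stylized,
  noise-free contact signature that makes boundary recovery exact and
  keeps threshold semantics unambiguous).
* **Bending.** During a touch, Δκ follows a half-cosine rise over the
  first 40% of the episode, a flat plateau at the drawn peak over the
  central 20%, and a half-cosine fall. The plateau means the 95th
  percentile of the episode's Δκ values equals the peak exactly in
  noiseless data (a strictly peaked ramp never attains its maximum under
  interpolated percentiles), so ground-truth recovery can be asserted
  exactly. Peaks are Gaussian per (location, direction), positive for
  protraction and negative for retraction, with sign enforced by
  resampling (so the effective generative law is a sign-truncated normal —
  parameter-recovery tests compare against its closed-form moments).
* **Δκ95 defaults.** The per-(location, direction) means are free
  parameters — the source analysis reports them only graphically. The
  defaults (protraction +0.012 / +0.030 / +0.005 mm⁻¹ and retraction
  −0.030 / −0.010 / −0.005 mm⁻¹ for posterior / middle / anterior, SD
  0.003) encode a grazing-contact gradient: the anterior pole sits at the
  edge of the whisker's reach and produces weak bending, while
  middle-protraction and posterior-retraction contacts bend strongly.
  Class means are separated by ≥ 1.7 SD within each direction, which makes
  Δκ95 genuinely informative beyond touch type, as in the recorded data.
* **Behavioural policy.** With probability λ (`p_perseverate`, default
  0.3) the previous choice is copied; otherwise the trial is
  sensory-guided: correct with probability 1 − ε plus a uniformly random
  choice with probability ε (`sensory_noise`, default 0.15). The first
  trial is forced onto the sensory branch. These defaults place simulated
  task performance near 0.73 with substantial perseveration, the regime of
  trained mice on this task. Under uniform i.i.d. locations the repeat
  probability has the closed form λ + (1 − λ)/3, independent of ε, which
  the tests exploit.

### What the synthetic data do not show

The generator is a statistical emulator, not a biomechanical model: no
video, no beam mechanics beyond the sign/magnitude statistics, a noise-free
distance channel, stationary whisking frequency and set point, perfectly
Markov choice behaviour, and no session-to-session drift, licking
artefacts, or tracking failures beyond an optional uniform frame-drop
rate. Passing tests therefore establishes that the *analysis code* is
correct and well-calibrated under the stated assumptions — not that those
assumptions hold for any particular recording. On real data the touch
threshold, band edges and the handling of curated touches would need
per-dataset attention.

## Problem sizes and runtime choices

The test suite and the acceptance script scale the computations to a
single CPU: the classifier-ordering and dissociation analyses use five
synthetic mice × 760 trials (four 190-trial sessions, the reported
per-mouse scale), null-calibration uses 500 sessions of 179 trials with
10,000-shuffle intervals, oracle equivalence sweeps 1,000 random trials,
and parameter recovery uses 1,000 trials per (location, direction) class.
Classifier chance uses the default 50 shuffle iterations; behavioural
chance uses 10,000.

## Known limitations

* The previous-choice classifier treats history as a single 6-level
  categorical predictor; longer histories (two or more trials back) are
  out of scope.
* Perseveration nulls permute whole choice sequences; block-preserving
  permutations (which would retain slow drifts) are not implemented.
* The nonparametric (kernel) variant of the continuous conditionals is not
  implemented; Gaussian conditionals are canonical here, consistent with
  the observation that results did not depend on that choice.
* `run_report()` aggregates one dataset (one animal's pooled sessions) per
  run; across-animal summaries are composed by the caller (as
  `scripts/acceptance.R` does).
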