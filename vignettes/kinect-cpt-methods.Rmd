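---
title: "Scoring motion-tracked continuous performance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring motion-tracked continuous performance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinectcpt)
```

## The task and what this package computes

In a continuous performance test (CPT) a stream of letters is presented
and the examinee responds to every letter except the forbidden
X-stimulus, for which the response must be withheld. In the
motion-tracked variant this package scores, the response is not a key
press but a raise of the dominant hand, recorded as a ~30 Hz stream of
3-D hand-joint positions. Tracking the whole movement rather than a
key event buys three things a keyboard cannot provide:

* a reaction time (RT) measured from stimulus onset to the moment the
  hand *starts* to rise, rather than to the completed key press;
* a completion time (CT), from movement onset until the hand returns to
  the rest position;
* a *continuous* measure of failed inhibition on X trials — the
  commission index — which also exposes *inhibited commissions*:
  movements begun and aborted, invisible to a keyboard.

The commission index of an X trial is the ratio of the hand-path length
during the X window to the larger of the path lengths in the two
neighbouring trial windows. A perfectly inhibited X trial between two
executed reactions scores near 0; a full-sized reaction to the X scores
near 1.

A participant is summarised by the medians of these per-trial measures:
on a fully compliant 60-stimulus session, 48 RTs, 48 CTs and 12
commission indices. These medians are then correlated with the three
factor scores of the SWAN rating scale (18 items, 0–100 web scoring;
items 1–9 inattention, 10–15 hyperactivity, 16–18 impulsivity), giving
the predictor-by-factor validity report.

## Schedules

Two presets are built in: the revised 3-minute design (60 stimuli, 12 X,
inter-stimulus intervals drawn from {2, 3, 5} s) and the legacy
15-minute design (360 stimuli, ISIs {1, 2, 4} s). Several details of
schedule construction are not fixed by the published task description
and are package policy, chosen once:

* **ISI mix** — each ISI is drawn independently and uniformly from the
  design set; sampling weights are exposed for sensitivity analyses.
* **X placement** — uniform random positions, except that the first
  stimulus is never an X: the commission-index denominator needs a
  preceding trial window.
* **Letters** — non-X letters are drawn uniformly from A–Z minus X.
* **Legacy X count** — the 360-stimulus design's X count is not stated;
  the preset keeps the revised design's 1-in-5 ratio (72), configurable.
* **First onset** — the schedule places the first stimulus at 2 s by
  default. Trajectory timestamps are non-negative by contract, so a
  lead-in recorded *before* a first onset at 0 would be unrepresentable;
  putting the lead-in inside session time keeps the pre-onset baseline
  buffer and premature-movement detection available on the first trial.
  Custom schedules may set `first_onset_s = 0`, in which case the first
  trial's baseline falls back to the session-global estimate.

## Movement-onset detection

The task description says only that RT runs until the participant
"starts to raise" the hand; the operational definition here is package
policy, exposed through `onset_params()`:

* Frame velocities are first differences of hand height. A movement
  candidate begins where a velocity Schmitt trigger arms: velocity
  exceeds `v_min` (default 0.15 m/s) and stays above it for `k = 3`
  consecutive frames (100 ms at 30 Hz); the trigger releases below
  40 % of `v_min`, so a ramp that dips briefly does not restart.
* A candidate becomes a *rise episode* only if elevation above the
  trial baseline subsequently exceeds `rise_min_m` (default 0.05 m).
  Episode counting also uses hysteresis: an episode ends when elevation
  re-enters the rest band (`rest_band_m`, default 0.05 m), which is the
  reported return time.
* The reported onset walks back from the sustained crossing through the
  contiguous frames still above the release threshold — the launch of
  the movement — and lands on the last at-rest sample. With the default
  kinematics this recovers a programmed onset to within one frame; a
  detector that reports only the first supra-threshold frame is biased
  late by up to ~1.3 frames, because the early portion of a smooth
  reach sits between the release and arm thresholds.
* Elevation that creeps above `rise_min_m` without any sustained
  velocity crossing (slow drift) is not a raise.

Defaults were chosen against the physics of the task: a 0.30 m raise in
0.35 s peaks near 1.6 m/s, an order of magnitude above the threshold,
while correlated 30 Hz skeletal jitter of ~1 mm produces frame
velocities around 0.01 m/s. The per-trial rest baseline is the median
hand position over the 0.25 s before stimulus onset (robust to slow
drift), with a session-global fallback (10th-percentile height) when no
pre-onset samples exist.

The detector's state machine is implemented in C++ for throughput; an
independent brute-force R implementation of the same definition lives in
the test suite and in `scripts/acceptance.R`, and the two are required
to agree exactly on 1 000 randomised synthetic trials.

## Per-trial measures and classification

* "Length of the hand displacement" is read as 3-D path length — the
  sum of Euclidean distances between consecutive tracked samples —
  rather than peak excursion; `path_length()` is the single primitive
  used for both the commission numerator and denominator, over each
  neighbour's full trial window (windows are half-open
  `[onset, next onset)` and partition the session).
* When an X-stimulus is last, only the previous neighbour exists and is
  used alone. When both neighbours are effectively motionless (below
  `d_min_m = 0.01` m), the ratio is not computable; such trials are
  classed invalid rather than given an arbitrary index.
* X trials are classed on the continuous index with configurable cuts:
  below `c_lo = 0.1` correct inhibition, `[c_lo, c_hi)` inhibited
  commission (begun and aborted), at or above `c_hi = 0.5` commission.
  The cuts label events for audit plots; the participant median always
  uses the continuous index.
* Non-X precedence: invalid trial (tracking failure, or more than 0.5 s
  untracked) > premature reaction (episode beginning before the
  stimulus) > multiple reaction (two or more episodes) > full reaction /
  partial omission (no return) / omission (no onset). Premature and
  invalid trials contribute to no median; medians over an even count are
  the mean of the central pair.

## The synthetic cohort

The simulator exists so the pipeline is testable end to end without
hardware or clinical data, and so parameter recovery is checkable
against a known generative law. It emulates:

* **Reaction times** — shifted lognormal,
  `rt = 0.15 + exp(log 0.45 − 0.004·impulsivity − 0.002·hyperactivity + 0.35·Z)`
  seconds: median ≈ 0.60 s at zero traits falling to ≈ 0.45 s at
  maximal impulsivity and hyperactivity, consistent with a low-trait
  child responding mostly slower than 500 ms and a high-trait child
  responding faster than 500 ms about half the time.
* **Omissions** — probability `0.01 + 0.0015·inattention` per non-X
  trial (16 % at the top of the scale).
* **X-trial excursions** — minimum-jerk bumps with amplitude
  `0.01 + 0.0025·impulsivity` m plus 0.02 m jitter, clamped at zero, so
  impulsive profiles produce larger aborted or completed movements.
* **Kinematics** — minimum-jerk rise (0.30 m in 0.35 s), 0.10 s hold,
  0.40 s return: the standard smooth point-to-point reach profile, which
  gives the onset detector realistic velocity ramps.
* **Sensor jitter** — AR(1) noise with 1 mm marginal sd and coefficient
  0.9. Skeletal-tracking jitter is temporally correlated; white noise of
  the same amplitude would inflate path lengths by an implausible
  ~0.3 m per window and distort the commission denominator.
* **SWAN items** — each item is its factor's latent trait plus iid
  Gaussian noise (sd 8), clamped to [0, 100]: the simplest structure
  under which factor means recover traits. It is a test harness, not a
  claim about real SWAN psychometrics.
* Small probabilities of premature starts (2 %, up to 0.3 s early) and
  second raises (5 %) reproduce the premature- and multiple-reaction
  event types seen in per-trial audit traces.

What the simulator does *not* emulate: age or sex effects, ADHD-subtype
mixtures, postural drift, learned or fatigued kinematics, tracking
dropouts (these are injected explicitly in tests). Passing tests
therefore demonstrate that the scoring machinery measures what the
generative model programs — not that the instrument is clinically valid,
which only real cohorts can show.

## The correlation report

Factor scores are item means rather than sums, keeping them on the 0–100
item scale; sums differ by a constant factor and leave correlations
unchanged. The correlation method is Pearson by default, with the
p-value from the two-sided t transform on n − 2 degrees of freedom
(Spearman is an option; which the original analysis used is not stated).
Missing predictors are handled pairwise-complete with the per-cell n
reported, cells with fewer than three complete pairs are marked not
computable, and raw p-values are reported by default (a Holm flag is
available). The headline clinical correlations themselves depend on an
unpublished 30-child cohort and are deliberately not reproduction
targets; on simulated cohorts the package instead verifies sign recovery
of the programmed impulsivity–RT link and type-I calibration under a
null model.

## Numerical choices and problem sizes

* Windows are half-open with 0-based stimulus indices; segmentation
  conserves samples exactly.
* Trajectory round-trips through CSV/JSONL are exact to better than
  1e-6 m; schedule and manifest JSON are written with fixed formatting
  so identical configuration and seed give byte-identical files.
* All randomness flows through explicit integer seeds with a pinned
  generator kind; cohort members get derived sub-seeds, so any
  participant can be regenerated alone.
* Calibration suites use 100 replicate cohorts of n = 200 for sign
  recovery of the impulsivity–RT link and 200 replicate cohorts of
  n = 30 (the study-scale cohort) for the null type-I rate, pooling the
  six predictor-factor cells; the detector/oracle equivalence suite uses
  1 000 randomised trials. These sizes give Monte-Carlo standard errors
  comfortably inside the asserted tolerances (±3 percentage points on
  the 5 % type-I rate).

## Known limitations

* The onset criterion, displacement metric and neighbour-window extent
  for the commission denominator are package policy; the source task
  description does not pin them down. All are exposed as parameters.
* Whether inhibited commissions were threshold-defined or
  clinician-annotated in the original instrument is unknown; here they
  are threshold-defined on the continuous index.
* The commission index degrades when both neighbouring trials are
  omissions (denominator near the noise floor); such trials are
  invalidated rather than scored.
* Only the dominant-hand joint is modelled; multi-joint streams and
  posture analysis are out of scope.
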