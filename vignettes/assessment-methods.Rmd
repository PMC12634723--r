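---
title: "Methods: multi-sensor scoring of the Minnesota Manual Dexterity Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor scoring of the Minnesota Manual Dexterity Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handdex)
```

## The assessment problem

The Minnesota Manual Dexterity Test (MMDT) asks a participant to move 60
two-colored discs (red on one face, black on the other) through two timed
phases: *placing* (discs inserted red-side up into the board holes) and
*turning* (each disc flipped in place). Conventional scoring records only
the completion time, which hides where dexterity breaks down: reaching,
grasping, manipulation, or cognitive pauses. `handdex` scores the test from
three synchronized sensor streams and interprets the measurements with a
clinical rulebase:

* a board camera (640 x 480 RGB frames) that times every disc placement and
  turn via color changes at known hole centres;
* an 8-channel forearm surface-EMG band (200 Hz) whose signals are
  classified into *hold* / *release* / *rest* to accumulate disc hold time;
* a forearm IMU (3-axis gyroscope in deg/s, 3-axis accelerometer in g) that
  summarizes arm kinematics and detects inactivity ("thinking time").

## Board vision

Each frame is reduced to 60 color decisions. Pixels within
`sample_radius` (default 5 px) of a hole centre are converted to HSV on the
half-degree scale (H in [0,180], S and V in [0,255]) with the standard
piecewise hue formula, classified against fixed ranges

| class | H | S | V |
|---|---|---|---|
| white | [0,180] | [0,30] | [220,255] |
| red | [0,10] u [160,180] | [100,255] | [30,255] |
| black | [0,180] | [0,255] | [0,30] |

and decided by majority vote; ties give `unknown`. The black and red ranges
overlap at low V, resolved by the precedence black > red > white (darkness
dominates). `unknown` never drives a state change, so shadows and flashes
fail safe. A per-hole state machine then emits events — in placing,
white->red is a correct placement and white->black an upside-down one; in
turning, red->black is a correct turn and red->white an incorrect removal.
A transition must persist for `debounce` frames (default 2) before its
event is committed, stamped with the first frame of the transition.
Per-disc durations are consecutive event gaps (the first relative to the
phase start), so they sum to the total phase time exactly.

Majority voting over a small disc rather than the single centre pixel, and
the 2-frame debounce, are this package's additions for noise robustness;
both are configurable down to the single-pixel, single-frame behaviour.

## EMG processing and hold/release classification

Each channel passes through the envelope chain: 20 dB amplification
(amplitude convention, x10), full-wave rectification, and a causal
2nd-order low-pass Butterworth filter with 3 Hz corner and unit DC gain
(single-pass, because the assessment runs in real time; zero-phase
filtering would be anticausal). Ringing undershoot is clipped at 0 since an
envelope is a magnitude.

Two derived quantities feed the classifier. The *muscle contraction level*

$$\mathrm{MCL}(t) = \frac{1}{N}\sum_{n=1}^{N}
  \frac{E_n(t) - E_n^{rest}}{E_n^{max} - E_n^{rest}}$$

positions the envelope between per-channel rest and maximum-voluntary-
contraction calibration levels; it gates rest (default gate 0.05, clamped
to [0, 1.5] against supra-calibration contractions). Above the gate, the
rest-subtracted normalized vector

$$E'_i(t) = \frac{E_i(t) - E_i^{rest}}{\sum_{j=1}^{L}(E_j(t) - E_j^{rest})},
 \qquad \textstyle\sum_i E'_i = 1$$

is the classifier input. The normalized vector (not the scalar MCL) is used
as input because a scalar cannot discriminate hold from release; the MCL
serves only as the activity gate.

The classifier is a log-linearized Gaussian mixture network (LLGMN): inputs
are expanded to $(1, x_1..x_D, x_i x_j\,(i \le j))$ — length
$1 + D + D(D+1)/2$, 45 for 8 channels — one weight vector per
(class, component) pair scores the expansion, scores pass through a global
softmax, and a class posterior is the sum of its components' normalized
scores. Because the log of a Gaussian density is a quadratic form, any
Gaussian mixture posterior is exactly representable; `llgmn_from_gaussians()`
performs that construction and the tests verify forward-pass agreement with
direct density evaluation to below 1e-6. One weight vector is pinned to
zero for identifiability. Training is full-batch gradient ascent on the
log-likelihood (rate 0.05 with backtracking halving whenever a step would
decrease the likelihood, at most 500 epochs, early stop when the gain falls
below 1e-8), deterministic given the seed; K = 1 component per class by
default.

Training data follow the calibration protocol: an 8-s recording per
gesture with the gesture held between seconds 2 and 6; 20 evenly spaced
samples are drawn from that window (a seeded random subsample is available;
even spacing is the default because it is deterministic and covers the
window). Labels are smoothed with a width-5 running mode to remove
single-sample flicker, ties at posterior 0.5 resolve to *release* so hold
time is never accrued on ambiguity, and label timestamps are shifted
earlier by the filter's DC group delay (15 samples at 200 Hz) to undo the
envelope latency — a pure timestamp correction that leaves the total hold
time, which is the count of hold samples times the step, unchanged.

## IMU kinematics

Accelerometer samples convert as $a = 9.81\,g$ with 9.81 m/s^2 subtracted
on Z, which is assumed to stay near world-vertical; no orientation fusion
is attempted, a deliberate physical simplification. Per phase the package
reports the per-axis maximum angular-velocity magnitude, per-axis
mean/min/max, and the mean of prominent acceleration peaks (local maxima
of |a| with prominence at least 0.3 m/s^2 — "peak" needs an explicit rule,
and prominence excludes noise wiggle riding on a real burst). Inactivity
time sums the maximal intervals in which every gyro axis stays below
10 deg/s and every compensated acceleration axis below 0.3 m/s^2; both
thresholds are configuration values with no canonical setting, and
inactivity is monotone non-decreasing in each. The IMU rate defaults to
50 Hz, the common armband hardware setting.

An open representational choice: a "maximum angular velocity" can be read
as the signed extremum or the extremum magnitude. The package reports
max |omega| per axis and exposes signed min/max alongside, so either
reading is recoverable.

## The expert rulebase

Rules are conjunctions (optionally disjunctions) of comparisons between
measured variables and named thresholds, evaluated in declaration order;
every firing rule emits its finding, and several can fire at once.
The shipped rulebase contains a "Normal" rule on the two phase totals,
over-time branch rules whose children check kinematic subcomponents
(subnormal roll velocity in turning: possible pronation–supination
restriction; subnormal mean acceleration in placing: possible elbow or
shoulder restriction), inactivity rules, and a per-disc delay family
instantiated from one template for all 60 discs in both phases. Inactivity
and per-disc rules are top-level: a long pause or a slow disc is worth
flagging whether or not the phase total crossed its limit. "Normal" is
suppressed whenever any abnormal finding fires — exclusive by construction,
since a screening summary should not read "Normal" next to an abnormality.

Threshold defaults: total-time limits 62 s (placing) and 67 s (turning);
the lower limits, which have no canonical values, ship as 30 s
placeholders. Kinematic floors (`nrot_*`, `nacc_*`) are derived from the
packaged healthy-cohort tables as mean − 2 sd, floored at 0 — a stated
convention for "the normal range", not a clinical calibration. Inactivity
and per-disc limits default to 10 s and 2 s. Every threshold is a plain
number in the configuration and can be changed.

Rulebases serialize to JSON; loading validates comparators, variable names
against the declared context, and id uniqueness, and a save/load round
trip preserves order, conditions and texts exactly. Validation errors are
raised at load, never mid-evaluation.

## Agreement metrics

Two percent-difference conventions coexist deliberately. Stopwatch
agreement uses the manual reference denominator,
$E_T = |T_s - T_m| / T_m \times 100$. The hold-time comparison table uses
the classifier denominator, $100\,|ht_c - ht_t| / ht_c$ — recomputing the
packaged table's difference column confirms that convention
(1.2/31.6 -> 3.8, 1.7/23.8 -> 7.1). Both are exported and reports label
which is in use. Reported aggregates round half away from zero at the
printed precision (several table footers are exact .x5 cases, e.g.
27.45 -> 27.5); the standard deviation is the sample (n−1) form.

## The synthetic session generator

No public recording of this instrumented test exists, so validation runs
on synthetic sessions with known ground truth. A schedule draws strictly
increasing per-disc event times (gaps of 1.0 +/- 0.15 s, matching healthy
placing totals near a minute), a hold window covering 45% of each gap
(the healthy cohort holds discs for about 44% of the phase), one
arm-movement burst per disc with amplitudes near the healthy reference
means (e.g. roll bursts of order 130 deg/s in placing, X accelerations of
order 2 m/s^2), and quiet intervals realizing target inactivity.

From a schedule the generators produce:

* **Frames** — white board, red/black discs at the scheduled holes,
  +/- 3 counts of uniform pixel noise, at 10 fps (a camera rate consistent
  with a few-hundred-millisecond decision loop; all timing tolerances are
  stated in frame intervals). Lighting modes: `shadow` multiplies RGB by
  0.10 over patches covering designated holes — 0.10 rather than a milder
  factor because a shadowed bright-red disc must actually cross into the
  black/unknown range to reproduce the characteristic failure mode —
  `flash` saturates those patches to white, `dim` halves the global value.
  A full-image renderer and a compact per-hole patch renderer draw
  identical pixels at the sampled locations; the tests assert their
  classifications agree.
* **EMG** — target envelopes (channels 4–5 rising to 90% of the
  calibration span inside hold windows, the remaining channels
  co-activating at 25%, trapezoid ramps of 0.15 s, Gaussian noise of 2% of
  span) converted to raw signed signals `env / gain * z / E|z|` with `z`
  standard normal, so the rectified low-passed envelope reproduces the
  target. Hold and release training gestures differ in channel signature
  (release adds extensor-side co-activation on channels 3 and 6 at half
  drive on 4–5).
* **IMU** — gravity baseline, quadrature-sinusoid baseline rotation
  (40 deg/s, so the arm is never spuriously "inactive" outside quiet
  intervals), half-sine bursts at scheduled times, sensor-level noise
  (0.06 deg/s, 4 mg).

Every generator is deterministic given its seed.

What the generator does *not* emulate: hand occlusion of the board,
specular reflection, electrode shift or crosstalk, biomechanically
realistic EMG spectra, orientation drift, or dropped discs. Passing tests
therefore demonstrate the correctness of the processing chain under
controlled conditions — color thresholds, state machine, classifier,
summaries, rules — not field robustness of a camera rig.

## Numerical and design notes

* Filter: digital Butterworth via bilinear transform with prewarped cutoff;
  DC gain asserted within 1e-9 of 1.
* The MCL inside a synthetic hold is about 0.41 (two channels at 0.9, six
  at 0.25), comfortably above the 0.05 gate; the gate, not the MCL
  magnitude, separates rest from motion.
* Board geometry defaults to 4 x 15 on 640 x 480 px, centres on a uniform
  grid (the test specifies 60 discs, not a camera-plane geometry); pixel
  coordinates are 0-based, x rightward, y downward, pixel-centre
  convention.
* Rounding for reports: half away from zero with a 1e-7 representation
  guard.
* Problem sizes in the shipped tests and acceptance script: unit tests use
  2–15-disc sessions; the detection study runs 50 sessions of 60 discs in
  compact patch-frame form; the disk-backed full-pipeline check uses a
  15-disc session (about 20 s of simulated time), sizes chosen to exercise
  every code path at desk scale.
* Known limitations: no dropped-disc detection, single (dominant-arm)
  EMG band so hold percentages under-estimate bimanual grasp time, no
  automatic hole-centre calibration from imagery, and the clinical
  thresholds are placeholders pending cohort calibration.
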