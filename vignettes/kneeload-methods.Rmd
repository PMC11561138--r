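---
title: "Methods: knee loading peaks from portable gait measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knee loading peaks from portable gait measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeload)
```

## The problem

Tibiofemoral (knee joint) contact forces during walking are normally
obtained from optical motion capture processed through musculoskeletal
modelling — scaling, inverse kinematics, inverse dynamics, static
optimization and joint-reaction analysis. That workflow needs a motion
laboratory and an expert, which rules it out for routine clinical use.
`kneeload` implements the alternative: predict only the stance-phase
*peaks* of the knee joint contact force (KJCF) from six simple inputs that
can be collected in a clinic —

* mass (kg), height (cm), age (years), sex (coded 0 = female, 1 = male),
* walking speed (cm/s), and
* a scalar knee-flexion-angle (KFA) summary (degrees),

where the last two are estimated either from a small set of inertial
measurement units (IMUs) or from a single sagittal-plane video camera whose
frames have been run through a 2D pose estimator. Nine response variables
are predicted: the loading-response (LR, early stance) peak, the
terminal-extension (TE, late stance) peak, and the full-stance maximum, for
each of the summed, medial-compartment and lateral-compartment loading
curves. The full-stance maximum is by construction the larger of LR and TE.

Because the package must be exercisable end-to-end without laboratory data,
it ships a deterministic synthetic gait simulator that plays the role of
the motion laboratory and provides exact ground truth for every stage.

## Feature definitions

**KFA predictor.** Given a stance-phase flexion curve, the predictor is the
maximum over the first half of stance minus the minimum over the second
half. With a stance window of `n` samples starting at index `s`, the half
boundary is `s + floor(n/2)`; the first half is `[s, mid)` and the second
`[mid, s+n)` — a deterministic tie-free split. The value may be negative
for atypical curves and is reported as-is.

**Nine-peak extraction.** Peak *locations* are strict interior local maxima
of the curve after 5-sample moving-average smoothing (edge-replicated), LR
being the largest local maximum in the first half of stance and TE the
largest in the second. Peak *values* are read from the raw curve at the
located samples: smoothing a narrow peak attenuates its height by several
percent, so reporting the smoothed value would bias every peak low. When a
half contains no interior local maximum (lateral-compartment curves can
lack the usual double-bump shape, and monotone ramps occur in degenerate
input), the fallback is the raw maximum over that half. Equal LR and TE
values make the full-stance maximum equal to both, so tie-breaking is
moot. The smoothing window is config-exposed because the behaviour of peak
detectors on real musculoskeletal output varies between implementations.

**Isometric-force scaling.** The helper
`scale_max_isometric_force(subject_mass, generic_mass)` returns
`1.5 * (mass ratio)^(2/3)`: muscle force scales with cross-sectional area,
assumed allometric in body mass with exponent 2/3, and the 1.5 multiplier
keeps simulated muscle activations submaximal at the fastest speeds.

## The prediction models

One network per response variable, nine in total. Each network has a single
hidden layer with exactly one tanh node:

`y = a * tanh(w . x + b1) + b2`

with inputs and target min-max normalized to [-1, 1] (the normalization is
stored with the model and inverted at prediction time; normalizing the
target keeps the two penalty scales of the objective commensurate).
Training minimizes the Bayesian-regularized objective

`F = beta * Ed + alpha * Ew`,  `Ed = sum(e^2)`,  `Ew = sum(theta^2)`

by Levenberg–Marquardt steps, with the hyperparameters re-estimated each
epoch by MacKay's evidence framework: `H = 2 beta J'J + 2 alpha I`,
`gamma = Nw - 2 alpha tr(H^-1)` (the effective number of parameters),
`alpha = gamma / (2 Ew)`, `beta = (N - gamma) / (2 Ed)`. No validation
split is used — the evidence updates control overfitting, which matters
because training sets here are modest. Weight initialization is a bounded
uniform draw scaled in the Nguyen–Widrow spirit, taken from the
configuration seed, so training is bit-reproducible. Convergence is
declared when an accepted step changes the objective by less than a
relative tolerance (default 1e-10) or when no step can be accepted.
Numerical parity with any particular commercial implementation of
Bayesian-regularization backpropagation is not claimed; the algorithm is
the standard one.

Pre-training: when an auxiliary cohort is supplied (in the synthetic
experiment, an older/heavier/slower cohort emulating a clinical knee-
osteoarthritis dataset), each network is first trained on it and the main
training continues from those weights. Both phases share the main
dataset's normalizations so the weight space is common.

The baseline is a first-order multiple linear regression
`y = a*mass + b*height + c*age + d*sex + e*speed + f*kfa + g`
fitted by ordinary least squares; inactive predictors (for the reduced
predictor sets `demographic`, `demographic+kfa`, `demographic+speed`)
carry coefficient zero. Sex coding is fixed at female = 0, male = 1.

## The IMU pipeline

Inputs are per-site streams of unit-quaternion orientation and 3-axis
acceleration at 100 Hz; the first frame is a neutral standing pose. No
orientation filtering is done — orientations are consumed as provided, as
with commercial sensor fusion.

**Gait events.** The acceleration magnitude of each shank is low-pass
filtered at 10 Hz; the dominant gait period is taken from its
autocorrelation (strongest lag beyond 0.4 s), and heel strikes are peaks
separated by at least 0.7 of that period with topographic prominence at
least 0.5 SD of the filtered signal. A fixed minimum separation alone is
not safe across the cadence range (a value long enough to reject
double-firing at slow cadence swallows true events at fast cadence), which
is why the separation is period-scaled. Finally only the longest run of
events whose spacing matches the period within 20% is kept; this discards
gait-initiation and trial-end transients.

**Knee flexion.** Per sensor, orientations are re-expressed relative to
frame 0 and converted to rotation vectors; the first principal axis of
those vectors is the axis of greatest rotation, which for sagittal walking
is the flexion axis. Rotation vectors (not raw quaternion components) make
that axis well-defined. The signed projections give per-frame segment
angles; knee flexion is the shank angle minus the thigh angle, zero at
frame 0, with the global sign chosen so the dominant excursion (swing
flexion) is positive. Light Savitzky–Golay smoothing (cubic, 11 samples)
is applied by default; the window is kept short so the early-stance
flexion peak is not attenuated at fast cadence.

**Walking speed.** Thighs and shanks are rigid bodies with lengths 0.245
and 0.246 of stature (standard anthropometric fractions, config-exposed)
hanging from a common hip point; orientations rotate the segment vectors
and the distal shank endpoints are the feet. During stance (heel strike to
heel strike + 0.62 x period) the planted foot is stationary in the world,
so the hip equals an unknown constant anchor minus the measured
foot-relative-to-hip vector. Consecutive stances of opposite legs overlap
during double support, which measures the offset between their anchors;
chaining offsets reconstructs the hip world trajectory over the whole
trial — foot-anchored odometry. Speed is the norm of the hip displacement
between two same-phase samples an integer number of strides apart divided
by the elapsed time. Sampling at equal stride phase matters: hip speed
fluctuates periodically within each stride, and windows locked to heel
strikes would otherwise alias that fluctuation into a systematic bias
rather than averaging it away. A naive reading — the displacement of the
stance foot relative to the hip between consecutive ipsilateral heel
strikes — is identically zero for periodic gait, which is why the
reconstruction goes through world-frame anchors. Displacement norms (not
components) keep the estimate invariant to any global rigid rotation of
the orientation data. Stance windows are edge-trimmed by 15% and endpoint
positions averaged over 5 samples because the detected acceleration peak
can sit a few samples off the true foot-contact instant.

The stance window for the IMU-side KFA predictor is heel strike to heel
strike + 0.62 x period (the same stance fraction the simulator uses),
since no force plate exists in portable use; windows are edge-trimmed by
15%, which leaves the interior extrema of the flexion curve untouched, and
the per-stance predictors are summarised by their median.

## The video pipeline

Inputs are per-frame 2D keypoints in the 25-landmark pose-estimator
dialect: pixel x, y and a confidence in [0, 1] per landmark, with the
image y axis pointing down. All angles are computed from vectors, so no
axis convention leaks into results.

**Scale.** Metres-per-pixel is estimated from the anthropometric ratio
ankle-to-vertex ≈ 0.936 x stature: on frames where the head and at least
one ankle are confidently detected and the person is inside the central
84% of the image, the pixel extent from head to the lower (planted) ankle
is measured and the median extent calibrates the scale. An explicit
override is honoured verbatim for calibrated setups.

**Speed.** The horizontal mid-hip pixel coordinate is regressed on time
with a least-absolute-deviations straight line (IRLS); the absolute slope
times the scale is the speed. The robust fit tolerates confidence dropouts
and occlusion episodes; the absolute value makes the estimate
direction-agnostic.

**Knee flexion.** Per frame, flexion is 180 degrees minus the included
angle between the knee-to-hip and knee-to-ankle vectors of the analyzed
leg. Frames below the confidence threshold (default 0.3) are linearly
interpolated from accepted neighbours rather than dropped, so the series
stays uniformly sampled for the predictor computation; if more than half
the frames fail the threshold the series is rejected. The same
Savitzky–Golay smoothing as the IMU side is applied.

**Proxy heel strikes.** The planted foot holds the ankle at a stable
ground level — the maximum pixel y. Ground-contact runs are frames whose
smoothed ankle y lies within a tolerance (15% of the robust vertical
excursion) of the ground level; each run start is a heel strike. An
earlier design located minima of the ankle vertical-pixel velocity, but in
image coordinates those minima mark early swing, not foot contact, so the
contact-run rule replaced it. Stance windows and the per-stance KFA
predictor then follow the IMU-side convention (0.62 stance fraction, 15%
trim, median).

## The synthetic gait simulator

The simulator is a planar (sagittal) model — the estimators it feeds are
all sagittal, and out-of-plane motion is represented only as orientation
noise. Each trial:

* opens with 0.5 s of neutral standing (the IMU zeroing assumption);
* advances the hip at the target speed after a smooth ramp, with a small
  (0.8 cm amplitude) two-per-stride horizontal speed oscillation;
* during each stance solves the thigh angle per frame (vectorized Newton
  iteration) so the planted ankle stays exactly anchored horizontally
  while knee flexion follows a sampled double-bump template: heel-strike
  value U(2, 6) deg, early-stance peak U(10, 25) deg placed at 25% of
  stance, late-stance minimum U(0, 8) deg at 75%, toe-off U(30, 40) deg.
  Template knots sit on sample indices and the segments are zero-slope
  cubic Hermite (monotone), so the ground-truth KFA predictor equals the
  sampled peak-minus-minimum difference exactly;
* fills swings with velocity-matched cubic Hermite segments rising to a
  U(60, 72) deg swing flexion peak, and lets the vertical hip position
  follow the planted-leg extent (the inverted-pendulum rise and fall),
  cross-faded between legs over double support;
* renders IMU streams by forward kinematics (orientations about the
  mediolateral axis; specific force from twice-differentiated sensor
  positions minus gravity, rotated into the sensor frame) with a half-sine
  heel-strike transient of 8 m/s^2 on shank and foot sensors — the impact
  transient real accelerometers record, and the feature the event detector
  keys on;
* projects hip, knee, ankle, head and neck landmarks into an orthographic
  sagittal camera (default 480 x 272 px at 0.0125 m/px) with configurable
  pixel jitter and confidence noise. When the knees cross, the far-side
  leg (the right leg when walking "left") is occluded: its keypoints are
  biased toward the near leg and its confidence scaled down, emulating
  direction-dependent occlusion in single-camera recordings.

Cohort defaults emulate a healthy adult laboratory cohort: age truncated
normal 29 +/- 6 on [20, 45], BMI 25.1 +/- 4.2 on [18.8, 40.4], P(male) =
29/46, mass = BMI x height^2. Comfortable speed is truncated normal
133.56 +/- 20 cm/s on [80, 200]; no per-subject speed distribution is
published for such cohorts beyond pooled statistics, so the spread is a
choice anchored to the pooled mean. Slow and fast trials are exactly
0.75x and 1.25x comfortable. Stance occupies 0.62 of the gait cycle
(typical adult walking). Stride length follows
`height * min(0.62 * (v/1.335)^0.5, 0.68)` m — the cap guarantees the
planar two-segment leg can span the stance-phase hip travel over an
anchored ankle at every admissible speed; the resulting cadences are
somewhat high at the fastest speeds, a deliberate trade for exact foot
anchoring. Trial validity (standing in for visual inspection of ground
reaction forces) is a Bernoulli flag with invalid probability 0.1.

The generative loading model makes the summed LR and TE bump heights
linear in the six predictors with a fixed medial share of 0.65 and
Gaussian peak-height noise of SD 350 N. The coefficients and noise were
chosen once so that peak magnitudes (~2.6 kN summed LR for an average
subject), compartment splits and residual spread sit in the range reported
for musculoskeletal analyses of adult walking; with them the end-to-end
synthetic experiment produces NRMSE around 0.11-0.16 and correlations
around 0.7-0.8 for the baseline models. Curves are two non-overlapping
raised-cosine bumps (width 0.24 of stance) centred on sample indices, so
noiseless extracted peaks equal the linear predictions exactly.

**What the simulator does not model** — and what passing tests therefore
do not show about real data: soft-tissue artefact, sensor drift and
magnetometer disturbance, out-of-plane kinematics, pose-estimator failure
modes beyond jitter/occlusion, ground-reaction-force waveforms, and any
true musculoskeletal dynamics (the loading model is a linear surrogate,
which is exactly why network and MLR accuracies tie on it). Speed and KFA
estimation errors under the "realistic" preset are consequently at the
low end of what field studies report: the structure of the comparison
(portable modalities vs. motion-capture baseline) transfers, the absolute
error levels do not.

## Evaluation rules

A subject enters the balanced test set only if every one of the six
walking configurations (3 instructed velocities x 2 directions) has at
least five valid trials; survivors contribute exactly the first five valid
trials per configuration (30 per subject), so no subject or configuration
is over-weighted. Peak metrics (RMSE, NRMSE, Pearson R, MAE) are pooled
over trials; NRMSE normalizes by the mean of the pooled reference values.
Predictor metrics are computed within each subject and averaged across
subjects with equal weight, with spread reported as the SD across
subjects. Population (divide-by-n) SD is used throughout — the choice is
about describing the cohort at hand, not estimating a superpopulation —
and is applied consistently. Occlusion effects are summarised as the
relative change in mean absolute error from baseline, aggregated per
subject by walking direction and response variable. Formal hypothesis
testing (repeated-measures ANOVA and post-hoc procedures) is deliberately
left to standard statistical software; the long-format observation table
written by `run_experiment()` is the input those tests need.

## Problem sizes and determinism

The bundled experiment defaults (and the sizes exercised in the test
suite) are: 60 training subjects x 6 trials, 20 pre-training subjects,
and 40 test subjects x 6 configurations x 7 trials, which leaves roughly
34 subjects (about 1000 trials) in the balanced test set after the
validity filter — proportionally similar attrition to laboratory
practice. All randomness funnels through a single root seed: cohorts,
per-trial templates, sensor noise, validity flags and weight
initialization derive sub-seeds from it, so identical configurations give
byte-identical outputs, including the written `metrics.csv` and the
manifest hash.

## Known limitations

Only peaks are predicted, not loading time series or impulses; the
simulator's linear loading surrogate cannot reveal nonlinear advantages a
single-hidden-node network might have on real musculoskeletal output; the
planar kinematic model makes the IMU pipeline's principal-axis step almost
trivially well-posed, whereas real sensors see cross-plane motion; and the
video scale calibration assumes the subject's full height is visible and
the camera roughly orthographic at the walking line.
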