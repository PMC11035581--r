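---
title: "Methods: wrist trajectory reconstruction from a single wrist-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist trajectory reconstruction from a single wrist-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingtrack)
```

# The problem

A wrist-worn inertial measurement unit (IMU) records 3-axis specific force
(accelerometer, m/s²) and 3-axis angular velocity (gyroscope, rad/s) at
200 Hz.  Reconstructing the 3D wrist path of a golf swing from these six
channels alone requires (i) knowing the rotation from the sensor frame *S*
to a ground-fixed user frame *U* at every instant, and (ii) double
integration of the gravity-compensated acceleration — both of which
accumulate unbounded drift from sensor noise and bias.  A full swing is a
severe test case: roughly 2.1 s long, with specific-force peaks above
100 m/s² and angular rates above 1500 deg/s.

`swingtrack` addresses both problems with the kinematic structure of the
swing itself:

* the wrist is (nearly) at rest at three events — address (ADD), top of
  backswing (BST) and finish (FIN) — giving three zero-velocity anchors;
* the wrist path closely follows a circle in an inclined swing plane,
  giving an endpoint constraint for the most drift-contaminated part of
  the trajectory.

# Conventions

Quaternions are Hamilton, scalar-first `(w, x, y, z)`, right-handed; `q`
denotes the rotation of sensor-frame vectors into the user frame,
`v_U = R(q) v_S`.  The user frame has Z up and Y along the swing
progression direction — i.e. the frame is *swing-aligned*, which matters
for what is observable (see "Observability" below).  The representative of
the `{q, -q}` pair with `w >= 0` ("northern hemisphere") is used for all
labels and reported estimates.  The accelerometer measures specific force,
so a stationary sensor reads `-g` rotated into the sensor frame;
user-frame acceleration is recovered as `a_U = R(q) f_S + g_vec` with
`g_vec = (0, 0, -9.80665)` m/s².  The gravity term is applied after
rotation, which is the single most consequential modelling step of the
pipeline: omitting it makes double integration meaningless.

# Orientation

## Strapdown propagation

Orientation is propagated from the address by the first-order quaternion
update `q(t+1) = q(t) + ½ (q(t) ⊗ (0, ω(t))) Δt`, renormalized after every
step.  The raw first-order update is not norm-preserving; renormalization
restores the unit constraint without changing the first-order behaviour,
and makes the unit-norm invariant testable at machine precision.
Higher-order integrators (e.g. fourth-order Runge–Kutta) are deliberately
out of scope.

## Address-pose estimation with a small CNN

The orientation at ADD is estimated from a standardized 6 × 1000 window
(3 accel rows, 3 gyro rows; 200 Hz × 5 s capacity) by a small
convolutional network: two 1-D convolutions and a max-pooling stage, each
followed by a hyperbolic tangent, then a fully connected layer whose four
outputs are renormalized to a unit quaternion.  The loss is the quaternion
distance `1 − |q_true · q_est|`, which is invariant under the quaternion
double cover, so label canonicalization is a reproducibility convention
rather than a correctness requirement.

The default window spans `[t_ADD − 100 ms, t_BST]`, left-aligned and
zero-padded to 1000 columns (truncated when longer): the static pre-address
segment encodes the gravity direction in the sensor frame, and the
backswing gyro pattern fixes the remaining yaw degree of freedom.
Alternative windows (`pre_add_only`, `to_imp`, `to_fin`) support the
input-range ablation; windows that include the downswing perform markedly
worse, because the violent dynamics dominate the features without adding
pose information.

Training uses Adam with a random 90/10 train/validation split by swing,
validation-based early stopping (the epoch cap is 400; in practice
training stops far earlier), and mild decoupled weight decay on the weight
matrices.  Tunable hyperparameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `C1`, `C2` | 8, 12 | convolution channels |
| `k1`, `k2` | 15, 9 | kernel widths (samples) |
| `s1` | 4 | stride of the first convolution |
| `pool` | 4 | max-pooling width |
| `lr` | 5e-3 | Adam learning rate |
| `batch` | 16 | minibatch size (swings) |
| `patience` | 40 | early-stopping patience (epochs) |
| `weight_decay` | 0.05 | decoupled weight decay |

These are configuration choices, not claims: the architecture sizes are
not prescribed by the method, only the overall structure is.

The statistical baseline is the average quaternion of the *other*
subjects' address orientations, computed by the eigenvector method
(principal eigenvector of the accumulated outer-product matrix), which is
the standard rotation average and is insensitive to per-sample sign flips
— naive componentwise averaging fails on antipodal representatives.

## Observability

A global rotation of the entire motion about gravity leaves every IMU
sample unchanged, so the absolute world yaw of the swing is fundamentally
unobservable from a single IMU.  This is why the user frame is defined
swing-aligned: the progression direction is fixed by the swing itself, and
the synthetic population (below) gives the residual plane-azimuth
variation a small spread (≈2 deg between subjects).  Tilt and sensor
mounting, in contrast, are observable through the gravity direction and
the backswing dynamics.

# Drift removal

With the estimated address quaternion, orientation is propagated over
`[t_ADD, t_FIN]`, acceleration is rotated to the user frame and gravity
removed, and cumulative trapezoidal integration yields the velocity
`v_ori` (zero at ADD by construction).

## Zero-velocity anchoring

A time-linear drift model is removed per axis: on `(ADD, BST]` a ramp
cancels the residual at BST; on `(BST, FIN]` the BST offset is removed
and a second ramp cancels the remaining FIN residual.  With the FIN
residual measured after the BST offset removal, all three anchors are
*exactly* zero — the variant implemented by default.  A literal
alternative (ramping the raw FIN value) leaves the FIN anchor displaced by
the BST offset whenever that offset is nonzero; it is available as
`correct_velocity(..., variant = "literal")` so the two readings of the
correction can be compared.

## Virtual circle endpoint constraint

Integrating `v_Vcal` gives `Traj_Vcal`.  The swing plane normal is the
smallest-singular-value right singular vector of the centred backswing
segment `[t_ADD, t_BST]` of `Traj_Vcal` (the backswing is used for both
the plane and the circle because later segments carry the most drift),
with the sign convention of a nonnegative Z component.  The virtual circle
is the algebraic (Kåsa) least-squares circle of the plane-projected
backswing points; an optional Gauss–Newton geometric refinement
(`refine = TRUE`) matters on short noisy arcs, where the algebraic fit has
a known inward radius bias.  The FIN endpoint is decomposed into its
out-of-plane component `d_FIN`, its in-plane projection `r_cal`, and the
corrected endpoint `ep`: the radial projection of `r_cal` onto the circle,
which is also the closest circle point.

## Bias estimation as an exact linear solve

The endpoint offset `Traj_Vcal(t_FIN) − ep` is attributed to a constant
sensor-frame accelerometer bias `b`.  Because the double integral is
linear in the acceleration, the endpoint displacement caused by `b` is
`M b`, where column *j* of the 3 × 3 response matrix `M` is the double
integral — under the same trapezoidal quadrature — of the rotated unit
bias `R(q(t)) e_j`.  Solving `M b = Traj_Vcal(t_FIN) − ep` (least squares
when `M` is ill-conditioned) and subtracting the per-sample double
integral of the rotated bias gives
`Traj_Tcal(t) = Traj_Vcal(t) − D(t) b`, whose endpoint lands on `ep` to
machine precision.  Computing the correction through this linearity
avoids a differentiate-then-reintegrate round trip, which is not exactly
invertible under discrete quadrature.  For a constant orientation this
reduces to the closed form `b = 2 · offset / T²`.

Two properties of this construction deserve emphasis.  First, applied to
the *un-anchored* double-integration endpoint with exact orientation, the
solve recovers an injected constant bias to machine precision — the
linear-solve oracle in the test suite.  Second, inside the full pipeline
the velocity anchoring has already absorbed most of the constant-bias
effect, so the endpoint-implied `b` is a residual quantity, not an
estimate of the physical sensor bias; its job is to put the endpoint on
the circle, and the tests assert exactly that.

# Segmentation

Events are defined on the wrist-speed profile: ADD is the last
plateau-edge local minimum before the first sustained rise, BST the
deepest minimum between the backswing peak and impact, IMP the global
speed maximum, FIN the plateau-edge minimum terminating the follow-through
deceleration.  Since a wrist-only system cannot observe the club head
crossing the ball position, the wrist-speed maximum is a documented
surrogate for impact (an external ball-crossing index is accepted when
available).

The trainable segmenter is a bidirectional tanh recurrent network over the
standardized 6-channel signal, downsampled by 4 (50 Hz), labelling every
sample with one of five phases (pre-address, backswing, downswing,
follow-through, post-finish).  Events are read off a left-to-right
constrained Viterbi decoding of the per-sample posteriors, which enforces
the phase order and at least one sample per phase, so the event-ordering
invariant holds for *any* network output.  Recordings whose peak angular
rate is below 3 rad/s — an order of magnitude below a slow swing — are
rejected before decoding, which catches motionless input that the decoder
would otherwise happily annotate.

# The synthetic swing generator

Real swing recordings are not distributed with the package; the generator
produces physically consistent recordings with complete ground truth so
that every stage has a quantitative acceptance surface.

**Geometry and profile.** The wrist moves on a circle of radius 1.1 m in
a plane tilted 55 deg, plus a small smooth out-of-plane excursion (2 cm
default; a flag generates exactly planar swings for exact tests).  The
circle angle is built from minimum-jerk-family polynomial segments with
zero angular speed and acceleration at the segment joints: a backswing
sweep of 1.3 rad, a downswing of 1.4 rad ending at peak speed, and a
two-stage follow-through deceleration.  Defaults give an ADD-to-FIN
duration of 2.14 s, a wrist path of ≈4.5 m, peak specific force of
≈104 m/s² and peak angular rate of ≈1530 deg/s — inside the
population mean ± 1 SD envelope of adult full swings reported for
wrist-worn sensors (≈111 ± 31 m/s², ≈1627 ± 230 deg/s, ≈4.4 m,
≈2.14 s).  Orientation is a path-following frame composed with a
forearm-roll term (spanning 150–350 deg across axes) and a fixed
sensor-mount offset.

**Discretization contract.** Two choices make the generator a usable
oracle rather than an approximate one.  The ideal gyro sample for step
*i* is derived from the exact relative quaternion between consecutive
true orientations through the tangent map, so first-order strapdown
integration reproduces the true orientation to machine precision — the
sampled gyro differs from the instantaneous angular velocity by under
0.2% at the rate peak, well inside sensor realism.  Ground-truth velocity
and trajectory are the exact integrals of the piecewise-linear
interpolant of the sampled user-frame acceleration, so trapezoidal
(re-)integration of the ideal signals reproduces them to well under a
millimetre.  Without these choices, first-order integration error of the
simulator itself (up to a few millimetres and a couple of degrees at
200 Hz) would be conflated with the pipeline errors under test.

**Noise model.** Gaussian noise (0.25 m/s², 0.008 rad/s), constant
sensor-frame biases (defaults of a few tenths of m/s² and a few
thousandths of rad/s, the regime of consumer MEMS parts), and optional
range saturation at ±16 g / ±2000 dps with the saturated samples recorded
in the ground truth.

**Population structure.** Subjects differ in plane tilt (sd 5.7 deg),
plane azimuth (sd 2.3 deg — kept small because world yaw is unobservable
and the frame is swing-aligned), circle radius, tempo, downswing roll and
sensor mounting (sd 8.6 deg).  Within a subject, swings differ by smaller
jitters of the same quantities plus a trial-to-trial wrist-posture/strap
rotation of sd 4.6 deg, and biases are redrawn per swing.  The
within-subject address-orientation spread (≈4 deg) is deliberately
nonzero and below the between-subject spread (≈8 deg): trial-to-trial
posture variation is what real datasets contain, and it is what lets a
learner identify the signal-to-orientation map locally instead of
memorizing subject identities.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about field data: soft-tissue and impact-shock
artifacts, time-varying or temperature-dependent biases, non-circular
path deviations beyond a smooth out-of-plane term, axis misalignment and
scale-factor errors, club/ball interaction, and segmentation label noise.
Absolute error levels on real recordings will differ; the package's
claims on synthetic data are about the *structure* of the method
(exactness of constraints, direction and rough magnitude of
improvements).

# Numerical choices and degenerate inputs

* Cumulative trapezoidal quadrature for all integrations; the same
  quadrature is used in the bias response matrix so the endpoint
  constraint is met exactly.
* Zero-phase filtering by default (5th-order Butterworth kernel run
  forward and backward, matching a 10th-order magnitude response at
  20 Hz) so that filtering does not bias event timing; a causal
  single-pass mode is available.
* Clipping threshold at 99.9% of full scale; repaired samples may exceed
  the range (they reconstruct the unsaturated signal); runs too close to
  a recording edge fall back to a one-sided spline with a warning.
* Plane fitting fails on collinear clouds (singular-value ratio below
  1e-6); endpoint projection fails when the projected endpoint hits the
  circle centre; the bias solve falls back to a pseudoinverse when the
  response matrix condition number exceeds 1e8.
* Event decoding enforces `ADD < BST < IMP < FIN` by construction and
  refuses motionless recordings.
* All randomness flows through explicit integer seeds; generation and
  tracking are bit-reproducible, and network training is reproducible
  because every stochastic step (initialization, splits, shuffling) uses
  the seeded R generator.

# Problem sizes

The test-suite benchmarks use a leave-one-out population of 6 subjects ×
10 swings for orientation estimation, a 20-swing noisy batch for
drift-correction efficacy, 5 subjects × 5 swings for segmentation, and
Monte-Carlo geometry checks with 100 replicates; the training epoch caps
in the benchmarks (250 for the CNN, 80 for the segmenter) are the sizes
at which results stabilize on this data.  These sizes are the package's
own benchmark design.

# Known limitations

* The correction anchors the trajectory at FIN; errors near impact are
  reduced but not anchored, and an impact-time constraint is out of
  scope.
* The endpoint-implied bias compensates whatever residual error reaches
  the endpoint — including orientation drift leakage — under a
  constant-sensor-bias model; it is not a sensor calibration.
* The heuristic event finder assumes a single-swing recording with
  stationary padding; continuous multi-swing streams need the trained
  segmenter.
* Absolute performance numbers are synthetic-data numbers; see the
  generator's non-goals above.
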