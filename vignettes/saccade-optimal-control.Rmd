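---
title: "Methods: a tendon-driven eye plant under optimal open-loop saccade control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tendon-driven eye plant under optimal open-loop saccade control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the mechanical
model and its assumptions, the identification and control machinery, the
parameters that matter and how their defaults were fixed, the numerical
choices, and what the test suite does and does not establish.

## Orientation conventions

All orientations live in a head-fixed right-handed frame: +x is the
torsional axis (positive roll clockwise from the subject's viewpoint), +y
the vertical axis (positive rotation downward), +z the horizontal axis
(positive rotation leftward).  Orientations are unit quaternions
`q = (cos(rho/2), sin(rho/2) n)` or, equivalently, Euler-Rodrigues
rotation vectors `r = tan(rho/2) n` in half-radian units; `r = 0` is the
primary position and Listing's plane in the primary frame is `r_x = 0`.
The quaternion sign ambiguity is resolved by keeping the scalar part
non-negative, which makes conversions single-valued.  Internally all
angles are radians (rotation vectors half-radians); user-facing inputs
and reported metrics are degrees, converted componentwise through
`x = tan(theta/2)`.

Two conversions deserve a note because they carry silently through every
analysis:

* the rotation-vector *rate* map `rdot = (w + w x r + (w.r) r)/2` is
  exact; its convenient inverse `w ~ 2 (rdot + r x rdot)` has error
  *exactly* `|r|^2 w` (one can show `2 (rdot + r x rdot) = (1+|r|^2) w`).
  Against a fixed velocity that is a second-order error; when orientation
  and velocity scale together, as they do across a family of saccades, it
  is third order.  The package ships the exact inverse too
  (`omega_from_rotvec_rate(..., exact = TRUE)`).
* torsional widths are standard deviations of half-radian residuals
  converted by the small-angle factor 2: a residual SD of `s` half-radians
  is reported as `2 s 180/pi` degrees.

## The plant

The model eye is a rigid globe (7 cm radius, inertia tensor `I0` of order
4.5e-4 kg m^2 with small off-diagonal terms) rotated about its fixed
center by the torques of six elastic tendons.  Each tendon runs from an
insertion on the globe (`Q_i`, rotating with the eye) to a cranial
insertion (`P_i`) at the end of a rigid rod attached to one of three
motors; the vertical recti and the obliques are routed through fixed via
points (`X_i`, "pulleys") that set their pulling directions.  Rotating
motor k by `u_k` turns its rod, moving the pair's two cranial insertions
in opposite directions along a circle of half the rod length — the
antagonistic drive.

Forces are Hookean in the path length `l_i` (globe insertion to via point
to cranial insertion), `F_i = kappa (l_i - l0_i)` clamped at zero when
slack: an elastic string cannot push.  The pulling direction at the globe
is the straight segment from `Q_i` toward the via point (or directly
toward `P_i` for the horizontal recti); geodesic wrapping of the string
over the globe surface is not modelled.  Torques are `tau_i = Q_i x F_i`.
Friction has a viscous part `-chi_dyn w` and a stiction rule: when the
eye is slower than `eps_stat` and the compensated torque is below
`chi_stat`, the net torque is cancelled exactly (the eye sticks until the
elastic torque exceeds the bound).  Gravity is ignored.  The gyroscopic
term `w x (I w)` is excluded by default: over saccade-like motion its
power relative to the inertial term stays below 2e-4
(`gyroscopic_ratio()`, checked in the acceptance suite), a direct
consequence of the smallness of `I0`'s off-diagonal terms and of
`(amplitude/2)^2` — the test constructs tanh-profile saccades of 2-60
degrees at main-sequence-consistent speeds and measures the ratio.

Key mechanical parameters, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| `kappa` | 6.0 | N/m | tendon elasticity, equal for all six |
| `pretension` | 0.05 | — | fractional stretch at the rest pose |
| `chi_dyn` | 0.02 | N m s/rad | viscosity; makes the plant overdamped |
| `chi_stat` | 0.006 | N m | stiction bound |
| `eps_stat` | 0.01 | rad/s | stiction velocity cutoff |
| `dt` | 0.01 | s | control/sampling tick |
| `substeps` | 10 | — | inner 1 ms integration substeps |
| `dz` | 0 | cm | common vertical shift of cranial insertions |

Tendon *rest lengths* are not part of the geometry table; they default to
`(1 - pretension)` times the rest-pose path length, identical fraction
for all six, so every tendon is taut at rest and the near-symmetry of the
geometry leaves the straight-ahead orientation a rest point.  The
residual net torque there (the geometry is only nearly symmetric) is an
order of magnitude below the stiction bound, so the origin is a genuine
equilibrium of the full dynamics; an exactly mirror-symmetrized variant
is used in tests to separate symmetry-forced cancellations from this
residual.

With these defaults the plant is strongly overdamped and *slow*: the
largest torque the tendons can produce inside the motors' physical range
(about 0.05 N m) against the viscosity caps eye speed near 165 deg/s, and
step responses settle with a ~0.3 s position time constant.  Every speed
the package reports must be read on this plant's own scale.  The
*scale-free* regularities — emergence and width of Listing's plane,
duration-amplitude slope, peak-velocity saturation, straightness,
cosine component stretching, the amplitude ~ Vpk*D relation, and the
geometry-dependence of the plane's pitch — are the quantities of
interest, and none of them depends on the absolute speed scale.

The `dz` option shifts all cranial insertions (and, by default, the via
points with them) vertically; shifting only the rod insertions has
virtually no effect because the via points pin the pulling directions,
which is why co-movement is the default.  Rebuilt plants are re-tensioned
(rest lengths recomputed at the straight-ahead pose).

## Simulation

Each 10 ms control tick is integrated with ten 1 ms semi-implicit Euler
substeps: the new angular velocity (from `alpha = I(q)^-1 tau`, with
`I(q)` frozen per substep) advances the quaternion through
`qdot = w q / 2`, followed by renormalization; the muscle geometry and
inertia are refreshed every substep, the cranial insertions once per tick
(the motor command is tick-constant).  The integrator is validated by
self-convergence (halving the substep changes a 20-degree movement's
endpoint by well under 0.1%), by exact agreement with a pure-R reference
step, and by energy dissipation (kinetic plus elastic potential energy is
non-increasing under constant input with stiction disabled).  Stiction is
applied at substep level by zeroing the velocity, which also prevents
chattering: once stuck, the eye stays stuck until the elastic torque
alone exceeds the bound.  Settling (for static maps) means staying below
0.5 deg/s for 100 ms, with a 5 s timeout; non-settling grid points are
reported and dropped, not fatal.  The static motor-to-orientation map
(`motor_range_grid()`) settles a grid of motor commands in snake order
with warm starts, covering an oculomotor range beyond ±45 degrees on all
three axes at ±35 degrees of motor rotation.

## Identification

The controller needs a linear model.  A 180 s three-channel binary
excitation (`prbs()`: ±0.25 rad, 50 ms bits, independent seeded streams
per channel) drives the plant from rest; the first 120 s train a 6-state
discrete model `x+ = A x + B u`, `r = C x + E u` (three orientation plus
three velocity coordinates is the plant's intrinsic state dimension), and
the remaining 60 s yield per-output NRMSE fitness
`100 (1 - ||r - rhat|| / ||r - rbar||)`.  Estimation is deterministic
MOESP-style subspace identification: an LQ factorization of
future-input / past-data / future-output block-Hankel matrices, with the
past as instruments against the equation error the nonlinear plant
leaves; the SVD of the relevant block is truncated at order 6, `C` and
`A` come from the extended observability matrix and its shift structure,
and `B`, `E` and the initial state from an ordinary least-squares fit of
the simulated response.  A high-order vector-ARX fit realized by
Ho-Kalman balanced truncation provides an independent cross-check route;
both recover a known random 6-state system's input-output map to well
under 1%.

Because the plant's true equilibrium is not exactly the origin and the
linear model has no affine term, the training data are demeaned and the
operating point `(u_op, y_op)` stored with the model; all control
computations work in deviations and re-attach the offsets.  Without this
the constant bias dominates the fit at small excitation.  Typical
validation fitness at the defaults: ~96% horizontal, ~91% vertical, ~87%
torsional.  The model is local: it is trusted (and used) only as a
planning model, with the nonlinear simulator as the executor.

## Optimal control

A saccade plan is an input series `U = [u_0 ... u_D]` minimizing

* accuracy: squared endpoint gaze error in `(r_y, r_z)` — torsion is
  deliberately left out of accuracy;
* energy: squared input increments `||dU||^2`, with the *first* increment
  taken relative to the holding input of the start orientation, so that
  not moving costs nothing (the literal convention, first block `u_0`
  itself, is available as `energy_mode = "literal"`);
* duration: hyperbolic reward discount `1 - 1/(1 + beta D)`;
* torsion: endpoint `r_{x,D}^2` (`AEDL1`) or whole-trajectory
  `sum_t r_{x,t}^2` (`AEDL2`);
* fixation force: `r_D' H_F r_D`, where `H_F` is the quadratic form
  least-squares fitted (with a constant, no linear term — the form's
  conditional torsion minimum `r_x = -(H_xy r_y + H_xz r_z)/H_xx` is a
  tilted plane through the origin, which is exactly the structure of a
  Listing plane) to total static tendon tension over a settled
  orientation grid, symmetrized and PSD-projected if needed.

Terminal conditions — gaze on target, stationary terminal state
`x_D = A x_D + B u_D`, and equal last two inputs (zero terminal input
velocity, hence zero acceleration in the model) — enter as quadratic
penalties of weight `1e6 lambda_A` by default; a hard-equality KKT mode
exists and agrees with the penalty mode to a small fraction of a degree.
Each fixed-duration problem is then an unconstrained convex quadratic,
solved by Cholesky back-substitution against per-duration factorizations
cached in a `saccade_planner()`; duration is chosen by scanning a 20-400
ms grid of the *full* objective (costs plus terminal penalties), which
prices out durations too short to comply, exactly as hard constraints
would.  A tiny ridge (1e-9) anchors input directions no cost constrains —
only relevant for `AD`, whose energy weight is zero and whose solutions
are otherwise non-unique.

Planning happens on the linear model; execution is a single open-loop
input series played through the nonlinear simulator, with the last input
held for 300 ms to measure the settled endpoint.  One
*plan-play-correct* refinement round is performed by default: the settled
endpoint's deviation from the linear prediction is fed back as an
output-bias estimate and the program is re-solved once.  This is the
package's stand-in for the training phase in which observed movements
recurrently tune motor outputs against the cost; it corrects the static
bias of the local model at eccentric orientations (endpoint errors drop
from several degrees to about one at large amplitudes, and endpoint
torsion under `AEDL1`/`Force` from a couple of degrees to a few tenths)
while the executed movement stays strictly open-loop.

### How the weights were fixed

The weights are free parameters of the scheme.  `lambda_A = lambda_E = 1`
anchor the scales; `calibrate_weights()` then fixes `lambda_D` and `beta`
against two duration anchors chosen *on the plant's own speed scale*: the
cost optimum of a 10-degree horizontal saccade at 130 ms and of a
40-degree saccade near 300 ms.  These anchors are where the planned motor
commands stay within the drivers' physical range and the nonlinear
playback tracks the plan; pushing the optimum faster just makes the
linear plan outrun the plant.  The shipped defaults
(`lambda_D = 5.1`, `beta = 0.2`) are this calibration's output, run once
and frozen.  The torsion and force weights are set so their effective
curvature on endpoint torsion dominates the energy term's weak torsion
preference across a chained batch (`lambda_LP1 = 1e4`,
`lambda_LP2 = 100`, `lambda_F = 1000`; the force quadratic's curvature is
~0.33 N per half-radian², so `lambda_F H_F` is commensurate with
`lambda_LP1`).  The force weight stays far below the enforced gaze
accuracy (1e6), preserving the intent that force minimization only
arbitrates among endpoints with the same gaze.

## Experiments and analyses

Batches chain saccades: Gaussian displacement components (SD 15 degrees)
from the previous *realized* endpoint, absolute targets clipped to ±40
degrees per component to stay inside the identified region.  The batch
records every realized trajectory sample (movement and fixation), which
is the population the plane fit sees.  The plane fit regresses
`r_x = a r_y + b r_z` through the origin (the normal's direction is the
object of interest); its torsional width is the residual SD in degrees,
and the plane's pitch is `atan2(n_z, n_x)`.  Main-sequence fits use a
profiled grid over the angular constant (the asymptotic velocity is a
linear subproblem) refined by Levenberg-Marquardt, which stays
deterministic and stable even for near-linear data, where the angular
constant runs past the amplitude range and the fit is flagged.
Straightness is the correlation of the *absolute* vertical and horizontal
rotation-vector velocity profiles over the planned movement window (the
sign of the raw correlation only encodes the movement's quadrant);
component stretching correlates the fixed 8-degree horizontal component's
peak velocity with the cosine of the direction angle across
0-to-30-degree vertical companions.  Amplitude is the exact single-axis
(quaternion geodesic) rotation angle from start to settled end; peak
speed is the largest `|w|` in the movement window; duration is the
planned `D` (threshold-based detection is unstable at 10 ms resolution).

The vertical-shift sweep rebuilds the plant per `dz`, re-identifies the
model with a fixed excitation seed (so differences reflect geometry, not
excitation), re-estimates the force quadratic, and runs a `Force` batch.
Across `dz` from -8 to +8 cm the fitted plane's pitch moves monotonically
through zero, reaching about ±12 degrees at the extremes, while widths
stay Listing-like; in this implementation an *upward* shift of the
cranial insertions pitches the plane's normal upward (positive `n_z`).
The checks are kept sign-robust (monotonicity, and magnitude at the
downward-pitching extreme) because the torsion sign hinges on viewpoint
conventions that are easy to invert.

## What the synthetic generators do and do not emulate

The package's known-truth generators — random stable 6-state systems,
rotation-vector clouds with prescribed normal and torsional scatter,
exact triangular-velocity saccades, tanh-profile saccade traces — exist
to give the estimators inputs with known answers.  They emulate the
*structure* the estimators assume (linear dynamics, a planar cloud,
single-peaked profiles), not real oculomotor data: no measurement noise,
no drifts or blinks, no amplitude-dependent profile skewness.  Passing
the recovery tests therefore shows the estimators are correct and
well-conditioned, not that real recordings would be fit this well.
Likewise the plant batches are simulations of this plant: emergence of a
Listing plane here demonstrates a sufficiency argument about cost
structure plus geometry, not a claim about any particular biological eye.

## Problem sizes in the default test run

The test suite runs reduced reproductions sized for a desk machine: 300
chained saccades per functional for the emergence analyses (`AED`,
`AEDL1`, `Force`; 100 for `AE`/`AD`), 7 settling points per motor axis
for the force quadratic, 150 saccades per shift across the nine-step
geometry sweep, 1000 random pairs for the half-angle bound, and 1e4
random compositions for quaternion-norm drift.  The full-scale batch
(1500 saccades) is a `run_batch(n = 1500)` call away and changes none of
the qualitative outcomes.

## Known limitations

* The plant's printed stiffness/viscosity pair caps eye speed near 165
  deg/s; absolute velocities (asymptotic main-sequence velocity ~130-200
  deg/s here) are on the model's own scale, and regimes that require
  very fast plants — near-linear main sequences under accuracy+duration
  costs with large overshoots — do not occur on this plant.
* The linear model is local; beyond ±40 degrees its predictions degrade,
  which is why targets are clipped and one refinement round is used.
* Muscle paths are straight segments through fixed via points: no globe
  wrapping, no active pulleys, no Hill-type force-velocity properties,
  no gravity, and strictly monocular control.
* Velocity-profile skewness is not analysed; at a 10 ms tick the profiles
  are too coarsely sampled for a stable skewness measure.
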