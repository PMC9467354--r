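---
title: "Modeling motor adaptation to curl force fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling motor adaptation to curl force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reachadapt)
```

## The models

`reachadapt` simulates fast planar reaching movements of a two-link arm
under a velocity-dependent (curl) force field and implements three accounts
of how adaptation to such a field might work.

**Plant.** The arm obeys
$\ddot\theta = M(\theta)^{-1}(\tau_u + \tau_e - C(\theta,\dot\theta))$
with the standard two-link inertia matrix and velocity-dependent torques
(no gravity in the horizontal plane). Parameters are anthropomorphic:
masses 1.4/1.1 kg, lengths 0.3/0.33 m, centre-of-mass offsets 0.11/0.16 m,
inertias 0.025/0.045 kg·m². The field applies the hand force
$F = D\,\dot{x}$ with $D = R(\psi)^{-1}\left[\begin{smallmatrix}0&0\\
\varphi&0\end{smallmatrix}\right]R(\psi)$: perpendicular to the velocity,
proportional to speed, counterclockwise for $\varphi>0$. All simulations
use the standard reach: initial configuration [45°, 90°], 0.1 m forward
($\psi = 90°$), $\varphi = 2$ N·s/m, goal configuration [60.7°, 60°]
obtained by elbow-up inverse kinematics.

**Compensation model.** A desired trajectory (0.5-s minimum-jerk transport
followed by a 0.5-s stationary posture) is executed by inverse-dynamics
feedforward plus elastic feedback $B(\theta-\theta^*)$ with
$B = 20\,I_2$ N·m/rad. Adaptation is a compensation torque
$\tau_c = -\tau_e^{\varphi}$ evaluated on the current state — a learned
state-to-force map, so the after-effect (field off, $\tau_c$ on) is exactly
the before-effect of the mirrored field. This model is provided for its
predictions only; it has no account of trajectory formation.

**Reoptimization model.** The control torque is produced by a linear
second-order muscle model ($\nu = 0.05$ s, gains 2/1) driven by a control
input $u$. The controller is an optimal feedback controller over the
8-dimensional state (joint angles, velocities, activations, excitations):
at every control step ($\delta = 0.01$ s) an iterative LQR re-solves the
regulator problem minimizing $w_u \int |u|^2 dt$ ($w_u = 10^{-5}$) plus
quadratic goal penalties, from the current state *estimate*. Movements are
paced by a series of via-points at 32/64/96% of the reach plus the target,
the active goal switching every $T_G = 0.13$ s (~7.7 Hz, the submovement
rate); the planning horizon is $T_H = 0.28$ s. Goal weights: position 10,
velocity 0.1, activation/excitation 0.01 at the final goal; position only
at intermediate via-points (the `boundary` presets add the other terms).
Adaptation = reoptimizing under the perturbed internal dynamics: in the
adapted and after-effect conditions both the controller's cost model and
the estimator use the field dynamics.

**Redirection model.** The identical controller and estimator, always
unaware of the field; adaptation consists solely of replacing the via-point
series $S$ by a remapped series $S'$ (`fitViaPoints()` provides a
deterministic greedy grid fit of the adapted path to a reference).

**Estimator.** Only position and velocity are observed
($H = [I_4\;O_4]$), with sensory delay $\Delta = 0.12$ s. The gain and
covariance follow the discrete Kalman recursions
$K = A P H^\top (H P H^\top + \Omega^\omega)^{-1}$,
$P^+ = \Omega^\xi + (A - KH) P A^\top$ (symmetrized each step), where $A$
is the Jacobian of the one-step flow. Two delay treatments are provided:
the default *delay-compensated* mode runs the filter at lag $\Delta$
against time-matched observations and forward-predicts through buffered
controls; the *literal* mode applies the delayed innovation against the
current estimate. The delay-compensated mode is the default because it is
the one consistent with an estimator described as optimal under delay; the
literal recursion distorts even unperturbed movements.

## Design decisions and numerical choices

* **Goal scheduling.** The receding-horizon idea admits several readings.
  The package default (`goalSchedule = "fixed_arrival"`) freezes each
  goal's arrival time when the goal is designated ($jT_G + T_H$), while the
  final goal keeps a receding horizon-end cost so that perturbed movements
  always retain a full horizon to finish (time flexibility). This makes
  goal updating control movement duration ($nT_G + T_H = 0.67$ s) and
  yields front-loaded, experimentally plausible velocity profiles with peak
  speed inside the instructed 0.25–0.35 m/s window. Two alternatives are
  available: `"current"` (only the current goal, penalized at the receding
  horizon end — movements trail the goal sequence and back-load), and
  `"deadline"` (all pending via deadlines penalized inside the horizon —
  via-points bind hard, but perturbed movements oscillate at the goal rate,
  which contradicts the monotone angle trends the predictions rest on).
* **Covariance units.** The estimator's diagonal covariance patterns
  (1, 1, 10, 10 sensory; 1 ... 1000 motor) are read in degree units for the
  kinematic entries and converted internally (`noiseUnits = "deg"`): they
  then mean a 1° position and 3.2°/s velocity observation noise, which is
  physiologically sensible. Read verbatim in radians (`"rad"`) they imply a
  57° position noise and a filter that nearly ignores its sensors; the
  headline predictions are almost identical under both readings.
* **Integration.** Fixed-step RK4 at the control step (0.01 s) everywhere;
  the plant optionally substeps (1 ms) when emulating 1000-Hz recordings.
  Linearizations are central finite differences of the one-step flow.
* **iLQR internals.** Levenberg-style regularization on the control
  Hessian, backtracking line search accepting any cost decrease,
  convergence at $10^{-8}$ relative improvement, warm start from the
  previous solve shifted by one step. Accepted iterations never increase
  the cost.
* **Angles** are radians internally; degrees at configuration and
  reporting boundaries. The trajectory angle is unwrapped only across
  samples where speed exceeds 0.01 m/s (below it the tangent is
  meaningless and the last defined value is carried).
* **Pipeline order** is fixed: filter positions → differentiate → filter
  each derivative → extract the movement → angle. Zero-phase filtering is
  applied with endpoint detrending and odd-reflection padding so that
  boundary transients never reach the analysis window; on noiseless model
  trajectories filtering changes the angle series by well under 0.5°.
* **Sign-change metric.** A crossing of the angle-derivative sign is
  scored only when the opposite sign persists for ≥ 3 samples; isolated
  near-zero dips of one sample are numerical.
* **Classification.** The training effect is an F-test of the exponential
  decay of lateral deviation against a constant model ($p < 10^{-3}$,
  decay rate ≥ 0.005/trial, positive amplitude): with over a hundred
  training trials a genuine decay is unambiguous by significance even when
  trial-to-trial jitter keeps $R^2$ modest. Partial compatibility requires
  a contiguous epoch of significantly positive after-effect derivative
  longer than 0.1 s — a genuine partial mirror spans roughly 0.1–0.3 s,
  while movement-onset transients last under 0.1 s.

## The synthetic cohort

`generateParticipant()` emulates what the analysis assumes about real
recordings: 1000-Hz planar hand paths in four categories with trial counts
17/19/107/34, trial-to-trial via-point jitter (σ = 4 mm), additive encoder-grade sensor
noise (σ = 0.02 mm, so the unfiltered kinematic spectra keep most power
below 10 Hz), and an exponential interpolation of the via-point
offsets toward the profile's remapped series across the combined
before-effect + adapted training sequence (rate 0.05/trial). Three
profiles: `mirror_absent` re-aims along a constant bearing (offsets
proportional to distance — flat-then-falling after-effect angle),
`mirror_present` remaps only the distal via-points (a sustained positive
derivative epoch mid-movement), `non_adapter` never remaps. Movement vigor is
calibrated automatically per condition (a deterministic, cached secant on
the planning-horizon divisor targeting a 0.30 m/s peak) — the analogue of
participants regulating their vigor from the speed feedback; valid-trial
rates are about 90% for either field direction, and the ~8 Hz goal pacing
is untouched.

What the generator does *not* emulate: signal-dependent motor noise,
return movements, rest pauses, fatigue, online learning within a block,
or the full trial-to-trial variability structure of human data. Passing
end-to-end tests therefore shows that the pipeline recovers the behavioral
structure the models predict, not that real participants behave this way.

## Problem sizes

The packaged analyses run single reaches of 1 s at a 10-ms control step
(100 iLQR re-solves per movement, horizon 28 steps), cohorts of 17–107
trials per category, and grid fits over 61 offsets per via-point; these
sizes reproduce the study conditions while keeping a full cohort analysis
in the order of seconds per participant.

## Known limitations

* The redirection after-effect of the *grid-fitted* remapped series shows
  a small but strictly positive early drift of the displayed angle
  (~+1° over the first 0.1 s, the tangent converging onto the first
  remapped bearing), and the baseline-matching fit prefers offsets that
  grow with distance, which tilts the mid-movement angle upward. A raw
  per-sample count of positive derivative therefore saturates near 20–60%
  even when the trace is, for all practical purposes, flat-then-falling;
  only a significance-based count over noisy trials (as in the participant
  classification) goes below 10%.
* The via-remapping can only partially cancel the field in the adapted
  condition (the delayed estimator under-corrects), so simulated adapted
  paths retain more curvature than well-trained human participants.
* The plant is a 2-DOF arm without muscle visco-elastic impedance; the
  model's lateral deviations at a given field level are accordingly larger
  than human ones, and all conditions here use the 2 N·s/m level.
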