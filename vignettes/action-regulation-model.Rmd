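---
title: "Modeling selection, stopping and switching of reaches with dynamic neural fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling selection, stopping and switching of reaches with dynamic neural fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachdnf)
```

## The model

`reachdnf` simulates rapid joystick reaches to cued targets in three task
protocols — decision-making, stop-signal, and switch — with a neurodynamical
architecture that couples dynamic neural fields (DNFs) to stochastic optimal
reach controllers.

Six fields are simulated. Four are *directional*: spatial sensory input,
expected outcome, reach cost, and reach planning, each with 181 neurons whose
preferred directions span 0–180° at 1° spacing (targets only occupy the upper
half-plane, so the lattice is non-circular with clamped boundaries). Two are
*unit-indexed* with no spatial metric: the stop-signal field (100 neurons)
and the pause field (100 neurons). Every field obeys leaky-integrator
dynamics of the Amari form

$$\tau \dot u = -u + h + S(t) + \int W(\Delta)\, g(u)\, + \,\xi,$$

integrated by the Euler method with step `dt = 10` ms, with a logistic
firing-rate function `g` and independent Gaussian activation noise scaled by
`sqrt(dt)`. Only the planning field carries a lateral kernel and noise by
default; the other fields act as filtered relays of their drives, which
keeps the number of noise sources interpretable and the integration cheap.

The planning field's kernel uses local Gaussian excitation plus constant
global inhibition. This choice (rather than a distance-limited surround) makes
any two target representations compete regardless of their angular
separation, which is what the choice tasks require: two bumps 60° apart must
still be rivals. The recurrent excitation is strong enough that an
established bump briefly outlives the removal of its input; the selection
dynamics therefore behave like a soft winner-take-all latch. That persistence
is scientifically load-bearing: an ongoing action's neural representation
does not vanish the instant its target disappears, and how quickly it can be
dismantled — by competition alone or with help from a pause signal — is
exactly what distinguishes the switching architectures below.

Wiring: sensory and outcome project one-to-one (excitatory) onto planning;
cost projects one-to-one inhibitory; the pause field projects one-to-all
inhibitory onto planning; the stop field projects one-to-all excitatory onto
the pause field. The cost field encodes a flat baseline before movement and,
once the cursor is moving, a drive increasing with angular distance from the
current heading, penalizing changes of movement direction.

### From fields to forces

Planning neurons whose activation exceeds the *action initiation threshold*
trigger reach controllers. Each active neuron `j` owns a policy $\pi_j$: a
finite-horizon LQR feedback law (backward Riccati recursion on the
discretized damped point-mass cursor, in goal-centred coordinates) steering
toward the point 20.37 cm along the neuron's preferred direction. The
executed force is the mixture

$$\pi_{mix}(x_t) = \sum_j d_j(x_t)\, \pi_j(x_t),$$

where the weights $d_j$ are the supra-threshold planning activations
normalized to sum to one — the *relative desirability* of each action. With
no neuron above threshold the force is zero and the cursor does not move.
When two neurons cross the threshold in the same step, both become active;
the mixture handles blending, so no argmax or tie-break is needed.

The controller is a linear-quadratic regulator with additive motor noise
rather than a full LQG loop with signal-dependent noise and state
estimation: the behavioral quantities the package targets (reaction-time
orderings, stop probabilities, switch-response orderings) depend on when and
which policies engage, not on fine error-correction statistics. Policy
horizons span a nominal movement time of 500 ms, capped by the time
remaining in the trial, so reaches complete in a human-like half second
rather than stretching to the deadline; a policy instantiated at a switch
re-spans what remains (including the 1 s deadline extension). Beyond-horizon
steps clamp to the terminal gains, so a finished policy holds its goal.

### The pause mechanism and the three switching architectures

The pause field implements motor inhibition: its summed rate inhibits the
whole planning field. It is engaged in four distinct ways:

* **Proactive** (tonic, moderate) while planning under *stop* anticipation —
  every stop-task trial, in all variants. This produces the response delay
  effect: reaction times lengthen when a stop signal may occur.
* **Reactive stop** (tonic, strong) after a stop signal, on top of the
  stop-field input; together they drive planning activity below threshold
  and keep it there, so the action is abandoned.
* **Reactive switch** (strong but *transient*, default 40 ms) after a switch
  signal. A tonic post-switch drive would indiscriminately suppress the new
  action as well and no switch could ever complete; a short pulse knocks
  down the established (old) bump — which has lost its input and cannot
  re-ignite — while the incoming target representation rebuilds right after.
* **Not at all** in the decision task.

The three architectures differ only in when the switch task engages the
pause field: `ARCH1` proactively during planning and reactively after the
signal in both trial types; `ARCH2` never; `ARCH3` only reactively, and only
in one-target (instructed) trials. Under `ARCH3`, a mid-flight one-target
switch is resolved by the pulse (fast), whereas a two-target switch must be
resolved by competition against the still-latched old action (slower) — the
direction of the one- vs two-target switch-RT difference therefore reverses
relative to `ARCH1`/`ARCH2`, which is the discriminating behavioral
prediction among the three hypotheses.

## Task protocols

All trials begin with a fore-period drawn uniformly from 1000–1100 ms,
then one target (instructed) or two targets with reward values 10 and 5
(choice) appear 20.37 cm from the origin; directions default to 120° and
60°. The cursor must enter a 2.75 cm acquisition disc (half the 5.5 cm cue
diameter, since the cursor centre is tracked) within 1000 ms.

* **Stop task**: in regulated trials the stop cue fires at the SSD after
  target onset. Success requires never entering the target disc and
  dropping below the stop-speed criterion (10% of the nominal peak speed,
  held ≥ 100 ms — the task itself states no numeric criterion) before the
  deadline.
* **Switch task**: at the SWSD the instructed target is replaced by one 60°
  away (adjacent-target geometry), or the high-reward target is removed in
  choice trials. The deadline extends by 1000 ms. Success requires reaching
  the new target without entering the removed target's disc.
* **Internally guided switch**: no reward values (both targets equally
  valued); the signal fires when the cursor's path length exceeds a random
  1.2–3.2% of the target distance, and in two-target trials the target
  closer to the cursor is removed. The printed threshold range implies a
  signal within about 0.24–0.65 cm of the origin — very early in the
  movement; it is implemented as stated, with the range config-exposed for
  sensitivity analyses.

Delays are anchored at target onset (the cue changes "after a short variable
delay" following presentation); a movement-onset anchor is available through
the event schedule for sensitivity analyses. Regulated trials follow the
1-up/1-down staircase: +50 ms after success, −50 ms after failure, clamped
at 0, initial value 250 ms. This rule converges to the delay yielding ~50%
success, which the acceptance script measures over the final 200 of 320
regulated trials. Condition fractions are realized exactly by shuffled
assignment, never by per-trial coin flips. One- and two-target regulated
blocks run separately with separate staircases, mirroring the task's
separate blocks.

Per-trial RNG substreams are derived from `(seed, trial index)` only, so
batches sharing a seed are noise-matched across task contexts and
architectures. Conditions that differ purely in pause engagement (e.g.
decision vs `ARCH2` switch planning) then yield *identical* trials — a
sharp version of the claim that the pause level is the only difference.

## Kinematic analysis

Simulated and recorded trajectories pass through the same entry point:
cubic smoothing splines per coordinate (R's `smooth.spline`, smoothing
selected by generalized cross-validation, which recovers a noiseless
minimum-jerk peak speed within 2%), speed from the spline derivative.

* **RT**: target onset to the first sample whose speed exceeds 10% of the
  trial's maximum. Applied to the simulated cursor exactly as to human
  joystick data, so model and human RTs are commensurable; the
  threshold-crossing time of the planning field is logged separately.
* **Exclusions**: RT < 100 ms (anticipation), then a single-pass removal of
  RTs more than 3 SD from the mean (the rule is not iterated).
* **SRT**: switch signal to the first sample moving (same 10% criterion)
  with heading inside a 30° cone around the *bearing from the current
  position to the new goal*. A cone around the target's direction from the
  origin fails for mid-flight redirections, which approach the new goal
  from a displaced position; the bearing-based cone is the reading of
  "starts to move towards the new target location" that treats early and
  late switches uniformly. In two-target switch analyses, trials in which
  the model had already committed to the low-reward target before the
  signal are excluded — removing the high-reward target then demands no
  change of action. Switch-RT batches start their staircase at 400 ms
  (config-exposed) so that fewer trials are spent in the staircase's
  initial climb.
* **Stop curves**: fraction of successful stops per SSD.

## The synthetic trajectory generator

`make_fixture_trajectory()` emulates recorded joystick data with known
ground truth: a quiescent fore-period, a minimum-jerk displacement profile
(bell-shaped speed, peak `1.875·amplitude/duration`), an optional mid-flight
redirection (a second minimum-jerk segment from the redirect point to the
second goal), additive Gaussian position noise, sampled at 100 Hz (real
recordings run at 60–100 Hz). It underpins the analysis tests: RT and SRT
extracted from fixtures are compared against dense-grid evaluations of the
same closed forms.

What the generator does *not* emulate: sensor dropout, hand tremor with
temporal structure (its noise is white), drift of the joystick zero,
curvature of unperturbed human reaches, or endpoint undershoot. Passing the
round-trip tests therefore validates the analysis code paths, not the
analysis's robustness to every artifact of real recordings.

## Numerical choices and degenerate inputs

* `dt = 10` ms everywhere (fields and plant); the ±50 ms staircase step is
  then a multiple of `dt`. `step_field` enforces `dt ≤ τ/5`.
* All field parameters are this package's own calibration, chosen once so
  that instructed reaches complete well within the deadline, choice reaches
  start later than instructed ones, the stop psychometric spans 0.5 inside
  the default SSD grid (200–800 ms), and the switch architectures separate;
  every value is a config-exposed `model_spec()` override.
* Default problem sizes in the tests and acceptance script — 50 trials per
  RT condition, 50 per SSD, 320 regulated staircase trials — are the sizes
  at which the targeted contrasts are statistically resolvable at the
  stated test levels.
* Degenerate inputs: no targets → zero drive and a stationary trial; a
  stationary trajectory → zero speed and `NA` RT; an SSD bin with no trials
  is omitted from the curve; staircases clamp at 0 ms; `filter_rts` with
  zero variance excludes nothing.
* The plant uses semi-implicit Euler (velocity first), which is what the
  LQR discretization assumes; the two never disagree about the dynamics.

## Limitations

The model is a systems-level account: fields are not mapped to anatomy, the
controller omits signal-dependent noise and sensory estimation, the cursor
is a point mass with no arm biomechanics, and learning (kernel plasticity,
practice effects across blocks) is out of scope. The internally guided
variant implements the printed distance-threshold range even though it
implies a very early switch signal; treat conclusions drawn from that
variant's absolute SRT values with care.
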