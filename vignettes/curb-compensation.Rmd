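---
title: "Minimum-work compensation for walking over a curb: model, synthetic cohort, and measurement pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-work compensation for walking over a curb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curbwalk)
```

## The walking model

`curbwalk` models a walker as a point mass `M` (the pelvis) carried by
rigid, massless legs of length `L`. Within a step the stance leg behaves as
an inverted pendulum: mechanical energy is conserved, speed is lowest at
midstance (leg vertical) and highest at the ends of the arc. Steps are
punctuated by an impulsive step-to-step transition: the trailing leg pushes
off along its own axis (the model's only actuation, work `u = M P^2 / 2`
for an impulse `P`), immediately followed by a perfectly inelastic
collision along the leading leg (the only dissipation). The transition
redirects the centre-of-mass velocity onto the next pendular arc:

* post-transition speed: `v+ = v- cos(Phi) + P sin(Phi)`,
* collision loss: `M (v- sin(Phi) - P cos(Phi))^2 / 2`,

with `Phi` the inter-leg angle. The state relevant to control is the
midstance speed `v_i` of each step `i`; `step_map()` advances it and
reports the step time, work, loss and horizontal advance. Terrain enters
as a single signed height change `b` at one step: the double-support
geometry tilts (`transition_geometry()` solves the two-circle
intersection), and climbing the curb converts kinetic to potential energy.

### The step-length convention

The walker takes steps of fixed length `S`, which this package interprets
through the leg splay angle: the legs open by `2 alpha` with
`alpha = S / (2 L)` radians, so the chord between footfall points is
`2 L sin(alpha)` and the inter-leg angle is `2 alpha` on any terrain (a
fixed chord fixes the angle). We adopted this convention — rather than
reading `S` directly as the chord — because it is the one that reproduces
the published bout works for this task to within their stated precision
(about 1%, versus about 10% for the chord reading); the difference is pure
bookkeeping in what "step length 0.79 L" denotes. At the nominal condition
(`V = 0.44 sqrt(gL)`, `S = 0.79 L`) the model's average forward speed is
0.48 `sqrt(gL)`, i.e. 1.49 m/s for a 1 m leg — ordinary human walking.

## The optimal-control task

The task is a bout of `N = 15` steps with the curb (`b = 0.075 L`,
about 7.5 cm) at step `i = 0`, entered at steady nominal gait. The
controls are the `N` push-offs. `solve_min_work()` minimizes total
push-off work subject to two constraints: the bout must end at nominal
speed, and must take exactly the time of `N` nominal level steps (no time
may be lost to the curb). The solution is *triphasic and anticipatory*:
speed up over a few steps before the curb, surrender momentum climbing it,
recover afterwards — and the cumulative time gain returns to zero.

Three alternatives are implemented for comparison:

* `simulate_no_compensation()` — nominal push-off regardless; the walker
  recovers speed passively but loses about 0.7 s over the bout at human
  scale.
* `solve_reactive()` — nonanticipatory control: push-offs are held at
  nominal up to and *including* the push-off onto the curb (a reactive
  controller cannot act before the perturbation has affected the body),
  with the remaining steps optimized under the same constraints. Defining
  reactivity as "free from `i = 0`" instead would let the controller act
  at the curb itself and nearly match the full optimum; only the stricter
  definition reproduces the published cost of reactive control, and it is
  the one consistent with compensation occurring after the disturbance.
* `solve_tight_regulation()` — every step time is pinned to nominal by a
  per-step root find.

At nominal conditions the works order as optimal < tight < reactive
(`scripts/acceptance.R` recomputes the values), all above the nominal
level bout, with the optimum about 10% above nominal.

Two properties make the single solved pattern reusable: *twofold
symmetry* (the Down-step optimum is nearly the Up-step optimum flipped in
both time and speed, correlation below -0.9) and *self-similarity*
(`self_similarity_report()`: one shape across speeds and step lengths,
with amplitude shrinking as speed grows, because a fixed curb perturbs a
larger kinetic energy relatively less, and growing linearly with curb
height in the small-height regime).

### Perturbation persistence

Linearizing the level step map about its fixed point at constant push-off
gives the eigenvalue of speed-perturbation decay. For this transition
model the eigenvalue is exactly `cos(2 alpha)` — independent of speed —
which at `S = 0.79 L` gives 90% decay in 6.6 steps
(`persistence_steps()`). A quoted figure of about 5.7 steps for this decay
would require `2 alpha` near 0.84 rad; no convention for `S` consistent
with the published works can produce it, so the package reports the value
its own map implies.

### Numerical choices

* Pendulum arc times are computed by 40-node Gauss-Legendre quadrature of
  `dt = d theta / thetadot`; the integrand is analytic for positive
  midstance speed, and the rule agrees with adaptive quadrature and a
  Runge-Kutta oracle far below 1e-8.
* The constrained solve is parameterized by the midstance speeds, not the
  push-offs: given consecutive speeds the joining push-off is closed-form,
  the terminal-speed constraint becomes a fixed endpoint, and only the
  scalar time constraint remains. It is enforced by a Lagrange multiplier
  driven to feasibility by a secant iteration (time residual below 1e-10),
  with BFGS inner minimizations cold-started at nominal gait — the problem
  is smooth and empirically unimodal from that start, and the solve is
  fully deterministic.
* Push-off non-negativity (an impulse cannot pull) is kept by a quadratic
  penalty during optimization and verified at the solution; a push-off so
  large that the leading-leg collision component reverses is clamped to
  zero loss and flagged (an inelastic point contact cannot add energy).
* Failure modes raise classed conditions (`curbwalk_vault_error`,
  `curbwalk_geometry_error`, `curbwalk_optimization_error`, ...) so
  callers can distinguish infeasible terrain from solver trouble.

## The synthetic cohort

No human recordings ship with the package. Instead `draw_cohort()`,
`generate_trial()` and `synthesize_foot_traces()` emulate the walkway
study so the whole measurement chain can be validated against known
ground truth: 12 subjects, a 30 m walkway with the 7.5 cm height change
at midpoint, Up-step / Down-step / level Control conditions, subject mean
speeds 1.38 ± 0.10 m/s, about 5% coefficient of variation between a
subject's trials and 2.2% i.i.d. per-step speed noise within a trial.
Each trial's true per-step speeds are the trial mean plus the
model-predicted compensation pattern scaled by `(b / b_up)(v_up / v)` —
linear in curb height, inversely proportional to speed — plus noise. Step
length follows a preferred-step relation `S(v) = 0.72 (v / 1.38)^0.42` m;
trials are trimmed to an odd step count so both feet cover identical
ground, which is what makes inter-foot detrending a drift correction
rather than a layout correction. Foot traces are smooth quintic swing
arcs between 120 ms stationary dwells, with forward-position drift built
from doubly integrated white accelerometer error (0.02 m/s² RMS) so the
zero-velocity machinery is genuinely exercised.

What the generator does *not* emulate: gyroscope/orientation error and
gravity leakage (the traces are planar positions, i.e. the output of an
upstream strapdown stage), stutter steps, within-trial step-length
fluctuations, and any human pattern differing in shape from the model's.
Passing tests therefore show that the pipeline and statistics recover
what was injected at realistic noise levels — not that real subjects
behave like the model.

## The measurement pipeline

`reconstruct_trial()` chains the stages a foot-mounted inertial analysis
would use:

1. `detect_footfalls()` — stationarity runs (speed < 0.05 m/s sustained
   80 ms or more, 0.4 s refractory), event time at the run midpoint with
   threshold crossings located by interpolation. The first and last
   footfall of a traversal merge into the standing periods at the walkway
   ends; their strides are unreliable and fall outside the analysis
   window.
2. `zupt_integrate()` — per-segment linear velocity correction forcing
   zero velocity at each footfall, then re-integration; exactly cancels a
   constant velocity bias per segment.
3. `build_stride_table()` / `detrend_feet()` — stride length, time and
   average speed per foot; a linear-in-time position correction makes
   both feet agree on total distance.
4. `body_speed_sequence()` — one speed per step by alternating feet, each
   sample the average speed of the stride beginning at that footfall,
   `i = 0` and `t = 0` at the footfall onto the curb, cropped to the
   central 8.5 m (about 12 steps), symmetric about the curb.

Because each sample is a *stride* average, the measured sequence is a
smoothed, forward-shifted image of the per-step speeds. Comparisons are
therefore made in like terms: `body_speed_trajectory(..., measure =
"stride")` and `true_body_speed(..., "stride")` express model and ground
truth in the measurement's own convention. Against that oracle the
pipeline recovers speeds to better than 0.5% with drift disabled and
about 0.3% RMS at default drift and noise, and recovers the injected
pattern at per-trial correlation above 0.9.

## Statistics

`pattern_correlation()` computes per-subject Pearson correlations of
fluctuation sequences (each trial's own mean removed) against a reference
over the common step indices, then a two-sided one-sample t-test of the
correlations against zero; `permutation_p_value()` checks the t-test
against a subject sign-flipping null. `fit_height_scaling()` and
`fit_speed_scaling()` pool all steps and trials into an ordinary
least-squares fit of `dv ~ (c * ratio + d) * dv_ref` with the ratio
`b / b_up` or `v / v_up`; on noise-free synthetic data they recover the
injected coefficients exactly, and the speed fit matches the closed-form
least-squares line through the injected `1/x` gains. Pooling ignores
subject-level clustering — a deliberate simplification, noted as a
limitation rather than modelled. Tests are two-sided at alpha = 0.05.

## Problem sizes and reproduction

The default analyses are desk-scale: a full `run_pipeline()` with the
12-subject, 4-trials-per-condition cohort (144 trials) runs in about a
minute on one CPU, and each constrained solve takes a couple of seconds.
The test suite uses smaller cohorts (2-6 subjects, 1-3 trials) except
where a statistical property needs the full design.
`scripts/acceptance.R` re-derives the headline model quantities — the
four strategy works, the persistence estimate and the uncompensated time
loss — from a fresh solve at the nominal condition.

## Known limitations

* Sagittal-plane point-mass mechanics only: no knees, ankles, swing-leg
  cost, step-width control or 3-D balance; curb heights much beyond
  0.1 L leave the model's vaulting regime.
* The reactive and tight strategies are two specific formalizations of
  "react after the disturbance" and "hold timing"; other reasonable
  definitions change their costs (see the reactive note above).
* The persistence estimate is structural (`cos(2 alpha)`); adding
  speed-dependent step lengths to the *transient* (not just the nominal
  condition) would speed decay substantially and is not modelled.
* The scaling regressions treat steps as exchangeable observations;
  with real cohorts a mixed model over subjects would be the cautious
  choice.
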