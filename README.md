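# curbwalk

Walking up a sidewalk curb is a small optimal-control problem: the curb
steals forward momentum and time unless the walker plans around it, and
among the infinitely many ways to make up the loss, one costs the least
mechanical work. `curbwalk` implements that problem end to end for
researchers in locomotion biomechanics and motor control:

* a **dynamic walking model** — a point mass `M` on rigid inverted-pendulum
  legs of length `L`, powered only by impulsive trailing-leg push-off
  (work `u = MP²/2`) and dissipating only through the inelastic leading-leg
  collision, with speed sampled once per step at midstance;
* the **minimum-work compensation** for a single Up- or Down-step
  (height `b = 0.075 L`) in a 15-step bout: minimize `Σᵢ uᵢ` subject to
  ending at nominal speed and conserving total walking time, solved by
  single shooting through the step map. The optimum is a triphasic,
  anticipatory pattern of speed fluctuations, compared against
  no-compensation, purely reactive, and tight-time-regulation strategies;
* a **synthetic walkway cohort** (12 subjects, 30 m walkway, 7.5 cm curb,
  self-selected speeds 1.38 ± 0.10 m/s) with full ground truth, emulating
  foot-mounted inertial measurement, including integration drift;
* the **measurement pipeline**: footfall detection, zero-velocity-update
  integration, stride tables, inter-foot detrending, per-step body-speed
  sequences cropped to the central 8.5 m;
* the **statistics**: per-subject pattern correlations with one-sample
  t-tests (plus a sign-flip permutation check), and the step-height
  (`Δv ≈ (c_b·b/b_up + d_b)·Δv^up`) and speed
  (`Δv ≈ (c_v·v̄/v̄_up + d_v)·Δv^up`) scaling regressions.

All model computation is dimensionless (`M = L = g = 1`); human scale uses
the speed unit `√(gL)` = 3.13 m/s and time unit `√(L/g)` = 0.32 s.

## Worked example

```r
library(curbwalk)

p <- walker_params()       # V = 0.44 √(gL), S = 0.79 L, b = 0.075 L
nominal_gait(p)$pushoff_work
#> [1] 0.03021                per-step work of steady level gait, MgL

opt <- solve_min_work(p)   # Up-step at i = 0 of a 15-step bout
opt
#> <control_solution: optimal strategy, 15 steps>
#>   total push-off work 0.4954 MgL over time 24.2299 (residual -7.02e-12)
#>  step_index pushoff_work midstance_speed step_time ...
#>          -2      0.03551          0.4683     1.555
#>          -1      0.04159          0.4991     1.493
#>           0      0.04756          0.3951     1.612
#>           1      0.03264          0.4182     1.724
#>           2      0.03123          0.4287     1.667
```

The solution reads directly as the triphasic strategy: the walker speeds
up ahead of the curb (midstance speed 0.499 at `i = -1` versus the nominal
0.44), surrenders momentum climbing it (0.395 at `i = 0`), then rebuilds
speed while the cumulative time gain returns to zero at the bout's end.
Comparing strategies:

```r
total_work(solve_reactive(p))           # 0.5200  (nonanticipatory)
total_work(solve_tight_regulation(p))   # 0.5047  (constant step timing)
nominal_gait(p)$bout_work               # 0.4531  (level walking, 15 steps)
persistence_steps(p)$steps              # 6.56 steps to shed 90% of a
                                        #   speed perturbation passively
```

Anticipation pays: the optimal bout costs ~9% more than level walking,
the alternatives 11-15% more. `body_speed_trajectory(opt)` converts the
solution to m/s for comparison with measured walking, and the synthetic
study runs end to end with

```r
res <- run_pipeline(out_dir = "run1", seed = 1)
res$report$correlation_vs_model   # ≈ 0.98: subjects' reconstructed
                                  # patterns track the injected optimum
res$report$height_scaling_cb      # ≈ 1: fluctuations scale with curb height
```

A command-line front end over the same functions ships in
`inst/scripts/curbwalk.R` (subcommands `predict`, `simulate`, `process`,
`analyze`, `reproduce`).

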