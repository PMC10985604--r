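# obstaclegait

Marker-based analysis of everyday obstacle negotiation — overstepping a
15 cm bar, crossing a 50 cm gap, balancing along a 20 cm corridor,
circumventing slalom poles — by children with gait disorders, compared
between a physical course and the same course in immersive virtual reality
(VR).  The package implements the complete computation chain from per-trial
3D marker trajectories to noninferiority verdicts, for researchers in
rehabilitation biomechanics and clinical movement analysis who want to
reproduce, extend or stress-test this style of study.

## What it computes

For each task-specific spatiotemporal parameter (step length/width, gait
speed, double stance, maximal step height and clearance of the leading and
trailing foot, signed pre/post-obstacle distances, single-stance times,
minimal shoulder–obstacle distance, task time, failure counts), the
pipeline forms per-participant paired differences

d̄ = mean(VR) − mean(physical),   over the first 6 valid trials per cell,

their z-based 95% confidence interval d̄ ± 1.96·s/√n, and a three-way
decision against an expert-panel noninferiority margin **m** whose sign
encodes the harmful direction:

* **noninferior** — the CI lies strictly on the acceptable side of m;
* **inferior** — the CI reaches the region at or beyond m *and* excludes 0;
* **inconclusive** — it reaches that region but still includes 0.

Upstream of the statistics sit TRC trajectory I/O, kinematic foot-strike /
foot-off detection (speed-threshold stance finding with sub-frame
change-point refinement), task-parameter extraction, validity screening
(wrong leading foot, marker failure, instruction violation) and
covariate-adaptive (minimization) condition-order assignment.  A synthetic
trajectory generator with closed-form ground truth — smooth minimum-jerk /
sinusoidal swing arcs over a prescribed placement schedule — stands in for
the unavailable laboratory recordings and makes every stage testable.

## Worked example

The statistical layer reproduces the published cohort analysis directly
from the bundled summary table (n = 20):

```r
library(obstaclegait)
out <- analyze_reference()          # CIs + decisions for every parameter
subset(out, !is.na(decision))
#>            task                      parameter mean_diff  ci_low ci_high margin     decision
#>    overstepping              max_step_height_L      3.77  1.2763   6.264     -2  noninferior
#>    overstepping              max_step_height_T     -1.75 -4.8485   1.349     -2 inconclusive
#>        crossing                    step_length     -1.75 -4.9142   1.414    -10  noninferior
#>       balancing                     step_width      1.05  0.2042   1.896      3  noninferior
#>   circumventing min_shoulder_obstacle_distance      0.25 -1.6959   2.196     -2  noninferior
```

i.e. four primary outcomes noninferior and the trailing-foot step height
inconclusive.  The same machinery works on your own paired differences:

```r
ds <- difference_stats(c(2.1, 5.3, -0.8, 6.2, 3.9, 1.0, 7.4, 2.2, 4.8, 0.3,
                         5.1, 3.3, 6.0, 2.8, 1.9, 4.4, 3.0, 5.6, 2.5, 4.1))
ds
#> mean difference 3.56 (SD 2.11), n = 20, 95% z-CI [2.63, 4.48]
classify_noninferiority(ds, -2)
#> CI [2.63, 4.48] vs margin -2.00 -> noninferior
```

A full synthetic study — trajectories, events, extraction, decisions:

```r
cfg <- synthetic_config(n_participants = 20, rng_seed = 1)
ds  <- simulate_study(cfg)          # 1600 trials, deterministic under the seed
res <- run_pipeline(ds)             # validity -> first-6-valid -> CIs -> verdicts
res$decisions
writeLines(render_summary_table(res))
```

## The analysis workflow

The `analysis/` scripts run the whole study as a narrative, writing tables
under `results/` (bulky regenerable trajectories go to `scratch/`):

```sh
Rscript analysis/01_simulate.R   # simulate cohort, write TRC trials + manifest
Rscript analysis/02_extract.R    # reload from disk, events, validity, parameters
Rscript analysis/03_analyze.R    # CIs, decisions, injected-shift recovery
Rscript analysis/04_report.R     # summary table + forest plot + comparison
```

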