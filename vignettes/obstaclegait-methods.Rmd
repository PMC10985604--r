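---
title: "Methods: obstacle-course gait analysis and noninferiority comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: obstacle-course gait analysis and noninferiority comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obstaclegait)
```

## The scientific question

Children and adolescents with gait disorders practice everyday walking
activities — stepping over a bar, crossing a gap, balancing along a narrow
corridor, circumventing obstacles — as part of neurorehabilitation.
Immersive virtual reality (VR) delivered through a head-mounted display can
present the same obstacles in a safe, motivating environment, but it is only
a useful therapy tool if the movements it elicits are the movements the
physical obstacles elicit.  The natural statistical framing is
*noninferiority*: for each task-specific spatiotemporal parameter, is the VR
condition at most an expert-accepted margin worse than the physical
condition?

`obstaclegait` implements the full computation chain of such a study:

1. **Trajectories** — nine reflective markers (toe, heel and ankle on each
   shoe; both acromia and a C7 proxy) sampled at 100 Hz while the child
   walks a 6.5 m course, stored as TRC files plus a manifest.
2. **Gait events** — algorithmic foot-strike / foot-off detection from
   marker kinematics.
3. **Task parameters** — the per-trial spatiotemporal outcome set of each
   of the five tasks, plus failure flags under a-priori rules.
4. **Study pipeline** — trial validity screening, first-six-valid
   selection, per-participant aggregation, paired VR − physical
   differences.
5. **Noninferiority statistics** — normality screen, z-based 95% CIs, and
   the three-way noninferior / inconclusive / inferior verdict against
   expert-panel margins.

Because the underlying motion-capture recordings of the validation study
are not public, the package ships a synthetic trajectory generator whose
ground truth is known in closed form; every downstream stage is validated
against it.

## The synthetic gait model

### Foot trajectories

A trial is a sequence of foot *placements* (heel ground positions)
alternating between feet.  During stance the foot is exactly stationary.  A
swing from one placement to the next same-foot placement follows a smooth
parameterised arc in normalized time $\tau \in [0,1]$:

* horizontal coordinates follow the minimum-jerk profile
  $\sigma(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$, so planar velocity and
  acceleration vanish at lift-off and touchdown;
* the vertical coordinate is $z(\tau) = a\,\sin(\pi\tau)$ with apex $a$,
  so the apex is analytically known and the vertical velocity at the swing
  boundaries is non-zero — the crisp kinematic signature that real heel
  impact provides, and what makes events detectable to sub-frame precision.

The trunk (shoulder markers) translates at constant forward speed; in the
circumventing task its lateral coordinate follows a cosine weave through
the pole slalom whose amplitude is calibrated by root-finding so that the
realised minimal shoulder–pole clearance equals the requested value
exactly.

Because stance positions, apexes and the event schedule are the model's own
inputs, every extracted parameter has an exact ground truth: placements
give step lengths/widths and pre/post-obstacle distances; apexes give
maximal step heights; the toe's height where its forward coordinate crosses
the bar is a one-dimensional root-find on the closed-form arc; single
stance times equal the prescribed crossing-swing durations; total task time
follows from the constant trunk speed and the ±1 m timing gate.

### What the generator emulates — and what it does not

Defaults reproduce the validation study's conditions: 20 participants, two
conditions, five tasks, eight recorded trials per task and condition
(six analysed), 100 Hz sampling, 1 mm isotropic marker jitter, and the
published physical-setup group means as baseline levels (e.g. 60.44 cm
step length, 1.10 m/s gait speed, 24.75% double stance, 27.53 cm leading
apex, 10.66 cm shoulder clearance).  Obstacle-task gait speed defaults to
0.9 m/s, a typical cautious negotiation speed; absolute task *total times*
are therefore not calibrated to the published means, and total-time
condition effects are not injected (they would require per-condition speed
modulation).

Participant heterogeneity: baseline profiles and task levels are drawn from
normals with the published physical-setup SDs, truncated by clamping to
physiologic ranges.  VR condition effects are participant-specific shifts
with the published difference-column means and SDs.  Two refinements make
the joint distribution match the printed table rather than a naive
independent-components model:

* **Level–shift correlation.**  With $VR = level + shift$ and all three
  SDs printed, $\rho = (\mathrm{sd}_{VR}^2 - \mathrm{sd}_{phys}^2 -
  \mathrm{sd}_{diff}^2) / (2\,\mathrm{sd}_{phys}\mathrm{sd}_{diff})$ is
  identified; it is negative for every parameter (shifts regress toward the
  mean), and the generator draws shifts accordingly.  Without this the
  simulated VR columns would be systematically over-dispersed and clamping
  would bias the circumventing clearance.
* **Crossing pre/post coupling.**  The crossing step length is the sum of
  the pre-gap distance, the 50 cm gap and the landing distance, so the
  three printed difference SDs are linearly dependent; the pre/post shifts
  are drawn bivariate-normal with the correlation (−0.61) implied by the
  printed step-length SD.

The crossing-task step length is measured from the trailing toe's stance
position to the leading heel's landing (this pipeline's convention; it is
stated explicitly because published condition means for that parameter are
not reproducible from the printed pre/post distances under any placement
convention, while the printed *differences* reconcile almost exactly:
−12.27 + 10.53 ≈ −1.75).  Absolute crossing step-length levels in
the synthetic cohort therefore differ from the published ones; differences
match.

Features of real data deliberately **not** modelled: foot rotation during
stance (markers translate rigidly), within-trial step-to-step variability
(each trial realises one parameter value, so single-step outliers — the
main driver of published balancing failure counts — are absent), soft
tissue artefact, camera occlusion patterns (dropout is i.i.d. per frame),
and visual event labelling.  Passing tests therefore demonstrate
correctness of the computation chain, not clinical validity on laboratory
recordings.

## Event detection

The detector is configured by `detection_params()`:

| parameter | default | meaning |
|---|---|---|
| `stance_speed_threshold` | 0.2 m/s | foot-marker speed below which a frame counts as stance |
| `min_stance_sec` | 0.05 s | minimum sustained stance |
| `merge_gap_frames` | 3 | hysteresis between sub-threshold runs |
| `filter_cutoff_hz` | 10 Hz | zero-lag low-pass before differentiation |
| `gate_z` | 10 mm | vertical gate for boundary refinement |
| `max_gap` | 10 frames | longest marker gap filled by cubic interpolation |

Positions are low-pass filtered with the magnitude response of a
forward–backward 2nd-order Butterworth (applied in the frequency domain
after endpoint detrending, which is transient-free for trials that start
and end in quiet stance).  Stance is where both toe and heel speeds stay
below the threshold; runs are merged across short blips and must last 50 ms.
Each boundary is then refined: around the coarse boundary, the foot height
(mean of heel and toe markers) is fitted with a local flat-plus-ramp
change-point model over a 0.1-frame grid of candidate touchdown times; with
quiet data a quadratic ramp term absorbs the slight curvature of the sine
approach, while under visible jitter the linear ramp is used (the quadratic
only adds variance).  Foot off is the same computation in reversed time.
If a strike and an off collide, the earlier sample wins and a warning is
logged.  A foot that never leaves stance yields a single strike and a
degenerate flag.

Measured on the generator: clean trials give events within 0.6 frames of
the schedule; at 3 mm jitter ≈99% of events fall within 2 frames.

## Parameter extraction conventions

* The **toe marker** defines pre-obstacle foot position and clearance; the
  **heel marker** defines landings.  Step height is measured above the
  floor (z = 0), not above the obstacle's top edge.
* Pre-obstacle distances are signed: negative when the toe is already past
  the obstacle's near edge (the published VR crossing mean is negative).
* Stance marker positions are means over the stationary frames (boundaries
  trimmed), which is exact on clean data and variance-optimal under
  isotropic jitter.
* Swing maxima and plane crossings are evaluated on cubic splines through
  the swing frames (interpolation error ~10⁻⁷ m for the model arcs),
  so clean-trial parameters agree with ground truth to well below the
  0.01 cm reporting precision; durations are accurate to one frame.
* The balancing analysis restricts step pairs to strikes inside the beam
  corridor; double-stance strides must *start* inside it (long strides may
  end beyond the 2 m beam).
* The minimal shoulder–obstacle distance is an exhaustive scan over every
  in-zone frame, both acromion markers and all poles — verified in tests
  against an independent triple-loop implementation, with exact equality.
* Failure rules (all configurable, thresholds in cm): maximum step height
  < 16 per foot, crossing step length < 51, any beam step width > 19,
  shoulder clearance < 2.

## Study pipeline

Validity verdicts (never exceptions) flag trials with the wrong leading
foot (detected crossing foot ≠ declared foot), required markers missing
beyond the interpolation limit inside the task zone, or an externally
recorded instruction violation.  The first six valid trials per
participant × condition × task are analysed, in recording order; a
shortfall analyses what is available and logs a warning, matching the
study's handling of two participants with only five valid trials.
Parameters are aggregated as arithmetic means, and differences follow the
VR − physical convention.  Cells present in only one condition are dropped
with an explicit log entry, never silently.

Condition order is assigned by covariate-adaptive minimization over
gender, age group (default bins <10, 10–14, ≥14 years; not stated by the
study, hence configurable) and functional-walking-ability group, with
randomization factor 1 (the minimizing arm is taken deterministically;
ties fall to a fair coin).

## Noninferiority statistics

For each parameter the paired differences get a mean, a sample SD and a
normal-approximation CI $\bar d \pm z_{0.975}\,s/\sqrt n$.  The z-based
interval is the default because it reproduces the published intervals
exactly from the published means and SDs at n = 20 (a t interval would be
wider); `method = "t"` is available.  Display rounding is half away from
zero to 2 decimals; all comparisons use unrounded values.

The margin's sign encodes the harmful direction.  With the axis oriented
that way: **noninferior** if the CI lies strictly on the acceptable side of
the margin (touching the margin is not noninferior — closed-interval
overlap); **inferior** if the CI reaches the region at or beyond the margin
*and* excludes zero; **inconclusive** otherwise.  The three outcomes are
exhaustive and mutually exclusive, which a 2 000-configuration randomized
test confirms.  Packaged margins (expert-panel medians): −2 cm for maximal
step height (both feet), −10 cm for crossing step length, +3 cm for
balancing step width, −2 cm for shoulder clearance.  Other parameters
require explicit panel input via `summarize_margin_panel()` (median and
IQR — a 15-member panel is too small for a normality assumption).

Enjoyment scores are compared with the Wilcoxon signed-rank test with
continuity correction (`stats::wilcox.test`).

## Numerical and testing choices

* All internal computation is in metres and seconds in a canonical frame
  (+X walking direction, +Z up, floor at z = 0); reported lengths are cm.
* Root-finds use `uniroot` at 10⁻¹⁰–10⁻¹² tolerances; weave-amplitude
  calibration brackets on a coarse grid first because the clearance
  response is only piecewise smooth.
* Frame-rate quantization sets the accuracy floor: events 1 frame, durations
  (two events) 2 frames, double stance about 1 percentage point per stride.
* Test problem sizes: the recovery test simulates one full 20-participant
  study (all five tasks) and checks every injected shift within 2 standard
  errors; decision replication runs 20 seeded 20-participant studies of the
  four obstacle tasks and requires each published verdict to recur in a
  majority of seeds; detector robustness uses 100 jitter realizations.
  These sizes mirror the study design while keeping the default test run
  in the minutes range.

## Known limitations

* The generator's trunk moves at constant speed, so gait speed and total
  task time carry no within-condition variance beyond what is injected.
* Failure *counts* are not calibrated: real failures often come from
  single aberrant steps, which the one-value-per-trial model cannot
  produce.
* The circumventing weave cannot realise clearances above ≈17 cm with the
  0.56 m pole spacing and child shoulder widths; drawn levels are clamped
  accordingly (rarely binding given the published means).
* Event detection is validated against synthetic ground truth only; the
  study's visual labelling criteria are unknown, so agreement with human
  labels cannot be quantified.
* C3D input is out of scope; TRC (and the manifest format) is the tested
  interchange path.
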