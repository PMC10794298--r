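---
title: "Estimating the intended trajectory in pursuit tracking"
author: "pursuittrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the intended trajectory in pursuit tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuittrack)
```

## The measurement problem

In a pursuit-tracking task a participant steers a cursor with a joystick to
follow a continuously moving target. In the variant this package supports,
the cursor's horizontal position is locked to the target and only vertical
motion is under the participant's control, so target and cursor form two
synchronized y-series sampled at the display frame rate (60 Hz).

The classical performance measure -- here called the **temporal tracking
error** -- is the vertical distance between cursor and target compared at the
same frame, $|c_y(t) - g_y(t)|$, reduced per trial by its mean or
root-mean-square. It is easy to compute but hard to interpret: it is minimal
wherever the two curves happen to cross, including crossings produced by a
direction change the participant did not expect, and it charges a purely
*temporal* misalignment (tracking the correct shape with a constant delay) at
the full vertical deviation.

The **spatial tracking error** instead measures the distance between each
cursor sample and the trajectory sample the participant was plausibly *aiming
for* at that moment -- the *intended* trajectory sample. Estimating that
sample for every cursor sample is the core algorithm of this package
(`track()`).

## The estimation model

Two assumptions identify the intended sample:

* **Similarity** -- a cursor direction change mirrors an intended target
  direction change of the same kind: cursor maxima correspond to target
  maxima, minima to minima.
* **Proximity** -- the intended direction change is the similar one closest
  in time and space. Because the target's horizontal progress is a clock
  (constant speed), temporal proximity is expressed by weighting the
  horizontal component of the distance double:
  $d_w = \sqrt{(2\,\Delta x)^2 + \Delta y^2}$.

The procedure is:

1. **Direction changes.** All strict local extrema of the target y-series
   are events (the trajectory is smooth by construction). For the cursor,
   only extrema with topographic prominence of at least 20 px are kept
   (about 2% of a 1080-px screen height), rejecting unintended joystick
   fluctuations.
2. **Matching.** Each cursor extremum is matched to the same-kind target
   extremum minimizing $d_w$. Matching is independent per cursor extremum:
   several cursor extrema may share one target extremum, which accommodates
   the typical case of fewer cursor than target direction changes. A match
   whose cursor extremum precedes its target extremum is *anticipatory*,
   otherwise *adaptive*.
3. **Assignment.** For a pursuit sample between consecutive cursor extrema
   $A$ and $B$ (matched to target extrema $A'$, $B'$), the candidate set is
   the inclusive run of trajectory samples between $A'$ and $B'$. The
   intended sample is the candidate minimizing the plain Euclidean distance;
   that distance is the per-sample spatial error. A sample whose intended
   sample lies strictly later in time is *anticipated*.

### Contracts the source description leaves open

Several details are not pinned down by the verbal description of the method;
this package fixes them as explicit contracts:

* *Double weighting* doubles the axis distance $\Delta x$, not its square.
* *Prominence* is the standard topographic definition, computed on the y
  series: walk from the extremum in both directions until a strictly higher
  (for maxima) sample or the series end; the prominence is the extremum value
  minus the higher of the two side minima. Boundary-adjacent extrema use the
  series end as base, so genuine direction changes near trial edges are not
  dropped. Filtering keeps extrema with prominence $\ge$ the threshold.
* *Plateaus* (runs of equal samples, frequent in integer-pixel data) are
  collapsed to their midpoint before the strict neighbor comparison.
* *Boundary samples* before the first and after the last cursor extremum are
  anchored to the trial's first and last sample, matched to the trajectory's
  first and last sample, so every pursuit sample receives an assignment.
* *Crossed matches* (target order inconsistent with cursor order) are
  span-repaired -- the candidate window is the [min, max] of the two matched
  indices -- and flagged, not re-optimized.
* *Ties*: equal candidate distances resolve to the earliest sample; a sample
  whose intended sample is itself is not anticipated; a match at identical
  indices is adaptive. All outputs are deterministic.
* *Anticipation* is decided on time indices rather than raw x, which makes
  leftward (mirrored) trials work without special-casing; all analysis
  results are invariant under left/right mirroring.

## The trajectory generator

The target path is the study's three-segment trigonometric design. Each
segment evaluates

$$f(x) = \sum_{i=1}^{3} a_i \sin(i x) + b_i \cos(i x)$$

over one full period of the fundamental ($2\pi$ by default, 240 dense samples
per segment). The outer segments draw $a_i, b_i$ uniformly from
$[-40, 40]$ px per trial; the middle segment uses the fixed amplitudes
$a = (37, -3, 26)$, $b = (23, -15, -9)$, so it is identical in every trial
and can support implicit sequence learning. Between segments, gaps of 30
dense samples are bridged by a cubic spline fitted through 10 flanking
samples on each side.

Design choices the generator makes where the design was genuinely open:

* **Start at the screen center.** The first segment's phase is anchored at a
  zero crossing of its waveform, so every trial starts exactly at the
  vertical center without shifting the curve -- a per-trial vertical shift
  would move the (deliberately constant) middle segment.
* **Horizontal extent.** One trial spans 900 px from the screen center
  toward the edge of the reference 1920x1080 display. With the default
  phase span this yields on the order of 19-20 target direction changes per
  trial, the scale reported for this task.
* **Constant speed by equal chords.** The target's speed is made constant by
  placing samples so that *consecutive sample distances* are equal: each
  sample is the first intersection of the path with a circle of the step
  radius around the previous sample, and the step is bisected so that an
  integer number of chords ends exactly on a region boundary. Resampling is
  done in three regions -- before, within, and after the constant segment --
  so the constant segment's sampled coordinates are bit-identical across all
  trials of a velocity level. Spacing is uniform to ~0.2%.
* **Velocity levels** default to 1.7, 2.4 and 3.4 px/frame. At 60 Hz these
  give a mean trial duration close to the study's 12 s across the six
  counterbalanced conditions (3 velocities x 2 sides, 12 repeats = 72
  trials). The levels are configurable; only their calibration to the mean
  duration is fixed by the study description.
* **Gap labels.** Spline-bridge samples inherit the adjacent random
  segment's label in summaries, keeping the constant segment uncontaminated.

## The pursuit simulator

`simulate_pursuit()` provides ground-truth fixtures:
$c_y(t) = \gamma\, g_y(t - L + \eta_t) + \beta + \text{oscillation} +
\varepsilon_t$, with hold-first/hold-last padding at the trial boundaries
(a participant resting at the start position), optional per-sample lag
jitter, a sinusoidal joystick oscillation, Gaussian noise, screen clamping,
and optionally *missed reversals*: around a skipped target extremum the lag
reference freezes, mimicking a participant who fails to react to a direction
change.

The simulator emulates the statistical structure the analysis cares about --
known lag/lead, noise below/above the prominence threshold, offsets, start
errors -- but not genuinely human control: no closed-loop dynamics, no
velocity-dependent motor noise, no learning within a session. Passing tests
therefore certify the *algorithmic* contracts (recovery of simulated lags
from matched direction changes, error orderings, QC behavior), not that the
spatial error is a valid psychological measure for any particular human
dataset.

## Quality control and summaries

* A trial is flagged when the cursor starts more than 100 px (strictly) from
  the screen center -- a deflected joystick at onset.
* A trial is flagged when its maximum temporal error exceeds the mean plus 3
  SD of the per-trial maxima pooled across the whole dataset. Flags are
  advisory: exclusion always requires a user-set visual-confirmation flag,
  never happens automatically.
* Per trial and per segment, summaries report the mean and RMS temporal
  error side by side (the source description uses both notions
  interchangeably; the mean is used in the summary tables, RMS is always
  available), the mean spatial error, and the anticipation rate (anticipated
  samples / all samples). The two random segments are additionally averaged
  (`random_avg`). Trials are retrospectively grouped into three contiguous
  near-equal blocks for practice-effect analyses.

## Known limitations

**The per-sample implied lag is attenuated on shallow slopes.** For a
pure-delay pursuit ($c_y(t) = g_y(t-L)$), the pursuit point at time $t$ sits
off the trajectory, displaced horizontally by $L$ steps. The nearest
trajectory point -- which is what the assignment selects -- is the foot of
the perpendicular onto the curve, not the time-delayed point. With local
slope $m$ (px vertical per px horizontal), the implied per-sample lag is
approximately $L\, m^2/(1+m^2)$: close to $L$ on steep stretches, near 0 on
flat ones. Under this task's geometry the median implied lag is roughly
0.6-0.75 of the true lag. Consequently, per-sample horizontal gaps
underestimate the visuomotor delay, and for small simulated *leads* a
fraction of samples on flat stretches is not labeled anticipated. The
matched direction changes do not suffer from this: the median index gap of
matched extremum pairs (`coef(fit)["lag"]`, `track_lag()`) recovers a
simulated delay exactly and is the package's recommended lag estimator. The
same geometry is why the spatial error is systematically *smaller* than the
temporal error for lagged tracking (the perpendicular distance
$\approx$ vertical distance $/\sqrt{1+m^2}$) -- the direction of the
error-type effect this measure was designed to expose.

**Event-level, not sample-level, stability of detection.** Adding a
sub-prominence oscillation to a pursuit leaves the *set* of detected
direction changes unchanged (same count and kinds) but can shift each
extremum's sample index by up to half an oscillation period; exact index
invariance under superimposed jitter is not attainable for any detector.

**Bridge steepness.** When the two segment endpoints flanking a gap land far
apart vertically, the 30-sample spline bridge is necessarily somewhat steeper
than the waveform's own steepest step (observed up to ~1.1x across 100
seeded trials). The bridge is smooth and continuous; it is just not
guaranteed to be flatter than the segments it connects.

**Matching is local.** Nearest-neighbor matching with span repair follows
the method's description; it is not a globally order-consistent (dynamic
programming) alignment. Crossed matches are rare, logged, and repaired
conservatively.

## Problem sizes used by the test suite

The suite exercises full-scale sessions where the contract is session-level
(72 trials, ~700 samples per trial) and reduced sizes where it is not:
brute-force oracle comparisons run on 100-300 random series of up to 200
samples; lag/lead recovery uses 20 full trials per condition; I/O and CLI
round trips use one-repeat (6-trial) sessions. The acceptance script analyzes
one full default session (72 trials, 150 ms lag, 5 px noise).

## A minimal analysis

```{r example, eval = FALSE}
cfg <- trajectory_config(seed = 7)
traj <- build_trajectory(cfg, velocity = 2)
trial <- simulate_pursuit(traj, pursuit_model(lag = 9, noise_sd = 5), seed = 7)
fit <- track(trial)
coef(fit)            # lag estimates, error means, anticipation rate
segment_summary(fit) # per-segment table
plot(fit)            # matches and both error series
```
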