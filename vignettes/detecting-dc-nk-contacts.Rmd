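---
title: "Detecting and timing DC-NK cell interactions in 3D tracking data"
author: "TrackContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and timing DC-NK cell interactions in 3D tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrackContacts)
```

## The measurement problem

Two-photon imaging of an explanted lymph node yields, after segmentation
and tracking, a table of 3D centroid positions per cell per frame. NK
cells in this tissue are highly motile (of order 10 μm/min), dendritic
cells form a dense, near-sessile network, and the frame interval is tens
of seconds. Deciding from such tracks whether an NK cell is *engaging* a
DC — as opposed to squeezing past one — cannot rest on proximity alone:
at a 25 μm contact radius, fast pass-bys are common. The detector in this
package therefore requires three conditions to hold simultaneously in a
frame, combining proximity with two independent signatures of arrest.

## The model

For an NK track with positions $\mathbf r(t_i)$ and a DC track sharing
its frame clock:

* **Instantaneous speed**
  $v(t_i) = |\mathbf r(t_i) - \mathbf r(t_{i-1})| / (t_i - t_{i-1})$,
  reported in μm/min. The first frame has no preceding step; $v(t_0)$ is
  defined to copy $v(t_1)$ so criterion series stay full-length. This
  convention only affects frame 0, where the confinement criterion is
  FALSE anyway (below), so it cannot create an event on its own.
* **FOV-average speed** $V_\mathrm{FOV}$: the mean over tracked NK cells
  of each track's mean speed — a two-stage mean, so short and long tracks
  weigh equally. DCs are excluded by default because a near-sessile
  population would drag the reference speed down and loosen the speed
  criterion; the cell-type set is a parameter and is recorded in output
  metadata.
* **Confinement ratio**
  $\mathrm{CR}(t_i) = |\mathbf r(t_i) - \mathbf r(t_0)| \,/\, L(t_i)$,
  where $L(t_i)$ is the cumulative path length from the track start: 1
  for perfectly straight motion, approaching 0 for confined motion. The
  ratio is taken cumulatively from the track start (one curve per cell
  per movie), not over a sliding window. Two numerical conventions: the
  indeterminate $0/0$ at the first frame resolves to 1 ("maximally
  straight"), and values are capped at 1 to absorb floating-point
  round-off in the triangle inequality. The phrase "distance run over
  trace length" admits the inverse reading; the convention here keeps
  CR in $[0, 1]$, which is the standard confinement ratio.

The per-frame criteria, at the published operating point
(`DetectorConfig()` defaults):

1. $\mathrm{Dist}(t_i) \le d$, $d = 25$ μm — inclusive. The printed
   threshold is "$\le$"; the distance-only baseline is described
   elsewhere with "$<$", a measure-zero distinction on real data that is
   fixed inclusively here for testability.
2. $v(t_i) \le \alpha V_\mathrm{FOV}$, $\alpha = 0.60$ — inclusive. The
   normalized speed $v_\mathrm{Norm}(t_i)$ is 0 exactly on frames meeting
   this criterion and $v(t_i)/V_\mathrm{FOV}$ otherwise, which is what
   criterion-timeline plots show.
3. $\mathrm{CR}(t_i) \le \mathrm{CR}(t_{i-1}) + \varepsilon$,
   $\varepsilon = 0.01$ — "constant or decreasing", with a small
   tolerance so that flat stretches contaminated by localization noise
   still count as constant. The first shared frame of a pair has no
   preceding value and is FALSE (a conservative start: an event cannot
   begin on a frame whose confinement trend is unobserved).

**Events** are maximal runs of consecutive shared frames on which all
three criteria hold, refined by a tolerance: an interior frame failing
exactly *one* criterion, with both neighbours fully qualifying, is
absorbed into the run. The reading adopted — absorbed frames must be
isolated and single-criterion, never two in a row — keeps events maximal
while never bridging two consecutive failures; several isolated absorbed
frames may occur in one event. Missing frames (tracking gaps) always
break runs: a gap is absent data, not an observed frame that failed, so
the tolerance does not apply to it. Duration is
$n_\mathrm{frames} \times \Delta t$ (a 1-frame event lasts one frame
interval, not zero), so planted $k$-frame contacts recover $k\,\Delta t$
exactly. Events are per NK-DC pair: one NK cell may hold simultaneous
events with different DCs, and no tie-breaking suppression is applied.

**Classes.** `touch_and_go` below 5 s, `long` at or above 900 s
(15 min), `intermediate` between. The 5 s bound is shorter than any
realistic two-photon frame interval, so at a 30 s cadence every detected
event is at least intermediate; the threshold is kept as printed and is
configurable (`touchAndGoS`), which is also how the 1 s-interval boundary
scan exercises it.

## Cohort statistics

`interactingFraction()` is the percent of tracked NK cells with at least
one event. `longFraction()` is per *cell*, not per event: a cell is long
if its longest event is long, since the population claim is about cells
showing long interaction times. Because the appropriate denominator is
ambiguous in cohort reports, `cohortSummary()` emits the long fraction
against both denominators (interacting cells and all tracked cells).
Between-condition comparisons use an unpaired, equal-variance, two-tailed
Student *t*-test with means ± SEM (SEM $= s/\sqrt n$, $n-1$ denominator);
a pooled variance of zero is flagged rather than raised. The unpaired
variant is the right one for independent cohorts of cells; the choice is
recorded in the JSON metadata of `runDetect()`.

## The synthetic benchmark

No tracking data are distributed with the package, so validation rests on
a generator whose ground truth is known exactly.

* **NK and T cells** follow persistent random walks: each frame's heading
  is $\hat h' \propto \kappa \hat h + (1-\kappa)\,\hat u$ with
  persistence $\kappa = 0.7$ and $\hat u$ uniform on the sphere; the step
  length is an independently drawn speed times the frame interval.
  Boundaries are reflective in both position and heading — without the
  heading flip, persistent walkers pin against the walls and folded steps
  bias the measured speed far below the drawn speed.
* **DCs** wobble around fixed anchors with a mean-reverting update
  (drift scale 0.5 μm/min), emulating a quasi-static dendritic network.
* **Planted episodes** steer an NK cell onto a DC in phases: a straight
  approach at 1.2× the nominal NK speed, scheduled each frame so the cell
  reaches a dwell sphere (radius $d/2$) one frame before the episode
  start, a fast holding orbit on that sphere if it arrives early, a slow
  dwell (0.15× nominal speed) in which every step points back toward the
  cell's own track origin — which strictly decreases the confinement
  ratio — while staying within the dwell distance of the drifting DC,
  and a fast radial departure. Because the flanking frames (orbit,
  departure) move at 1.2× nominal while the speed threshold is at most
  0.6× the cohort average, they always fail the speed criterion, and a
  noiseless planted $k$-frame episode is detected with exactly $k$
  frames. The initial placement of a planted cell is scaled to what the
  approach can cover before its episode, so the schedule is feasible at
  any frame interval.
* **Noise** (localization jitter, i.i.d. Gaussian per coordinate, and
  independent frame drops) is applied after the dynamics via
  `addNoise()`, so noise never feeds back into motion. Every field of
  view is generated from a stream derived from (seed, FOV index) and is
  bit-identical under reruns.

### Default study conditions and why

Volume 300 × 300 × 100 μm and a 30 s frame interval over 120 frames — a
typical two-photon lymph-node field at a 20× objective and a one-hour
movie. NK nominal speed 10 μm/min (the motile steady-state regime); T
cells 10 ± 2 μm/min, matching the published T-cell validation figure.
8 DCs per volume give a dense enough field that planted NK cells always
have a reachable partner.

One calibration deserves emphasis. The benchmark's purpose is
planted-parameter recovery: the planted episodes must be essentially the
*only* contacts, or recovered fractions cannot be compared to planted
ones. Chance contacts arise when a cell happens to be slow, confined and
within 25 μm of a DC in the same frame, and localization jitter alone
widens the apparent per-frame speed by about ±1.4 μm/min at 0.5 μm jitter
and 30 s frames. The generator therefore defaults to a tight speed
dispersion (between-track sd 0.5, within-track sd 0.5 μm/min), under
which emergent contacts touch only ~1-2% of cells — well inside the
binomial error of the recovery experiments. Real NK cohorts are broader;
consequences of widening the dispersion are emergent touch-and-go
contacts, which on real data are genuine brief encounters rather than
errors. This is the main respect in which passing recovery tests does
*not* certify behaviour on real data: the benchmark certifies the
detector's segmentation and timing, not the biological prevalence of
brief chance contacts.

### What the experiments check

`recoveryExperiment()` simulates replicate fields of view, detects, and
compares planted versus recovered quantities. The shipped validation
(`tests/testthat/test-acceptance.R`) runs, in about three minutes total:

* exact agreement of the run/absorption semantics with an independent
  run-merging reference on 1000 random criterion sequences;
* planted interacting fractions 10/45/52/90% at 100 NK cells per FOV,
  20 replicates, 0.5 μm jitter — recovered means inside the planted
  values' 95% binomial intervals — plus planted long-among-interacting
  fractions of 1% vs 12%, recovered within binomial error and separated
  at $p < 0.05$ by the *t*-test across replicates (the steady-state
  versus inflamed contrast as a detectable difference);
* duration fidelity: noiseless planted episodes recovered at exactly
  their planted frame count; with 0.5 μm jitter, median absolute error
  at most one frame;
* null specificity: zero events across 50 replicates with NK and DC
  populations held at least $2d$ apart;
* metric invariants: CR within $[0,1]$ on random tracks, 1 on straight
  lines, 0 on closed loops at the return frame; the speed estimator
  unbiased within 2% on constant-speed cohorts (the residual ~1% comes
  from mid-step boundary bounces, where observed displacement is
  genuinely shorter than the path).

Problem sizes (100 cells, 120 frames, 20 replicates) were chosen as the
smallest at which binomial intervals are tight enough to be informative
while a full validation stays in the minutes range on one CPU.

## Numerical and degenerate-input choices

* Thresholds are inclusive ($\le$) throughout.
* A pair with no shared frames yields an empty series/event table, not an
  error; a FOV with no NK or no DC tracks is a contract error in
  `detectAll()`.
* `validateFov()` reports findings (duplicate frames, single-point
  tracks, clock inconsistencies, gaps) instead of raising, so imperfect
  exports can be triaged; `readTracks()` raises only on structural
  problems (missing/unknown columns, non-numeric coordinates, decreasing
  time) and infers the frame interval as the median per-frame time gap,
  which is row-order-invariant and robust to dropped frames.
* The candidate-pair gate in `detectAll()` (skip pairs whose bounding
  boxes are farther apart than $2d$) is a pure optimization: the bound is
  a lower bound on distance, so gated-out pairs can never meet the
  distance criterion; a test asserts gate-on/gate-off identity.
* The distance-only baseline's on/off indicator is emitted as −1 (on) / 0
  (off), and the digitized distance uses the plot constants −0.15 (met) /
  0 (not met); detection uses the booleans only.

## Known limitations

* The simulator has no lymph-node anatomy (T-cell zones, vessels), no
  chemotaxis, and no photobleaching; DC shape is a point, so "distance"
  is centroid distance in both simulation and detection.
* Whether confinement-ratio monotonicity should be judged per frame
  (implemented) or over a whole candidate window is underdetermined by
  the published description; the per-frame reading with tolerance
  $\varepsilon$ reproduces the highlighted flat-or-decreasing stretches
  of criterion-timeline plots.
* The package starts from tracks; segmentation and tracking quality are
  upstream concerns.
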