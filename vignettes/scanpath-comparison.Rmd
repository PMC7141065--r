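---
title: "Methods: multi-participant scanpath comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-participant scanpath comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpathcmp)
```

This vignette documents the models, conventions and numerical choices behind
`scanpathcmp`, in the order the pipeline applies them.

## From fixations to scanpaths

The unit of raw data is the *fixation*: a participant, a stimulus, an onset
time (ms), a position (pixels, origin top-left, y downward — the
eye-tracker convention) and a duration (ms). Fixations with non-positive
durations, negative onsets, unparseable fields, or onsets that fail to
increase strictly within a participant-stimulus series are reported and
skipped rather than aborting a read, because real exports contain dropouts;
`read_fixations()` attaches the rejected rows so the totality `valid +
rejected = rows` is always checkable.

AOIs are axis-aligned rectangles, *half-open* on the right and bottom
(`[x0, x1) × [y0, y1)`). Half-openness is load-bearing: a layout that tiles
the stimulus then assigns every interior point to exactly one AOI, with no
double-claiming on shared edges. The same convention is reused for grid
cells, with one pragmatic exception — a point exactly on the stimulus's
right or bottom edge is assigned to the last cell, so the closed stimulus
rectangle is fully covered.

`assign_aoi()` resolves overlapping AOIs by file order (first match wins),
making token assignment deterministic for any layout. Fixations outside
every AOI map to a sentinel token; the default policy *drops* them when
building scanpaths, because AOI-string analyses conventionally contain only
AOI labels, and a `keep` policy is available for sensitivity analysis. With
the drop policy, two fixations straddling a dropped off-AOI fixation count
as adjacent — this keeps transition totals consistent with string length
(total transitions = tokens − 1).

## Edit distance and truncation

Scanpath similarity is the unit-cost Levenshtein distance on token
sequences; tokens are whole labels, so multi-character AOI names are single
symbols. The dynamic programme is implemented in C++ (a rolling-row table);
a deliberately naive recursive reference implementation
(`levenshtein_reference()`) is exported for validation and refuses inputs
beyond 24 combined tokens, where exponential blowup begins.

Truncation (`truncate_scanpath()`) collapses each maximal run of equal
tokens to one token. It is idempotent, never lengthens a sequence, and
relates the two transition views: the transition matrix of a truncated
scanpath equals the off-diagonal part of the raw matrix with self-counts
zeroed. Distances are computed on *raw* (un-truncated) scanpaths by
default; truncation is an explicit preprocessing step, because repeat
fixations are part of observed behavior and the two choices answer
different questions. Note that truncation is not contraction-safe for the
metric — `d(truncate(a), truncate(b)) ≤ d(a, b)` is false in general — so
no such property is relied on anywhere.

Pairwise matrices are normalised by their global maximum for display. The
divisor is recorded (`norm_max` attribute, and in figure sidecars) so any
figure can be mapped back to raw edit counts; an all-zero matrix is left
unchanged and merely flagged, avoiding 0/0.

Length summaries report the sample SD (n−1; 0 for a single scanpath), the
mode as the most frequent length with ties broken toward the *smallest*
value, and the range as the single number max − min.

## Dwell grids from DBSCAN core points

To segment a stimulus without hand-drawn regions, fixation points are
clustered with DBSCAN (Euclidean metric; a core point has at least
`min_pts` neighbours, itself included, within `eps`). `derive_core_radius()`
walks a descending ladder of candidate radii and returns the smallest at
which any core point exists; the grid cell dimension is then one core-point
*diameter*. Each stimulus axis gets the largest number of cells whose side
is at least that diameter, stretched to tile exactly — cells may be
rectangular, which increases coverage of a rectangular stimulus. Defaults:
`min_pts = 5` and the ladder 64, 48, 32, 24, 16, 12, 8 px, spanning
coarse-to-fine cell sizes sensible for ~1280 px stimuli viewed at typical
eye-tracking accuracy (~0.5–1° ≈ 15–40 px); both are exposed because no
single choice suits all stimulus scales. Cell sizing pools fixations across
participants and groups per stimulus, so both groups' heatmaps share one
geometry and cellwise differences are meaningful.

DBSCAN details that matter for reproducibility: border points (non-core
points within `eps` of a core point) are assigned to the cluster of their
*nearest* core neighbour, lowest index on a tie. Classic DBSCAN leaves
border assignment dependent on visit order; the nearest-core rule makes the
output a deterministic function of the input.

Each fixation contributes its full duration to the single cell containing
its point — no duration-weighted splatting — so the conservation law
*Σ cells + excluded out-of-bounds duration = Σ durations* holds exactly and
is asserted in the tests.

## Group statistics

All group comparisons are two-sided Mann–Whitney U tests in the
`stats::wilcox.test` convention: W is the U statistic of the first sample
(number of pairs with x > y, ties counting ½). The exact distribution is
enumerated when both samples have ≤ 8 observations and no ties; otherwise
the normal approximation with continuity and tie correction is used. A
degenerate comparison in which every pooled value is identical returns
`W = n_x·n_y/2, p = 1` by convention rather than failing. The per-AOI
duration family tests the individual fixation durations pooled by group per
AOI, at the Bonferroni level `alpha / n_AOIs` (0.05/13 ≈ 0.004 for the
13-AOI layout); AOIs one group never fixated are flagged untestable rather
than aborting the family. No correction is applied across stimuli — the
family is the per-AOI table of a single stimulus.

`group_distance_test()` offers two observation units. The default,
`per-participant-mean`, treats each participant's mean distance to
same-group peers as one observation (16/14 participants give 16/14
observations); `pooled-pairs` uses all within-group pairwise distances
(120/91). The pooled unit exposes the pairwise structure signal directly
and is the more sensitive choice in the separation experiments below, at
the cost of non-independent observations; the per-participant unit is the
statistically conservative default.

## The synthetic gaze generator

The generator exists so every stage is testable against known truth. One
participant's data is drawn as: scanpath length from a rounded lognormal;
an AOI sequence from a first-order Markov chain; per-fixation durations
lognormal; per-fixation positions from an isotropic Gaussian hotspot at the
AOI centre (SD one sixth of the smaller AOI side) mixed with a uniform
component (`p_uniform = 0.2`), clamped into the half-open AOI rectangle;
onsets cumulative with a uniform 20–80 ms inter-fixation gap.

Defaults, chosen once:

- **Layout.** 13 AOIs tiling a 1280×960 stimulus: a 4×3 block of lead
  panels over the upper three quarters plus a full-width bottom rhythm
  strip, labelled A–M in reading order — the structure of a printed
  12-lead ECG.
- **Length.** `meanlog = 2.8913, sdlog = 0.6989`, moment-matched to a mean
  of 23 AOI visits with SD 18.25 — a heavy right tail in which a few very
  long scanpaths coexist with a mode near 9–11.
- **Duration.** `meanlog = 5.52, sdlog = 0.606` (mean ≈ 300 ms,
  SD ≈ 200 ms), ordinary reading-task fixation durations.
- **Dynamics.** The default chain is a *reading-order* scan
  (`reading_order_transitions()`): re-fixate the current AOI with
  probability 0.45 (mean run length ≈ 1.8, matching the run structure of
  observed AOI strings), step to the next AOI in reading order with 0.30,
  and jump anywhere else with the remaining mass (cross-referencing).
- **Group separation.** An "incorrect reader" is constructed by blending
  the transition matrix and initial distribution toward uniform:
  `(1−λ)P + λU`. λ is the single separation dial: λ = 0 gives identical
  groups, λ = 1 a memoryless uniform scan.

The separation experiments use `systematic_gaze_model()` — the λ-blend's
base taken to its idealized limit (`p_self = 0, p_next = 1`, start at A),
i.e. the deterministic taught reading sequence. Under it, two correct
readers' token strings differ exactly by their length difference, so the
within-correct distances carry no structural noise and the blend weight
alone drives group separation. This is deliberately an idealization: real
correct readers re-fixate (use the default model when realism matters more
than a clean separation dial).

Seeding: each participant's seed is a stable function of the master seed,
their group and their index, so enlarging one group never perturbs existing
participants' data, and identical seeds reproduce byte-identical datasets.

What the generator does *not* emulate: saccade trajectories, pupil data,
measurement noise or drift, fixation-detection artefacts, stimulus content
(AOI-specific salience beyond the hotspot centres), or correlation between
a participant's accuracy and scanpath length. Consequently, passing tests
demonstrate the *mechanics* — distances, grids, counts and tests computed
correctly under known dynamics — not that real correct/incorrect readers
differ, which only real data can show.

## Calibration of the stochastic checks

Two quantitative design notes, since they shape what the test suite can
assert.

**Separation power.** With 15 participants per group, λ = 0.6, and the
heavy-tailed length distribution shared by both groups, the detection
probability of the built-in direction (incorrect group more mutually
distant, read off the rank direction of the pooled-pairs Mann–Whitney) is
about 0.96 per simulated study. The limiting factor is not the effect size:
in the replicates that fail, one group's sampled lengths are so dispersed
that its within-group distances — which are bounded below by pairwise
length differences — genuinely exceed the other's *in that sample*, so the
in-sample direction itself inverts and detection is impossible at any
blend weight. The test suite runs 100 replicates at fixed seeds and
documents the observed rate.

**Distributional recovery.** For a multinomial row with cell probabilities
`p_j` estimated from `n` visits, the expected L1 error is approximately
`Σ_j sqrt(2 p_j (1−p_j) / (π n))`. At 10,000 simulated fixations a 13-state
chain yields ~770 visits per row, giving an expected L1 near 0.09 for a
row with a dozen small cells — so a tight L1 band at that depth can only be
met by concentrated rows. The routine recovery test therefore uses a
4-state layout (~2,500 visits/row, expected L1 ≈ 0.028) against a 0.05
band, and the 13-state check is reported at its observed magnitude.

Problem sizes used by the test suite (full edit-distance enumeration over
3-token sequences of length ≤ 5, 50 DBSCAN instances of 200 points, 2,000
null replicates for the test level, 100 separation replicates, 10,000-point
binning checks) were chosen to make the stochastic assertions statistically
meaningful while keeping a full run in the low minutes.

## Known limitations

- Levenshtein distance treats all substitutions equally; spatially adjacent
  AOIs are as "far" as opposite corners. Needleman–Wunsch-style weighted
  costs and vector-based similarity measures are out of scope.
- Distance comparisons between groups are length-confounded by design: the
  distance between two scanpaths is at least their length difference. The
  group test answers "are this group's AOI strings more mutually distant?",
  not "is the transition structure different?" — for the latter, compare
  transition matrices directly.
- DBSCAN is O(n²) in the number of fixations; fine for study-sized pools
  (tens of thousands), not for raw gaze samples.
- The CLI's heatmap geometry is derived from the pooled fixations of the
  file it is given; comparing heatmaps across *files* requires fixing the
  grid externally.
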