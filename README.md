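# scanpathcmp

Comparing how many people look at the same image — and whether people who
read it *correctly* look at it differently from people who read it
*incorrectly* — is a standard problem in eye-tracking studies of expert
image interpretation (radiographs, ECG printouts, maps). `scanpathcmp` is an
R toolkit for exactly this setting: a stimulus tiled by labelled areas of
interest (AOIs), many participants, and a post-hoc split into correct and
incorrect interpretation groups.

## What it computes

A participant's **scanpath** is the ordered sequence of AOI labels visited
by their fixations, written as a token string such as
`{M,M,I,I,M,G,G,E,E,B,A,A,M,M,I,I}`. The toolkit covers:

- **String-edit comparison.** The distance between two scanpaths *a*, *b*
  is the Levenshtein distance *d(a, b)* — the minimum number of unit-cost
  insertions, deletions and substitutions turning one token sequence into
  the other. All participants are compared pairwise into a symmetric
  distance matrix, normalised by its maximum so several matrices share one
  `[0, 1]` visual scale (`pairwise_distances()`, `normalize_distmat()`).
- **Truncation.** Collapsing each run of repeated tokens
  (`{M,M,M,B,B,A,B,C}` → `{M,B,A,B,C}`) removes fixation frequency and
  keeps visit order (`truncate_scanpath()`).
- **Data-driven dwell grids.** Instead of researcher-drawn AOIs, fixations
  are clustered with DBSCAN; the smallest radius that still admits a core
  point sets a grid cell dimension (cell side = core-point diameter), and
  total fixation duration is binned per cell into comparable heatmaps
  (`derive_core_radius()`, `make_grid()`, `bin_dwell()`).
- **Transition analysis.** Directed AOI→AOI visit transitions, including
  within-AOI self-transitions, aggregated per group and exportable as
  chord-diagram edge lists (`transition_matrix()`, `subset_and_edges()`).
- **Group statistics.** Two-sided Mann–Whitney U tests (W = U of the first
  sample, the `stats::wilcox.test` convention) per AOI on fixation
  durations with Bonferroni correction, and on within-group scanpath
  distances (`mann_whitney()`, `per_aoi_duration_tests()`,
  `group_distance_test()`).
- **Synthetic studies.** A seeded Markov-chain gaze simulator over a
  13-AOI ECG-style layout (12 leads + rhythm strip, labels A–M), with
  heavy-tailed scanpath lengths, lognormal durations and per-AOI spatial
  hotspots, so every pipeline stage is testable without any real gaze data
  (`gaze_model()`, `simulate_study()`, `blend_toward_uniform()`).
- **Figures.** Distance-matrix panels per group, web (radar) diagrams of
  scanpath length per stimulus, annotated grid heatmaps, and directed chord
  diagrams; every figure writes a CSV of its exact plotted values and a
  JSON metadata sidecar.

## Worked example

```r
library(scanpathcmp)

layout <- default_ecg_layout()                     # 13 AOIs, A-M
correct_model   <- gaze_model(layout)              # systematic reader
incorrect_model <- blend_toward_uniform(correct_model, lambda = 0.6)
study <- simulate_study(correct_model, incorrect_model,
                        n_correct = 16, n_incorrect = 14, seed = 7)

scanpaths <- lapply(split(study$fixations, study$fixations$participant),
                    function(f) build_scanpath(f, layout))
scanpaths[["C01"]]
#> <scanpath> C01 @ ecg [9 tokens]: {L,M,M,H,H,H,I,I,I}
truncate_scanpath(scanpaths[["C01"]])
#> <scanpath> C01 @ ecg [4 tokens, truncated]: {L,M,H,I}

length_summary(scanpaths, truncated = TRUE)
#>   mean       sd mode range  n
#> 1   15 8.554088   14    35 30

d <- pairwise_distances(unname(scanpaths))
res <- group_distance_test(d, study$groups)
res$summary
#>       group n_obs     mean       sd
#> 1   correct    16 25.30833 6.306205
#> 2 incorrect    14 22.38462 7.305356
res$test
#>     W          p n_x n_y alpha_adjusted significant
#> 1 172 0.01337134  16  14           0.05        TRUE

radius <- derive_core_radius(study$fixations[, c("x", "y")], min_pts = 5)
make_grid(layout$width, layout$height, radius)
#> <gridspec> 1280x960 px, 80 cols x 60 rows (cells 16.0x16.0 px, base 16 px)
```

The length summary reads: across the 30 simulated participants the
truncated scanpaths average 15 AOI visits (SD 8.6), the most common length
is 14 and the lengths span a range of 35. The group comparison reports each
participant's mean Levenshtein distance to same-group peers; here W = 172
with p = 0.013, the correct group's scanpaths being on average 25.3 edits
apart. The grid line says the smallest DBSCAN core-point radius on the
pooled fixations was 8 px, so cells are 16 px (one core-point diameter)
and the 1280×960 stimulus splits into 80 × 60 cells.

The same pipeline is scriptable from a shell:

```sh
exec/scanpathcmp simulate --seed 7 --n-correct 16 --n-incorrect 14 --out-dir data
exec/scanpathcmp distmat --fixations data/fixations.tsv --aois data/aois.csv \
    --groups data/groups.csv --out-dir out
exec/scanpathcmp stats   --fixations data/fixations.tsv --aois data/aois.csv \
    --groups data/groups.csv --out-dir out
```

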