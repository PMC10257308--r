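# bottomuse

Fine-scale benthic bottom-use analysis for diving marine predators.

Obligate benthic foragers such as the Australian sea lion (*Neophoca
cinerea*) spend most of a foraging trip underwater, where GPS cannot see
them. `bottomuse` reconstructs their three-dimensional foraging paths from
archival tag data and identifies the core modes of benthic foraging effort,
for movement ecologists working with combined
accelerometer/magnetometer/TDR/GPS deployments:

1. **Dead-reckoning.** Tri-axial head acceleration (25 Hz, ±4 G) is split
   into static and dynamic components with a 3 s running mean; pitch and
   roll follow from the static gravity vector
   (`pitch = atan2(-g_x, sqrt(g_y² + g_z²))`), and a tilt-compensated
   compass heading from the 2 Hz magnetometer after applying the local
   declination/inclination (Seal Bay defaults: 7.698°, −68.012°). Speed is
   inferred from the depth rate and pitch (`v = |dz/dt| / |sin pitch|`,
   with a cruising fallback at shallow pitch), the pseudo-track is
   integrated at 1 Hz on the depth clock, and the track is georeferenced by
   forcing it through the satellite-count- (≥ 5) and speed-filtered
   (≤ 6 m/s) Fastloc GPS fixes, distributing the accumulated drift linearly
   in time within each inter-fix segment.
2. **Dive segmentation.** The zero-offset-corrected depth record is
   smoothed with a 20 s window, dives are detected above a 5 m threshold,
   and each dive's **bottom phase** is the contiguous span deeper than 80 %
   of its maximum depth.
3. **Bottom-use clustering.** Seven per-dive predictors — bottom time,
   time-at-depth index (bottom time / max depth), bottom distance,
   depth-variability index (sd/mean of bottom depth), bottom speed,
   sinuosity and colony distance — are screened for collinearity
   (Pearson |r| > 0.750), z-scored, and partitioned by Hartigan–Wong
   k-means with the number of clusters chosen by average silhouette width.
   Backwards stepwise regression of the cluster indicator (terms with
   p > 0.05 iteratively removed) confirms the most parsimonious predictor
   set, and the clustering loop re-runs until that set is stable.

A seeded synthetic-trip simulator (`simulate_trip()`) emits raw sensor
streams with known ground truth — two benthic dive archetypes differing in
bottom duration, substrate rugosity and path tortuosity — so every stage of
the pipeline can be validated end to end.

## Worked example

```r
library(bottomuse)

trip     <- simulate_trip(trip_config(duration_h = 8, seed = 42))
analysis <- run_trip_analysis(trip$bundle, bottomuse_config(seed = 42),
                              trip$calibration)

print(analysis$summary)
#> locations: 119 (8.01 h trip, 14.86 h^-1)
#> bottom phases: 53 | bottom time 162 +/- 91 s | max depth 99.1 m
#> clusters: 27/26 (50.94/49.06%)

print(analysis$cluster$solution)
#> k-means solution: k = 2, sizes = 27/26
#>   WCSS 237.641 | BCSS 126.359 | avg silhouette 0.324

round(analysis$cluster$stepwise$p_values, 5)
#> bottom_time   tad_index   sinuosity
#>     0.00000     0.00005     0.03762

truth_score(analysis, trip$truth)
#> dive recall 1.00 | cluster ARI 1.00 | track RMSE 24.4 m (linear interp 81.8 m)
```

Reading the output: the 8 h trip yielded 119 usable GPS fixes and 53 bottom
phases; silhouette selection picked two clusters of 27 and 26 dives
(50.94 % / 49.06 %), the stepwise model kept bottom time, the time-at-depth
index and sinuosity as significant discriminators of the two modes (all
p ≤ 0.05), and against the simulator's ground truth every dive was
detected, the two behavioural archetypes were recovered perfectly
(adjusted Rand index 1.0), and the dead-reckoned track is more than three
times closer to the true path than straight-line interpolation between the
same GPS fixes.

`run_pipeline(input_dir, out_dir, config)` performs the same analysis from
sensor CSV files on disk and writes the georeferenced track (CSV +
GeoJSON), dive table, metrics, cluster assignments, a solution JSON and a
summary JSON, each stamped with the full parameter set. A thin command-line
front end with `simulate` / `run` / `export` subcommands is installed at
`inst/cli/bottomuse.R`.

## Documentation

The methods vignette (`vignettes/bottom-use-methods.Rmd`) describes the
reconstruction model and its assumptions, every tunable parameter with its
default and rationale, what the synthetic trips do and do not emulate, and
the known limitations of the approach.
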