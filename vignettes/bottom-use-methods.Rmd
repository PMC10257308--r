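---
title: "Dead-reckoned tracks and benthic bottom-use clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dead-reckoned tracks and benthic bottom-use clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bottomuse)
```

# The problem

Benthic-foraging pinnipeds surface briefly and dive continuously, so GPS
alone yields a position every several minutes at best and nothing at all
about where an animal moved while at depth. This package reconstructs the
sub-surface path by dead-reckoning — integrating heading, speed and body
orientation from tag sensors between known surface positions — and then
characterises how the animal used the seabed, dive by dive, with a
clustering analysis of bottom-phase metrics.

The pipeline assumes a deployment of the kind used on adult female
Australian sea lions at Seal Bay, Kangaroo Island: a head-mounted tri-axial
accelerometer (25 Hz, ±4 G) and magnetometer (2 Hz, µT), a 1 Hz time-depth
recorder, and Fastloc-style GPS snapshots attempted every two minutes at
the surface.

# Sensor preparation

**Calibration.** Before deployment the tag is rotated through all
orientations; each axis's raw extrema are mapped onto the physical-unit
extrema by an affine map (slope/intercept of the line through the two
endpoints). Per-axis independent affine maps are deliberate: full
soft-/hard-iron ellipsoid fitting is out of scope, and residual
magnetometer distortion is treated as part of the position error the GPS
coercion absorbs (see *Limitations*).

**GPS filtering.** Fixes solved from four or fewer satellites are
discarded (`min_sat = 5`), then a forward-sequential speed filter drops any
fix implying a great-circle speed above 6 m/s from the last retained fix —
the ceiling of plausible sea-lion swimming. The forward-sequential rule
(rather than a global optimisation) is deterministic and idempotent, so a
filtered series passed through the filter again is unchanged.

**Zero-offset correction.** Pressure transducers drift over a trip. The
surface baseline is estimated as the rolling 10th percentile of
near-surface samples (< 3 m) in a 2 h window, evaluated at regular knots,
interpolated over the whole record and subtracted. A low quantile resists
contamination by shallow dive samples; the price is a small lag under
fast monotone drift (a rolling low quantile of a linear ramp reads the
ramp ~40 % of a window early), which is negligible at the multi-hour
drift scales of real transducers. Within-dive depth differences are
preserved for offsets that are constant at the dive scale because the
baseline is interpolated from surface intervals on either side.

**Alignment.** The 1 Hz depth clock is the master timebase, since depth
drives both dive segmentation and the dead-reckoning timestep.
Acceleration is averaged within each one-second bin; the slower
magnetometer is linearly interpolated to the grid. Rows missing any
channel (logger gaps) are flagged and contribute no displacement.

# Dead-reckoning

**Static/dynamic split.** A centred 3 s running mean separates the
gravity (static) component of acceleration from dynamic movement. The
decomposition is exact (static + dynamic ≡ input), including at the edges
where the window shrinks symmetrically.

**Attitude.** With device axes x surge (forward), y sway (right), z heave
(down, so a level tag reads +1 G), pitch and roll follow from the
normalised static vector:
pitch = atan2(−g~x~, √(g~y~² + g~z~²)), roll = atan2(g~y~, g~z~).
Samples whose static norm falls below 0.2 G (violent manoeuvre or glitch)
are flagged and their gravity direction interpolated from neighbours. The
axis and sign conventions are fixed by round-trip tests against an
independent rotation-matrix oracle: forward-rotating gravity or the
geomagnetic field by a known attitude and inverting recovers the attitude
to 10⁻⁹ rad and the heading to 10⁻⁶ rad.

**Heading.** The calibrated field vector is de-rotated by roll and then
pitch — the exact inverse of the z–y–x body rotation:

* m~xh~ = m~x~ cos P + m~y~ sin R sin P + m~z~ cos R sin P
* m~yh~ = m~y~ cos R − m~z~ sin R
* heading = wrap(atan2(−m~yh~, m~xh~) + declination)

The local magnetic model is declination 7.698°, inclination −68.012°
(Seal Bay). When the de-rotated horizontal field falls below 5 % of the
total field the heading is unobservable; such samples are flagged and
interpolated through the unit circle.

**Speed.** The tags carry no speed sensor, so speed is inferred from
geometry: when |pitch| ≥ 5°, v = |dz/dt| / |sin pitch|, clipped at twice
the GPS speed threshold; otherwise a configurable cruising fallback
(default 1.0 m/s) is used. Two properties make this tolerable: a benthic
forager pitches steeply whenever it changes depth, and the georeferencing
step rescales each inter-fix segment through the GPS positions, so a
multiplicative speed error largely cancels. A constant-speed strategy is
available (`speed_method = "constant"`) for sensitivity analyses. At
pitch ≈ 0 the horizontal speed is genuinely unobservable from depth rate —
no estimator can do better than a prior there.

**Integration and georeferencing.** Each one-second step advances the
track by v·dt·cos(pitch) along the heading (sample i's attitude drives the
step to i+1 — the integrator's left-endpoint convention). The resulting
pseudo-track is pinned to geography by anchoring each inter-fix segment at
its opening fix, measuring the mismatch at the closing fix, and adding the
correction linearly in time across the segment: the simplest defensible
drift model, affine in time, exact at every fix. Degrees/metres conversion
is local equirectangular at the segment latitude; distances are haversine.
Samples outside the first/last fix are anchored without correction.

# Dive segmentation and bottom metrics

The corrected depth record is smoothed with a centred 20 s rolling mean;
dives are maximal runs of smoothed depth ≥ 5 m (the threshold is
configurable; 5 m cleanly separates dives from surface swimming for this
species). The **bottom phase** is the contiguous span from the first to
the last sample deeper than 80 % of the dive's maximum depth — brief
excursions above the line inside the span remain "bottom", matching a
benthic forager tracking rugose substrate. Descent and ascent are the
remainder, so the three phases partition the dive. The cited
smoothing-spline phase machinery is deliberately reduced to smoothing plus
the 80 % rule, because the 80 % criterion is the operative definition of
the benthic bottom phase; raising the fraction can only shrink the span
(a tested monotonicity property).

Seven per-dive predictors are computed from the bottom phase and the
georeferenced track:

| predictor | definition | units |
|---|---|---|
| `bottom_time` | span of the bottom phase | s |
| `tad_index` | bottom time / maximum dive depth | s/m |
| `bottom_distance` | summed track distance within the bottom phase | m |
| `depth_var_index` | sd / mean of bottom depths (sample sd) | — |
| `bottom_speed` | bottom distance / bottom time | m/s |
| `sinuosity` | bottom distance / great-circle chord of the phase | ≥ 1 |
| `colony_distance` | mean great-circle distance to the colony | km |

Sample (n−1) standard deviation is used in the depth-variability index —
the field's conventional estimator. Sinuosity is capped (default 50) when
the bottom path closes on itself and the chord degenerates. Colony
distance averages over bottom samples rather than using the dive midpoint.

# Clustering and predictor selection

Predictors are screened for collinearity: while any pair exceeds Pearson
|r| = 0.750 *strictly*, the member of the worst pair with the larger mean
absolute correlation to all other predictors is dropped — a deterministic,
documented tie-break. Survivors are z-scored and clustered with
Hartigan–Wong k-means (best of 25 seeded restarts), with k ∈ 2..8 chosen
by average silhouette width (Euclidean distance; ties broken toward
smaller k for parsimony). For two clusters, the cluster indicator is
regressed on the z-scored predictors by least squares and the least
significant term with p > 0.05 is removed iteratively; the decision loop
{z-score → silhouette k-selection → k-means → stepwise} repeats on the
retained columns until the set is stable. The column set strictly
shrinks, so the loop terminates within one pass per predictor.

OLS on a 0/1 indicator was chosen because the analysis reports per-term
p-values and an adjusted R²; a logistic alternative would not report the
latter. Stepwise refinement is undefined for k ≠ 2: if silhouette
selection drifts away from two clusters after pruning, the loop returns
the most recent coherent two-cluster iteration with a message.

Two caveats discovered while validating on synthetic data are worth
stating plainly. First, average silhouette width on z-scored, skewed
metrics with several uninformative dimensions is a fragile selector: with
moderate cluster separation, higher-k partitions that carve heavy tails
can outscore the true two-mode split, and which wins can change between
stochastic realisations of the same process. Second, predictors that are
products of an informative quantity with independent noise (bottom
distance ≈ speed × time; time-at-depth ≈ time / depth) carry no cluster
signal *conditional on* bottom time, so backwards stepwise selection may
legitimately drop them even when their marginal contrasts are large.
Neither behaviour is a defect of the implementation; both are properties
of the method that practitioners should anticipate on real data.

# The synthetic trip generator

`simulate_trip()` emits raw sensor streams (25 Hz accel in counts, 2 Hz
mag, 1 Hz depth, surface GPS at 120 s cadence with satellite counts) from
a known 1 Hz truth path, built with the same kinematics the dead-reckoner
assumes: horizontal step v·cos(pitch) along the heading, vertical rate
−v·sin(pitch), gravity and the geomagnetic field rotated into the device
frame by the true attitude. Sensor noise, a constant transducer offset
and GPS position noise are configurable; every stream derives from one
seed, so a trip is byte-reproducible.

A trip is outbound transit, a foraging patch of repeated benthic dives,
and a homebound transit. Dives draw from two archetypes mixed
Bernoulli(0.5): a lower-effort mode (bottom duration 70–115 s range,
flat substrate ~0.5 % of depth, near-straight bottom paths) and a
higher-effort mode (175–330 s, ridge-like relief ~8.5 % of depth with a
period the swim speed can track, tortuous OU heading). The duration
ranges of the modes are disjoint — these are distinct behaviours, not
overlapping tails. Per-dive bottom depth (U(25, 100) m) and horizontal
bottom speed (N(1.0, 0.7) m/s, clipped) are drawn independently of the
archetype, making bottom speed and colony distance pure-noise predictors
and decorrelating the derived indices from bottom time; a 20 s swimming
undulation keeps pitch informative for speed inference while being nulled
by the 20 s metric smoother. Relief is capped near 10 % of bottom depth
because beyond ~11 % the plateau itself would leave the > 80 %-of-max
band — a structural compression of the depth-variability index that the
generator respects rather than fights; the realised depth-variability
contrast between archetypes is therefore modest.

Default trip duration is 8 h (~55 dives) — long enough for the
two-archetype structure to be recoverable, short enough that the full
pipeline runs in seconds in tests and the acceptance script. Real trips
of 47–85 h are simulated by raising `duration_h`.

What the simulator does *not* emulate: ocean currents (dead-reckoning
drift is purely sensor-driven here), soft-/hard-iron magnetometer
distortion, Fastloc solver error structure (position noise is isotropic
Gaussian), tidal depth modulation, prey fields, and postural roll (the
truth roll is zero; roll handling is exercised by the rotation-oracle
tests instead). Passing end-to-end tests therefore demonstrates the
internal consistency and recovery power of the pipeline under its own
assumptions, not field accuracy.

# Numerical choices

* Timebase: UTC epoch seconds; all alignment is to the 1 Hz depth clock.
* Running means use exact cumulative sums with shrinking symmetric edge
  windows, so decompositions are exact to machine precision.
* Heading interpolation (for flagged samples) is through cos/sin to avoid
  wrap artefacts; heading is stored in [0, 2π).
* The Earth is a sphere of radius 6 378 137 m for haversine distances and
  local equirectangular scaling; at dive scales (≪ 10 km) the error is
  far below GPS noise.
* k-means uses `nstart = 25` restarts under a locally-scoped seed;
  identical seeds give identical solutions, and the caller's RNG state is
  restored.
* Degenerate inputs: all-submerged records skip zero-offset correction
  with a warning; constant metric columns are dropped with a warning
  before correlation; dives shorter than 3 samples are discarded;
  sub-metre bottom chords trigger the sinuosity cap.

# Limitations

* Speed is inferred, not measured; absolute track scale between fixes
  leans on the GPS coercion. Long fix gaps (> 10 min) inflate mid-segment
  position error.
* No current correction: in strong currents the "track" is through water,
  not over ground, between fixes.
* The affine sensor calibration cannot remove soft-iron heading bias; a
  constant bias rotates pseudo-track segments, which the fix coercion
  largely absorbs but does not eliminate.
* Average-silhouette k-selection is fragile under uninformative predictor
  dimensions (see above); inspecting the full silhouette curve
  (`sil_curve` in the loop result) is strongly advised before trusting a
  selected k.
* The stepwise confirmation is defined for two clusters only, matching
  the analysis it reproduces.
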