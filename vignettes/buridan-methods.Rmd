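---
title: "Locomotor phenotyping in Buridan's paradigm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locomotor phenotyping in Buridan's paradigm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the data

In Buridan's paradigm a fly with clipped wings walks on a round platform
(117 mm diameter) surrounded by water, between two opposing black stripes
it can see but never reach (11° wide as seen from the platform center,
293 mm away). Wild-type flies typically shuttle back and forth between the
two landmarks; how strongly they do so, and how they move in general, is a
sensitive behavioral fingerprint. The raw material for analysis is the
tracked centroid position of one fly over a nominally 5-minute recording:
a time series $(t_i, x_i, y_i)$ in millimetres, origin at the platform
center, at whatever frame rate the tracker ran (the reader accepts
irregular sampling; the simulator defaults to 20 Hz).

`buridan` ingests one CSV data file plus one flat-YAML metadata file per
fly, computes twelve per-fly locomotor parameters, renders transition
plots (occupancy heat maps of moving time), and runs the group-level
statistics: activity-outlier filtering, PCA over the twelve metrics,
normality-gated two-way ANOVA on a principal component, Tukey HSD
contrasts and a compact-letter strain grouping.

## From track to steps

The trajectory is differentiated into per-step quantities: step $i$ covers
$[t_i, t_{i+1}]$ with displacement $d_i$, speed $v_i = d_i/\Delta t_i$,
and heading $\theta_i = \operatorname{atan2}(\Delta y_i, \Delta x_i)$.
A step is *moving* when $v_i \ge$ `immobility_speed_mm_s`. The cutoff that
separates walking from sitting is nowhere fixed by the assay itself; the
default of 1 mm/s is of the order of body-length-scale tracker jitter per
second and is deliberately kept in one place (the step series), so every
downstream metric inherits a single consistent walking/sitting decision.
No smoothing is applied before differentiation by default; a centered
boxcar (`smooth_window`, odd number of samples) is available for noisy
trackers but changes turning-angle statistics and is therefore opt-in.

Turning angles are defined between *consecutive moving* steps only and
wrapped to [0°, 180°]; zero-length steps have undefined heading. Because
angle statistics depend on the differencing granularity, the package
works at the native frame-to-frame step level throughout and documents
rather than hides that choice.

A *pause* is a maximal run of immobile steps lasting strictly more than
`min_pause_s` (default 1 s — a stop of exactly 1 s is not a pause).
Shorter stops are absorbed into the surrounding activity bout, so bouts
and pauses tile the record exactly; bout/pause boundaries are placed at
the sample times delimiting the immobile run. A record with no moving
step at all counts as one pause spanning it.

## The twelve parameters

| column | definition | units |
|---|---|---|
| `median_speed` | median speed over moving steps | mm/s |
| `distance_per_min` | raw path length / duration × 60 | mm/min |
| `turning_angle` | median absolute heading change, moving pairs | deg |
| `meander` | median of per-step turn/speed ratio | deg·s/mm |
| `thigmo_moving` | moving time beyond $R/\sqrt2$, fraction | — |
| `thigmo_sitting` | pause time beyond $R/\sqrt2$, fraction | — |
| `stripe_deviation` | median angle between heading and direction to the nearer stripe | deg |
| `n_walks` | end-zone alternations between the stripes | count |
| `n_pauses` | pauses (> 1 s immobile) | count |
| `bout_duration` | median activity-bout length | s |
| `pause_length` | median pause length | s |
| `time_active` | summed bout length | s |

Three definitions deserve comment.

*Thigmotaxis.* The platform is split at radius $R/\sqrt2$ = 41.37 mm,
which makes the outer ring and the inner disc exactly equal in area, so a
position-indifferent fly scores 0.5. Time is weighted by step duration
and the radial position of the step midpoint decides the region.

*Stripe deviation.* For each moving step the bearing from the fly's
current position to each stripe center is computed and the smaller of the
two wrapped differences to the heading is taken. With opposed stripes the
per-step value lies in [0°, 90°] and an uncorrelated random walk scores a
median of 45°: at every reachable position both angular arcs between the
two stripe directions exceed 90°, which pins the median of a uniform
heading's nearest-stripe deviation at exactly 45°. The acceptance script
recomputes this baseline by simulation; the package treats ~45° as "no
fixation" and the strongest fixators in a typical study reach ~10°. A
single-stripe convention would instead give 90° for a random walk, which
is why the nearest-stripe reading is the default and only convention.

*Meander.* The ratio-then-median reading is used (median over steps of
per-step turn divided by per-step speed). The alternative
median-turn/median-speed is available via `meander(steps, per_step =
FALSE)`; the two differ in how they weight slow, twisty episodes, and the
per-step version is the default because it is a genuine per-step
tortuosity distribution rather than a ratio of two marginals.

*Walks.* A "walk between the stripes" needs a start/end rule; the package
defines an end zone in front of each stripe (beyond half the platform
radius, within 45° of the stripe bearing, both configurable) and counts
alternating entries. The oscillating rim-to-rim construction in the test
suite pins the semantics: seven traversals count seven walks.

## Transition plots

Occupancy maps histogram the step midpoints of *moving* steps only,
weighted by step duration, on a 2 mm grid (about 59 × 59 over the
platform), then apply a separable Gaussian smooth (σ = 1 bin by default;
the grid is padded by four smoothing scales so the kernel never runs off
the edge and total mass is conserved). Immobile time is excluded — the
plots show where the fly walked, not where it sat. Per-fly maps are
pooled within strain × replicate by summing counts (averaging normalized
maps is a reasonable alternative; summing weights flies by how much they
moved and is the default). For display, values are divided by the map
maximum and every cell at or above 95 % of the maximum saturates to the
top color level.

## Group statistics

Flies travelling less than 50 mm/min on average are excluded before any
statistics ("smaller than" is strict: a fly at exactly 50.0 is kept).
The twelve metrics are then centered and scaled to unit variance before
PCA. Scaling is a substantive choice: the metrics mix mm/s, counts,
proportions and degrees, so covariance-matrix PCA would be dominated by
whichever metric happens to have the largest numeric range;
correlation-matrix PCA is the only defensible default, with
`scale. = FALSE` available for sensitivity analysis. Flies with undefined
metrics (e.g. a fly that never pauses has no `pause_length`) are dropped
from the PCA with a warning, as are zero-variance columns. Component
signs are made reproducible by forcing the largest-magnitude loading of
each component positive.

Shapiro–Wilk normality is recorded for PC1–PC3. The ANOVA is reported
for whichever component the user selects (default PC2), with a prominent
warning when that component fails the gate — the classical analysis
tested only a component that passed. The model is a two-way
fixed-effects ANOVA, `score ~ strain * replicate`, with Type II sums of
squares (robust to the mild imbalance that the outlier filter
introduces; with a single replicate level the model collapses to a
one-way ANOVA). Tukey HSD contrasts over strains follow, and strains are
merged into groups by a compact-letter display: each letter is a maximal
set of strains with no significant pairwise difference inside it.
Transitive significance patterns yield disjoint groups; non-transitive
ones yield overlapping letters and are flagged (`disjoint = FALSE`)
rather than forced into a partition. Replicates are pooled for PCA
fitting and appear only as a factor in the ANOVA.

## The synthetic-data generator

Every stage is testable without the original deposited data because the
package ships a generative model of the assay:

- **Movement**: while moving, the new heading is a von Mises mixture —
  with weight `1 − fixation_strength` it continues the previous heading
  (concentration `persistence_kappa`, default 8), with weight
  `fixation_strength` it points at the stripe the fly is currently
  facing (concentration `fixation_kappa`). Step speeds are gamma
  distributed (`mean_speed_mm_s` = 15, `speed_cv` = 0.3 by default —
  a briskly walking fly).
- **Pausing**: a two-state Markov process with per-second stop and
  resume probabilities (`p_stop` = 0.1, `p_go` = 0.5), converted to
  per-step probabilities at the sampling interval.
- **Arena**: positions are reflected radially at the rim (the real fly
  turns at the water moat); all points stay on the platform.
- **Design**: `simulate_study()` crosses strains with two replicates,
  each fly seeded from the master seed, and the second replicate adds a
  small shift on activity parameters (default +1 mm/s mean speed) —
  mirroring a replicate main effect that is real but numerically small.
  `default_study_spec()` encodes a five-strain design with three planted
  behavioral groups (two strong fixators, two weak fixators, one
  hyperactive intermediate), 12 flies per cell, 5-minute records.

The uncorrelated random walk (`simulate_random_walk()`) is the fixation
null model: i.i.d. uniform headings, constant speed, no pauses. Its
stripe-deviation score is the baseline discussed above.

What the generator does *not* emulate: tracker dropouts and
reinitializations, pixel quantization, body-orientation information
(centroid only), wall-following micro-behavior at the moat, and any
correlation structure between metrics beyond what the movement model
induces. Passing tests therefore demonstrate that the pipeline measures
what the model plants, not that any particular real strain behaves this
way.

For calibrating the statistical stage at scale,
`simulate_metrics_table()` skips trajectories entirely and draws
standardized metric vectors directly (unit normals with planted group
shifts on a subset of metrics and a small replicate offset). The type-I
error and group-recovery calibrations in the test suite run on this
generator — 5 strains × 2 replicates × 12 flies, shifts of 1.5
within-group SD on 3 of 12 metrics, 100 recovery and 400 null
replicates — because trajectory-level simulation at that replication
count would add nothing but runtime to a question about the statistics.
Trajectory-level recovery of the planted three-group design is tested
once, end to end, at reduced size (4 flies per cell, 60 s records), and
the remaining trajectory-level tests use 10–120 s records; the
random-walk baseline and the acceptance script use the full 5-minute,
200-fly setting.

## Numerical choices and degenerate inputs

- Angles are degrees in every user-facing value; internal arithmetic is
  radians.
- Duplicate timestamps are a hard error (no step can be formed); a
  decreasing time column is rejected with the first offending row.
- Points beyond the rim by more than a 1 mm noise tolerance are clipped
  to the rim with a warning; recordings shorter than 95 % of the nominal
  300 s pass with a warning and all metrics use the actual duration.
- A completely immobile fly yields a valid metrics row: zero distance,
  zero active time, `NaN` for the angle and speed metrics (with
  warnings), a defined sitting-thigmotaxis value — and is then excluded
  by the 50 mm/min filter, which is exactly what the filter is for.
- The von Mises sampler is the Best–Fisher rejection method; κ = 0
  degenerates to the uniform circular distribution and κ = ∞ to the mean
  direction, so the fixation mixture interpolates cleanly between an
  uncorrelated walk and deterministic aiming.
- Ties in the compact-letter grouping are resolved by set inclusion
  (insert-and-absorb), never by p-value ordering.

## Known limitations

- The exclusion count and F statistics of the original study can only be
  reproduced from its deposited raw data; the package tracks them as
  external benchmarks (the report exposes exactly those quantities) and
  validates the machinery on planted simulations instead.
- The walk-counting zones and the immobility cutoff are conventions;
  both are exposed in the configuration and their defaults are pinned by
  construction tests rather than by any external ground truth.
- Statistics assume one row per fly; repeated measures of the same
  animal are out of scope.
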