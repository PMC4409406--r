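# macromove

Movement-path analysis for video-tracked benthic macroinvertebrates.

Laboratory studies of small aquatic animals — the crawling isopod *Asellus
aquaticus*, the swimming amphipod *Gammarus pulex* — record an individual
carrying a small fluorescent marker in a 1 m² arena with an overhead camera,
one frame per second for an hour. From those recordings, movement ecologists
want a small set of per-individual statistics that can be compared across
experimental treatments (marking, light regime, population density): how
much of the time the animal rests, how far it moves per second, how sharply
it turns, and how tortuous its path is independent of the measurement
scale. `macromove` implements that entire analysis chain in R, plus a
synthetic-data generator that reproduces the statistical structure of such
recordings so every stage can be tested without the original videos.

## What it computes

**Tracking.** Each frame is thresholded at the background mean plus 5 SD
(background estimated per frame, excluding the brightest 1% of pixels); the
largest connected component of at least 4 px is the marker and its
intensity-weighted centre of gravity, converted to arena coordinates, is
the position. A stationary-marker calibration (`estimate_noise_floor()`)
measures the positional jitter of the rig and justifies the resting
threshold.

**Path filtering.** Positions within 10 cm of a wall are discarded (fence
behaviour), detection gaps and margin excursions split tracks, and every
surviving run of consecutive 1-s positions with at least 5 locations is an
analysis path.

**Per-path metrics.** Step length `D_i` (distance per 1-s interval, cm),
with steps under 1 mm classed as resting moments; resting fraction; stops
per metre; signed turning angles in (−180°, 180°] between successive
relocation steps; and a maximum-likelihood classification of the
step-length distribution as exponential or power-law ("Lévy-like"),
decided by an AIC margin of 2.

**Fractal dimension.** Path tortuosity is summarised scale-independently by
the divider method: measuring the path with rulers of length δ gives

```
L(δ) = k δ^(1−D)
```

so the fractal dimension `D` is one minus the slope of log L against
log δ. `D = 1` for a straight line, `D = 2` for plane-filling Brownian
motion. `fractal_mean()` walks 200 log-spaced divider sizes along the
polyline in both directions, averages the two measured lengths, and fits
the log–log regression; per-individual values average the per-path
estimates.

**Circular statistics and comparisons.** Turning angles are treated on the
circle (circular mean, resultant length R̄, von Mises κ, circular
boxplot), treatments are compared with the rank-based Watson–Wheeler test,
and the scalar metrics follow the scheme: Welch's t-test / one-way ANOVA
for resting time and for log(D−1)-transformed fractal dimension, Wilcoxon
rank-sum / Kruskal–Wallis for step lengths.

## Worked example

Simulate an hour of a correlated random walk (move/rest bouts, exponential
steps with mean 0.5 cm, von Mises turning with κ = 2), then run the chain:

```r
library(macromove)

params <- crw_params(n_steps = 3600, p_move_to_rest = 0.1, p_rest_to_move = 0.2,
                     step_model = step_exponential(2), turn_kappa = 2)
traj <- generate_crw(params, seed = 1)

segments <- traj |> build_paths() |> filter_min_locations(5)
summarize_paths(segments, total_recording_points = 3601)
#>   n_paths mean_duration_s sd_duration_s available_points_pct
#> 1       2           1562.         2200.                 86.8

sm <- segment_metrics(segments, divider = divider_config(0.25, 25, 100))
dplyr::select(sm, segment_id, n_points, mean_step_cm, resting_fraction, D)
#>   segment_id n_points mean_step_cm resting_fraction     D
#> 1 s001           3119        0.608            0.449  1.42
#> 2 s002              8        0.620            0.286  1.08

circular_summary(pooled_turning_angles(segments)$theta_deg)
#>       n mean_deg R_bar sd_deg kappa mean_arith_deg sd_arith_deg
#> 1  1266   -0.409 0.662   52.1  1.79         -0.814         53.6

fractal_mean(segments[segments$segment_id == "s001", ],
             divider_config(0.25, 25, 200))
#> Divider-method fractal dimension
#>   D = 1.4214 (k = 796, r^2 = 0.8912, 200 divider sizes used)
```

86.8% of the recording survives the 10-cm margin rule; the walker rests 45%
of its intervals (generated occupancy 1/3, plus short moving steps below
the 1-mm threshold); relocation steps average 0.61 cm; the pooled turning
angles concentrate around 0° (κ ≈ 1.8); and the path's tortuosity sits,
as a correlated walk should, between the straight-line limit 1 and the
Brownian limit 2. `fit_step_distribution()` on this path's relocation steps
gives the verdict `exponential`, matching the generating model, and
`autoplot()` on a `fractal_estimate` or a `step_dist_fit` draws the
corresponding diagnostic figure. For multi-treatment data,
`generate_density_experiment()`, `build_summary_table()` and
`compare_treatments()` (or `run_pipeline()` for the whole chain with CSV
outputs and a manifest) complete the workflow.

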