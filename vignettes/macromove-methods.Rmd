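---
title: "Methods: movement-path analysis for 1-Hz arena tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-path analysis for 1-Hz arena tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macromove)
```

`macromove` analyses 1-Hz position series of a single marked benthic
macroinvertebrate in a rectangular arena. This vignette documents the
models and procedures, the parameters that matter, the numerical choices,
and what the synthetic-data module does and does not emulate.

## The data model

The unit of observation is a detection: at each whole second, either a
position `(x, y)` in cm from the bottom-left arena corner (y pointing up),
or a missing record when the marker was not visible. All downstream
analysis operates on *path segments*: maximal runs of consecutive 1-s
detections that stay strictly outside a wall margin. Three filtering rules
produce them:

* **Margin rule.** Points whose distance to the nearest wall is less than
  or equal to `margin_cm` (default 10 cm in the default 100 × 100 cm arena)
  are discarded, because wall-following ("fence") behaviour would bias
  free-movement statistics. The boundary itself is excluded — "within the
  margin" is read inclusively.
* **Gap rule.** A missing detection or a margin excursion splits the
  track. Nothing is interpolated: bridging a gap would fabricate steps
  across unobserved intervals, and with no published interpolation rule to
  follow, preserving missingness is the conservative choice.
* **Minimum-length rule.** Segments with fewer than 5 locations are
  dropped — too short for a stable divider regression — and the same
  filter is applied before *all* metrics, so every statistic describes the
  same set of paths.

Durations are computed from point counts (`n − 1` seconds), not
timestamps, since spacing is fixed at 1 s.

## Movement metrics

* **Step length** `D_i`: Euclidean displacement per 1-s interval.
* **Resting**: a step below `rest_threshold_cm` (default 0.1 cm) is a
  resting moment. The default is the calibrated noise margin: a stationary
  marker jitters by up to about half a millimetre per axis between frames,
  and a resting animal additionally breathes and shifts in place, so 1 mm
  separates genuine relocation from apparent motion.
  `estimate_noise_floor()` reproduces that calibration from a
  stationary-marker recording: it reports the maximum absolute per-axis
  frame-to-frame displacement and recommends twice that value, floored at
  0.1 cm. A tie — a step of exactly the threshold — counts as relocation,
  so the two classes are exhaustive.
* **Turning angle** θ: the signed angle (counterclockwise positive,
  in (−180°, 180°], 180° included for exact reversals) between successive
  displacement vectors. Angles are only computed between relocation steps
  adjacent in time; a resting interval breaks the chain, because heading
  during rest is unobservable at 1 Hz and sub-threshold displacements are
  noise. The generator makes the mirrored assumption (heading persists
  through rest bouts), keeping simulator and analyser consistent.
* **Stops per metre**: move→rest transitions divided by the path distance.
* **Step-distribution classification**: maximum-likelihood fits of a
  shifted exponential and a Pareto density `∝ x^(−μ)` to the relocation
  steps above a common cutoff `x_min` (default: the rest threshold, below
  which steps are noise), compared by AIC. A margin of 2 AIC units — the
  conventional boundary between "barely worth mentioning" and positive
  evidence — is required for a verdict, and fewer than 50 eligible steps
  always returns `inconclusive`. The power-law verdict is the
  heavy-tailed, Lévy-like pattern; no claim about an optimal-foraging
  mechanism is implied.

## The divider-method fractal dimension

Step lengths and turning angles depend on the sampling scale. Path
tortuosity is therefore also summarised by the fractal dimension `D` from
the divider (ruler) method: measure the path with ruler length δ, obtaining
`L(δ) = k δ^(1−D)`, and estimate `D = 1 − slope` by ordinary least squares
of `log L` on `log δ` across `n_dividers` (default 200) log-spaced ruler
sizes. The defaults span 0.25 cm (half an *Asellus* body length) to the
100-cm observation scale; for short synthetic paths where 100 cm is not
meaningful, `divider_config_for_path()` caps the largest ruler at half the
path's bounding-box diagonal.

Numerical choices in the walk:

* Each divider step lands on the *exact* interpolated point of the
  polyline at chord distance δ from the current anchor (solving a
  quadratic per polyline edge), not on the nearest vertex — vertex
  snapping biases `L` upward at ruler sizes comparable to the 1-s step
  scale.
* The terminal remainder (straight distance from the last anchor to the
  path end) is added to `L`, which keeps `L(δ)` exactly equal to the true
  length on straight paths for every δ, anchoring the `D = 1` limit.
* Ruler sizes too large to fit a single step are dropped from the
  regression rather than extrapolated; at least 10 usable sizes are
  required.
* The path is walked forward and backward and the two lengths averaged.
  The published "fractal mean" estimator averages over traversals in an
  unspecified way; the two-direction average is this package's explicit
  stand-in, not a clone.
* When an individual contributes several eligible paths, the per-path
  estimates are averaged with equal weight.

On rough paths, `L(δ)` is decreasing only as a trend: adjacent ruler sizes
reshuffle where the divider lands, so small local increases (occasionally
larger than δ itself) are expected and harmless to the regression. An
estimate below `D = 0.95` triggers a warning, since the estimator should
not fall materially below the straight-line limit.

The estimator is validated against its three analytic anchors: a straight
line (`D = 1`, exact), a level-5 triadic Koch polyline
(`D = log 4 / log 3 ≈ 1.262` within its self-similar scale range, rulers
between the smallest feature `extent/3^5` and `extent/3`), and dense
planar Brownian motion (`D → 2`, rulers well above the per-step scale and
below the path extent). The test suite and `scripts/acceptance.R` recompute
all three.

## Circular statistics

Turning angles live on the circle (−180° ≡ 180°). `circular_summary()`
reports the circular mean direction, mean resultant length R̄, circular SD
`sqrt(−2 ln R̄)`, and the von Mises concentration κ via the standard
piecewise rational inversion of the Bessel ratio. Because summary tables
in this literature sometimes print linear statistics, the arithmetic mean
and SD are exported alongside, labelled, with no claim about which a given
published table used. An exactly antipodal sample has R̄ = 0 and an
undefined mean direction; this is signalled (warning, `NA`) rather than
silently resolved.

`watson_wheeler()` compares two or more treatment groups of pooled
relocation angles nonparametrically — appropriate since the groups'
concentrations differ. Pooled angles are ranked on the circle, scored as
`β = 2π · rank / N`, and `W = 2 Σ (C_i² + S_i²) / n_i` is referred to
χ²(2(k−1)). Rank scores require distinct values, so exact ties are broken
by adding deterministic uniform jitter below 10⁻⁶ degrees — far beneath
measurement resolution — from a fixed internal seed that does not disturb
the caller's RNG stream. Groups below 10 angles trigger a warning about
the χ² approximation. Pooling angles across individuals within a
treatment mirrors the field's practice; it is pseudo-replicated by
construction, which is documented rather than corrected.

The circular boxplot summary uses the sample circular median (the
observed angle minimising mean arc distance; ties broken deterministically
by taking the first candidate in sorted order, which sacrifices exact
rotation equivariance only in tied cases), hinges as quartiles of signed
arc deviations from the median, and fences at 1.5 circular IQRs beyond
the hinges.

## Treatment comparisons

`compare_treatments()` implements a fixed dispatch table — every
(metric, group count) pair maps to exactly one test:

| metric | 2 groups | > 2 groups | transform |
|---|---|---|---|
| resting time | Welch's t | one-way ANOVA | none |
| fractal dimension | Welch's t | one-way ANOVA | log(D − 1) |
| step length | Wilcoxon rank-sum | Kruskal–Wallis | none |
| turning angle | Watson–Wheeler | Watson–Wheeler | none |

The unit of replication is the individual (metrics are aggregated per
individual first); only turning angles are pooled. The log(D − 1)
transform maps the estimator's domain onto the real line; estimates at or
below 1 (possible through estimator noise) are clipped to 1 + 10⁻⁶ with a
warning rather than dropped. The ANOVA is the classical one-way form, and
no multiple-testing correction is applied across metrics — each metric is
reported on its own, as is conventional in this literature; treat the
family-wise error accordingly.

Within an individual, resting fractions and step means are pooled over
intervals (weighted by interval counts), whereas the fractal dimension is
the unweighted mean over paths — a short path says as much about
tortuosity-per-scale as a long one, but contributes fewer intervals.

## The synthetic-data module

`generate_crw()` produces the structure the analysis assumes: a two-state
(move/rest) Markov chain at 1-s resolution with transition probabilities
`p_move_to_rest` and `p_rest_to_move` (stationary rest occupancy
`p_mr/(p_mr+p_rm)`), moving steps from an exponential or Pareto model,
von Mises turning angles centred on straight-ahead with concentration κ,
heading frozen through rest bouts, specular reflection at the walls
(implemented as coordinate folding, which is exactly equivalent for
axis-aligned boxes), and independent Gaussian observation jitter
(default SD 0.02 cm, keeping typical apparent motion of a resting walker
below the 0.05 cm detection granularity) on the recorded coordinates.
`render_frames()` turns a trajectory into 8-bit grayscale frames — a 2-D
Gaussian blob on Gaussian background noise, with per-frame occlusion
emulating fluorescence dropout — so the ImageJ-style detection stage can
be tested end to end. `generate_density_experiment()` builds labelled
multi-treatment cohorts with per-individual sub-seeds derived from one
master seed.

What the generator deliberately does **not** emulate: multi-animal
occlusion and identity swaps (the protocol tracks one marked individual),
3-D movement (dispersal is planar for these species), step-time
autocorrelation beyond first-order bout structure, directional wall
attraction (fence behaviour is excluded by the margin rule anyway), lamp
drift, or water-surface refraction. Passing tests therefore demonstrate
that the pipeline recovers the statistics of data that satisfy its
assumptions — not that those assumptions hold for any particular real
recording.

One interaction deserves emphasis: the step-based resting fraction counts
*all* sub-threshold intervals, so if the moving-step distribution places
mass below 1 mm (an exponential with mean 0.5 cm puts about 18% of its
steps there), the resting fraction sits above the bout occupancy by
construction. Parameter-recovery tests therefore use step models bounded
away from the threshold; with real animals the same caveat applies to
interpreting resting time when typical steps approach the noise floor.

## Problem sizes and calibration conditions

The test suite exercises: the straight-line and Koch anchors at 200
divider sizes; the Brownian anchor on ten 10⁵-step walks; Watson–Wheeler
size on 2000 two-group uniform replicates (n = 100 per group, nominal 5%
level, acceptance band 3.5–6.5%); occupancy, step-mean and κ recovery at
n ≈ 10⁴ (3 SE bands, with the occupancy SE inflated by the bout chain's
autocorrelation factor (1+ρ)/(1−ρ)); step-model classification on 100
replicates of 10⁴ draws (≥95% correct required); filter rules against a
loop-based brute-force oracle on 100 random detection series; a
rendered-frame round trip at 4 px/cm (RMS error budget 0.05 cm); a
0.3-vs-0.6 rest-occupancy contrast with 20 individuals per group over 50
replicates (≥90% detection required); and null-scenario calibration of
the Welch and Wilcoxon branches over 500 replicates (3–7% rejection
band). These sizes were chosen so each check is statistically meaningful
while the whole suite stays comfortably fast on one CPU.

## Known limitations

* Detection assumes a single bright blob; two markers in frame resolve to
  the larger one with no identity logic.
* The Watson–Wheeler χ² reference and the κ inversion are asymptotic
  approximations; both are flagged or documented where small samples make
  them unreliable.
* The divider estimator's traversal-averaging scheme is a stand-in for
  unpublished software internals; absolute `D` values from different
  divider implementations can differ by a few hundredths, which is why
  comparisons across treatments should use one implementation throughout.
* `fit_step_distribution()` compares exactly two candidate families;
  "inconclusive" does not mean "neither", merely that the data above
  `x_min` do not separate them by the AIC margin.
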