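---
title: "Movement inference from Fastloc-GPS telemetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement inference from Fastloc-GPS telemetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastloctrack)
```

`fastloctrack` implements the inference chain used to describe the daily,
seasonal, and migratory movements of benthic-stage sea turtles tracked with
snapshot-GPS ("Fastloc") transmitters on an isolated shallow platform. This
vignette explains each model in the chain, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices that matter when reproducing the
pipeline.

## Quality control of fixes

Fastloc position solutions carry two quality covariates: the number of GPS
satellites used and a unitless residual-error score. A fix is screened out
when it used **fewer than 6 satellites** or its **residual exceeded 30**
(`flag_implausible()`, thresholds in `qc_config()`). We read the two-clause
rule disjunctively (either failing clause removes the fix): retaining
5-satellite solutions would contradict the sub-100 m accuracy such screening
is meant to guarantee, since published trials attribute that accuracy only to
solutions with 6 or more satellites. The conjunctive reading remains
available via `qc_config(rule = "and")`. Both boundaries are inclusive for
retention: exactly 6 satellites or a residual of exactly 30 passes.

Screened fixes then pass a data-driven speed filter (`speed_filter()`): on
each sweep, an interior fix is removed when the great-circle speeds required
to reach it *and* to leave it both exceed `vmax`, and sweeps repeat until
stable. The default `vmax` of 10 km/h is roughly four times typical
migratory travel rates for immature green turtles (about 2.3 km/h), so it is
generous for residency movements while still catching gross position errors.
The conjunctive inbound/outbound test never removes a genuine fast traveller,
because a real displacement is consistent between neighbours while an errant
fix requires an implausible out-and-back. Endpoints have only one adjacent
speed, so they are removed only under a stricter single-sided test at
`3 * vmax`; this asymmetric endpoint rule is our choice, made so that a
corrupt first or last fix cannot anchor the filter.

The first 24 h after release are excluded from residence-area analyses
(`exclude_initial_window()`): behaviour immediately after capture, handling,
and tag attachment is not representative. Tracks are split into bursts
wherever consecutive fixes are more than 3 days apart (`split_on_gaps()`);
phases spanning such gaps are never reported as distinct.

## Regularization and phase segmentation

Fixes are re-discretized to a regular 12-h series (`rediscretize()`) by
linear interpolation along the chord between bracketing fixes, with no
epochs emitted inside gaps longer than 3 days. Twelve hours matches the
duty-cycled sampling while averaging over the diel cycle, so segmentation
responds to shifts in *where the animal lives*, not to daily commuting.
Coordinates are projected to a local azimuthal-equidistant plane centred on
the track centroid; at platform scale (~50 km) the area and distance
distortions of this projection are far below 0.1%, well under the other
error sources.

`segment_track()` fits a piecewise-stationary model: within a segment, x and
y are independent Gaussians with segment-specific mean and variance. For a
given number of segments K the breakpoints minimising the summed negative
log-likelihood are found by exact dynamic programming subject to a minimum
segment length (`lmin`, default 40 epochs = 20 days), not by heuristic
search; the test suite verifies equality with exhaustive enumeration on
short series. The 20-day floor means a reported phase is a period of
habitat use, not a weather event.

K is selected by the normalized-contrast threshold rule: the optimal
contrast J(K) is rescaled so it falls from Kmax to 1, and the largest K
whose normalized one-step decrease exceeds 0.75 is retained. Applied alone,
this rule has a known failure mode: on structureless series the rescaling
inflates tiny, noise-level decreases (their normalized values hover around
1, above any fixed threshold), so some K > 1 is always selected. We
therefore additionally require each added segment to lower the *raw*
contrast by at least `guard * log(n)` (default `guard = 3`, the BIC scale
for the four parameters a segment adds). On iid noise the raw decreases are
an order of magnitude below this guard, while a 10-sigma planted shift
exceeds it by a factor of ~20, so the guard separates the two regimes
cleanly without touching the threshold rule where there is real structure.

Whether two phases occupy distinct space is judged by the Bhattacharyya
coefficient of their kernel utilization distributions computed on a shared
grid, each masked to its own 95% isopleth and renormalized
(`phase_ud_overlap()`); BC < 0.5 marks distinct periods of habitat use.
The unmasked variant (`mask_level = NULL`) is used in validation because it
has a closed form for Gaussian samples: BC = exp(-d^2 / (8 (s^2 + h^2)))
for equal-covariance clusters a distance d apart.

## Home ranges

`kde_ud()` evaluates a bivariate Gaussian kernel density on a regular grid
(cell edge 50 m by default) and normalises it to integrate to one. A 50-m
cell resolves the smallest distinct use areas in this system (0.003–0.2
km^2) with tens of cells or more; the grid pads the data bounding box by
3h so no appreciable mass is clipped. The L% isopleth (`isopleth()`) is
the smallest-area region holding L% of the mass: cells are ranked by
density and accumulated to the level, the cutoff density is contoured for
polygon output, and the area is the level-set cell count times cell area.
Contiguity is judged by 8-connectivity of the level-set cells before
polygonisation, so a one-cell diagonal bridge counts as connected.

The smoothing parameter follows the contiguity-based ad hoc rule
(`select_h_adhoc()`): start from the reference value h0 = sigma n^(-1/6)
(sigma the pooled per-axis standard deviation), then shrink h by a factor
of 0.95 per step while the 95% isopleth remains a single connected region,
returning the last contiguous value. The source procedure says only
"gradually reduced"; 0.95 per step resolves h to within 5%, which is far
finer than the sampling variability of the isopleth itself. Shrinking
stops at half a grid cell, below which the kernel can no longer be
represented on the grid. If h0 itself is non-contiguous the rule cannot be
satisfied and h0 is returned flagged.

`mcp()` is the classical minimum convex polygon ("total residence area"),
with optional central-percentile trimming by distance from the centroid.
When fix times are available the cumulative hull area by tracking day is
computed, and the asymptote check passes when the final 10% of tracking
days adds less than 5% of the final area — the criterion for the tracking
period having captured the full residence area.

## Distinct use areas

`label_fixes()` attaches the covariates the classification needs:
photoperiod from solar elevation at the fix position and time (day = centre
of the sun above the horizon, computed with a standard low-precision solar
ephemeris accurate to a fraction of a degree), season by the month rule
(warm = May–November, cool = December–April, the months in which platform
water temperatures tend to sit above vs below 20 °C), seagrass membership
by point-in-polygon against the habitat map, and depth sampled from the
bathymetry. Photoperiod uses the sun rather than clock hours because civil
time drifts about two hours against solar time over the year at this
longitude; diel occupancy histograms, by contrast, deliberately use local
clock hours (fixed UTC-4) because that is how tag duty cycles and field
sampling are scheduled.

`find_use_areas()` replaces manual digitisation of location clusters with
density-connected clustering: a fix is a core point when at least
`min_count` fixes (default 15) lie within `eps` (default 100 m), and
clusters are the connected components of core neighbourhoods. The 100-m
radius comes from the accuracy of >= 6-satellite Fastloc solutions (95% of
positions within ~70 m of truth): fixes from one physical site scatter on
that scale, so a smaller eps would shatter real clusters and a much larger
one would merge adjacent sites, which in this system can sit only a few
hundred metres apart. Each cluster's polygon is its convex hull buffered by
eps/2, compensating the positional scatter at the cluster edge.

Classification mirrors the field interpretation: clusters mostly on
seagrass are foraging areas (on-meadow foraging and resting cannot be
separated with position data alone, so the on-meadow class is the combined
f/r); off-meadow clusters are day or night resting areas by photoperiod
majority; and any cluster used at least 80% in the cool season at a mean
depth at least 1.5 times the animal's foraging-area depth is overridden to
a cool-weather refuge. The 80% / 1.5x override operationalises "visited
only during cool months, at greater average depth" while tolerating the
occasional warm-season visit and shallow-bathymetry noise; both constants
are exposed as arguments.

Binned dive summaries use means weighted by the proportion of time per bin
(`weighted_mean_bins()`), with bin midpoints and an open top bin whose
midpoint is the lower edge plus half the preceding bin's width — the only
defensible convention when the archive does not record the within-bin
distribution. Displacement-temperature coupling
(`distance_temperature_correlation()`) pairs each fix's distance from the
25% UD mean centre with the buoy temperature nearest in time (within 24 h),
aggregates to daily means so autocorrelated within-day fixes do not inflate
the sample size, and applies Pearson's product-moment test.

## Migration metrics

`detect_departure()` declares a departure at the first fix outside the
platform boundary that is not followed by any inside fix within 5 days;
shorter outside loops are forays, which `detect_forays()` recovers as 4–15
day excursions beyond the residency 95% isopleth in the 30 days before
departure. Path metrics (`path_metrics()`) are computed over the pelagic
portion of the track (depth > 200 m when bathymetry is available, otherwise
outside the platform polygon): total path distance, the circular mean and
circular SD of per-step initial great-circle bearings, travel rates with
steps longer than 12 h excluded (a rate across a transmission gap is a
lower bound, not a rate), and day/night rates by the photoperiod of each
step's midpoint, compared with a Welch t test. Bearing is a per-step
circular statistic rather than an endpoint bearing because reported
per-track bearing dispersions are well under a degree, which only a
step-wise statistic produces. The 3-position straightness index
(`straightness_3pt()`) averages d(A,C) / (d(A,B) + d(B,C)) over
consecutive triples after dropping zero-length steps; it is 1 exactly on
forward-collinear paths and sqrt(2)/2 on a right-angle dogleg.

## Detectability

`detection_rate()` estimates the probability that one entrapment-net set
within an animal's foraging area captures it: captures divided by sets
during the residency period, restricted to animals resident for more than a
year at a single sampling site (otherwise the set denominator is
unknowable). The study-level summary is the arithmetic mean and sample SD
over full-precision ratios; rounding to the reporting precision happens
only on display, which matters — summarising pre-rounded rates shifts the
mean by a visible amount at n = 11.

## The synthetic-track generator

`simulate_track()` is a first-class, tested module, and its defaults *are*
the study conditions the rest of the package assumes. Movement is a
discrete-time biased random walk stepped every 30 simulated minutes: each
step relaxes toward the centre of the active behavioural role
(Ornstein-Uhlenbeck-style attraction, pull 1/h, isotropic step noise 30 m)
plus Gaussian noise. The active role follows a diel schedule in local time
(fixed UTC-4, no daylight saving, matching local convention): foraging
06:00–09:00 and 17:00–20:00, off-meadow day rest 10:00–16:00, night rest
otherwise — the twice-daily meadow attendance pattern the occupancy
analysis is designed to detect. Rest centres sit several hundred metres
from the meadow and the cool refuge ~3 km away at greater depth, matching
the reported inter-area distances. Water temperature is a day-of-year
sinusoid (mean 23.9 °C, amplitude 7.75 °C, maximum in mid-August, matching
the observed 15.7–31.2 °C seasonal range) with optional AR(1) noise;
whenever it drops below 20 °C the refuge role overrides the schedule.
After an optional migration start date, steps become directed travel at
2.27 km/h along a fixed bearing (default 230°, the southwestward corridor)
with von-Mises-like heading noise.

`observe_fixes()` passes the true path through the tag's observation model:
one candidate per even GMT hour, retained with probability 0.3 (matching
the reported ~560 fixes over ~280 days per animal), Gaussian position
error with sd 25 m for >= 6-satellite fixes (85% of retentions) and 250 m
otherwise, plus rare 5-km outliers. Residual scores are synthetic — no
residual distribution is published — and are constructed so the screening
rules have known truth: poor fixes exceed the threshold of 30 with
probability 0.95, clean fixes never do. Sensitivity and false-positive
rates quoted for the QC stage are therefore rates *under this error
model*, not field estimates.

The generator deliberately does not emulate: current-advected drift or any
hydrodynamics, 3-D dive trajectories (only binned time-at-depth summaries),
tag failure modes, or spatially heterogeneous temperature. Passing the
recovery suites therefore demonstrates that the estimators invert the
generator's behavioural model at realistic noise levels — it does not
certify performance on real tracks whose error structure departs from this
model.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to exercise each estimator
meaningfully while remaining quick to reproduce: segmentation recovery on
200-epoch series (100 days at 12-h spacing) over 20 seeded replicates;
DP-vs-enumeration equivalence on all series up to length 60 with lmin = 10;
use-area and departure recovery on 40–60 day simulated tracks over 20
replicates; closed-form KDE and Bhattacharyya checks at n = 2,000–10,000
points on 50-m grids. Variances in the segmentation likelihood are floored
at 1e-8 m^2 to keep the log-likelihood finite on degenerate (constant)
stretches. Ties in the dynamic program resolve to the earliest breakpoint.
Degenerate KDE inputs (all points identical) are an error for `kde_ud()`
and fall back to minimum smoothing with a warning in `phase_ud_overlap()`,
where a BC must still be produced.

## Known limitations

Per-animal reproduction of the published home-range and correlation values
is not possible — the underlying fix data were never deposited — so the
packaged report tables carry the published per-animal values and all
aggregate statistics are recomputed from them; only the synthetic suites
validate the estimators end to end. The segmentation selection rule is
conservative by construction (the guard suppresses marginal phases), which
matches the source study's own experience that visually apparent shifts
were not always detected. The detectability estimator assumes constant
site fidelity between captures and ignores the diel availability bias it
itself documents (mid-day absences from the meadow overlapping the field
sampling window), so it should be read as an upper bound on per-set
capture probability during sampling hours.
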