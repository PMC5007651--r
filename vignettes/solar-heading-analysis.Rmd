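---
title: "Solar-referenced analysis of caching and recovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solar-referenced analysis of caching and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Diurnal animals in open, landmark-poor habitat can use the sun as a
directional reference. Full *time compensation* (a sun compass that corrects
continuously for the sun's motion) is thought to be restricted to specialist
navigators; a simpler alternative is *time-limited* use, in which an animal
reuses specific positional information — for example, the sun's azimuth at a
remembered moment, or the mirror-symmetric point of that azimuth on the solar
arc — without continuous compensation.

This package implements the full analysis chain for testing that idea in a
scatter-hoarding, central-place-foraging rodent (the Cape ground squirrel,
*Xerus inauris*, in the semi-arid southern Kalahari): GPS tracks from a
provisioning point to a cache are reduced to angular offsets from the solar
azimuth; the offset distribution is tested for bimodality and modelled as a
two-component Gaussian mixture; cache recoveries are classified by whether
the solar azimuth at recovery is closer to the azimuth 24 h after caching
("A24") or to that azimuth's North–South mirror image ("PRE24"); and the
supporting mixed-model, straightness and foraging-area analyses are run
alongside. Because the original field data are not publicly deposited, a
seeded synthetic generator reproduces the *design* of such a study so every
stage is testable.

## Solar ephemeris

`solar_position()` implements the NOAA/Meeus low-precision solar position
(geometric mean longitude and anomaly, equation of centre, apparent longitude
with the leading nutation term, obliquity, equation of time, hour angle).
Against an independently implemented reference algorithm (the PSA ephemeris,
a structurally different formulation via right ascension/declination and
sidereal time) agreement is ~0.01°, far below the ~0.5° tolerance that
matters here: with ±1.5 m GPS accuracy, bearing error on a 15 m track is
about 8°, so ephemeris error is negligible.

Conventions, fixed once:

* Azimuth is degrees clockwise from **true** north in [0, 360). The field
  practice of reading azimuths from online calculators is assumed to refer
  to true north; magnetic declination at the site is small but nonzero.
* All stored instants are UTC. The site's civil time (UTC+2, no DST) is a
  presentation concern only.
* Sunrise/sunset use the standard −0.833° horizon (solar radius plus mean
  refraction), refined by bisection on the elevation so returned instants
  match `solar_position()` to < 0.2°. No other refraction modelling is done.
* `observation_periods()` divides sunrise→sunset into five equal parts; the
  four interior points are the daily session start times (the animals are
  below ground near sunrise and sunset themselves).
* `mirrored_azimuth(az) = (360 − az) mod 360` is the reflection across the
  North–South plane; it is an involution and fixes the meridian.

## Track angles

One angle per track: the bearing from the first fix (provisioning point) to
the last fix (cache), computed in a local equirectangular projection centred
on the group's burrow (projection error < 1 cm at 200 m — far below GPS
noise). Intermediate fixes contribute only to path length and straightness.
This "endpoints only" reading is the only one consistent with a single angle
per caching movement.

The signed offset from the solar azimuth at the cache instant is wrapped to
(−π, π], positive to the right (clockwise) of the sun. Tracks made *away*
from the sun (|offset| > π/2) are reflected about the ±π/2 line,
`a → sign(a)·(π − |a|)`, bounding everything to [−π/2, π/2] while preserving
the left/right sign. Bounded data avoid circular statistics downstream; the
cost is that toward and away movements are pooled, which is justified
empirically by comparing the two magnitude distributions (a KS check in the
pipeline). Reversing a bearing by 180° preserves the reflected magnitude and
flips the toward/away flag — the property the pooling relies on.

Tracks whose Euclidean displacement is below 3 m (twice the GPS accuracy)
are flagged degenerate: their bearing is noise-dominated. They are excluded
from angle analyses but retained for straightness. The straightness index is
Euclidean displacement over observed path length; because fixes were taken
only at deviations from a straight path, observed path length is a lower
bound on the true path, and no correction is attempted.

## Dip test

`dip_statistic()` is an exact implementation (C++) of the classical
unimodality statistic: the smallest sup-norm distance between the empirical
CDF and any unimodal CDF, computed by the iterative greatest-convex-minorant
/ least-concave-majorant modal-interval algorithm. Two practical notes:

* The fitted unimodal CDF may jump at its mode; the single-count atom
  allowances in the algorithm encode this, and give the known lower bound
  D ≥ 1/(2n) (a two-point sample attains 0.25 exactly).
* `dip_test()` uses a Monte-Carlo null of uniform samples of the same size —
  the customary reference null, under which the dip is asymptotically
  largest among unimodal distributions, making the test conservative against
  peaked unimodal alternatives.

During development the implementation was verified to reproduce the standard
reference implementation to 10⁻¹² over 20 000 random samples (n = 2–200,
with heavy ties); a frozen subset of those oracle values is asserted in the
test suite.

## Two-component mixture

`em_fit()` is a standard univariate two-component Gaussian EM.
Initialisation is a deterministic quantile split (below/above the median)
plus randomly perturbed restarts — a reproducible baseline with stochastic
escape from local optima; the best converged log-likelihood wins and the
winning run's log-likelihood trace is retained (it must be monotone, and the
tests assert this). Labels are ordered μ₁ < μ₂ throughout, including in
every bootstrap replicate, which resolves label switching by mean ordering.
λ is the mixing proportion of component 1 (the occasional description of λ
as an "overlap" is treated as loose phrasing).

Standard errors come from a parametric bootstrap (B = 2000 by default):
simulate from the fitted mixture, refit, take SDs across converged
replicates; more than 10 % non-convergence is recorded as a warning in the
result. For simulation studies where 2000 refits per dataset are
prohibitive, `mixture_se_hessian()` provides Wald SEs from the numerically
differentiated observed information; these are what the acceptance
calibration uses for confidence-interval coverage.

Component comparisons (`compare_components()`) use hard assignment by
maximum responsibility — the analysis compares "extracted" component
subsamples, implying disjoint sets — then negate the left-of-sun component
so both live on a positive scale, and run a KS comparison, a Welch magnitude
test, and per-component tests against zero (the sun's direction). The KS
p-values here ignore both parameter estimation and repeated measures on
subjects; they are diagnostics. Subject/group structure is handled only in
the mixed-model layer.

## Recovery classification

For a cache made at time *t*: θ_a is the solar azimuth at *t* + 24 h
(evaluated at the burrow centre, matching how field azimuths were obtained),
θ_b its North–South mirror. A recovery is A24 if the recovery-instant
azimuth is circularly closer to θ_a, else PRE24; an exact tie goes to A24
(deterministic, measure-zero under continuous time). Recoveries with the sun
below the horizon are flagged unclassifiable. The accuracy measure
`az_error_deg` is the smaller circular distance between the recovery azimuth
and either the cache azimuth or its mirror — the mirror handling is needed
because a perfect PRE24 recovery matches the mirrored cache azimuth; both
raw distances are retained for transparency. Recovery *tracks* are
deliberately out of scope: only event times are consumed.

## Mixed models

`fit_lmm()`/`lrt()` wrap lme4 with random intercepts for subject nested in
group. All likelihood-ratio comparisons use ML (REML likelihoods are not
comparable across fixed-effect structures); all tested effects are fixed
effects, so the χ² reference applies without boundary corrections. The
modelling machinery is deliberately bought, not built — the scientific
content of this package is in the solar/angular/mixture modules.

`paper_model_suite()` runs the named models. Two choices deserve note:

* Model (a) regresses the **axial** track bearing — away-from-sun tracks
  rotated by 180° — on the solar azimuth, both as signed degrees from north.
  Without the folding, pooled toward/away tracks sit 180° apart and cancel
  the slope; with it, the bearing tracks the sun's azimuth with slope ≈ 1
  across the day, while model (b) (reflected angle ~ observation period)
  stays flat. That pair of results is the signature of a constant solar
  offset maintained across the day.
* The `group_size` used in the event-level models is the number of
  individuals *present* at the event, which varies within a group. A
  constant per-group size would be absorbed entirely by the group random
  intercept and make the category/group-size model degenerate.

## Foraging areas

The used area per subject is an alpha-shape area of its provisioning start
points at the smallest alpha for which every point lies on or in the shape;
the null is the circle around the burrow through the farthest start point.
The alpha shape is built from a Delaunay triangulation (small point sets;
brute-force empty-circumcircle test in C++, with a deterministic symbolic
perturbation so cocircular inputs such as rectangles triangulate uniquely —
areas are computed from the unperturbed coordinates). "Covered" is
operationalised as: every input point is a vertex of the retained complex
(triangles with circumradius ≤ alpha) *and* the complex is edge-connected.
The connectivity requirement is what makes convex-position inputs reproduce
their convex hull exactly — each ear triangle is forced by its private
vertex, and connecting the ears forces the entire adjacency tree — while
still letting concave clouds (a C-shape) shed the large mouth-spanning
triangles. The minimal covering alpha is found by binary search over the
finite, sorted set of triangle circumradii, which is the exact version of a
bisection with tolerance. The
notion of a "minimum convex hull with an alpha parameter" is internally
contradictory (alpha shapes are generally non-convex), so both the
alpha-shape and convex-hull areas are reported, with the convex hull as the
degenerate-case fallback, and the hull-versus-null comparison is run as a
paired (within-subject) mixed model on log areas as well as being reported
per subject.

## The synthetic world

`synth_config()` defaults encode the stated design: study site 26°58′S,
21°49′E; April–July observation window; 9 subjects across 5 groups; 4
observation periods per day from the 5-way daylight split; 5 provisioning
trials per session; GPS radial accuracy 1.5 m; group sizes 3–36; mixture
component means −1.01 and 0.59 rad; expected straightness 0.89; recoveries
placed (with 30 min timing jitter) at the A24 instant or the same/next-day
PRE24 mirror instant, racing an exponential theft hazard that increases with
the number of individuals present.

Calibration choices the field study does not print, fixed once and recorded
in the truth output:

* Component SDs 0.35 and 0.40 rad and mixing weight λ = 0.45 (the larger
  component to the right of the sun), chosen so that the angle distribution
  at the field sample size (~265 tracks) is visibly bimodal and rejects
  unimodality in a majority of runs.
* 3 observation days per subject with 50 % session attendance — matching
  the "3 repeats attempted, some missed" protocol and giving ≈ 250–300
  tracks per run.
* Track lengths lognormal with median 15 m (consistent with foraging radii
  of a few tens of metres); start points at lognormal distances (median
  12 m) from the burrow, which produces the strongly clustered
  start-point pattern (hull ≪ null area).
* Two intermediate fixes per track — fixes are taken only at deviations on
  near-straight tracks — with lateral jitter calibrated by Monte-Carlo so
  the *expected straightness including GPS noise* equals the target. GPS
  noise alone imposes a straightness ceiling; at the defaults the ceiling is
  ≈ 0.90, leaving room to hit 0.89. With `gps_sd_m = 0` and
  `straightness_target = 1` the generator is exactly noise-free: recovered
  reflected angles equal the latent draws to CSV-digit precision,
  straightness is exactly 1, and classification is 100 % correct.
* Theft hazard 0.015 + 0.005·(individuals present) per *daylight* hour
  (nights are skipped, since the animals are below ground); with presence
  fluctuating around 70 % of residents this yields roughly half of caches
  stolen, nearly all thefts within 24 h, and a clearly negative
  survival-versus-group-size slope.
* Mixture draws are truncated to [−π/2, π/2] by resampling; this shifts the
  left component's realised mean by ≈ +0.03 rad relative to the nominal
  −1.01 (its 2σ tail crosses −π/2). The truth tables record the realised
  draws, so estimator checks compare against what was actually generated.

What the generator does **not** emulate: terrain, landmarks and any
cue-combination behaviour; movement autocorrelation between sessions; social
dynamics beyond the presence count; seasonal behavioural change. A green
test therefore establishes that the *estimators and classifiers recover a
world with the assumed structure* — not that real squirrels behave this way.
One known divergence: because recovery timing jitter is constant in time,
the induced azimuth error grows with the azimuth's angular speed, which
correlates with solar elevation — so the synthetic world shows an
error-versus-elevation effect that the field analysis did not.

## Numerical choices

* EM: tolerance 10⁻⁸ on the log-likelihood gain, 2000 iterations max,
  20 starts by default; component SDs floored at 10⁻⁶·sd(x) to reject
  degenerate spikes; failed starts are discarded, and an error is raised
  only if every start fails.
* Dip Monte-Carlo: 10 000 null replicates by default; seeded calls restore
  the caller's RNG state.
* Sunrise/sunset: 40 bisection iterations (sub-second); results memoised
  per (date, location).
* `time_at_azimuth()`: 97-point daylight grid to bracket the crossing, then
  bisection to 1 s; returns NA for azimuths the sun never reaches that day
  (e.g. due south in austral winter at the site).
* Degenerate inputs error early with specific messages (zero-range samples,
  coincident fixes, empty cache lists, k > n).

## Limitations

* The dip test's uniform null is conventional but conservative for peaked
  unimodal alternatives.
* KS tests involving estimated parameters are reported as diagnostics, not
  inference.
* LRT p-values rely on the asymptotic χ² reference; at the field's
  recovery-level sample sizes (n ≈ 20) they are approximate, exactly as in
  the motivating analysis.
* The equirectangular projection and the planar alpha shape are only valid
  at the ≤ few-hundred-metre scale of central-place foraging data.
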