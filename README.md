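# solarcache

Solar-referenced analysis of food-caching and cache-recovery behaviour in a
central-place foraging rodent.

## The problem

In open, landmark-poor habitat such as the southern Kalahari, a diurnal
animal can use the sun's azimuth as a *heading indicator*: set a bearing at
a consistent angular offset from the sun, move in a near-straight line, and
later reuse that solar information to reorientate. Full time compensation (a
sun compass that continuously corrects for the sun's movement) is not
required if the animal reuses *fixed points* of the solar ephemeris — the
azimuth 24 hours after caching, or the mirror image of that azimuth across
the North–South plane, which the sun occupies at the same elevation earlier
in the day (time-limited sun use).

`solarcache` implements the complete analysis chain for this question:

* a self-contained **solar ephemeris** (NOAA/Meeus low-precision position,
  sunrise/sunset at the −0.833° horizon, the 5-way daylight split that
  schedules field sessions, and the arc-symmetry mirror
  `az → (360 − az) mod 360`);
* **track geometry**: local equirectangular projection, bearings,
  straightness (Euclidean over path length), and the angle transform — the
  signed offset of a track bearing from the solar azimuth, wrapped to
  (−π, π] (positive = right of the sun) and reflected about ±π/2 into
  [−π/2, π/2] so circular statistics can be avoided;
* **distributional analysis**: Hartigan's dip statistic (exact C++
  implementation) with a Monte-Carlo uniform null, a two-component Gaussian
  mixture fitted by EM with parametric-bootstrap standard errors,
  Kolmogorov–Smirnov comparisons and moment diagnostics;
* **recovery classification**: each recovered cache is A24 or PRE24
  according to whether the solar azimuth at recovery is circularly closer to
  the azimuth 24 h post-cache (θ_a) or to its North–South mirror (θ_b),
  plus the Yates-corrected proportion test
  χ² = (|k − n·p₀| − ½)² / (n·p₀(1 − p₀));
* **mixed-model inference**: lme4-backed LMMs with subject-nested-in-group
  random intercepts and ML likelihood-ratio tests for the named models of
  the analysis;
* **foraging areas**: alpha-shape area of start points (smallest alpha
  covering every point) versus the circular null through the farthest point;
* a seeded **synthetic-data generator** reproducing the field design
  (9 subjects / 5 groups, 4 daily observation periods, 5 trials per session,
  bimodal angular offsets with component means −1.01 and 0.59 rad,
  straightness 0.89, ±1.5 m GPS noise, group-size-dependent theft hazard,
  A24/PRE24-timed recoveries), so the whole pipeline is testable without
  field data.

## Worked example

```r
library(solarcache)

sim <- generate_synthetic(synth_config(seed = 7))
rep <- run_pipeline(sim$fixes, sim$events, sim$burrows, seed = 7,
                    B = 200, n_mc = 2000)
print(rep)
```

```
Pipeline report: 295 tracks (294 with angles), 295 cache events
  dip D = 0.0541 (MC p = 0.000)
  mixture: lambda = 0.42, mu = (-0.971, 0.558), sigma = (0.306, 0.421)
  mean straightness = 0.891 (skewness -1.43)
  recoveries: 157 (PRE24 94 / A24 63), prop test chi2 = 5.73, p = 0.017
  mean % of null area covered: 25.9%
```

Reading the output: the dip statistic rejects unimodality of the reflected
track angles (the Monte-Carlo p is the share of uniform null samples with a
larger dip); the mixture recovers the two angular offsets the generator
planted at −1.01 and 0.59 rad — animals heading left or right of the sun at
consistent offsets; tracks are nearly straight (index close to 1, left-
skewed); recoveries split between the PRE24 and A24 solar-arc categories,
compared with a 50:50 null by the continuity-corrected proportion test; and
start points cover only a small fraction of the circular null area, i.e.
foraging is strongly clustered around the burrow. The exact numbers above
are what `print(rep)` emits for seed 7 on this package version; any
differences you see indicate a real behavioural change, since the whole
chain is deterministic given the seed.

Classification of a single recovery:

```r
cache_t <- as.POSIXct("2014-05-10 07:30:00", tz = "UTC")
classify_recovery(cache_t, cache_t + 86400)   # exactly +24 h -> A24
#>   theta_a_deg theta_b_deg az_recovery_deg category dist_a_deg dist_b_deg
#> 1    49.13143    310.8686        49.13143      A24          0   98.26287
#>   az_cache_deg elevation_at_cache_deg az_error_deg unclassifiable
#> 1     49.34484               27.74667    0.2134055          FALSE
```

File-based runs and a small CLI (`sun`, `synth`, `all` subcommands) are
available through `run_pipeline_files()` and `inst/cli/solarcache-cli.R`.

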