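Package: solarcache
Title: Solar-Referenced Analysis of Food-Caching and Recovery Tracks
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the caching and cache-recovery behaviour of a
    central-place foraging rodent relative to the position of the sun. The
    package provides a self-contained low-precision solar ephemeris (position,
    sunrise/sunset, daily observation-period scheduling, solar-arc mirroring),
    geometry of GPS cache tracks (bearing, straightness, signed and reflected
    angular offsets from the solar azimuth), distributional analysis of track
    angles (Hartigan's dip test, two-component Gaussian mixture fitted by EM
    with bootstrap standard errors, Kolmogorov-Smirnov comparisons, moment
    diagnostics), solar-arc symmetric classification of cache recoveries
    (PRE24 versus A24), linear mixed-model inference with likelihood-ratio
    tests, alpha-hull foraging-area estimation against a circular null, and a
    seeded synthetic-data generator so that the complete pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
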