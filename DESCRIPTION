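Package: divtempo
Title: Diversification Tempo Analysis on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistics and simulators for studying the tempo of lineage
    diversification on ultrametric, time-calibrated phylogenies (chronograms).
    Implements sister-clade species-richness tests (Slowinski-Guyer),
    Magallon-Sanderson net-diversification estimators with an extinction
    fraction, the relative cladogenesis (broken-stick) rate-shift test with
    Bonferroni correction, the gamma statistic with the constant-rates (CR)
    test and its Monte Carlo analogue (MCCR) corrected for incomplete random
    taxon sampling, lineages-through-time curves with simulation envelopes,
    and maximum-likelihood fitting with AIC comparison of six diversification
    models (pure birth, constant birth-death, declining speciation, rising
    extinction, and one- and two-breakpoint piecewise Yule models).
    Includes forward and backward birth-death chronogram simulators
    (constant-rate, piecewise-constant, and continuously time-varying) with
    random tip subsampling, so every statistic can be calibrated and
    power-tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
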