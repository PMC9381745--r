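Package: atps
Title: Liquid-Liquid Equilibrium Analysis for Polymer-Salt Aqueous Two-Phase Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising polymer-salt aqueous two-phase systems
    (ATPS) from tabular liquid-liquid equilibrium measurements: binodal-curve
    fitting with the Merchuk and Zafarani-Moattar empirical correlations,
    tie-line characterisation (tie-line length, lever-rule mass-balance checks)
    and consistency testing via the Othmer-Tobias, Bancroft and Setschenow
    correlations, refractometric composition analysis, and drug-partitioning
    analytics (partition coefficients, extraction efficiencies, Diamond-Hsu
    correlations). Includes a seeded synthetic-data generator emulating the
    statistical structure of such measurements, so every analysis stage can be
    benchmarked for parameter recovery without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
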