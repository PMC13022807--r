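Package: ligninKMC
Title: Threshold-Filtered Kinetic Monte Carlo Simulation of Lignin Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiscale stochastic simulator of acid-solvent lignin
    fractionation. Couples macroscale delignification/redeposition mass
    balances and a two-phase energy balance to a Gillespie direct-method
    kinetic Monte Carlo engine over explicit syringyl/guaiacyl chains
    (beta-O-4 scission, condensation, demethoxylation). Provides an
    Arrhenius activation-energy threshold filter that prunes kinetically
    irrelevant events from the catalog before rate evaluation, and a
    shrinking-horizon model predictive controller that steers the
    weight-average molar mass and the S/G ratio of the dissolved lignin
    to set-points by manipulating the heating jacket.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
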