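Package: bioswing
Title: Sulfur-Cycle Biological pH-Swing Mineral Carbonation Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled kinetic-equilibrium modeling of biological pH-swing
    mineral carbonation for atmospheric CO2 removal. Simulates a two-reactor
    sulfur cycle in which microbial sulfur oxidation (an Acidithiobacillus
    thiooxidans-like organism) acidifies a stirred tank to drive forsterite
    dissolution, and microbial sulfate reduction (a Desulfovibrio
    vulgaris-like organism fed dissolved hydrogen) alkalinizes a second tank
    to absorb air CO2 and precipitate MgCO3 on seed crystals. Includes
    equilibrium carbonate/sulfide speciation with charge-balance pH and
    Davies activity corrections, Monod growth kinetics, shrinking-particle
    mineral dissolution, saturation-index seeded crystal growth, gas-liquid
    mass transfer for sparged stirred vessels, scenario scheduling for the
    hydrogen sulfide and thiosulfate cycle variants, a multi-mineral
    tailings-dissolution validation scenario, and synthetic-data generation
    for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
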