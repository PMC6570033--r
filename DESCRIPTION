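Package: cadsoil
Title: Cadmium Bioavailability in Soils from DGT Measurements, Soil
    Properties and a Biotic Ligand Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the potential vulnerability of soils to
    cadmium contamination from intact soil properties.  Implements the
    diffusive gradients in thin-films (DGT) concentration calculation,
    correlation and maximum-likelihood factor analysis of soil
    physicochemical properties with proxy-variable selection, per-level and
    interaction multiple-regression models for log10 DGT-measured cadmium,
    and a biotic ligand model (mass-action cation-ligand equilibrium with a
    speciation solver and two-stage affinity-constant estimation).  A
    synthetic-data generator reproduces the statistical structure of the
    soil-property and spiking-experiment tables so that every stage of the
    pipeline can be tested without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
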