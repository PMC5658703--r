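Package: emuflux
Title: Stationary 13C Metabolic Flux Analysis via Elementary Metabolite Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stationary 13C metabolic flux analysis of central
    carbon metabolism. Parses metabolic network models with carbon atom
    transitions, builds exact stoichiometric steady-state machinery, predicts
    mass isotopologue distributions (MIDs) from flux vectors and tracer
    specifications by elementary metabolite unit (EMU) decomposition, corrects
    GC/MS spectra for natural isotope abundance, computes extracellular
    consumption and production rates and label summary statistics, fits free
    fluxes to parallel-tracer MID and rate data by variance-weighted least
    squares with multistart, derives profile-likelihood confidence intervals,
    and classifies flux changes between two conditions by confidence-interval
    overlap. Includes a synthetic-data generator for two-condition,
    two-tracer experiments with ground-truth fluxes, and a packaged central
    carbon network (glycolysis, pentose phosphate pathway, TCA cycle,
    glutaminolysis, reductive carboxylation) emulating a colorectal carcinoma
    cell model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
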