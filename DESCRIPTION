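Package: ndfo
Title: Bioenergetics, Stoichiometry and Community Function of
    Nitrate-Dependent Iron Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for studying nitrate-dependent ferrous-iron
    oxidation (NDFO) in anoxic groundwater systems. Computes standard,
    pH-referenced and in-situ Gibbs free energies per electron-mol for
    microbial redox couples, dissolved ferric iron from mineral solubility
    equilibria, and proton-motive-force/ATP feasibility landscapes over
    substrate/product log-ratio grids. Provides censored reactor mass
    balances (influent-effluent removals under detection limits, observed
    versus expected Fe:NO3 consumption ratios, abiotic oxygen corrections,
    iron accumulation closure), a rule engine for genome-resolved function
    calls (iron oxidation, denitrification steps, carbon fixation, MIMAG
    quality) with community-level denitrification complementarity, and
    seeded synthetic-data generators emulating a pilot-scale groundwater
    filter and its metagenome-assembled genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
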