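Package: psas
Title: Solubility-Slope Indices of Amino-Acid/Amino-Acid Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pairwise amino-acid interactions from
    solubility assays of aromatic amino acids dissolved in amino-acid
    "solvents" (free amino acids used as cosolutes). The central quantity
    is the PSAS, the slope of the saturation-solubility ratio (water = 1)
    of an aromatic solute against the molar concentration of the solvent
    amino acid; positive slopes mark solubilizing (droplet-like)
    interactions and negative slopes insolubilizing (aggregate-like)
    interactions. The package bundles eight classical amino-acid scales
    (solubility in water, side-chain hydrophobicity, in/out propensity,
    hydropathy, helix/sheet/coil propensities, aromaphilicity), a seeded
    simulator of the saturation assay including an absorbance
    standard-curve observation layer, fixed- and free-intercept slope
    estimators with diagnostics, interaction classification, rank-based
    comparison of fitted slopes against the classical scales, and
    sliding-window sequence profiling with any scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
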