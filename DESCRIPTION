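Package: ankgroove
Title: Interface Analysis, Inner-Groove Layer Statistics and ITC Fitting for
    ANK-Repeat/Peptide Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising how ankyrin (ANK) tandem-repeat
    proteins recognise short peptides in their concave inner groove.
    Provides PDB/mmCIF parsing into a flat atom table, Shrake-Rupley style
    solvent-accessible surface area (SASA) with a deterministic Fibonacci
    point lattice, buried-surface-area and interface inventories (geometric
    hydrogen bonds, hydrophobic contacts), assignment of 33-residue ANK
    repeat frames and extraction of the four inner-groove layer positions
    (rho1, Phi1, Phi2, rho2), residue-class preference statistics with an
    exact binomial enrichment test, a one-site (Wiseman) isothermal
    titration calorimetry forward model with simulation and nonlinear
    least-squares fitting, and synthetic-data generators with known ground
    truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
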