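Package: descreen
Title: Segment-Thermodynamics Screening of Drug Solubility in Deep
    Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts and rank-orders the relative solubility of drug-like
    solutes in multicomponent solvents, in particular deep eutectic
    solvents (DES), from sigma-profiles: area-weighted histograms of
    surface screening-charge density.  Implements the segment
    statistical-thermodynamics model (misfit and hydrogen-bond contact
    energies, the self-consistent sigma-potential, solute chemical
    potentials and mole-fraction solubility), solvent-composition and
    unit arithmetic (molar ratios, mg/g to mole fraction, fold ratios and
    log-unit differences), predicted-versus-experimental comparison
    statistics, and a seeded synthetic-data generator so the whole
    pipeline is testable without quantum chemistry.  Ships the molar
    compositions and measured solubility table of an eleven-drug,
    ten-solvent DES screening study as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
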