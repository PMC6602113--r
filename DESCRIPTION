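Package: opfkin
Title: Kinetic Modelling of the Yeast Oxidative Protein Folding Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic modelling of electron flow through the
    yeast oxidative protein folding pathway, from glutathione via protein
    disulfide isomerase (Pdi1p) and the ER oxidase Ero1p to molecular
    oxygen.  Simulates Clarke-electrode oxygen-consumption assays
    (including DTT-driven Ero1p calibration and dithionite
    depletion/recovery runs), extracts windowed consumption rates from
    traces, calibrates and globally fits rate constants with a repeated,
    RMSD-ranked protocol, and converts the fitted in vitro kinetics into
    an in vivo capacity/demand calculus for the endoplasmic reticulum
    (molecule-count to concentration conversion, proteome-wide disulfide
    demand, overexpression predictions).  Includes seeded generators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
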