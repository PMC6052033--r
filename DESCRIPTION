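Package: nprebind
Title: Kinetic Modelling of pH-Dependent Ligand Rebinding in Nitrophorins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing CO rebinding kinetics in ferrous heme
    proteins of the nitrophorin family. Implements forward simulation and
    global nonlinear least-squares fitting of a seven-state microscopic
    reaction scheme (geminate rebinding, internal docking sites, solvent
    escape and bimolecular re-entry, conformational relaxation),
    maximum-entropy inversion of rebinding progress curves into lifetime
    distributions, singular value decomposition of time-resolved
    difference-absorption maps with isosbestic-point detection and
    femtosecond/nanosecond curve merging, and the proton-linkage
    thermodynamic cycle that couples aspartate ionization to the
    closed-open conformational transition and its apparent pKa. A
    synthetic-data module generates realistic progress curves and rank-1
    transient-absorption maps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    Matrix,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'cycle.R'
    'scheme.R'
    'fit.R'
    'mem.R'
    'svdmap.R'
    'synthetic.R'
    'io.R'
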