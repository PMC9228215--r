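Package: anionbind
Title: Host-Guest Anion Binding Analysis from Titrations, Calorimetry
    and Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing anion binding by synthetic receptors
    such as cyclopeptides. Solves equilibrium speciation over arbitrary
    receptor-anion stoichiometries (including competing anion dimerization),
    fits cumulative stability constants to full-spectrum fluorimetric and UV
    titrations and to fast-exchange NMR shift titrations by global
    multivariate regression (variable projection), fits single-site
    isothermal titration calorimetry thermograms with dilution-heat
    correction, builds solvent-transfer thermodynamic cycles from reaction
    Gibbs energies and solubility data, and post-processes molecular dynamics
    coordinate ensembles (coordination matrices, hydrogen-bond census,
    PCA/cluster representative structures, ring-centroid distributions).
    A synthetic-data generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
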