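Package: hiqem
Title: Hierarchical Quantum Embedding with Machine-Learned Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for hierarchical QM/QM/MM modelling on model
    Hamiltonians: Huzinaga-type projection-based multi-orbital-set embedding
    with an exact energy decomposition, ensemble high-dimensional neural
    network potentials with transfer learning and element-dependent
    stoichiometric shift fitting, and nonequilibrium-switching end-state
    corrections assembled through a thermodynamic cycle with propagated
    uncertainties. Includes seeded generators for model electronic systems
    and three-tier toy potential-energy surfaces so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    optparse
Config/testthat/edition: 3
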