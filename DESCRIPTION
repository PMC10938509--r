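Package: polembed
Title: Polarizable Direct Reaction Field QM/MM Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of polarizable QM/MM embedding by the
    direct reaction field method with exact (damped) polarization integrals.
    The molecular-mechanics environment is a Thole/Applequist model of point
    charges and interacting induced dipoles; its response enters the quantum
    Hamiltonian itself through one- and two-electron corrections built from
    damped electric-field and core-polarization-potential integrals, so that a
    single Hamiltonian describes every electronic state. Includes a minimal
    restricted Hartree-Fock engine over s- and p-type Gaussian bases,
    analytical nuclear, point-charge and polarizable-site gradients validated
    against finite differences, coarse-graining of distant polarizable sites,
    synthetic solvent-shell fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
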