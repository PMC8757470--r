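Package: gasci
Title: Stochastic Generalized Active Space Configuration Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for configuration-interaction calculations in generalized
    active spaces (GAS): constraint algebra over partitioned orbital spaces
    with local or cumulative occupation bounds, supergroup enumeration and
    fast index lookup, exact Hilbert-space and spin-adapted (van Vleck-Sherman)
    counting with arbitrary-precision integers, FCIDUMP integral handling,
    Slater-Condon matrix elements and exact diagonalization oracles,
    precomputed heat-bath (PCHB) excitation generation with per-supergroup
    alias tables that propose only GAS-allowed determinants, full FCIQMC
    walker dynamics (initiator, adaptive shift, semistochastic core
    projection, blocking analysis), and reduced-density-matrix based
    properties including spin expectation values and pseudonatural orbitals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
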