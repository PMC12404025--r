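Package: hdatd
Title: Density-Fitted TD-DFT Linear Response with the Hybrid Diagonal Approximation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Linear-response time-dependent density functional theory built on
    auxiliary density fitting (TD-ADFT). Computes vertical singlet and triplet
    excitation energies, oscillator strengths and dynamic polarizabilities of
    closed-shell molecules for pure, global-hybrid and range-separated-hybrid
    functionals. Hybrid functionals enter through the hybrid diagonal
    approximation (HDA): only the diagonal exact-exchange elements are kept,
    as orbital-energy shifts, so the response eigenproblem retains the
    index-aligned pure-functional structure and can be applied matrix-free.
    Includes a Gaussian integral engine (McMurchie-Davidson recurrences, Boys
    function, erf-attenuated operators), a restricted Kohn-Sham SCF host with
    density-fitted Coulomb and exact Fock exchange, Becke-partitioned
    exchange-correlation quadrature grids, a Davidson eigensolver, and a
    four-center reference mode that serves as an exact-exchange oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
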