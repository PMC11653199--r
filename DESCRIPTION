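Package: vqehop
Title: Surface-Hopping Nonadiabatic Dynamics with Variational Quantum Electronic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid quantum-classical nonadiabatic molecular dynamics. Builds
    geometry-parametrized active-space qubit Hamiltonians (Jordan-Wigner mapped,
    with Pauli-string measurement grouping), solves ground and excited electronic
    states by statevector simulation of the k-UpCCGSD ansatz with the variational
    quantum eigensolver (VQE) and penalty-based variational quantum deflation
    (VQD), and derives Hellmann-Feynman gradients, nonadiabatic couplings,
    transition dipoles and configuration-interaction expansions from the
    converged states. These feed a fewest-switches surface-hopping driver with
    local-diabatization electronic propagation, harmonic Wigner initial-condition
    sampling, and population-kinetics analysis tools. Analytic two-state model
    providers make every stage runnable without an external electronic-structure
    backend.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), Matrix, jsonlite
Config/testthat/edition: 3
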