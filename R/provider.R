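# Electronic-structure provider contract. A provider encapsulates the
# classical mean-field stage: it must return active-space integrals,
# MO coefficients, cross-geometry MO overlaps and dipole integrals, all
# deterministically (bit-identical for identical geometries).

#' Define an active space
#'
#' @param n_electrons number of active electrons.
#' @param n_orbitals number of active spatial orbitals.
#' @param frozen_core_energy energy of the frozen core (hartree), folded
#'   into the Hamiltonian constant by providers.
#' @param orbital_indices selected MO indices (strictly increasing), or
#'   NULL when the provider has a fixed window.
#' @export
active_space <- function(n_electrons, n_orbitals, frozen_core_energy = 0,
                         orbital_indices = NULL) {
  stopifnot(n_electrons > 0, n_electrons <= 2 * n_orbitals)
  if (!is.null(orbital_indices)) {
    stopifnot(all(diff(orbital_indices) > 0),
              length(orbital_indices) == n_orbitals)
  }
  structure(list(n_electrons = as.integer(n_electrons),
                 n_orbitals = as.integer(n_orbitals),
                 frozen_core_energy = frozen_core_energy,
                 orbital_indices = orbital_indices),
            class = "active_space")
}

#' Assemble a provider from its capability closures
#'
#' @param integrals function(geometry, active_space) ->
#'   `spin_orbital_integrals`.
#' @param mo_coefficients function(geometry) -> MO coefficient matrix.
#' @param cross_overlap function(geometry_a, geometry_b) -> MO-basis
#'   overlap matrix between the two geometries.
#' @param dipole_integrals function(geometry) -> list of 3 one-electron
#'   matrices (x, y, z) in the active MO basis, or NULL if unsupported.
#' @param name provider label.
#' @export
electronic_structure_provider <- function(integrals, mo_coefficients = NULL,
                                          cross_overlap = NULL,
                                          dipole_integrals = NULL,
                                          name = "custom") {
  structure(list(integrals = integrals, mo_coefficients = mo_coefficients,
                 cross_overlap = cross_overlap,
                 dipole_integrals = dipole_integrals, name = name),
            class = "electronic_structure_provider")
}

#' Build the active-space qubit Hamiltonian at a geometry
#'
#' Provider integrals -> second quantization -> Jordan-Wigner, with
#' coefficient pruning at `tol`.
#'
#' @param provider an `electronic_structure_provider`.
#' @param geom a `geometry`.
#' @param aspace an `active_space`.
#' @param tol pruning tolerance.
#' @return a Hermitian `qubit_operator` on `2 * n_orbitals` qubits.
#' @export
build_qubit_hamiltonian <- function(provider, geom, aspace, tol = 1e-12) {
  ints <- provider$integrals(geom, aspace)
  jordan_wigner(second_quantized_hamiltonian(ints), tol = tol)
}

#' Finite-difference derivative of the qubit Hamiltonian
#'
#' Central difference `(H(R+d) - H(R-d)) / (2d)` along one Cartesian
#' component, built from two displaced-geometry Hamiltonians under the
#' provider's (deterministic) active-space selection. The constant term
#' carries the nuclear-repulsion/core derivative, so state gradients are
#' complete expectation values of this operator.
#'
#' @param provider an `electronic_structure_provider`.
#' @param geom a `geometry`.
#' @param aspace an `active_space`.
#' @param atom 1-based atom index; @param axis 1, 2 or 3.
#' @param shift_angstrom displacement (default 0.001 angstrom).
#' @return a `qubit_operator` in hartree/bohr.
#' @export
hamiltonian_derivative <- function(provider, geom, aspace, atom, axis,
                                   shift_angstrom = 0.001) {
  stopifnot(shift_angstrom > 0)
  d <- shift_angstrom * au$bohr_per_angstrom
  hp <- tryCatch(
    build_qubit_hamiltonian(provider, displace_geometry(geom, atom, axis, d), aspace),
    error = function(e) stop("backend failure at displaced geometry (atom ",
                             atom, ", axis ", axis, ", +", d, " bohr): ",
                             conditionMessage(e)))
  hm <- tryCatch(
    build_qubit_hamiltonian(provider, displace_geometry(geom, atom, axis, -d), aspace),
    error = function(e) stop("backend failure at displaced geometry (atom ",
                             atom, ", axis ", axis, ", -", d, " bohr): ",
                             conditionMessage(e)))
  qop_scale(qop_add(hp, qop_scale(hm, -1)), 1 / (2 * d))
}

#' All Cartesian components of the Hamiltonian derivative
#'
#' One derivative build serves all electronic states; returns the
#' component operators indexed `[[atom]][[axis]]`.
#'
#' @inheritParams hamiltonian_derivative
#' @export
hamiltonian_gradient_components <- function(provider, geom, aspace,
                                            shift_angstrom = 0.001) {
  lapply(seq_len(nrow(geom$coords)), function(a)
    lapply(1:3, function(ax)
      hamiltonian_derivative(provider, geom, aspace, a, ax, shift_angstrom)))
}

#' Active-space dipole operator components
#'
#' Second-quantized electronic dipole restricted to the active space and
#' Jordan-Wigner mapped. Nuclear and frozen contributions are constants
#' and cancel in transition moments, so they are omitted.
#'
#' @param provider an `electronic_structure_provider` with
#'   `dipole_integrals`.
#' @param geom a `geometry`; @param aspace an `active_space`.
#' @return list of 3 `qubit_operator`s (x, y, z).
#' @export
dipole_operator <- function(provider, geom, aspace) {
  if (is.null(provider$dipole_integrals)) {
    stop("provider '", provider$name, "' does not supply dipole integrals")
  }
  dints <- provider$dipole_integrals(geom)
  lapply(dints, function(D) {
    n <- nrow(D); ns <- 2L * n
    terms <- list(); coef <- complex(0)
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (abs(D[p, q]) < 1e-14) next
      for (sp in 0:1) {
        terms[[length(terms) + 1L]] <-
          list(modes = c(2L * (p - 1L) + sp, 2L * (q - 1L) + sp),
               dagger = c(TRUE, FALSE))
        coef <- c(coef, D[p, q])
      }
    }
    jordan_wigner(fermion_operator(ns, terms, coef), n_qubits = ns)
  })
}
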