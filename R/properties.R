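# Electronic properties from converged variational states: Hellmann-
# Feynman gradients, approximate nonadiabatic coupling vectors,
# transition dipoles / oscillator strengths, and CI-type expansions for
# cross-step overlaps.

#' Hellmann-Feynman state gradients
#'
#' Gradient of state m, component (atom, axis) =
#' `<psi_m| dH/dR |psi_m>`, with the nuclear-repulsion/core derivative
#' carried by the constant term of the derivative operators. Pulay terms
#' are neglected by construction. One derivative build serves all states.
#'
#' @param state_set an `electronic_state_set`.
#' @param dH_components derivative operators from
#'   [hamiltonian_gradient_components()] (`[[atom]][[axis]]`).
#' @return list (one per state) of N x 3 matrices in hartree/bohr.
#' @export
state_gradients <- function(state_set, dH_components) {
  n_atoms <- length(dH_components)
  lapply(state_set$states, function(st) {
    g <- matrix(0, n_atoms, 3)
    for (a in seq_len(n_atoms)) for (ax in 1:3) {
      g[a, ax] <- expectation(st$statevector, dH_components[[a]][[ax]])
    }
    g
  })
}

#' Approximate nonadiabatic coupling vector between two states
#'
#' `d_ml(atom, axis) = <psi_m| dH/dR |psi_l> / (E_l - E_m)` -- the
#' Hellmann-Feynman-type approximation valid when both states are exact
#' eigenstates. Antisymmetric under m <-> l for real wavefunctions. Near
#' degeneracy (gap below `degeneracy_floor`) the 1/gap amplification is
#' unreliable: the vector is computed with the floor in the denominator
#' and flagged.
#'
#' @param state_m,state_l `variational_state`s.
#' @param dH_components derivative operators (`[[atom]][[axis]]`).
#' @param degeneracy_floor minimum energy gap (hartree, default 1e-6).
#' @return list with `vector` (N x 3 matrix, 1/bohr), `gap` (hartree,
#'   signed `E_l - E_m`) and `near_degenerate` flag.
#' @export
nac_vector <- function(state_m, state_l, dH_components,
                       degeneracy_floor = 1e-6) {
  gap <- state_l$energy - state_m$energy
  if (identical(state_m, state_l) || gap == 0) {
    stop("NAC undefined for identical states (zero gap)")
  }
  near <- abs(gap) < degeneracy_floor
  denom <- if (near) sign(gap) * degeneracy_floor else gap
  n_atoms <- length(dH_components)
  v <- matrix(0, n_atoms, 3)
  for (a in seq_len(n_atoms)) for (ax in 1:3) {
    v[a, ax] <- Re(transition_expectation(state_m$statevector,
                                          dH_components[[a]][[ax]],
                                          state_l$statevector)) / denom
  }
  list(vector = v, gap = gap, near_degenerate = near)
}

#' Transition dipole moment and oscillator strength
#'
#' `mu_ml = <psi_m|mu|psi_l>` over the active-space dipole operators, and
#' the length-gauge oscillator strength `f = (2/3) |dE| |mu|^2` in atomic
#' units.
#'
#' @param state_m,state_l distinct `variational_state`s.
#' @param dipole_ops list of 3 `qubit_operator`s from [dipole_operator()].
#' @return list with `dipole` (3-vector, a.u.), `f` (dimensionless),
#'   `gap` (hartree) and `degenerate` flag.
#' @export
transition_dipole_and_f <- function(state_m, state_l, dipole_ops) {
  de <- state_l$energy - state_m$energy
  mu <- vapply(dipole_ops, function(op)
    Re(transition_expectation(state_m$statevector, op, state_l$statevector)),
    numeric(1))
  list(dipole = mu, f = (2 / 3) * abs(de) * sum(mu^2), gap = de,
       degenerate = abs(de) < 1e-12)
}

#' Extract a CI-type expansion from a variational state
#'
#' Reads the determinant amplitudes off the Jordan-Wigner computational
#' basis (interleaved spin ordering), keeps coefficients with modulus
#' at or above `threshold`, and reports the retained norm. Together with
#' the MO matrix this is the portable wavefunction form used for
#' cross-geometry overlaps.
#'
#' @param state a `variational_state` (or bare statevector).
#' @param threshold amplitude cutoff in (0, 1), default 1e-6.
#' @param mo_matrix MO coefficient matrix of this geometry (optional,
#'   stored alongside).
#' @param norm_budget warn when the retained squared norm falls below
#'   this (default 0.999).
#' @return object of class `ci_expansion`: `alpha`/`beta` (lists of
#'   0-based occupied spatial-orbital index vectors), `coef`,
#'   `norm_retained`, `n_orbitals`, `mo_matrix`.
#' @export
extract_ci_expansion <- function(state, threshold = 1e-6, mo_matrix = NULL,
                                 norm_budget = 0.999) {
  stopifnot(threshold > 0, threshold < 1)
  psi <- if (inherits(state, "variational_state")) state$statevector else state
  n_qubits <- as.integer(round(log2(length(psi))))
  n_orb <- n_qubits %/% 2L
  keep <- which(Mod(psi) >= threshold)
  ord <- keep[order(-Mod(psi[keep]))]
  amask <- sum(bitwShiftL(1L, seq(0L, n_qubits - 1L, by = 2L)))
  alpha <- list(); beta <- list()
  for (i in seq_along(ord)) {
    b <- ord[i] - 1L
    occ_a <- integer(0); occ_b <- integer(0)
    for (p in seq_len(n_orb) - 1L) {
      if (bitwAnd(b, bitwShiftL(1L, 2L * p)) != 0L) occ_a <- c(occ_a, p)
      if (bitwAnd(b, bitwShiftL(1L, 2L * p + 1L)) != 0L) occ_b <- c(occ_b, p)
    }
    alpha[[i]] <- occ_a; beta[[i]] <- occ_b
  }
  retained <- sum(Mod(psi[ord])^2)
  if (retained < norm_budget) {
    warning(sprintf("CI expansion retains only %.6f of the norm", retained))
  }
  structure(list(alpha = alpha, beta = beta, coef = psi[ord],
                 norm_retained = retained, n_orbitals = n_orb,
                 mo_matrix = mo_matrix),
            class = "ci_expansion")
}

#' @export
print.ci_expansion <- function(x, max_dets = 8L, ...) {
  cat(sprintf("<ci_expansion: %d determinants, norm %.8f>\n",
              length(x$coef), x$norm_retained))
  n <- min(length(x$coef), max_dets)
  for (i in seq_len(n)) {
    occ <- rep("0", x$n_orbitals)
    for (p in x$alpha[[i]]) occ[p + 1] <- "a"
    for (p in x$beta[[i]]) {
      occ[p + 1] <- if (occ[p + 1] == "a") "2" else "b"
    }
    cat(sprintf("  |%s>  %s\n", paste(occ, collapse = ""),
                format(x$coef[i], digits = 6)))
  }
  if (length(x$coef) > n) cat(sprintf("  ... %d more\n", length(x$coef) - n))
  invisible(x)
}

#' Serialize CI expansions to a determinant table
#' @param exp a `ci_expansion`; @param path file path.
#' @export
write_ci_expansion <- function(exp, path) {
  lines <- vapply(seq_along(exp$coef), function(i) {
    occ <- rep("0", exp$n_orbitals)
    for (p in exp$alpha[[i]]) occ[p + 1] <- "a"
    for (p in exp$beta[[i]]) occ[p + 1] <- if (occ[p + 1] == "a") "2" else "b"
    sprintf("%s\t%.16e\t%.16e", paste(occ, collapse = ""),
            Re(exp$coef[i]), Im(exp$coef[i]))
  }, character(1))
  writeLines(c("determinant\tre\tim", lines), path)
}
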