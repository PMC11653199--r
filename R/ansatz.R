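# k-UpCCGSD ansatz: per layer, all generalized spin-adapted singles over
# spatial-orbital pairs p < q and all paired (same-spatial-orbital)
# doubles p -> q; k layers concatenated. The unitary is realized as an
# ordered product of exponentials of the Jordan-Wigner images of the
# anti-Hermitian generators, one Pauli rotation per term in a pinned
# lexicographic order (the terms of each generator commute, so the order
# is a convention, not an approximation).

# anti-Hermitian generator of the spin-adapted generalized single p -> q
.single_generator <- function(p, q, n_so) {
  terms <- list(); coef <- complex(0)
  for (sp in 0:1) {
    terms[[length(terms) + 1L]] <- list(modes = c(2L * q + sp, 2L * p + sp),
                                        dagger = c(TRUE, FALSE))
    coef <- c(coef, 1 + 0i)
    terms[[length(terms) + 1L]] <- list(modes = c(2L * p + sp, 2L * q + sp),
                                        dagger = c(TRUE, FALSE))
    coef <- c(coef, -1 + 0i)
  }
  fermion_operator(n_so, terms, coef)
}

# anti-Hermitian generator of the paired double (p alpha, p beta) ->
# (q alpha, q beta)
.paired_double_generator <- function(p, q, n_so) {
  fermion_operator(n_so, list(
    list(modes = c(2L * q, 2L * q + 1L, 2L * p + 1L, 2L * p),
         dagger = c(TRUE, TRUE, FALSE, FALSE)),
    list(modes = c(2L * p, 2L * p + 1L, 2L * q + 1L, 2L * q),
         dagger = c(TRUE, TRUE, FALSE, FALSE))),
    c(1 + 0i, -1 + 0i))
}

#' Build a k-UpCCGSD ansatz
#'
#' @param n_qubits number of qubits (= active spin orbitals).
#' @param n_electrons number of active electrons (even; the reference is
#'   the closed-shell determinant occupying the lowest spatial orbitals).
#' @param k number of layers.
#' @return an object of class `kupccgsd_ansatz` with the flattened
#'   rotation list, parameter labels and the reference determinant.
#' @export
build_kupccgsd <- function(n_qubits, n_electrons, k = 1L) {
  if (n_electrons %% 2L != 0L) {
    stop("k-UpCCGSD with paired doubles requires an even electron count")
  }
  stopifnot(k >= 1, n_qubits %% 2L == 0L, n_electrons <= n_qubits)
  n_orb <- n_qubits %/% 2L
  rotations <- list(); labels <- character(0)
  generators <- list()
  pidx <- 0L
  for (layer in seq_len(k)) {
    for (kind in c("S", "D")) {
      for (p in 0:(n_orb - 2L)) for (q in (p + 1L):(n_orb - 1L)) {
        gen <- if (kind == "S") .single_generator(p, q, n_qubits)
               else .paired_double_generator(p, q, n_qubits)
        gq <- jordan_wigner(gen)
        if (max(abs(Re(gq$coef))) > 1e-12) {
          stop("internal error: generator image not anti-Hermitian")
        }
        pidx <- pidx + 1L
        labels <- c(labels, sprintf("L%d_%s_%d_%d", layer, kind, p, q))
        ordw <- order(gq$x1, gq$z1)
        for (j in ordw) {
          rotations[[length(rotations) + 1L]] <-
            list(x = gq$x1[j], z = gq$z1[j], g = Im(gq$coef[j]), param = pidx)
        }
        generators[[pidx]] <- gq
      }
    }
  }
  ref <- bitwShiftL(1L, n_electrons) - 1L  # lowest spin orbitals occupied
  structure(list(n_qubits = as.integer(n_qubits),
                 n_electrons = as.integer(n_electrons), k = as.integer(k),
                 n_params = pidx, param_labels = labels,
                 rotations = rotations, generators = generators,
                 reference = ref),
            class = "kupccgsd_ansatz")
}

#' @export
print.kupccgsd_ansatz <- function(x, ...) {
  cat(sprintf("<k-UpCCGSD ansatz: %d qubits, %d electrons, k=%d, %d parameters>\n",
              x$n_qubits, x$n_electrons, x$k, x$n_params))
  invisible(x)
}

#' Reference determinant statevector of an ansatz
#' @param ansatz a `kupccgsd_ansatz`.
#' @export
reference_state <- function(ansatz) {
  psi <- complex(bitwShiftL(1L, ansatz$n_qubits))
  psi[ansatz$reference + 1L] <- 1 + 0i
  psi
}

# apply exp(i phi P) with P^2 = I: cos(phi) psi + i sin(phi) P psi
.apply_rotation <- function(psi, x, z, phi) {
  if (phi == 0) return(psi)
  cos(phi) * psi + 1i * sin(phi) * apply_pauli_word(psi, x, z)
}

#' Prepare the ansatz state for a parameter vector
#'
#' @param ansatz a `kupccgsd_ansatz`.
#' @param theta numeric parameter vector of length `ansatz$n_params`.
#' @return complex statevector of unit norm.
#' @export
prepare_state <- function(ansatz, theta) {
  if (length(theta) != ansatz$n_params) {
    stop("theta has length ", length(theta), ", ansatz expects ",
         ansatz$n_params)
  }
  psi <- reference_state(ansatz)
  for (rot in ansatz$rotations) {
    psi <- .apply_rotation(psi, rot$x, rot$z, theta[rot$param] * rot$g)
  }
  psi
}

# cost and analytic gradient by reverse (adjoint) sweep. The cost is
# <psi|H|psi> + sum_j lambda_j |<chi_j|psi>|^2; both pieces share the
# effective bra lam = H psi + sum_j lambda_j <chi_j|psi> chi_j, and
# d(cost)/d(phi_rot) = 2 Re <lam| i g P |psi_partial>.
.cost_and_gradient <- function(ansatz, theta, H, penalty_states = list(),
                               lambda = numeric(0), want_gradient = TRUE) {
  psi <- prepare_state(ansatz, theta)
  Hpsi <- apply_qop(H, psi)
  cost <- Re(sum(Conj(psi) * Hpsi))
  energy <- cost
  lam <- Hpsi
  for (j in seq_along(penalty_states)) {
    ov <- sum(Conj(penalty_states[[j]]) * psi)
    cost <- cost + lambda[j] * Mod(ov)^2
    lam <- lam + lambda[j] * ov * penalty_states[[j]]
  }
  if (!want_gradient) {
    return(list(cost = cost, energy = energy, psi = psi))
  }
  grad <- numeric(ansatz$n_params)
  phi <- psi
  for (j in rev(seq_along(ansatz$rotations))) {
    rot <- ansatz$rotations[[j]]
    ang <- theta[rot$param] * rot$g
    dpsi <- 1i * rot$g * apply_pauli_word(phi, rot$x, rot$z)
    grad[rot$param] <- grad[rot$param] + 2 * Re(sum(Conj(lam) * dpsi))
    phi <- .apply_rotation(phi, rot$x, rot$z, -ang)
    lam <- .apply_rotation(lam, rot$x, rot$z, -ang)
  }
  list(cost = cost, energy = energy, psi = psi, gradient = grad)
}
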