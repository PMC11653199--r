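# Statevector simulation. Basis index b encodes the computational state
# with qubit q stored in bit q (qubit 0 least significant); amplitudes are
# a complex vector of length 2^n indexed by b + 1.

.check_sv_qubits <- function(op) {
  if (any(op$x2 != 0L) || any(op$z2 != 0L) || op$n_qubits > 20) {
    stop("statevector operations support at most 20 qubits")
  }
}

#' Apply a single Pauli word to a statevector
#'
#' @param psi complex amplitude vector of length `2^n`.
#' @param x,z symplectic bit masks of the word (X on bits of `x`, Z on bits
#'   of `z`, Y where both are set).
#' @return the transformed amplitude vector.
#' @export
apply_pauli_word <- function(psi, x, z) {
  n <- length(psi)
  b <- 0:(n - 1L)
  ny <- .popcount(bitwAnd(x, z))
  glob <- c(1 + 0i, 1i, -1 + 0i, -1i)[(ny %% 4L) + 1L]
  sgn <- 1 - 2 * (.popcount(bitwAnd(z, b)) %% 2L)
  out <- complex(n)
  out[bitwXor(b, x) + 1L] <- glob * sgn * psi
  out
}

#' Apply a qubit operator to a statevector
#' @param op a `qubit_operator`; @param psi complex amplitude vector.
#' @export
apply_qop <- function(op, psi) {
  .check_sv_qubits(op)
  out <- complex(length(psi))
  for (i in seq_along(op$coef)) {
    out <- out + op$coef[i] * apply_pauli_word(psi, op$x1[i], op$z1[i])
  }
  out
}

#' Transition matrix element of a qubit operator
#'
#' Computes `<bra|op|ket>` (complex in general).
#'
#' @param bra,ket complex amplitude vectors; @param op a `qubit_operator`.
#' @export
transition_expectation <- function(bra, op, ket) {
  sum(Conj(bra) * apply_qop(op, ket))
}

#' Expectation value of a Hermitian qubit operator
#'
#' `sum_a w_a <psi|P_a|psi>`, guaranteed real for Hermitian input.
#'
#' @param psi complex amplitude vector; @param op a Hermitian
#'   `qubit_operator`.
#' @export
expectation <- function(psi, op) {
  if (!is_hermitian_qop(op)) stop("expectation requires a Hermitian operator")
  val <- transition_expectation(psi, op, psi)
  if (abs(Im(val)) > 1e-8) stop("expectation value not real: ", val)
  Re(val)
}

#' Dense matrix of a qubit operator
#' @param op a `qubit_operator` with at most 12 qubits.
#' @export
qop_matrix <- function(op) {
  .check_sv_qubits(op)
  if (op$n_qubits > 12) stop("dense matrix capped at 12 qubits")
  dim <- bitwShiftL(1L, op$n_qubits)
  b <- 0:(dim - 1L)
  M <- matrix(0 + 0i, dim, dim)
  for (i in seq_along(op$coef)) {
    x <- op$x1[i]; z <- op$z1[i]
    ny <- .popcount(bitwAnd(x, z))
    glob <- c(1 + 0i, 1i, -1 + 0i, -1i)[(ny %% 4L) + 1L]
    sgn <- 1 - 2 * (.popcount(bitwAnd(z, b)) %% 2L)
    M[cbind(bitwXor(b, x) + 1L, b + 1L)] <-
      M[cbind(bitwXor(b, x) + 1L, b + 1L)] + op$coef[i] * glob * sgn
  }
  M
}

# basis indices of the fixed particle-number / S_z sector; alpha spin
# orbitals sit on even qubits, beta on odd (interleaved convention)
.sector_indices <- function(n_qubits, n_electrons, sz2 = 0L) {
  b <- 0:(bitwShiftL(1L, n_qubits) - 1L)
  amask <- sum(bitwShiftL(1L, seq(0L, n_qubits - 1L, by = 2L)))
  bmask <- sum(bitwShiftL(1L, seq(1L, n_qubits - 1L, by = 2L)))
  na <- .popcount(bitwAnd(b, as.integer(amask)))
  nb <- .popcount(bitwAnd(b, as.integer(bmask)))
  b[na + nb == n_electrons & (na - nb) == sz2]
}

#' Total-spin operator S^2 as a qubit operator
#'
#' Built from the Jordan-Wigner images of `S+`, `S-` and `Sz` under the
#' interleaved spin-orbital ordering; `S^2 = S+ S- + Sz^2 - Sz`. Useful
#' for classifying oracle eigenvectors by spin symmetry.
#'
#' @param n_qubits number of qubits (even).
#' @export
s_squared_qop <- function(n_qubits) {
  n_orb <- n_qubits %/% 2L
  terms_p <- lapply(seq_len(n_orb) - 1L, function(p)
    list(modes = c(2L * p, 2L * p + 1L), dagger = c(TRUE, FALSE)))
  Sp <- jordan_wigner(fermion_operator(n_qubits, terms_p,
                                       rep(1 + 0i, n_orb)))
  terms_m <- lapply(seq_len(n_orb) - 1L, function(p)
    list(modes = c(2L * p + 1L, 2L * p), dagger = c(TRUE, FALSE)))
  Sm <- jordan_wigner(fermion_operator(n_qubits, terms_m,
                                       rep(1 + 0i, n_orb)))
  terms_z <- unlist(lapply(seq_len(n_orb) - 1L, function(p) list(
    list(modes = c(2L * p, 2L * p), dagger = c(TRUE, FALSE)),
    list(modes = c(2L * p + 1L, 2L * p + 1L), dagger = c(TRUE, FALSE)))),
    recursive = FALSE)
  Sz <- jordan_wigner(fermion_operator(n_qubits, terms_z,
                                       rep(c(0.5 + 0i, -0.5 + 0i), n_orb)))
  qop_add(qop_add(qop_mul(Sp, Sm), qop_mul(Sz, Sz)), qop_scale(Sz, -1))
}

#' Exact eigenvalues of a qubit Hamiltonian (dense oracle)
#'
#' Dense diagonalization, optionally restricted to the particle-number and
#' S_z sector of a reference determinant. Used as the independent oracle
#' against which variational energies are validated.
#'
#' @param H a Hermitian `qubit_operator` with at most 12 qubits.
#' @param n number of lowest eigenvalues to return.
#' @param n_electrons if non-NULL, restrict to this electron count.
#' @param sz2 twice the spin projection (default 0).
#' @return list with `values` (ascending), `vectors` (columns, embedded in
#'   the full 2^n space) and `basis` (basis indices of the sector).
#' @export
exact_spectrum <- function(H, n = 1L, n_electrons = NULL, sz2 = 0L) {
  M <- qop_matrix(H)
  dim <- nrow(M)
  if (is.null(n_electrons)) {
    sub <- 0:(dim - 1L)
  } else {
    sub <- .sector_indices(H$n_qubits, n_electrons, sz2)
  }
  Ms <- M[sub + 1L, sub + 1L, drop = FALSE]
  e <- eigen(Ms, symmetric = TRUE)
  ord <- order(e$values)
  k <- min(n, length(sub))
  vals <- e$values[ord][seq_len(k)]
  vecs <- matrix(0 + 0i, dim, k)
  for (j in seq_len(k)) vecs[sub + 1L, j] <- e$vectors[, ord[j]]
  list(values = vals, vectors = vecs, basis = sub)
}
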