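# Second-quantized fermionic operators over spin orbitals (modes).
#
# Mode ordering is interleaved: alpha spin of spatial orbital p sits on
# mode 2p, beta on mode 2p+1 (0-based). A term is an ordered product of
# creation/annihilation operators; the operator is a weighted sum of terms.

#' Construct a fermionic operator
#'
#' @param n_modes number of spin orbitals.
#' @param terms list of terms; each term is a list with integer vector
#'   `modes` (0-based) and logical vector `dagger` of equal length. A term
#'   with zero operators is a constant.
#' @param coef complex coefficients, one per term.
#' @return an object of class `fermion_operator`.
#' @export
fermion_operator <- function(n_modes, terms = list(), coef = complex()) {
  stopifnot(length(terms) == length(coef))
  structure(list(n_modes = as.integer(n_modes), terms = terms,
                 coef = as.complex(coef)),
            class = "fermion_operator")
}

#' @export
print.fermion_operator <- function(x, max_terms = 10L, ...) {
  cat(sprintf("<fermion_operator: %d modes, %d terms>\n",
              x$n_modes, length(x$coef)))
  n <- min(length(x$coef), max_terms)
  for (i in seq_len(n)) {
    t <- x$terms[[i]]
    ops <- if (length(t$modes) == 0) "1" else
      paste(sprintf("a%s_%d", ifelse(t$dagger, "+", ""), t$modes), collapse = " ")
    cat(sprintf("  %s  %s\n", format(x$coef[i], digits = 8), ops))
  }
  if (length(x$coef) > n) cat(sprintf("  ... %d more\n", length(x$coef) - n))
  invisible(x)
}

#' Adjoint of a fermionic operator
#' @param op a `fermion_operator`.
#' @export
fermion_adjoint <- function(op) {
  op$terms <- lapply(op$terms, function(t)
    list(modes = rev(t$modes), dagger = rev(!t$dagger)))
  op$coef <- Conj(op$coef)
  op
}

#' Second-quantized electronic Hamiltonian from active-space integrals
#'
#' Assembles `sum h_rs a+_r a_s + 1/2 sum g_pqrs a+_p a+_q a_s a_r` plus the
#' constant core energy (nuclear repulsion + frozen-core contribution), all
#' in spin-orbital form.
#'
#' @param integrals a `spin_orbital_integrals` object (see
#'   [spin_orbital_integrals()]).
#' @param tol integrals with modulus below `tol` are skipped.
#' @return a `fermion_operator`.
#' @export
second_quantized_hamiltonian <- function(integrals, tol = 1e-14) {
  h <- integrals$h; g <- integrals$g
  n <- integrals$n_spin_orbitals
  if (max(abs(h - Conj(t(h)))) > 1e-10) stop("one-electron matrix is not Hermitian")
  terms <- list(); coef <- complex(0)
  terms[[1]] <- list(modes = integer(0), dagger = logical(0))
  coef[1] <- integrals$core_energy
  idx <- which(abs(h) > tol, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; s <- idx[i, 2]
    terms[[length(terms) + 1]] <- list(modes = c(r - 1L, s - 1L),
                                       dagger = c(TRUE, FALSE))
    coef <- c(coef, h[r, s])
  }
  idx4 <- which(abs(g) > tol)
  if (length(idx4)) {
    ai <- arrayInd(idx4, dim(g))
    cf <- g[idx4] / 2
    for (i in seq_along(idx4)) {
      p <- ai[i, 1]; q <- ai[i, 2]; r <- ai[i, 3]; s <- ai[i, 4]
      if (p == q || r == s) next   # a+a+ or aa on the same mode vanishes
      terms[[length(terms) + 1]] <- list(modes = c(p - 1L, q - 1L, s - 1L, r - 1L),
                                         dagger = c(TRUE, TRUE, FALSE, FALSE))
      coef <- c(coef, cf[i])
    }
  }
  fermion_operator(n, terms, coef)
}

#' Dense matrix of a fermionic operator in the occupation-number basis
#'
#' Built directly from ladder-operator algebra on occupation bitstrings
#' (bit q of the basis index = occupation of mode q), independent of any
#' Pauli-algebra code path; serves as the brute-force oracle for the
#' Jordan-Wigner transformation.
#'
#' @param op a `fermion_operator` with `n_modes <= 14`.
#' @return a dense complex matrix of dimension `2^n_modes`.
#' @export
fermion_matrix <- function(op) {
  n <- op$n_modes
  stopifnot(n <= 14)
  dim <- bitwShiftL(1L, n)
  M <- matrix(0 + 0i, dim, dim)
  b0 <- 0:(dim - 1L)
  for (i in seq_along(op$coef)) {
    t <- op$terms[[i]]
    b <- b0; sgn <- rep(1, dim); alive <- rep(TRUE, dim)
    # operators act right-to-left
    for (j in rev(seq_along(t$modes))) {
      p <- t$modes[j]; bit <- bitwShiftL(1L, p); below <- bit - 1L
      occ <- bitwAnd(b, bit) != 0L
      if (t$dagger[j]) { alive <- alive & !occ } else { alive <- alive & occ }
      sgn <- sgn * (1 - 2 * (.popcount(bitwAnd(b, below)) %% 2L))
      b <- bitwXor(b, bit)
    }
    if (length(t$modes) == 0) {
      M <- M + diag(rep(op$coef[i], dim))
    } else if (any(alive)) {
      src <- which(alive)
      M[cbind(b[src] + 1L, src)] <- M[cbind(b[src] + 1L, src)] +
        op$coef[i] * sgn[src]
    }
  }
  M
}
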