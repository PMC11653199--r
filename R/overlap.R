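# Cross-timestep wavefunction overlaps from CI expansions, and Loewdin
# orthonormalization of the resulting matrix.

#' Overlap of two Slater determinants across geometries
#'
#' Determinant of the occupied-orbital submatrix of the MO cross-overlap,
#' factorized over spin blocks (alpha and beta determinants multiply).
#' Determinants with mismatched per-spin electron counts overlap to zero
#' by convention.
#'
#' @param alpha_bra,beta_bra 0-based occupied spatial orbitals of the bra.
#' @param alpha_ket,beta_ket same for the ket.
#' @param mo_cross_overlap MO-basis overlap matrix between the bra and
#'   ket geometries (rows: bra MOs, columns: ket MOs).
#' @export
determinant_pair_overlap <- function(alpha_bra, beta_bra, alpha_ket,
                                     beta_ket, mo_cross_overlap) {
  if (length(alpha_bra) != length(alpha_ket) ||
      length(beta_bra) != length(beta_ket)) {
    return(0)
  }
  da <- if (length(alpha_bra) == 0) 1 else
    det(mo_cross_overlap[alpha_bra + 1L, alpha_ket + 1L, drop = FALSE])
  db <- if (length(beta_bra) == 0) 1 else
    det(mo_cross_overlap[beta_bra + 1L, beta_ket + 1L, drop = FALSE])
  da * db
}

#' CI wavefunction overlap matrix between two time steps
#'
#' `S_ml = <psi_m(t)|psi_l(t + dt)> = sum_ij c_i^(m)* c_j^(l) <D_i|D_j>`
#' with determinant-pair overlaps evaluated through the MO cross-overlap
#' and cached across state pairs.
#'
#' @param expansions_bra,expansions_ket lists of `ci_expansion`s (one per
#'   state) at the earlier/later geometry.
#' @param mo_cross_overlap MO cross-overlap matrix between the two
#'   geometries.
#' @return real matrix `S` with attribute `"truncation_warning"` when a
#'   truncated expansion fell below its norm budget.
#' @export
ci_overlap_matrix <- function(expansions_bra, expansions_ket,
                              mo_cross_overlap) {
  nb <- length(expansions_bra); nk <- length(expansions_ket)
  no <- unique(c(vapply(expansions_bra, function(e) e$n_orbitals, integer(1)),
                 vapply(expansions_ket, function(e) e$n_orbitals, integer(1))))
  if (length(no) != 1) stop("expansions span different active spaces")
  cache <- new.env(hash = TRUE, parent = emptyenv())
  pair_ov <- function(ea, i, eb, j) {
    key <- paste(paste(ea$alpha[[i]], collapse = ","),
                 paste(ea$beta[[i]], collapse = ","),
                 paste(eb$alpha[[j]], collapse = ","),
                 paste(eb$beta[[j]], collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- determinant_pair_overlap(ea$alpha[[i]], ea$beta[[i]],
                                      eb$alpha[[j]], eb$beta[[j]],
                                      mo_cross_overlap)
      cache[[key]] <- val
    }
    val
  }
  S <- matrix(0, nb, nk)
  warn <- FALSE
  for (m in seq_len(nb)) {
    ea <- expansions_bra[[m]]
    if (ea$norm_retained < 0.999) warn <- TRUE
    for (l in seq_len(nk)) {
      eb <- expansions_ket[[l]]
      acc <- 0 + 0i
      for (i in seq_along(ea$coef)) for (j in seq_along(eb$coef)) {
        acc <- acc + Conj(ea$coef[i]) * eb$coef[j] * pair_ov(ea, i, eb, j)
      }
      S[m, l] <- Re(acc)
    }
  }
  if (any(vapply(expansions_ket, function(e) e$norm_retained < 0.999,
                 logical(1)))) warn <- TRUE
  attr(S, "truncation_warning") <- warn
  S
}

#' Loewdin orthonormalization
#'
#' `T = S (S^T S)^(-1/2)`: the closest orthogonal matrix to `S` in the
#' Frobenius norm. Singular or nearly singular input (smallest singular
#' value below `singular_tol`) indicates that a state left the tracked
#' space between steps (trivial-crossing pathology) and raises an error
#' naming the most affected state.
#'
#' @param S square overlap matrix.
#' @param singular_tol smallest allowed singular value (default 1e-6).
#' @export
lowdin_orthonormalize <- function(S, singular_tol = 1e-6) {
  stopifnot(nrow(S) == ncol(S))
  sv <- svd(S)
  if (min(sv$d) < singular_tol) {
    worst <- which.max(abs(sv$v[, which.min(sv$d)]))
    stop(sprintf(paste0("overlap matrix singular (smallest singular value ",
                        "%.3e): state %d lost between steps ",
                        "(trivial crossing?)"), min(sv$d), worst))
  }
  sv$u %*% t(sv$v)
}
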