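# Jordan-Wigner transformation: a+_p -> (X_p - iY_p)/2 * Z_0..Z_{p-1},
# a_p -> (X_p + iY_p)/2 * Z_0..Z_{p-1}; occupation 1 maps to qubit state |1>.

# bit mask of mode p split over the two 30-bit halves (vectorized over p)
.mode_bit <- function(p) {
  lo <- ifelse(p < 30L, bitwShiftL(1L, pmin(p, 29L)), 0L)
  hi <- ifelse(p >= 30L, bitwShiftL(1L, pmax(p - 30L, 0L)), 0L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# mask of all modes strictly below p
.below_mask <- function(p) {
  lo <- ifelse(p <= 30L, bitwShiftL(1L, pmin(p, 30L)) - 1L, bitwShiftL(1L, 30L) - 1L)
  hi <- ifelse(p > 30L, bitwShiftL(1L, pmax(p - 30L, 0L)) - 1L, 0L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Jordan-Wigner transformation of a fermionic operator
#'
#' Maps each ladder operator to its Pauli-string image with a Z parity
#' chain on all lower modes, expands the products, and merges duplicate
#' words. Hermitian input yields Hermitian output.
#'
#' @param op a `fermion_operator`.
#' @param n_qubits number of qubits of the image (default `op$n_modes`).
#' @param tol coefficient pruning tolerance (default 1e-12).
#' @return a `qubit_operator`.
#' @export
jordan_wigner <- function(op, n_qubits = op$n_modes, tol = 1e-12) {
  if (max(vapply(op$terms, function(t) if (length(t$modes)) max(t$modes) else -1L,
                 integer(1)), -1L) >= n_qubits) {
    stop("mode index exceeds n_qubits")
  }
  lens <- vapply(op$terms, function(t) length(t$modes), integer(1))
  out_x1 <- out_x2 <- out_z1 <- out_z2 <- integer(0)
  out_c <- complex(0)
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    if (L == 0L) {
      out_x1 <- c(out_x1, integer(length(sel)))
      out_x2 <- c(out_x2, integer(length(sel)))
      out_z1 <- c(out_z1, integer(length(sel)))
      out_z2 <- c(out_z2, integer(length(sel)))
      out_c <- c(out_c, op$coef[sel])
      next
    }
    modes <- matrix(0L, length(sel), L)
    dag <- matrix(FALSE, length(sel), L)
    for (k in seq_along(sel)) {
      modes[k, ] <- op$terms[[sel[k]]]$modes
      dag[k, ] <- op$terms[[sel[k]]]$dagger
    }
    for (branch in 0:(bitwShiftL(1L, L) - 1L)) {
      x1 <- x2 <- z1 <- z2 <- integer(length(sel))
      cf <- op$coef[sel]
      for (j in seq_len(L)) {
        p <- modes[, j]
        ybranch <- bitwAnd(bitwShiftR(branch, j - 1L), 1L) == 1L
        mb <- .mode_bit(p); bm <- .below_mask(p)
        fx1 <- mb$lo; fx2 <- mb$hi
        if (ybranch) {
          fz1 <- bitwOr(bm$lo, mb$lo); fz2 <- bitwOr(bm$hi, mb$hi)
          fc <- ifelse(dag[, j], -0.5i, 0.5i)
        } else {
          fz1 <- bm$lo; fz2 <- bm$hi
          fc <- rep(0.5 + 0i, length(p))
        }
        pr <- .pmul(x1, x2, z1, z2, cf, fx1, fx2, fz1, fz2, fc)
        x1 <- pr$x1; x2 <- pr$x2; z1 <- pr$z1; z2 <- pr$z2; cf <- pr$coef
      }
      out_x1 <- c(out_x1, x1); out_x2 <- c(out_x2, x2)
      out_z1 <- c(out_z1, z1); out_z2 <- c(out_z2, z2)
      out_c <- c(out_c, cf)
    }
  }
  qop_collect(new_qop(n_qubits, out_x1, out_x2, out_z1, out_z2, out_c), tol)
}

#' Jordan-Wigner transform of homogeneous term groups (fast path)
#'
#' Vectorized variant of [jordan_wigner()] for operators given as groups
#' of terms sharing one creation/annihilation pattern, e.g. all
#' `a+_p a_q` or all `a+_p a+_q a_s a_r`. Used for large structural
#' Hamiltonians where the list-of-terms representation is too slow.
#'
#' @param groups list of groups; each group is a list with `modes`
#'   (n_terms x L integer matrix, 0-based, operators left to right),
#'   `dagger` (length-L logical pattern shared by the group's terms) and
#'   `coef` (complex vector).
#' @param n_qubits qubit count of the image.
#' @param tol pruning tolerance.
#' @return a `qubit_operator`.
#' @export
jordan_wigner_terms <- function(groups, n_qubits, tol = 1e-12) {
  out_x1 <- out_x2 <- out_z1 <- out_z2 <- list()
  out_c <- list(); gi <- 0L
  for (grp in groups) {
    modes <- grp$modes; dag <- grp$dagger; L <- length(dag)
    if (L == 0L) {
      gi <- gi + 1L
      nsel <- length(grp$coef)
      out_x1[[gi]] <- integer(nsel); out_x2[[gi]] <- integer(nsel)
      out_z1[[gi]] <- integer(nsel); out_z2[[gi]] <- integer(nsel)
      out_c[[gi]] <- grp$coef
      next
    }
    keep <- rep(TRUE, nrow(modes))
    # a+a+ or aa on identical modes annihilates the term
    for (j1 in seq_len(L - 1)) for (j2 in (j1 + 1):L) {
      if (dag[j1] == dag[j2]) keep <- keep & modes[, j1] != modes[, j2]
    }
    modes <- modes[keep, , drop = FALSE]
    cf0 <- grp$coef[keep]
    if (nrow(modes) == 0) next
    mb <- lapply(seq_len(L), function(j) .mode_bit(modes[, j]))
    bm <- lapply(seq_len(L), function(j) .below_mask(modes[, j]))
    for (branch in 0:(bitwShiftL(1L, L) - 1L)) {
      x1 <- x2 <- z1 <- z2 <- integer(nrow(modes))
      cf <- cf0
      for (j in seq_len(L)) {
        ybranch <- bitwAnd(bitwShiftR(branch, j - 1L), 1L) == 1L
        fx1 <- mb[[j]]$lo; fx2 <- mb[[j]]$hi
        if (ybranch) {
          fz1 <- bitwOr(bm[[j]]$lo, mb[[j]]$lo)
          fz2 <- bitwOr(bm[[j]]$hi, mb[[j]]$hi)
          fc <- if (dag[j]) -0.5i else 0.5i
        } else {
          fz1 <- bm[[j]]$lo; fz2 <- bm[[j]]$hi
          fc <- 0.5 + 0i
        }
        pr <- .pmul(x1, x2, z1, z2, cf, fx1, fx2, fz1, fz2, fc)
        x1 <- pr$x1; x2 <- pr$x2; z1 <- pr$z1; z2 <- pr$z2; cf <- pr$coef
      }
      gi <- gi + 1L
      out_x1[[gi]] <- x1; out_x2[[gi]] <- x2
      out_z1[[gi]] <- z1; out_z2[[gi]] <- z2
      out_c[[gi]] <- cf
    }
  }
  qop_collect(new_qop(n_qubits,
                      unlist(out_x1), unlist(out_x2),
                      unlist(out_z1), unlist(out_z2),
                      unlist(out_c)), tol)
}

#' Sparse spin-orbital term groups from spatial integrals
#'
#' Expands spatial chemist-notation integrals directly into the
#' homogeneous term groups consumed by [jordan_wigner_terms()], without
#' materializing the dense spin-orbital tensor.
#'
#' @param h1 spatial one-electron matrix.
#' @param eri spatial two-electron array `(pq|rs)`.
#' @param core_energy constant term.
#' @return list of term groups.
#' @export
expand_spatial_integrals_sparse <- function(h1, eri, core_energy = 0) {
  groups <- list()
  if (core_energy != 0) {
    groups[[length(groups) + 1L]] <-
      list(modes = matrix(integer(0), 1, 0), dagger = logical(0),
           coef = as.complex(core_energy))
  }
  nz1 <- which(abs(h1) > 0, arr.ind = TRUE)
  if (nrow(nz1)) {
    p <- rep(nz1[, 1] - 1L, each = 2L); q <- rep(nz1[, 2] - 1L, each = 2L)
    sp <- rep(0:1, times = nrow(nz1))
    groups[[length(groups) + 1L]] <-
      list(modes = cbind(2L * p + sp, 2L * q + sp),
           dagger = c(TRUE, FALSE),
           coef = as.complex(rep(h1[nz1], each = 2L)))
  }
  nz2 <- which(abs(eri) > 0, arr.ind = TRUE)
  if (nrow(nz2)) {
    m <- nrow(nz2)
    p <- rep(nz2[, 1] - 1L, each = 4L); q <- rep(nz2[, 2] - 1L, each = 4L)
    r <- rep(nz2[, 3] - 1L, each = 4L); s <- rep(nz2[, 4] - 1L, each = 4L)
    sig <- rep(c(0L, 0L, 1L, 1L), times = m)
    tau <- rep(c(0L, 1L, 0L, 1L), times = m)
    # 1/2 (pq|rs) a+_{p sig} a+_{r tau} a_{s tau} a_{q sig}
    groups[[length(groups) + 1L]] <-
      list(modes = cbind(2L * p + sig, 2L * r + tau, 2L * s + tau, 2L * q + sig),
           dagger = c(TRUE, TRUE, FALSE, FALSE),
           coef = as.complex(rep(eri[nz2] / 2, each = 4L)))
  }
  groups
}
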