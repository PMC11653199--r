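# Measurement grouping of Pauli strings.
#
# Two counters are provided because the literature uses "native bases"
# loosely: count_pauli_strings() counts the distinct Pauli words (one
# measurement circuit per string, identity included as the constant term),
# while count_native_pauli_bases() merges words qubit-wise (two words share
# a basis iff on every qubit their factors are equal or one is identity).
# Clique grouping uses full (not merely qubit-wise) commutation.

# do words a and b commute as operators? (symplectic criterion)
.words_commute <- function(ax1, ax2, az1, az2, bx1, bx2, bz1, bz2) {
  p <- .popcount(bitwAnd(ax1, bz1)) + .popcount(bitwAnd(ax2, bz2)) +
       .popcount(bitwAnd(az1, bx1)) + .popcount(bitwAnd(az2, bx2))
  p %% 2L == 0L
}

# deterministic processing order: Pauli weight descending, then
# lexicographic on the symplectic masks; identity words dropped
.nonidentity_order <- function(op, weight_first = TRUE) {
  nid <- which(op$x1 != 0L | op$x2 != 0L | op$z1 != 0L | op$z2 != 0L)
  w <- .popcount(bitwOr(op$x1[nid], op$z1[nid])) +
       .popcount(bitwOr(op$x2[nid], op$z2[nid]))
  if (weight_first) nid[order(-w, op$x1[nid], op$x2[nid], op$z1[nid], op$z2[nid])]
  else nid[order(op$x1[nid], op$x2[nid], op$z1[nid], op$z2[nid])]
}

#' Count native measurement bases by qubit-wise merging
#'
#' Greedily merges the non-constant Pauli words of `op` into measurement
#' bases: a word fits an existing basis iff on every qubit its factor
#' equals the basis factor or one of the two is the identity. Merging is
#' first-fit over words in a fixed deterministic order, so the result is
#' reproducible.
#'
#' @param op a Hermitian `qubit_operator`.
#' @return integer number of bases.
#' @export
count_native_pauli_bases <- function(op) {
  ord <- .nonidentity_order(op, weight_first = FALSE)
  bx1 <- bx2 <- bz1 <- bz2 <- integer(0)
  for (i in ord) {
    wx1 <- op$x1[i]; wx2 <- op$x2[i]; wz1 <- op$z1[i]; wz2 <- op$z2[i]
    fit <- 0L
    if (length(bx1)) {
      # conflict on a qubit where both are non-identity and letters differ
      both1 <- bitwAnd(bitwOr(wx1, wz1), bitwOr(bx1, bz1))
      both2 <- bitwAnd(bitwOr(wx2, wz2), bitwOr(bx2, bz2))
      diff1 <- bitwOr(bitwXor(wx1, bx1), bitwXor(wz1, bz1))
      diff2 <- bitwOr(bitwXor(wx2, bx2), bitwXor(wz2, bz2))
      ok <- bitwAnd(both1, diff1) == 0L & bitwAnd(both2, diff2) == 0L
      if (any(ok)) fit <- which(ok)[1L]
    }
    if (fit > 0L) {
      bx1[fit] <- bitwOr(bx1[fit], wx1); bx2[fit] <- bitwOr(bx2[fit], wx2)
      bz1[fit] <- bitwOr(bz1[fit], wz1); bz2[fit] <- bitwOr(bz2[fit], wz2)
    } else {
      bx1 <- c(bx1, wx1); bx2 <- c(bx2, wx2)
      bz1 <- c(bz1, wz1); bz2 <- c(bz2, wz2)
    }
  }
  length(bx1)
}

#' Group Pauli strings into mutually commuting cliques
#'
#' Partitions the non-constant Pauli words of `op` into cliques in which
#' every pair commutes as operators (full commutation). Greedy first-fit
#' over words ordered by Pauli weight (descending, ties broken
#' lexicographically) -- seedless and deterministic.
#'
#' @param op a Hermitian `qubit_operator`.
#' @return list of integer vectors, each indexing the terms of `op` that
#'   form one clique.
#' @export
group_commuting_cliques <- function(op) {
  ord <- .nonidentity_order(op, weight_first = TRUE)
  n <- length(ord)
  # clique storage: preallocated member arrays, grown geometrically
  cl_x1 <- list(); cl_x2 <- list(); cl_z1 <- list(); cl_z2 <- list()
  members <- list(); sizes <- integer(0)
  # up to 4 representative members per clique for the vectorized
  # pre-filter (padded by repetition while the clique is small)
  nrep <- 4L
  rep_x1 <- rep_x2 <- rep_z1 <- rep_z2 <- matrix(0L, nrep, n)
  for (i in ord) {
    wx1 <- op$x1[i]; wx2 <- op$x2[i]; wz1 <- op$z1[i]; wz2 <- op$z2[i]
    placed <- FALSE
    if (length(sizes)) {
      # cheap pre-filter: a word can only join a clique if it commutes
      # with the clique's representative members (vectorized across
      # cliques)
      ncl <- length(sizes)
      okrep <- rep(TRUE, ncl)
      for (k in seq_len(nrep)) {
        okrep <- okrep & .words_commute(rep_x1[k, seq_len(ncl)],
                                        rep_x2[k, seq_len(ncl)],
                                        rep_z1[k, seq_len(ncl)],
                                        rep_z2[k, seq_len(ncl)],
                                        wx1, wx2, wz1, wz2)
      }
      cand <- which(okrep)
      # probe large cliques first (ties by creation order): the bulk of
      # the words lands within the first few probes
      for (ci in cand[order(-sizes[cand])]) {
        s <- sizes[ci]
        # scan members in chunks with early exit: failing probes usually
        # meet an anticommuting member quickly
        fits <- TRUE
        start <- 1L
        while (start <= s) {
          end <- min(start + 15L, s)
          rng <- start:end
          if (!all(.words_commute(cl_x1[[ci]][rng], cl_x2[[ci]][rng],
                                  cl_z1[[ci]][rng], cl_z2[[ci]][rng],
                                  wx1, wx2, wz1, wz2))) {
            fits <- FALSE
            break
          }
          start <- end + 1L
        }
        if (fits) {
          if (s == length(cl_x1[[ci]])) {  # grow
            grow <- max(2L * s, 8L)
            length(cl_x1[[ci]]) <- grow; length(cl_x2[[ci]]) <- grow
            length(cl_z1[[ci]]) <- grow; length(cl_z2[[ci]]) <- grow
            length(members[[ci]]) <- grow
          }
          cl_x1[[ci]][s + 1L] <- wx1; cl_x2[[ci]][s + 1L] <- wx2
          cl_z1[[ci]][s + 1L] <- wz1; cl_z2[[ci]][s + 1L] <- wz2
          members[[ci]][s + 1L] <- i
          sizes[ci] <- s + 1L
          if (s < nrep) {
            rep_x1[s + 1L, ci] <- wx1; rep_x2[s + 1L, ci] <- wx2
            rep_z1[s + 1L, ci] <- wz1; rep_z2[s + 1L, ci] <- wz2
          }
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      k <- length(sizes) + 1L
      cl_x1[[k]] <- wx1; cl_x2[[k]] <- wx2
      cl_z1[[k]] <- wz1; cl_z2[[k]] <- wz2
      members[[k]] <- i; sizes[k] <- 1L
      rep_x1[, k] <- wx1; rep_x2[, k] <- wx2
      rep_z1[, k] <- wz1; rep_z2[, k] <- wz2
    }
  }
  lapply(seq_along(members), function(ci) members[[ci]][seq_len(sizes[ci])])
}
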