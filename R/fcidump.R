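# FCIDUMP (Molpro dialect) I/O and spatial -> spin-orbital expansion.
#
# The file carries spatial-orbital integrals in chemist notation (ij|kl)
# with 1-based indices and 8-fold permutational symmetry; records with
# k = l = 0 are one-electron h_ij, the all-zero-index record is the core
# (nuclear repulsion + frozen core) energy.

#' Spin-orbital integral container
#'
#' Holds the one-electron matrix `h` (hartree), the two-electron tensor
#' `g` indexed so that the Hamiltonian is
#' `sum h_rs a+_r a_s + 1/2 sum g_pqrs a+_p a+_q a_s a_r`, and the constant
#' `core_energy` (nuclear repulsion plus any frozen-core contribution).
#' Spin orbitals are interleaved: alpha of spatial orbital p at index
#' 2p, beta at 2p+1 (0-based).
#'
#' @param h complex/numeric Hermitian matrix, n x n.
#' @param g numeric 4-index array, n^4.
#' @param core_energy scalar (hartree).
#' @return an object of class `spin_orbital_integrals`.
#' @export
spin_orbital_integrals <- function(h, g, core_energy = 0) {
  n <- nrow(h)
  stopifnot(ncol(h) == n, all(dim(g) == n), n %% 2L == 0L)
  if (max(abs(h - Conj(t(h)))) > 1e-10) stop("h must be Hermitian")
  structure(list(h = h, g = g, core_energy = core_energy,
                 n_spin_orbitals = as.integer(n)),
            class = "spin_orbital_integrals")
}

#' Expand spatial-orbital integrals to spin orbitals
#'
#' Converts chemist-notation spatial integrals `(pq|rs)` to the
#' spin-orbital tensor of [spin_orbital_integrals()] under the interleaved
#' alpha/beta ordering.
#'
#' @param h1 spatial one-electron matrix (n_orb x n_orb).
#' @param eri spatial two-electron array `(pq|rs)`, chemist notation.
#' @param core_energy scalar constant.
#' @return a `spin_orbital_integrals` object.
#' @export
expand_spatial_integrals <- function(h1, eri, core_energy = 0) {
  n <- nrow(h1); ns <- 2L * n
  h <- matrix(0, ns, ns)
  for (sp in 0:1) {
    h[cbind(rep(2 * seq_len(n) - 2L + sp + 1L, each = n),
            rep(2 * seq_len(n) - 2L + sp + 1L, times = n))] <- t(h1)
  }
  g <- array(0, dim = rep(ns, 4))
  # H2e = 1/2 sum_{pqrs, sig, tau} (pq|rs) a+_{p sig} a+_{r tau} a_{s tau} a_{q sig}
  # so g[p sig, r tau, q sig, s tau] accumulates (pq|rs)
  nz <- which(abs(eri) > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    p <- nz[i, 1]; q <- nz[i, 2]; r <- nz[i, 3]; s <- nz[i, 4]
    v <- eri[p, q, r, s]
    for (sig in 0:1) for (tau in 0:1) {
      g[2 * p - 1L + sig, 2 * r - 1L + tau, 2 * q - 1L + sig, 2 * s - 1L + tau] <-
        g[2 * p - 1L + sig, 2 * r - 1L + tau, 2 * q - 1L + sig, 2 * s - 1L + tau] + v
    }
  }
  spin_orbital_integrals(h, g, core_energy)
}

#' Read an FCIDUMP file
#'
#' Parses the Molpro FCIDUMP dialect, restores the 8-fold permutational
#' symmetry of the two-electron integrals, and expands to spin orbitals.
#'
#' @param path file path.
#' @return a `spin_orbital_integrals` object; the spatial data (list with
#'   `h1`, `eri`, `core_energy`, `n_orb`, `n_electrons`, `ms2`, `orbsym`)
#'   is attached as attribute `"spatial"`.
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  hdr_end <- grep("&END|/", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP header: no &END in ", path)
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  getval <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), hdr))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  norb <- getval("NORB"); nelec <- getval("NELEC"); ms2 <- getval("MS2")
  if (is.na(norb)) stop("malformed FCIDUMP header: NORB missing in ", path)
  osm <- regmatches(hdr, regexec("ORBSYM\\s*=\\s*([0-9, ]+)", hdr))[[1]]
  orbsym <- if (length(osm) >= 2) {
    as.integer(strsplit(gsub("\\s", "", osm[2]), ",")[[1]])
  } else NULL
  h1 <- matrix(0, norb, norb)
  eri <- array(0, dim = rep(norb, 4))
  core <- 0
  for (ln in lines[-seq_len(hdr_end)]) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 5) stop("malformed FCIDUMP record: '", ln, "'")
    v <- as.numeric(parts[1]); ix <- as.integer(parts[2:5])
    if (anyNA(ix) || any(ix < 0) || any(ix > norb)) {
      stop("orbital index out of range in record: '", ln, "'")
    }
    i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
    if (i == 0 && j == 0 && k == 0 && l == 0) {
      core <- v
    } else if (k == 0 && l == 0) {
      h1[i, j] <- v; h1[j, i] <- v
    } else if (any(ix == 0)) {
      stop("malformed FCIDUMP record (partial zero indices): '", ln, "'")
    } else {
      perms <- rbind(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                     c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i))
      eri[perms] <- v
    }
  }
  out <- expand_spatial_integrals(h1, eri, core)
  attr(out, "spatial") <- list(h1 = h1, eri = eri, core_energy = core,
                               n_orb = norb, n_electrons = nelec,
                               ms2 = ms2, orbsym = orbsym)
  out
}

#' Write an FCIDUMP file
#'
#' Writes spatial integrals in the Molpro dialect with one representative
#' per 8-fold symmetry class, at full double precision (round trips are
#' lossless to printed precision).
#'
#' @param h1 spatial one-electron matrix.
#' @param eri spatial two-electron array, chemist `(pq|rs)`.
#' @param core_energy scalar.
#' @param n_electrons electron count for the header.
#' @param path output path.
#' @param ms2 twice the spin projection (header field).
#' @param orbsym integer irrep labels (header field, optional).
#' @export
write_fcidump <- function(h1, eri, core_energy, n_electrons, path,
                          ms2 = 0L, orbsym = NULL) {
  n <- nrow(h1)
  hdr <- sprintf("&FCI NORB=%d,NELEC=%d,MS2=%d,", n, n_electrons, ms2)
  if (!is.null(orbsym)) {
    hdr <- c(hdr, sprintf(" ORBSYM=%s,", paste(orbsym, collapse = ",")))
  }
  hdr <- c(hdr, " ISYM=1,", "&END")
  recs <- character(0)
  fmt <- function(v, i, j, k, l) sprintf("%.16e %4d %4d %4d %4d", v, i, j, k, l)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    for (r in seq_len(p)) for (s in seq_len(r)) {
      if (p == r && s > q) next
      v <- eri[p, q, r, s]
      if (abs(v) > 0) recs <- c(recs, fmt(v, p, q, r, s))
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    if (abs(h1[p, q]) > 0) recs <- c(recs, fmt(h1[p, q], p, q, 0L, 0L))
  }
  recs <- c(recs, fmt(core_energy, 0L, 0L, 0L, 0L))
  writeLines(c(hdr, recs), path)
}
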