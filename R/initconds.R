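# Initial conditions: fully numerical Hessians, harmonic normal modes,
# ground-state Wigner phase-space sampling, nuclear-ensemble absorption
# spectra, and stochastic initial-state selection from oscillator
# strengths.

#' Fully numerical Hessian from energies
#'
#' Central finite differences of a scalar energy function: diagonal
#' elements from 3-point, mixed elements from 4-point double
#' displacements. The result is symmetrized as `(H + H^T)/2`.
#'
#' @param energy_fn function(geometry) -> ground-state energy (hartree).
#' @param geom a `geometry` (should be a minimum).
#' @param displacement step (bohr, default 0.01).
#' @return 3N x 3N symmetric matrix (hartree/bohr^2) with the raw
#'   asymmetry attached as attribute `"asymmetry"`.
#' @export
numerical_hessian <- function(energy_fn, geom, displacement = 0.01) {
  stopifnot(displacement > 0)
  n <- 3L * nrow(geom$coords)
  d <- displacement
  shift <- function(i, s) {
    atom <- (i - 1L) %/% 3L + 1L; ax <- (i - 1L) %% 3L + 1L
    displace_geometry(geom, atom, ax, s)
  }
  ener <- function(g) {
    v <- tryCatch(energy_fn(g), error = function(e)
      stop("energy evaluation failed at displaced geometry (",
           paste(round(g$coords, 5), collapse = " "), "): ",
           conditionMessage(e)))
    v
  }
  e0 <- ener(geom)
  H <- matrix(0, n, n)
  ep <- numeric(n); em <- numeric(n)
  for (i in seq_len(n)) {
    ep[i] <- ener(shift(i, d)); em[i] <- ener(shift(i, -d))
    H[i, i] <- (ep[i] + em[i] - 2 * e0) / d^2
  }
  shift2 <- function(i, si, j, sj) {
    g <- shift(i, si)
    displace_geometry(g, (j - 1L) %/% 3L + 1L, (j - 1L) %% 3L + 1L, sj)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    H[i, j] <- (ener(shift2(i, d, j, d)) - ener(shift2(i, d, j, -d)) -
                ener(shift2(i, -d, j, d)) + ener(shift2(i, -d, j, -d))) /
               (4 * d^2)
    H[j, i] <- H[i, j]
  }
  Hs <- (H + t(H)) / 2
  attr(Hs, "asymmetry") <- max(abs(H - t(H))) / max(abs(H), 1e-300)
  Hs
}

#' Harmonic normal modes from a Hessian
#'
#' Mass-weighted diagonalization with rigid translations (and rotations,
#' for non-linear molecules) projected out. Frequencies are reported in
#' cm^-1; imaginary modes (negative curvature) come out as negative
#' numbers and are flagged.
#'
#' @param hessian 3N x 3N Cartesian Hessian (hartree/bohr^2).
#' @param geom the `geometry` the Hessian belongs to (masses, positions
#'   for the rotational projector).
#' @param linear is the molecule linear (drop 5 instead of 6 rigid
#'   modes)? Default auto-detect from the moments of inertia.
#' @param zero_tol frequencies below this (cm^-1, absolute value) count
#'   as rigid-body remnants.
#' @return object of class `normal_modes`: `frequencies` (cm^-1),
#'   `modes` (3N x n_modes, mass-weighted, orthonormal),
#'   `cartesian_modes` (unnormalized Cartesian displacements),
#'   `n_imaginary`.
#' @export
normal_modes <- function(hessian, geom, linear = NULL, zero_tol = 1) {
  masses <- geom$masses
  n_at <- length(masses)
  n <- 3L * n_at
  stopifnot(nrow(hessian) == n, max(abs(hessian - t(hessian))) < 1e-8)
  m3 <- rep(masses, each = 3L)
  Hmw <- hessian / sqrt(outer(m3, m3))
  # rigid-body basis in mass-weighted coordinates
  com <- colSums(geom$coords * masses) / sum(masses)
  xyz <- sweep(geom$coords, 2, com)
  if (is.null(linear)) {
    inertia <- matrix(0, 3, 3)
    for (i in seq_len(n_at)) {
      r <- xyz[i, ]
      inertia <- inertia + masses[i] * (sum(r^2) * diag(3) - outer(r, r))
    }
    ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
    linear <- min(ev) < 1e-8 * max(ev, 1)
  }
  rigid <- matrix(0, n, 0)
  for (ax in 1:3) {
    t_vec <- rep(0, n); t_vec[seq(ax, n, by = 3L)] <- sqrt(m3[seq(ax, n, by = 3L)])
    rigid <- cbind(rigid, t_vec)
  }
  axes <- diag(3)
  for (ax in 1:3) {
    r_vec <- as.vector(t(xyz %*% .cross_matrix(axes[ax, ]))) * sqrt(m3)
    if (sum(r_vec^2) > 1e-12) rigid <- cbind(rigid, r_vec)
  }
  qrR <- qr(rigid)
  Q <- qr.Q(qrR)[, seq_len(qrR$rank), drop = FALSE]
  P <- diag(n) - Q %*% t(Q)
  Hp <- P %*% Hmw %*% P
  e <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  omega2 <- e$values
  freq_cm <- sign(omega2) * sqrt(abs(omega2)) * au$cm1_per_hartree
  n_rigid <- if (linear) 5L else 6L
  n_expected <- n - n_rigid
  ord_abs <- order(abs(freq_cm))
  vib <- sort(ord_abs[-seq_len(n_rigid)])
  if (sum(abs(freq_cm) <= zero_tol) > n_rigid) {
    stop("more than ", n_rigid, " near-zero modes: geometry is not a ",
         "clean minimum or the Hessian is rank-deficient")
  }
  ord <- vib[order(freq_cm[vib])]
  modes <- e$vectors[, ord, drop = FALSE]
  freqs <- freq_cm[ord]
  cart <- modes / sqrt(m3)
  structure(list(frequencies = freqs, modes = modes,
                 cartesian_modes = cart, masses = masses,
                 n_imaginary = sum(freqs < 0), linear = linear,
                 geometry = geom),
            class = "normal_modes")
}

.cross_matrix <- function(u) {
  matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3)
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes: %d modes%s>\n", length(x$frequencies),
              if (x$n_imaginary) sprintf(" (%d imaginary)", x$n_imaginary) else ""))
  cat("  frequencies (cm^-1):", paste(sprintf("%.1f", x$frequencies),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Harmonic Wigner sampling of the ground vibrational state
#'
#' Per mode, mass-weighted position and momentum are drawn from the
#' independent Gaussians of the v = 0 Wigner distribution
#' (`sd(Q) = sqrt(hbar / 2 omega)`, `sd(P) = sqrt(hbar omega / 2)`) and
#' transformed back to Cartesian displacements and velocities.
#'
#' @param modes a `normal_modes` object; all retained frequencies must be
#'   real and positive unless listed in `exclude`.
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param exclude indices of modes to leave unsampled (e.g. a known
#'   imaginary torsion).
#' @return list of samples, each a list with `geometry` and `velocities`.
#' @export
wigner_sample <- function(modes, n_samples, seed = 1L, exclude = integer(0)) {
  sel <- setdiff(seq_along(modes$frequencies), exclude)
  if (any(modes$frequencies[sel] <= 0)) {
    stop("imaginary/zero frequency present; exclude the mode explicitly ",
         "to sample the remaining ones")
  }
  omega <- modes$frequencies[sel] / au$cm1_per_hartree
  m3 <- rep(modes$masses, each = 3L)
  rng <- .counter_rng(seed)
  gauss <- function(k) stats::qnorm(pmin(pmax(rng(k), 1e-12), 1 - 1e-12))
  lapply(seq_len(n_samples), function(i) {
    Q <- gauss(length(sel)) * sqrt(1 / (2 * omega))
    P <- gauss(length(sel)) * sqrt(omega / 2)
    dq_mw <- modes$modes[, sel, drop = FALSE] %*% Q
    dp_mw <- modes$modes[, sel, drop = FALSE] %*% P
    g <- modes$geometry
    g$coords <- g$coords + matrix(dq_mw / sqrt(m3), ncol = 3, byrow = TRUE)
    vel <- matrix(dp_mw / sqrt(m3), ncol = 3, byrow = TRUE)
    list(geometry = g, velocities = vel)
  })
}

#' Nuclear-ensemble absorption spectrum
#'
#' For every geometry of the ensemble, vertical excitation energies and
#' oscillator strengths for all excited states are computed through the
#' supplied single-point function, and each transition contributes a
#' Gaussian line of area f at its excitation energy.
#'
#' @param ensemble list of samples (as from [wigner_sample()]).
#' @param single_point function(geometry) -> list with `energies`
#'   (hartree, ground first) and `f` (oscillator strengths of
#'   excitations from the ground state, length n_states - 1).
#' @param fwhm Gaussian full width at half maximum (eV, default 0.1).
#' @param grid energy grid (eV) for the curves.
#' @return object of class `absorption_spectrum`: `grid`, `per_state`
#'   (matrix, one column per excited state), `total`, `n_failed`.
#' @export
simulate_spectrum <- function(ensemble, single_point, fwhm = 0.1,
                              grid = seq(0, 15, by = 0.02)) {
  stopifnot(length(ensemble) > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  per_state <- NULL
  n_failed <- 0L
  for (s in ensemble) {
    res <- tryCatch(single_point(s$geometry), error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    nex <- length(res$f)
    if (is.null(per_state)) per_state <- matrix(0, length(grid), nex)
    de_ev <- (res$energies[-1] - res$energies[1]) / au$hartree_per_ev
    for (m in seq_len(nex)) {
      per_state[, m] <- per_state[, m] + res$f[m] *
        exp(-(grid - de_ev[m])^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    }
  }
  n_ok <- length(ensemble) - n_failed
  if (n_ok == 0) stop("no ensemble point converged")
  per_state <- per_state / n_ok
  structure(list(grid = grid, per_state = per_state,
                 total = rowSums(per_state), n_failed = n_failed),
            class = "absorption_spectrum")
}

#' Stochastic initial-state selection from excitation data
#'
#' Keeps excitations inside the energy window and accepts each with
#' probability `f / p_norm` (acceptance-rejection against the oscillator
#' strength), yielding initial conditions with delta-initialized
#' coefficients on the selected state.
#'
#' @param ensemble list of samples with `geometry` and `velocities`.
#' @param excitations list (parallel to `ensemble`) with `energies`
#'   (hartree) and `f` per sample.
#' @param window c(lower, upper) excitation window (eV).
#' @param p_norm normalization of the acceptance probability; must be at
#'   least the largest in-window f. NULL: 1.01 * that maximum.
#' @param n_wanted stop after this many accepted conditions (NULL: scan
#'   the whole ensemble).
#' @param seed RNG seed.
#' @return list of initial conditions (`geometry`, `velocities`, `state`
#'   (1-based adiabatic index), `excitation_ev`, `f`).
#' @export
select_initial_conditions <- function(ensemble, excitations, window,
                                      p_norm = NULL, n_wanted = NULL,
                                      seed = 1L) {
  stopifnot(window[1] < window[2])
  fs_in <- c()
  for (ex in excitations) {
    de <- (ex$energies[-1] - ex$energies[1]) / au$hartree_per_ev
    fs_in <- c(fs_in, ex$f[de >= window[1] & de <= window[2]])
  }
  if (length(fs_in) == 0) {
    near <- unlist(lapply(excitations, function(ex)
      (ex$energies[-1] - ex$energies[1]) / au$hartree_per_ev))
    stop("no excitation falls inside [", window[1], ", ", window[2],
         "] eV; nearest excitation energies: ",
         paste(sprintf("%.3f", utils::head(sort(near), 5)), collapse = ", "))
  }
  if (max(fs_in) == 0) return(list())  # nothing absorbs in the window
  if (is.null(p_norm)) p_norm <- 1.01 * max(fs_in)
  if (p_norm < max(fs_in)) {
    stop("p_norm must be >= the largest in-window oscillator strength")
  }
  rng <- .counter_rng(seed)
  out <- list()
  for (i in seq_along(ensemble)) {
    ex <- excitations[[i]]
    de <- (ex$energies[-1] - ex$energies[1]) / au$hartree_per_ev
    for (m in seq_along(ex$f)) {
      if (de[m] < window[1] || de[m] > window[2]) next
      if (rng(1) < ex$f[m] / p_norm) {
        out[[length(out) + 1L]] <-
          list(geometry = ensemble[[i]]$geometry,
               velocities = ensemble[[i]]$velocities,
               state = m + 1L, excitation_ev = de[m], f = ex$f[m])
        if (!is.null(n_wanted) && length(out) >= n_wanted) return(out)
      }
    }
  }
  out
}
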