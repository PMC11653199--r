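# Self-contained model systems. Every pipeline stage is exercisable with
# these fixtures alone: an analytic two-state avoided crossing (exposed
# both as a 2x2 matrix model and as a 2-electron/2-orbital fermionic
# provider), canonical H2/STO-3G integrals, structural ethylene-like
# Hamiltonians for measurement-grouping analysis, FCIDUMP grids, and
# synthetic hop-time ensembles for the kinetic fits.

#' Analytic two-state avoided-crossing model
#'
#' Diabatic surfaces `V11 = slope * R`, `V22 = -slope * R` crossing at
#' R = 0, coupled by a Gaussian `V12 = (gap/2) exp(-R^2 / (2 w^2))`, so the
#' adiabatic gap at the crossing equals `gap`. Closed forms for the
#' adiabatic surfaces, mixing angle and first-order nonadiabatic coupling
#' are exposed for use as oracles; the model also presents itself as a
#' 1-qubit operator.
#'
#' @param gap adiabatic gap at the crossing (hartree).
#' @param coupling_width Gaussian width w of the coupling (bohr).
#' @param slope magnitude of the diabatic slopes (hartree/bohr).
#' @return an object of class `avoided_crossing` with closure fields
#'   `diabatic(R)`, `adiabatic(R)`, `mixing_angle(R)`, `nac(R)`,
#'   `gradients(R)`, `qubit_op(R)`.
#' @export
make_avoided_crossing <- function(gap = 0.04, coupling_width = 0.5,
                                  slope = 0.02) {
  stopifnot(gap >= 0, coupling_width > 0, slope > 0)
  out <- .two_state_closures(
    V11 = function(R) slope * R,
    V22 = function(R) -slope * R,
    V12 = function(R) (gap / 2) * exp(-R^2 / (2 * coupling_width^2)),
    dV11 = function(R) rep(slope, length(R)),
    dV22 = function(R) rep(-slope, length(R)),
    dV12 = function(R) -(R / coupling_width^2) *
      (gap / 2) * exp(-R^2 / (2 * coupling_width^2)))
  out$gap <- gap; out$coupling_width <- coupling_width; out$slope <- slope
  out
}

#' Bound two-state model: displaced harmonic wells with a crossing
#'
#' Diabatic ground well `V11 = k/2 R^2`, excited well
#' `V22 = e_vert + k/2 (R - delta)^2 - k delta^2 / 2 ...` shifted so the
#' two curves cross between the minima, coupled by a Gaussian centered
#' at the crossing. A desk-scale cartoon of photoexcited dynamics: the
#' ground state has a true minimum (so numerical Hessians and Wigner
#' sampling apply), vertical excitation puts the system on the upper
#' adiabat, and relaxation funnels it through the avoided crossing.
#'
#' @param k harmonic force constant (hartree/bohr^2).
#' @param delta displacement of the excited well (bohr).
#' @param e_vert vertical excitation energy at R = 0 (hartree).
#' @param gap adiabatic gap at the crossing (hartree).
#' @param coupling_width Gaussian width of the coupling (bohr).
#' @return an `avoided_crossing` object (same closures).
#' @export
make_bound_crossing <- function(k = 0.02, delta = 2.5, e_vert = 0.15,
                                gap = 0.02, coupling_width = 0.4) {
  stopifnot(k > 0, delta > 0, e_vert > 0, gap >= 0, coupling_width > 0)
  V11 <- function(R) 0.5 * k * R^2
  V22 <- function(R) e_vert + 0.5 * k * (R - delta)^2 - 0.5 * k * delta^2
  # diabats cross where V11 = V22: R_x = e_vert / (k delta)
  Rx <- e_vert / (k * delta)
  V12 <- function(R) (gap / 2) * exp(-(R - Rx)^2 / (2 * coupling_width^2))
  out <- .two_state_closures(
    V11 = V11, V22 = V22, V12 = V12,
    dV11 = function(R) k * R,
    dV22 = function(R) k * (R - delta),
    dV12 = function(R) -((R - Rx) / coupling_width^2) * V12(R))
  out$k <- k; out$delta <- delta; out$e_vert <- e_vert
  out$crossing <- Rx; out$gap <- gap; out$coupling_width <- coupling_width
  out
}

# closures shared by the two-state models; the eigenvector frame is
# continuous in R (lower state (cos th, sin th), upper (-sin th, cos th))
.two_state_closures <- function(V11, V22, V12, dV11, dV22, dV12) {
  mixing_angle <- function(R) 0.5 * atan2(2 * V12(R), V22(R) - V11(R))
  diabatic <- function(R) {
    matrix(c(V11(R), V12(R), V12(R), V22(R)), 2, 2)
  }
  adiabatic <- function(R) {
    avg <- (V11(R) + V22(R)) / 2
    half <- sqrt(((V11(R) - V22(R)) / 2)^2 + V12(R)^2)
    th <- mixing_angle(R)
    list(values = c(avg - half, avg + half),
         vectors = matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
  }
  nac <- function(R) {
    # d12 = <1|d/dR|2> = -d(theta)/dR for this eigenvector frame
    y <- 2 * V12(R); x <- V22(R) - V11(R)
    yp <- 2 * dV12(R); xp <- dV22(R) - dV11(R)
    -0.5 * (yp * x - y * xp) / (x^2 + y^2)
  }
  gradients <- function(R) {
    davg <- (dV11(R) + dV22(R)) / 2
    half <- sqrt(((V11(R) - V22(R)) / 2)^2 + V12(R)^2)
    dhalf <- (((V11(R) - V22(R)) / 2) * (dV11(R) - dV22(R)) / 2 +
              V12(R) * dV12(R)) / pmax(half, 1e-300)
    c(davg - dhalf, davg + dhalf)
  }
  qubit_op <- function(R) {
    qop(1, c("I", "Z0", "X0"),
        c((V11(R) + V22(R)) / 2, (V11(R) - V22(R)) / 2, V12(R)))
  }
  structure(list(diabatic = diabatic, adiabatic = adiabatic,
                 mixing_angle = mixing_angle, nac = nac,
                 gradients = gradients, qubit_op = qubit_op),
            class = "avoided_crossing")
}

#' Two-electron/two-orbital fermionic embedding of an avoided crossing
#'
#' An `electronic_structure_provider` whose two lowest singlet states
#' follow the diabatic curves of `model` exactly. The molecular coordinate
#' is the distance between the two (dummy) atoms minus `r_ref`. The two
#' closed-shell determinants play the diabatic states: with on-site
#' repulsion `u` and inter-orbital Coulomb `j` large, the open-shell
#' configurations are pushed far above, leaving a clean 2x2 block whose
#' diagonal is `V11/V22` and whose coupling is the exchange integral
#' `V12`. Orbitals are geometry-independent, so cross-geometry MO overlaps
#' are the identity.
#'
#' @param model an `avoided_crossing`.
#' @param u on-site Coulomb repulsion (hartree).
#' @param j inter-orbital Coulomb repulsion (hartree).
#' @param r_ref reference distance (bohr) mapped to model coordinate 0.
#' @param dipole_strength off-diagonal one-electron dipole matrix element
#'   (a.u.) along x; the two orbitals have opposite parity.
#' @param core_shift constant added to the core energy (hartree). The
#'   default -2 makes the total energies negative (bound-molecule-like),
#'   so that the customary deflation weight `lambda = |E_gs|` is valid;
#'   a constant shifts all surfaces rigidly and leaves forces, couplings
#'   and dynamics unchanged.
#' @export
two_level_provider <- function(model, u = 1.0, j = 2.5, r_ref = 4.0,
                               dipole_strength = 0.8, core_shift = -2.0) {
  coord <- function(geom) {
    sqrt(sum((geom$coords[1, ] - geom$coords[2, ])^2)) - r_ref
  }
  integrals <- function(geom, aspace) {
    stopifnot(aspace$n_electrons == 2L, aspace$n_orbitals == 2L)
    R <- coord(geom)
    V <- model$diabatic(R)
    h1 <- diag(c((V[1, 1] - u) / 2, (V[2, 2] - u) / 2))
    eri <- array(0, dim = rep(2, 4))
    eri[1, 1, 1, 1] <- u; eri[2, 2, 2, 2] <- u
    eri[1, 1, 2, 2] <- j; eri[2, 2, 1, 1] <- j
    k <- V[1, 2]
    for (ix in list(c(1, 2, 1, 2), c(2, 1, 1, 2), c(1, 2, 2, 1), c(2, 1, 2, 1))) {
      eri[ix[1], ix[2], ix[3], ix[4]] <- k
    }
    core <- aspace$frozen_core_energy + core_shift
    out <- expand_spatial_integrals(h1, eri, core_energy = core)
    attr(out, "spatial") <- list(h1 = h1, eri = eri, core_energy = core,
                                 n_orb = 2L, n_electrons = 2L, ms2 = 0L,
                                 orbsym = NULL)
    out
  }
  prov <- electronic_structure_provider(
    integrals = integrals,
    mo_coefficients = function(geom) diag(2),
    cross_overlap = function(geom_a, geom_b) diag(2),
    dipole_integrals = function(geom) {
      list(matrix(c(0, dipole_strength, dipole_strength, 0), 2, 2),
           matrix(0, 2, 2), matrix(0, 2, 2))
    },
    name = "two_level_avoided_crossing")
  prov$core_shift <- core_shift
  prov$model <- model
  prov$coordinate <- coord
  prov
}

#' Geometry placing the two-level provider at model coordinate R
#' @param R model coordinate (bohr); @param r_ref reference distance;
#' @param mass atom mass in electron masses (default 2000, a light
#'   nuclear mass typical of scattering models).
#' @export
two_level_geometry <- function(R, r_ref = 4.0, mass = 2000) {
  geometry(c("X", "X"),
           matrix(c(0, 0, 0, r_ref + R, 0, 0), 2, 3, byrow = TRUE),
           masses = c(mass, mass))
}

#' Canonical H2/STO-3G active-space integrals
#'
#' The standard minimal-basis hydrogen-molecule integrals at the
#' equilibrium bond length 0.735 angstrom, in the RHF MO basis (hartree):
#' the workhorse 4-qubit benchmark system.
#'
#' @return a `spin_orbital_integrals` object (4 spin orbitals).
#' @export
h2_sto3g_integrals <- function() {
  h1 <- diag(c(-1.252477495, -0.475934275))
  eri <- array(0, dim = rep(2, 4))
  eri[1, 1, 1, 1] <- 0.674488766
  eri[2, 2, 2, 2] <- 0.697397510
  eri[1, 1, 2, 2] <- 0.663468096; eri[2, 2, 1, 1] <- 0.663468096
  k <- 0.181288808
  for (ix in list(c(1, 2, 1, 2), c(2, 1, 1, 2), c(1, 2, 2, 1), c(2, 1, 2, 1))) {
    eri[ix[1], ix[2], ix[3], ix[4]] <- k
  }
  out <- expand_spatial_integrals(h1, eri, core_energy = 0.713776188)
  attr(out, "spatial") <- list(h1 = h1, eri = eri,
                               core_energy = 0.713776188,
                               n_orb = 2L, n_electrons = 2L, ms2 = 0L,
                               orbsym = c(1L, 5L))
  out
}

# deterministic value stream for structural Hamiltonians (plain LCG;
# only the *pattern* of nonzero integrals matters, values must merely be
# generic enough to avoid accidental cancellations)
.lcg_stream <- function(n, seed = 12345) {
  state <- seed
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (1103515245 * state + 12345) %% 2147483648
    out[i] <- state / 2147483648 - 0.5
  }
  out
}

# generic symmetry-blocked spatial integrals for a set of orbitals with
# abelian irrep labels (xor composition): integral allowed iff the labels
# multiply to the totally symmetric irrep
.symmetry_blocked_integrals <- function(irreps, seed = 12345) {
  n <- length(irreps)
  vals <- .lcg_stream(n * n + n^4, seed)
  vi <- 0L
  nxt <- function() { vi <<- vi + 1L; vals[vi] }
  h1 <- matrix(0, n, n)
  for (p in seq_len(n)) for (q in p:n) {
    if (irreps[p] == irreps[q]) {
      v <- nxt(); h1[p, q] <- v; h1[q, p] <- v
    }
  }
  eri <- array(0, dim = rep(n, 4))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    for (r in seq_len(n)) for (s in seq_len(n)) {
      if (bitwXor(bitwXor(irreps[p], irreps[q]),
                  bitwXor(irreps[r], irreps[s])) != 0L) next
      if (eri[p, q, r, s] != 0) next
      v <- nxt()
      perms <- rbind(c(p, q, r, s), c(q, p, r, s), c(p, q, s, r), c(q, p, s, r),
                     c(r, s, p, q), c(s, r, p, q), c(r, s, q, p), c(s, r, q, p))
      eri[perms] <- v
    }
  }
  list(h1 = h1, eri = eri)
}

#' Synthetic ethylene pi/sigma/pi* active-space integrals (4e, 3o)
#'
#' A stand-in for the HF/6-31G (4 electron, 3 orbital) active space of
#' ethylene, built from symmetry alone: the sigma, pi and pi* orbitals
#' belong to three distinct D2h irreps, so the one-electron matrix is
#' diagonal and only Coulomb/exchange-type two-electron integrals survive.
#' Values are physically plausible hartree-scale numbers, not ab initio
#' ones -- the Pauli-string structure of the Jordan-Wigner Hamiltonian,
#' which drives the measurement-grouping analysis, is fixed by the
#' symmetry pattern and does not depend on them.
#'
#' @return a `spin_orbital_integrals` object (6 spin orbitals) with the
#'   spatial data attached as attribute `"spatial"`.
#' @export
ethylene_4e3o_synthetic_integrals <- function() {
  # orbital order: sigma(CC), pi, pi*
  h1 <- diag(c(-6.8412, -5.9236, -5.1184))
  eri <- array(0, dim = rep(3, 4))
  uu <- c(0.6721, 0.5894, 0.5477)
  jj <- matrix(0, 3, 3); kk <- matrix(0, 3, 3)
  jj[1, 2] <- 0.5583; jj[1, 3] <- 0.5239; jj[2, 3] <- 0.4874
  kk[1, 2] <- 0.1412; kk[1, 3] <- 0.1098; kk[2, 3] <- 0.1763
  for (p in 1:3) eri[p, p, p, p] <- uu[p]
  for (p in 1:2) for (q in (p + 1):3) {
    eri[p, p, q, q] <- jj[p, q]; eri[q, q, p, p] <- jj[p, q]
    for (ix in list(c(p, q, p, q), c(q, p, p, q), c(p, q, q, p), c(q, p, q, p))) {
      eri[ix[1], ix[2], ix[3], ix[4]] <- kk[p, q]
    }
  }
  core <- -37.4421
  out <- expand_spatial_integrals(h1, eri, core_energy = core)
  attr(out, "spatial") <- list(h1 = h1, eri = eri, core_energy = core,
                               n_orb = 3L, n_electrons = 4L, ms2 = 0L,
                               orbsym = c(1L, 2L, 3L))
  out
}

#' Structural full-6-31G ethylene Hamiltonian (frozen core)
#'
#' Builds the Jordan-Wigner qubit Hamiltonian of a generic real
#' Hamiltonian with the D2h symmetry structure of ethylene's full 6-31G
#' orbital space after freezing the two carbon 1s core MOs: 24 spatial
#' orbitals with irrep multiset {6 ag, 6 b1u, 4 b2u, 4 b3g, 2 b3u, 2 b2g}
#' (the symmetry-adapted basis-function counts minus the core), 48
#' qubits. Coefficient values are generic; the set of Pauli strings --
#' and hence all measurement-grouping counts -- is determined by which
#' integrals symmetry allows, so this object supports the
#' measurement-reduction analysis without an SCF backend.
#'
#' @param tol coefficient pruning tolerance.
#' @return a `qubit_operator` on 48 qubits (counting/grouping only; far
#'   too large for statevector work).
#' @export
ethylene_631g_structural_hamiltonian <- function(tol = 1e-12) {
  # D2h as xor group: ag=0, b1u=1, b2u=2, b3g=3, b3u=4, b2g=5
  irreps <- c(rep(0L, 6), rep(1L, 6), rep(2L, 4), rep(3L, 4),
              rep(4L, 2), rep(5L, 2))
  ints <- .symmetry_blocked_integrals(irreps)
  groups <- expand_spatial_integrals_sparse(ints$h1, ints$eri)
  jordan_wigner_terms(groups, n_qubits = 2L * length(irreps), tol = tol)
}

#' Write an FCIDUMP grid for a model system
#'
#' Generates per-point FCIDUMP files and a manifest (TSV with the model
#' coordinate and reference full-CI energies from dense diagonalization of
#' the fermionic Hamiltonian) for backend-free testing of the variational
#' stack.
#'
#' @param system `"avoided_crossing"` (2e/2o grid over the model
#'   coordinate) or `"h2"` (the single canonical STO-3G point).
#' @param coords numeric vector of model coordinates (bohr), ignored for
#'   `"h2"`.
#' @param dir output directory (created if missing).
#' @param model an `avoided_crossing` (for the default system).
#' @param n_states number of reference energies per point.
#' @return the manifest as a data.frame (also written to
#'   `file.path(dir, "manifest.tsv")`).
#' @export
generate_fcidump_grid <- function(system = c("avoided_crossing", "h2"),
                                  coords = seq(-2, 2, length.out = 11),
                                  dir = tempfile("fcigrid"),
                                  model = make_avoided_crossing(),
                                  n_states = 2L) {
  system <- match.arg(system)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  if (system == "h2") coords <- 0
  for (i in seq_along(coords)) {
    if (system == "avoided_crossing") {
      prov <- two_level_provider(model)
      aspace <- active_space(2, 2)
      ints <- prov$integrals(two_level_geometry(coords[i]), aspace)
      spat <- attr(ints, "spatial")
      nelec <- 2L
    } else {
      ints <- h2_sto3g_integrals()
      spat <- attr(ints, "spatial")
      nelec <- 2L
    }
    fname <- sprintf("point_%03d.fcidump", i)
    write_fcidump(spat$h1, spat$eri, spat$core_energy, nelec,
                  file.path(dir, fname))
    H <- second_quantized_hamiltonian(ints)
    M <- fermion_matrix(H)
    sub <- .sector_indices(ints$n_spin_orbitals, nelec, 0L) + 1L
    ev <- sort(Re(eigen(M[sub, sub], symmetric = TRUE,
                        only.values = TRUE)$values))
    rows[[i]] <- data.frame(index = i, coordinate = coords[i],
                            file = fname,
                            t(setNames(ev[seq_len(min(n_states, length(ev)))],
                                       paste0("E", seq_len(min(n_states, length(ev))) - 1L))))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Synthesize surface-hopping population curves from a kinetic model
#'
#' Draws per-trajectory hop times from the closed-form kinetics and
#' averages state indicators on a time grid, emulating the binomial noise
#' of a finite trajectory ensemble.
#'
#' @param model `"delayed_exponential"` (S1 -> S0 after delay `t0` with
#'   time constant `tau1`) or `"sequential"` (S2 -> S1 -> S0 with
#'   constants `tau2`, `tau1`).
#' @param params named list of the model parameters (fs).
#' @param n_traj number of trajectories.
#' @param seed RNG seed.
#' @param grid time grid (fs).
#' @return a `population_series` (see [populations()]).
#' @export
synthesize_population_curves <- function(model = c("delayed_exponential", "sequential"),
                                         params, n_traj = 141L, seed = 1L,
                                         grid = seq(0, 150, by = 0.5)) {
  model <- match.arg(model)
  rng <- .counter_rng(seed)
  if (model == "delayed_exponential") {
    hop <- params$t0 + stats::qexp(rng(n_traj), rate = 1 / params$tau1)
    pops <- vapply(grid, function(t) {
      s1 <- mean(hop > t)
      c(S0 = 1 - s1, S1 = s1)
    }, numeric(2))
    mat <- t(pops)
  } else {
    h2 <- stats::qexp(rng(n_traj), rate = 1 / params$tau2)
    h1 <- h2 + stats::qexp(rng(n_traj), rate = 1 / params$tau1)
    mat <- t(vapply(grid, function(t) {
      s2 <- mean(h2 > t)
      s1 <- mean(h2 <= t & h1 > t)
      c(S0 = 1 - s1 - s2, S1 = s1, S2 = s2)
    }, numeric(3)))
  }
  structure(list(time = grid, fractions = mat, n_trajectories = n_traj),
            class = "population_series")
}

# counter-based uniform stream: deterministic, independent of the global
# RNG state
.counter_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}
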