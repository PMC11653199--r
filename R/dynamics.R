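# Fewest-switches surface hopping with local-diabatization electronic
# propagation: velocity-Verlet nuclei on one adiabatic surface,
# stochastic hops driven by the population flux of the active state,
# energy-based decoherence, and exact energy conservation across hops by
# velocity rescaling along the nuclear momentum.

#' Surface-hopping run configuration
#'
#' @param n_states number of electronic states propagated.
#' @param dt_nuclear nuclear time step (fs, default 0.5).
#' @param dt_electronic electronic substep (fs, default 0.02); must
#'   divide the nuclear step.
#' @param decoherence_C energy-based decoherence parameter (hartree
#'   units of the standard formula; default 0.1 a.u.).
#' @param max_time trajectory end time (fs).
#' @param ground_state_dwell stop after this long continuously in the
#'   ground state (fs; 20 for methanimine-like runs, 10 for
#'   ethylene-like).
#' @param drift_threshold total-energy drift (eV) beyond which the
#'   trajectory is flagged discarded.
#' @param seed RNG seed for the hopping random numbers.
#' @export
sh_config <- function(n_states, dt_nuclear = 0.5, dt_electronic = 0.02,
                      decoherence_C = 0.1, max_time = 150,
                      ground_state_dwell = 20, drift_threshold = 0.2,
                      seed = 1L) {
  n_sub <- dt_nuclear / dt_electronic
  if (abs(n_sub - round(n_sub)) > 1e-9) {
    stop("dt_electronic must divide dt_nuclear")
  }
  structure(list(n_states = as.integer(n_states), dt_nuclear = dt_nuclear,
                 dt_electronic = dt_electronic, n_substeps = as.integer(round(n_sub)),
                 decoherence_C = decoherence_C, max_time = max_time,
                 ground_state_dwell = ground_state_dwell,
                 drift_threshold = drift_threshold, seed = as.integer(seed)),
            class = "sh_config")
}

#' Kinetic energy of a geometry's velocities
#' @param velocities N x 3 matrix (bohr / a.u. time).
#' @param masses per-atom masses (electron masses).
#' @export
kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * rowSums(velocities^2))
}

#' One velocity-Verlet step on a fixed surface
#'
#' Positions advance with the current forces, the force provider is
#' evaluated once at the new geometry, then velocities advance with the
#' average of old and new forces.
#'
#' @param geom a `geometry`; @param velocities N x 3 (bohr/a.u. time).
#' @param forces_t current forces (N x 3, hartree/bohr).
#' @param forces_provider function(geometry) -> forces at the new
#'   positions.
#' @param dt time step (a.u. time).
#' @return list with `geometry`, `velocities`, `forces`.
#' @export
velocity_verlet_step <- function(geom, velocities, forces_t,
                                 forces_provider, dt) {
  m <- geom$masses
  geom$coords <- geom$coords + velocities * dt + forces_t / (2 * m) * dt^2
  forces_new <- forces_provider(geom)
  velocities <- velocities + (forces_t + forces_new) * dt / (2 * m)
  list(geometry = geom, velocities = velocities, forces = forces_new)
}

# sign-fixed Loewdin transformation: columns flipped so diag(T) >= 0,
# pinning the arbitrary global phase of each state between steps
.signed_lowdin <- function(S, singular_tol = 1e-6) {
  T <- lowdin_orthonormalize(S, singular_tol)
  flip <- which(diag(T) < 0)
  if (length(flip)) T[, flip] <- -T[, flip]
  T
}

#' Local-diabatization propagation of the electronic coefficients
#'
#' The step transformation `T` is the sign-fixed Loewdin orthogonalization
#' of the cross-step overlap matrix; the diabatic Hamiltonian is
#' interpolated linearly from `diag(E_t)` to `T diag(E_tdt) T^T` and the
#' diabatic coefficients are advanced by the exponential midpoint rule
#' over the electronic substeps (exact for piecewise-constant H). The
#' returned adiabatic coefficients are `T^T d`, and the accumulated
#' adiabatic-basis propagator is unitary.
#'
#' @param a complex adiabatic coefficients at t.
#' @param E_t,E_tdt adiabatic energies (hartree) at the step ends.
#' @param S cross-step overlap matrix.
#' @param dt nuclear step (a.u. time).
#' @param n_substeps number of electronic substeps.
#' @return list with `a` (coefficients at t+dt), `propagator` (adiabatic
#'   basis) and `T`.
#' @export
propagate_electronic_LD <- function(a, E_t, E_tdt, S, dt, n_substeps = 25L) {
  T <- .signed_lowdin(S)
  H0 <- diag(E_t)
  H1 <- T %*% diag(E_tdt) %*% t(T)
  d <- a
  G <- diag(1 + 0i, length(a))
  tau <- dt / n_substeps
  for (k in seq_len(n_substeps)) {
    Hm <- H0 + ((k - 0.5) / n_substeps) * (H1 - H0)
    e <- eigen(Hm, symmetric = TRUE)
    U <- e$vectors %*% (exp(-1i * e$values * tau) * t(e$vectors))
    d <- U %*% d
    G <- U %*% G
  }
  P <- t(T) %*% G
  list(a = as.vector(t(T) %*% d), propagator = P, T = T)
}

#' Fewest-switches hopping probabilities in the propagator form
#'
#' The net population lost by the active state over the step is
#' apportioned among target states by the propagator flux `|P_lm|^2`
#' (how much of the active state's amplitude the step carried to l).
#' Probabilities are clamped at zero and sum to at most 1; a diagonal
#' propagator or a non-decreasing active population gives all zeros.
#'
#' @param a_t,a_tdt coefficients before/after the step.
#' @param propagator adiabatic-basis step propagator.
#' @param active active state index (1-based).
#' @return numeric vector of per-state hop probabilities (zero at
#'   `active`).
#' @export
hopping_probabilities <- function(a_t, a_tdt, propagator, active) {
  n <- length(a_t)
  p <- numeric(n)
  pop_t <- Mod(a_t[active])^2
  pop_tdt <- Mod(a_tdt[active])^2
  if (pop_t <= 0) return(p)
  loss <- (pop_t - pop_tdt) / pop_t
  if (loss <= 0) return(p)
  w <- Mod(propagator[, active])^2
  w[active] <- 0
  if (sum(w) <= 0) return(p)
  p <- pmax(0, loss * w / sum(w))
  p[active] <- 0
  p
}

#' Stochastic hop attempt with momentum-direction velocity rescaling
#'
#' Draws the target by the fewest-switches rule; an energetically
#' accessible hop rescales the velocities along the nuclear momentum so
#' the total energy is conserved exactly, an inaccessible one is
#' frustrated (state and velocities unchanged).
#'
#' @param active current state; @param probabilities from
#'   [hopping_probabilities()].
#' @param energies adiabatic energies (hartree).
#' @param velocities N x 3; @param masses per-atom masses.
#' @param xi uniform random number in `[0, 1)`.
#' @param direction optional N x 3 rescaling direction used when the
#'   momentum vanishes (e.g. the target-state force).
#' @return list with `active`, `velocities`, `hopped`, `frustrated`,
#'   `target`.
#' @export
attempt_hop <- function(active, probabilities, energies, velocities,
                        masses, xi, direction = NULL) {
  cum <- cumsum(probabilities)
  target <- NA_integer_
  for (l in seq_along(cum)) {
    if (probabilities[l] > 0 && xi < cum[l]) { target <- l; break }
  }
  if (is.na(target)) {
    return(list(active = active, velocities = velocities, hopped = FALSE,
                frustrated = FALSE, target = NA_integer_))
  }
  ekin <- kinetic_energy(velocities, masses)
  ekin_new <- ekin + energies[active] - energies[target]
  if (ekin_new < 0) {
    return(list(active = active, velocities = velocities, hopped = FALSE,
                frustrated = TRUE, target = target))
  }
  if (ekin > 0) {
    velocities <- velocities * sqrt(ekin_new / ekin)
  } else if (ekin_new > 0) {
    if (is.null(direction) || sum(direction^2) == 0) {
      stop("hop from zero kinetic energy needs a rescaling direction")
    }
    u <- direction / sqrt(sum(direction^2))
    c0 <- sqrt(2 * ekin_new / sum(masses * rowSums(u^2)))
    velocities <- c0 * u
  }
  list(active = target, velocities = velocities, hopped = TRUE,
       frustrated = FALSE, target = target)
}

#' Energy-based decoherence correction
#'
#' Damps every inactive amplitude with the characteristic time
#' `tau = (1/|E_l - E_m|) (1 + C/E_kin)` and rescales the active
#' amplitude to restore the norm. Vanishing kinetic energy suppresses
#' the decay entirely (tau -> infinity), and degenerate pairs do not
#' decohere.
#'
#' @param a complex coefficients; @param active active state index.
#' @param energies adiabatic energies (hartree).
#' @param ekin nuclear kinetic energy (hartree).
#' @param dt time step (a.u. time); @param C parameter (default 0.1).
#' @export
apply_decoherence <- function(a, active, energies, ekin, dt, C = 0.1) {
  stopifnot(C > 0)
  if (ekin <= 0) return(a)
  pop_active <- Mod(a[active])^2
  if (pop_active == 0) return(a)
  for (l in seq_along(a)) {
    if (l == active) next
    gap <- abs(energies[l] - energies[active])
    if (gap == 0) next
    tau <- (1 / gap) * (1 + C / ekin)
    a[l] <- a[l] * exp(-dt / tau)
  }
  rest <- sum(Mod(a[-active])^2)
  a[active] <- a[active] * sqrt((1 - rest) / pop_active)
  a
}

#' Run one surface-hopping trajectory
#'
#' Per nuclear step: advance positions, evaluate the electronic driver
#' at the new geometry (energies, per-state gradients, cross-step
#' overlap), finish the velocity-Verlet velocity update on the active
#' surface, propagate the coefficients by local diabatization, apply the
#' decoherence correction, attempt a hop, and log. The trajectory ends
#' at `max_time` or after the configured continuous dwell in the ground
#' state, and is flagged `discarded` when the total-energy drift exceeds
#' the threshold.
#'
#' @param init list with `geometry`, `velocities` (N x 3, bohr/a.u.
#'   time), `state` (1-based initial adiabatic state) and optionally
#'   `coefficients`.
#' @param driver electronic driver: list with `n_states`,
#'   `init(geometry)` and `step(geometry, prev_point)`; see
#'   [model_sh_driver()] and [vqe_sh_driver()].
#' @param config an `sh_config`.
#' @return an object of class `trajectory`: per-step `steps` data frame,
#'   `hops` data frame, `geometries`, final flags.
#' @export
run_trajectory <- function(init, driver, config) {
  dt <- config$dt_nuclear / au$fs_per_au_time
  geom <- init$geometry
  v <- init$velocities
  active <- init$state
  n <- config$n_states
  a <- if (!is.null(init$coefficients)) init$coefficients else {
    z <- complex(n); z[active] <- 1 + 0i; z
  }
  rng <- .counter_rng(config$seed)
  point <- driver$init(geom)
  etot0 <- point$energies[active] + kinetic_energy(v, geom$masses)
  rows <- list(); hops <- list(); geoms <- list(geom)
  t_fs <- 0
  dwell <- if (active == 1L) 0 else NA_real_
  log_row <- function() {
    ek <- kinetic_energy(v, geom$masses)
    etot <- point$energies[active] + ek
    data.frame(time = t_fs, active = active,
               t(setNames(point$energies, paste0("E", seq_len(n) - 1L))),
               t(setNames(Mod(a)^2, paste0("pop", seq_len(n) - 1L))),
               ekin = ek, etot = etot, drift = etot - etot0)
  }
  rows[[1]] <- log_row()
  terminated <- "max_time"
  while (t_fs < config$max_time - 1e-9) {
    F_t <- -point$gradients[[active]]
    geom_new <- geom
    geom_new$coords <- geom$coords + v * dt + F_t / (2 * geom$masses) * dt^2
    point_new <- tryCatch(driver$step(geom_new, point), error = function(e) e)
    if (inherits(point_new, "error")) {
      terminated <- paste0("aborted: ", conditionMessage(point_new))
      break
    }
    F_new <- -point_new$gradients[[active]]
    v <- v + (F_t + F_new) * dt / (2 * geom$masses)
    prop <- propagate_electronic_LD(a, point$energies, point_new$energies,
                                    point_new$overlap, dt,
                                    config$n_substeps)
    a_new <- prop$a
    ekin <- kinetic_energy(v, geom_new$masses)
    a_dec <- apply_decoherence(a_new, active, point_new$energies, ekin, dt,
                               config$decoherence_C)
    probs <- hopping_probabilities(a, a_new, prop$propagator, active)
    hop <- attempt_hop(active, probs, point_new$energies, v,
                       geom_new$masses, rng(1),
                       direction = -point_new$gradients[[which.max(probs)]])
    t_fs <- t_fs + config$dt_nuclear
    if (hop$hopped || hop$frustrated) {
      hops[[length(hops) + 1L]] <-
        data.frame(time = t_fs, from = active, to = hop$target,
                   frustrated = hop$frustrated,
                   gap = point_new$energies[hop$target] -
                         point_new$energies[active])
      attr(hops[[length(hops)]], "geometry") <- geom_new
    }
    active <- hop$active
    v <- hop$velocities
    a <- a_dec   # the hop itself leaves the coefficients untouched
    geom <- geom_new
    point <- point_new
    geoms[[length(geoms) + 1L]] <- geom
    rows[[length(rows) + 1L]] <- log_row()
    if (active == 1L) {
      dwell <- if (is.na(dwell)) 0 else dwell + config$dt_nuclear
      if (!is.na(dwell) && dwell >= config$ground_state_dwell) {
        terminated <- "ground_dwell"
        break
      }
    } else {
      dwell <- NA_real_
    }
  }
  steps <- do.call(rbind, rows)
  hopdf <- if (length(hops)) do.call(rbind, hops) else
    data.frame(time = numeric(0), from = integer(0), to = integer(0),
               frustrated = logical(0), gap = numeric(0))
  hop_geoms <- lapply(hops, function(h) attr(h, "geometry"))
  drift_max <- max(abs(steps$drift))
  structure(list(steps = steps, hops = hopdf, hop_geometries = hop_geoms,
                 geometries = geoms, final_state = active,
                 final_velocities = v, coefficients = a,
                 terminated = terminated,
                 discarded = drift_max > config$drift_threshold *
                   au$hartree_per_ev,
                 drift_max = drift_max, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(paste0("<trajectory: %d steps, final state S%d, %d hops ",
                     "(%d frustrated), drift %.2e hartree, %s%s>\n"),
              nrow(x$steps) - 1L, x$final_state - 1L,
              sum(!x$hops$frustrated), sum(x$hops$frustrated),
              x$drift_max, x$terminated,
              if (x$discarded) ", DISCARDED" else ""))
  invisible(x)
}

#' Run an ensemble of trajectories
#'
#' Counter-based seeding: trajectory i uses `config$seed + i`, so
#' ensembles are reproducible and extendable.
#'
#' @param inits list of initial conditions (see [run_trajectory()]).
#' @param driver electronic driver; @param config an `sh_config`.
#' @param keep_discarded keep energy-drift-discarded trajectories
#'   (default FALSE drops them, as customary).
#' @export
run_ensemble <- function(inits, driver, config, keep_discarded = FALSE) {
  out <- lapply(seq_along(inits), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    run_trajectory(inits[[i]], driver, cfg)
  })
  if (!keep_discarded) out <- out[!vapply(out, function(t) t$discarded, logical(1))]
  out
}

#' Analytic-model surface-hopping driver
#'
#' Exposes an [make_avoided_crossing()] model as an electronic driver:
#' one dummy atom moving along x, exact adiabatic energies and
#' gradients, and cross-step overlaps from the closed-form eigenvector
#' frames.
#'
#' @param model an `avoided_crossing`.
#' @export
model_sh_driver <- function(model) {
  mk_point <- function(geom, prev = NULL) {
    R <- geom$coords[1, 1]
    ad <- model$adiabatic(R)
    grads <- lapply(1:2, function(m) {
      g <- matrix(0, nrow(geom$coords), 3)
      g[1, 1] <- model$gradients(R)[m]
      g
    })
    S <- if (is.null(prev)) NULL else t(prev$aux$vectors) %*% ad$vectors
    list(energies = ad$values, gradients = grads, overlap = S,
         aux = list(vectors = ad$vectors, R = R))
  }
  list(n_states = 2L,
       init = function(geom) mk_point(geom),
       step = function(geom, prev) mk_point(geom, prev))
}

#' VQE/VQD surface-hopping driver
#'
#' The full hybrid pipeline as an electronic driver: per geometry, solve
#' the state set variationally (warm-started from the previous step's
#' angles), form Hellmann-Feynman gradients from one finite-difference
#' Hamiltonian-derivative build, extract CI expansions, and compute the
#' cross-step overlap matrix through the provider's MO cross-overlaps.
#'
#' @param provider an `electronic_structure_provider`.
#' @param aspace an `active_space`.
#' @param n_states states to propagate.
#' @param ansatz a `kupccgsd_ansatz`.
#' @param lambda VQD penalty weight (NULL: magnitude of the ground-state
#'   energy).
#' @param ci_threshold CI-expansion amplitude cutoff.
#' @param shift_angstrom finite-difference displacement.
#' @export
vqe_sh_driver <- function(provider, aspace, n_states, ansatz,
                          lambda = NULL, ci_threshold = 1e-6,
                          shift_angstrom = 0.001) {
  mk_point <- function(geom, prev = NULL) {
    H <- build_qubit_hamiltonian(provider, geom, aspace)
    ss <- solve_state_set(H, n_states, ansatz,
                          warm_start = if (is.null(prev)) NULL else prev$aux$state_set,
                          lambda = lambda)
    dH <- hamiltonian_gradient_components(provider, geom, aspace,
                                          shift_angstrom)
    grads <- state_gradients(ss, dH)
    mo <- provider$mo_coefficients(geom)
    exps <- lapply(ss$states, function(st)
      extract_ci_expansion(st, threshold = ci_threshold, mo_matrix = mo))
    S <- NULL
    if (!is.null(prev)) {
      Smo <- provider$cross_overlap(prev$aux$geometry, geom)
      S <- ci_overlap_matrix(prev$aux$expansions, exps, Smo)
    }
    list(energies = ss$energies, gradients = grads, overlap = S,
         aux = list(state_set = ss, expansions = exps, geometry = geom))
  }
  list(n_states = as.integer(n_states),
       init = function(geom) mk_point(geom),
       step = function(geom, prev) mk_point(geom, prev))
}
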