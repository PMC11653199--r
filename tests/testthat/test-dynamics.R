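# Velocity-Verlet integration, local-diabatization propagation, hopping,
# decoherence and full trajectories.

test_that("velocity-Verlet handles free, harmonic and reversed motion", {
  g <- geometry("X", matrix(0, 1, 3), masses = 1000)
  v <- matrix(c(0.002, 0, 0), 1, 3)
  # zero force: uniform linear motion
  st <- list(geometry = g, velocities = v,
             forces = matrix(0, 1, 3))
  for (i in 1:10) {
    st <- velocity_verlet_step(st$geometry, st$velocities, st$forces,
                               function(gg) matrix(0, 1, 3), 10)
  }
  expect_equal(st$geometry$coords[1, 1], 0.002 * 100, tolerance = 1e-12)
  expect_equal(st$velocities, v)
  # harmonic oscillator: energy conserved to O(dt^2), period to 0.1%
  k <- 0.05; m <- 1000
  fprov <- function(gg) { f <- -k * gg$coords; f }
  omega <- sqrt(k / m); period <- 2 * pi / omega
  dt <- period / 2000
  g2 <- geometry("X", matrix(c(0.4, 0, 0), 1, 3), masses = m)
  st <- list(geometry = g2, velocities = matrix(0, 1, 3),
             forces = -k * g2$coords)
  e0 <- 0.5 * k * 0.4^2
  xprev <- 0.4; crossed <- c()
  tt <- 0
  emax <- 0
  for (i in 1:4200) {
    st <- velocity_verlet_step(st$geometry, st$velocities, st$forces, fprov, dt)
    tt <- tt + dt
    x <- st$geometry$coords[1, 1]
    etot <- 0.5 * k * sum(st$geometry$coords^2) +
      kinetic_energy(st$velocities, st$geometry$masses)
    emax <- max(emax, abs(etot - e0))
    # upward zero crossings of x are separated by exactly one period
    if (xprev < 0 && x >= 0 && st$velocities[1, 1] > 0) {
      crossed <- c(crossed, tt)
    }
    xprev <- x
  }
  expect_lt(emax, 1e-6)
  expect_gte(length(crossed), 2L)
  expect_lt(abs(diff(crossed)[1] - period) / period, 1e-3)
  # time reversal: negate velocities, step back, recover the start
  fwd <- velocity_verlet_step(g2, matrix(c(0.001, 0, 0), 1, 3),
                              -k * g2$coords, fprov, 10)
  bwd <- velocity_verlet_step(fwd$geometry, -fwd$velocities, fwd$forces,
                              fprov, 10)
  expect_lt(max(abs(bwd$geometry$coords - g2$coords)), 1e-10)
  expect_lt(max(abs(-bwd$velocities - matrix(c(0.001, 0, 0), 1, 3))), 1e-10)
})

test_that("LD propagation reduces to pure phases without coupling", {
  E <- c(-0.3, 0.2)
  a0 <- c(0.6, 0.8) + 0i
  pr <- propagate_electronic_LD(a0, E, E, diag(2), dt = 8, n_substeps = 10)
  expect_equal(Mod(pr$a), Mod(a0), tolerance = 1e-12)
  expect_equal(pr$a, a0 * exp(-1i * E * 8), tolerance = 1e-10)
  expect_lt(max(abs(pr$T - diag(2))), 1e-12)
})

test_that("LD propagator stays unitary and norm-conserving over random steps", {
  set.seed(23)
  a <- c(1, 0, 0) + 0i
  for (i in 1:200) {
    th <- stats::rnorm(3, sd = 0.1)
    A <- matrix(0, 3, 3)
    A[upper.tri(A)] <- th; A <- A - t(A)
    S <- as.matrix(Matrix::expm(Matrix::Matrix(A))) *
      (0.95 + 0.1 * stats::runif(1))
    E1 <- sort(stats::rnorm(3)); E2 <- sort(stats::rnorm(3))
    pr <- propagate_electronic_LD(a, E1, E2, S, dt = 5, n_substeps = 5)
    expect_lt(max(abs(Conj(t(pr$propagator)) %*% pr$propagator - diag(3))),
              1e-8)
    a <- pr$a
    expect_equal(sum(Mod(a)^2), 1, tolerance = 1e-8)
  }
})

test_that("LD populations converge to the NAC-based TDSE solution", {
  mod <- make_avoided_crossing()
  v <- 0.0108; R0 <- -4; Rend <- 4
  oracle <- tdse_nac_populations(mod, R0, v, (Rend - R0) / v, dt = 0.01)
  errs <- vapply(c(5, 1.25), function(dt_n) {
    Rs <- seq(R0, Rend, by = v * dt_n)
    a <- c(0, 1) + 0i
    for (i in seq_len(length(Rs) - 1)) {
      ad1 <- mod$adiabatic(Rs[i]); ad2 <- mod$adiabatic(Rs[i + 1])
      S <- t(ad1$vectors) %*% ad2$vectors
      a <- propagate_electronic_LD(a, ad1$values, ad2$values, S, dt_n,
                                   n_substeps = 25L)$a
    }
    max(abs(Mod(a)^2 - oracle))
  }, numeric(1))
  expect_lt(errs[2], 1e-4)
  expect_gt(errs[1] / errs[2], 8)  # observed order >= 2 in dt
})

test_that("hopping probabilities express the fewest-switches flux rule", {
  a_t <- c(sqrt(0.7), sqrt(0.3)) + 0i
  # diagonal propagator: no hops
  expect_equal(hopping_probabilities(a_t, a_t, diag(2) + 0i, 2), c(0, 0))
  # unchanged active population: no hops
  P <- matrix(c(0.8, 0.6, -0.6, 0.8), 2, 2) + 0i
  a2 <- c(sqrt(0.7), sqrt(0.3)) + 0i
  expect_equal(hopping_probabilities(a_t, a2, P, 2), c(0, 0))
  # population loss apportioned by propagator flux, bounded by 1
  a3 <- c(sqrt(0.9), sqrt(0.1)) + 0i
  p <- hopping_probabilities(a_t, a3, P, 2)
  expect_gte(min(p), 0)
  expect_lte(sum(p), 1)
  expect_equal(sum(p), (0.3 - 0.1) / 0.3, tolerance = 1e-12)
  # zero active population: all zero
  expect_equal(hopping_probabilities(c(1, 0) + 0i, a3, P, 2), c(0, 0))
})

test_that("hop attempts conserve energy exactly or are frustrated", {
  masses <- c(2000, 2000)
  v <- matrix(c(0.003, 0, 0, -0.003, 0, 0), 2, 3, byrow = TRUE)
  E <- c(-0.1, -0.05)
  # random number beyond the probabilities: no hop
  res <- attempt_hop(2, c(0.2, 0), E, v, masses, xi = 0.9)
  expect_false(res$hopped)
  expect_equal(res$velocities, v)
  # successful downhill hop: exact energy conservation
  res2 <- attempt_hop(2, c(0.5, 0), E, v, masses, xi = 0.1)
  expect_true(res2$hopped)
  e_before <- E[2] + kinetic_energy(v, masses)
  e_after <- E[1] + kinetic_energy(res2$velocities, masses)
  expect_lt(abs(e_after - e_before), 1e-10)
  # frustrated uphill hop: state and velocities unchanged
  vs <- matrix(c(1e-4, 0, 0, -1e-4, 0, 0), 2, 3, byrow = TRUE)
  res3 <- attempt_hop(1, c(0, 0.5), c(-0.1, 0.1), vs, masses, xi = 0.1)
  expect_false(res3$hopped)
  expect_true(res3$frustrated)
  expect_equal(res3$velocities, vs)
  # downhill from rest: always allowed, speed increases along direction
  v0 <- matrix(0, 2, 3)
  dir <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
  res4 <- attempt_hop(2, c(1, 0), E, v0, masses, xi = 0.0, direction = dir)
  expect_true(res4$hopped)
  expect_gt(kinetic_energy(res4$velocities, masses), 0)
  expect_lt(abs(E[1] + kinetic_energy(res4$velocities, masses) - E[2]), 1e-12)
})

test_that("decoherence damping matches its closed form", {
  a <- c(sqrt(0.8), sqrt(0.2)) + 0i
  E <- c(-0.2, -0.1); ekin <- 0.02; dt <- 20; C <- 0.1
  out <- apply_decoherence(a, 1, E, ekin, dt, C)
  tau <- (1 / 0.1) * (1 + C / ekin)
  expected2 <- sqrt(0.2) * exp(-dt / tau)
  expect_equal(Mod(out[2]), expected2, tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # all population already on the active state: unchanged
  pure <- c(1, 0) + 0i
  expect_equal(apply_decoherence(pure, 1, E, ekin, dt, C), pure)
  # degenerate pair does not decay
  adeg <- apply_decoherence(a, 1, c(-0.2, -0.2), ekin, dt, C)
  expect_equal(adeg, a)
  # zero kinetic energy suppresses the decay
  expect_equal(apply_decoherence(a, 1, E, 0, dt, C), a)
})

test_that("uncoupled trajectories stay adiabatic with bounded drift", {
  # two parallel harmonic surfaces, zero coupling: no hops ever
  k <- 0.03; m <- 1500
  driver <- list(
    n_states = 2L,
    init = function(geom) {
      x <- geom$coords[1, 1]
      list(energies = c(0.5 * k * x^2, 0.5 * k * x^2 + 0.2),
           gradients = lapply(1:2, function(s) {
             gm <- matrix(0, 1, 3); gm[1, 1] <- k * x; gm
           }),
           overlap = NULL, aux = NULL)
    },
    step = function(geom, prev) {
      p <- driver$init(geom); p$overlap <- diag(2); p
    })
  g0 <- geometry("X", matrix(c(0.5, 0, 0), 1, 3), masses = m)
  cfg <- sh_config(2, dt_nuclear = 0.25, dt_electronic = 0.0125,
                   max_time = 100 * 0.25, ground_state_dwell = 1e9, seed = 3)
  tr <- run_trajectory(list(geometry = g0, velocities = matrix(0, 1, 3),
                            state = 2L), driver, cfg)
  expect_equal(nrow(tr$hops), 0L)
  expect_equal(tr$final_state, 2L)
  expect_lt(tr$drift_max, 1e-4)
  expect_lt(max(abs(tr$steps$pop1 - 1)), 1e-12)
})

test_that("ensemble statistics agree with an independent NAC-based FSSH reference", {
  mod <- make_avoided_crossing()
  mass <- 2000; R0 <- -6; v0 <- 0.004
  n_traj <- 120
  # package implementation
  drv <- model_sh_driver(mod)
  cfg0 <- sh_config(2, dt_nuclear = 0.25, dt_electronic = 0.0125,
                    max_time = 0.25 * 450, ground_state_dwell = 1e9, seed = 100)
  finals <- vapply(seq_len(n_traj), function(i) {
    cfg <- cfg0; cfg$seed <- 100 + i
    tr <- run_trajectory(list(
      geometry = geometry("X", matrix(c(R0, 0, 0), 1, 3), masses = mass),
      velocities = matrix(c(v0, 0, 0), 1, 3), state = 2L), drv, cfg)
    tr$final_state
  }, integer(1))
  frac_lower <- mean(finals == 1L)
  # independent reference
  rng <- test_rng(4242)
  finals_ref <- vapply(seq_len(n_traj), function(i) {
    fssh_nac_reference(mod, R0, v0, mass, state = 2L,
                       dt_n = 0.25 / au$fs_per_au_time,
                       n_steps = 450, rng = rng)$state
  }, integer(1))
  frac_ref <- mean(finals_ref == 1L)
  se <- sqrt(frac_ref * (1 - frac_ref) / n_traj) +
    sqrt(frac_lower * (1 - frac_lower) / n_traj)
  expect_lt(abs(frac_lower - frac_ref), 3 * se + 0.02)
})
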