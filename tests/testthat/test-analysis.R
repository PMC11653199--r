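# Population curves, kinetic fits, internal coordinates, hopping
# statistics and the quantum yield.

# minimal hand-built trajectory for population tests
mock_trajectory <- function(times, actives, final_state = actives[length(actives)],
                            n_states = 2L, geoms = NULL) {
  steps <- data.frame(time = times, active = actives)
  structure(list(steps = steps, final_state = final_state,
                 hops = data.frame(time = numeric(0), from = integer(0),
                                   to = integer(0), frustrated = logical(0),
                                   gap = numeric(0)),
                 hop_geometries = list(),
                 geometries = geoms,
                 config = list(n_states = n_states, dt_nuclear = diff(times)[1]),
                 discarded = FALSE),
            class = "trajectory")
}

test_that("population fractions average active-state indicators", {
  t1 <- mock_trajectory(seq(0, 10, 1), rep(2L, 11))
  p <- populations(list(t1, t1), grid = seq(0, 10, 1))
  expect_true(all(p$fractions[, "S1"] == 1))
  # one of two trajectories hops at t = 5: step of 0.5
  acts <- c(rep(2L, 5), rep(1L, 6))
  t2 <- mock_trajectory(seq(0, 10, 1), acts)
  p2 <- populations(list(t1, t2), grid = seq(0, 10, 1))
  expect_equal(p2$fractions[, "S1"], c(rep(1, 5), rep(0.5, 6)),
               ignore_attr = TRUE)
  expect_true(all(abs(rowSums(p2$fractions) - 1) < 1e-12))
  # terminated trajectories held in their final state
  t3 <- mock_trajectory(seq(0, 5, 1), c(2L, 2L, 1L, 1L, 1L, 1L))
  p3 <- populations(list(t3), grid = seq(0, 10, 1))
  expect_equal(unname(p3$fractions[11, "S0"]), 1)
  p3d <- populations(list(t3), grid = seq(0, 10, 1), hold_terminated = FALSE)
  expect_true(all(is.nan(p3d$fractions[8:11, "S0"]) |
                  p3d$fractions[8:11, "S0"] == 0))
  expect_error(populations(list(t1), grid = numeric(0)), "grid")
})

test_that("delayed-exponential fits recover parameters and flag flat series", {
  grid <- seq(0, 400, by = 0.5)
  p1 <- ifelse(grid <= 30, 1, exp(-(grid - 30) / 136))
  ser <- structure(list(time = grid, fractions = cbind(S0 = 1 - p1, S1 = p1),
                        n_trajectories = 141L), class = "population_series")
  fit <- fit_delayed_exponential(ser, "S1", t0 = 30)
  expect_equal(fit$tau1, 136, tolerance = 1e-6)
  expect_equal(fit$lifetime, 166, tolerance = 1e-6)
  fit_free <- fit_delayed_exponential(ser, "S1")
  expect_equal(fit_free$tau1, 136, tolerance = 1e-3)
  expect_equal(fit_free$t0, 30, tolerance = 1e-2)
  flat <- structure(list(time = grid,
                         fractions = cbind(S0 = rep(0, length(grid)),
                                           S1 = rep(1, length(grid))),
                         n_trajectories = 10L), class = "population_series")
  expect_match(fit_delayed_exponential(flat, "S1")$flags, "unidentifiable")
  # binomial-noise recovery within 2 sigma at the ensemble size used
  reps <- vapply(1:8, function(r) {
    sp <- synthesize_population_curves("delayed_exponential",
                                       list(t0 = 30, tau1 = 136),
                                       n_traj = 141, seed = 100 + r,
                                       grid = grid)
    fit_delayed_exponential(sp, "S1", t0 = 30)$tau1
  }, numeric(1))
  sd_tau <- stats::sd(reps)
  expect_lt(abs(mean(reps) - 136), 2 * sd_tau / sqrt(8) + 6)
})

test_that("sequential kinetics fits recover parameters including limits", {
  grid <- seq(0, 120, by = 0.25)
  p2 <- exp(-grid / 14)
  p1 <- vqehop:::.sequential_intermediate(grid, 14, 35)
  ser <- structure(list(time = grid,
                        fractions = cbind(S0 = 1 - p1 - p2, S1 = p1, S2 = p2),
                        n_trajectories = 85L), class = "population_series")
  fit <- fit_sequential_kinetics(ser)
  expect_equal(fit$tau2, 14, tolerance = 1e-4)
  expect_equal(fit$tau1, 35, tolerance = 1e-4)
  # equal-rate limit: closed form continuous (no singularity)
  eq <- vqehop:::.sequential_intermediate(grid, 20, 20)
  near <- vqehop:::.sequential_intermediate(grid, 20, 20.0001)
  expect_lt(max(abs(eq - near)), 1e-4)
  p1e <- vqehop:::.sequential_intermediate(grid, 20, 20)
  p2e <- exp(-grid / 20)
  sere <- structure(list(time = grid,
                         fractions = cbind(S0 = 1 - p1e - p2e, S1 = p1e,
                                           S2 = p2e),
                         n_trajectories = 85L), class = "population_series")
  fite <- fit_sequential_kinetics(sere)
  expect_equal(fite$tau2, 20, tolerance = 1e-3)
  expect_equal(fite$tau1, 20, tolerance = 1e-3)
  # tau2 -> 0: S1 becomes a single exponential born at t = 0
  small <- vqehop:::.sequential_intermediate(grid, 1e-6, 35)
  expect_lt(max(abs(small - exp(-grid / 35))[grid > 1]), 1e-4)
})

test_that("internal coordinates satisfy the textbook cases and rigid invariance", {
  sq <- geometry(rep("X", 4),
                 matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3,
                        byrow = TRUE))
  expect_equal(internal_coordinate(sq, 1:4), 0)
  ra <- geometry(rep("X", 4),
                 matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0), 4, 3,
                        byrow = TRUE))
  expect_equal(abs(internal_coordinate(ra, 1:4, fold_dihedral = FALSE)), 90)
  expect_equal(internal_coordinate(sq, c(1, 2, 3)), 90)
  expect_equal(internal_coordinate(sq, c(1, 2)), 1 / au$bohr_per_angstrom,
               tolerance = 1e-12)
  # random rigid motion leaves all coordinates unchanged
  set.seed(31)
  th <- stats::rnorm(3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, 3)
  rot <- Rx %*% Rz
  g2 <- ra
  g2$coords <- ra$coords %*% t(rot) +
    matrix(stats::rnorm(3), 4, 3, byrow = TRUE)
  for (ix in list(c(1, 2), c(1, 2, 3), 1:4)) {
    expect_equal(internal_coordinate(g2, ix), internal_coordinate(ra, ix),
                 tolerance = 1e-10)
  }
  collinear <- geometry(rep("X", 4),
                        matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3,
                               byrow = TRUE))
  expect_error(internal_coordinate(collinear, 1:4), "collinear")
})

test_that("hopping statistics summarize hop-geometry coordinates", {
  g1 <- geometry(rep("X", 4),
                 matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0), 4, 3,
                        byrow = TRUE))
  mk_hop_traj <- function(dihedral_geom, t_hop) {
    tr <- mock_trajectory(c(0, t_hop), c(2L, 1L), n_states = 2L)
    tr$hops <- data.frame(time = t_hop, from = 2L, to = 1L,
                          frustrated = FALSE, gap = -0.1)
    tr$hop_geometries <- list(dihedral_geom)
    tr
  }
  t1 <- mk_hop_traj(g1, 5)
  hs <- hopping_statistics(list(t1), list(dih = 1:4), from = 2L, to = 1L)
  expect_equal(nrow(hs$table), 1L)
  expect_equal(hs$summary$mean, 90)
  # two hops with dihedrals 90 and 0: mean 45
  g2 <- geometry(rep("X", 4),
                 matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1, 1, 0), 4, 3,
                        byrow = TRUE))
  t2 <- mk_hop_traj(g2, 7)
  hs2 <- hopping_statistics(list(t1, t2), list(dih = 1:4))
  expect_equal(nrow(hs2$table), 2L)
  expect_equal(hs2$summary$mean, mean(c(90, 0)))
  # no hops: empty tables, no error
  hs0 <- hopping_statistics(list(mock_trajectory(c(0, 1), c(2L, 2L))),
                            list(dih = 1:4))
  expect_equal(nrow(hs0$table), 0L)
})

test_that("quantum yield reproduces counts, limits and Bernoulli statistics", {
  qy <- quantum_yield_counts(30, 38)
  expect_equal(qy$yield, 38 / 68, tolerance = 1e-12)
  expect_equal(qy$sd, sqrt((38 / 68) * (30 / 68) / 68), tolerance = 1e-12)
  all_trans <- quantum_yield_counts(0, 25)
  expect_equal(all_trans$yield, 1)
  expect_equal(all_trans$sd, 0)
  # synthetic Bernoulli(0.5) ensemble through the geometry-based path
  frame <- function(phi) {
    geometry(rep("X", 4),
             matrix(c(-0.5, 1, 0, 0, 0, 0, 1.5, 0, 0,
                      2.0, cos(phi * pi / 180), sin(phi * pi / 180)),
                    4, 3, byrow = TRUE))
  }
  planar <- frame(20)    # folded dihedral 20 deg (reactant side)
  twisted <- frame(160)  # folded dihedral 160 deg (isomerized side)
  expect_equal(internal_coordinate(planar, 1:4), 20, tolerance = 1e-8)
  expect_equal(internal_coordinate(twisted, 1:4), 160, tolerance = 1e-8)
  rng <- test_rng(77)
  n <- 400
  trajs <- lapply(seq_len(n), function(i) {
    tr <- mock_trajectory(c(0, 1), c(2L, 1L), final_state = 1L)
    tr$geometries <- list(if (rng(1) < 0.5) planar else twisted)
    tr
  })
  qy2 <- quantum_yield(trajs, 1:4)
  expect_equal(qy2$n_ground, n)
  expect_equal(qy2$n_unassigned, 0L)
  expect_lt(abs(qy2$yield - 0.5), 3 * qy2$sd + 0.01)
})
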