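# k-UpCCGSD ansatz and the VQE/VQD solvers against dense-diagonalization
# oracles.

test_that("ansatz has the expected parameter counts and reference behavior", {
  a1 <- build_kupccgsd(6, 4, k = 1)
  expect_equal(a1$n_params, 6L)   # 3 singles + 3 paired doubles
  a2 <- build_kupccgsd(6, 4, k = 2)
  expect_equal(a2$n_params, 12L)
  # theta = 0 prepares the closed-shell reference exactly
  expect_equal(prepare_state(a1, numeric(6)), reference_state(a1))
  # a k=2 state with zero-padded second layer equals the k=1 state
  set.seed(5); th <- stats::rnorm(6, sd = 0.2)
  expect_equal(prepare_state(a2, c(th, numeric(6))), prepare_state(a1, th),
               tolerance = 1e-12)
  expect_error(build_kupccgsd(6, 3, k = 1), "even")
})

test_that("prepared states conserve particle number and S_z at any angle", {
  anz <- build_kupccgsd(6, 4, k = 1)
  Nop <- jordan_wigner(fermion_operator(6, lapply(0:5, function(p)
    list(modes = c(p, p), dagger = c(TRUE, FALSE))), rep(1 + 0i, 6)))
  Sz2 <- s_squared_qop(6)
  set.seed(8)
  for (rep in 1:5) {
    th <- stats::rnorm(6, sd = 0.7)
    psi <- prepare_state(anz, th)
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-12)
    expect_equal(expectation(psi, Nop), 4, tolerance = 1e-12)
    # closed-shell reference is a singlet; the ansatz preserves S^2
    expect_lt(abs(expectation(psi, Sz2)), 1e-10)
  }
})

test_that("single-generator rotation matches the dense matrix exponential", {
  anz <- build_kupccgsd(4, 2, k = 1)
  # isolate the paired-double generator (parameter 2)
  th <- c(0, pi / 2)
  psi <- prepare_state(anz, th)
  G <- qop_matrix(anz$generators[[2]])
  # dense exponential of the anti-Hermitian generator via its Hermitian
  # factor: exp(theta G) = V exp(i theta h) V^dagger with G = i V h V^dagger
  Hh <- -1i * (pi / 2) * G
  eh <- eigen(Hh)
  U <- eh$vectors %*% (exp(1i * eh$values) * Conj(t(eh$vectors)))
  expect_lt(max(abs(psi - U %*% reference_state(anz))), 1e-10)
  # 2 pi periodicity of a single-generator rotation (up to global phase)
  psi2 <- prepare_state(anz, th + c(0, 2 * pi))
  phase <- sum(Conj(psi) * psi2)
  expect_equal(Mod(phase), 1, tolerance = 1e-10)
  expect_lt(max(abs(psi2 - phase * psi)), 1e-9)
})

test_that("expectation values agree with the dense quadratic form", {
  q <- random_hermitian_qop(4, 20, seed = 21)
  psi <- random_state(4, seed = 22)
  expect_equal(expectation(psi, q), dense_expectation(psi, q),
               tolerance = 1e-10)
  expect_equal(expectation(psi, qop(4, "I", 1)), 1, tolerance = 1e-12)
  e0 <- complex(16); e0[1] <- 1
  expect_equal(expectation(e0, qop(4, "Z0", 1)), 1, tolerance = 1e-12)
  expect_error(expectation(psi, qop(4, "X0", 1i)), "Hermitian")
})

test_that("analytic gradients match finite differences", {
  H <- h2_hamiltonian()
  anz <- build_kupccgsd(4, 2, k = 2)
  set.seed(30); th <- stats::rnorm(anz$n_params, sd = 0.4)
  g <- vqehop:::.cost_and_gradient(anz, th, H)$gradient
  num <- vapply(seq_along(th), function(i) {
    e <- 1e-6
    tp <- th; tp[i] <- tp[i] + e
    tm <- th; tm[i] <- tm[i] - e
    (vqehop:::.cost_and_gradient(anz, tp, H, want_gradient = FALSE)$cost -
     vqehop:::.cost_and_gradient(anz, tm, H, want_gradient = FALSE)$cost) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g - num)), 1e-7)
})

test_that("VQE reaches the exact ground state on fixtures", {
  # diagonal Hamiltonian with the reference already optimal
  Hd <- qop(4, c("I", "Z0", "Z1", "Z2", "Z3"), c(-1, 0.5, 0.5, -0.5, -0.5))
  anz <- build_kupccgsd(4, 2, k = 1)
  st <- vqe(Hd, anz)
  expect_true(st$converged)
  expect_equal(st$energy, expectation(reference_state(anz), Hd),
               tolerance = 1e-8)
  # H2: matches dense diagonalization to 1e-7
  H <- h2_hamiltonian()
  ex <- exact_spectrum(H, 1, n_electrons = 2, sz2 = 0)
  st2 <- vqe(H, anz)
  expect_lt(abs(st2$energy - ex$values[1]), 1e-7)
  # variational bound: every evaluation sits above the exact minimum
  set.seed(40)
  for (rep in 1:5) {
    th <- stats::rnorm(anz$n_params)
    e <- expectation(prepare_state(anz, th), H)
    expect_gte(e, ex$values[1] - 1e-12)
  }
})

test_that("VQD resolves excited states and flags weak penalties", {
  H <- h2_hamiltonian()
  anz2 <- build_kupccgsd(4, 2, k = 2)
  # full singlet spectrum with an adequate penalty weight
  ss <- solve_state_set(H, 3, anz2, lambda = 2.5)
  ex <- exact_spectrum(H, 6, n_electrons = 2, sz2 = 0)
  S2 <- s_squared_qop(4)
  s2v <- apply(ex$vectors, 2, function(v)
    Re(sum(Conj(v) * apply_qop(S2, v))))
  singlets <- ex$values[s2v < 0.1]
  expect_lt(max(abs(ss$energies - singlets[1:3])), 1e-6)
  expect_false(ss$flagged)
  expect_lt(max(ss$overlap2[upper.tri(ss$overlap2)]), 1e-5)
  # degenerate ground level: deflation returns the orthogonal partner
  dprov <- two_level_provider(make_avoided_crossing(gap = 0))
  Hdeg <- build_qubit_hamiltonian(dprov, two_level_geometry(0),
                                  active_space(2, 2))
  anz1 <- build_kupccgsd(4, 2, k = 1)
  g0 <- vqe(Hdeg, anz1)
  p1 <- vqd(Hdeg, anz1, list(g0), lambda = 2)
  expect_lt(abs(p1$energy - g0$energy), 1e-6)
  expect_lt(Mod(sum(Conj(g0$statevector) * p1$statevector))^2, 1e-5)
  # lambda below the gap misses the excited state and is detected
  gs <- vqe(H, anz2)
  weak <- vqd(H, anz2, list(gs), lambda = 0.05, multistart = 5L)
  exc <- singlets[2]
  # with a too-small penalty the converged cost dips below the true
  # excited energy (collapse), which the solver flags
  expect_true(length(weak$flags) > 0 || weak$energy < exc - 1e-6)
})

test_that("warm starts cut the iteration count along a geometry scan", {
  mod <- make_bound_crossing()
  prov <- two_level_provider(mod)
  asp <- active_space(2, 2)
  anz <- build_kupccgsd(4, 2, k = 1)
  coords <- seq(0, 1.2, by = 0.3)
  cold_iters <- warm_iters <- numeric(0)
  prev <- NULL
  for (R in coords) {
    H <- build_qubit_hamiltonian(prov, two_level_geometry(R), asp)
    cold <- vqe(H, anz)
    warm <- if (is.null(prev)) cold else vqe(H, anz, theta0 = prev$theta)
    cold_iters <- c(cold_iters, cold$n_iterations)
    warm_iters <- c(warm_iters, warm$n_iterations)
    expect_lt(abs(warm$energy - cold$energy), 1e-8)
    prev <- warm
  }
  expect_lte(mean(warm_iters), mean(cold_iters))
})

test_that("two-level provider states track the analytic surfaces", {
  mod <- make_avoided_crossing()
  prov <- two_level_provider(mod)
  asp <- active_space(2, 2)
  anz <- build_kupccgsd(4, 2, k = 1)
  for (R in c(-1.5, 0, 0.8)) {
    H <- build_qubit_hamiltonian(prov, two_level_geometry(R), asp)
    ss <- solve_state_set(H, 2, anz)
    ad <- mod$adiabatic(R)
    expect_lt(max(abs(ss$energies - (ad$values + prov$core_shift))), 1e-7)
    # exact-diagonalization cross-check in the right sector
    ex <- exact_spectrum(H, 2, n_electrons = 2, sz2 = 0)
    expect_lt(max(abs(ss$energies - ex$values[1:2])), 1e-6)
  }
})
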