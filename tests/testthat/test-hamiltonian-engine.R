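# Pauli algebra, Jordan-Wigner mapping, FCIDUMP I/O and Hamiltonian
# derivatives.

test_that("Jordan-Wigner maps elementary fermionic operators correctly", {
  # number operator a+_0 a_0 -> (I - Z0)/2
  num <- fermion_operator(2, list(list(modes = c(0L, 0L),
                                       dagger = c(TRUE, FALSE))), 1 + 0i)
  qn <- jordan_wigner(num)
  expect_equal(qop_matrix(qn), qop_matrix(qop(2, c("I", "Z0"), c(0.5, -0.5))))
  # hopping a+_1 a_0 + h.c. -> (X0 X1 + Y0 Y1)/2
  hop <- fermion_operator(2, list(
    list(modes = c(1L, 0L), dagger = c(TRUE, FALSE)),
    list(modes = c(0L, 1L), dagger = c(TRUE, FALSE))), c(1, 1) + 0i)
  qh <- jordan_wigner(hop)
  expect_equal(qop_matrix(qh),
               qop_matrix(qop(2, c("X0 X1", "Y0 Y1"), c(0.5, 0.5))))
})

test_that("JW image equals the brute-force fermionic matrix and preserves spectra", {
  # H2 Hamiltonian: qubit matrix equals ladder-operator matrix exactly
  ints <- h2_sto3g_integrals()
  ferm <- second_quantized_hamiltonian(ints)
  expect_lt(max(abs(qop_matrix(jordan_wigner(ferm)) - fermion_matrix(ferm))),
            1e-12)
  # random Hermitian two- and four-operator terms on 3 modes
  set.seed(4)
  for (rep in 1:3) {
    c2 <- stats::rnorm(1); c4 <- stats::rnorm(1)
    f <- fermion_operator(3, list(
      list(modes = c(0L, 2L), dagger = c(TRUE, FALSE)),
      list(modes = c(2L, 0L), dagger = c(TRUE, FALSE)),
      list(modes = c(0L, 1L, 2L, 1L), dagger = c(TRUE, TRUE, FALSE, FALSE)),
      list(modes = c(1L, 2L, 1L, 0L), dagger = c(TRUE, TRUE, FALSE, FALSE))),
      c(c2, c2, c4, c4) + 0i)
    q <- jordan_wigner(f)
    expect_true(is_hermitian_qop(q))
    ev_q <- sort(Re(eigen(qop_matrix(q), only.values = TRUE)$values))
    ev_f <- sort(Re(eigen(fermion_matrix(f), only.values = TRUE)$values))
    expect_lt(max(abs(ev_q - ev_f)), 1e-10)
  }
})

test_that("grouped fast-path JW agrees with the general path", {
  sp <- attr(ethylene_4e3o_synthetic_integrals(), "spatial")
  H1 <- jordan_wigner(second_quantized_hamiltonian(
    ethylene_4e3o_synthetic_integrals()))
  H2 <- jordan_wigner_terms(
    expand_spatial_integrals_sparse(sp$h1, sp$eri, sp$core_energy),
    n_qubits = 6)
  expect_lt(max(abs(qop_matrix(H1) - qop_matrix(H2))), 1e-12)
})

test_that("qubit operators serialize losslessly", {
  q <- random_hermitian_qop(4, 12, seed = 9)
  path <- tempfile()
  write_qubit_operator(q, path)
  q2 <- read_qubit_operator(path)
  expect_equal(qop_matrix(q2), qop_matrix(q), tolerance = 1e-12)
})

test_that("FCIDUMP parsing handles the core-only and round-trip cases", {
  # core-energy-only file
  path <- tempfile()
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END",
               " 1.5 0 0 0 0"), path)
  ints <- read_fcidump(path)
  expect_equal(ints$core_energy, 1.5)
  expect_equal(max(abs(ints$h)), 0)
  expect_equal(max(abs(ints$g)), 0)
  # round trip of the H2 integrals
  sp <- attr(h2_sto3g_integrals(), "spatial")
  p2 <- tempfile()
  write_fcidump(sp$h1, sp$eri, sp$core_energy, 2L, p2)
  back <- attr(read_fcidump(p2), "spatial")
  expect_lt(max(abs(back$h1 - sp$h1)), 1e-12)
  expect_lt(max(abs(back$eri - sp$eri)), 1e-12)
  expect_lt(abs(back$core_energy - sp$core_energy), 1e-12)
  # malformed inputs
  p3 <- tempfile(); writeLines("no header here", p3)
  expect_error(read_fcidump(p3), "header")
  p4 <- tempfile()
  writeLines(c("&FCI NORB=2,NELEC=2,MS2=0,", "&END", " 0.5 3 1 1 1"), p4)
  expect_error(read_fcidump(p4), "out of range")
})

test_that("chemist-to-spin-orbital expansion matches a hand-built dense tensor", {
  # single integral (11|11) = 0.6746 on 2 spatial orbitals: expand by the
  # explicit double sum over spins and compare Hamiltonian matrices
  eri <- array(0, dim = rep(2, 4)); eri[1, 1, 1, 1] <- 0.6746
  h1 <- matrix(0, 2, 2)
  ints <- expand_spatial_integrals(h1, eri)
  g <- array(0, dim = rep(4, 4))
  for (sig in 0:1) for (tau in 0:1) {
    p <- 1 + sig; r <- 1 + tau; q <- 1 + sig; s <- 1 + tau
    g[p, r, q, s] <- g[p, r, q, s] + 0.6746
  }
  expect_equal(ints$g, g)
  # and the resulting operator matrix agrees with direct fermionic algebra
  ferm <- second_quantized_hamiltonian(ints)
  M <- fermion_matrix(ferm)
  # (11|11) acts only on the doubly occupied first spatial orbital:
  # <11bar|H|11bar> = 0.6746
  idx <- 3L + 1L  # |0011> = modes 0,1 occupied
  expect_equal(Re(M[idx, idx]), 0.6746, tolerance = 1e-12)
})

test_that("Hamiltonian derivative is exact for linear models and O(shift^2) for quadratic", {
  # provider linear in the coordinate: one spatial orbital, h = a + b x
  lin <- electronic_structure_provider(
    integrals = function(geom, aspace) {
      x <- geom$coords[1, 1]
      expand_spatial_integrals(matrix(-1 + 0.3 * x, 1, 1),
                               array(0.2, dim = rep(1, 4)), core_energy = 0.1 * x)
    }, name = "linear")
  g <- geometry("X", matrix(c(0.7, 0, 0), 1, 3), masses = 1)
  asp <- active_space(2, 1)
  d1 <- hamiltonian_derivative(lin, g, asp, 1, 1, shift_angstrom = 0.001)
  d2 <- hamiltonian_derivative(lin, g, asp, 1, 1, shift_angstrom = 0.05)
  expect_lt(max(abs(qop_matrix(d1) - qop_matrix(d2))), 1e-9)
  # quadratic model: H(x) = H0 + x^2 V -> central difference is exact
  quad <- electronic_structure_provider(
    integrals = function(geom, aspace) {
      x <- geom$coords[1, 1]
      expand_spatial_integrals(matrix(-1 + 0.3 * x^2, 1, 1),
                               array(0, dim = rep(1, 4)))
    }, name = "quadratic")
  x0 <- 0.7
  dq <- hamiltonian_derivative(quad, g, asp, 1, 1, shift_angstrom = 0.01)
  exact_q <- jordan_wigner(second_quantized_hamiltonian(
    expand_spatial_integrals(matrix(2 * 0.3 * x0, 1, 1),
                             array(0, dim = rep(1, 4)))))
  expect_lt(max(abs(qop_matrix(exact_q) - qop_matrix(dq))), 1e-9)
  # cubic model: the leading finite-difference error is O(shift^2)
  cub <- electronic_structure_provider(
    integrals = function(geom, aspace) {
      x <- geom$coords[1, 1]
      expand_spatial_integrals(matrix(-1 + 0.3 * x^3, 1, 1),
                               array(0, dim = rep(1, 4)))
    }, name = "cubic")
  errs <- vapply(c(0.02, 0.01), function(s) {
    d <- hamiltonian_derivative(cub, g, asp, 1, 1, shift_angstrom = s)
    exact <- jordan_wigner(second_quantized_hamiltonian(
      expand_spatial_integrals(matrix(3 * 0.3 * x0^2, 1, 1),
                               array(0, dim = rep(1, 4)))))
    max(abs(qop_matrix(exact) - qop_matrix(d)))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.5)  # halving the shift quarters the error
})

test_that("symmetric diatomic gives equal and opposite derivative operators", {
  prov <- two_level_provider(make_avoided_crossing())
  g <- two_level_geometry(0.4)
  asp <- active_space(2, 2)
  dA <- hamiltonian_derivative(prov, g, asp, 1, 1)
  dB <- hamiltonian_derivative(prov, g, asp, 2, 1)
  expect_lt(max(abs(qop_matrix(dA) + qop_matrix(dB))), 1e-8)
})

test_that("dipole operator handles constant, single-orbital and parity cases", {
  prov0 <- electronic_structure_provider(
    integrals = function(geom, aspace) NULL,
    dipole_integrals = function(geom) list(matrix(0, 2, 2), matrix(0, 2, 2),
                                           matrix(0, 2, 2)),
    name = "zero-dipole")
  ops <- dipole_operator(prov0, two_level_geometry(0), active_space(2, 2))
  expect_true(all(vapply(ops, function(o) length(o$coef) == 0, logical(1))))
  # one spatial orbital, mu = [[d]]: d times the number operator
  prov1 <- electronic_structure_provider(
    integrals = function(geom, aspace) NULL,
    dipole_integrals = function(geom) list(matrix(0.7, 1, 1), matrix(0, 1, 1),
                                           matrix(0, 1, 1)),
    name = "one-orbital")
  opx <- dipole_operator(prov1, two_level_geometry(0), active_space(2, 1))[[1]]
  numop <- jordan_wigner(fermion_operator(2, list(
    list(modes = c(0L, 0L), dagger = c(TRUE, FALSE)),
    list(modes = c(1L, 1L), dagger = c(TRUE, FALSE))), c(0.7, 0.7) + 0i))
  expect_lt(max(abs(qop_matrix(opx) - qop_matrix(numop))), 1e-12)
  # no dipole capability -> error
  prov2 <- electronic_structure_provider(integrals = function(g, a) NULL,
                                         name = "no-dipoles")
  expect_error(dipole_operator(prov2, two_level_geometry(0), active_space(2, 2)),
               "dipole")
})
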