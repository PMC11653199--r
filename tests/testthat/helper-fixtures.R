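# Shared fixtures and independent oracles for the test suite.

# Jordan-Wigner H2/STO-3G Hamiltonian (4 qubits), cached per session
h2_hamiltonian <- local({
  H <- NULL
  function() {
    if (is.null(H)) {
      H <<- jordan_wigner(second_quantized_hamiltonian(h2_sto3g_integrals()))
    }
    H
  }
})

# random Hermitian qubit operator with reproducible words
random_hermitian_qop <- function(n_qubits, n_terms, seed) {
  set.seed(seed)
  letters3 <- c("X", "Y", "Z")
  words <- vapply(seq_len(n_terms), function(i) {
    k <- sample(0:n_qubits, 1)
    if (k == 0) return("I")
    qs <- sort(sample(0:(n_qubits - 1), k))
    paste(paste0(sample(letters3, k, replace = TRUE), qs), collapse = " ")
  }, character(1))
  qop(n_qubits, words, stats::rnorm(n_terms))
}

# random normalized statevector
random_state <- function(n_qubits, seed) {
  set.seed(seed)
  v <- complex(real = stats::rnorm(2^n_qubits),
               imaginary = stats::rnorm(2^n_qubits))
  v / sqrt(sum(Mod(v)^2))
}

# dense matrix inner-product oracle for expectation values
dense_expectation <- function(psi, op) {
  Re(Conj(psi) %*% qop_matrix(op) %*% psi)[1]
}

# brute-force Slater-determinant overlap by summing over permutations
# (per spin block), valid for tiny electron counts
permutation_overlap <- function(alpha_bra, beta_bra, alpha_ket, beta_ket, S) {
  block <- function(occ_a, occ_b) {
    n <- length(occ_a)
    if (n != length(occ_b)) return(0)
    if (n == 0) return(1)
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      }
      out
    }
    sgn <- function(p) {
      s <- 1
      for (i in seq_along(p)) for (j in seq_len(i - 1)) {
        if (p[j] > p[i]) s <- -s
      }
      s
    }
    acc <- 0
    for (p in perms(seq_along(occ_b))) {
      term <- sgn(p)
      for (i in seq_along(occ_a)) {
        term <- term * S[occ_a[i] + 1, occ_b[p[i]] + 1]
      }
      acc <- acc + term
    }
    acc
  }
  block(alpha_bra, alpha_ket) * block(beta_bra, beta_ket)
}

# independent adiabatic-basis TDSE with analytic NACs along a forced
# linear path R(t) = R0 + v t (RK4)
tdse_nac_populations <- function(model, R0, v, t_total, dt = 0.05,
                                 a0 = c(0, 1) + 0i) {
  rhs <- function(R, a) {
    ad <- model$adiabatic(R)
    d12 <- model$nac(R)
    D <- matrix(c(0, -d12, d12, 0), 2, 2)  # D[k,l] = d_kl = <k|d/dR|l>
    -1i * ad$values * a - v * (D %*% a)
  }
  a <- a0
  ts <- seq(0, t_total, by = dt)
  for (t in ts[-length(ts)]) {
    R <- R0 + v * t
    k1 <- rhs(R, a)
    k2 <- rhs(R + v * dt / 2, a + dt / 2 * k1)
    k3 <- rhs(R + v * dt / 2, a + dt / 2 * k2)
    k4 <- rhs(R + v * dt, a + dt * k3)
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  Mod(a)^2
}

# independent NAC-based fewest-switches reference on the 1-D analytic
# model: velocity-Verlet nuclei, RK4 electronic TDSE with analytic NACs,
# classic flux-based hop probabilities, rescaling along the velocity,
# and the same energy-based decoherence correction as the package
fssh_nac_reference <- function(model, R0, v0, mass, state, dt_n, n_steps,
                               n_sub = 20L, rng, decoherence_C = 0.1) {
  R <- R0; v <- v0; m <- state
  a <- c(0, 0) + 0i; a[m] <- 1
  for (step in seq_len(n_steps)) {
    grad <- model$gradients(R)[m]
    Rn <- R + v * dt_n - grad / (2 * mass) * dt_n^2
    gradn <- model$gradients(Rn)[m]
    vn <- v - (grad + gradn) * dt_n / (2 * mass)
    # electronic propagation + accumulated hop flux over the step
    dt_e <- dt_n / n_sub
    hop_flux <- c(0, 0)
    for (k in seq_len(n_sub)) {
      frac <- (k - 0.5) / n_sub
      Rk <- R + frac * (Rn - R)
      vk <- v + frac * (vn - v)
      ad <- model$adiabatic(Rk)
      d12 <- model$nac(Rk)
      D <- matrix(c(0, -d12, d12, 0), 2, 2)  # D[k,l] = d_kl
      rhs <- function(aa) -1i * ad$values * aa - vk * (D %*% aa)
      k1 <- rhs(a); k2 <- rhs(a + dt_e / 2 * k1)
      k3 <- rhs(a + dt_e / 2 * k2); k4 <- rhs(a + dt_e * k3)
      for (l in 1:2) {
        if (l == m) next
        # contribution to d(rho_mm): -2 Re(v d_ml a_l a_m^*); negative
        # values are population flowing out of m toward l
        fl <- -2 * Re(vk * D[m, l] * a[l] * Conj(a[m])) * dt_e
        if (fl < 0) hop_flux[l] <- hop_flux[l] - fl
      }
      a <- a + dt_e / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    pm <- Mod(a[m])^2
    probs <- if (pm > 0) pmin(hop_flux / pm, 1) else c(0, 0)
    # energy-based decoherence (same closed form as the package; applied
    # after the step's hop probabilities are formed, affecting only the
    # subsequent evolution)
    ekin_dec <- 0.5 * mass * vn^2
    if (ekin_dec > 0 && Mod(a[m])^2 > 0) {
      adn <- model$adiabatic(Rn)
      for (l in 1:2) {
        if (l == m) next
        gapd <- abs(adn$values[l] - adn$values[m])
        if (gapd > 0) {
          a[l] <- a[l] * exp(-dt_n / ((1 / gapd) * (1 + decoherence_C / ekin_dec)))
        }
      }
      rest <- sum(Mod(a[-m])^2)
      a[m] <- a[m] * sqrt((1 - rest) / Mod(a[m])^2)
    }
    xi <- rng(1)
    cum <- cumsum(probs)
    for (l in 1:2) {
      if (l != m && probs[l] > 0 && xi < cum[l]) {
        ad <- model$adiabatic(Rn)
        ekin <- 0.5 * mass * vn^2
        ekin_new <- ekin + ad$values[m] - ad$values[l]
        if (ekin_new >= 0) {
          vn <- sign(vn) * sqrt(2 * ekin_new / mass)
          m <- l
        }
        break
      }
    }
    R <- Rn; v <- vn
  }
  list(R = R, v = v, state = m, populations = Mod(a)^2)
}

# deterministic uniform stream shared with the package convention
test_rng <- function(seed) {
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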