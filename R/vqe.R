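# Variational solvers: VQE for the ground state, penalty-based VQD for
# excited states, and the sequential state-set driver with warm starts.

.new_variational_state <- function(theta, psi, energy, n_iterations,
                                   converged, grad_norm, flags = character(0)) {
  structure(list(theta = theta, statevector = psi, energy = energy,
                 n_iterations = n_iterations, converged = converged,
                 grad_norm = grad_norm, flags = flags),
            class = "variational_state")
}

#' @export
print.variational_state <- function(x, ...) {
  cat(sprintf("<variational_state: E = %.10f hartree, %d iterations, %s%s>\n",
              x$energy, x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

#' Variational quantum eigensolver (statevector simulation)
#'
#' BFGS minimization of `<psi(theta)|H|psi(theta)>` with analytic
#' parameter gradients from an adjoint sweep, starting at `theta0`
#' (cold start `theta = 0` prepares the Hartree-Fock reference).
#'
#' @param H a Hermitian `qubit_operator`.
#' @param ansatz a `kupccgsd_ansatz`.
#' @param theta0 starting parameters (default zeros).
#' @param maxit iteration cap (default 500).
#' @param grad_tol gradient-norm convergence criterion (default 1e-6).
#' @param frozen_mask optional logical vector; parameters marked TRUE are
#'   held at their `theta0` values.
#' @return a `variational_state`.
#' @export
vqe <- function(H, ansatz, theta0 = rep(0, ansatz$n_params), maxit = 500L,
                grad_tol = 1e-6, frozen_mask = NULL) {
  vqd(H, ansatz, lower_states = list(), lambda = numeric(0),
      theta0 = theta0, maxit = maxit, grad_tol = grad_tol,
      frozen_mask = frozen_mask)
}

#' Variational quantum deflation for excited states
#'
#' Minimizes `<H> + sum_j lambda_j |<psi_j|psi(theta)>|^2`; the overlap
#' penalty restricts the search to the subspace orthogonal to the
#' supplied lower states. The penalty weight should exceed the energy
#' gap to the target state; the customary choice is the magnitude of the
#' VQE ground-state energy.
#'
#' @param H a Hermitian `qubit_operator`.
#' @param ansatz a `kupccgsd_ansatz`.
#' @param lower_states list of `variational_state`s (or bare
#'   statevectors) to deflate against.
#' @param lambda positive penalty weight(s), recycled over
#'   `lower_states`.
#' @param theta0 starting parameters.
#' @param maxit iteration cap; @param grad_tol gradient-norm criterion.
#' @param orthogonality_tol final squared-overlap threshold above which
#'   the state is flagged as collapsed onto a lower state.
#' @param frozen_mask optional logical mask of parameters to freeze.
#' @param multistart number of deterministic perturbed restarts tried
#'   when a start collapses onto a lower state. A cold start sits at a
#'   Brillouin-type stationary point of the penalized cost (the gradient
#'   along every single excitation vanishes at the closed-shell
#'   reference), so deflation from `theta = 0` needs the perturbed
#'   restarts; warm starts normally succeed immediately.
#' @return a `variational_state`.
#' @export
vqd <- function(H, ansatz, lower_states, lambda, theta0 = rep(0, ansatz$n_params),
                maxit = 500L, grad_tol = 1e-6, orthogonality_tol = 1e-5,
                frozen_mask = NULL, multistart = 4L) {
  n <- ansatz$n_params
  alt <- rep_len(c(1, -1), n)
  starts <- list(theta0, theta0 + 0.15, theta0 + 0.15 * alt,
                 theta0 - 0.15, theta0 - 0.15 * alt,
                 theta0 + 0.3 * seq_len(n) / n)
  starts <- starts[seq_len(min(1L + multistart, length(starts)))]
  best <- NULL
  for (th0 in starts) {
    cand <- .vqd_once(H, ansatz, lower_states, lambda, th0, maxit,
                      grad_tol, orthogonality_tol, frozen_mask)
    if (is.null(best) || (!length(cand$flags) && length(best$flags)) ||
        (length(cand$flags) == 0 && length(best$flags) == 0 &&
         cand$energy < best$energy)) {
      best <- cand
    }
    if (!length(best$flags)) break
  }
  best
}

.vqd_once <- function(H, ansatz, lower_states, lambda, theta0,
                      maxit, grad_tol, orthogonality_tol, frozen_mask) {
  if (!is_hermitian_qop(H)) stop("H must be Hermitian")
  if (length(lower_states) > 0) {
    if (any(lambda <= 0)) stop("penalty weight lambda must be positive")
    lambda <- rep_len(lambda, length(lower_states))
  }
  chis <- lapply(lower_states, function(s) {
    if (inherits(s, "variational_state")) s$statevector else s
  })
  free <- if (is.null(frozen_mask)) rep(TRUE, ansatz$n_params) else !frozen_mask
  th_full <- theta0
  fn <- function(par) {
    th <- th_full; th[free] <- par
    .cost_and_gradient(ansatz, th, H, chis, lambda, want_gradient = FALSE)$cost
  }
  gr <- function(par) {
    th <- th_full; th[free] <- par
    .cost_and_gradient(ansatz, th, H, chis, lambda)$gradient[free]
  }
  fit <- stats::optim(theta0[free], fn = fn, gr = gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  th <- th_full; th[free] <- fit$par
  res <- .cost_and_gradient(ansatz, th, H, chis, lambda)
  gnorm <- sqrt(sum(res$gradient[free]^2))
  flags <- character(0)
  conv <- gnorm <= max(grad_tol, 1e-6) || fit$convergence == 0
  if (!conv) flags <- c(flags, "not_converged")
  for (j in seq_along(chis)) {
    ov2 <- Mod(sum(Conj(chis[[j]]) * res$psi))^2
    if (ov2 > orthogonality_tol) {
      flags <- c(flags, sprintf("overlap_with_lower_%d=%.2e", j, ov2))
    }
  }
  .new_variational_state(th, res$psi, res$energy,
                         n_iterations = unname(fit$counts["gradient"]),
                         converged = conv && !length(flags), grad_norm = gnorm,
                         flags = flags)
}

#' Solve an ordered set of electronic states at one geometry
#'
#' Sequential VQE (ground state) then VQD (excited states, each deflated
#' against all previously converged states), optionally warm-started from
#' the previous time step's parameters. States are sorted by energy with
#' a stable sort so that warm-started state tracking is preserved through
#' degeneracies.
#'
#' @param H a Hermitian `qubit_operator`.
#' @param n_states number of states (>= 1).
#' @param ansatz a `kupccgsd_ansatz` used for every state
#'   (`ansatz_policy = "uniform"`), or the policy `"grow"` under which
#'   state m uses `m` layers with the lower layers frozen at their
#'   warm-start values.
#' @param warm_start an `electronic_state_set` from a nearby geometry, or
#'   a list of theta vectors, or NULL for a cold (theta = 0) start.
#' @param lambda penalty weight; default is the magnitude of the VQE
#'   ground-state energy.
#' @param ansatz_policy `"uniform"` or `"grow"`.
#' @param ... passed to [vqd()].
#' @return an object of class `electronic_state_set`.
#' @export
solve_state_set <- function(H, n_states, ansatz, warm_start = NULL,
                            lambda = NULL, ansatz_policy = c("uniform", "grow"),
                            ...) {
  stopifnot(n_states >= 1)
  ansatz_policy <- match.arg(ansatz_policy)
  get_theta0 <- function(m, n_par) {
    th <- NULL
    if (inherits(warm_start, "electronic_state_set") &&
        length(warm_start$states) >= m) {
      th <- warm_start$states[[m]]$theta
    } else if (is.list(warm_start) && length(warm_start) >= m) {
      th <- warm_start[[m]]
    }
    if (is.null(th)) th <- numeric(0)
    c(th, numeric(max(0, n_par - length(th))))[seq_len(n_par)]
  }
  states <- vector("list", n_states)
  anz <- ansatz
  states[[1]] <- vqe(H, anz, theta0 = get_theta0(1, anz$n_params), ...)
  lam_used <- if (is.null(lambda)) abs(states[[1]]$energy) else lambda
  for (m in seq_len(n_states - 1L) + 1L) {
    if (ansatz_policy == "grow") {
      anz <- build_kupccgsd(ansatz$n_qubits, ansatz$n_electrons, k = m)
      th0 <- get_theta0(m, anz$n_params)
      frozen <- rep(FALSE, anz$n_params)
      # freeze the layers already converged for the lower states unless
      # the warm start supplies a full-length vector
      if (length(get_theta0(m, ansatz$n_params)) < anz$n_params) {
        frozen[seq_len((m - 1L) * ansatz$n_params)] <- TRUE
      }
    } else {
      th0 <- get_theta0(m, anz$n_params)
      frozen <- NULL
    }
    states[[m]] <- vqd(H, anz, lower_states = states[seq_len(m - 1L)],
                       lambda = lam_used, theta0 = th0,
                       frozen_mask = frozen, ...)
  }
  energies <- vapply(states, function(s) s$energy, numeric(1))
  ord <- order(energies)  # stable
  states <- states[ord]
  energies <- energies[ord]
  nv <- length(states)
  overlap2 <- matrix(0, nv, nv)
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    overlap2[a, b] <- Mod(sum(Conj(states[[a]]$statevector) *
                              states[[b]]$statevector))^2
  }
  flagged <- any(vapply(states, function(s) length(s$flags) > 0, logical(1)))
  structure(list(states = states, energies = energies,
                 lambda_used = lam_used, overlap2 = overlap2,
                 flagged = flagged),
            class = "electronic_state_set")
}

#' @export
print.electronic_state_set <- function(x, ...) {
  cat(sprintf("<electronic_state_set: %d states%s>\n", length(x$states),
              if (x$flagged) ", FLAGGED" else ""))
  for (m in seq_along(x$states)) {
    cat(sprintf("  S%d  E = %.10f hartree (%d iterations)\n", m - 1L,
                x$energies[m], x$states[[m]]$n_iterations))
  }
  invisible(x)
}
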