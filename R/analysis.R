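# Ensemble analysis: adiabatic population curves, kinetic-model fits,
# internal-coordinate and hopping-geometry statistics, and the
# photoisomerization quantum yield with its binomial uncertainty.

#' Adiabatic populations from a trajectory ensemble
#'
#' The fraction of trajectories whose active state is m at each grid
#' time. Trajectories that terminated early (ground-state dwell rule)
#' are held at their final state for the rest of the grid; with
#' `hold_terminated = FALSE` they instead drop out of the denominator.
#'
#' @param trajectories list of `trajectory` objects.
#' @param grid time grid (fs); NULL: the first trajectory's grid
#'   extended to the longest run.
#' @param n_states number of states (default from the trajectories).
#' @param hold_terminated see above.
#' @return object of class `population_series` with `time`, `fractions`
#'   (grid x states matrix) and `n_trajectories`.
#' @export
populations <- function(trajectories, grid = NULL, n_states = NULL,
                        hold_terminated = TRUE) {
  stopifnot(length(trajectories) >= 1)
  if (is.null(n_states)) {
    n_states <- trajectories[[1]]$config$n_states
  }
  if (is.null(grid)) {
    tmax <- max(vapply(trajectories, function(t) max(t$steps$time), numeric(1)))
    grid <- seq(0, tmax, by = trajectories[[1]]$config$dt_nuclear)
  }
  if (length(grid) == 0) stop("empty time grid")
  counts <- matrix(0, length(grid), n_states)
  denom <- numeric(length(grid))
  for (tr in trajectories) {
    st <- tr$steps
    for (gi in seq_along(grid)) {
      t <- grid[gi]
      if (t <= max(st$time) + 1e-9) {
        act <- st$active[which.min(abs(st$time - t))]
      } else if (hold_terminated) {
        act <- tr$final_state
      } else {
        next
      }
      counts[gi, act] <- counts[gi, act] + 1
      denom[gi] <- denom[gi] + 1
    }
  }
  frac <- counts / pmax(denom, 1)
  colnames(frac) <- paste0("S", seq_len(n_states) - 1L)
  structure(list(time = grid, fractions = frac,
                 n_trajectories = length(trajectories)),
            class = "population_series")
}

#' @export
print.population_series <- function(x, ...) {
  cat(sprintf("<population_series: %d time points, %d states, %d trajectories>\n",
              length(x$time), ncol(x$fractions), x$n_trajectories))
  invisible(x)
}

#' Delayed-exponential fit of an excited-state population
#'
#' `P(t) = 1` for `t <= t0`, `exp(-(t - t0)/tau1)` after: a plateau
#' followed by first-order decay. The reported lifetime is `tau1 + t0`.
#'
#' @param series a `population_series`.
#' @param state column to fit (name or index; default `"S1"`).
#' @param t0 fixed delay time (fs), or NULL to fit it too.
#' @return object of class `kinetic_fit` with `tau1`, `t0`, `lifetime`,
#'   `residual_norm`, `flags`.
#' @export
fit_delayed_exponential <- function(series, state = "S1", t0 = NULL) {
  t <- series$time
  p <- series$fractions[, state]
  if (max(p) - min(p) < 1e-3) {
    return(structure(list(model = "delayed_exponential", tau1 = Inf,
                          t0 = if (is.null(t0)) NA_real_ else t0,
                          lifetime = Inf, residual_norm = 0,
                          flags = "unidentifiable: series does not decay"),
                     class = "kinetic_fit"))
  }
  model <- function(par) {
    tau1 <- par[1]; tt0 <- if (is.null(t0)) par[2] else t0
    pred <- ifelse(t <= tt0, 1, exp(-(t - tt0) / tau1))
    sum((pred - p)^2)
  }
  start <- if (is.null(t0)) c(50, 10) else 50
  fit <- stats::optim(start, model, method = if (is.null(t0)) "Nelder-Mead" else "Brent",
                      lower = if (is.null(t0)) -Inf else 1e-3,
                      upper = if (is.null(t0)) Inf else 1e6,
                      control = list(maxit = 5000, reltol = 1e-14))
  tau1 <- fit$par[1]; tt0 <- if (is.null(t0)) fit$par[2] else t0
  flags <- character(0)
  if (tau1 <= 0) flags <- "nonpositive tau"
  structure(list(model = "delayed_exponential", tau1 = tau1, t0 = tt0,
                 lifetime = tau1 + tt0, residual_norm = sqrt(fit$value),
                 flags = flags),
            class = "kinetic_fit")
}

# closed form of the intermediate population of the irreversible chain
# A -> B -> C with A(0) = 1: rates kA = 1/tau2 (S2 decay), kB = 1/tau1
.sequential_intermediate <- function(t, tau2, tau1) {
  if (abs(tau1 - tau2) < 1e-9 * max(tau1, tau2)) {
    return(t * exp(-t / tau1) / tau1)   # equal-rate limit
  }
  kA <- 1 / tau2; kB <- 1 / tau1
  kA / (kB - kA) * (exp(-kA * t) - exp(-kB * t))
}

#' Two-step irreversible kinetics fit
#'
#' Simultaneous least squares of `P_S2(t) = exp(-t/tau2)` and the
#' sequential-intermediate closed form for `P_S1` (with its equal-rate
#' limit handled analytically).
#'
#' @param series a `population_series` containing columns S1 and S2.
#' @return a `kinetic_fit` with `tau1`, `tau2`.
#' @export
fit_sequential_kinetics <- function(series) {
  t <- series$time
  p2 <- series$fractions[, "S2"]; p1 <- series$fractions[, "S1"]
  if (max(p2) - min(p2) < 1e-3) {
    return(structure(list(model = "sequential", tau1 = NA_real_,
                          tau2 = Inf, residual_norm = 0,
                          flags = "unidentifiable: S2 does not decay"),
                     class = "kinetic_fit"))
  }
  obj <- function(par) {
    tau2 <- exp(par[1]); tau1 <- exp(par[2])
    sum((exp(-t / tau2) - p2)^2) +
      sum((.sequential_intermediate(t, tau2, tau1) - p1)^2)
  }
  fit <- stats::optim(log(c(20, 50)), obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
  structure(list(model = "sequential", tau2 = exp(fit$par[1]),
                 tau1 = exp(fit$par[2]), residual_norm = sqrt(fit$value),
                 flags = character(0)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit: %s>\n", x$model))
  if (x$model == "delayed_exponential") {
    cat(sprintf("  tau1 = %.3f fs, t0 = %.3f fs, lifetime = %.3f fs\n",
                x$tau1, x$t0, x$lifetime))
  } else {
    cat(sprintf("  tau2 = %.3f fs, tau1 = %.3f fs\n", x$tau2, x$tau1))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Internal coordinate of a geometry
#'
#' Bond length (angstrom), bond angle (degrees, in [0, 180]) or proper
#' dihedral (degrees; signed by the IUPAC right-hand convention in
#' (-180, 180], optionally folded to [0, 180] for cis/trans statistics).
#'
#' @param geom a `geometry`.
#' @param indices 2, 3 or 4 one-based atom indices.
#' @param fold_dihedral fold the dihedral to [0, 180] (default TRUE, the
#'   convention used for cis/trans classification).
#' @export
internal_coordinate <- function(geom, indices, fold_dihedral = TRUE) {
  x <- geom$coords[indices, , drop = FALSE]
  if (length(indices) == 2) {
    return(sqrt(sum((x[1, ] - x[2, ])^2)) / au$bohr_per_angstrom)
  }
  if (length(indices) == 3) {
    u <- x[1, ] - x[2, ]; v <- x[3, ] - x[2, ]
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    return(acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  }
  if (length(indices) == 4) {
    b1 <- x[2, ] - x[1, ]; b2 <- x[3, ] - x[2, ]; b3 <- x[4, ] - x[3, ]
    n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
    if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
      stop("dihedral undefined: collinear atoms")
    }
    m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
    ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    return(if (fold_dihedral) abs(ang) else ang)
  }
  stop("indices must have length 2, 3 or 4")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Internal coordinates at hopping geometries
#'
#' Evaluates the requested internal coordinates at every logged hop
#' between the given state pair and reports per-coordinate means and
#' standard deviations.
#'
#' @param trajectories list of `trajectory` objects.
#' @param coordinate_specs named list of index vectors (see
#'   [internal_coordinate()]).
#' @param from,to restrict to hops between these states (1-based; NULL
#'   keeps all non-frustrated hops).
#' @return list with `table` (one row per hop) and `summary` (mean, sd
#'   per coordinate). No hops gives empty tables, not an error.
#' @export
hopping_statistics <- function(trajectories, coordinate_specs,
                               from = NULL, to = NULL) {
  rows <- list()
  for (tr in trajectories) {
    if (nrow(tr$hops) == 0) next
    for (h in seq_len(nrow(tr$hops))) {
      if (tr$hops$frustrated[h]) next
      if (!is.null(from) && tr$hops$from[h] != from) next
      if (!is.null(to) && tr$hops$to[h] != to) next
      g <- tr$hop_geometries[[h]]
      vals <- vapply(coordinate_specs, function(ix)
        internal_coordinate(g, ix), numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(time = tr$hops$time[h], from = tr$hops$from[h],
                   to = tr$hops$to[h], t(vals))
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), from = integer(0), to = integer(0))
  summ <- if (nrow(tab) > 0) {
    data.frame(coordinate = names(coordinate_specs),
               mean = vapply(names(coordinate_specs),
                             function(nm) mean(tab[[nm]]), numeric(1)),
               sd = vapply(names(coordinate_specs),
                           function(nm) stats::sd(tab[[nm]]), numeric(1)))
  } else {
    data.frame(coordinate = character(0), mean = numeric(0), sd = numeric(0))
  }
  list(table = tab, summary = summ)
}

#' Photoisomerization quantum yield with binomial uncertainty
#'
#' Trajectories that ended in the ground state are classified by their
#' final folded dihedral: at or below `cis_cutoff` degrees they count as
#' regenerated reactant, at or above `trans_cutoff` as photoisomerized;
#' the band in between stays unassigned. The yield is
#' `Phi = isomerized / assigned` with the binomial standard deviation
#' `sigma = sqrt(Phi (1 - Phi) / n_assigned)`.
#'
#' @param trajectories list of `trajectory` objects.
#' @param dihedral_indices 4 atom indices of the classifying dihedral.
#' @param cis_cutoff,trans_cutoff degrees, `0 < cis < trans < 180`.
#' @return list with `yield`, `sd`, `n_cis`, `n_trans`, `n_unassigned`,
#'   `n_ground`.
#' @export
quantum_yield <- function(trajectories, dihedral_indices,
                          cis_cutoff = 50, trans_cutoff = 125) {
  stopifnot(cis_cutoff > 0, cis_cutoff < trans_cutoff, trans_cutoff < 180)
  n_cis <- n_trans <- n_un <- n_ground <- 0L
  for (tr in trajectories) {
    if (tr$final_state != 1L) next
    n_ground <- n_ground + 1L
    g <- tr$geometries[[length(tr$geometries)]]
    dih <- internal_coordinate(g, dihedral_indices, fold_dihedral = TRUE)
    if (dih <= cis_cutoff) n_cis <- n_cis + 1L
    else if (dih >= trans_cutoff) n_trans <- n_trans + 1L
    else n_un <- n_un + 1L
  }
  n_assigned <- n_cis + n_trans
  if (n_assigned == 0) {
    return(list(yield = NA_real_, sd = NA_real_, n_cis = n_cis,
                n_trans = n_trans, n_unassigned = n_un,
                n_ground = n_ground, flags = "no assigned outcomes"))
  }
  phi <- n_trans / n_assigned
  list(yield = phi, sd = sqrt(phi * (1 - phi) / n_assigned),
       n_cis = n_cis, n_trans = n_trans, n_unassigned = n_un,
       n_ground = n_ground, flags = character(0))
}

#' Quantum yield from explicit outcome counts
#'
#' The same estimator as [quantum_yield()] applied to pre-counted
#' reactant/product numbers.
#'
#' @param n_cis,n_trans assigned outcome counts.
#' @export
quantum_yield_counts <- function(n_cis, n_trans) {
  n <- n_cis + n_trans
  if (n == 0) stop("no assigned outcomes")
  phi <- n_trans / n
  list(yield = phi, sd = sqrt(phi * (1 - phi) / n), n_assigned = n)
}

#' Write a population series as TSV
#' @param series a `population_series`; @param path file path.
#' @export
write_population_series <- function(series, path) {
  df <- data.frame(time_fs = series$time, series$fractions,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
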