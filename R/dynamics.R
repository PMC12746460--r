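# Population propagation and dissipation accumulation for one realization.

#' Propagate exciton populations with the rate master equation
#'
#' Integrates `dP_A/dt = sum_{B != A} [-K_BA P_A + K_AB P_B]` with the
#' classical fourth-order Runge-Kutta scheme at a fixed step.  The rate
#' matrix conserves total population exactly, so `sum_A P_A(t) = 1` holds to
#' accumulation roundoff at every step, and golden-rule rate equations
#' preserve positivity.
#'
#' Alongside the populations the propagator accumulates the running time
#' integrals `Q_A(t) = integral_0^t P_A(t') dt'` by the trapezoidal rule at
#' full step resolution; these are what time-integrated dissipation fields
#' are built from (see [accumulate_dissipation()]).
#'
#' @param K Rate matrix with `K[A, B]` the rate constant of transfer from
#'   site A to site B (fs^-1, zero diagonal), or a `rate_set` from
#'   [build_rate_set()].
#' @param P0 Initial populations (non-negative, summing to 1).
#' @param dt Integration step in fs (default 0.5).
#' @param t_end Final time in fs; must be an integer multiple of `dt`.
#' @param store_stride Store every `store_stride`-th step (the initial and
#'   final points are always stored).
#' @return An object of class `population_trajectory`: list with `t` (fs),
#'   `P` (stored steps x sites), `Q` (same shape, fs), `dt`, `labels`.
#' @export
propagate_populations <- function(K, P0, dt = 0.5, t_end, store_stride = 1L) {
  if (inherits(K, "rate_set")) {
    labels <- K$labels
    K <- K$K
  } else {
    labels <- rownames(K)
  }
  K <- as.matrix(K)
  n <- nrow(K)
  if (is.null(labels)) labels <- paste0("site", seq_len(n))
  if (ncol(K) != n || any(K < 0) || any(diag(K) != 0)) {
    stop_validation("`K` must be a square non-negative rate matrix with zero diagonal")
  }
  if (length(P0) != n) stop_validation("`P0` length must match the number of sites")
  if (any(P0 < 0)) stop_validation("`P0` must be non-negative")
  if (abs(sum(P0) - 1) > 1e-10) stop_validation("`P0` must sum to 1")
  if (dt <= 0) stop_validation("`dt` must be positive")
  n_steps <- round(t_end / dt)
  if (n_steps < 1 || abs(n_steps * dt - t_end) > 1e-9 * max(1, t_end)) {
    stop_validation("`t_end` must be a positive integer multiple of `dt`")
  }
  store_stride <- max(1L, as.integer(store_stride))

  # generator: dP/dt = M P
  M <- t(K)
  diag(M) <- -rowSums(K)

  keep <- unique(c(seq(0L, n_steps, by = store_stride), n_steps))
  n_keep <- length(keep)
  P_out <- matrix(0, n_keep, n, dimnames = list(NULL, labels))
  Q_out <- matrix(0, n_keep, n, dimnames = list(NULL, labels))
  P <- as.numeric(P0)
  Q <- numeric(n)
  P_out[1L, ] <- P
  slot <- 2L
  for (step in seq_len(n_steps)) {
    k1 <- M %*% P
    k2 <- M %*% (P + dt / 2 * k1)
    k3 <- M %*% (P + dt / 2 * k2)
    k4 <- M %*% (P + dt * k3)
    P_new <- P + dt / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    Q <- Q + dt / 2 * (P + P_new)
    P <- P_new
    if (slot <= n_keep && step == keep[slot]) {
      P_out[slot, ] <- P
      Q_out[slot, ] <- Q
      slot <- slot + 1L
    }
  }
  structure(list(t = keep * dt, P = P_out, Q = Q_out, dt = dt, labels = labels),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<population_trajectory> %d sites, %d stored steps to %.4g fs\n",
              ncol(x$P), n, x$t[n]))
  cat("final populations:", paste(sprintf("%s=%.4f", x$labels, x$P[n, ]),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Instantaneous dissipation function D_A(omega, t)
#'
#' Frequency-resolved rate of energy flow into the local environment of
#' chromophore A,
#' `D_A(omega, t) = sum_{B != A} [J^A_BA(omega) P_A(t) + J^A_AB(omega) P_B(t)]`.
#' Negative values indicate energy absorption from the environment.
#'
#' @param A Site label or index.
#' @param rateset A `rate_set` from [build_rate_set()].
#' @param P Populations: a vector (one time) or a matrix (times x sites).
#' @return A vector over the rate set's frequency grid, or a matrix
#'   (frequencies x times); units cm^-1 fs^-1 per cm^-1.
#' @export
dissipation_function <- function(A, rateset, P) {
  if (!inherits(rateset, "rate_set")) stop_validation("expected a `rate_set`")
  iA <- site_index(rateset, A)
  n <- rateset$n_sites
  Pm <- if (is.matrix(P)) t(P) else matrix(P, nrow = n)
  if (nrow(Pm) != n) stop_validation("`P` must have one entry per site")
  out_A <- rowSums(rateset$J_out[, iA, , drop = TRUE])
  D <- outer(out_A, Pm[iA, ]) + rateset$J_in[, iA, ] %*% Pm
  if (ncol(D) == 1L) as.numeric(D) else D
}

#' Accumulate the time-integrated dissipation field
#'
#' Builds the accumulated chromophore dissipation
#' `E_A(omega, t) = integral_0^t D_A(omega, t') dt'` at the requested
#' snapshot times, together with the total `E_Tot = sum_A E_A`.  Because the
#' dissipative spectral densities are constant within a realization, the
#' time integral factorizes exactly through the trapezoidal population
#' integrals `Q_A(t)` carried by the trajectory; snapshot times falling
#' between stored steps are interpolated linearly.
#'
#' @param rateset A `rate_set` from [build_rate_set()].
#' @param traj A [propagate_populations()] trajectory on consistent grids.
#' @param snapshot_times Times (fs) at which to extract the field; all must
#'   lie within the propagated interval.
#' @return An object of class `dissipation_field`: list with `omega_grid`
#'   (cm^-1), `delta_omega`, `snapshot_times`, `E_acc` (array
#'   frequencies x sites x snapshots, cm^-1 per cm^-1), `E_tot`
#'   (frequencies x snapshots) and `labels`.
#' @export
accumulate_dissipation <- function(rateset, traj, snapshot_times) {
  if (!inherits(rateset, "rate_set")) stop_validation("expected a `rate_set`")
  if (!inherits(traj, "population_trajectory")) {
    stop_validation("expected a `population_trajectory`")
  }
  t_max <- traj$t[length(traj$t)]
  if (any(snapshot_times < 0) || any(snapshot_times > t_max + 1e-9)) {
    stop_validation("snapshot times must lie within [0, t_end]")
  }
  n <- rateset$n_sites
  n_w <- length(rateset$omega_grid)
  n_s <- length(snapshot_times)
  Qs <- vapply(seq_len(n), function(a) {
    stats::approx(traj$t, traj$Q[, a], xout = snapshot_times, rule = 2)$y
  }, numeric(n_s))
  Qs <- matrix(Qs, nrow = n_s)   # snapshots x sites
  E_acc <- array(0, dim = c(n_w, n, n_s),
                 dimnames = list(NULL, rateset$labels, NULL))
  for (a in seq_len(n)) {
    out_a <- rowSums(rateset$J_out[, a, , drop = TRUE])
    E_acc[, a, ] <- outer(out_a, Qs[, a]) +
      rateset$J_in[, a, ] %*% t(Qs)
  }
  E_tot <- apply(E_acc, c(1, 3), sum)
  structure(list(omega_grid = rateset$omega_grid,
                 delta_omega = rateset$delta_omega,
                 snapshot_times = snapshot_times,
                 E_acc = E_acc, E_tot = matrix(E_tot, nrow = n_w),
                 labels = rateset$labels),
            class = "dissipation_field")
}

#' @export
print.dissipation_field <- function(x, ...) {
  ns <- length(x$snapshot_times)
  tot <- sum(x$E_tot[, ns]) * x$delta_omega
  cat(sprintf("<dissipation_field> %d frequencies, %d sites, snapshots at %s fs\n",
              length(x$omega_grid), length(x$labels),
              paste(signif(x$snapshot_times, 4), collapse = ", ")))
  cat(sprintf("net dissipated energy at %g fs: %.4g cm^-1\n",
              x$snapshot_times[ns], tot))
  invisible(x)
}

#' Frequency-band totals of an accumulated dissipation field
#'
#' Integrates `E_A(omega, t)` over contiguous frequency bands, per
#' chromophore and in total, at one snapshot.  Useful for comparing the
#' contribution of low-frequency protein/breathing modes against far-detuned
#' high-frequency intramolecular vibrations.
#'
#' @param field A [accumulate_dissipation()] result.
#' @param band_edges Strictly increasing band boundaries (cm^-1) covering
#'   sub-ranges of the frequency grid; band i is `[edge_i, edge_{i+1})`.
#' @param snapshot Index or time (fs) of the snapshot to summarize; defaults
#'   to the last one.
#' @return A data frame with one row per band: `band_lo`, `band_hi`, one
#'   column per chromophore, and `total` (all cm^-1).
#' @export
band_summary <- function(field, band_edges, snapshot = NULL) {
  if (!inherits(field, "dissipation_field")) {
    stop_validation("expected a `dissipation_field`")
  }
  if (length(band_edges) < 2L || any(diff(band_edges) <= 0)) {
    stop_validation("`band_edges` must be strictly increasing with >= 2 values")
  }
  rng <- range(field$omega_grid)
  if (band_edges[1] > rng[2] || band_edges[length(band_edges)] < rng[1]) {
    stop_validation("`band_edges` do not overlap the frequency grid")
  }
  if (is.null(snapshot)) {
    s <- length(field$snapshot_times)
  } else if (snapshot %in% seq_along(field$snapshot_times)) {
    s <- as.integer(snapshot)
  } else {
    s <- which(abs(field$snapshot_times - snapshot) < 1e-9)
    if (length(s) != 1L) stop_validation("`snapshot` does not match a stored snapshot")
  }
  bin <- findInterval(field$omega_grid, band_edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  n_band <- length(band_edges) - 1L
  slice <- matrix(field$E_acc[, , s], nrow = length(field$omega_grid))
  res <- matrix(0, n_band, length(field$labels),
                dimnames = list(NULL, field$labels))
  for (b in seq_len(n_band)) {
    sel <- bin == b
    if (any(sel)) {
      res[b, ] <- colSums(slice[sel, , drop = FALSE]) * field$delta_omega
    }
  }
  out <- data.frame(band_lo = band_edges[-length(band_edges)],
                    band_hi = band_edges[-1], res, check.names = FALSE)
  out$total <- rowSums(res)
  out
}
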