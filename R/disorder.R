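# Quasi-static Gaussian site-energy disorder: counter-based sampling and
# ensemble averaging with shared fast-bath quantities.

# ---- counter-based pseudo-random normals -------------------------------
#
# Disorder draws must be fully determined by (seed, realization, site) so
# that parallel execution cannot reorder them.  No counter-based generator
# is available through R's RNG API, so a 32-bit splitmix-style avalanche
# hash is implemented here with exact integer arithmetic on doubles
# (products are kept below 2^53 by 16-bit splitting).  The hash output is
# mapped to (0,1) and through the normal quantile function.

# (a * b) mod 2^32 for a, b in [0, 2^32)
mulmod32 <- function(a, b) {
  bh <- b %/% 65536
  bl <- b %% 65536
  (a * bl + ((a * bh) %% 65536) * 65536) %% 4294967296
}

# bitwise xor for values in [0, 2^32), via 16-bit halves
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

# one avalanche round (murmur3-style finalizer with a golden-ratio offset)
mix32 <- function(z) {
  z <- (z + 2654435769) %% 4294967296
  z <- xor32(z, z %/% 65536)
  z <- mulmod32(z, 2246822507)
  z <- xor32(z, z %/% 8192)
  z <- mulmod32(z, 3266489909)
  xor32(z, z %/% 65536)
}

# standard-normal deviate keyed on the counter triple
counter_normal <- function(seed, realization, site) {
  h <- mix32(seed %% 4294967296)
  h <- mix32(xor32(h, realization %% 4294967296))
  h <- mix32(xor32(h, site %% 4294967296))
  stats::qnorm((h + 0.5) / 4294967296)
}

#' Disorder ensemble specification
#'
#' @param sigma_per_site Gaussian site-energy disorder width per chromophore
#'   (cm^-1, >= 0); a scalar is recycled.  Typically the
#'   [sigma_slow()] widths of the slow bath components.
#' @param n_realizations Number of independent noise realizations (>= 1).
#' @param seed Integer seed; together with the realization and site indices
#'   it fully determines every draw.
#' @return An object of class `disorder_spec`.
#' @export
disorder_spec <- function(sigma_per_site, n_realizations = 10000L, seed = 1L) {
  if (!is.numeric(sigma_per_site) || any(sigma_per_site < 0) ||
      any(!is.finite(sigma_per_site))) {
    stop_validation("`sigma_per_site` must be finite and >= 0")
  }
  if (!is.numeric(n_realizations) || length(n_realizations) != 1L ||
      n_realizations < 1) {
    stop_validation("`n_realizations` must be >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("`seed` must be a finite number")
  }
  structure(list(sigma_per_site = as.numeric(sigma_per_site),
                 n_realizations = as.integer(n_realizations),
                 seed = as.numeric(seed)),
            class = "disorder_spec")
}

#' Sample one disorder realization of the site energies
#'
#' Adds independent Gaussian shifts `delta_A ~ N(0, sigma_A)` to the site
#' energies.  Each draw is a pure function of
#' `(seed, realization_index, site index)`, so results are identical across
#' reruns and across any parallel scheduling.  Electronic couplings are not
#' modulated.
#'
#' @param model An [exciton_model()].
#' @param spec A [disorder_spec()].
#' @param realization_index Realization counter (1-based).
#' @return Numeric vector of perturbed site energies (cm^-1).
#' @export
sample_site_energies <- function(model, spec, realization_index) {
  if (!inherits(model, "exciton_model")) stop_validation("expected an `exciton_model`")
  if (!inherits(spec, "disorder_spec")) stop_validation("expected a `disorder_spec`")
  n <- model$n_sites
  sigma <- rep_len(spec$sigma_per_site, n)
  if (all(sigma == 0)) return(model$site_energies)
  z <- vapply(seq_len(n), function(s) {
    counter_normal(spec$seed, realization_index, s)
  }, numeric(1))
  model$site_energies + sigma * z
}

#' Run a quasi-static disorder ensemble
#'
#' For each realization, draws perturbed site energies from the slow-bath
#' disorder distribution, recomputes the rate integrals (the only
#' energy-dependent quantities -- the line-broadening functions,
#' reorganization energies and mode discretizations in `setup` are shared
#' bitwise across all realizations), propagates the populations, and
#' accumulates the dissipation field at the configured snapshot times.
#' Populations and fields are averaged arithmetically.
#'
#' Realizations are processed in fixed-size blocks reduced in index order,
#' so the result is byte-identical for any number of parallel workers.
#'
#' @param setup A [prepare_baths()] result.
#' @param spec A [disorder_spec()]; by default built from the setup's
#'   [sigma_slow()] widths with the config's `n_realizations` and `seed`.
#' @param config Optional [run_config()] overriding the one in `setup`.
#' @return An object of class `ensemble_result`: list with `t` and
#'   `mean_populations`, `mean_field` (a `dissipation_field` of ensemble
#'   means), `mean_K`, `site_dissipation` (data frame of per-chromophore
#'   frequency-integrated final dissipation: mean and standard error),
#'   `mean_energy_drop` (ensemble-mean electronic energy released up to the
#'   final snapshot, each realization evaluated with its own energies;
#'   cm^-1), `n_realizations`, `sigma`, `seed`, `config`.
#' @export
run_ensemble <- function(setup, spec = NULL, config = NULL) {
  if (!inherits(setup, "bath_setup")) stop_validation("expected a `bath_setup`")
  config <- if (is.null(config)) setup$config else as_run_config(config)
  if (is.null(spec)) {
    spec <- disorder_spec(setup$sigma, config$n_realizations, config$seed)
  }
  if (!inherits(spec, "disorder_spec")) stop_validation("expected a `disorder_spec`")
  if (length(setup$envelope_end) && max(setup$envelope_end) > 1e-6) {
    bad <- which(setup$envelope_end > 1e-6)
    stop_convergence(sprintf(
      "rate integrals not converged at T_max for pair(s) %s (envelope up to %.2g); extend t_max_rate_fs",
      paste(apply(setup$pairs[bad, , drop = FALSE], 1, paste, collapse = "-"),
            collapse = ", "),
      max(setup$envelope_end)))
  }
  model <- setup$model
  n <- model$n_sites
  P0 <- numeric(n)
  P0[site_index(model, config$initial_site)] <- 1

  one_realization <- function(r) {
    E_r <- sample_site_energies(model, spec, r)
    rs <- build_rate_set(setup, energies = E_r, warn_envelope = FALSE)
    traj <- propagate_populations(rs, P0, dt = config$dt_fs,
                                  t_end = config$t_end_dynamics_fs,
                                  store_stride = config$store_stride)
    field <- accumulate_dissipation(rs, traj, config$snapshot_times_fs)
    n_s <- length(config$snapshot_times_fs)
    site_diss <- colSums(matrix(field$E_acc[, , n_s], ncol = n)) * field$delta_omega
    # electronic energy released up to the final snapshot, with this
    # realization's energies (the quantity the dissipation must balance)
    t_s <- config$snapshot_times_fs[n_s]
    P_end <- vapply(seq_len(n), function(a) {
      stats::approx(traj$t, traj$P[, a], xout = t_s, rule = 2)$y
    }, numeric(1))
    drop <- sum((P0 - P_end) * E_r)
    list(P = traj$P, t = traj$t, E_acc = field$E_acc, K = rs$K,
         site_diss = site_diss, drop = drop)
  }

  n_real <- spec$n_realizations
  block_size <- 25L   # fixed: reduction order independent of worker count
  blocks <- split(seq_len(n_real), (seq_len(n_real) - 1L) %/% block_size)
  run_block <- function(idx) {
    acc <- NULL
    sd_rows <- matrix(0, length(idx), n)
    for (k in seq_along(idx)) {
      res <- one_realization(idx[k])
      sd_rows[k, ] <- res$site_diss
      if (is.null(acc)) {
        acc <- res
      } else {
        acc$P <- acc$P + res$P
        acc$E_acc <- acc$E_acc + res$E_acc
        acc$K <- acc$K + res$K
        acc$drop <- acc$drop + res$drop
      }
    }
    acc$site_diss_rows <- sd_rows
    acc
  }
  n_workers <- max(1L, as.integer(config$n_workers))
  block_results <- if (n_workers > 1L) {
    parallel::mclapply(blocks, run_block, mc.cores = n_workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(blocks, run_block)
  }
  for (b in block_results) {
    if (inherits(b, "try-error") || is.null(b$P)) {
      stop("ensemble worker failed: ", paste(as.character(b), collapse = " "))
    }
  }
  total <- block_results[[1]]
  sd_rows <- total$site_diss_rows
  if (length(block_results) > 1L) {
    for (b in block_results[-1]) {
      total$P <- total$P + b$P
      total$E_acc <- total$E_acc + b$E_acc
      total$K <- total$K + b$K
      total$drop <- total$drop + b$drop
      sd_rows <- rbind(sd_rows, b$site_diss_rows)
    }
  }
  mean_P <- total$P / n_real
  mean_E <- total$E_acc / n_real
  mean_K <- total$K / n_real
  E_tot <- apply(mean_E, c(1, 3), sum)
  mean_field <- structure(list(omega_grid = setup$omega_grid,
                               delta_omega = setup$delta_omega,
                               snapshot_times = config$snapshot_times_fs,
                               E_acc = mean_E,
                               E_tot = matrix(E_tot, nrow = length(setup$omega_grid)),
                               labels = model$labels),
                          class = "dissipation_field")
  se <- if (n_real > 1) apply(sd_rows, 2, stats::sd) / sqrt(n_real) else rep(NA_real_, n)
  site_diss <- data.frame(site = model$labels,
                          dissipation_cm1 = colMeans(sd_rows),
                          std_error = se, row.names = NULL)
  structure(list(t = total$t, mean_populations = mean_P,
                 mean_field = mean_field, mean_K = mean_K,
                 site_dissipation = site_diss,
                 mean_energy_drop = total$drop / n_real,
                 n_realizations = n_real,
                 sigma = rep_len(spec$sigma_per_site, n),
                 seed = spec$seed, config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  nt <- length(x$t)
  cat(sprintf("<ensemble_result> %d realizations, %d sites\n",
              x$n_realizations, ncol(x$mean_populations)))
  cat("mean final populations:",
      paste(sprintf("%.4f", x$mean_populations[nt, ]), collapse = ", "), "\n")
  cat("per-site dissipation at final snapshot (cm^-1):\n")
  print(x$site_dissipation, digits = 4)
  invisible(x)
}
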