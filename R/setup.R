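# Shared per-model preparation: everything that does not depend on the
# (possibly disorder-perturbed) site energies is computed exactly once here
# and reused across every realization of the ensemble -- the slow/fast
# splitting, disorder widths, mode discretizations, line-broadening
# functions, and the per-pair envelopes exp(-g_A - g_B).

#' Prepare shared bath quantities for a model
#'
#' Splits each chromophore's spectral density into slow and fast components
#' at `omega_star`, derives the quasi-static disorder width of the slow
#' part, discretizes the fast part into effective modes on a common
#' frequency grid, and evaluates the line-broadening function of every fast
#' bath on the rate-integration time grid.  All of these are independent of
#' the site energies, so a disorder ensemble reuses one `bath_setup` across
#' all realizations.
#'
#' @param model An [exciton_model()].
#' @param baths Named list (one per site, in model order) of
#'   [spectral_density()] or [synthetic_bath_spec()] objects.
#' @param config A [run_config()].
#' @param cache_dir Optional directory for caching line-broadening functions
#'   on disk, keyed by a fingerprint of the density, temperature and grids.
#' @return An object of class `bath_setup`.
#' @export
prepare_baths <- function(model, baths, config, cache_dir = NULL) {
  if (!inherits(model, "exciton_model")) stop_validation("expected an `exciton_model`")
  config <- as_run_config(config)
  n <- model$n_sites
  if (length(baths) != n) {
    stop_validation("`baths` must supply one spectral density per site")
  }
  densities <- lapply(seq_len(n), function(i) {
    b <- baths[[i]]
    if (inherits(b, "synthetic_bath_spec")) {
      make_synthetic_density(b, label = model$labels[i])
    } else {
      assert_spectral_density(b)
    }
  })
  rng <- vapply(densities, function(d) range(d$omega), numeric(2))
  if (max(abs(rng[1, ] - rng[1, 1])) > 1e-9 || max(abs(rng[2, ] - rng[2, 1])) > 1e-9) {
    stop_validation("all chromophore densities must share a common frequency range")
  }

  consts <- physical_constants(config$temperature_K)
  t_rate <- seq(0, config$t_max_rate_fs, by = config$dt_fs)
  wt <- trapezoid_weights(t_rate)

  splits <- lapply(densities, split_spectral_density, omega_star = config$omega_star_cm1)
  sigma <- vapply(splits, function(s) sigma_slow(s$slow, consts), numeric(1))
  lambda_fast <- vapply(splits, function(s) reorganization_energy(s$fast), numeric(1))
  frac <- vapply(splits, `[[`, numeric(1), "slow_fraction")
  bad <- which(frac > 0.05)
  if (length(bad)) {
    warning(sprintf(
      "slow-bath fraction exceeds 5%% for %s (max %.1f%%); consider lowering omega_star",
      paste(model$labels[bad], collapse = ", "), 100 * max(frac)), call. = FALSE)
  }

  disc <- lapply(splits, function(s) discretize_bath(s$fast, config$n_modes))
  omega_grid <- disc[[1]]$mode_freqs
  for (d in disc) {
    if (max(abs(d$mode_freqs - omega_grid)) > 1e-9) {
      stop_validation("discretized mode grids differ between chromophores")
    }
  }
  lambda_modes <- vapply(disc, `[[`, numeric(length(omega_grid)), "mode_lambdas")
  lambda_modes <- matrix(lambda_modes, ncol = n,
                         dimnames = list(NULL, model$labels))

  g <- lapply(seq_len(n), function(i) {
    lineshape_cached(splits[[i]]$fast, consts, t_rate, cache_dir)
  })

  # per-pair decay envelopes W_AB(t) = exp(-g_A - g_B), with trapezoid
  # weights folded in; only pairs with nonzero coupling are kept
  pairs <- which(upper.tri(model$couplings) & model$couplings != 0, arr.ind = TRUE)
  W <- vector("list", nrow(pairs))
  envelope_end <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    gsum <- g[[i]]$g_values + g[[j]]$g_values
    envelope_end[p] <- exp(-Re(gsum)[length(t_rate)])
    W[[p]] <- wt * exp(-gsum)
  }

  structure(list(
    model = model, consts = consts, config = config,
    densities = densities, splits = splits, sigma = stats::setNames(sigma, model$labels),
    lambda_fast = stats::setNames(lambda_fast, model$labels),
    slow_fraction = stats::setNames(frac, model$labels),
    disc = disc, omega_grid = omega_grid,
    delta_omega = disc[[1]]$delta, lambda_modes = lambda_modes,
    coth_mode = coth_stable(consts$beta * omega_grid / 2),
    g = g, t_rate = t_rate, wt = wt,
    pre_mode = exp(-1i * omega_grid[1] * t_rate / consts$hbar),
    pairs = pairs, W = W, envelope_end = envelope_end
  ), class = "bath_setup")
}

#' @export
print.bath_setup <- function(x, ...) {
  cat(sprintf("<bath_setup> %d sites, %d modes on [%.3g, %.4g] cm^-1, T = %g K\n",
              x$model$n_sites, length(x$omega_grid), x$omega_grid[1],
              x$omega_grid[length(x$omega_grid)], x$consts$temperature))
  cat(sprintf("  omega* = %g cm^-1; slow fractions: %s\n", x$config$omega_star_cm1,
              paste(sprintf("%.1f%%", 100 * x$slow_fraction), collapse = " ")))
  cat(sprintf("  sigma_slow: %s cm^-1\n",
              paste(sprintf("%.1f", x$sigma), collapse = " ")))
  invisible(x)
}

# optional on-disk cache for line-broadening functions
lineshape_cached <- function(J_fast, consts, t_rate, cache_dir) {
  if (is.null(cache_dir)) return(line_broadening(J_fast, consts, t_rate))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- sprintf("g_%s.rds", density_fingerprint(J_fast, consts, t_rate))
  path <- file.path(cache_dir, fp)
  if (file.exists(path)) {
    g <- readRDS(path)
    g$label <- J_fast$label
    return(g)
  }
  g <- line_broadening(J_fast, consts, t_rate)
  saveRDS(g, path)
  g
}

density_fingerprint <- function(J, consts, t_rate) {
  key <- paste(
    sprintf("%.17g", c(range(J$omega), length(J$omega), sum(J$values),
                       sum(J$values^2), sum(J$omega * J$values),
                       consts$temperature, t_rate[2] - t_rate[1],
                       t_rate[length(t_rate)])),
    collapse = "_")
  # stable short hex digest of the key string
  bytes <- utf8ToInt(key)
  h <- c(2166136261, 16777619)
  acc <- 0
  for (b in bytes) acc <- ((acc * 31) %% 2147483647 + b) %% 2147483647
  sprintf("%08x%04x", acc, length(bytes) %% 65536)
}

#' Assemble the full rate set of a model
#'
#' For every ordered pair of coupled chromophores, evaluates the transfer
#' rate constant, the dissipative potential on the common mode-frequency
#' grid, and the forward/backward dissipative spectral densities of both
#' local baths (using the bin-averaged `lambda_j / delta` as
#' `J(omega)/omega`, which keeps the mode-resolved and frequency-resolved
#' views consistent).
#'
#' @param setup A [prepare_baths()] result.
#' @param energies Optional replacement site energies (cm^-1), e.g. a
#'   disorder realization; defaults to the model's energies.
#' @param warn_envelope Warn when a pair's time-integrand envelope has not
#'   decayed below 1e-6 at the final integration time.
#' @return An object of class `rate_set` with elements `K` (matrix,
#'   `K[A, B]` = rate of A to B transfer, fs^-1), `omega_grid`,
#'   `delta_omega`, `J_out` and `J_in` (arrays frequencies x sites x sites:
#'   `J_out[, A, B]` multiplies `P_A`, `J_in[, A, B]` multiplies `P_B` in
#'   the dissipation of A's bath for the A-B pair), `energies`, `labels`.
#' @export
build_rate_set <- function(setup, energies = NULL, warn_envelope = TRUE) {
  if (!inherits(setup, "bath_setup")) stop_validation("expected a `bath_setup`")
  model <- setup$model
  n <- model$n_sites
  if (is.null(energies)) energies <- model$site_energies
  if (length(energies) != n || any(!is.finite(energies))) {
    stop_validation("`energies` must supply one finite value per site")
  }
  if (warn_envelope && length(setup$envelope_end) && max(setup$envelope_end) > 1e-6) {
    warning(sprintf("rate integrand envelope at T_max reaches %.2g (> 1e-6); extend t_max_rate_fs",
                    max(setup$envelope_end)), call. = FALSE)
  }
  hbar <- setup$consts$hbar
  t_rate <- setup$t_rate
  n_w <- length(setup$omega_grid)
  dt <- setup$config$dt_fs
  dom <- setup$delta_omega
  plan <- czt_plan(dom * dt / hbar, length(t_rate), n_w)

  K <- matrix(0, n, n, dimnames = list(model$labels, model$labels))
  J_out <- array(0, dim = c(n_w, n, n),
                 dimnames = list(NULL, model$labels, model$labels))
  J_in <- array(0, dim = c(n_w, n, n),
                dimnames = list(NULL, model$labels, model$labels))
  jw <- sweep(setup$lambda_modes, 2, dom, "/")   # lambda_j/delta ~ J(omega)/omega

  for (p in seq_len(nrow(setup$pairs))) {
    i <- setup$pairs[p, 1]; j <- setup$pairs[p, 2]
    V <- model$couplings[i, j]
    c2 <- 2 * V^2 / hbar^2
    lam_sum <- setup$g[[i]]$lambda_total + setup$g[[j]]$lambda_total
    dE <- energies[j] - energies[i]
    # the reorganization shift keeps its sign in both directions; only the
    # site-energy difference flips between the forward and backward process
    phase_lam <- exp(-1i * (lam_sum / hbar) * t_rate)
    phase_dE <- exp(-1i * (dE / hbar) * t_rate)
    F_ji <- setup$W[[p]] * phase_lam * phase_dE        # i -> j process (K_{ji})
    F_ij <- setup$W[[p]] * phase_lam * Conj(phase_dE)  # j -> i process (K_{ij})
    K[i, j] <- c2 * Re(sum(F_ji))
    K[j, i] <- c2 * Re(sum(F_ij))
    I_ji <- ipot_czt(F_ji, t_rate, setup$omega_grid, setup$coth_mode, hbar,
                     plan = plan, pre = setup$pre_mode)
    I_ij <- ipot_czt(F_ij, t_rate, setup$omega_grid, setup$coth_mode, hbar,
                     plan = plan, pre = setup$pre_mode)
    # dissipation into i's bath: forward (weight P_i) uses I_ji, backward
    # (weight P_j) uses I_ij; the same potentials serve j's bath
    J_out[, i, j] <- c2 * jw[, i] * I_ji
    J_in[, i, j] <- c2 * jw[, i] * I_ij
    J_out[, j, i] <- c2 * jw[, j] * I_ij
    J_in[, j, i] <- c2 * jw[, j] * I_ji
  }
  K[K < 0 & K > -1e-18] <- 0   # clip fp negatives of strictly zero rates
  structure(list(labels = model$labels, n_sites = n, K = K,
                 omega_grid = setup$omega_grid, delta_omega = dom,
                 J_out = J_out, J_in = J_in,
                 energies = stats::setNames(as.numeric(energies), model$labels)),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> %d sites, %d frequencies\n", x$n_sites,
              length(x$omega_grid)))
  cat("rate constants K[from, to] (fs^-1):\n")
  print(signif(x$K, 4))
  invisible(x)
}
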