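# Run configuration, the end-to-end simulation pipeline, bath validation,
# and the result container (RDS payload + flat delimited-text exports +
# JSON metadata).

#' Simulation run configuration
#'
#' Collects every tunable of the pipeline with the conventional production
#' defaults: rate integrals by trapezoid with a 0.5 fs step to 30 ps,
#' population dynamics to 5 ps with snapshots at 40, 200, 600 and 5000 fs,
#' 4000 effective bath modes, and a 20 cm^-1 slow/fast cutoff chosen so that
#' the slow bath carries only a few percent of the reorganization energy.
#'
#' @param temperature_K Bath temperature (K).
#' @param omega_star_cm1 Slow/fast splitting cutoff (cm^-1).
#' @param n_modes Number of effective harmonic modes for the fast bath.
#' @param dt_fs Time step for rate integrals and RK4 propagation (fs).
#' @param t_max_rate_fs Upper limit of the rate time integrals (fs).
#' @param t_end_dynamics_fs Propagation end time (fs).
#' @param snapshot_times_fs Times at which the accumulated dissipation field
#'   is extracted (fs); all must be <= `t_end_dynamics_fs`.
#' @param initial_site Site label or index initially carrying the
#'   excitation.
#' @param n_realizations Disorder ensemble size.
#' @param seed Ensemble seed.
#' @param store_stride Population storage stride (steps).
#' @param n_workers Parallel workers for the ensemble (results are
#'   scheduling independent).
#' @param band_edges_cm1 Frequency band boundaries for [band_summary()]
#'   reporting.
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature_K = 300,
                       omega_star_cm1 = 20,
                       n_modes = 4000,
                       dt_fs = 0.5,
                       t_max_rate_fs = 30000,
                       t_end_dynamics_fs = 5000,
                       snapshot_times_fs = c(40, 200, 600, 5000),
                       initial_site = 1L,
                       n_realizations = 1L,
                       seed = 1L,
                       store_stride = 1L,
                       n_workers = 1L,
                       band_edges_cm1 = NULL) {
  cfg <- list(temperature_K = temperature_K, omega_star_cm1 = omega_star_cm1,
              n_modes = n_modes, dt_fs = dt_fs, t_max_rate_fs = t_max_rate_fs,
              t_end_dynamics_fs = t_end_dynamics_fs,
              snapshot_times_fs = snapshot_times_fs,
              initial_site = initial_site,
              n_realizations = n_realizations, seed = seed,
              store_stride = store_stride, n_workers = n_workers,
              band_edges_cm1 = band_edges_cm1)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  num_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!num_pos(cfg$temperature_K)) stop_validation("temperature_K must be > 0")
  if (!num_pos(cfg$omega_star_cm1)) stop_validation("omega_star_cm1 must be > 0")
  if (!num_pos(cfg$n_modes) || cfg$n_modes < 2) stop_validation("n_modes must be >= 2")
  if (!num_pos(cfg$dt_fs)) stop_validation("dt_fs must be > 0")
  if (!num_pos(cfg$t_max_rate_fs)) stop_validation("t_max_rate_fs must be > 0")
  if (!num_pos(cfg$t_end_dynamics_fs)) stop_validation("t_end_dynamics_fs must be > 0")
  if (!is.numeric(cfg$snapshot_times_fs) || !length(cfg$snapshot_times_fs) ||
      any(cfg$snapshot_times_fs < 0)) {
    stop_validation("snapshot_times_fs must be non-negative")
  }
  if (any(cfg$snapshot_times_fs > cfg$t_end_dynamics_fs)) {
    stop_validation("snapshot times must not exceed t_end_dynamics_fs")
  }
  if (!num_pos(cfg$n_realizations)) stop_validation("n_realizations must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stop_validation("seed must be a finite number")
  }
  if (!num_pos(cfg$store_stride)) stop_validation("store_stride must be >= 1")
  if (!num_pos(cfg$n_workers)) stop_validation("n_workers must be >= 1")
  if (!is.null(cfg$band_edges_cm1) &&
      (length(cfg$band_edges_cm1) < 2L || any(diff(cfg$band_edges_cm1) <= 0))) {
    stop_validation("band_edges_cm1 must be strictly increasing")
  }
  structure(cfg, class = "run_config")
}

as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.list(x)) return(do.call(run_config, x))
  stop_validation("expected a `run_config` or a list of config fields")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Validate chromophore baths against the slow/fast splitting criterion
#'
#' Per-chromophore report of the quantities governing the quasi-static
#' treatment of the slow bath: total and slow reorganization energy, slow
#' fraction, and disorder width.  A warning is issued when the slow bath
#' carries more than 5% of a chromophore's reorganization energy, in which
#' case `omega_star` should be lowered.
#'
#' @param model An [exciton_model()].
#' @param baths Named list of [spectral_density()] or
#'   [synthetic_bath_spec()] per site.
#' @param config A [run_config()] (temperature and `omega_star_cm1` are
#'   used).
#' @return A data frame with one row per chromophore: `site`,
#'   `lambda_total_cm1`, `lambda_slow_cm1`, `slow_fraction`,
#'   `sigma_slow_cm1`.
#' @export
validate_baths <- function(model, baths, config = run_config()) {
  config <- as_run_config(config)
  consts <- physical_constants(config$temperature_K)
  if (length(baths) != model$n_sites) {
    stop_validation("`baths` must supply one density per site")
  }
  rows <- lapply(seq_len(model$n_sites), function(i) {
    b <- baths[[i]]
    J <- if (inherits(b, "synthetic_bath_spec")) {
      make_synthetic_density(b, label = model$labels[i])
    } else {
      assert_spectral_density(b)
    }
    sp <- split_spectral_density(J, config$omega_star_cm1)
    data.frame(site = model$labels[i],
               lambda_total_cm1 = reorganization_energy(J),
               lambda_slow_cm1 = reorganization_energy(sp$slow),
               slow_fraction = sp$slow_fraction,
               sigma_slow_cm1 = sigma_slow(sp$slow, consts))
  })
  out <- do.call(rbind, rows)
  bad <- out$slow_fraction > 0.05
  if (any(bad)) {
    warning(sprintf("slow-bath fraction exceeds 5%% for: %s",
                    paste(out$site[bad], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Run the full dissipation-pathway pipeline
#'
#' Convenience driver: prepares the shared bath quantities, runs the
#' disorder ensemble (a single deterministic realization when
#' `n_realizations = 1` and all disorder widths are zero), and summarizes
#' the final dissipation field by frequency band.
#'
#' @param model An [exciton_model()], or `NULL` to use an FMO-like preset.
#' @param baths Named list of per-site baths; `NULL` with `preset` uses the
#'   preset's synthetic densities.
#' @param config A [run_config()].
#' @param preset Optional [fmo_like_model()] preset name (`"bchl1"` or
#'   `"bchl6"`); supplies `model`, `baths` and the initial site.
#' @param sigma_override Optional disorder widths replacing the
#'   [sigma_slow()] values computed from the slow baths.
#' @param output_dir Optional directory; when given, the result container
#'   is written there (see [write_results()]).
#' @return An object of class `dissipath_result`: list with `ensemble`
#'   (an `ensemble_result`), `setup` summary fields, `bands` (the
#'   [band_summary()] at the final snapshot), `validation` (the
#'   [validate_baths()] table) and `config`.
#' @export
simulate_dissipation <- function(model = NULL, baths = NULL,
                                 config = run_config(), preset = NULL,
                                 sigma_override = NULL, output_dir = NULL) {
  config <- as_run_config(config)
  if (!is.null(preset)) {
    fm <- fmo_like_model(preset)
    model <- fm$model
    baths <- fm$bath_specs
    config$initial_site <- fm$initial_site
  }
  if (is.null(model) || is.null(baths)) {
    stop_validation("supply `model` and `baths`, or a `preset`")
  }
  validation <- suppressWarnings(validate_baths(model, baths, config))
  setup <- prepare_baths(model, baths, config)
  spec <- disorder_spec(
    if (is.null(sigma_override)) setup$sigma else rep_len(sigma_override, model$n_sites),
    config$n_realizations, config$seed)
  ens <- run_ensemble(setup, spec, config)
  edges <- config$band_edges_cm1
  if (is.null(edges)) {
    hi <- max(setup$omega_grid)
    edges <- if (hi > 800) c(min(setup$omega_grid), 800, hi) else range(setup$omega_grid)
  }
  bands <- band_summary(ens$mean_field, edges)
  res <- structure(list(ensemble = ens, bands = bands,
                        validation = validation,
                        sigma = setup$sigma,
                        slow_fraction = setup$slow_fraction,
                        lambda_fast = setup$lambda_fast,
                        envelope_end = setup$envelope_end,
                        config = config),
                   class = "dissipath_result")
  if (!is.null(output_dir)) write_results(res, output_dir)
  res
}

#' @export
print.dissipath_result <- function(x, ...) {
  cat(sprintf("<dissipath_result> %d sites, %d realizations, T = %g K\n",
              ncol(x$ensemble$mean_populations), x$ensemble$n_realizations,
              x$config$temperature_K))
  print(x$ensemble)
  cat("band summary at final snapshot (cm^-1):\n")
  print(x$bands, digits = 4)
  invisible(x)
}

#' Write the result container
#'
#' Serializes a [simulate_dissipation()] result as a structured container:
#' `results.rds` (full numeric payload), `populations.tsv`,
#' `dissipation_snapshot_<t>fs.tsv` (one per snapshot: frequency grid,
#' per-chromophore and total accumulated dissipation), `band_summary.tsv`,
#' `site_dissipation.tsv`, and `meta.json` echoing every effective
#' parameter with units.
#'
#' @param res A `dissipath_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  if (!inherits(res, "dissipath_result")) stop_validation("expected a `dissipath_result`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(res, file.path(dir, "results.rds"))
  ens <- res$ensemble
  pop <- data.frame(t_fs = ens$t, ens$mean_populations, check.names = FALSE)
  utils::write.table(pop, file.path(dir, "populations.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  fld <- ens$mean_field
  for (s in seq_along(fld$snapshot_times)) {
    tab <- data.frame(omega_cm1 = fld$omega_grid,
                      matrix(fld$E_acc[, , s], ncol = length(fld$labels),
                             dimnames = list(NULL, fld$labels)),
                      total = fld$E_tot[, s], check.names = FALSE)
    utils::write.table(tab,
                       file.path(dir, sprintf("dissipation_snapshot_%gfs.tsv",
                                              fld$snapshot_times[s])),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(res$bands, file.path(dir, "band_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ens$site_dissipation, file.path(dir, "site_dissipation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    package = "dissipath",
    version = as.character(utils::packageVersion("dissipath")),
    config = unclass(res$config),
    units = list(frequency = "cm^-1", time = "fs", energy = "cm^-1",
                 rate = "fs^-1", dissipation_density = "cm^-1 per cm^-1"),
    sigma_slow_cm1 = as.list(res$sigma),
    slow_fraction = as.list(res$slow_fraction),
    n_realizations = ens$n_realizations,
    seed = ens$seed
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
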