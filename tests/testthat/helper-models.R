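# Shared builders for small test systems.  All fixtures are generated in
# code; grids are kept coarse enough for fast unit tests while staying well
# inside the convergence regime of the quadratures they exercise.

kB_test <- 0.695035
hbar_test <- 5308.8

# Drude (overdamped) density tabulated on a uniform grid
drude_density <- function(lambda = 35, gamma = 50, omega_max = 2000,
                          n = 4000, label = "drude") {
  omega <- seq_len(n) * (omega_max / n)
  spectral_density(omega, (2 / pi) * lambda * gamma * omega / (omega^2 + gamma^2),
                   label = label)
}

# underdamped Brownian-oscillator peak
peak_density <- function(center, width = 5, lambda = 10, omega_max = 2000,
                         n = 4000, label = "peak") {
  omega <- seq_len(n) * (omega_max / n)
  J <- (2 / pi) * lambda * width * omega * center^2 /
    ((omega^2 - center^2)^2 + width^2 * omega^2)
  spectral_density(omega, J, label = label)
}

zero_density <- function(omega_max = 2000, n = 100) {
  spectral_density(seq_len(n) * (omega_max / n), rep(0, n), label = "zero")
}

dimer_model <- function(dE = 100, V = 20, labels = c("A", "B")) {
  exciton_model(c(dE, 0), matrix(c(0, V, V, 0), 2), labels)
}

# standard small setup used by rate/dynamics tests: identical Drude baths
dimer_setup <- function(dE = 100, V = 20, temperature = 300, lambda = 35,
                        gamma = 50, t_max = 5000, n_modes = 400,
                        t_end = 3000, snapshots = c(40, t_end), ...) {
  model <- dimer_model(dE, V)
  J <- drude_density(lambda, gamma)
  cfg <- run_config(temperature_K = temperature, n_modes = n_modes,
                    t_max_rate_fs = t_max, t_end_dynamics_fs = t_end,
                    snapshot_times_fs = snapshots, ...)
  setup <- suppressWarnings(prepare_baths(model, list(J, J), cfg))
  list(model = model, J = J, cfg = cfg, setup = setup)
}

# Marcus nonadiabatic rate (high-temperature closed form)
marcus_rate <- function(dE_BA, lambda_tot, V, temperature) {
  kT <- kB_test * temperature
  (2 * pi / hbar_test) * V^2 / sqrt(4 * pi * lambda_tot * kT) *
    exp(-(dE_BA + lambda_tot)^2 / (4 * lambda_tot * kT))
}

# frequency integral of a dissipation-field slice for one site
site_integral <- function(field, site, snapshot) {
  i <- match(site, field$labels)
  sum(field$E_acc[, i, snapshot]) * field$delta_omega
}

total_integral <- function(field, snapshot) {
  sum(field$E_tot[, snapshot]) * field$delta_omega
}
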