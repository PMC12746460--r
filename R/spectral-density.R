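#' Tabulated spectral density
#'
#' A spectral density J(omega) describes the frequency-resolved coupling
#' between a chromophore's electronic excitation and its vibrational
#' environment.  The package works in the convention where the
#' reorganization energy is `Lambda = integral J(omega)/omega d omega`
#' (no 1/pi prefactor), with both `omega` and `J` in cm^-1.
#'
#' @param omega Strictly increasing frequency grid (cm^-1), all >= 0.
#' @param values J(omega) values (cm^-1), all >= 0.  If the grid starts at
#'   exactly 0 the first value must be 0, so that J/omega stays finite.
#' @param label Chromophore identifier.
#' @return An object of class `spectral_density`.
#' @seealso [reorganization_energy()], [split_spectral_density()],
#'   [read_spectral_density()]
#' @export
spectral_density <- function(omega, values, label = "J") {
  if (!is.numeric(omega) || !is.numeric(values)) {
    stop_validation("`omega` and `values` must be numeric")
  }
  if (length(omega) < 2L) {
    stop_validation("a spectral density needs at least 2 grid points")
  }
  if (length(omega) != length(values)) {
    stop_validation("`omega` and `values` must have the same length")
  }
  if (anyNA(omega) || anyNA(values) || any(!is.finite(omega)) || any(!is.finite(values))) {
    stop_validation("spectral density grid and values must be finite")
  }
  if (any(diff(omega) <= 0)) {
    stop_validation("`omega` must be strictly increasing")
  }
  if (omega[1] < 0) {
    stop_validation("`omega` must be non-negative")
  }
  if (any(values < 0)) {
    stop_validation("spectral density values must be non-negative")
  }
  if (omega[1] == 0 && values[1] != 0) {
    stop_validation("J(0) must be 0 when the grid starts at omega = 0")
  }
  structure(list(omega = as.numeric(omega), values = as.numeric(values),
                 label = as.character(label)[1]),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density> '%s': %d points on [%.4g, %.4g] cm^-1, Lambda = %.4g cm^-1\n",
              x$label, length(x$omega), x$omega[1], x$omega[length(x$omega)],
              reorganization_energy(x)))
  invisible(x)
}

# J(omega)/omega on the tabulated grid with the omega -> 0 limit filled by the
# low-frequency slope (ohmic-like behaviour J ~ eta * omega).
j_over_omega <- function(J) {
  out <- J$values / J$omega
  if (J$omega[1] == 0) out[1] <- J$values[2] / J$omega[2]
  out
}

#' Reorganization energy of a spectral density
#'
#' Computes `Lambda = integral_0^inf J(omega)/omega d omega` by composite
#' trapezoidal quadrature on the tabulated grid.  `Lambda` measures the total
#' electron-vibrational coupling strength: the energy the environment relaxes
#' after a vertical electronic transition.
#'
#' @param J A [spectral_density()].
#' @return Reorganization energy in cm^-1 (>= 0).
#' @examples
#' om <- seq(0.5, 5000, by = 0.5)
#' drude <- spectral_density(om, (2 / pi) * 35 * 50 * om / (om^2 + 50^2))
#' reorganization_energy(drude)   # ~= 35
#' @export
reorganization_energy <- function(J) {
  assert_spectral_density(J)
  pracma::trapz(J$omega, j_over_omega(J))
}

assert_spectral_density <- function(J) {
  if (!inherits(J, "spectral_density")) {
    stop_validation("expected a `spectral_density` object")
  }
  invisible(J)
}

#' Split a spectral density into slow and fast components
#'
#' Applies the smooth time-scale-separation filter
#' `S(omega, omega*) = (1 - (omega/omega*)^2)^2` for `omega < omega*` and 0
#' otherwise: `J_slow = S * J`, `J_fast = J - J_slow`.  The slow component is
#' later treated as quasi-static site-energy noise while the fast component
#' enters the explicit dissipation dynamics.  The splitting function is C^1 at
#' the cutoff and the two components add back to the parent exactly,
#' pointwise.
#'
#' @param J A [spectral_density()].
#' @param omega_star Cutoff frequency in cm^-1 (> 0).
#' @return An object of class `bath_split`: list with `omega_star`, `slow`,
#'   `fast` (both `spectral_density`) and `slow_fraction`
#'   (Lambda_slow / Lambda_total; 0 for a zero bath).
#' @export
split_spectral_density <- function(J, omega_star) {
  assert_spectral_density(J)
  if (!is.numeric(omega_star) || length(omega_star) != 1L ||
      !is.finite(omega_star) || omega_star <= 0) {
    stop_validation("`omega_star` must be a single positive frequency (cm^-1)")
  }
  S <- splitting_function(J$omega, omega_star)
  slow_values <- S * J$values
  fast_values <- J$values - slow_values
  slow <- spectral_density(J$omega, slow_values, paste0(J$label, "_slow"))
  fast <- spectral_density(J$omega, fast_values, paste0(J$label, "_fast"))
  lam_tot <- reorganization_energy(J)
  frac <- if (lam_tot > 0) reorganization_energy(slow) / lam_tot else 0
  structure(list(omega_star = omega_star, slow = slow, fast = fast,
                 slow_fraction = frac),
            class = "bath_split")
}

#' @export
print.bath_split <- function(x, ...) {
  cat(sprintf("<bath_split> omega* = %g cm^-1, slow fraction = %.3g%%\n",
              x$omega_star, 100 * x$slow_fraction))
  invisible(x)
}

splitting_function <- function(omega, omega_star) {
  ifelse(omega < omega_star, (1 - (omega / omega_star)^2)^2, 0)
}

#' Quasi-static disorder width of a slow bath
#'
#' Standard deviation of the Gaussian site-energy noise generated by a slow
#' bath component:
#' `sigma_slow = sqrt(integral_0^inf J_slow(omega) coth(beta omega / 2) d omega)`
#' in the package's energy-unit convention.  In the high-temperature limit
#' this reduces to the classical result `sigma^2 = 2 Lambda_slow kB T`.
#'
#' @param J_slow Slow spectral-density component (a [spectral_density()]).
#' @param consts A [physical_constants()].
#' @return Disorder width in cm^-1 (>= 0).
#' @export
sigma_slow <- function(J_slow, consts) {
  assert_spectral_density(J_slow)
  assert_constants(consts)
  x <- consts$beta * J_slow$omega / 2
  integrand <- J_slow$values * coth_stable(pmax(x, .Machine$double.xmin))
  if (J_slow$omega[1] == 0) {
    # J coth(beta w/2) -> (J/w) * 2/beta as w -> 0
    integrand[1] <- (J_slow$values[2] / J_slow$omega[2]) * 2 / consts$beta
  }
  sqrt(max(pracma::trapz(J_slow$omega, integrand), 0))
}

assert_constants <- function(consts) {
  if (!inherits(consts, "physical_constants")) {
    stop_validation("expected a `physical_constants` object")
  }
  invisible(consts)
}

#' Discretize a spectral density into effective harmonic modes
#'
#' Represents a (typically fast) spectral density by `n_modes` effective
#' harmonic oscillators with equally spaced frequencies spanning the tabulated
#' support.  The discrete reorganization energy of mode j is the bin integral
#' `lambda_j = integral_bin J(omega)/omega d omega` over the half-open bin
#' around its centre frequency, evaluated from the cumulative trapezoidal
#' integral of the tabulated density; the bin rule makes
#' `sum_j lambda_j = Lambda` hold by construction (the interior bin edges
#' telescope).
#'
#' @param J A [spectral_density()].
#' @param n_modes Number of modes (>= 2); the conventional production value
#'   is 4000.
#' @return An object of class `discretized_bath`: list with `mode_freqs`
#'   (bin-centre frequencies, cm^-1), `mode_lambdas` (cm^-1), `delta`
#'   (bin width) and `omega_range`.
#' @export
discretize_bath <- function(J, n_modes = 4000) {
  assert_spectral_density(J)
  if (!is.numeric(n_modes) || length(n_modes) != 1L || n_modes < 2) {
    stop_validation("`n_modes` must be a single integer >= 2")
  }
  n_modes <- as.integer(n_modes)
  lo <- J$omega[1]
  hi <- J$omega[length(J$omega)]
  if (hi <= lo) stop_validation("spectral density support is empty")
  edges <- seq(lo, hi, length.out = n_modes + 1L)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  cum <- pracma::cumtrapz(J$omega, j_over_omega(J))[, 1]
  cum_at_edges <- stats::approx(J$omega, cum, xout = edges)$y
  lambdas <- diff(cum_at_edges)
  lambdas[lambdas < 0] <- 0   # guard fp noise; integrand is non-negative
  structure(list(mode_freqs = centres, mode_lambdas = lambdas,
                 delta = edges[2] - edges[1], omega_range = c(lo, hi)),
            class = "discretized_bath")
}

#' @export
print.discretized_bath <- function(x, ...) {
  cat(sprintf("<discretized_bath> %d modes on [%.4g, %.4g] cm^-1, sum lambda_j = %.4g cm^-1\n",
              length(x$mode_freqs), x$omega_range[1], x$omega_range[2],
              sum(x$mode_lambdas)))
  invisible(x)
}

#' Read / write a tabulated spectral density
#'
#' Two-column delimited text (frequency cm^-1, J cm^-1); lines starting with
#' `#` are comments.
#'
#' @param file Path to the density file.
#' @param label Chromophore identifier for the returned object.
#' @return `read_spectral_density()` returns a [spectral_density()];
#'   `write_spectral_density()` returns the file path invisibly.
#' @export
read_spectral_density <- function(file, label = basename(file)) {
  if (!file.exists(file)) stop_validation(sprintf("density file not found: %s", file))
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("omega", "J"))
  spectral_density(tab$omega, tab$J, label = label)
}

#' @param J A [spectral_density()] to write.
#' @rdname read_spectral_density
#' @export
write_spectral_density <- function(J, file) {
  assert_spectral_density(J)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# spectral density '%s': omega (cm^-1), J (cm^-1)", J$label), con)
  utils::write.table(data.frame(J$omega, J$values), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
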