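# unit system: energies and frequencies in cm^-1, time in fs
HBAR_CM_FS <- 5308.8   # hbar, cm^-1 fs
KB_CM_K <- 0.695035    # Boltzmann constant, cm^-1 / K

#' Physical constants and thermal state
#'
#' Bundles the unit system used throughout the package: energies and
#' frequencies are expressed in wavenumbers (cm^-1), time in femtoseconds.
#' In this convention a tabulated "frequency" is the quantum of mode energy,
#' so phase factors are always `omega * t / hbar` and thermal factors
#' `coth(beta * omega / 2)`.
#'
#' @param temperature Bath temperature in Kelvin (> 0).
#' @return An object of class `physical_constants`: a list with elements
#'   `hbar` (cm^-1 fs), `kB` (cm^-1/K), `temperature` (K) and `beta`
#'   (1/cm^-1).
#' @examples
#' pc <- physical_constants(300)
#' pc$kB * pc$temperature   # thermal energy, ~208 cm^-1
#' @export
physical_constants <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop_validation("`temperature` must be a single positive number (Kelvin)")
  }
  structure(
    list(hbar = HBAR_CM_FS, kB = KB_CM_K, temperature = temperature,
         beta = 1 / (KB_CM_K * temperature)),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("<physical_constants> T = %g K, kB T = %.4g cm^-1, hbar = %g cm^-1 fs\n",
              x$temperature, x$kB * x$temperature, x$hbar))
  invisible(x)
}

# Numerically safe coth: series below x = 1e-3 avoids overflow of 1/tanh
# while keeping relative error < 1e-13 at the switch point.
coth_stable <- function(x) {
  out <- x
  small <- abs(x) < 1e-3
  out[small] <- 1 / x[small] + x[small] / 3
  out[!small] <- 1 / tanh(x[!small])
  out
}

# condition helpers: distinct classes so the CLI can map them to exit codes
stop_validation <- function(msg, call. = FALSE) {
  stop(structure(class = c("dissipath_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_convergence <- function(msg) {
  stop(structure(class = c("dissipath_convergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
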