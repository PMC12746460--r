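# Pairwise golden-rule quantities: transfer rate constants, dissipative
# potentials, dissipative spectral densities, and mode-resolved dissipation
# rate constants.
#
# All ordered-pair integrands share the same complex kernel
#   F_BA(t) = exp[-i t (E_B - E_A + Lambda_A + Lambda_B)/hbar] exp[-g_A(t) - g_B(t)]
# evaluated on the rate time grid with trapezoid weights folded in:
#   K_BA           = (2|V|^2/hbar^2) Re sum_t F_BA(t)
#   I_BA(omega)    = Re sum_t F_BA(t) [cos(omega t/hbar) - i coth(beta omega/2) sin(omega t/hbar)]
# The omega-resolved transform is evaluated exactly on uniform frequency
# grids through the chirp-z machinery in czt.R.

pair_kernel <- function(E_A, E_B, lam_A, lam_B, g_A, g_B, wt, t_grid, hbar) {
  a <- (E_B - E_A + lam_A + lam_B) / hbar
  wt * exp(-1i * a * t_grid - g_A - g_B)
}

rate_from_kernel <- function(Fw, V, hbar) {
  (2 * V^2 / hbar^2) * Re(sum(Fw))
}

# Dissipative potential on a uniform positive frequency grid via two chirp-z
# transforms (e^{-i omega t} and e^{+i omega t} half-range transforms).
ipot_czt <- function(Fw, t_grid, omega_grid, coth_vec, hbar,
                     plan = NULL, pre = NULL) {
  dt <- t_grid[2] - t_grid[1]
  dom <- omega_grid[2] - omega_grid[1]
  theta <- dom * dt / hbar
  K <- length(omega_grid)
  if (is.null(pre)) pre <- exp(-1i * omega_grid[1] * t_grid / hbar)
  if (is.null(plan)) plan <- czt_plan(theta, length(t_grid), K)
  Gp <- czt_sum(Fw * pre, theta, K, plan)
  Gm <- Conj(czt_sum(Conj(Fw) * pre, theta, K, plan))
  Re((Gp + Gm) / 2 + coth_vec * (Gp - Gm) / 2)
}

ipot_direct <- function(Fw, t_grid, omega_grid, coth_vec, hbar,
                        block_size = 2e7) {
  n_w <- length(omega_grid)
  out <- numeric(n_w)
  chunk <- max(1L, floor(block_size / length(t_grid)))
  i0 <- 1L
  # Re{F (cos - i c sin)} = Re(F) cos + c Im(F) sin
  while (i0 <= n_w) {
    idx <- i0:min(i0 + chunk - 1L, n_w)
    ph <- outer(t_grid / hbar, omega_grid[idx])
    out[idx] <- colSums(Re(Fw) * cos(ph)) +
      coth_vec[idx] * colSums(Im(Fw) * sin(ph))
    i0 <- i0 + chunk
  }
  out
}

check_pair_args <- function(A, B, model, g_A, g_B) {
  iA <- site_index(model, A)
  iB <- site_index(model, B)
  if (iA == iB) stop_validation("A and B must be different sites")
  if (!inherits(g_A, "line_broadening") || !inherits(g_B, "line_broadening")) {
    stop_validation("g_A and g_B must be `line_broadening` objects")
  }
  if (length(g_A$t_grid) != length(g_B$t_grid) ||
      max(abs(g_A$t_grid - g_B$t_grid)) > 0) {
    stop_validation("g_A and g_B must share the same time grid")
  }
  list(iA = iA, iB = iB)
}

#' Golden-rule excitation transfer rate constant
#'
#' Rate constant `K_BA` for excitation hopping from site A to site B in
#' second-order perturbation theory in the electronic coupling:
#' \deqn{K_{BA} = \frac{2|V_{AB}|^2}{\hbar^2}\,\mathrm{Re}\int_0^\infty
#'   e^{-it(E_B-E_A+\Lambda_A+\Lambda_B)/\hbar}\, e^{-g_A(t)-g_B(t)}\,dt,}
#' evaluated by the trapezoidal rule on the shared time grid of the two
#' line-broadening functions.  A warning is issued when the integrand
#' envelope `|exp(-g_A - g_B)|` at the final time still exceeds `1e-6` of its
#' peak (unconverged time integral).
#'
#' @param A,B Site labels or indices (A != B).
#' @param model An [exciton_model()].
#' @param g_A,g_B [line_broadening()] objects for the two sites, on a common
#'   time grid; their `lambda_total` fields supply the reorganization
#'   energies.
#' @param consts A [physical_constants()].
#' @param warn_envelope Emit the convergence warning? (default `TRUE`).
#' @return Rate constant in fs^-1.
#' @export
rate_constant <- function(A, B, model, g_A, g_B, consts, warn_envelope = TRUE) {
  assert_constants(consts)
  ij <- check_pair_args(A, B, model, g_A, g_B)
  V <- model$couplings[ij$iA, ij$iB]
  if (V == 0) return(0)
  t_grid <- g_A$t_grid
  wt <- trapezoid_weights(t_grid)
  env_end <- exp(-Re(g_A$g_values + g_B$g_values)[length(t_grid)])
  if (warn_envelope && env_end > 1e-6) {
    warning(sprintf("rate integrand envelope at T_max is %.2g of its peak (> 1e-6); extend t_grid",
                    env_end), call. = FALSE)
  }
  Fw <- pair_kernel(model$site_energies[ij$iA], model$site_energies[ij$iB],
                    g_A$lambda_total, g_B$lambda_total,
                    g_A$g_values, g_B$g_values, wt, t_grid, consts$hbar)
  rate_from_kernel(Fw, V, consts$hbar)
}

#' Dissipative potential I_BA(omega)
#'
#' Frequency-resolved capacity of an environmental mode at `omega` to absorb
#' (positive values) or supply (negative values) energy during the A to B
#' excitation transfer, per unit reorganization energy:
#' \deqn{I_{BA}(\omega) = \mathrm{Re}\int_0^\infty
#'   e^{-it(E_B-E_A+\Lambda_A+\Lambda_B)/\hbar} e^{-g_A(t)-g_B(t)}
#'   [\cos(\omega t/\hbar) - i\coth(\beta\omega/2)\sin(\omega t/\hbar)]\,dt.}
#' The same potential applies to the local modes of both chromophores
#' involved in the A to B process.
#'
#' @inheritParams rate_constant
#' @param omega_grid Strictly positive frequency grid (cm^-1).  Uniform grids
#'   are evaluated by the exact chirp-z transform; non-uniform grids fall
#'   back to blocked direct summation.
#' @param method `"auto"`, `"czt"` or `"direct"`.
#' @return Numeric vector `I_BA(omega)` (fs) over `omega_grid`.
#' @export
dissipative_potential <- function(A, B, omega_grid, model, g_A, g_B, consts,
                                  method = c("auto", "czt", "direct")) {
  assert_constants(consts)
  method <- match.arg(method)
  ij <- check_pair_args(A, B, model, g_A, g_B)
  if (any(omega_grid <= 0) || any(!is.finite(omega_grid))) {
    stop_validation("`omega_grid` must be strictly positive and finite")
  }
  uniform <- is_uniform_grid(omega_grid)
  if (method == "auto") method <- if (uniform) "czt" else "direct"
  if (method == "czt" && !uniform) {
    stop_validation("czt evaluation needs a uniform omega grid; use method = \"direct\"")
  }
  t_grid <- g_A$t_grid
  wt <- trapezoid_weights(t_grid)
  Fw <- pair_kernel(model$site_energies[ij$iA], model$site_energies[ij$iB],
                    g_A$lambda_total, g_B$lambda_total,
                    g_A$g_values, g_B$g_values, wt, t_grid, consts$hbar)
  cth <- coth_stable(consts$beta * omega_grid / 2)
  if (method == "czt") {
    ipot_czt(Fw, t_grid, omega_grid, cth, consts$hbar)
  } else {
    ipot_direct(Fw, t_grid, omega_grid, cth, consts$hbar)
  }
}

#' Dissipative spectral densities J^A_BA and J^A_AB
#'
#' Frequency-resolved rates of energy deposition into the local environment
#' of chromophore A during the forward (A to B, weighted by `P_A`) and
#' backward (B to A, weighted by `P_B`) transfer processes:
#' \deqn{J^A_{BA}(\omega) = \frac{2|V_{AB}|^2}{\hbar^2}\frac{J_A(\omega)}{\omega}
#'   I_{BA}(\omega), \qquad
#'   J^A_{AB}(\omega) = \frac{2|V_{AB}|^2}{\hbar^2}\frac{J_A(\omega)}{\omega}
#'   I_{AB}(\omega).}
#' Values may be negative: those modes absorb energy rather than dissipate
#' it.
#'
#' @inheritParams rate_constant
#' @param J_A [spectral_density()] of chromophore A, interpolated onto
#'   `omega_grid`; alternatively supply `j_over_omega` directly (e.g. the
#'   bin-averaged `lambda_j / delta` of a discretized bath) and pass
#'   `J_A = NULL`.
#' @param I_BA,I_AB Dissipative potentials on `omega_grid`
#'   (see [dissipative_potential()]).
#' @param omega_grid Frequency grid shared by all inputs.
#' @param j_over_omega Optional explicit `J_A(omega)/omega` values on
#'   `omega_grid`.
#' @return List with components `J_BA` and `J_AB` (fs^-1 per cm^-1) on
#'   `omega_grid`.
#' @export
dissipative_spectral_densities <- function(A, B, J_A, I_BA, I_AB, model,
                                           omega_grid, j_over_omega = NULL) {
  iA <- site_index(model, A)
  iB <- site_index(model, B)
  if (iA == iB) stop_validation("A and B must be different sites")
  if (length(I_BA) != length(omega_grid) || length(I_AB) != length(omega_grid)) {
    stop_validation("I_BA / I_AB grids do not match `omega_grid`")
  }
  if (is.null(j_over_omega)) {
    assert_spectral_density(J_A)
    rng <- range(J_A$omega)
    if (omega_grid[1] < rng[1] - 1e-9 || omega_grid[length(omega_grid)] > rng[2] + 1e-9) {
      stop_validation("`omega_grid` extends beyond the support of J_A")
    }
    j_over_omega <- stats::approx(J_A$omega, j_over_omega(J_A),
                                  xout = omega_grid, rule = 2)$y
  } else if (length(j_over_omega) != length(omega_grid)) {
    stop_validation("`j_over_omega` length does not match `omega_grid`")
  }
  V <- model$couplings[iA, iB]
  c2 <- 2 * V^2 / HBAR_CM_FS^2
  list(J_BA = c2 * j_over_omega * I_BA,
       J_AB = c2 * j_over_omega * I_AB)
}

#' Mode-resolved dissipation rate constants
#'
#' Dissipation rate constant of the j-th effective mode of chromophore A for
#' the A to B transfer process:
#' `K^Aj_BA = (2|V_AB|^2/hbar^2) * lambda_j * I_BA(omega_j)`, with the
#' dissipative potential interpolated linearly onto the mode frequencies.
#'
#' @inheritParams dissipative_spectral_densities
#' @param bath A [discretize_bath()] result for chromophore A.
#' @param I_BA Dissipative potential values on `omega_grid`.
#' @return Numeric vector of per-mode rate constants (cm^-1 fs^-1).
#' @export
mode_rate_constants <- function(A, B, bath, I_BA, omega_grid, model) {
  iA <- site_index(model, A)
  iB <- site_index(model, B)
  if (iA == iB) stop_validation("A and B must be different sites")
  if (!inherits(bath, "discretized_bath")) {
    stop_validation("`bath` must be a `discretized_bath`")
  }
  if (min(bath$mode_freqs) < min(omega_grid) - 1e-9 ||
      max(bath$mode_freqs) > max(omega_grid) + 1e-9) {
    stop_validation("mode frequencies fall outside the grid of I_BA")
  }
  V <- model$couplings[iA, iB]
  I_at_modes <- stats::approx(omega_grid, I_BA, xout = bath$mode_freqs, rule = 2)$y
  (2 * V^2 / HBAR_CM_FS^2) * bath$mode_lambdas * I_at_modes
}
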