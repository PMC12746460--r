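# Golden-rule rate constants, dissipative potentials and spectral densities:
# Marcus and detailed-balance oracles, the energy sum rule, and the
# mode-resolved view.

pc300 <- physical_constants(300)

test_that("uncoupled or identical-site pairs behave trivially", {
  model <- dimer_model(dE = 100, V = 0)
  J <- drude_density()
  tgrid <- seq(0, 2000, by = 0.5)
  g <- line_broadening(J, pc300, tgrid)
  expect_identical(rate_constant("A", "B", model, g, g, pc300), 0)
  expect_error(rate_constant("A", "A", model, g, g, pc300),
               class = "dissipath_validation_error")

  # identical sites: forward and backward rates coincide
  model2 <- dimer_model(dE = 0, V = 20)
  kf <- rate_constant("A", "B", model2, g, g, pc300, warn_envelope = FALSE)
  kb <- rate_constant("B", "A", model2, g, g, pc300, warn_envelope = FALSE)
  expect_equal(kf, kb, tolerance = 1e-12)
})

test_that("high-temperature Drude dimer reproduces the Marcus closed form", {
  pc600 <- physical_constants(600)
  model <- dimer_model(dE = 100, V = 20)   # downhill A -> B by 100 cm^-1
  J <- drude_density(35, 53, n = 20000)
  lam <- reorganization_energy(J)
  tgrid <- seq(0, 5000, by = 0.5)
  g <- line_broadening(J, pc600, tgrid)
  K <- rate_constant("A", "B", model, g, g, pc600)
  K_marcus <- marcus_rate(dE_BA = -100, lambda_tot = 2 * lam, V = 20,
                          temperature = 600)
  expect_equal(K / K_marcus, 1, tolerance = 0.10)
})

test_that("detailed balance holds on Drude and Drude-plus-peak dimers", {
  tgrid <- seq(0, 6000, by = 0.5)
  for (bath in list(drude_density(35, 53),
                    {
                      Jd <- drude_density(35, 53)
                      Jp <- peak_density(180, width = 10, lambda = 15)
                      spectral_density(Jd$omega, Jd$values + Jp$values)
                    })) {
    g <- line_broadening(bath, pc300, tgrid)
    model <- dimer_model(dE = 100, V = 20)
    kf <- rate_constant("A", "B", model, g, g, pc300, warn_envelope = FALSE)
    kb <- rate_constant("B", "A", model, g, g, pc300, warn_envelope = FALSE)
    expect_gt(kf, 0)
    expect_equal(kf / kb, exp(100 / (kB_test * 300)), tolerance = 0.01)
  }
})

test_that("dissipative potential is real, symmetric for identical sites, and
           czt agrees with direct evaluation", {
  model <- dimer_model(dE = 0, V = 20)
  J <- drude_density()
  tgrid <- seq(0, 2000, by = 0.5)
  g <- line_broadening(J, pc300, tgrid)
  om <- seq(2, 1000, by = 2)
  I_BA <- dissipative_potential("A", "B", om, model, g, g, pc300)
  I_AB <- dissipative_potential("B", "A", om, model, g, g, pc300)
  expect_true(is.numeric(I_BA))
  expect_equal(I_BA, I_AB, tolerance = 1e-10)

  sub <- c(1, 57, 200, 499)
  I_dir <- dissipative_potential("A", "B", om[sub], model, g, g, pc300,
                                 method = "direct")
  expect_equal(I_BA[sub], I_dir, tolerance = 1e-9)

  expect_error(dissipative_potential("A", "B", c(-1, 5), model, g, g, pc300),
               class = "dissipath_validation_error")
})

test_that("energy sum rule: frequency-integrated dissipation equals K * (E_A - E_B)", {
  # both baths of the A -> B process use the same dissipative potential I_BA,
  # and the rule holds with bare site-energy differences
  s <- dimer_setup(dE = 100, V = 20, t_max = 6000)
  rs <- build_rate_set(s$setup)
  dom <- rs$delta_omega
  for (pair in list(c(1, 2), c(2, 1))) {
    i <- pair[1]; j <- pair[2]
    # the i -> j process feeds i's bath via J_out[, i, j] (weight P_i) and
    # j's bath via J_in[, j, i] (also weight P_i)
    lhs <- (sum(rs$J_out[, i, j]) + sum(rs$J_in[, j, i])) * dom
    rhs <- unname(rs$K[i, j] * (rs$energies[i] - rs$energies[j]))
    expect_equal(lhs, rhs, tolerance = 0.02)
  }
})

test_that("dissipative spectral densities vanish without coupling or bath and
           integrate to the sum rule", {
  s <- dimer_setup(dE = 100, V = 20, t_max = 6000)
  rs <- build_rate_set(s$setup)
  model <- s$model
  g <- s$setup$g[[1]]
  om <- rs$omega_grid
  I_BA <- dissipative_potential("A", "B", om, model, g, g, pc300)
  I_AB <- dissipative_potential("B", "A", om, model, g, g, pc300)

  # V = 0: identically zero
  m0 <- dimer_model(dE = 100, V = 0)
  dd0 <- dissipative_spectral_densities("A", "B", s$J, I_BA, I_AB, m0, om)
  expect_true(all(dd0$J_BA == 0) && all(dd0$J_AB == 0))

  # J_A = 0: identically zero regardless of I
  ddz <- dissipative_spectral_densities("A", "B", zero_density(n = 4000),
                                        I_BA, I_AB, model, om)
  expect_true(all(ddz$J_BA == 0))

  # continuous-density route integrates to K_BA (E_A - E_B) as well
  # (the fast bath component is what enters the explicit dynamics)
  dd <- dissipative_spectral_densities("A", "B", s$setup$splits[[1]]$fast,
                                       I_BA, I_AB, model, om)
  lhs <- 2 * pracma::trapz(om, dd$J_BA)   # identical baths: B side doubles it
  rhs <- rs$K[1, 2] * 100
  expect_equal(lhs, rhs, tolerance = 0.02)
})

test_that("mode-resolved rate constants converge to the frequency integral", {
  s <- dimer_setup(dE = 100, V = 20, t_max = 6000)
  model <- s$model
  g <- s$setup$g[[1]]
  om <- seq(0.5, 2000, by = 0.5)   # covers every discretized mode frequency
  I_BA <- dissipative_potential("A", "B", om, model, g, g, pc300)
  fast <- s$setup$splits[[1]]$fast

  target <- (2 * 20^2 / hbar_test^2) *
    pracma::trapz(om, stats::approx(fast$omega, dissipath:::j_over_omega(fast),
                                    om, rule = 2)$y * I_BA)
  for (n_modes in c(1000, 4000)) {
    bath <- discretize_bath(fast, n_modes)
    km <- mode_rate_constants("A", "B", bath, I_BA, om, model)
    expect_equal(sum(km), target, tolerance = 0.01)
    # zero-lambda modes contribute nothing; signs follow I
    expect_true(all(km[bath$mode_lambdas == 0] == 0))
    idx <- which(bath$mode_lambdas > 1e-8)
    I_at <- stats::approx(om, I_BA, bath$mode_freqs[idx], rule = 2)$y
    expect_true(all(sign(km[idx]) == sign(I_at) | I_at == 0))
  }
})

test_that("symmetric dimer: dissipative spectral densities cancel", {
  # at zero gap, emission and absorption balance at every frequency, so the
  # dissipative densities vanish pointwise up to quadrature roundoff
  s <- dimer_setup(dE = 0, V = 20, t_max = 6000)
  rs <- build_rate_set(s$setup)
  net <- (sum(rs$J_out[, 1, 2]) + sum(rs$J_in[, 2, 1])) * rs$delta_omega
  flux_scale <- rs$K[1, 2] * 100   # a 100 cm^-1 gap's worth of energy flux
  expect_lt(abs(net), 1e-8 * flux_scale)
})
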