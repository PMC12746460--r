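# Population propagation and dissipation accumulation.

test_that("zero rate matrix leaves the initial populations untouched", {
  K <- matrix(0, 3, 3)
  traj <- propagate_populations(K, c(0.2, 0.3, 0.5), dt = 1, t_end = 100)
  expect_true(all(abs(traj$P - rep(c(0.2, 0.3, 0.5), each = nrow(traj$P))) == 0))
})

test_that("two-site relaxation matches the closed-form linear-ODE solution", {
  k12 <- 2e-3; k21 <- 5e-4
  K <- matrix(c(0, k12, k21, 0), 2, byrow = TRUE)  # K[1,2]=k12: 1->2
  traj <- propagate_populations(K, c(1, 0), dt = 0.5, t_end = 4000)
  p_eq <- k21 / (k12 + k21)
  exact <- p_eq + (1 - p_eq) * exp(-(k12 + k21) * traj$t)
  expect_equal(traj$P[, 1], exact, tolerance = 1e-6)
  # conservation and positivity at every stored step
  expect_lt(max(abs(rowSums(traj$P) - 1)), 1e-10)
  expect_true(all(traj$P >= -1e-12))
})

test_that("long-time two-site populations obey the Boltzmann ratio", {
  s <- dimer_setup(dE = 100, V = 50, t_end = 4000, snapshots = 4000)
  rs <- build_rate_set(s$setup)
  traj <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 4000)
  n <- nrow(traj$P)
  ratio <- unname(traj$P[n, 1] / traj$P[n, 2])   # site A is 100 cm^-1 above B
  expect_equal(ratio, exp(-100 / (kB_test * 300)), tolerance = 0.01)
})

test_that("halving the RK4 step changes stored results by less than 1e-4", {
  s <- dimer_setup(dE = 100, V = 50, t_end = 2000, snapshots = 2000)
  rs <- build_rate_set(s$setup)
  t1 <- propagate_populations(rs, c(1, 0), dt = 1, t_end = 2000)
  t2 <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 2000,
                              store_stride = 2)
  expect_equal(t1$P, t2$P, tolerance = 1e-4)
  f1 <- accumulate_dissipation(rs, t1, 2000)
  f2 <- accumulate_dissipation(rs, t2, 2000)
  expect_equal(f1$E_acc, f2$E_acc, tolerance = 1e-4)
})

test_that("invalid initial conditions and steps are rejected", {
  K <- matrix(0, 2, 2)
  expect_error(propagate_populations(K, c(0.6, 0.6), dt = 1, t_end = 10),
               class = "dissipath_validation_error")
  expect_error(propagate_populations(K, c(-0.1, 1.1), dt = 1, t_end = 10),
               class = "dissipath_validation_error")
  expect_error(propagate_populations(K, c(1, 0), dt = -1, t_end = 10),
               class = "dissipath_validation_error")
})

test_that("dissipation function: locality, additivity over partners, sign", {
  # 3-site chain: A-B coupled, B-C coupled, A-C uncoupled
  V <- matrix(0, 3, 3); V[1, 2] <- V[2, 1] <- 30; V[2, 3] <- V[3, 2] <- 30
  model <- exciton_model(c(200, 100, 0), V, c("A", "B", "C"))
  J <- drude_density()
  cfg <- run_config(n_modes = 200, t_max_rate_fs = 5000,
                    t_end_dynamics_fs = 2000, snapshot_times_fs = 2000)
  setup <- suppressWarnings(prepare_baths(model, list(J, J, J), cfg))
  rs <- build_rate_set(setup)

  # all population on C: A is decoupled from C, so A's bath is silent
  D_A <- dissipation_function("A", rs, c(0, 0, 1))
  expect_true(all(D_A == 0))

  # additivity over partners: the two-partner D_B equals the sum of the
  # A-only and C-only contributions (each a pairwise term of the sum)
  P <- c(0.3, 0.5, 0.2)
  D_B <- dissipation_function("B", rs, P)
  D_via_A <- rs$J_out[, 2, 1] * P[2] + rs$J_in[, 2, 1] * P[1]
  D_via_C <- rs$J_out[, 2, 3] * P[2] + rs$J_in[, 2, 3] * P[3]
  expect_equal(D_B, D_via_A + D_via_C, tolerance = 1e-12)
})

test_that("accumulated dissipation starts at zero and sums over chromophores", {
  s <- dimer_setup(dE = 100, V = 50, t_end = 2000, snapshots = c(0, 2000))
  rs <- build_rate_set(s$setup)
  traj <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 2000)
  fld <- accumulate_dissipation(rs, traj, c(0, 2000))
  expect_true(all(fld$E_acc[, , 1] == 0))
  expect_equal(fld$E_tot, apply(fld$E_acc, c(1, 3), sum), tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_error(accumulate_dissipation(rs, traj, 3000),
               class = "dissipath_validation_error")
})

test_that("global energy conservation on two- and three-site models", {
  # two-site downhill
  s <- dimer_setup(dE = 200, V = 50, t_end = 4000, snapshots = 4000)
  rs <- build_rate_set(s$setup)
  traj <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 4000)
  fld <- accumulate_dissipation(rs, traj, 4000)
  n <- nrow(traj$P)
  elec <- sum((traj$P[1, ] - traj$P[n, ]) * s$model$site_energies)
  expect_equal(total_integral(fld, 1), elec, tolerance = 0.02)

  # three-site chain with an uphill first step
  V <- matrix(0, 3, 3); V[1, 2] <- V[2, 1] <- 40; V[2, 3] <- V[3, 2] <- 40
  model3 <- exciton_model(c(100, 220, 0), V, c("A", "B", "C"))
  J <- drude_density()
  cfg <- run_config(n_modes = 300, t_max_rate_fs = 6000,
                    t_end_dynamics_fs = 5000, snapshot_times_fs = c(40, 5000))
  setup3 <- suppressWarnings(prepare_baths(model3, list(J, J, J), cfg))
  rs3 <- build_rate_set(setup3)
  traj3 <- propagate_populations(rs3, c(1, 0, 0), dt = 0.5, t_end = 5000)
  fld3 <- accumulate_dissipation(rs3, traj3, c(40, 5000))
  n3 <- nrow(traj3$P)
  elec3 <- sum((traj3$P[1, ] - traj3$P[n3, ]) * model3$site_energies)
  expect_equal(total_integral(fld3, 2), elec3, tolerance = 0.02)
})

test_that("symmetric dimer dissipates nothing net at long times", {
  s <- dimer_setup(dE = 0, V = 50, t_end = 4000, snapshots = 4000)
  rs <- build_rate_set(s$setup)
  traj <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 4000)
  fld <- accumulate_dissipation(rs, traj, 4000)
  expect_lt(abs(total_integral(fld, 1)), 1e-6)
})

test_that("band summary partitions the frequency integral", {
  s <- dimer_setup(dE = 200, V = 50, t_end = 3000, snapshots = 3000)
  rs <- build_rate_set(s$setup)
  traj <- propagate_populations(rs, c(1, 0), dt = 0.5, t_end = 3000)
  fld <- accumulate_dissipation(rs, traj, 3000)
  rng <- range(fld$omega_grid)
  full <- band_summary(fld, c(rng[1], rng[2] + 1e-9))
  expect_equal(full$total, total_integral(fld, 1), tolerance = 1e-12)
  two <- band_summary(fld, c(rng[1], 800, rng[2] + 1e-9))
  expect_equal(sum(two$total), full$total, tolerance = 1e-12)
  expect_error(band_summary(fld, c(800, 500)),
               class = "dissipath_validation_error")
  expect_error(band_summary(fld, c(5000, 6000)),
               class = "dissipath_validation_error")
})
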