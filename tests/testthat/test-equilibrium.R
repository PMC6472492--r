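test_that("the equilibrium satisfies R0 = 1 and the resource mass balance", {
  eq <- solve_equilibrium(p_default)
  expect_false(eq$extinct)
  expect_gt(eq$R_tilde, 0)
  expect_lt(eq$R_tilde, p_default$Rmax)
  expect_lt(abs(eq$trajectory$R0 - 1), 1e-8)
  G <- resource_growth_rate(eq$R_tilde, p_default)
  expect_lt(abs(eq$resource_residual), 1e-10 * G)
  expect_true(all(coef(eq) >= 0))
})

test_that("biomass production and mortality losses balance at stationarity", {
  for (p in list(p_default, update_params(p_default, Q = 1.1),
                 update_params(p_default, P = 1.15))) {
    eq <- solve_equilibrium(p)
    lh <- eq$trajectory
    # d(sF)/da integrated over life: s_b + int g F = int mu s F (+ tail)
    expect_lt(abs(p$s_b + lh$GI - lh$MU) / lh$MU, 1e-6)
  }
})

test_that("the conversion constant chi rescales only absolute abundances", {
  eq1 <- solve_equilibrium(p_default)
  eq2 <- solve_equilibrium(update_params(p_default, chi = 2))
  expect_equal(eq2$R_tilde, eq1$R_tilde, tolerance = 1e-12)
  expect_equal(eq2$b_tilde, eq1$b_tilde / 2, tolerance = 1e-10)
  expect_equal(eq2$total_biomass, eq1$total_biomass / 2, tolerance = 1e-10)
  expect_equal(eq2$asymptotic_size, eq1$asymptotic_size, tolerance = 1e-10)
})

test_that("with faster-rising maintenance the resource pins at the MRD of the largest size", {
  p <- update_params(p_default, Q = 1, P = 1.2)
  eq <- solve_equilibrium(p)
  mrd_top <- maintenance_resource_density(eq$asymptotic_size, p)
  expect_lt(abs(eq$R_tilde - mrd_top) / eq$R_tilde, 0.01)
  expect_lt(eq$asymptotic_size, p$s_m)
  # juvenile production surplus: maturation flux exceeds reproduction,
  # and standing biomass accumulates in the adult stage
  expect_gt(eq$maturation_rate_biomass, eq$reproduction_rate_biomass)
  expect_gt(eq$adult_biomass, eq$juvenile_biomass)
})

test_that("a non-viable consumer yields the extinct-equilibrium marker", {
  eq <- solve_equilibrium(update_params(p_default, mu_c = 0.05))
  expect_true(eq$extinct)
  expect_equal(eq$b_tilde, 0)
  expect_equal(eq$total_biomass, 0)
})

test_that("an equilibrium sweep returns one well-formed row per grid point", {
  grid <- c(0.95, 1, 1.05)
  sw <- ecological_sweep("Q", grid, p_default)
  expect_s3_class(sw, "deb_sweep")
  expect_equal(nrow(sw), 3)
  expect_equal(sw$Q, grid)
  expect_true(all(is.finite(sw$R_tilde)))
  expect_true(all(sw$asymptotic_size > p_default$s_j))
  expect_error(ecological_sweep("Q", c(1, 0.9, 1.1), p_default), "monotone")
})

test_that("a sweep with cycle detection flags only the unstable side", {
  sw <- ecological_sweep("Q", c(0.9, 1.2), p_default, with_cycles = TRUE,
                         t_max = 25000, transient = 18000)
  expect_identical(sw$cyclic, c(FALSE, TRUE))
  expect_gt(sw$amplitude[2], 0.01)
  # envelopes straddle the (unstable) equilibrium value
  expect_lt(sw$R_min[2], sw$R_tilde[2])
  expect_gt(sw$R_max[2], sw$R_tilde[2])
})
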