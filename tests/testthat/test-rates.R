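test_that("ingestion follows a saturating type-II response with allometric maximum", {
  p <- p_default
  expect_equal(ingestion_rate(0, 1, p), 0)
  expect_equal(ingestion_rate(0, 5, p), 0)
  # at R = H the response is half-saturated
  expect_equal(ingestion_rate(3, 1, p), p$M / 2)
  # saturation limit M (s/s_r)^Q
  expect_equal(ingestion_rate(1e12, 2, p), p$M * 2, tolerance = 1e-8)
  # strictly increasing and bounded in R
  R <- c(0.1, 0.5, 1, 5, 20)
  I <- ingestion_rate(R, 2, p)
  expect_true(all(diff(I) > 0))
  expect_true(all(I < p$M * 2))
  # homogeneity in size
  s <- c(0.2, 1, 3.7, 9)
  for (Q in c(0.8, 1, 1.3)) {
    pq <- update_params(p, Q = Q)
    expect_equal(ingestion_rate(2, s, pq),
                 (s / pq$s_rI)^Q * ingestion_rate(2, pq$s_rI, pq))
  }
  expect_error(ingestion_rate(1, 0, p), "positive")
  expect_error(ingestion_rate(-1, 1, p), "nonnegative")
})

test_that("biomass production is assimilation minus maintenance, split in sign parts", {
  p <- p_default
  expect_equal(biomass_production(3, 1, p), 0.5 * 0.05 - 0.01)
  # zero exactly at the maintenance resource density
  for (s in c(0.1, 1, 4, 10)) {
    mrd <- maintenance_resource_density(s, p)
    expect_equal(biomass_production(mrd, s, p), 0,
                 tolerance = 1e-12 * p$T * (s / p$s_rT)^p$P)
  }
  # sign convention and complementarity of the parts
  grid <- expand.grid(R = c(0, 0.3, 0.75, 2, 10), s = c(0.1, 1, 5, 10))
  om <- biomass_production(grid$R, grid$s, p)
  op <- production_pos(grid$R, grid$s, p)
  on <- production_neg(grid$R, grid$s, p)
  expect_equal(op + on, om)
  expect_true(all(op * on == 0))
  expect_true(all(op >= 0) && all(on <= 0))
})

test_that("allocation to growth is a C1 smoothstep from maturation to maximum size", {
  p <- p_default
  expect_equal(allocation_fraction(0.5 * (p$s_b + p$s_j), p), 1)
  expect_equal(allocation_fraction((p$s_j + p$s_m) / 2, p), 0.5)
  expect_equal(allocation_fraction(p$s_m, p), 0)
  s <- seq(p$s_b, p$s_m, length.out = 400)
  k <- allocation_fraction(s, p)
  expect_true(all(k >= 0 & k <= 1))
  expect_true(all(diff(k) <= 0))
  # zero slope at both ends of the adult range
  eps <- 1e-4
  expect_lt(abs(allocation_fraction(p$s_j + eps, p) - 1) / eps, 1e-4)
  expect_lt(abs(allocation_fraction(p$s_m - eps, p)) / eps, 1e-4)
  # floating-point overshoot above s_m clamps to zero
  expect_equal(allocation_fraction(p$s_m * (1 + 1e-12), p), 0)
  expect_error(allocation_fraction(p$s_b / 2, p), "below")
})

test_that("growth and fecundity vanish under starvation and split production by kappa", {
  p <- p_default
  expect_equal(growth_rate(3, 1, p), 0.015)  # juvenile: all production to growth
  expect_equal(growth_rate(0.5, 1, p), 0)    # below the MRD of 0.75
  expect_equal(growth_rate(3, p$s_m, p), 0)  # kappa(s_m) = 0
  expect_equal(fecundity_rate(3, 0.5, p), 0) # juveniles do not reproduce
  expect_equal(fecundity_rate(0.5, 5, p), 0) # starving adults do not either
  # at s_m all production goes to reproduction
  om <- biomass_production(3, p$s_m, p)
  expect_equal(fecundity_rate(3, p$s_m, p), om / p$s_b)
  # growth + s_b * fecundity account for all positive production
  s <- seq(p$s_b, p$s_m, length.out = 50)
  expect_equal(growth_rate(3, s, p) + p$s_b * fecundity_rate(3, s, p),
               production_pos(3, s, p))
})

test_that("mortality adds stage and mass-specific starvation terms to the background", {
  p <- update_params(p_default, mu_j = 0)
  expect_equal(mortality_rate(3, 0.5, p), 0.0015)
  pa <- update_params(p_default, mu_a = 0.002)
  expect_equal(mortality_rate(3, 5, pa), 0.0015 + 0.002)
  # full starvation at R = 0: deficit is maintenance, mass-specific
  expect_equal(mortality_rate(0, 1, p_default), 0.0015 + 0.01)
  grid <- expand.grid(R = c(0, 0.5, 2, 10), s = c(0.1, 0.9, 1.1, 10))
  expect_true(all(mortality_rate(grid$R, grid$s, p_default) >=
                    p_default$mu_c))
})

test_that("the maintenance resource density has the closed form and sentinel behaviour", {
  # equal exponents: size-independent, H T / (sigma M - T)
  for (x in c(0.8, 1, 1.19)) {
    p <- update_params(p_default, Q = x, P = x)
    s <- seq(p$s_b, p$s_m, length.out = 200)
    mrd <- maintenance_resource_density(s, p)
    expect_equal(mrd, rep(0.75, length(s)), tolerance = 1e-13)
  }
  # P > Q: rises with size; Q > P: falls with size
  s <- seq(0.1, 10, length.out = 50)
  expect_true(all(diff(maintenance_resource_density(
    s, update_params(p_default, P = 1.2))) > 0))
  expect_true(all(diff(maintenance_resource_density(
    s, update_params(p_default, Q = 1.2))) < 0))
  # maintenance above saturated assimilation: no finite root
  p_inf <- update_params(p_default, P = 2.5)
  expect_identical(maintenance_resource_density(10, p_inf), Inf)
  expect_error(maintenance_resource_density(-1, p_default), "positive")
})

test_that("resource renewal is semi-chemostat", {
  p <- p_default
  expect_equal(resource_growth_rate(p$Rmax, p), 0)
  expect_equal(resource_growth_rate(0, p), 0.3)
  R1 <- 4; R2 <- 22
  expect_equal(resource_growth_rate(R1, p) + resource_growth_rate(R2, p),
               2 * resource_growth_rate((R1 + R2) / 2, p))
})

test_that("parameter validation enforces the model's viability constraints", {
  expect_error(deb_params(s_b = 2), "s_b < s_j")
  expect_error(deb_params(sigma = 0), "sigma")
  expect_error(deb_params(sigma = 0.05), "cover maintenance")
  expect_error(deb_params(mu_c = -1), "nonnegative")
  expect_warning(deb_params(s_r = 20), "trade-off")
  expect_error(update_params(p_default, nope = 1), "unknown")
  # replacing s_r drags the per-process reference masses along
  p2 <- update_params(p_default, s_r = 2)
  expect_equal(p2$s_rI, 2)
  expect_equal(p2$s_rT, 2)
})
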