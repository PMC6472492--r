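test_that("juvenile growth at equal unit exponents matches the exponential closed form", {
  p <- p_default  # Q = P = 1, s_r = 1
  R <- 3
  rate <- p$sigma * p$M * R / (R + p$H) - p$T  # 0.015/day
  lh <- life_history(R, p)
  juv <- lh$a < lh$a_j
  expect_equal(lh$s[juv], p$s_b * exp(rate * lh$a[juv]), tolerance = 1e-6)
  expect_equal(lh$a_j, log(p$s_j / p$s_b) / rate, tolerance = 1e-6)
})

test_that("survivorship follows the piecewise-constant-hazard closed form without starvation", {
  p <- update_params(p_default, mu_j = 0.001, mu_a = 0.002)
  R <- 3  # above the (size-independent) MRD, so no starvation at any size
  lh <- life_history(R, p)
  muj <- p$mu_c + p$mu_j
  mua <- p$mu_c + p$mu_a
  Fref <- ifelse(lh$a <= lh$a_j, exp(-muj * lh$a),
                 exp(-muj * lh$a_j - mua * (lh$a - lh$a_j)))
  expect_equal(lh$F, Fref, tolerance = 1e-7)
})

test_that("the adaptive integrator agrees with a brute-force Euler oracle", {
  p <- p_default
  R <- 3
  targets <- c(40, 100, 200, 300)  # spans maturation at ~153.5 d
  oracle <- euler_life_history(R, p, targets, dt = 1e-4)
  lh <- life_history(R, p, at = targets)
  for (v in c("s", "F", "Theta", "B")) {
    mine <- stats::approx(lh$a, lh[[v]], targets)$y
    ref <- oracle[, v]
    scale <- pmax(abs(ref), 1e-3)
    # the bound is set by the first-order oracle's own truncation error,
    # which halves when dt is halved
    expect_lt(max(abs(mine - ref) / scale), 5e-5)
  }
})

test_that("R0 is monotone in resource density and robust to the survival cutoff", {
  p <- p_default
  R0s <- vapply(c(1, 2, 3, 5, 10), lifetime_R0, numeric(1), p = p)
  expect_true(all(diff(R0s) > 0))
  r_a <- lifetime_R0(3, p, numerics_config(survival_cutoff = 1e-9))
  r_b <- lifetime_R0(3, p, numerics_config(survival_cutoff = 5e-10))
  expect_lt(abs(r_a - r_b) / r_a, 1e-6)
})

test_that("age at maturation decreases with resource density", {
  p <- p_default
  aj <- vapply(c(1.5, 3, 10),
               function(R) life_history(R, p)$a_j, numeric(1))
  expect_true(all(diff(aj) < 0))
})

test_that("below the newborn MRD the life history stalls with zero reproduction", {
  p <- p_default
  lh <- life_history(0.4, p)  # MRD is 0.75 at all sizes
  expect_equal(lh$R0, 0)
  expect_true(all(lh$s == p$s_b))
  expect_true(all(lh$B == 0))
  expect_true(is.na(lh$a_j))
  expect_gt(lh$Theta_inf, 0)  # starving individuals still ingest
})

test_that("trajectory invariants hold across parameter regimes", {
  variants <- list(
    p_default,
    update_params(p_default, Q = 1.2),
    update_params(p_default, P = 1.2),          # growth stalls below s_m
    update_params(p_default, mu_j = 0.002, mu_a = 0.001),
    update_params(p_default, s_b = 0.05))
  for (p in variants) {
    for (R in c(1.2, 3)) {
      lh <- life_history(R, p)
      expect_true(all(diff(lh$s) >= -1e-12))
      expect_true(all(lh$F > 0 & lh$F <= 1))
      expect_true(all(diff(lh$F) <= 0))
      expect_true(all(diff(lh$B) >= 0))
      expect_true(all(diff(lh$Theta) >= 0))
      expect_equal(lh$s[1], p$s_b)
      expect_lte(lh$s_end, p$s_m)
    }
  }
})

test_that("a trajectory exports to CSV with the documented schema", {
  lh <- life_history(3, p_default)
  f <- tempfile(fileext = ".csv")
  export_trajectory(lh, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("age", "size", "survivorship",
                                  "cum_fecundity", "cum_ingestion"))
  expect_equal(back$size, lh$s)
})
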