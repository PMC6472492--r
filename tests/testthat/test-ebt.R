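test_that("without consumers the resource follows the semi-chemostat closed form", {
  sim <- ebt_simulate(p_default, t_max = 500,
                      init = list(R = 5, cohorts = matrix(c(0, 0.1, 0, 0), 1)))
  ref <- 30 - (30 - 5) * exp(-0.01 * sim$ts$time)
  expect_lt(max(abs(sim$ts$resource - ref)), 1e-8)
})

test_that("in the stable regime the cohort simulation settles on the equilibrium solution", {
  eq <- solve_equilibrium(p_default)
  sim <- ebt_simulate(p_default, t_max = 8000,
                      init = ebt_init_equilibrium(eq), perturb = 0.05)
  tail_ts <- sim$ts[sim$ts$time > 6000, ]
  expect_lt(abs(mean(tail_ts$resource) / eq$R_tilde - 1), 0.01)
  expect_lt(abs(mean(tail_ts$juvenile_biomass) / eq$juvenile_biomass - 1),
            0.01)
  expect_lt(abs(mean(tail_ts$adult_biomass) / eq$adult_biomass - 1), 0.01)
  cyc <- detect_cycles(sim, transient = 4000)
  expect_false(cyc$cyclic)
})

test_that("refining the closure interval and step leaves long-run averages unchanged", {
  eq <- solve_equilibrium(p_default)
  init <- ebt_init_equilibrium(eq)
  avg <- function(o) {
    sim <- ebt_simulate(p_default, t_max = 3000, init = init,
                        perturb = 0.05, options = o)
    tl <- sim$ts[sim$ts$time > 2500, ]
    c(mean(tl$resource), mean(tl$total_biomass))
  }
  a1 <- avg(ebt_options())
  a2 <- avg(ebt_options(dt = 0.25, dt_cohort = 1.25, record_every = 1.25))
  expect_lt(max(abs(a2 / a1 - 1)), 0.005)
})

test_that("cycle detection recovers the period and amplitude of a known signal", {
  t <- seq(0, 1000, by = 2.5)
  ts <- synthetic_ts(t, 1 + 0.05 * sin(2 * pi * t / 100))
  cyc <- detect_cycles(ts, transient = 100)
  expect_true(cyc$cyclic)
  expect_equal(cyc$period, 100, tolerance = 0.01)
  expect_equal(cyc$amplitude, 0.1, tolerance = 0.02)
  flat <- detect_cycles(synthetic_ts(t, rep(1, length(t))))
  expect_false(flat$cyclic)
  expect_equal(flat$amplitude, 0)
  expect_true(is.na(flat$period))
})

test_that("state variables stay in their physical ranges through cycles", {
  p <- update_params(p_default, Q = 1.2)
  eq <- solve_equilibrium(p)
  sim <- ebt_simulate(p, t_max = 6000, init = ebt_init_equilibrium(eq),
                      perturb = 0.05)
  ts <- sim$ts
  expect_true(all(ts$resource >= 0 & ts$resource <= p$Rmax * (1 + 1e-9)))
  expect_true(all(ts$juvenile_biomass >= 0))
  expect_true(all(ts$adult_biomass >= 0))
  coh <- sim$final_state$cohorts
  expect_true(all(coh[, "density"] >= 0))
  expect_true(all(coh[, "mass"] >= p$s_b & coh[, "mass"] <= p$s_m))
})

test_that("exceeding the cohort cap raises an actionable error", {
  eq <- solve_equilibrium(p_default)
  expect_error(
    ebt_simulate(p_default, t_max = 200, init = ebt_init_equilibrium(eq),
                 options = ebt_options(max_cohorts = 50)),
    "dt_cohort")
})

test_that("a mutant identical to the resident drifts neutrally", {
  inv <- invasion_experiment(p_default, "Q", p_default$Q,
                             t_attract = 3000, t_invade = 12000)
  expect_equal(inv$outcome, "neutral")
  expect_lt(abs(inv$log_share_growth), log(2))
  final_share <- inv$share$mutant_share[nrow(inv$share)]
  expect_gt(final_share, 1e-7)
  expect_lt(final_share, 1e-5)
})

test_that("invasion outcomes in the cyclic attractor agree with the selection gradient", {
  p <- update_params(p_default, Q = 1.25)  # cyclic side, above the CSS
  toward <- invasion_experiment(p, "Q", 1.22, t_attract = 15000,
                                t_invade = 40000)
  expect_equal(toward$outcome, "invades")
  expect_true(toward$resident_cyclic)
  away <- invasion_experiment(p, "Q", 1.28, t_attract = 15000,
                              t_invade = 40000)
  expect_equal(away$outcome, "fails")
})
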