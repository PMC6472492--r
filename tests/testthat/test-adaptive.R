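test_that("a mutant identical to the resident has unit invasion fitness", {
  eq <- solve_equilibrium(p_default)
  expect_equal(mutant_R0(c(Q = p_default$Q), eq$R_tilde, p_default), 1,
               tolerance = 1e-7)
  expect_equal(mutant_R0(c(P = p_default$P), eq$R_tilde, p_default), 1,
               tolerance = 1e-7)
})

test_that("mutant fitness increases with assimilation efficiency", {
  eq <- solve_equilibrium(p_default)
  r0 <- vapply(c(0.5, 0.55, 0.6),
               function(sg) mutant_R0(c(sigma = sg), eq$R_tilde, p_default),
               numeric(1))
  expect_true(all(diff(r0) > 0))
})

test_that("selection on the ingestion exponent changes sign across its singular value", {
  expect_gt(selection_gradient("Q", p_default), 0)
  expect_lt(selection_gradient("Q", update_params(p_default, Q = 1.35)), 0)
})

test_that("the selection gradient is robust to the finite-difference step", {
  n1 <- numerics_config()
  n2 <- numerics_config(fd_step = n1$fd_step / 2)
  eq <- solve_equilibrium(p_default, n1)
  g1 <- selection_gradient("Q", p_default, n1, eq)
  g2 <- selection_gradient("Q", p_default, n2, eq)
  expect_lt(abs(g1 - g2) / abs(g1), 1e-5)
})

test_that("the singular ingestion exponent is a CSS at a resource-density minimum", {
  css <- find_css("Q", p_default)
  x <- css$traits[["Q"]]
  # the singular value of one exponent stays close to the other, fixed one
  expect_lt(abs(x - p_default$P), 0.05)
  expect_lt(abs(css$gradient), 1e-4)
  expect_true(css$evolutionarily_stable)
  expect_true(css$convergence_stable)
  expect_true(css$R_tilde_local_min)
})

test_that("realized reproductive output scales smoothly over the adult range", {
  eq <- solve_equilibrium(p_default)
  b1 <- reproduction_scaling_check(eq)
  expect_true(is.finite(b1))
  expect_gt(b1, 0)
  # a per-capita quantity: invariant to the resource-conversion constant
  eq2 <- solve_equilibrium(update_params(p_default, chi = 3))
  expect_equal(reproduction_scaling_check(eq2), b1, tolerance = 1e-8)
})

test_that("the joint singular value ignores scale parameters but tracks the reference mass", {
  base <- find_joint_css(p_default)
  x0 <- base$traits[["Q"]]
  # doubling the ingestion constant or the resource ceiling: no effect
  cssM <- find_joint_css(update_params(p_default, M = 0.2),
                         start = base$traits)
  expect_lt(abs(cssM$traits[["Q"]] - x0), 2e-3)
  cssR <- find_joint_css(update_params(p_default, Rmax = 60),
                         start = base$traits)
  expect_lt(abs(cssR$traits[["Q"]] - x0), 2e-3)
  # raising the reference mass lowers the common value
  cssr <- find_joint_css(update_params(p_default, s_r = 2))
  expect_lt(cssr$traits[["Q"]], x0 - 0.05)
  expect_lt(abs(cssr$trait_gap), 1e-3)
})
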