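#' Invasion fitness of a mutant in a resident environment
#'
#' Expected lifetime reproductive success of a rare mutant carrying modified
#' trait values, evaluated in the environment set by the resident: because
#' the only feedback variable is the resource density, the resident
#' environment is fully described by its equilibrium resource density
#' `R_tilde`, and mutant fitness is simply `R0` at that density with mutant
#' parameters. A mutant with `R0 > 1` can invade; the resident itself has
#' `R0 = 1` by the definition of equilibrium.
#'
#' @param traits Named numeric vector of mutated parameters (typically
#'   `c(Q = ...)`, `c(P = ...)` or both).
#' @param R_resident Resident equilibrium resource density (mg/L).
#' @param p Resident [deb_params()].
#' @param n A [numerics_config()].
#' @return Mutant R0 (dimensionless).
#' @examples
#' \donttest{
#' eq <- solve_equilibrium(deb_params())
#' mutant_R0(c(Q = 1.01), eq$R_tilde, deb_params())
#' }
#' @export
mutant_R0 <- function(traits, R_resident, p, n = numerics_config()) {
  mp <- do.call(update_params, c(list(p), as.list(traits)))
  lifetime_R0(R_resident, mp, n)
}

#' Selection gradient on a scaling exponent
#'
#' Central finite difference of mutant R0 with respect to the mutant trait,
#' evaluated at the resident trait value in the resident's equilibrium
#' environment (step `n$fd_step`). A positive gradient means selection for
#' larger trait values.
#'
#' @param trait `"Q"` or `"P"` (any numeric parameter is accepted).
#' @param p Resident [deb_params()].
#' @param n A [numerics_config()].
#' @param eq Optional pre-solved resident [solve_equilibrium()] result.
#' @return The fitness slope (per unit trait).
#' @export
selection_gradient <- function(trait, p, n = numerics_config(), eq = NULL) {
  if (is.null(eq)) eq <- solve_equilibrium(p, n)
  if (eq$extinct) stop("resident population is not viable")
  h <- n$fd_step
  x <- p[[trait]]
  (mutant_R0(stats::setNames(x + h, trait), eq$R_tilde, p, n) -
     mutant_R0(stats::setNames(x - h, trait), eq$R_tilde, p, n)) / (2 * h)
}

# both selection gradients at one resident; shares the equilibrium solve
gradient_QP <- function(p, n, bracket = NULL) {
  eq <- solve_equilibrium(p, n, bracket = bracket)
  if (eq$extinct) stop("resident population is not viable at Q = ", p$Q,
                       ", P = ", p$P)
  h <- n$fd_step
  g <- c(Q = (mutant_R0(c(Q = p$Q + h), eq$R_tilde, p, n) -
                mutant_R0(c(Q = p$Q - h), eq$R_tilde, p, n)) / (2 * h),
         P = (mutant_R0(c(P = p$P + h), eq$R_tilde, p, n) -
                mutant_R0(c(P = p$P - h), eq$R_tilde, p, n)) / (2 * h))
  list(g = g, eq = eq)
}

classify_singular <- function(trait, x_star, p, n, eq, h2 = 0.02) {
  # mutant curvature: R0(resident trait) = 1 exactly at equilibrium
  up <- mutant_R0(stats::setNames(x_star + h2, trait), eq$R_tilde, p, n)
  dn <- mutant_R0(stats::setNames(x_star - h2, trait), eq$R_tilde, p, n)
  d2 <- (up - 2 + dn) / h2^2
  # convergence: slope of the selection gradient across residents
  g_up <- selection_gradient(
    trait, do.call(update_params,
                   c(list(p), stats::setNames(list(x_star + h2), trait))), n)
  g_dn <- selection_gradient(
    trait, do.call(update_params,
                   c(list(p), stats::setNames(list(x_star - h2), trait))), n)
  dg <- (g_up - g_dn) / (2 * h2)
  list(
    mutant_curvature = d2,
    evolutionarily_stable = if (abs(d2) > 1e-6) d2 < 0 else NA,
    gradient_slope = dg,
    convergence_stable = if (abs(dg) > 1e-6) dg < 0 else NA)
}

#' Locate and classify a singular strategy of one scaling exponent
#'
#' Finds the trait value at which the selection gradient vanishes, by
#' bracketed root finding over the resident trait (each evaluation re-solves
#' the resident ecological equilibrium). The singular point is classified by
#' the second-order mutant curvature (negative: evolutionarily stable) and
#' the slope of the gradient across residents (negative: convergence
#' stable); a point with both is a continuously stable strategy (CSS). The
#' equilibrium resource density is also checked for a local minimum at the
#' singular point, the model's geometric signature of an ESS.
#'
#' @param trait `"Q"` or `"P"`.
#' @param p Baseline [deb_params()]; the non-evolving exponent stays at its
#'   value in `p`.
#' @param n A [numerics_config()].
#' @param bracket Search interval for the trait.
#' @return An object of class `deb_css`: `traits` (named singular value),
#'   `gradient` at the point, classification fields, `R_tilde_local_min`,
#'   and the resident `equilibrium`.
#' @examples
#' \donttest{
#' find_css("Q", deb_params())
#' }
#' @export
find_css <- function(trait, p, n = numerics_config(), bracket = c(0.5, 1.6)) {
  eq_bracket <- NULL
  gfun <- function(x) {
    px <- do.call(update_params, c(list(p), stats::setNames(list(x), trait)))
    eq <- solve_equilibrium(px, n, bracket = eq_bracket)
    if (eq$extinct) stop("resident not viable at ", trait, " = ", x)
    eq_bracket <<- c(eq$R_tilde * 0.5, min(px$Rmax, eq$R_tilde * 2))
    selection_gradient(trait, px, n, eq = eq)
  }
  g_lo <- gfun(bracket[1]); g_hi <- gfun(bracket[2])
  if (sign(g_lo) == sign(g_hi))
    stop("selection gradient does not change sign on [",
         bracket[1], ", ", bracket[2], "]: endpoints ",
         signif(g_lo, 4), ", ", signif(g_hi, 4))
  root <- stats::uniroot(gfun, bracket, f.lower = g_lo, f.upper = g_hi,
                         tol = 1e-7)$root
  p_star <- do.call(update_params,
                    c(list(p), stats::setNames(list(root), trait)))
  eq <- solve_equilibrium(p_star, n, bracket = eq_bracket)
  cls <- classify_singular(trait, root, p_star, n, eq)
  dR <- 0.02
  R_nbr <- vapply(c(root - dR, root + dR), function(x) {
    solve_equilibrium(do.call(update_params,
                              c(list(p), stats::setNames(list(x), trait))),
                      n, bracket = c(eq$R_tilde * 0.5, eq$R_tilde * 2))$R_tilde
  }, numeric(1))
  out <- c(list(traits = stats::setNames(root, trait),
                gradient = selection_gradient(trait, p_star, n, eq = eq),
                R_tilde_local_min = all(R_nbr > eq$R_tilde),
                equilibrium = eq),
           cls)
  class(out) <- "deb_css"
  out
}

#' Joint singular strategy of both scaling exponents
#'
#' Solves the simultaneous vanishing of the selection gradients on the
#' ingestion exponent Q and the maintenance exponent P, by a damped
#' quasi-Newton iteration on the two-dimensional gradient (forward-difference
#' Jacobian; every evaluation re-solves the resident equilibrium). At the
#' joint singular point the model predicts equal exponents, making the
#' maintenance resource density independent of body mass: competitive
#' asymmetry is selected away.
#'
#' @param p Baseline [deb_params()].
#' @param n A [numerics_config()].
#' @param start Numeric length-2 starting point `c(Q, P)`.
#' @param grad_tol Convergence tolerance on the gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `deb_css` with `traits = c(Q, P)`, the final
#'   gradient, per-trait classification, `trait_gap` (`Q - P` at the point)
#'   and the resident `equilibrium`.
#' @examples
#' \donttest{
#' css <- find_joint_css(deb_params())
#' css$traits
#' }
#' @export
find_joint_css <- function(p, n = numerics_config(),
                           start = c(Q = 1.1, P = 1.1),
                           grad_tol = 2e-4, max_iter = 40) {
  x <- c(Q = unname(start[1]), P = unname(start[2]))
  bracket <- NULL
  hJ <- 1e-3
  ev <- function(x) {
    px <- update_params(p, Q = x[["Q"]], P = x[["P"]])
    gr <- gradient_QP(px, n, bracket = bracket)
    bracket <<- c(gr$eq$R_tilde * 0.5, min(p$Rmax, gr$eq$R_tilde * 2))
    gr
  }
  cur <- ev(x)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(cur$g^2)) < grad_tol) break
    J <- matrix(0, 2, 2, dimnames = list(c("Q", "P"), c("Q", "P")))
    for (v in c("Q", "P")) {
      xh <- x; xh[v] <- xh[v] + hJ
      J[, v] <- (ev(xh)$g - cur$g) / hJ
    }
    step <- tryCatch(-solve(J, cur$g), error = function(e) -cur$g * 0.01)
    nrm <- sqrt(sum(step^2))
    if (nrm > 0.1) step <- step * (0.1 / nrm)
    lambda <- 1
    repeat {
      cand <- ev(x + lambda * step)
      if (sqrt(sum(cand$g^2)) < sqrt(sum(cur$g^2)) || lambda < 1 / 16) break
      lambda <- lambda / 2
    }
    moved <- sqrt(sum((lambda * step)^2))
    x <- x + lambda * step
    cur <- cand
    if (moved < 1e-8) break
  }
  if (sqrt(sum(cur$g^2)) >= 10 * grad_tol)
    warning("joint singular point not fully converged: |gradient| = ",
            signif(sqrt(sum(cur$g^2)), 3))
  p_star <- update_params(p, Q = x[["Q"]], P = x[["P"]])
  cls_Q <- classify_singular("Q", x[["Q"]], p_star, n, cur$eq)
  cls_P <- classify_singular("P", x[["P"]], p_star, n, cur$eq)
  out <- list(traits = x, gradient = cur$g,
              trait_gap = x[["Q"]] - x[["P"]],
              classification = list(Q = cls_Q, P = cls_P),
              evolutionarily_stable =
                isTRUE(cls_Q$evolutionarily_stable) &&
                isTRUE(cls_P$evolutionarily_stable),
              convergence_stable =
                isTRUE(cls_Q$convergence_stable) &&
                isTRUE(cls_P$convergence_stable),
              iterations = it, equilibrium = cur$eq)
  class(out) <- "deb_css"
  out
}

#' @export
print.deb_css <- function(x, ...) {
  cat("Singular strategy\n")
  for (nm in names(x$traits))
    cat(sprintf("  %s* = %.6g\n", nm, x$traits[[nm]]))
  if (!is.null(x$trait_gap))
    cat(sprintf("  Q* - P* = %.3g\n", x$trait_gap))
  cat(sprintf("  |selection gradient| = %.3g\n", sqrt(sum(x$gradient^2))))
  es <- x$evolutionarily_stable; cs <- x$convergence_stable
  cat(sprintf("  evolutionarily stable: %s; convergence stable: %s\n",
              ifelse(is.na(es), "near-neutral", es),
              ifelse(is.na(cs), "near-neutral", cs)))
  if (!is.null(x$equilibrium) && !x$equilibrium$extinct)
    cat(sprintf("  resident equilibrium R~ = %.6g mg/L\n",
                x$equilibrium$R_tilde))
  invisible(x)
}

#' @export
coef.deb_css <- function(object, ...) object$traits

#' Evolutionary isocline of one exponent against the other
#'
#' Singular value of the evolving exponent at each value of the fixed
#' exponent, located by [find_css()] with warm-started brackets
#' (continuation along the grid).
#'
#' @param evolving `"Q"` or `"P"`.
#' @param fixed_grid Numeric grid for the other exponent.
#' @param p Baseline [deb_params()].
#' @param n A [numerics_config()].
#' @param bracket Initial search bracket for the evolving trait.
#' @return A data frame of class `deb_isocline` with columns `fixed`,
#'   `css`, `gradient` (re-verified at the reported point) and the resident
#'   equilibrium resource density.
#' @export
evolutionary_isocline <- function(evolving, fixed_grid, p,
                                  n = numerics_config(),
                                  bracket = c(0.5, 1.6)) {
  fixed <- setdiff(c("Q", "P"), evolving)
  if (length(fixed) != 1L) stop("evolving must be 'Q' or 'P'")
  rows <- vector("list", length(fixed_grid))
  br <- bracket
  for (i in seq_along(fixed_grid)) {
    pf <- do.call(update_params,
                  c(list(p), stats::setNames(list(fixed_grid[i]), fixed)))
    css <- tryCatch(find_css(evolving, pf, n, bracket = br),
                    error = function(e) NULL)
    if (is.null(css)) {  # re-scan the full default bracket
      css <- find_css(evolving, pf, n, bracket = c(0.5, 1.6))
    }
    x <- css$traits[[evolving]]
    br <- c(max(0.4, x - 0.08), min(1.8, x + 0.08))
    rows[[i]] <- data.frame(fixed = fixed_grid[i], css = x,
                            gradient = css$gradient,
                            R_tilde = css$equilibrium$R_tilde)
  }
  out <- do.call(rbind, rows)
  attr(out, "evolving") <- evolving
  attr(out, "fixed") <- fixed
  class(out) <- c("deb_isocline", "data.frame")
  out
}

#' Sweep the joint singular strategy along one model parameter
#'
#' Continuation of [find_joint_css()] along a parameter grid (each solution
#' warm-starts the next), with stage-structured equilibrium outputs at every
#' singular point. This is how the evolutionary response of the exponents to
#' stage-specific mortality and to the juvenile/adult size ranges is
#' computed.
#'
#' @param param Name of the swept parameter (e.g. `"mu_j"`, `"mu_a"`,
#'   `"s_b"`, `"s_m"`).
#' @param grid Numeric grid of parameter values.
#' @param p Baseline [deb_params()].
#' @param n A [numerics_config()].
#' @param start Starting point `c(Q, P)` for the first grid point.
#' @return A data frame of class `deb_sweep`: parameter value, `Q_css`,
#'   `P_css`, gradient norm, and the equilibrium outputs at the singular
#'   point.
#' @export
css_sweep <- function(param, grid, p, n = numerics_config(),
                      start = c(Q = 1.1, P = 1.1)) {
  stopifnot(param %in% names(p))
  rows <- vector("list", length(grid))
  x0 <- start
  for (i in seq_along(grid)) {
    pi_ <- do.call(update_params,
                   c(list(p), stats::setNames(list(grid[i]), param)))
    css <- find_joint_css(pi_, n, start = x0)
    x0 <- css$traits
    eq <- css$equilibrium
    rows[[i]] <- data.frame(
      param = grid[i], Q_css = css$traits[["Q"]], P_css = css$traits[["P"]],
      gradient_norm = sqrt(sum(css$gradient^2)), t(coef(eq)))
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  class(out) <- c("deb_sweep", "data.frame")
  attr(out, "swept") <- param
  out
}

#' Scaling of realized reproductive output with adult body mass
#'
#' At a resident equilibrium, regresses the log reproductive biomass flux
#' `log(s_b * b(R_tilde, s))` on `log(s)` over the realized adult size range
#' and returns the fitted exponent. At a joint singular point with equal
#' exponents above one, realized reproduction scales hyperallometrically
#' (exponent above one) even though the maintenance resource density is
#' size-independent.
#'
#' @param eq A [solve_equilibrium()] result or a `deb_css` object (its
#'   resident equilibrium is used).
#' @param n_sizes Number of adult sizes in the regression grid.
#' @param trim Fraction of the adult size range trimmed at both ends (the
#'   flux vanishes at maturation where allocation to reproduction starts at
#'   zero).
#' @return The fitted exponent (slope of the log-log regression).
#' @export
reproduction_scaling_check <- function(eq, n_sizes = 60L, trim = 0.05) {
  if (inherits(eq, "deb_css")) eq <- eq$equilibrium
  stopifnot(inherits(eq, "deb_equilibrium"), !eq$extinct)
  p <- eq$params
  s_hi <- min(eq$asymptotic_size, p$s_m * (1 - 1e-9))
  rng <- s_hi - p$s_j
  s <- seq(p$s_j + trim * rng, s_hi - trim * rng, length.out = n_sizes)
  flux <- p$s_b * fecundity_rate(eq$R_tilde, s, p)
  if (any(flux <= 0)) stop("nonpositive reproductive flux in the adult range")
  unname(stats::coef(stats::lm(log(flux) ~ log(s)))[2])
}
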