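#' Solve the ecological equilibrium
#'
#' Finds the equilibrium of the consumer-resource system from the condition
#' that expected lifetime reproductive success equals one,
#' `R0(R_tilde) = 1`, and the resource mass balance. `R0(R)` is continuous
#' and strictly increasing on the interval where it is positive, so the
#' equilibrium resource density is the unique root of `R0(R) - 1` on
#' `(0, Rmax)`, located by bracketed root finding. The population birth rate
#' then follows from balancing resource renewal against the consumption of
#' the stationary population,
#' `b_tilde = delta (Rmax - R_tilde) / (chi * Theta_inf(R_tilde))`,
#' where `Theta_inf` is the expected lifetime resource ingestion of one
#' individual. Stage-structured biomasses and biomass fluxes are read off
#' the same life-history solution (see [population_outputs()]).
#'
#' If even at `R = Rmax` an individual cannot replace itself
#' (`R0(Rmax) <= 1`) the consumer population is not viable and an extinct
#' equilibrium (resource at `Rmax`, zero consumer) is returned with
#' `extinct = TRUE`.
#'
#' @param p A [deb_params()] object.
#' @param n A [numerics_config()] object.
#' @param bracket Optional initial bracket for the equilibrium resource
#'   density (used to warm-start continuation runs); it is widened
#'   automatically if it does not bracket the root.
#' @return An object of class `deb_equilibrium`: `R_tilde`, `b_tilde`,
#'   `juvenile_biomass`, `adult_biomass`, `total_biomass`,
#'   `maturation_rate_biomass`, `reproduction_rate_biomass`,
#'   `asymptotic_size`, `a_j`, `extinct`, the solved life history
#'   (`trajectory`), the resource-balance residual and a parameter snapshot.
#' @examples
#' eq <- solve_equilibrium(deb_params())
#' eq
#' @export
solve_equilibrium <- function(p, n = numerics_config(), bracket = NULL) {
  stopifnot(inherits(p, "deb_params"))
  hi <- p$Rmax * (1 - 1e-9)
  f <- function(R) lifetime_R0(R, p, n) - 1
  f_hi <- f(hi)
  if (f_hi <= 0) {
    lh <- life_history(hi, p, n)
    out <- list(R_tilde = p$Rmax, b_tilde = 0,
                juvenile_biomass = 0, adult_biomass = 0, total_biomass = 0,
                maturation_rate_biomass = 0, reproduction_rate_biomass = 0,
                asymptotic_size = lh$s_end, a_j = lh$a_j,
                extinct = TRUE, trajectory = lh,
                resource_residual = 0, params = p, numerics = n)
    class(out) <- "deb_equilibrium"
    return(out)
  }

  lo <- 1e-6
  if (!is.null(bracket)) {
    blo <- max(lo, bracket[1]); bhi <- min(hi, bracket[2])
    if (blo < bhi && f(blo) < 0) {
      fb <- f(bhi)
      if (fb > 0) { lo <- blo; hi <- bhi; f_hi <- fb }
    }
  }
  root <- stats::uniroot(f, c(lo, hi), f.upper = f_hi,
                         tol = n$root_tol)$root
  lh <- life_history(root, p, n)
  b_tilde <- p$delta * (p$Rmax - root) / (p$chi * lh$Theta_inf)
  out <- list(R_tilde = root, b_tilde = b_tilde,
              extinct = FALSE, trajectory = lh,
              resource_residual =
                resource_growth_rate(root, p) -
                p$chi * b_tilde * lh$Theta_inf,
              params = p, numerics = n)
  out <- c(out, population_outputs(b_tilde, lh, p))
  class(out) <- "deb_equilibrium"
  out
}

#' Stage-structured population outputs at equilibrium
#'
#' Converts a solved life history and population birth rate into standing
#' stage biomasses and life-stage transition fluxes. With stationary age
#' distribution density `b_tilde * F(a)`:
#' juvenile biomass is `b_tilde * int_0^{a_j} s(a) F(a) da`, adult biomass
#' the complementary integral, the biomass maturation rate is
#' `b_tilde * F(a_j) * s_j` and the biomass reproduction rate is the newborn
#' mass flux `b_tilde * s_b`.
#'
#' @param b_tilde Population birth rate (newborns/day).
#' @param lh A [life_history()] solution at the equilibrium resource density.
#' @param p A [deb_params()] object.
#' @return A named list with `juvenile_biomass`, `adult_biomass`,
#'   `total_biomass`, `maturation_rate_biomass`, `reproduction_rate_biomass`,
#'   `asymptotic_size` and `a_j`.
#' @export
population_outputs <- function(b_tilde, lh, p) {
  juv <- b_tilde * lh$SB_juv
  ad <- b_tilde * lh$SB_adult
  list(juvenile_biomass = juv, adult_biomass = ad,
       total_biomass = juv + ad,
       maturation_rate_biomass =
         if (is.na(lh$a_j)) 0 else b_tilde * lh$F_aj * p$s_j,
       reproduction_rate_biomass = b_tilde * p$s_b,
       asymptotic_size = lh$s_end, a_j = lh$a_j)
}

#' @export
print.deb_equilibrium <- function(x, ...) {
  if (x$extinct) {
    cat(sprintf("Extinct equilibrium: consumer not viable (R0(Rmax) <= 1); resource at Rmax = %g mg/L\n",
                x$params$Rmax))
    return(invisible(x))
  }
  cat("Consumer-resource equilibrium\n")
  cat(sprintf("  resource density R~  : %.6g mg/L\n", x$R_tilde))
  cat(sprintf("  population birth rate: %.6g /day\n", x$b_tilde))
  cat(sprintf("  biomass (juv/adult)  : %.6g / %.6g g\n",
              x$juvenile_biomass, x$adult_biomass))
  cat(sprintf("  fluxes (matur/repro) : %.6g / %.6g g/day\n",
              x$maturation_rate_biomass, x$reproduction_rate_biomass))
  cat(sprintf("  asymptotic size      : %.6g g (age at maturation %.4g d)\n",
              x$asymptotic_size, x$a_j))
  invisible(x)
}

#' @export
summary.deb_equilibrium <- function(object, ...) {
  print(object)
  if (!object$extinct) {
    lh <- object$trajectory
    cat(sprintf("  R0 residual          : %.3g\n", lh$R0 - 1))
    cat(sprintf("  resource balance     : %.3g mg/(L day)\n",
                object$resource_residual))
    cat(sprintf("  MRD at asymptotic s  : %.6g mg/L\n",
                maintenance_resource_density(object$asymptotic_size,
                                             object$params)))
  }
  invisible(object)
}

#' @export
coef.deb_equilibrium <- function(object, ...) {
  c(R_tilde = object$R_tilde, b_tilde = object$b_tilde,
    juvenile_biomass = object$juvenile_biomass,
    adult_biomass = object$adult_biomass,
    total_biomass = object$total_biomass,
    maturation_rate_biomass = object$maturation_rate_biomass,
    reproduction_rate_biomass = object$reproduction_rate_biomass,
    asymptotic_size = object$asymptotic_size)
}

#' Equilibrium (and cycle) sweep over one model parameter
#'
#' Solves the ecological equilibrium along a grid of one parameter,
#' warm-starting each root bracket from the neighbouring solution, and
#' optionally classifies the stability of each point by perturbing the
#' equilibrium in a cohort (EBT) simulation and testing for sustained
#' resource oscillations (see [detect_cycles()]). When cycles are present
#' the min/max envelopes of resource and stage biomasses over the attractor
#' are recorded.
#'
#' @param param Name of the parameter to sweep (a field of [deb_params()]).
#' @param grid Strictly monotone numeric grid of parameter values.
#' @param p Baseline [deb_params()].
#' @param n A [numerics_config()].
#' @param with_cycles If `TRUE`, run the EBT from the (slightly perturbed)
#'   equilibrium state at each grid point and flag cycles.
#' @param t_max,transient Simulated days and discarded transient for the
#'   cycle test (only used when `with_cycles = TRUE`).
#' @return A data frame of class `deb_sweep` with one row per grid point:
#'   equilibrium fields plus, if requested, `cyclic`, `amplitude`, `period`
#'   and envelope columns.
#' @examples
#' \donttest{
#' sw <- ecological_sweep("Q", seq(0.9, 1.1, by = 0.1), deb_params())
#' sw
#' }
#' @export
ecological_sweep <- function(param, grid, p, n = numerics_config(),
                             with_cycles = FALSE,
                             t_max = 30000, transient = 20000) {
  stopifnot(param %in% names(p), is.numeric(grid), length(grid) >= 1)
  if (length(grid) > 1 && !all(diff(grid) > 0) && !all(diff(grid) < 0))
    stop("grid must be strictly monotone")
  rows <- vector("list", length(grid))
  bracket <- NULL
  for (i in seq_along(grid)) {
    pi_ <- do.call(update_params, c(list(p), stats::setNames(list(grid[i]), param)))
    eq <- solve_equilibrium(pi_, n, bracket = bracket)
    if (!eq$extinct)
      bracket <- c(eq$R_tilde * 0.5, min(pi_$Rmax, eq$R_tilde * 2))
    row <- data.frame(param = grid[i], t(coef(eq)), extinct = eq$extinct)
    if (with_cycles && !eq$extinct) {
      ts <- ebt_simulate(pi_, t_max = t_max, init = ebt_init_equilibrium(eq),
                         perturb = 0.05)
      cyc <- detect_cycles(ts, transient = transient)
      row$cyclic <- cyc$cyclic
      row$amplitude <- cyc$amplitude
      row$period <- cyc$period
      row$R_min <- cyc$envelopes["resource", "min"]
      row$R_max <- cyc$envelopes["resource", "max"]
      row$juv_min <- cyc$envelopes["juvenile_biomass", "min"]
      row$juv_max <- cyc$envelopes["juvenile_biomass", "max"]
      row$adult_min <- cyc$envelopes["adult_biomass", "min"]
      row$adult_max <- cyc$envelopes["adult_biomass", "max"]
    } else if (with_cycles) {
      row[c("cyclic", "amplitude", "period", "R_min", "R_max",
            "juv_min", "juv_max", "adult_min", "adult_max")] <-
        c(FALSE, 0, NA, rep(NA, 6))
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  class(out) <- c("deb_sweep", "data.frame")
  attr(out, "swept") <- param
  out
}
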