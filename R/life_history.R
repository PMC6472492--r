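#' Integrate an individual life history at fixed resource density
#'
#' Solves the individual-level ODE system of the model at a constant resource
#' density `R`: growth in body mass, survivorship, cumulative (survival-
#' weighted) reproduction and cumulative ingestion as functions of age,
#'
#' \deqn{ds/da = g(R,s), \quad dF/da = -\mu(R,s)F, \quad
#'       dB/da = b(R,s)F, \quad d\Theta/da = I(R,s)F,}
#'
#' starting from `s(0) = s_b`, `F(0) = 1`. Integration stops when
#' survivorship falls below `n$survival_cutoff` (or at `n$max_age`); the age
#' at maturation is located as an exact root of `s - s_j`, so that the
#' stage-specific mortality switch happens at the precise age. Three further
#' bookkeeping integrals (survival-weighted body mass, growth flux and
#' mortality biomass loss) are accumulated for the stage-structured
#' equilibrium outputs.
#'
#' The terminal value of `B` is the expected lifetime reproductive success
#' R0, the quantity whose unit value defines the ecological equilibrium and
#' whose response to a trait change defines invasion fitness.
#'
#' @param R Resource density (mg/L), held constant over the life.
#' @param p A [deb_params()] object.
#' @param n A [numerics_config()] object.
#' @param n_grid Number of output ages per life stage (the integrator's
#'   internal step control is independent of this).
#' @param at Optional extra ages (days) to include in the output grid.
#' @return An object of class `deb_life_history` with elements `a`, `s`, `F`,
#'   `B`, `Theta` (trajectory vectors), `a_j` (age at maturation, `NA` if the
#'   individual never matures), `F_aj`, `s_end`, `R0`, `Theta_inf`, the stage
#'   biomass integrals `SB_juv` and `SB_adult`, the lifetime growth and
#'   mortality biomass fluxes `GI` and `MU`, and the inputs.
#' @examples
#' lh <- life_history(3, deb_params())
#' lh$R0
#' head(as.data.frame(lh))
#' @export
life_history <- function(R, p, n = numerics_config(), n_grid = 150L,
                         at = NULL) {
  stopifnot(inherits(p, "deb_params"))
  stopifnot(inherits(n, "deb_numerics"))
  if (length(R) != 1L || !is.finite(R) || R < 0)
    stop("R must be a single nonnegative resource density")

  om_b <- biomass_production(R, p$s_b, p)
  if (om_b <= 0) return(lh_stalled_at_birth(R, p, n))

  cutoff <- n$survival_cutoff

  rhs <- function(a, y, stage_mu) {
    s <- min(y[1], p$s_m)
    F_ <- y[2]
    I <- p$M * (s / p$s_rI)^p$Q * R / (R + p$H)
    om <- p$sigma * I - p$T * (s / p$s_rT)^p$P
    op <- max(om, 0)
    kap <- allocation_fraction(s, p)
    g <- kap * op
    b <- (1 - kap) * op / p$s_b
    mu <- p$mu_c + stage_mu + max(-om, 0) / s
    list(c(g, -mu * F_, b * F_, I * F_, s * F_, g * F_, mu * s * F_))
  }

  age_grid <- function(from, to, k) {
    if (to <= from) return(c(from, to))
    g <- c(from, from + 10^seq(log10(min(0.1, (to - from) / 2)),
                               log10(to - from), length.out = k))
    if (!is.null(at)) g <- c(g, at[at > from & at < to])
    unique(sort(g))
  }

  y0 <- c(s = p$s_b, F = 1, B = 0, Theta = 0, SB = 0, GI = 0, MU = 0)
  t1 <- age_grid(0, n$max_age, n_grid)
  ph1 <- deSolve::lsodar(
    y = y0, times = t1, func = rhs, parms = p$mu_j,
    rtol = n$rel_tol, atol = n$abs_tol,
    rootfunc = function(a, y, stage_mu) c(y[1] - p$s_j, y[2] - cutoff))
  if (attr(ph1, "istate")[1] < 0)
    stop("life-history integrator failed in the juvenile phase at R = ", R,
         "; last state: ", paste(signif(ph1[nrow(ph1), ], 6), collapse = ", "))
  m1 <- unclass(ph1)
  end1 <- m1[nrow(m1), ]
  matured <- end1[["s"]] >= p$s_j * (1 - 1e-8) && end1[["F"]] > cutoff

  if (matured) {
    a_j <- end1[["time"]]
    F_aj <- end1[["F"]]
    SB_juv <- end1[["SB"]]
    y1 <- end1[-1]
    y1[["s"]] <- p$s_j
    t2 <- age_grid(a_j, n$max_age, n_grid)
    ph2 <- deSolve::lsodar(
      y = y1, times = t2, func = rhs, parms = p$mu_a,
      rtol = n$rel_tol, atol = n$abs_tol,
      rootfunc = function(a, y, stage_mu) y[2] - cutoff)
    if (attr(ph2, "istate")[1] < 0)
      stop("life-history integrator failed in the adult phase at R = ", R,
           "; last state: ",
           paste(signif(ph2[nrow(ph2), ], 6), collapse = ", "))
    m2 <- unclass(ph2)
    m <- rbind(m1, m2[-1, , drop = FALSE])
    endf <- m2[nrow(m2), ]
  } else {
    a_j <- NA_real_
    F_aj <- NA_real_
    SB_juv <- end1[["SB"]]
    m <- m1
    endf <- end1
  }

  structure(list(
    a = m[, "time"], s = pmin(m[, "s"], p$s_m), F = m[, "F"],
    B = m[, "B"], Theta = m[, "Theta"],
    a_j = a_j, F_aj = F_aj,
    s_end = min(endf[["s"]], p$s_m),
    R0 = endf[["B"]], Theta_inf = endf[["Theta"]],
    SB_juv = SB_juv, SB_adult = endf[["SB"]] - SB_juv,
    GI = endf[["GI"]], MU = endf[["MU"]],
    R = R, params = p, numerics = n), class = "deb_life_history")
}

# Closed-form degenerate life history when the resource does not even cover
# maintenance at the size at birth: no growth, no reproduction, constant
# hazard with starvation term.
lh_stalled_at_birth <- function(R, p, n) {
  om <- biomass_production(R, p$s_b, p)
  mu <- p$mu_c + p$mu_j - om / p$s_b
  a_end <- min(n$max_age, -log(n$survival_cutoff) / mu)
  a <- seq(0, a_end, length.out = 50L)
  F_ <- exp(-mu * a)
  I <- ingestion_rate(R, p$s_b, p)
  structure(list(
    a = a, s = rep(p$s_b, length(a)), F = F_,
    B = rep(0, length(a)), Theta = I * (1 - F_) / mu,
    a_j = NA_real_, F_aj = NA_real_,
    s_end = p$s_b, R0 = 0,
    Theta_inf = I * (1 - F_[length(F_)]) / mu,
    SB_juv = p$s_b * (1 - F_[length(F_)]) / mu, SB_adult = 0,
    GI = 0, MU = p$s_b * (1 - F_[length(F_)]),
    R = R, params = p, numerics = n), class = "deb_life_history")
}

#' @export
print.deb_life_history <- function(x, ...) {
  cat(sprintf("Life history at R = %g mg/L\n", x$R))
  cat(sprintf("  R0 = %.6g, lifetime ingestion = %.6g g\n",
              x$R0, x$Theta_inf))
  if (is.na(x$a_j)) cat("  never matures; ")
  else cat(sprintf("  matures at age %.4g d (survival %.3g); ",
                   x$a_j, x$F_aj))
  cat(sprintf("terminal size %.6g g at age %.4g d\n",
              x$s_end, x$a[length(x$a)]))
  invisible(x)
}

#' @export
as.data.frame.deb_life_history <- function(x, ...) {
  data.frame(age = x$a, size = x$s, survivorship = x$F,
             cum_fecundity = x$B, cum_ingestion = x$Theta)
}

#' Expected lifetime reproductive success at fixed resource density
#'
#' R0, the expected number of offspring produced over a lifetime lived at
#' constant resource density `R`. Strictly increasing in `R` wherever it is
#' positive and finite; `R0(R) = 1` defines the ecological equilibrium and
#' `R0 > 1` for a rare mutant in a resident environment means invasion.
#'
#' @inheritParams life_history
#' @return A single number.
#' @examples
#' lifetime_R0(3, deb_params())
#' @export
lifetime_R0 <- function(R, p, n = numerics_config()) {
  life_history(R, p, n)$R0
}
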