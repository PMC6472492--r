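#' Individual-level rate functions
#'
#' The pure rate functions of the net-production DEB model: every population
#' and evolutionary computation in the package composes these. All are
#' vectorized over `R` and `s` (recycled).
#'
#' @param R Resource density (mg/L), nonnegative.
#' @param s Body mass (g), positive.
#' @param p A [deb_params()] object.
#' @name rates
NULL

check_Rs <- function(R, s) {
  if (any(R < 0)) stop("resource density R must be nonnegative")
  if (any(s <= 0)) stop("body mass s must be positive")
}

#' @describeIn rates Mass intake `M (s/s_rI)^Q R/(R+H)` (g/day): a Holling
#'   type-II functional response times an allometric maximum ingestion rate.
#' @export
ingestion_rate <- function(R, s, p) {
  check_Rs(R, s)
  p$M * (s / p$s_rI)^p$Q * R / (R + p$H)
}

#' @describeIn rates Net biomass production
#'   `Omega = sigma I(R,s) - T (s/s_rT)^P` (g/day): assimilated intake minus
#'   maintenance. Negative values signal starvation.
#' @export
biomass_production <- function(R, s, p) {
  check_Rs(R, s)
  p$sigma * ingestion_rate(R, s, p) - p$T * (s / p$s_rT)^p$P
}

#' @describeIn rates Positive part `max(Omega, 0)`: the flux available for
#'   growth and reproduction.
#' @export
production_pos <- function(R, s, p) pmax(biomass_production(R, s, p), 0)

#' @describeIn rates Negative part `min(Omega, 0)`: the starvation deficit.
#' @export
production_neg <- function(R, s, p) pmin(biomass_production(R, s, p), 0)

#' @describeIn rates Fraction `kappa(s)` of net production allocated to
#'   somatic growth: 1 for juveniles, a cubic smoothstep from 1 at the
#'   maturation size `s_j` to 0 at the maximum size `s_m` for adults.
#'   Continuously differentiable across both stage boundaries. Masses above
#'   `s_m` (floating-point overshoot in integrators) clamp to 0; masses
#'   below `s_b` are a domain error.
#' @export
allocation_fraction <- function(s, p) {
  if (any(s < p$s_b - 1e-12 * p$s_b))
    stop("allocation_fraction: body mass below size at birth")
  L <- pmin(pmax((s - p$s_j) / (p$s_m - p$s_j), 0), 1)
  1 - 3 * L^2 + 2 * L^3
}

#' @describeIn rates Somatic growth rate `kappa(s) max(Omega, 0)` (g/day);
#'   zero under starvation and at the maximum size.
#' @export
growth_rate <- function(R, s, p) {
  allocation_fraction(s, p) * production_pos(R, s, p)
}

#' @describeIn rates Fecundity `(1 - kappa(s)) max(Omega, 0) / s_b`
#'   (offspring/day); zero for juveniles and under starvation.
#' @export
fecundity_rate <- function(R, s, p) {
  (1 - allocation_fraction(s, p)) * production_pos(R, s, p) / p$s_b
}

#' @describeIn rates Per-capita mortality (per day): background plus
#'   stage-specific mortality plus the mass-specific starvation deficit
#'   `|min(Omega, 0)| / s`.
#' @export
mortality_rate <- function(R, s, p) {
  check_Rs(R, s)
  stage <- ifelse(s < p$s_j, p$mu_j, p$mu_a)
  p$mu_c + stage - production_neg(R, s, p) / s
}

#' Maintenance resource density
#'
#' The resource density at which an individual of mass `s` exactly covers its
#' maintenance requirements (`Omega = 0`); lower values mean a superior
#' competitor. Closed form `H theta / (sigma M - theta)` with
#' `theta = T (s/s_rT)^P / (s/s_rI)^Q`. When maintenance exceeds the
#' saturated assimilation rate (`theta >= sigma M`) there is no finite root
#' and `Inf` is returned, so parameter sweeps over extreme exponents do not
#' abort. For `Q = P` (and equal reference masses) the MRD is independent of
#' body mass: competition is then size-symmetric.
#'
#' @inheritParams rates
#' @return Resource density (mg/L), possibly `Inf`.
#' @examples
#' maintenance_resource_density(1, deb_params())  # 0.75 mg/L, any s when Q = P
#' @export
maintenance_resource_density <- function(s, p) {
  if (any(s <= 0)) stop("body mass s must be positive")
  theta <- p$T * (s / p$s_rT)^p$P / (s / p$s_rI)^p$Q
  out <- ifelse(theta >= p$sigma * p$M, Inf,
                p$H * theta / (p$sigma * p$M - theta))
  out
}

#' @describeIn rates Semi-chemostat resource renewal `delta (Rmax - R)`
#'   (mg L^-1 day^-1).
#' @export
resource_growth_rate <- function(R, p) {
  if (any(R < 0)) stop("resource density R must be nonnegative")
  p$delta * (p$Rmax - R)
}
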