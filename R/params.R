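#' Model parameters for the size-structured consumer-resource model
#'
#' Constructs and validates the full parameter set of the dynamic energy
#' budget (DEB) consumer-resource model. Defaults are the standard
#' parameterization of the model: a consumer born at 0.1 g maturing at 1 g
#' with maximum size 10 g feeding on a semi-chemostat resource.
#'
#' Maximum ingestion is `M * (s / s_rI)^Q * R / (R + H)` and maintenance is
#' `T * (s / s_rT)^P`, so `Q` and `P` are the body-mass scaling exponents of
#' ingestion and maintenance and `s_r` is the reference mass at which the two
#' power laws rotate. By default `s_rI = s_rT = s_r`, giving the standard
#' juvenile-adult trade-off when `s_r` equals the maturation size.
#'
#' @param Rmax Maximum resource density (mg/L).
#' @param delta Resource renewal rate (per day).
#' @param Q Scaling exponent of maximum ingestion (dimensionless).
#' @param P Scaling exponent of maintenance (dimensionless).
#' @param M Maximum ingestion rate of an individual of reference mass (g/day).
#' @param T Maintenance rate of an individual of reference mass (g/day).
#' @param mu_c Background mortality (per day).
#' @param mu_j Additional juvenile mortality (per day).
#' @param mu_a Additional adult mortality (per day).
#' @param sigma Assimilation efficiency (dimensionless, in (0, 1]).
#' @param H Half-saturation resource density of the Holling type-II
#'   functional response (mg/L).
#' @param s_b Body mass at birth (g).
#' @param s_j Body mass at maturation (g).
#' @param s_m Maximum body mass (g).
#' @param s_r Reference body mass (g).
#' @param s_rI,s_rT Optional separate reference masses for ingestion and
#'   maintenance (g); default to `s_r`.
#' @param chi Conversion constant linking total consumer ingestion (g/day) to
#'   resource depletion (mg L^-1 day^-1). The equilibrium resource density,
#'   R0 and all evolutionary outputs are independent of `chi`; it rescales
#'   only the population birth rate and absolute biomasses.
#'
#' @return An object of class `deb_params` (a named list).
#' @examples
#' p <- deb_params()
#' p
#' deb_params(Q = 1.2, s_b = 0.05)
#' @export
deb_params <- function(Rmax = 30, delta = 0.01, Q = 1, P = 1,
                       M = 0.1, T = 0.01,
                       mu_c = 0.0015, mu_j = 0, mu_a = 0,
                       sigma = 0.5, H = 3,
                       s_b = 0.1, s_j = 1, s_m = 10,
                       s_r = 1, s_rI = s_r, s_rT = s_r,
                       chi = 1) {
  p <- list(Rmax = Rmax, delta = delta, Q = Q, P = P, M = M, T = T,
            mu_c = mu_c, mu_j = mu_j, mu_a = mu_a, sigma = sigma, H = H,
            s_b = s_b, s_j = s_j, s_m = s_m, s_r = s_r,
            s_rI = s_rI, s_rT = s_rT, chi = chi)
  p <- lapply(p, as.numeric)
  class(p) <- "deb_params"
  validate_deb_params(p)
  p
}

validate_deb_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number")
  if (!(p$s_b > 0 && p$s_b < p$s_j && p$s_j < p$s_m))
    stop("size parameters must satisfy 0 < s_b < s_j < s_m")
  if (p$sigma <= 0 || p$sigma > 1) stop("sigma must lie in (0, 1]")
  for (nm in c("Rmax", "delta", "M", "T", "H", "s_r", "s_rI", "s_rT", "chi"))
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be positive")
  for (nm in c("mu_c", "mu_j", "mu_a"))
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be nonnegative")
  if (p$sigma * p$M <= p$T)
    stop("sigma * M must exceed T: the reference individual can never ",
         "cover maintenance at any resource density")
  if (p$s_r < p$s_b || p$s_r > p$s_m)
    warning("s_r outside [s_b, s_m]: the juvenile-adult trade-off in the ",
            "scaling exponents degenerates and selection on Q and P can ",
            "become directional")
  invisible(p)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("DEB consumer-resource model parameters\n")
  cat(sprintf("  resource : Rmax = %g mg/L, delta = %g /day, H = %g mg/L\n",
              x$Rmax, x$delta, x$H))
  cat(sprintf("  energetics: M = %g g/day, T = %g g/day, sigma = %g, Q = %g, P = %g\n",
              x$M, x$T, x$sigma, x$Q, x$P))
  cat(sprintf("  sizes    : s_b = %g, s_j = %g, s_m = %g, s_r = %g g",
              x$s_b, x$s_j, x$s_m, x$s_r))
  if (x$s_rI != x$s_r || x$s_rT != x$s_r)
    cat(sprintf(" (s_rI = %g, s_rT = %g)", x$s_rI, x$s_rT))
  cat("\n")
  cat(sprintf("  mortality: mu_c = %g, mu_j = %g, mu_a = %g /day\n",
              x$mu_c, x$mu_j, x$mu_a))
  if (x$chi != 1) cat(sprintf("  chi = %g\n", x$chi))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and re-validated.
#'
#' @param p A [deb_params()] object.
#' @param ... Named scalar replacements, e.g. `Q = 1.2`.
#' @return A `deb_params` object.
#' @examples
#' p2 <- update_params(deb_params(), Q = 1.2, mu_j = 0.001)
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "deb_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("all replacements must be named")
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  # a bare s_r replacement drags the per-process reference masses along,
  # unless those are replaced explicitly as well
  if ("s_r" %in% names(repl)) {
    if (!("s_rI" %in% names(repl)) && p$s_rI == p$s_r)
      repl$s_rI <- repl$s_r
    if (!("s_rT" %in% names(repl)) && p$s_rT == p$s_r)
      repl$s_rT <- repl$s_r
  }
  p[names(repl)] <- lapply(repl, as.numeric)
  validate_deb_params(p)
  p
}

#' Numerical settings for life-history integration and root solving
#'
#' @param rel_tol,abs_tol Relative and absolute tolerances of the
#'   life-history ODE integrator.
#' @param survival_cutoff Integration of an individual life history stops
#'   once survivorship drops below this value; the neglected tail carries a
#'   vanishing share of lifetime reproduction at the default mortality rates.
#' @param max_age Hard cap on individual age (days).
#' @param root_tol Tolerance of scalar root solves (equilibrium resource
#'   density, singular strategies).
#' @param fd_step Finite-difference step (in exponent units) for selection
#'   gradients.
#' @return An object of class `deb_numerics`.
#' @examples
#' numerics_config(rel_tol = 1e-10)
#' @export
numerics_config <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                            survival_cutoff = 1e-9, max_age = 1e5,
                            root_tol = 1e-10, fd_step = 1e-4) {
  n <- list(rel_tol = rel_tol, abs_tol = abs_tol,
            survival_cutoff = survival_cutoff, max_age = max_age,
            root_tol = root_tol, fd_step = fd_step)
  if (any(!vapply(n, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                  logical(1))))
    stop("all numerical settings must be positive scalars")
  if (n$survival_cutoff >= 1) stop("survival_cutoff must be < 1")
  class(n) <- "deb_numerics"
  n
}

#' @export
print.deb_numerics <- function(x, ...) {
  cat("Numerical settings:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}
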