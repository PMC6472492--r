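#' Options for the cohort (EBT) simulator
#'
#' Numerical settings of the Escalator Boxcar Train integration. Newborns
#' produced within one closure interval `dt_cohort` are pooled and inserted
#' as one cohort at the size at birth; the coupled cohort-resource system is
#' advanced with classical RK4 steps of length `dt` between closures. Old
#' cohorts whose masses have converged (all individuals near the asymptotic
#' size) are merged to keep the cohort count bounded.
#'
#' @param dt RK4 time step (days).
#' @param dt_cohort Boundary-cohort closure interval (days).
#' @param record_every Output sampling interval (days).
#' @param extinct_frac Cohorts whose number falls below this fraction of the
#'   initial total number are removed.
#' @param max_cohorts Hard cap on the live cohort count.
#' @param merge_tol Relative mass difference below which two old cohorts of
#'   the same lineage are merged (number-weighted).
#' @param merge_min_age Minimum cohort age (days) before merging is allowed.
#' @return A list of class `ebt_options`.
#' @export
ebt_options <- function(dt = 0.5, dt_cohort = 2.5, record_every = 2.5,
                        extinct_frac = 1e-12, max_cohorts = 10000,
                        merge_tol = 2e-3, merge_min_age = 150) {
  o <- list(dt = dt, dt_cohort = dt_cohort, record_every = record_every,
            extinct_frac = extinct_frac, max_cohorts = max_cohorts,
            merge_tol = merge_tol, merge_min_age = merge_min_age)
  stopifnot(o$dt > 0, o$dt_cohort >= o$dt, o$record_every > 0,
            o$extinct_frac >= 0, o$max_cohorts > 10, o$merge_tol >= 0)
  class(o) <- "ebt_options"
  o
}

params_vec <- function(p) unlist(p[c("Rmax", "delta", "Q", "P", "M", "T",
                                     "mu_c", "mu_j", "mu_a", "sigma", "H",
                                     "s_b", "s_j", "s_m", "s_rI", "s_rT",
                                     "chi")])

# cohort-extinction cutoffs, relative to each lineage's own initial numbers
# so that a rare mutant lineage is not eroded by the resident-scale cutoff
ebt_extinct_abs <- function(coh, frac) {
  tot <- vapply(0:1, function(l) sum(coh[coh[, 4] == l, 1]), numeric(1))
  if (tot[2] == 0) tot[2] <- tot[1]
  if (tot[1] == 0) tot[1] <- tot[2]
  frac * tot
}

#' Simulate the full size-structured population through time
#'
#' Escalator Boxcar Train simulation of the consumer size distribution
#' coupled to the semi-chemostat resource. Each cohort of similar-sized
#' individuals is advanced by its mass growth and mortality rates (including
#' starvation mortality when the resource falls below the cohort's
#' maintenance resource density), reproduction from all cohorts is collected
#' into a boundary cohort inserted at the size at birth, and the resource is
#' depleted by total population ingestion.
#'
#' @param p Resident [deb_params()].
#' @param t_max Simulated time (days).
#' @param init Initial state: a list with `R` (resource density) and
#'   `cohorts` (matrix with columns density, mass, age, lineage), e.g. from
#'   [ebt_init_equilibrium()] or the `final_state` of a previous run.
#'   Default: resource at `Rmax` and a single newborn cohort of unit density.
#' @param mutant_p Optional second [deb_params()] for the mutant lineage
#'   (lineage 1 in `init$cohorts`); defaults to the resident parameters.
#' @param options An [ebt_options()] list.
#' @param perturb Relative perturbation applied to all initial cohort
#'   numbers (used to test stability of an equilibrium state).
#' @return An object of class `ebt_sim`: a list with `ts` (data frame of
#'   time, resource, stage biomasses by lineage, birth rates, cohort count),
#'   `final_state`, `params` and `options`.
#' @examples
#' \donttest{
#' sim <- ebt_simulate(deb_params(), t_max = 2000)
#' plot(sim)
#' }
#' @export
ebt_simulate <- function(p, t_max, init = NULL, mutant_p = NULL,
                         options = ebt_options(), perturb = 0) {
  stopifnot(inherits(p, "deb_params"), t_max > 0)
  if (is.null(init))
    init <- list(R = p$Rmax,
                 cohorts = matrix(c(1, p$s_b, 0, 0), nrow = 1))
  coh <- as.matrix(init$cohorts)
  if (ncol(coh) == 2) coh <- cbind(coh, 0, 0)
  if (ncol(coh) == 3) coh <- cbind(coh, 0)
  stopifnot(ncol(coh) == 4, all(coh[, 1] >= 0), all(coh[, 2] > 0))
  if (perturb != 0) coh[, 1] <- coh[, 1] * (1 + perturb)
  t0 <- if (!is.null(init$time)) init$time else 0
  res <- .ebt_run(params_vec(p),
                  if (is.null(mutant_p)) numeric(0) else params_vec(mutant_p),
                  coh, init$R, t0, t0 + t_max,
                  options$dt, options$dt_cohort, options$record_every,
                  ebt_extinct_abs(coh, options$extinct_frac),
                  as.integer(options$max_cohorts),
                  options$merge_tol, options$merge_min_age)
  ts <- data.frame(time = res$time, resource = res$resource,
                   juvenile_biomass = res$juv_biomass,
                   adult_biomass = res$adult_biomass,
                   total_biomass = res$juv_biomass + res$adult_biomass,
                   juvenile_biomass_mutant = res$juv_biomass_mutant,
                   adult_biomass_mutant = res$adult_biomass_mutant,
                   birth_rate = res$birth_rate,
                   birth_rate_mutant = res$birth_rate_mutant,
                   n_cohorts = res$n_cohorts)
  structure(list(ts = ts,
                 final_state = list(R = res$final_R,
                                    cohorts = res$final_cohorts,
                                    time = t0 + t_max),
                 params = p, mutant_params = mutant_p, options = options),
            class = "ebt_sim")
}

#' Initial EBT state approximating a solved equilibrium
#'
#' Discretizes the stationary age distribution `b_tilde * F(a)` of a solved
#' equilibrium into cohorts of equal age width, so that an EBT run can be
#' started on (or near) the equilibrium.
#'
#' @param eq A [solve_equilibrium()] result.
#' @param da Age width of the initial cohorts (days).
#' @return A list with `R` and `cohorts` suitable for [ebt_simulate()].
#' @export
ebt_init_equilibrium <- function(eq, da = 10) {
  stopifnot(inherits(eq, "deb_equilibrium"), !eq$extinct)
  lh <- eq$trajectory
  ages <- seq(0, max(lh$a), by = da)
  Fa <- stats::approx(lh$a, lh$F, ages, rule = 2)$y
  sa <- stats::approx(lh$a, lh$s, ages, rule = 2)$y
  keep <- Fa * eq$b_tilde * da > 0
  list(R = eq$R_tilde,
       cohorts = cbind(density = eq$b_tilde * Fa[keep] * da,
                       mass = sa[keep], age = ages[keep], lineage = 0))
}

#' @export
print.ebt_sim <- function(x, ...) {
  ts <- x$ts
  cat(sprintf("EBT simulation: %g days, %d records, final cohort count %d\n",
              max(ts$time) - min(ts$time), nrow(ts),
              nrow(x$final_state$cohorts)))
  cat(sprintf("  final resource %.5g mg/L, total biomass %.5g g\n",
              ts$resource[nrow(ts)], ts$total_biomass[nrow(ts)]))
  invisible(x)
}

#' @export
plot.ebt_sim <- function(x, ...) {
  ts <- x$ts
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(ts$time, ts$resource, type = "l", xlab = "time (d)",
                 ylab = "resource (mg/L)", ...)
  graphics::matplot(ts$time, cbind(ts$juvenile_biomass, ts$adult_biomass),
                    type = "l", lty = 1, col = c("grey50", "black"),
                    xlab = "time (d)", ylab = "biomass (g)")
  graphics::legend("topright", c("juvenile", "adult"), lty = 1,
                   col = c("grey50", "black"), bty = "n")
  invisible(x)
}

#' Classify an EBT run as stable or cyclic
#'
#' Discards a transient, then flags sustained population cycles when the
#' relative peak-to-trough amplitude of the resource exceeds a threshold.
#' The cycle period is estimated from the mean spacing of resource peaks
#' (local maxima above the mid-range), and min/max envelopes of the output
#' series over the retained window are reported.
#'
#' @param sim An [ebt_simulate()] result (or its `ts` data frame).
#' @param transient Days discarded from the start of the series.
#' @param threshold Relative resource amplitude above which the run is
#'   classified as cyclic.
#' @return A list: `cyclic`, `amplitude`, `period` (`NA` when stable) and
#'   `envelopes` (matrix with rows resource/juvenile/adult/total biomass).
#' @export
detect_cycles <- function(sim, transient = 0, threshold = 0.01) {
  ts <- if (inherits(sim, "ebt_sim")) sim$ts else as.data.frame(sim)
  ts <- ts[ts$time >= min(ts$time) + transient, , drop = FALSE]
  if (nrow(ts) < 5) stop("too few records after transient removal")
  R <- ts$resource
  amp <- (max(R) - min(R)) / mean(R)
  cyclic <- amp > threshold
  period <- NA_real_
  if (cyclic) {
    mid <- (max(R) + min(R)) / 2
    k <- 2:(length(R) - 1)
    pk <- k[R[k] >= R[k - 1] & R[k] > R[k + 1] & R[k] > mid]
    # collapse plateau/adjacent detections within a few samples
    if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 3)]
    if (length(pk) > 1) period <- mean(diff(ts$time[pk]))
  }
  series <- c("resource", "juvenile_biomass", "adult_biomass",
              "total_biomass")
  env <- t(vapply(series, function(v) range(ts[[v]]), numeric(2)))
  colnames(env) <- c("min", "max")
  list(cyclic = cyclic, amplitude = amp, period = period, envelopes = env)
}

#' Fate of a rare mutant introduced into the resident attractor
#'
#' Runs the resident population onto its attractor (equilibrium or cycle),
#' introduces a rare mutant lineage differing in one trait, and follows the
#' two-lineage EBT (lineages share the resource). For a cyclic resident the
#' mutant is introduced at a resource maximum of the cycle by default.
#' The outcome is read off the long-run trend of the mutant biomass share.
#'
#' @param p Resident [deb_params()].
#' @param trait Name of the mutated trait (typically `"Q"` or `"P"`).
#' @param value Mutant trait value.
#' @param t_attract Days of resident-only simulation before introduction.
#' @param t_invade Days of two-lineage simulation after introduction.
#' @param mutant_frac Initial mutant biomass as a fraction of resident
#'   biomass.
#' @param phase Introduction phase for cyclic residents: `"peak"` introduces
#'   at a resource maximum, `"end"` at the end of the spin-up run.
#' @param options An [ebt_options()] list.
#' @param n A [numerics_config()] (used for the equilibrium start).
#' @return A list of class `ebt_invasion`: `outcome`
#'   (`"invades"`, `"fails"` or `"neutral"`), the log growth factor of the
#'   mutant biomass share, the share series, and the underlying simulation.
#' @export
invasion_experiment <- function(p, trait, value,
                                t_attract = 15000, t_invade = 15000,
                                mutant_frac = 1e-6, phase = c("peak", "end"),
                                options = ebt_options(),
                                n = numerics_config()) {
  phase <- match.arg(phase)
  mutant_p <- do.call(update_params,
                      c(list(p), stats::setNames(list(value), trait)))
  eq <- solve_equilibrium(p, n)
  spin <- ebt_simulate(p, t_max = t_attract,
                       init = ebt_init_equilibrium(eq),
                       options = options, perturb = 0.05)
  state <- spin$final_state
  cyc <- detect_cycles(spin, transient = t_attract / 2)
  if (cyc$cyclic && phase == "peak" && !is.na(cyc$period)) {
    # advance to the next resource maximum before introducing the mutant
    look <- ebt_simulate(p, t_max = 1.5 * cyc$period, init = state,
                         options = options)
    i_pk <- which.max(look$ts$resource)
    t_pk <- look$ts$time[i_pk] - state$time
    if (t_pk > options$dt_cohort)
      state <- ebt_simulate(p, t_max = t_pk, init = state,
                            options = options)$final_state
  }
  res_biomass <- sum(state$cohorts[, "density"] * state$cohorts[, "mass"])
  seed <- mutant_frac * res_biomass / p$s_b
  state$cohorts <- rbind(state$cohorts,
                         c(seed, mutant_p$s_b, 0, 1))
  run <- ebt_simulate(p, t_max = t_invade, init = state,
                      mutant_p = mutant_p, options = options)
  ts <- run$ts
  mut <- ts$juvenile_biomass_mutant + ts$adult_biomass_mutant
  tot <- mut + ts$total_biomass
  share <- mut / tot
  # Long-run trend of the mutant share. In a cyclic attractor the share
  # oscillates strongly within each cycle, so the trend is read at matching
  # cycle phases (resource maxima); in a stable environment plain averages
  # over the first and last tenth of the run are compared.
  if (share[length(share)] == 0) {
    return(structure(list(outcome = "fails", log_share_growth = -Inf,
                          share = data.frame(time = ts$time,
                                             mutant_share = share),
                          resident_cyclic = cyc$cyclic, sim = run),
                     class = "ebt_invasion"))
  }
  R <- ts$resource
  k <- 2:(length(R) - 1)
  mid <- (max(R) + min(R)) / 2
  pk <- k[R[k] >= R[k - 1] & R[k] > R[k + 1] & R[k] > mid]
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 3)]
  if (cyc$cyclic && length(pk) >= 3) {
    fit <- stats::lm(log(share[pk]) ~ ts$time[pk])
    growth <- unname(stats::coef(fit)[2]) * (max(ts$time) - min(ts$time))
  } else {
    # windows at 40-50% and 90-100% of the run, both past the initial
    # age-structure transient of the newly seeded lineage
    nr <- nrow(ts)
    k10 <- max(2L, nr %/% 10L)
    w1 <- seq.int(max(1L, (4L * nr) %/% 10L), length.out = k10)
    w2 <- seq.int(nr - k10 + 1L, nr)
    growth <- log(mean(share[w2]) / mean(share[w1]))
  }
  outcome <- if (abs(growth) < log(2)) "neutral"
             else if (growth > 0) "invades" else "fails"
  structure(list(outcome = outcome, log_share_growth = growth,
                 share = data.frame(time = ts$time, mutant_share = share),
                 resident_cyclic = cyc$cyclic, sim = run),
            class = "ebt_invasion")
}

#' @export
print.ebt_invasion <- function(x, ...) {
  cat(sprintf("Mutant invasion experiment: %s (log share growth %.3g; resident %s)\n",
              x$outcome, x$log_share_growth,
              if (x$resident_cyclic) "cyclic" else "stable"))
  invisible(x)
}
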