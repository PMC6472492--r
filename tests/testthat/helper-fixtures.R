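# shared fixtures: all data used by the tests is generated in code

p_default <- deb_params()
n_default <- numerics_config()

# forward-Euler integration of the individual-level ODEs at fixed R;
# independent brute-force oracle for the adaptive life-history integrator
euler_life_history <- function(R, p, targets, dt = 1e-4) {
  s <- p$s_b; F_ <- 1; B <- 0; Theta <- 0
  a <- 0
  fr <- R / (R + p$H)
  out <- matrix(NA_real_, length(targets), 5,
                dimnames = list(NULL, c("age", "s", "F", "B", "Theta")))
  for (k in seq_along(targets)) {
    nstep <- round((targets[k] - a) / dt)
    h <- (targets[k] - a) / nstep
    for (i in seq_len(nstep)) {
      I <- p$M * (s / p$s_rI)^p$Q * fr
      om <- p$sigma * I - p$T * (s / p$s_rT)^p$P
      op <- max(om, 0)
      L <- min(max((s - p$s_j) / (p$s_m - p$s_j), 0), 1)
      kap <- 1 - 3 * L^2 + 2 * L^3
      mu <- p$mu_c + (if (s < p$s_j) p$mu_j else p$mu_a) + max(-om, 0) / s
      B <- B + h * (1 - kap) * op / p$s_b * F_
      Theta <- Theta + h * I * F_
      F_ <- F_ * (1 - h * mu)
      s <- min(s + h * kap * op, p$s_m)
    }
    a <- targets[k]
    out[k, ] <- c(a, s, F_, B, Theta)
  }
  out
}

# synthetic population time series shaped like an ebt_simulate() output
synthetic_ts <- function(time, resource) {
  data.frame(time = time, resource = resource,
             juvenile_biomass = 1 + 0 * time, adult_biomass = 2 + 0 * time,
             total_biomass = 3 + 0 * time)
}
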