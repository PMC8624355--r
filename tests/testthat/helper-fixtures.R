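# Shared fixtures: the magnetite-like parameter sets used across the suite.

const_default <- physical_constants()
med_default <- medium(T = 300, eta = 0.00235)

# reference particle: K = 11 kJ/m^3 at its agglomeration threshold size
p_ref <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)

# anisotropy-scaling pair: same size and MS, K differing by 2x
p_k10 <- particle_spec(d = 20e-9, K = 10e3, MS = 4.8e5)
p_k20 <- particle_spec(d = 20e-9, K = 20e3, MS = 4.8e5)

# numerically evaluated Boltzmann CDF of x = m.n for barrier sigma
boltzmann_cdf <- function(sigma, n_grid = 20001L) {
  x <- seq(-1, 1, length.out = n_grid)
  w <- exp(sigma * x^2)
  cw <- cumsum(w)
  cw <- (cw - cw[1]) / (cw[length(cw)] - cw[1])
  stats::approxfun(x, cw)
}

# slow-sweep dynamic protocol for comparing sLLG at T = 0 with the
# quasistatic solver (100 kHz, 5 ps steps)
slow_protocol <- function(Hmax) {
  field_protocol(Hmax, 1e5, n_cycles = 2, n_steps_per_cycle = 2000000L)
}

# independent scan oracles for the timescale crossing, written directly from
# the defining expressions (own constants, no package internals)
oracle_tau_neel <- function(d, K, T = 300, tau0 = 1e-9) {
  s <- K * (pi / 6) * d^3 / (1.380649e-23 * T)
  sqrt(pi) / 2 * tau0 * exp(s) / sqrt(s)
}
oracle_tau_diff <- function(d, MS, eta = 0.00235, T = 300, tnm = 0) {
  kBT <- 1.380649e-23 * T
  x <- (1.256e-6 * (MS * (pi / 6) * d^3)^2 / (2 * pi * kBT))^(1 / 3)
  x^2 * 6 * pi * eta * (d / 2 + tnm) / kBT
}
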