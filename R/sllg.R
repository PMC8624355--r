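# Finite-temperature dynamic hysteresis: stochastic Landau-Lifshitz-Gilbert
# macrospin ensemble driven by an AC field. The inner time loop is compiled
# (src/sllg.cpp); this file owns parameter bookkeeping, seeding, thermal-field
# calibration, cycle folding and loop/SAR reduction.

# Brown fluctuation-dissipation thermal field (A/m, per component, per step)
.sllg_sigma_h <- function(particle, llg, dt, constants) {
  if (llg$T == 0) return(0)
  V <- magnetic_volume(particle)
  sqrt(2 * llg$alpha * constants$kB * llg$T /
         (constants$mu0^2 * llg$gamma_e * particle$MS * V * dt))
}

.sllg_check_dt <- function(particle, Hmax, dt, llg, constants) {
  hk <- anisotropy_field(particle, constants)
  dt_max <- 1 / (llg$gamma_e * constants$mu0 * (hk + Hmax) * 10)
  if (dt > dt_max) {
    stop("timestep too coarse: dt = ", signif(dt, 3), " s does not resolve ",
         "the precession about H_K + Hmax (need dt <= ", signif(dt_max, 3),
         " s); increase n_steps_per_cycle.", call. = FALSE)
  }
}

# run RNG-dependent code under a local seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Dynamic hysteresis loop from the stochastic LLG macrospin model
#'
#' Integrates, for an ensemble of non-interacting uniaxial macrospins with
#' fixed easy axes, the Landau-Lifshitz-Gilbert equation
#' `dm/dt = -gamma mu0/(1+alpha^2) [m x H_eff + alpha m x (m x H_eff)]`
#' with `H_eff = H_K (m.n) n + H(t) z + H_th`, where the thermal field
#' `H_th` is white Gaussian noise with per-component variance
#' `2 alpha kB T / (mu0^2 gamma MS V dt)` (Brown's fluctuation-dissipation
#' relation; zero at T = 0). A stochastic Heun scheme with per-step
#' renormalisation of `|m|` is used; the first field cycle is discarded as a
#' transient and the remaining cycles are folded by phase and averaged over
#' the ensemble.
#'
#' Easy axes are fixed in space (the physical-rotation heating channel is not
#' simulated); the Brownian timescale enters the agglomeration model only.
#'
#' @param particle A [particle_spec()].
#' @param protocol A [field_protocol()]. The timestep is
#'   `1/(f * n_steps_per_cycle)` and must resolve the precession about
#'   `H_K + Hmax` (an error is raised otherwise).
#' @param llg An [llg_params()] object.
#' @param constants A [physical_constants()] object.
#' @param axes Optional `n_particles x 3` matrix of unit easy axes; by
#'   default drawn uniformly on the sphere with `llg$seed`.
#' @param record_every Thinning of the recorded magnetisation (default keeps
#'   about 2000 samples per cycle).
#' @return An object of class `hysteresis_loop` with the phase-folded closed
#'   cycle (`H`, `M` in A/m), `area` (J/m^3), `sar` (W/g), and the integrator
#'   diagnostic `max_norm_dev` (largest deviation of `|m|` from 1 after
#'   renormalisation).
#' @examples
#' \donttest{
#' p <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)
#' proto <- field_protocol(Hmax = mT_to_A_per_m(30), f = 765e3,
#'                         n_cycles = 2, n_steps_per_cycle = 250000)
#' loop <- sllg_simulate(p, proto, llg_params(T = 300, n_particles = 20))
#' loop$sar
#' }
#' @export
sllg_simulate <- function(particle, protocol, llg = llg_params(),
                          constants = physical_constants(), axes = NULL,
                          record_every = NULL) {
  stopifnot(inherits(protocol, "field_protocol"), inherits(llg, "llg_params"))
  if (protocol$n_cycles < 2) {
    stop("need n_cycles >= 2: the first cycle is discarded as a transient.",
         call. = FALSE)
  }
  dt <- 1 / (protocol$f * protocol$n_steps_per_cycle)
  .sllg_check_dt(particle, protocol$Hmax, dt, llg, constants)
  if (is.null(record_every)) {
    record_every <- max(1L, protocol$n_steps_per_cycle %/% 2000L)
  }
  if (protocol$n_steps_per_cycle %% record_every != 0) {
    stop("`record_every` must divide n_steps_per_cycle so cycles fold ",
         "exactly.", call. = FALSE)
  }
  nsteps <- protocol$n_cycles * protocol$n_steps_per_cycle
  tt <- (0:nsteps) * dt
  happ <- switch(protocol$waveform,
    sinusoidal = protocol$Hmax * sin(2 * pi * protocol$f * tt),
    triangular = {
      ph <- (protocol$f * tt + 0.75) %% 1          # start at 0, rise first
      protocol$Hmax * (4 * abs(ph - 0.5) - 1)
    })

  res <- .with_seed(llg$seed, {
    if (is.null(axes)) axes <- random_axes(llg$n_particles)
    m0 <- axes * sign(axes[, 3] + (axes[, 3] == 0))  # start along +z side
    sigma_h <- .sllg_sigma_h(particle, llg, dt, constants)
    .sllg_core(m0, axes, anisotropy_field(particle, constants), llg$alpha,
               llg$gamma_e * constants$mu0, sigma_h, happ, dt,
               as.integer(record_every), 0L)
  })

  per_cycle <- protocol$n_steps_per_cycle %/% record_every
  mz <- matrix(res$mz, nrow = per_cycle)        # one column per cycle
  mz_avg <- rowMeans(mz[, -1, drop = FALSE])    # discard transient cycle
  H <- happ[1 + seq_len(per_cycle) * record_every]
  # close the cycle: phase 0 == phase 2*pi
  H <- c(H[per_cycle], H)
  M <- particle$MS * c(mz_avg[per_cycle], mz_avg)
  area <- loop_area(H, M, constants = constants)
  structure(list(H = H, M = M, area = area,
                 sar = area * protocol$f / (particle$rho * 1000),
                 Hmax = protocol$Hmax, f = protocol$f, particle = particle,
                 max_norm_dev = res$max_norm_dev,
                 n_particles = nrow(res$m_final)),
            class = "hysteresis_loop")
}

#' Zero-field equilibrium sampling of the macrospin orientation
#'
#' Runs the stochastic LLG integrator at `H = 0` and returns samples of the
#' easy-axis projection `m.n`. In equilibrium these follow the Boltzmann
#' distribution `p(x) ~ exp(sigma x^2)` on `[-1, 1]` with
#' `sigma = K V/(kB T)`, which provides a direct statistical check of the
#' thermal-field calibration.
#'
#' @param particle A [particle_spec()].
#' @param llg An [llg_params()] object (`T > 0`).
#' @param dt Timestep, s.
#' @param n_steps Total integration steps.
#' @param sample_every Steps between retained samples.
#' @param burn_in Steps discarded before sampling starts.
#' @param constants A [physical_constants()] object.
#' @return Numeric vector of `m.n` samples (ensemble x time, flattened).
#' @export
sllg_equilibrium <- function(particle, llg = llg_params(alpha = 1),
                             dt = 5e-12, n_steps = 200000L,
                             sample_every = 2000L, burn_in = 20000L,
                             constants = physical_constants()) {
  stopifnot(llg$T > 0, n_steps > burn_in)
  .sllg_check_dt(particle, 0, dt, llg, constants)
  .with_seed(llg$seed, {
    axes <- random_axes(llg$n_particles)
    m0 <- axes
    sigma_h <- .sllg_sigma_h(particle, llg, dt, constants)
    happ <- numeric(n_steps + 1)
    res <- .sllg_core(m0, axes, anisotropy_field(particle, constants),
                      llg$alpha, llg$gamma_e * constants$mu0, sigma_h, happ,
                      dt, 0L, as.integer(sample_every))
    keep <- seq_len(nrow(res$mdotn)) * sample_every > burn_in
    as.numeric(res$mdotn[keep, , drop = FALSE])
  })
}
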