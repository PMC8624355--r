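# Closed-form relaxation / interaction physics of a single-domain particle.
# Internal kernels are vectorized over the diameter so the profile builder and
# the scalar user-facing operations share one code path.

.vol <- function(d) (pi / 6) * d^3

.gamma_ratio <- function(d, MS, lcc, kBT, mu0) {
  mu0 * (MS * .vol(d))^2 / (2 * pi * lcc^3 * kBT)
}

.x_diff <- function(d, MS, kBT, mu0) {
  (mu0 * (MS * .vol(d))^2 / (2 * pi * kBT))^(1 / 3)
}

.tau_neel <- function(d, K, kBT, tau0) {
  sigma <- K * .vol(d) / kBT
  (sqrt(pi) / 2) * tau0 * exp(sigma) / sqrt(sigma)
}

.tau_diff <- function(d, MS, tnm, eta, kBT, mu0) {
  x <- .x_diff(d, MS, kBT, mu0)
  x^2 * 6 * pi * eta * (d / 2 + tnm) / kBT
}

.tau_brown <- function(d, tnm, eta, kBT) {
  vhyd <- (4 * pi / 3) * (d / 2 + tnm)^3
  3 * eta * vhyd / kBT
}

#' Ratio of dipolar to thermal energy for two aligned moments
#'
#' The conventional agglomeration-likelihood estimate: the magnetostatic
#' energy of two parallel point dipoles `m = MS*V` at centre distance `lcc`,
#' divided by `kB*T`,
#' `Gamma = mu0 (MS V)^2 / (2 pi lcc^3 kB T)`.
#' `Gamma > 1` signals that dipolar binding beats thermal agitation. Note the
#' ratio knows nothing about the anisotropy `K`.
#'
#' @param particle A [particle_spec()].
#' @param med A [medium()].
#' @param lcc Centre-to-centre distance, m. Must be at least `d` (touching
#'   spheres); smaller values would overlap the cores.
#' @param constants A [physical_constants()] object.
#' @return Dimensionless ratio `Gamma >= 0`.
#' @examples
#' p <- particle_spec(d = 7e-9, K = 11e3, MS = 4.8e5)
#' dipolar_thermal_ratio(p, medium(), lcc = p$d)  # ~1 at the 7 nm threshold
#' @export
dipolar_thermal_ratio <- function(particle, med = medium(), lcc,
                                  constants = physical_constants()) {
  stopifnot(is.numeric(lcc), lcc > 0)
  if (any(lcc < particle$d)) {
    stop("`lcc` must be >= the particle diameter: centres of touching ",
         "spheres cannot be closer than d.", call. = FALSE)
  }
  .gamma_ratio(particle$d, particle$MS, lcc, constants$kB * med$T,
               constants$mu0)
}

#' Neel relaxation time
#'
#' High-barrier thermal-activation estimate of the internal moment-flip time
#' over the uniaxial anisotropy barrier,
#' `tau_N = (sqrt(pi)/2) tau0 exp(sigma) / sqrt(sigma)` with
#' `sigma = K V / (kB T)`. The expression is an asymptote valid for
#' `sigma > 1`; below that a warning is raised (but the value is still
#' returned so profiles can span small sizes).
#'
#' @inheritParams dipolar_thermal_ratio
#' @return Neel time, s.
#' @examples
#' p <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)
#' neel_time(p, medium())  # ~6e-4 s
#' @export
neel_time <- function(particle, med = medium(),
                      constants = physical_constants()) {
  sigma <- particle$K * magnetic_volume(particle) / (constants$kB * med$T)
  if (sigma < 1) {
    warning("reduced barrier sigma = KV/kBT = ", signif(sigma, 3),
            " < 1: the high-barrier Neel expression loses validity.",
            call. = FALSE)
  }
  .tau_neel(particle$d, particle$K, constants$kB * med$T, constants$tau0)
}

#' Diffusion distance at which dipolar energy overtakes thermal energy
#'
#' The centre distance `<x>` at which the two-dipole interaction energy equals
#' `kB*T` (i.e. the `Gamma = 1` contour):
#' `<x> = [mu0 (MS V)^2 / (2 pi kB T)]^(1/3)`.
#' By construction `dipolar_thermal_ratio(..., lcc = <x>)` is exactly 1.
#'
#' @inheritParams dipolar_thermal_ratio
#' @return Distance, m (0 when `MS = 0`).
#' @export
diffusion_distance <- function(particle, med = medium(),
                               constants = physical_constants()) {
  .x_diff(particle$d, particle$MS, constants$kB * med$T, constants$mu0)
}

#' Translational diffusion time across the dipolar capture distance
#'
#' Time for the particle to diffuse across `<x>` (see
#' [diffusion_distance()]) with Stokes-Einstein drag on the hydrodynamic
#' radius: `tau_diff = <x>^2 * 6 pi eta R_hyd / (kB T)`. Linear in viscosity
#' and in `R_hyd`; for a bare particle it grows as `d^5`.
#'
#' @inheritParams dipolar_thermal_ratio
#' @return Diffusion time, s.
#' @export
diffusion_time <- function(particle, med = medium(),
                           constants = physical_constants()) {
  .tau_diff(particle$d, particle$MS, particle$tnm, med$eta,
            constants$kB * med$T, constants$mu0)
}

#' Brownian rotation (Debye) time
#'
#' Characteristic time for physical rotation of the whole (coated) particle in
#' the viscous medium, `tau_B = 3 eta V_hyd / (kB T)`.
#'
#' @inheritParams dipolar_thermal_ratio
#' @return Rotation time, s.
#' @export
brown_rotation_time <- function(particle, med = medium(),
                                constants = physical_constants()) {
  .tau_brown(particle$d, particle$tnm, med$eta, constants$kB * med$T)
}

#' Blocking-temperature size threshold (ZFC/FC criterion)
#'
#' Inverts the conventional zero-field-cooled blocking relation
#' `T_B = K V / (25 kB)` for the sphere diameter that blocks at temperature
#' `TB`: `d_TB = [150 kB TB * 6/(pi ... )]`, i.e. `V = 25 kB TB / K`.
#' Sizes above `d_TB` are blocked (remanent) on the conventional
#' magnetometry timescale at `TB`.
#'
#' @param K Uniaxial anisotropy constant, J/m^3.
#' @param TB Blocking temperature, K (default 300, room temperature).
#' @param constants A [physical_constants()] object.
#' @return Diameter `d_TB`, m. Strictly decreasing in `K` as `K^(-1/3)`.
#' @examples
#' blocking_size(11e3) * 1e9  # 26.2 nm
#' @export
blocking_size <- function(K, TB = 300, constants = physical_constants()) {
  stopifnot(is.numeric(K), all(K > 0), is.numeric(TB), all(TB > 0))
  V <- 25 * constants$kB * TB / K
  (6 * V / pi)^(1 / 3)
}

#' Relaxation-timescale profile over a diameter grid
#'
#' Vectorized evaluation of the five characteristic quantities as a function
#' of the core diameter: Neel time, Brownian rotation time, translational
#' diffusion time, the dipole/thermal ratio `Gamma` at contact (`lcc = d`),
#' and the diffusion distance `<x>`.
#'
#' @param K Uniaxial anisotropy constant, J/m^3.
#' @param MS Saturation magnetisation, A/m.
#' @param tnm Nonmagnetic coating thickness, m.
#' @param med A [medium()].
#' @param constants A [physical_constants()] object.
#' @param d_grid Strictly increasing vector of positive diameters, m.
#' @return A `data.frame` of class `relaxation_profile` with columns
#'   `d`, `tau_N`, `tau_B`, `tau_diff`, `gamma`, `x_diff` (all SI).
#' @examples
#' prof <- relaxation_profile(11e3, 4.8e5, d_grid = seq(10, 30, 0.5) * 1e-9)
#' head(prof)
#' @export
relaxation_profile <- function(K, MS, tnm = 0, med = medium(),
                               constants = physical_constants(),
                               d_grid) {
  stopifnot(is.numeric(d_grid), length(d_grid) >= 1, all(d_grid > 0))
  if (is.unsorted(d_grid, strictly = TRUE)) {
    stop("`d_grid` must be strictly increasing.", call. = FALSE)
  }
  kBT <- constants$kB * med$T
  out <- data.frame(
    d = d_grid,
    tau_N = .tau_neel(d_grid, K, kBT, constants$tau0),
    tau_B = .tau_brown(d_grid, tnm, med$eta, kBT),
    tau_diff = .tau_diff(d_grid, MS, tnm, med$eta, kBT, constants$mu0),
    gamma = .gamma_ratio(d_grid, MS, d_grid, kBT, constants$mu0),
    x_diff = .x_diff(d_grid, MS, kBT, constants$mu0)
  )
  class(out) <- c("relaxation_profile", "data.frame")
  attr(out, "params") <- list(K = K, MS = MS, tnm = tnm, T = med$T,
                              eta = med$eta, tau0 = constants$tau0)
  out
}

#' Write a relaxation profile as CSV in display units
#'
#' Exports `d` and `<x>` in nm and the three timescales in seconds, columns
#' `d_nm, tau_N_s, tau_B_s, tau_diff_s, gamma, x_diff_nm`.
#'
#' @param profile A [relaxation_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "relaxation_profile"))
  out <- data.frame(d_nm = profile$d * 1e9,
                    tau_N_s = profile$tau_N,
                    tau_B_s = profile$tau_B,
                    tau_diff_s = profile$tau_diff,
                    gamma = profile$gamma,
                    x_diff_nm = profile$x_diff * 1e9)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
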