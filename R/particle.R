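#' Specify one monodisperse single-domain particle type
#'
#' Geometry and magnetic constants of a spherical, uniaxial single-domain
#' nanoparticle. The magnetic core has diameter `d`; a nonmagnetic coating of
#' thickness `tnm` enlarges the hydrodynamic radius (`d/2 + tnm`) that governs
#' viscous drag, but not the magnetic volume.
#'
#' @param d Magnetic core diameter, m.
#' @param K Uniaxial anisotropy constant, J/m^3.
#' @param MS Saturation magnetisation, A/m.
#' @param tnm Nonmagnetic coating thickness, m (default 0).
#' @param rho Mass density, kg/m^3. Default 5180 (magnetite), used only to
#'   express volumetric heating as W/g.
#'
#' @return An object of class `particle_spec`.
#' @examples
#' p <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)
#' magnetic_volume(p)
#' anisotropy_field(p)
#' @export
particle_spec <- function(d, K, MS, tnm = 0, rho = 5180) {
  stopifnot(is.numeric(d), length(d) == 1, is.numeric(K), length(K) == 1,
            is.numeric(MS), length(MS) == 1, is.numeric(tnm), length(tnm) == 1,
            is.numeric(rho), length(rho) == 1)
  if (d <= 0) stop("`d` must be positive.", call. = FALSE)
  if (K <= 0) stop("`K` must be positive.", call. = FALSE)
  if (MS < 0) stop("`MS` must be non-negative.", call. = FALSE)
  if (tnm < 0) stop("`tnm` must be non-negative.", call. = FALSE)
  if (rho <= 0) stop("`rho` must be positive.", call. = FALSE)
  structure(list(d = d, K = K, MS = MS, tnm = tnm, rho = rho),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf(
    "Particle: d = %.2f nm, K = %.3g kJ/m^3, MS = %.3g kA/m, tnm = %.2f nm\n",
    x$d * 1e9, x$K / 1e3, x$MS / 1e3, x$tnm * 1e9))
  invisible(x)
}

#' Embedding fluid
#'
#' Temperature and dynamic viscosity of the medium the particles diffuse and
#' rotate in. The default viscosity, 0.00235 kg/(m s), is representative of the
#' nanoscale intracellular environment; water is 0.001 kg/(m s).
#'
#' @param T Absolute temperature, K.
#' @param eta Dynamic viscosity, kg/(m s).
#' @return An object of class `medium`.
#' @examples
#' medium()                 # intracellular-like default
#' medium(eta = 0.001)      # water
#' @export
medium <- function(T = 300, eta = 0.00235) {
  stopifnot(is.numeric(T), length(T) == 1, is.numeric(eta), length(eta) == 1)
  if (T <= 0) stop("`T` must be positive.", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive.", call. = FALSE)
  structure(list(T = T, eta = eta), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("Medium: T = %g K, eta = %g kg/(m s)\n", x$T, x$eta))
  invisible(x)
}

#' Magnetic core volume of a spherical particle
#' @param particle A [particle_spec()].
#' @return Volume `(pi/6) d^3`, m^3.
#' @export
magnetic_volume <- function(particle) {
  (pi / 6) * particle$d^3
}

#' Hydrodynamic radius (core radius plus coating)
#' @param particle A [particle_spec()].
#' @return `d/2 + tnm`, m.
#' @export
hydrodynamic_radius <- function(particle) {
  particle$d / 2 + particle$tnm
}

#' Hydrodynamic volume of the coated sphere
#' @param particle A [particle_spec()].
#' @return `(4 pi/3) (d/2 + tnm)^3`, m^3.
#' @export
hydrodynamic_volume <- function(particle) {
  (4 * pi / 3) * hydrodynamic_radius(particle)^3
}

#' Anisotropy field of a uniaxial particle
#'
#' `H_K = 2 K / (mu0 MS)`, the field scale for coherent reversal; switching
#' fields of a Stoner-Wohlfarth particle lie between `0.5 H_K` and `H_K`.
#'
#' @param particle A [particle_spec()].
#' @param constants A [physical_constants()] object.
#' @return Anisotropy field, A/m.
#' @export
anisotropy_field <- function(particle, constants = physical_constants()) {
  if (particle$MS <= 0) stop("anisotropy field requires MS > 0.", call. = FALSE)
  2 * particle$K / (constants$mu0 * particle$MS)
}
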