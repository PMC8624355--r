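# Sample-concentration limit of validity: the dilute, non-interacting
# assumptions hold while the nearest-neighbour distance exceeds the dipolar
# capture distance <x>.

#' Nearest-neighbour distance in a random monodisperse dispersion
#'
#' Tewari-Gokhale approximation for the mean centre-to-centre distance to the
#' nearest neighbour of randomly placed monodisperse (coated) spheres at
#' volume fraction `c`:
#' `l_NN = (d + 2 tnm) * (0.4465 / c^(1/3)) * (1 + 1.02625 c^0.6423)`.
#' Strictly decreasing in `c` over the physically relevant range and linear
#' in the coated diameter, to which it tends asymptotically as packing grows.
#'
#' @param particle A [particle_spec()].
#' @param c Volume fraction(s), dimensionless in (0, 1).
#' @return Distance(s), m.
#' @examples
#' p <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)
#' nearest_neighbor_distance(p, 0.01) * 1e9  # ~48 nm at 1% volume fraction
#' @export
nearest_neighbor_distance <- function(particle, c) {
  stopifnot(is.numeric(c))
  if (any(c <= 0 | c >= 1)) {
    stop("`c` is a volume fraction and must lie in (0, 1).", call. = FALSE)
  }
  (particle$d + 2 * particle$tnm) * (0.4465 / c^(1 / 3)) *
    (1 + 1.02625 * c^0.6423)
}

#' Concentration threshold of the dilute-suspension assumptions
#'
#' Solves `l_NN(c) = <x>` for the volume fraction at which the mean
#' nearest-neighbour distance shrinks to the dipolar capture distance of the
#' particle (evaluated from the bare magnetic size; the coating enters only
#' through the `d + 2 tnm` factor of `l_NN`). Below `c_aggl` a particle at
#' its agglomeration threshold size still has, on average, no neighbour
#' within dipolar reach and the single-particle treatment is self-consistent.
#'
#' @param particle A [particle_spec()], normally at its `d_aggl` for the
#'   anisotropy of interest.
#' @param med A [medium()].
#' @param constants A [physical_constants()] object.
#' @param c_bracket Search interval for the volume fraction.
#' @param tol Relative solver tolerance on `c`.
#' @return Threshold concentration as a percent volume fraction.
#' @examples
#' daggl <- find_d_aggl(11e3, 4.8e5)$d_aggl
#' find_c_aggl(particle_spec(d = daggl, K = 11e3, MS = 4.8e5))  # ~0.3%
#' @export
find_c_aggl <- function(particle, med = medium(),
                        constants = physical_constants(),
                        c_bracket = c(1e-8, 0.7), tol = 1e-10) {
  x <- diffusion_distance(particle, med, constants)
  g <- function(c) nearest_neighbor_distance(particle, c) - x
  glo <- g(c_bracket[1])
  ghi <- g(c_bracket[2])
  if (glo < 0 || ghi > 0) {
    stop("no concentration solves l_NN(c) = <x> on the bracket: the capture ",
         "distance <x> = ", signif(x * 1e9, 4), " nm lies outside the ",
         "attainable l_NN range [", signif(nearest_neighbor_distance(
           particle, c_bracket[2]) * 1e9, 4), ", ",
         signif(nearest_neighbor_distance(particle, c_bracket[1]) * 1e9, 4),
         "] nm.", call. = FALSE)
  }
  root <- uniroot(g, lower = c_bracket[1], upper = c_bracket[2],
                  tol = tol * min(c_bracket[2], 1))$root
  100 * root
}
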