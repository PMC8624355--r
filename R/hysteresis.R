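# Quasistatic (T = 0) Stoner-Wohlfarth hysteresis: astroid switching field,
# branch-following loop solver vectorized over easy-axis orientations, loop
# area and SAR bookkeeping.

#' AC field protocol
#'
#' @param Hmax Field amplitude, A/m (convert lab mT values with
#'   [mT_to_A_per_m()]).
#' @param f Frequency, Hz.
#' @param waveform `"sinusoidal"` (default; matches the usual hyperthermia
#'   drive) or `"triangular"`.
#' @param n_cycles Number of field cycles; the first is discarded as a
#'   transient by the dynamic simulator.
#' @param n_steps_per_cycle Time steps per cycle (>= 100).
#' @return An object of class `field_protocol`.
#' @export
field_protocol <- function(Hmax, f, waveform = c("sinusoidal", "triangular"),
                           n_cycles = 3, n_steps_per_cycle = 1000) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(Hmax), Hmax >= 0, is.numeric(f), f > 0,
            n_cycles >= 1, n_steps_per_cycle >= 100)
  structure(list(Hmax = Hmax, f = f, waveform = waveform,
                 n_cycles = as.integer(n_cycles),
                 n_steps_per_cycle = as.integer(n_steps_per_cycle)),
            class = "field_protocol")
}

#' Integrator and thermal-bath settings for the stochastic LLG simulator
#'
#' @param alpha Gilbert damping (dimensionless, > 0). Default 0.1.
#' @param gamma_e Gyromagnetic ratio, rad/(s T).
#' @param T Temperature, K (0 switches the thermal field off).
#' @param seed RNG seed for the thermal noise and the random axes.
#' @param n_particles Ensemble size (>= 1).
#' @return An object of class `llg_params`.
#' @export
llg_params <- function(alpha = 0.1, gamma_e = 1.76e11, T = 300,
                       seed = 1L, n_particles = 100L) {
  stopifnot(alpha > 0, gamma_e > 0, T >= 0, n_particles >= 1)
  structure(list(alpha = alpha, gamma_e = gamma_e, T = T,
                 seed = as.integer(seed),
                 n_particles = as.integer(n_particles)),
            class = "llg_params")
}

#' Stoner-Wohlfarth switching field (astroid)
#'
#' Reduced switching field `h_sw = H_sw/H_K` of a uniaxial macrospin whose
#' easy axis makes angle `psi` with the field:
#' `h_sw = (cos(psi)^(2/3) + sin(psi)^(2/3))^(-3/2)`.
#' Angles outside `[0, pi/2]` are folded in by the symmetry of the astroid.
#'
#' @param psi Easy-axis angle(s) to the field axis, rad.
#' @return Reduced switching field(s) in `[1/2, 1]`; 1 at `psi = 0, pi/2`,
#'   minimum 0.5 at `pi/4`.
#' @examples
#' sw_switching_field(c(0, pi / 6, pi / 4))
#' @export
sw_switching_field <- function(psi) {
  stopifnot(is.numeric(psi))
  psi <- abs(psi) %% pi
  psi <- ifelse(psi > pi / 2, pi - psi, psi)
  (cos(psi)^(2 / 3) + sin(psi)^(2 / 3))^(-3 / 2)
}

# Follow the occupied local minimum of the reduced energy
#   e(theta) = 0.5 sin^2(theta - psi) - h cos(theta)
# from a previous configuration. Damped Newton with a gradient-flow fallback
# past spinodal points; active-set iteration so converged orientations cost
# nothing. theta, psi are vectors of equal length.
.sw_relax <- function(theta, psi, h, tol = 1e-11, maxit = 400L) {
  act <- seq_along(theta)
  for (it in seq_len(maxit)) {
    th <- theta[act]
    ps <- psi[act]
    g <- 0.5 * sin(2 * (th - ps)) + h * sin(th)
    cv <- cos(2 * (th - ps)) + h * cos(th)
    # clamped Newton with a curvature floor in convex regions; past a
    # spinodal (cv <= 0) flow downhill with a minimum escape step so flat
    # unstable tops (where both g and cv vanish) cannot trap the iterate
    step <- ifelse(cv > 0, -g / pmax(cv, 1e-3),
                   -sign(g) * pmax(pmin(abs(g) / 0.2, 0.3), 0.02))
    step <- ifelse(cv <= 0 & g == 0, 0.02, step)
    step <- pmax(pmin(step, 0.5), -0.5)
    theta[act] <- th + step
    # converged once the gradient (or, at degenerate flat minima right on
    # the astroid, the position update) is negligible on a stable branch
    keep <- (abs(g) > tol & abs(step) > 1e-9) | cv <= 0
    act <- act[keep]
    if (length(act) == 0) return(theta)
  }
  stop("quasistatic energy minimisation did not converge (", length(act),
       " orientations unresolved); refine the field stepping.", call. = FALSE)
}

#' Quasistatic (T = 0) Stoner-Wohlfarth hysteresis loop
#'
#' Sweeps the field quasistatically over one closed cycle
#' `+Hmax -> -Hmax -> +Hmax` and, for each easy-axis orientation, follows the
#' occupied local minimum of the macrospin energy
#' `E = K V sin^2(theta - psi) - mu0 MS V H cos(theta)`, jumping only when the
#' minimum loses metastability (coherent-reversal switching on the astroid).
#' The ensemble magnetisation is the weighted average of the orientation
#' loops. For a 3D random easy-axis distribution the natural weight is
#' `sin(psi)`; equivalently, pass orientations sampled uniformly in
#' `cos(psi)` with equal weights (see [sw_random_psi()]).
#'
#' For an aligned ensemble saturating sweep (`psi = 0`, `Hmax >= H_K`) the
#' loop is rectangular with coercive field `H_K` and area `8K`; a saturated
#' random ensemble dissipates close to `2K` per cycle.
#'
#' @param particle A [particle_spec()].
#' @param psi Easy-axis angle(s) to the field axis, rad (vector = ensemble).
#' @param Hmax Field amplitude, A/m.
#' @param weights Ensemble weights (default equal).
#' @param n_steps Field samples over the closed cycle (odd; default 2001).
#' @param f Optional drive frequency, Hz, used only to convert the loop area
#'   into a SAR.
#' @param constants A [physical_constants()] object.
#' @return An object of class `hysteresis_loop`: list with `H`, `M` (closed
#'   sampled cycle, A/m), `area` (J/m^3), `sar` (W/g, `NA` without `f`).
#' @examples
#' p <- particle_spec(d = 20e-9, K = 10e3, MS = 4.8e5)
#' loop <- sw_quasistatic_loop(p, psi = 0, Hmax = 1.5 * anisotropy_field(p))
#' loop$area / p$K  # 8: the aligned-axis loss bound
#' @export
sw_quasistatic_loop <- function(particle, psi, Hmax, weights = NULL,
                                n_steps = 2001L, f = NULL,
                                constants = physical_constants()) {
  stopifnot(is.numeric(psi), length(psi) >= 1, Hmax >= 0, n_steps >= 101)
  hk <- anisotropy_field(particle, constants)
  hmax <- Hmax / hk
  if (is.null(weights)) weights <- rep(1, length(psi))
  stopifnot(length(weights) == length(psi), all(weights >= 0))
  # clamp the symmetric orientations: theta = 0 is a (possibly unstable)
  # equilibrium at psi = 0 exactly, so branch-following needs a tilt
  psi <- abs(psi) %% pi
  psi <- ifelse(psi > pi / 2, pi - psi, psi)
  psi <- pmin(pmax(psi, 1e-6), pi / 2 - 1e-6)

  m <- (as.integer(n_steps) + 1L) %/% 2L
  hs <- c(seq(hmax, -hmax, length.out = m), seq(-hmax, hmax, length.out = m)[-1])
  # prepared state: positive saturation branch at +Hmax
  theta <- .sw_relax(rep(1e-3, length(psi)), psi, hmax)
  W <- sum(weights)
  M <- numeric(length(hs))
  for (i in seq_along(hs)) {
    theta <- .sw_relax(theta, psi, hs[i])
    M[i] <- particle$MS * sum(weights * cos(theta)) / W
  }
  H <- hs * hk
  area <- loop_area(H, M, constants = constants)
  sar <- if (is.null(f)) NA_real_ else area * f / (particle$rho * 1000)
  structure(list(H = H, M = M, area = area, sar = sar,
                 Hmax = Hmax, f = if (is.null(f)) NA_real_ else f,
                 particle = particle),
            class = "hysteresis_loop")
}

#' Random 3D easy-axis orientation angles for ensemble loops
#'
#' Deterministic equal-weight quadrature over the random-axis distribution:
#' midpoints of a uniform grid in `u = cos(psi)` on `(0, 1)`, which carries
#' the `sin(psi)` orientation weight exactly.
#'
#' @param n Number of orientations.
#' @return Angles in `(0, pi/2)`, rad.
#' @export
sw_random_psi <- function(n) {
  stopifnot(n >= 1)
  acos((seq_len(n) - 0.5) / n)
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("Hysteresis loop: Hmax = %.3g A/m (%.1f mT), %d samples\n",
              x$Hmax, x$Hmax * 1.256e-6 * 1e3, length(x$H)))
  cat(sprintf("  area = %.4g J/m^3", x$area))
  if (!is.na(x$sar)) cat(sprintf("  SAR = %.4g W/g at %.3g kHz", x$sar,
                                 x$f / 1e3))
  cat("\n")
  invisible(x)
}

#' Hysteresis-loop area (energy loss per cycle)
#'
#' Trapezoidal closed-contour integral `area = mu0 |oint M dH|` of a sampled
#' cycle. The trajectory must be closed: first and last field samples equal.
#'
#' @param H Applied-field samples, A/m.
#' @param M Magnetisation samples, A/m.
#' @param constants A [physical_constants()] object.
#' @return Loss per cycle and unit magnetic volume, J/m^3 (non-negative).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)
#' loop_area(1e4 * cos(th), 1e5 * sin(th))  # ellipse: mu0*pi*Hmax*M0
#' @export
loop_area <- function(H, M, constants = physical_constants()) {
  stopifnot(is.numeric(H), is.numeric(M), length(H) == length(M),
            length(H) >= 3)
  n <- length(H)
  if (abs(H[1] - H[n]) > 1e-9 * max(abs(H), 1)) {
    stop("open trajectory: first and last field samples differ; ",
         "loop_area() needs a closed cycle.", call. = FALSE)
  }
  constants$mu0 * abs(sum((M[-1] + M[-n]) / 2 * diff(H)))
}

#' SAR versus field amplitude, with the anisotropy-scaling collapse columns
#'
#' Computes the specific absorption rate `SAR = A f / rho` over a grid of
#' field amplitudes and appends the reduced coordinates in which curves for
#' different anisotropy constants collapse: `Hmax/H_K` on the abscissa and
#' the normalized loss `A/(2K)` (equal to `SAR/(2 K f / rho)`) on the
#' ordinate, bounded above by 1 for a random ensemble (8K/2K limits).
#'
#' Method `"sw"` (default) evaluates the T = 0 quasistatic Stoner-Wohlfarth
#' ensemble; `"sllg"` runs the finite-temperature stochastic LLG dynamic
#' simulation via [sllg_simulate()] and requires `llg`.
#'
#' @param particle A [particle_spec()].
#' @param f Drive frequency, Hz.
#' @param Hmax_list Increasing field amplitudes, A/m.
#' @param method `"sw"` or `"sllg"`.
#' @param llg An [llg_params()] object (required for `"sllg"`).
#' @param psi Orientation angles for `"sw"` (default 256-point random-axis
#'   quadrature from [sw_random_psi()]).
#' @param n_steps Field samples per quasistatic cycle (`"sw"`).
#' @param n_steps_per_cycle,n_cycles Dynamic-protocol settings (`"sllg"`).
#' @param constants A [physical_constants()] object.
#' @return A `data.frame` with columns `Hmax`, `area` (J/m^3), `sar` (W/g),
#'   `h_reduced` (`Hmax/H_K`), `sar_norm` (`A/(2K)`).
#' @examples
#' p <- particle_spec(d = 20e-9, K = 10e3, MS = 4.8e5)
#' hk <- anisotropy_field(p)
#' sar_sweep(p, f = 765e3, Hmax_list = hk * c(0.4, 0.6, 1))
#' @export
sar_sweep <- function(particle, f, Hmax_list, method = c("sw", "sllg"),
                      llg = NULL, psi = sw_random_psi(256L), n_steps = 1001L,
                      n_steps_per_cycle = 250000L, n_cycles = 3L,
                      constants = physical_constants()) {
  method <- match.arg(method)
  stopifnot(is.numeric(Hmax_list), !is.unsorted(Hmax_list))
  hk <- anisotropy_field(particle, constants)
  rows <- lapply(Hmax_list, function(hm) {
    if (hm == 0) {
      area <- 0
    } else if (method == "sw") {
      area <- sw_quasistatic_loop(particle, psi, hm, n_steps = n_steps,
                                  constants = constants)$area
    } else {
      if (is.null(llg)) stop("method 'sllg' needs `llg`.", call. = FALSE)
      proto <- field_protocol(hm, f, n_cycles = n_cycles,
                              n_steps_per_cycle = n_steps_per_cycle)
      area <- sllg_simulate(particle, proto, llg, constants)$area
    }
    data.frame(Hmax = hm, area = area,
               sar = area * f / (particle$rho * 1000),
               h_reduced = hm / hk, sar_norm = area / (2 * particle$K))
  })
  do.call(rbind, rows)
}
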