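# Scenario stage: self-contained parameter sets for every figure/table-style
# study the package reproduces, plus seeded random easy-axis ensembles. The
# whole analysis runs from these scenarios with no external data.

#' Bundle a named study scenario
#'
#' @param name Identifier.
#' @param particles List of [particle_spec()] objects.
#' @param med A [medium()].
#' @param protocols List of [field_protocol()] objects (may be empty).
#' @param llg An [llg_params()] object or `NULL`.
#' @param seed Integer seed governing any randomness in the scenario.
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(name, particles, med = medium(), protocols = list(),
                         llg = NULL, seed = 1L) {
  stopifnot(is.character(name), length(name) == 1, is.list(particles),
            all(vapply(particles, inherits, TRUE, "particle_spec")),
            inherits(med, "medium"))
  structure(list(name = name, particles = particles, medium = med,
                 protocols = protocols, llg = llg, seed = as.integer(seed)),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d particle type(s), %d protocol(s), seed %d\n",
              x$name, length(x$particles), length(x$protocols), x$seed))
  invisible(x)
}

#' Built-in study scenarios
#'
#' The catalogue of parameter sets the analysis stages consume, stored with
#' the magnetite-like values conventional in the hyperthermia literature
#' (`MS = 4.8e5` A/m, `K` of order 10 kJ/m^3, intracellular-like viscosity
#' 0.00235 kg/(m s), T = 300 K):
#' \describe{
#'   \item{`table1`}{Threshold comparison: bare particles with
#'     `K = 8, 11, 15` kJ/m^3.}
#'   \item{`fig1_profiles`}{Relaxation-time profiles over d for the three K.}
#'   \item{`fig2_coating`}{Coating sensitivity, `tnm = 0, 5, 20` nm at
#'     `K = 11` kJ/m^3.}
#'   \item{`fig2_viscosity`}{Viscosity sensitivity,
#'     `eta = 0.001, 0.00235, 0.044` kg/(m s).}
#'   \item{`fig3_sw`}{Anisotropy-scaling study: `d = 20` nm, `MS = 480` kA/m,
#'     `K = 10, 20` kJ/m^3, 765 kHz, `Hmax` 25 mT.}
#'   \item{`fig4_fig5_loops`}{Dynamic loops of the three threshold-sized
#'     particles (`d_aggl` from `table1`) at 205 and 765 kHz.}
#'   \item{`fig6_concentration`}{Concentration-validity study for the
#'     threshold-sized particles with `tnm = 0, 5, 10, 20` nm.}
#' }
#'
#' @param name Optional scenario name; omit for the full named list.
#' @param seed Seed stored in the scenarios.
#' @return A `scenario_set`, or a named list of all of them.
#' @examples
#' names(builtin_scenarios())
#' builtin_scenarios("table1")
#' @export
builtin_scenarios <- function(name = NULL, seed = 1L) {
  MS <- 4.8e5
  med <- medium(T = 300, eta = 0.00235)
  tab1_K <- c(8e3, 11e3, 15e3)
  tab1_d <- c(24.8e-9, 22.0e-9, 19.5e-9)   # threshold sizes for tab1_K
  p_tab1 <- lapply(seq_along(tab1_K), function(i)
    particle_spec(d = tab1_d[i], K = tab1_K[i], MS = MS))
  protos_45 <- unlist(lapply(c(205e3, 765e3), function(f)
    lapply(mT_to_A_per_m(c(10, 20, 30)), function(h)
      field_protocol(h, f, n_cycles = 3, n_steps_per_cycle = 250000))),
    recursive = FALSE)
  cat_all <- list(
    table1 = scenario_set("table1", p_tab1, med, seed = seed),
    fig1_profiles = scenario_set("fig1_profiles", p_tab1, med, seed = seed),
    fig2_coating = scenario_set(
      "fig2_coating",
      lapply(c(0, 5e-9, 20e-9), function(t)
        particle_spec(d = 22e-9, K = 11e3, MS = MS, tnm = t)),
      med, seed = seed),
    fig2_viscosity = scenario_set(
      "fig2_viscosity",
      list(particle_spec(d = 22e-9, K = 11e3, MS = MS)),
      med, seed = seed),
    fig3_sw = scenario_set(
      "fig3_sw",
      lapply(c(10e3, 20e3), function(K)
        particle_spec(d = 20e-9, K = K, MS = 4.8e5)),
      med,
      protocols = list(field_protocol(mT_to_A_per_m(25), 765e3,
                                      n_cycles = 3,
                                      n_steps_per_cycle = 250000)),
      llg = llg_params(T = 0, seed = seed),
      seed = seed),
    fig4_fig5_loops = scenario_set(
      "fig4_fig5_loops", p_tab1, med,
      protocols = protos_45,
      llg = llg_params(T = 300, seed = seed, n_particles = 50),
      seed = seed),
    fig6_concentration = scenario_set(
      "fig6_concentration",
      unlist(lapply(seq_along(tab1_K), function(i)
        lapply(c(0, 5e-9, 10e-9, 20e-9), function(t)
          particle_spec(d = tab1_d[i], K = tab1_K[i], MS = MS, tnm = t))),
        recursive = FALSE),
      med, seed = seed)
  )
  # viscosity variants are a perturbation of the embedding medium
  attr(cat_all$fig2_viscosity, "eta_values") <- c(0.001, 0.00235, 0.044)
  if (is.null(name)) return(cat_all)
  if (!name %in% names(cat_all)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(cat_all), collapse = ", "), call. = FALSE)
  }
  cat_all[[name]]
}

#' Seeded uniform random unit vectors (easy-axis ensembles)
#'
#' Draws directions uniformly on the unit sphere by normalising standard
#' Gaussian 3-vectors. When `seed` is given the caller's RNG state is saved
#' and restored, so the draw is reproducible without side effects.
#'
#' @param n Number of axes (>= 1).
#' @param seed Optional integer seed.
#' @return An `n x 3` matrix of unit rows.
#' @examples
#' a <- random_axes(5, seed = 42)
#' rowSums(a^2)
#' @export
random_axes <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Vary one parameter of a scenario over a list of values
#'
#' Produces one derived scenario per value, everything else held fixed.
#' Recognised parameter paths: `"tnm"`, `"d"`, `"K"`, `"MS"` (applied to
#' every particle), `"eta"`, `"T"` (the medium), `"Hmax"`, `"f"` (every
#' protocol).
#'
#' @param base A [scenario_set()].
#' @param parameter Parameter path (see above).
#' @param values Numeric values, SI units.
#' @return A list of `scenario_set` objects, one per value (empty list for
#'   empty `values`).
#' @examples
#' sc <- builtin_scenarios("table1")
#' length(perturb_grid(sc, "eta", c(0.001, 0.00235, 0.044)))
#' @export
perturb_grid <- function(base, parameter, values) {
  stopifnot(inherits(base, "scenario_set"), is.numeric(values))
  part_fields <- c("tnm", "d", "K", "MS")
  med_fields <- c("eta", "T")
  proto_fields <- c("Hmax", "f")
  if (!parameter %in% c(part_fields, med_fields, proto_fields)) {
    stop("unknown parameter path '", parameter, "'; recognised: ",
         paste(c(part_fields, med_fields, proto_fields), collapse = ", "),
         call. = FALSE)
  }
  lapply(values, function(v) {
    s <- base
    if (parameter %in% part_fields) {
      s$particles <- lapply(s$particles, function(p) {
        p[[parameter]] <- v
        do.call(particle_spec, p)
      })
    } else if (parameter %in% med_fields) {
      m <- unclass(s$medium)
      m[[parameter]] <- v
      s$medium <- do.call(medium, m)
    } else {
      s$protocols <- lapply(s$protocols, function(pr) {
        pr[[parameter]] <- v
        field_protocol(pr$Hmax, pr$f, pr$waveform, pr$n_cycles,
                       pr$n_steps_per_cycle)
      })
    }
    s$name <- paste0(base$name, "_", parameter, "=", format(v, trim = TRUE))
    s
  })
}
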