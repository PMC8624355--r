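#' Physical constants for nanoparticle relaxation and hysteresis models
#'
#' Bundles the constants every model in the package depends on. Defaults use
#' `mu0 = 1.256e-6` T m/A (the rounded value conventional in the magnetic
#' hyperthermia literature rather than the CODATA `4*pi*1e-7`) and the SI-exact
#' Boltzmann constant. The Neel attempt-time prefactor `tau0` is not directly
#' measurable for a given sample; physically admissible values span
#' 1e-12 to 1e-9 s and the default sits at the upper end, which is the value
#' consistent with the room-temperature magnetite threshold sizes this package
#' reproduces (see the methods vignette).
#'
#' @param mu0 Vacuum permeability, T m/A.
#' @param kB Boltzmann constant, J/K.
#' @param tau0 Neel attempt-time prefactor, s. Must lie in \[1e-12, 1e-9\].
#' @param gamma_e Electron gyromagnetic ratio, rad/(s T).
#'
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' const <- physical_constants()
#' const$kB
#' @export
physical_constants <- function(mu0 = 1.256e-6,
                               kB = 1.380649e-23,
                               tau0 = 1e-9,
                               gamma_e = 1.76e11) {
  stopifnot(is.numeric(mu0), mu0 > 0, is.numeric(kB), kB > 0,
            is.numeric(gamma_e), gamma_e > 0, is.numeric(tau0))
  if (tau0 < 1e-12 || tau0 > 1e-9) {
    stop("`tau0` must lie within [1e-12, 1e-9] s, the physically admissible ",
         "attempt-time range for single-domain particles.", call. = FALSE)
  }
  structure(list(mu0 = mu0, kB = kB, tau0 = tau0, gamma_e = gamma_e),
            class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  mu0     = %.4g T m/A\n", x$mu0))
  cat(sprintf("  kB      = %.6g J/K\n", x$kB))
  cat(sprintf("  tau0    = %.3g s\n", x$tau0))
  cat(sprintf("  gamma_e = %.3g rad/(s T)\n", x$gamma_e))
  invisible(x)
}

#' Convert a field amplitude from mT to A/m
#'
#' Laboratory AC-field amplitudes are usually quoted as `mu0*H` in mT; the
#' models here work with `H` in A/m. The conversion uses the same `mu0` as the
#' rest of the package so that round-trips are exact.
#'
#' @param mT Field amplitude(s) as `mu0*H`, in millitesla.
#' @param constants A [physical_constants()] object.
#' @return Field amplitude(s) `H` in A/m.
#' @examples
#' mT_to_A_per_m(25)
#' @export
mT_to_A_per_m <- function(mT, constants = physical_constants()) {
  mT * 1e-3 / constants$mu0
}
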