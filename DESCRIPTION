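Package: magaggl
Title: Magnetic Agglomeration Size Thresholds and Hyperthermia Performance
    of Single-Domain Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the purely magnetic agglomeration of single-domain
    magnetic nanoparticles by comparing the Neel internal-relaxation time
    against the Brownian translational-diffusion and rotation timescales,
    and converts the comparison into anisotropy-dependent size thresholds.
    Benchmarks the timescale criterion against the dipolar-to-thermal
    energy ratio and the zero-field-cooled blocking-temperature criterion,
    simulates the associated heating performance (quasistatic
    Stoner-Wohlfarth loops and finite-temperature stochastic
    Landau-Lifshitz-Gilbert dynamic hysteresis with specific absorption
    rates), and derives the sample-concentration range over which the
    dilute, non-interacting assumptions hold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
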