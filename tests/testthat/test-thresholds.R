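# Threshold stage: d_aggl root finding, the Gamma and blocking criteria,
# and the coating/viscosity sensitivity scans.

test_that("d_aggl reproduces the three-anisotropy reference thresholds", {
  expected <- c(`8000` = 24.8, `11000` = 22.0, `15000` = 19.5)
  for (K in c(8e3, 11e3, 15e3)) {
    res <- find_d_aggl(K, MS = 4.8e5)
    expect_s3_class(res, "threshold_result")
    expect_equal(res$d_aggl * 1e9, expected[[as.character(K)]],
                 tolerance = 0.005)
    expect_identical(res$binding_mechanism, "diffusion")
    # ordering of the three criteria
    expect_lt(res$d_gamma, res$d_aggl)
    expect_lt(res$d_aggl, res$d_TB)
  }
})

test_that("at the root the Neel time equals the limiting mechanical time", {
  res <- find_d_aggl(11e3, MS = 4.8e5)
  p <- particle_spec(d = res$d_aggl, K = 11e3, MS = 4.8e5)
  tn <- neel_time(p, med_default)
  tlim <- max(diffusion_time(p, med_default),
              brown_rotation_time(p, med_default))
  expect_equal(tn, tlim, tolerance = 1e-6)
  # just above the root the moment outlasts both mechanical timescales
  p_up <- particle_spec(d = res$d_aggl + 0.1e-9, K = 11e3, MS = 4.8e5)
  expect_gt(neel_time(p_up, med_default),
            max(diffusion_time(p_up, med_default),
                brown_rotation_time(p_up, med_default)))
})

test_that("root finder agrees with a dense 0.01 nm scan oracle", {
  for (K in c(8e3, 11e3, 15e3)) {
    res <- find_d_aggl(K, MS = 4.8e5)
    # brute-force oracle: first sign change of the log ratio on a 0.01 nm grid
    ds <- seq(10e-9, 40e-9, by = 0.01e-9)
    prof <- suppressWarnings(relaxation_profile(K, 4.8e5, d_grid = ds))
    g <- log(prof$tau_N) - log(pmax(prof$tau_diff, prof$tau_B))
    i <- which(g[-1] > 0 & g[-length(g)] <= 0)[1]
    expect_lte(abs(res$d_aggl - ds[i]), 0.011e-9)
  }
})

test_that("d_aggl decreases with K and an error reports an empty bracket", {
  d <- vapply(c(8e3, 11e3, 15e3),
              function(K) find_d_aggl(K, MS = 4.8e5)$d_aggl, 0)
  expect_true(all(diff(d) < 0))
  expect_error(find_d_aggl(11e3, MS = 4.8e5, d_bracket = c(30e-9, 40e-9)),
               "no sign change")
})

test_that("Gamma = 1 contact diameter is K-free and scales as MS^(-2/3)", {
  d7 <- find_d_gamma(4.8e5)
  expect_equal(round(d7 * 1e9), 7)
  # closed form vs numeric root of the contact ratio
  g <- function(d) dipolar_thermal_ratio(
    particle_spec(d = d, K = 11e3, MS = 4.8e5), med_default, lcc = d) - 1
  d_num <- uniroot(g, c(2e-9, 20e-9), tol = 1e-15)$root
  expect_equal(d7, d_num, tolerance = 1e-9)
  expect_equal(find_d_gamma(2.4e5) / d7, 2^(2 / 3), tolerance = 1e-12)
})

test_that("coating thickens the threshold by sub-nm amounts", {
  sc <- scan_coating(11e3, 4.8e5, tnm_list = c(0, 5e-9, 20e-9))
  d <- vapply(sc, function(r) r$d_aggl, 0) * 1e9
  expect_equal(d[[1]], find_d_aggl(11e3, 4.8e5)$d_aggl * 1e9)
  expect_true(all(diff(d) > 0))
  expect_equal(d[[2]] - d[[1]], 0.2, tolerance = 0.5)   # ~ +0.2 nm
  expect_lt(d[[3]] - d[[1]], 1)                         # still sub-nm
})

test_that("viscosity shifts the threshold with the expected sign", {
  sv <- scan_viscosity(11e3, 4.8e5, eta_list = c(0.001, 0.00235, 0.044))
  d <- vapply(sv, function(r) r$d_aggl, 0) * 1e9
  expect_true(all(diff(d) > 0))           # non-decreasing in eta
  expect_equal(d[[2]] - d[[1]], 0.6, tolerance = 0.35)  # water ~0.5-0.6 nm down
  # identical viscosity -> identical result
  expect_equal(d[[2]], find_d_aggl(11e3, 4.8e5)$d_aggl * 1e9)
})

test_that("threshold table reproduces the reference comparison", {
  tab <- threshold_table(c(8e3, 11e3, 15e3), MS = 4.8e5)
  expect_equal(tab$d_aggl_nm, c(24.8, 22.0, 19.5))
  expect_equal(tab$d_TB_nm, c(29.1, 26.2, 23.6))
  expect_true(all(tab$d_TB_nm > tab$d_aggl_nm))
  expect_equal(attr(tab, "mean_gap_nm"), 4.2)
  # single-K degenerate case matches the scalar operations
  tab1 <- threshold_table(11e3, MS = 4.8e5)
  expect_equal(tab1$d_aggl_nm,
               round(find_d_aggl(11e3, 4.8e5)$d_aggl * 1e9, 1))
  expect_equal(tab1$d_TB_nm, round(blocking_size(11e3) * 1e9, 1))
})
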