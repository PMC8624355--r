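# Closed-form physics: dipole/thermal ratio, the three timescales, the
# diffusion distance, the blocking size, and their vectorized profile.

test_that("constructors enforce their domain invariants", {
  expect_error(particle_spec(d = -1e-9, K = 1e4, MS = 1e5), "`d`")
  expect_error(particle_spec(d = 1e-8, K = 0, MS = 1e5), "`K`")
  expect_error(particle_spec(d = 1e-8, K = 1e4, MS = 1e5, tnm = -1e-9), "tnm")
  expect_error(medium(T = 0), "`T`")
  expect_error(medium(eta = -1), "`eta`")
  expect_error(physical_constants(tau0 = 1e-8), "tau0")
  expect_error(physical_constants(tau0 = 1e-13), "tau0")

  p <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5, tnm = 5e-9)
  expect_equal(magnetic_volume(p), pi / 6 * (22e-9)^3)
  expect_equal(hydrodynamic_radius(p), 16e-9)
  # V_hyd >= V with equality iff tnm = 0
  expect_gt(hydrodynamic_volume(p), magnetic_volume(p))
  p0 <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5)
  expect_equal(hydrodynamic_volume(p0), magnetic_volume(p0))
  expect_gt(anisotropy_field(p), 0)
})

test_that("dipole/thermal ratio matches its definition and scalings", {
  # contact ratio ~1 at the 7 nm energy-criterion threshold
  p7 <- particle_spec(d = 7e-9, K = 11e3, MS = 4.8e5)
  expect_equal(dipolar_thermal_ratio(p7, med_default, lcc = p7$d), 1,
               tolerance = 0.05)
  # d = 22 nm touching spheres: ~32, and exactly (22/7)^3 times the 7 nm
  # value by the V^2/lcc^3 = d^3 contact scaling
  g22 <- dipolar_thermal_ratio(p_ref, med_default, lcc = p_ref$d)
  expect_equal(g22, 32, tolerance = 0.02)
  expect_equal(g22 / dipolar_thermal_ratio(p7, med_default, p7$d),
               (22 / 7)^3, tolerance = 1e-10)
  # zero moment -> zero ratio; K plays no role
  p_ms0 <- particle_spec(d = 22e-9, K = 11e3, MS = 0)
  expect_equal(dipolar_thermal_ratio(p_ms0, med_default, 22e-9), 0)
  p_k2 <- particle_spec(d = 22e-9, K = 99e3, MS = 4.8e5)
  expect_equal(dipolar_thermal_ratio(p_k2, med_default, 30e-9),
               dipolar_thermal_ratio(p_ref, med_default, 30e-9))
  # centres cannot overlap
  expect_error(dipolar_thermal_ratio(p_ref, med_default, lcc = 20e-9),
               "lcc")
})

test_that("Neel time follows the high-barrier expression", {
  # sigma = 1 closed form: (sqrt(pi)/2) e tau0
  kBT <- const_default$kB * 300
  d1 <- (6 * kBT / (pi * 11e3))^(1 / 3)
  p1 <- particle_spec(d = d1, K = 11e3, MS = 4.8e5)
  expect_equal(neel_time(p1, med_default),
               sqrt(pi) / 2 * exp(1) * const_default$tau0,
               tolerance = 1e-12)
  # reference particle: ~6e-4 s (sigma ~ 14.8)
  expect_equal(neel_time(p_ref, med_default), 6e-4, tolerance = 0.05)
  # higher K -> more stable moment at equal size
  p8 <- particle_spec(d = 22e-9, K = 8e3, MS = 4.8e5)
  p15 <- particle_spec(d = 22e-9, K = 15e3, MS = 4.8e5)
  expect_gt(neel_time(p15, med_default), neel_time(p8, med_default))
  # below the validity barrier: warn, still evaluate
  tiny <- particle_spec(d = 6e-9, K = 8e3, MS = 4.8e5)
  expect_warning(tn <- neel_time(tiny, med_default), "sigma")
  expect_gt(tn, 0)
})

test_that("diffusion distance closes the Gamma = 1 identity", {
  # <x> for the reference particle ~70 nm
  expect_equal(diffusion_distance(p_ref, med_default) * 1e9, 70,
               tolerance = 0.01)
  # Gamma(lcc = <x>) = 1 to machine precision across parameter sets
  for (K in c(8e3, 15e3)) for (d in c(15e-9, 22e-9, 35e-9)) {
    p <- particle_spec(d = d, K = K, MS = 4.8e5)
    x <- diffusion_distance(p, med_default)
    expect_equal(dipolar_thermal_ratio(p, med_default, lcc = x), 1,
                 tolerance = 1e-12)
  }
  p_ms0 <- particle_spec(d = 22e-9, K = 11e3, MS = 0)
  expect_equal(diffusion_distance(p_ms0, med_default), 0)
})

test_that("diffusion and rotation times match derived values and scalings", {
  # derived values at d = 22 nm, bare particle
  expect_equal(diffusion_time(p_ref, med_default), 6e-4, tolerance = 0.05)
  expect_equal(brown_rotation_time(p_ref, med_default), 9.5e-6,
               tolerance = 0.01)
  # linear in viscosity
  expect_equal(diffusion_time(p_ref, medium(eta = 2 * 0.00235)),
               2 * diffusion_time(p_ref, med_default), tolerance = 1e-12)
  # linear in R_hyd through the coating
  p_c <- particle_spec(d = 22e-9, K = 11e3, MS = 4.8e5, tnm = 5e-9)
  expect_equal(diffusion_time(p_c, med_default) /
                 diffusion_time(p_ref, med_default),
               16 / 11, tolerance = 1e-12)
  # unit construction for tau_B: V_hyd = kB T/(3 eta) -> 1 s
  kBT <- const_default$kB * 300
  d_unit <- 2 * (kBT / (3 * 0.00235) * 3 / (4 * pi))^(1 / 3)
  p_unit <- particle_spec(d = d_unit, K = 11e3, MS = 4.8e5)
  expect_equal(brown_rotation_time(p_unit, med_default), 1,
               tolerance = 1e-12)
})

test_that("blocking size inverts TB = KV/25kB and scales as K^(-1/3)", {
  expect_equal(blocking_size(11e3) * 1e9, 26.2, tolerance = 0.002)
  expect_equal(blocking_size(15e3) * 1e9, 23.6, tolerance = 0.002)
  expect_equal(blocking_size(8 * 11e3), blocking_size(11e3) / 2,
               tolerance = 1e-12)
})

test_that("relaxation profile is vectorized, monotone and scalar-consistent", {
  d_grid <- seq(8, 40, by = 0.5) * 1e-9
  prof <- suppressWarnings(
    relaxation_profile(11e3, 4.8e5, d_grid = d_grid))
  expect_equal(nrow(prof), length(d_grid))
  expect_true(all(unlist(prof[c("tau_N", "tau_B", "tau_diff")]) > 0))
  expect_true(all(diff(prof$tau_N) > 0))
  expect_true(all(diff(prof$tau_B) > 0))
  expect_true(all(diff(prof$tau_diff) > 0))
  # element-wise agreement with the scalar operations
  for (i in c(1L, 30L, length(d_grid))) {
    p <- particle_spec(d = d_grid[i], K = 11e3, MS = 4.8e5)
    expect_equal(prof$tau_N[i],
                 suppressWarnings(neel_time(p, med_default)))
    expect_equal(prof$tau_B[i], brown_rotation_time(p, med_default))
    expect_equal(prof$tau_diff[i], diffusion_time(p, med_default))
    expect_equal(prof$gamma[i],
                 dipolar_thermal_ratio(p, med_default, lcc = p$d))
    expect_equal(prof$x_diff[i], diffusion_distance(p, med_default))
  }
  # the Gamma column has no K dependence
  prof2 <- suppressWarnings(
    relaxation_profile(15e3, 4.8e5, d_grid = d_grid))
  expect_equal(prof$gamma, prof2$gamma)
  # tau_N grows with K everywhere on the grid
  expect_true(all(prof2$tau_N > prof$tau_N))
  expect_error(relaxation_profile(11e3, 4.8e5, d_grid = c(2e-8, 1e-8)),
               "increasing")
})

test_that("profile CSV export writes display-unit columns", {
  prof <- relaxation_profile(11e3, 4.8e5, d_grid = c(20, 25, 30) * 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  got <- utils::read.csv(path)
  expect_named(got, c("d_nm", "tau_N_s", "tau_B_s", "tau_diff_s", "gamma",
                      "x_diff_nm"))
  expect_equal(got$d_nm, c(20, 25, 30))
  expect_equal(got$tau_diff_s, prof$tau_diff, tolerance = 1e-6)
})
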