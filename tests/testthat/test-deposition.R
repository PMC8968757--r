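test_that("transport properties match aerosol-mechanics oracles", {
  tp <- particle_transport(c(1, 2, 100))
  # continuum limit: slip factor -> 1 for large particles
  expect_equal(tp$slip_factor[3], 1, tolerance = 2e-3)
  # settling scales as d^2 * Cc; slip decreases with size so the 2:1 um
  # ratio sits just below the no-slip value of 4 (frozen oracle: 3.696)
  ratio <- tp$settling_velocity[2] / tp$settling_velocity[1]
  expect_equal(ratio, 3.696, tolerance = 0.015)
  expect_lt(ratio, 4)
  # Stokes-Einstein at body temperature, 1 um unit-density sphere
  expect_equal(tp$diffusion_coefficient[1], 2.8e-7, tolerance = 0.15)
  expect_error(particle_transport(-1), class = "aerodose_invalid_input")
})

test_that("regional fractions always close to unity", {
  lung <- lung_model()
  br <- breathing_pattern()
  for (d in c(0.01, 0.1, 0.5, 1, 5, 10)) {
    r <- monodisperse_deposition(d, lung, br)
    expect_equal(r$head_fraction + r$tracheobronchial_fraction +
                   r$pulmonary_fraction + r$exhaled_fraction, 1,
                 tolerance = 1e-12)
    expect_equal(r$total_fraction, r$head_fraction +
                   r$tracheobronchial_fraction + r$pulmonary_fraction)
    expect_true(all(unlist(r[1:5]) >= 0 & unlist(r[1:5]) <= 1))
  }
})

test_that("total deposition is U-shaped with its minimum between 0.1 and 1 um", {
  d <- c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  tot <- vapply(d, function(x) monodisperse_deposition(x)$total_fraction,
                numeric(1))
  imin <- which.min(tot)
  expect_gte(d[imin], 0.1)
  expect_lte(d[imin], 1)
  # diffusion-dominated and impaction-dominated limits
  expect_gt(tot[d == 0.01], tot[d == 0.2])
  expect_gt(tot[d == 10], tot[d == 1])
})

test_that("coarse particles deposit in the head, not the deep lung", {
  r <- monodisperse_deposition(10, breathing = breathing_pattern(mouth_fraction = 1))
  expect_gt(r$head_fraction, r$pulmonary_fraction)
})

test_that("total deposition does not decrease with tidal volume", {
  tots <- vapply(c(400, 500, 625, 750, 1000), function(v) {
    monodisperse_deposition(1, breathing = breathing_pattern(tidal_volume = v))$total_fraction
  }, numeric(1))
  expect_true(all(diff(tots) >= -1e-9))
})

test_that("polydisperse integration collapses to monodisperse at GSD 1", {
  mono <- monodisperse_deposition(0.93)
  poly <- polydisperse_deposition(lognormal_psd(0.93, 1.0))
  for (f in c("head_fraction", "tracheobronchial_fraction",
              "pulmonary_fraction", "total_fraction")) {
    expect_equal(poly[[f]], mono[[f]], tolerance = 1e-3)
  }
})

test_that("quadrature is converged at the default size", {
  psd <- lognormal_psd(0.93, 1.43)
  r32 <- polydisperse_deposition(psd, n_quadrature = 32)
  r64 <- polydisperse_deposition(psd, n_quadrature = 64)
  r128 <- polydisperse_deposition(psd, n_quadrature = 128)
  for (f in c("head_fraction", "tracheobronchial_fraction",
              "pulmonary_fraction", "total_fraction", "exhaled_fraction")) {
    expect_lt(abs(r64[[f]] - r32[[f]]), 0.005)
    expect_lt(abs(r128[[f]] - r64[[f]]), 0.005)
  }
})

test_that("exhaled fraction is the complement of total deposition", {
  r <- polydisperse_deposition(lognormal_psd(1.0, 1.43))
  expect_equal(exhaled_fraction(r), 1 - r$total_fraction)
  r0 <- r; r0$total_fraction <- 0
  expect_equal(exhaled_fraction(r0), 1)
  r1 <- r; r1$total_fraction <- 1
  expect_equal(exhaled_fraction(r1), 0)
  r25 <- r; r25$total_fraction <- 0.25
  expect_equal(exhaled_fraction(r25), 0.75)
})

test_that("lung model scales morphometry to FRC with doubling airway counts", {
  lung <- lung_model(frc = 3300)
  gen <- lung$generations
  expect_equal(gen$count, 2^(0:23))
  expect_true(all(gen$length_cm > 0 & gen$diameter_cm > 0))
  expect_equal(sum(gen$volume_cm3) + lung$alveolar_volume, 3300,
               tolerance = 1e-9)
  # volume scales linearly with FRC
  big <- lung_model(frc = 4950)
  expect_equal(sum(big$generations$volume_cm3) + big$alveolar_volume, 4950,
               tolerance = 1e-9)
})
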