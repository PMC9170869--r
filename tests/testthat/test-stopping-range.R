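test_that("Bethe mass stopping power matches an independent evaluation", {
  al <- material_aluminum()
  hav <- material_havar()
  teo2 <- material_teo2()

  # frozen values from the independent K-parameterized evaluation
  expect_equal(mass_stopping_power(al, 10), 34.282, tolerance = 1e-4)
  expect_equal(mass_stopping_power(hav, 18), 18.420, tolerance = 1e-4)

  for (E in c(2, 5, 10, 14.8, 18, 25, 30)) {
    expect_equal(mass_stopping_power(al, E), oracle_stopping(c(Al = 1), E),
                 tolerance = 1e-4)
    expect_equal(mass_stopping_power(teo2, E), oracle_stopping(TEO2_FR, E),
                 tolerance = 1e-4)
    expect_equal(mass_stopping_power(hav, E), oracle_stopping(HAVAR_FR, E),
                 tolerance = 1e-4)
  }
})

test_that("mass stopping power is density-independent and decreasing in energy", {
  lo <- material_teo2(density = 5.65)
  hi <- material_teo2(density = 11.3)
  E <- seq(5, 30, by = 0.5)
  expect_equal(mass_stopping_power(lo, E), mass_stopping_power(hi, E),
               tolerance = 1e-14)
  for (m in list(lo, material_aluminum(), material_havar(),
                 material_molybdenum())) {
    expect_true(all(diff(mass_stopping_power(m, E)) < 0))
    expect_true(all(mass_stopping_power(m, E) > 0))
  }
})

test_that("energies outside the validity window are rejected, not extrapolated", {
  al <- material_aluminum()
  expect_error(mass_stopping_power(al, 0.05), "validity window")
  expect_error(mass_stopping_power(al, 35), "validity window")
  expect_error(csda_range(al, 0.05), "validity window")
  expect_error(stopping_model(low_energy_cutoff = 0.05), ">= 0.1")
})

test_that("CSDA range matches brute-force integration and is strictly increasing", {
  al <- material_aluminum()
  teo2 <- material_teo2()

  expect_equal(csda_range(al, 10), oracle_range_um(c(Al = 1), 2.7, 10),
               tolerance = 1e-3)
  expect_equal(csda_range(teo2, 14.8), 782, tolerance = 5e-3)

  # oracle equivalence on randomized (material, energy) cases
  mats <- list(list(m = al, fr = c(Al = 1), rho = 2.7),
               list(m = teo2, fr = TEO2_FR, rho = 5.65),
               list(m = material_havar(), fr = HAVAR_FR, rho = 8.3))
  set.seed(42)
  for (i in seq_len(20)) {
    pick <- mats[[sample.int(3, 1)]]
    E <- runif(1, 2, 28)
    expect_equal(csda_range(pick$m, E),
                 oracle_range_um(pick$fr, pick$rho, E),
                 tolerance = 1e-3)
  }

  E <- seq(1, 30, by = 0.25)
  expect_true(all(diff(csda_range(teo2, E)) > 0))
  # vanishing integral at the cutoff
  expect_lt(csda_range(teo2, stopping_model()$low_energy_cutoff), 3)
})

test_that("slab degradation: identity, ordering, additivity and range inversion", {
  hav <- material_havar()
  teo2 <- material_teo2()

  expect_equal(energy_after_slab(hav, 0, 18), 18)
  e1 <- energy_after_slab(hav, 0.2, 18)
  expect_lt(e1, 18)
  expect_equal(e1, 14.8, tolerance = 0.3 / 14.8)

  expect_error(energy_after_slab(hav, -0.1, 18), "non-negative")

  # a 1 mm TeO2 slab absorbs a 14.8 MeV beam outright
  expect_true(is_stopped(energy_after_slab(teo2, 1.0, 14.8)))
  expect_false(is_stopped(energy_after_slab(teo2, 0.5, 14.8)))

  # additivity: slab a then b == slab (a+b), within 1e-3 MeV
  set.seed(7)
  mats <- list(hav, teo2, material_aluminum())
  for (i in seq_len(15)) {
    m <- mats[[sample.int(3, 1)]]
    E <- runif(1, 8, 25)
    total_mm <- csda_range(m, E) / 1000 * 0.8      # stay below the range
    a <- runif(1, 0.1, 0.9) * total_mm
    b <- total_mm - a
    two <- energy_after_slab(m, b, energy_after_slab(m, a, E))
    one <- energy_after_slab(m, total_mm, E)
    expect_equal(two, one, tolerance = 1e-3 / one)
  }

  # inversion: R(E_out) == R(E_in) - t, within 0.1%
  for (tmm in c(0.05, 0.2, 0.35)) {
    eo <- energy_after_slab(hav, tmm, 18)
    expect_equal(csda_range(hav, eo), csda_range(hav, 18) - tmm * 1000,
                 tolerance = 1e-3)
  }
})

test_that("energy window in target closes at the cutoff when the beam stops", {
  teo2 <- material_teo2()
  w <- energy_window_in_target(teo2, 0.5, 14.8)
  expect_false(w$fully_stopped)
  expect_gt(w$energy_out_MeV, stopping_model()$low_energy_cutoff)
  w2 <- energy_window_in_target(teo2, 1.0, 14.8)
  expect_true(w2$fully_stopped)
  expect_equal(w2$energy_out_MeV, stopping_model()$low_energy_cutoff)
  w3 <- energy_window_in_target(teo2, 0, 14.8)
  expect_equal(w3$energy_in_MeV, 14.8)
  expect_equal(w3$energy_out_MeV, 14.8)
  expect_false(w3$fully_stopped)
})

test_that("straggled range distribution is reproducible and brackets the CSDA range", {
  teo2 <- material_teo2()
  d1 <- simulate_range_distribution(teo2, 14.8, 1e5, seed = 1)
  d1b <- simulate_range_distribution(teo2, 14.8, 1e5, seed = 1)
  expect_identical(d1$weights, d1b$weights)
  expect_identical(d1$mode_um, d1b$mode_um)

  expect_gt(d1$mode_um, 770)
  expect_lt(d1$mode_um, 930)
  # mode close to the CSDA range relative to the straggling width
  expect_lt(abs(d1$mode_um - d1$csda_um), 3 * d1$straggling_sd_um)

  d2 <- simulate_range_distribution(teo2, 14.8, 1e5, seed = 2)
  expect_lt(abs(d2$mode_um - d1$mode_um), 3)

  expect_error(simulate_range_distribution(teo2, 14.8, 50, seed = 1), ">= 100")

  # simulation leaves the global RNG untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_range_distribution(teo2, 14.8, 200, seed = 9))
  expect_identical(.Random.seed, before)
})
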