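# Thick-target activation against analytic limits and a depth-slab oracle.

flat_xs <- function(sigma_mb = 100) {
  cross_section_table("flat", get_nuclide("I-124"),
                      c(1, 15, 30), rep(sigma_mb, 3), source = "synthetic")
}

test_that("thin-target limit reproduces the closed-form activation", {
  teo2 <- material_teo2()
  xs <- flat_xs(100)
  tgt <- target_spec(teo2, 0.002, parent_abundance = 0.0474)  # ~0.02 MeV loss
  beam <- beam_spec(14.8, 10, 1.5)
  y <- thick_target_eob_activity(xs, tgt, beam)

  n_parent_per_g <- 6.02214076e23 * tgt$parent_mass_fraction * 0.0474 / 127.60
  n_areal <- n_parent_per_g * 5.65 * 0.002 / 10            # atoms/cm^2
  lam <- get_nuclide("I-124")$decay_constant_per_h
  a_closed <- 10e-6 / 1.602176634e-19 * n_areal * 100e-27 *
    (1 - exp(-lam * 1.5)) / 1e6
  expect_equal(y$eob_activity_MBq, a_closed, tolerance = 1e-3)
  expect_lt(abs(y$energy_window_MeV[1] - y$energy_window_MeV[2]), 0.1)
})

test_that("EOB activity matches the depth-slab brute-force oracle", {
  teo2 <- material_teo2()
  xs <- calibrated_toy_xs()
  lam <- xs$product$decay_constant_per_h

  run_case <- function(thick_mm, E, cur, th, abund) {
    tgt <- target_spec(teo2, thick_mm, parent_abundance = abund)
    y <- suppressWarnings(
      thick_target_eob_activity(xs, tgt, beam_spec(E, cur, th)))
    a_oracle <- oracle_slab_activity_MBq(
      xs, TEO2_FR, 5.65, thick_mm,
      6.02214076e23 * tgt$parent_mass_fraction * abund / 127.60,
      E, cur, th, lam)
    expect_equal(y$eob_activity_MBq, a_oracle, tolerance = 5e-3)
  }

  # the headline case: 0.5 mm target, degraded beam, 10 uA, 1.5 h
  run_case(0.5, 14.8, 10, 1.5, 0.0474)

  set.seed(11)
  for (i in seq_len(6)) {
    run_case(runif(1, 0.1, 1.0), runif(1, 10, 18), runif(1, 5, 20),
             runif(1, 0.5, 4), runif(1, 0.04, 1))
  }
})

test_that("EOB activity is linear in current and saturates in irradiation time", {
  teo2 <- material_teo2()
  set.seed(5)
  for (i in seq_len(25)) {
    xs <- calibrated_toy_xs(peak_energy = runif(1, 11, 15))
    tgt <- target_spec(teo2, runif(1, 0.1, 1), parent_abundance = runif(1, 0.04, 1))
    E <- runif(1, 8, 18); cur <- runif(1, 1, 20); th <- runif(1, 0.5, 5)
    y1 <- suppressWarnings(thick_target_eob_activity(xs, tgt, beam_spec(E, cur, th)))
    y2 <- suppressWarnings(thick_target_eob_activity(xs, tgt, beam_spec(E, 2 * cur, th)))
    expect_equal(y2$eob_activity_MBq, 2 * y1$eob_activity_MBq, tolerance = 1e-12)
    y3 <- suppressWarnings(thick_target_eob_activity(xs, tgt, beam_spec(E, cur, 2 * th)))
    expect_gte(y3$eob_activity_MBq, y1$eob_activity_MBq)
    expect_lte(y1$eob_activity_MBq, y1$saturation_activity_MBq)
  }

  # saturation: 20 vs 40 half-lives differ by < 0.01%
  xs <- calibrated_toy_xs()
  thalf <- xs$product$half_life_h
  tgt <- target_spec(teo2, 0.5, parent_abundance = 0.0474)
  y20 <- thick_target_eob_activity(xs, tgt, beam_spec(14.8, 10, 20 * thalf))
  y40 <- thick_target_eob_activity(xs, tgt, beam_spec(14.8, 10, 40 * thalf))
  expect_equal(y20$eob_activity_MBq, y40$eob_activity_MBq, tolerance = 1e-4)
  expect_equal(y40$eob_activity_MBq, y40$saturation_activity_MBq,
               tolerance = 1e-4)
})

test_that("EOB activity scales exactly linearly with parent abundance", {
  teo2 <- material_teo2()
  xs <- calibrated_toy_xs()
  beam <- beam_spec(14.8, 10, 1.5)
  nat <- thick_target_eob_activity(
    xs, target_spec(teo2, 0.5, parent_abundance = 0.0474), beam)
  enr <- thick_target_eob_activity(
    xs, target_spec(teo2, 0.5, parent_abundance = 0.995), beam)
  expect_equal(enr$eob_activity_MBq / nat$eob_activity_MBq, 0.995 / 0.0474,
               tolerance = 1e-12)
})

test_that("yield normalization divides EOB activity by integrated charge", {
  expect_equal(yield_per_uAh(35.594, 15, 1.5), 1.582, tolerance = 1e-3)
  expect_equal(yield_per_uAh(23.199, 10, 1.5), 1.547, tolerance = 1e-3)
  expect_equal(yield_per_uAh(0, 10, 1.5), 0)
  expect_error(yield_per_uAh(10, 0, 1.5), "> 0")
  expect_error(yield_per_uAh(10, 10, 0), "> 0")
})

test_that("sweeps cover the foil x target grid with stopped rows flagged", {
  teo2 <- material_teo2()
  hav <- material_havar()
  xs <- calibrated_toy_xs()
  tgt <- target_spec(teo2, 0.5, parent_abundance = 0.0474)
  beam <- beam_spec(18, 10, 1.5)

  # zero-thickness foil column equals the no-degrader computation
  sw <- sweep_production(xs, tgt, c(0.3, 0.5), hav, c(0, 0.2), beam)
  expect_equal(nrow(sw), 4)
  direct <- thick_target_eob_activity(xs, tgt, beam)
  row0 <- sw[sw$foil_mm == 0 & sw$target_mm == 0.5, ]
  expect_equal(row0$eob_MBq, direct$eob_activity_MBq, tolerance = 1e-12)
  expect_equal(row0$energy_at_target_MeV, 18)

  # a foil thicker than the proton range absorbs the beam
  sw2 <- sweep_production(xs, tgt, 0.5, hav, c(0.2, 3), beam)
  expect_false(sw2$foil_stopped[sw2$foil_mm == 0.2])
  expect_true(sw2$foil_stopped[sw2$foil_mm == 3])
  expect_equal(sw2$eob_MBq[sw2$foil_mm == 3], 0)

  # doubling the current doubles every yield cell
  beam2 <- beam_spec(18, 20, 1.5)
  sw3 <- sweep_production(xs, tgt, c(0.3, 0.5), hav, c(0, 0.2), beam2)
  expect_equal(sw3$eob_MBq, 2 * sw$eob_MBq, tolerance = 1e-12)
})

test_that("for a thin target the optimal Havar thickness sits at 0.2-0.3 mm", {
  # with the excitation function peaked near 13 MeV, a thin (< 0.5 mm)
  # target wants the beam placed on the peak, i.e. a 0.2-0.3 mm degrader
  teo2 <- material_teo2()
  xs <- calibrated_toy_xs()
  tgt <- target_spec(teo2, 0.3, parent_abundance = 0.0474)
  sw <- sweep_production(xs, tgt, 0.3, material_havar(),
                         seq(0.05, 0.5, by = 0.05), beam_spec(18, 10, 1.5))
  best <- sw$foil_mm[which.max(sw$eob_MBq)]
  expect_gte(best, 0.2)
  expect_lte(best, 0.3)
})
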