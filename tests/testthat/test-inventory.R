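test_that("single-activity decay follows A0 * 2^(-t/T)", {
  n10 <- nuclide("X", 10, "h")
  expect_equal(decay_activity(100, n10, 10), 50)
  expect_equal(decay_activity(100, n10, 0), 100)
  expect_error(decay_activity(100, n10, -1), "back-extrapolation")

  i124 <- nuclide("I-124", 4.2, "d")
  expect_equal(decay_activity(214.711, i124, 72), 130.499,
               tolerance = 1.5e-2)
})

test_that("inventory decay is entry-wise with the semigroup property", {
  inv <- random_inventory(12, c(0.01, 2000), c(0.1, 5000), seed = 3)
  for (split in list(c(1, 71), c(36, 36), c(0.5, 0.5))) {
    two <- decay_inventory(decay_inventory(inv, split[1]), split[2])
    one <- decay_inventory(inv, sum(split))
    expect_equal(two$activities_MBq, one$activities_MBq, tolerance = 1e-12)
    expect_equal(two$reference_time_h, one$reference_time_h)
  }
  # total activity strictly decreases with time
  totals <- vapply(c(0, 1, 10, 100, 500), function(t)
    total_activity(decay_inventory(inv, t)), 0)
  expect_true(all(diff(totals) < 0))
  # negligibility flag
  d <- decay_inventory(inv, 5000)
  expect_true(any(d$negligible))
  expect_identical(names(d$negligible), names(d$activities_MBq))
})

test_that("totals and fractions reproduce the reference inventories", {
  inv6 <- load_fixture("inventory_enriched_10uA")
  expect_equal(total_activity(inv6), 5845.112, tolerance = 0.01 / 5845)
  inv8 <- load_fixture("inventory_natural_10uA")
  expect_equal(total_activity(inv8), 8377.059, tolerance = 0.01 / 8377)

  d8 <- decay_inventory(inv8, 72)
  expect_equal(activity_fraction(d8, "I-124"), 41.47, tolerance = 1 / 41.47)
  d6 <- decay_inventory(inv6, 72)
  expect_equal(activity_fraction(d6, "I-124"), 87.71, tolerance = 1 / 87.71)

  solo <- activity_inventory(nuclide("I-124", 4.2, "d"), 5)
  expect_equal(activity_fraction(solo, "I-124"), 100)
  expect_equal(total_activity(solo), 5)
  expect_error(activity_fraction(solo, "I-999"), "not in the inventory")
})

test_that("decayed totals match the published 72 h inventories", {
  d8 <- decay_inventory(load_fixture("inventory_natural_10uA"), 72)
  expect_equal(total_activity(d8), 33.966, tolerance = 1e-2)
  d9 <- decay_inventory(load_fixture("inventory_natural_15uA"), 71.49)
  expect_equal(total_activity(d9), 50.32, tolerance = 2e-2)
})

test_that("purity solver matches the scan oracle and the two-nuclide closed form", {
  # randomized product/impurity inventories with a guaranteed crossing
  set.seed(21)
  for (i in seq_len(8)) {
    prod <- nuclide("PROD", runif(1, 80, 200), "h")
    imp <- nuclide("IMP", runif(1, 5, 25), "h")
    slow <- nuclide("SLOW", runif(1, 200, 1200), "h")
    inv <- activity_inventory(list(prod, imp, slow),
                              c(runif(1, 50, 300), runif(1, 20, 500),
                                runif(1, 0.5, 5)))
    res <- purity_time(inv, "IMP", product = "PROD")
    t_scan <- oracle_purity_scan(inv, "IMP")
    if (is.na(t_scan)) {
      expect_identical(res$status, "no_crossing")
    } else {
      expect_identical(res$status, "solved")
      expect_lt(abs(res$release_time_h - t_scan), 0.02)
      expect_lt(abs(res$impurity_fraction - 0.0035), 1e-6)
    }
  }

  # two-nuclide closed form: t = ln(r0 (1-theta)/theta) / (lam_imp - lam_prod)
  prod <- nuclide("PROD", 100.8, "h")
  imp <- nuclide("IMP", 13.2, "h")
  inv2 <- activity_inventory(list(prod, imp), c(100, 150))
  res2 <- purity_time(inv2, "IMP", product = "PROD")
  theta <- 0.0035
  r0 <- 150 / 100
  t_closed <- log(r0 * (1 - theta) / theta) /
    (imp$decay_constant_per_h - prod$decay_constant_per_h)
  expect_equal(res2$release_time_h, t_closed, tolerance = 1e-4)
  expect_equal(oracle_purity_scan(inv2, "IMP"), t_closed, tolerance = 0.02 / t_closed)
})

test_that("purity solver reports already-pure and no-crossing outcomes", {
  prod <- nuclide("PROD", 100, "h")
  imp <- nuclide("IMP", 10, "h")
  clean <- activity_inventory(list(prod, imp), c(100, 0))
  res <- purity_time(clean, "IMP", product = "PROD")
  expect_identical(res$status, "already_pure")
  expect_equal(res$release_time_h, 0.5)

  # impurity longer-lived than everything else: fraction only grows
  long_imp <- activity_inventory(list(nuclide("PROD", 5, "h"),
                                      nuclide("IMP", 5000, "h")),
                                 c(1000, 30))
  res2 <- purity_time(long_imp, "IMP", product = "PROD")
  expect_identical(res2$status, "no_crossing")
  expect_length(res2$fraction_range, 2)
  expect_error(purity_time(long_imp, "GHOST"), "not in the inventory")
})

test_that("relative difference follows |sim - exp| / exp * 100", {
  expect_equal(relative_difference(20.72, 33.30), 60.71, tolerance = 1e-4)
  expect_equal(relative_difference(56.61, 50.32), 11.11, tolerance = 1e-3)
  expect_equal(relative_difference(7.3, 7.3), 0)
  expect_error(relative_difference(0, 10), "> 0")
})

test_that("inventories round-trip through CSV", {
  inv <- load_fixture("inventory_natural_15uA")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_inventory_csv(inv, tmp)
  back <- read_inventory_csv(tmp)
  expect_equal(back$activities_MBq, inv$activities_MBq, tolerance = 1e-12)
  expect_equal(vapply(back$nuclides, `[[`, 0, "half_life_h"),
               vapply(inv$nuclides, `[[`, 0, "half_life_h"),
               tolerance = 1e-12)
})
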