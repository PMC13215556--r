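test_that("theoretical oxygen demand matches reaction balancing", {
  # biomass: C5H7O2N + 5 O2 -> 5 CO2 + 2 H2O + NH3; 160/113
  expect_equal(round(thod_per_gram("C5H7O2N"), 2), 1.42)
  # glucose: C6H12O6 + 6 O2 -> 6 CO2 + 6 H2O; 192/180
  expect_equal(thod_per_gram("C6H12O6"), 192 / 180)
  # H2 + 1/2 O2 -> H2O; 16/2
  expect_equal(thod_per_gram("H2"), 8)
  # CH4 + 2 O2 -> CO2 + 2 H2O; 64/16
  expect_equal(thod_per_gram("CH4"), 4)
  # acetate: C2H4O2 + 2 O2; 64/60
  expect_equal(thod_per_gram("C2H4O2"), 64 / 60)
})

test_that("ThOD is scale invariant, positive, and decreasing in oxygen", {
  set.seed(11)
  for (i in 1:25) {
    f <- elemental_formula(C = sample(1:12, 1), H = sample(1:20, 1),
                           O = sample(0:6, 1), N = sample(0:2, 1))
    thod <- thod_per_gram(f)
    doubled <- elemental_formula(C = 2 * f[["C"]], H = 2 * f[["H"]],
                                 O = 2 * f[["O"]], N = 2 * f[["N"]])
    expect_equal(thod_per_gram(doubled), thod)
    if (thod > 0) {
      more_o <- elemental_formula(C = f[["C"]], H = f[["H"]],
                                  O = f[["O"]] + 1, N = f[["N"]])
      expect_lt(thod_per_gram(more_o), thod)
    }
  }
  expect_gt(thod_per_gram("C3H8"), 0)
})

test_that("formula parsing and validation reject malformed input", {
  expect_equal(as.integer(parse_formula("C5H7O2N")), c(5L, 7L, 2L, 1L))
  expect_equal(molar_mass("C5H7O2N"), 113)
  expect_equal(format(parse_formula("C6H12O6")), "C6H12O6")
  expect_error(parse_formula("C6S2"), "only C, H, O, N")
  expect_error(parse_formula(""), "non-empty")
  expect_error(elemental_formula(), "at least one atom")
  expect_error(elemental_formula(C = -1, H = 4), "non-negative")
})

test_that("cod_of_mass is linear with correct units", {
  glucose <- nutrient_spec("glucose", "sugar", "C6H12O6")
  expect_equal(cod_of_mass(0, glucose), 0)
  expect_equal(cod_of_mass(100, glucose), 100 * 192 / 180)
  biomass <- nutrient_spec("biomass", "biomass", "C5H7O2N")
  expect_equal(round(cod_of_mass(1, biomass), 2), 1.42)
  # linearity
  expect_equal(cod_of_mass(7, glucose), 7 * cod_of_mass(1, glucose))
  expect_error(cod_of_mass(-1, glucose), "non-negative")
})

test_that("energy conversion round-trips and rejects bad factors", {
  expect_equal(cod_to_kcal(0, 3.2), 0)
  expect_equal(cod_to_kcal(10, 3.2), 32)
  expect_equal(kcal_to_cod(cod_to_kcal(12.7, 2.9), 2.9), 12.7)
  expect_error(cod_to_kcal(1, 0), "positive")
  expect_error(kcal_to_cod(1, -2), "positive")
})

test_that("nutrient_spec cross-checks explicit COD against the formula", {
  expect_silent(nutrient_spec("g", "sugar", "C6H12O6",
                              cod_specific = 1.066))
  expect_error(nutrient_spec("g", "sugar", "C6H12O6", cod_specific = 1.2),
               "disagrees")
  expect_error(nutrient_spec("x", "sugar"), "formula or an explicit")
})

test_that("registry ships consistent specific COD and reads from CSV", {
  reg <- default_nutrient_registry()
  expect_true(all(reg$cod_specific > 0))
  expect_equal(registry_lookup(reg, "ch4")$cod_specific, 4)
  expect_error(registry_lookup(reg, "nope"), "unknown nutrient")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(reg)[c("id", "nutrient_class", "formula")],
                   path, row.names = FALSE)
  reg2 <- read_nutrient_registry(path)
  expect_equal(reg2$cod_specific, reg$cod_specific, tolerance = 1e-12)
})

test_that("methane volume conversion follows the ideal gas law", {
  # 1 mol at 25 C, 1 atm occupies 24.465 L -> 64 gCOD
  expect_equal(ch4_volume_to_gcod(24465.4), 64, tolerance = 1e-3)
  expect_equal(ch4_volume_to_gcod(0), 0)
})
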