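# Formula-level derivations. Expected values are closed forms evaluated by
# hand or anchored to the printed experimental ranges.

test_that("buoyant_force applies the buoyancy correction and validates inputs", {
  expect_equal(buoyant_force(0), 0)
  # 1 mg steel in aqueous medium: m g (1 - 1/7.8) = 8.552 uN, rounds to 9
  expect_equal(buoyant_force(1), 1 * 9.81 * (1 - 1 / 7.8))
  expect_equal(round(buoyant_force(1)), 9)
  expect_equal(round(buoyant_force(2)), 17)
  # linear and monotone in mass; reduces to m g as medium density -> 0
  m <- c(0.5, 1, 1.5, 2)
  expect_equal(buoyant_force(m), m * buoyant_force(1))
  expect_equal(buoyant_force(1, medium_density_g_cm3 = 1e-9), 9.81,
               tolerance = 1e-6)
  expect_error(buoyant_force(1, object_density_g_cm3 = 0.9), "float")
})

test_that("branch_tension splits the unabsorbed force across branches", {
  expect_equal(round(branch_tension(9, 0.25, 2), 1), 3.4)
  expect_equal(branch_tension(5, 0, 1), 5)
  expect_equal(round(branch_tension(buoyant_force(2), 0.25, 2), 1), 6.4)
  expect_error(branch_tension(1, 1, 2))
})

test_that("applied_stress is 4F / (pi d^2) and relates to strain via E = 1 kPa", {
  expect_equal(applied_stress(0, 0.3), 0)
  # 1 mg weight on a 0.33 mm gut is ~100 Pa
  expect_equal(applied_stress(buoyant_force(1), 0.33), 100, tolerance = 0.01)
  expect_equal(applied_stress(buoyant_force(1), 0.40), 68, tolerance = 0.01)
  expect_error(applied_stress(1, 0), "diameter")
  # stress * cross-section = force to machine precision; halving d quadruples
  f <- 8.55; d <- 0.37
  expect_equal(applied_stress(f, d) * pi * d^2 / 4, f)
  expect_equal(applied_stress(f, d / 2), 4 * applied_stress(f, d))
  # printed stress/strain pairs imply a 1 kPa effective modulus
  expect_equal(elastic_strain(100), 0.10)
  expect_equal(elastic_strain(140), 0.14)
  expect_equal(elastic_strain(0), 0)
})

test_that("effective_viscosity follows eta = sigma dT / strain", {
  expect_equal(effective_viscosity(100, 48, 1.0), 100 * 48 * 3600)
  expect_equal(effective_viscosity(200, 48, 0.5), 2 * effective_viscosity(100, 48, 0.5))
  expect_error(effective_viscosity(100, 48, 0), "irreversible")
  # round trip: eta * strain / dT = sigma
  eta <- effective_viscosity(87, 36, 0.42)
  expect_equal(eta * 0.42 / (36 * 3600), 87)
})

test_that("relative changes and the dry-mass / cell-number formulas agree", {
  expect_equal(relative_change(1, 1), 0)
  expect_equal(relative_change(10, 8.2), -0.18)
  expect_equal(relative_change(1, 3), 2)
  expect_error(relative_change(0, 1), "before")

  expect_equal(dry_mass_change(0.100 * 2.3, 2.3, 0.100), 0)
  expect_equal(dry_mass_change(0.147, 1, 0.100), 0.47)
  expect_equal(dry_mass_change(0.081, 1, 0.100), -0.19)
  expect_equal(cell_number_change(4.15e5 * 1.7, 1.7), 0)
  expect_equal(cell_number_change(9.30e5, 1), 1.241, tolerance = 1e-3)
  expect_equal(cell_number_change(0, 1), -1)

  # both are exactly relative_change applied to the reference quantities
  Vi <- c(0.8, 1.3); mf <- c(0.09, 0.2); Nf <- c(5e5, 9e5)
  expect_equal(dry_mass_change(mf, Vi, 0.1), relative_change(0.1 * Vi, mf))
  expect_equal(cell_number_change(Nf, Vi, 4.15e5),
               relative_change(4.15e5 * Vi, Nf))

  expect_equal(dry_mass_fraction(0.100), 10)
  expect_equal(dry_mass_fraction(0), 0)
  expect_equal(dry_mass_fraction(0.081), 8.1)
  expect_error(dry_mass_fraction(1.2), "below")
})

test_that("cantilever calibration fits, inverts, and is statistically sound", {
  s_true <- 3.2e5  # deg/N
  tab <- generate_calibration_data(s_true, c(1, 2, 3, 4))
  expect_equal(nrow(tab), 4)
  cal <- fit_cantilever(tab)
  expect_equal(cal$sensitivity_deg_per_N, s_true, tolerance = 1e-9)
  expect_equal(cal$intercept_deg, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  # noise-free round trip is the identity
  expect_equal(deflection_to_dry_mass(tab$deflection_deg, cal), c(1, 2, 3, 4))
  expect_equal(deflection_to_dry_mass(cal$intercept_deg, cal), 0)

  # noisy recovery within 3 SE, and jitter reproducible per seed
  tabn <- generate_calibration_data(s_true, c(1, 2, 3, 4), noise_sd_deg = 0.5,
                                    seed = 7)
  expect_identical(tabn,
                   generate_calibration_data(s_true, c(1, 2, 3, 4),
                                             noise_sd_deg = 0.5, seed = 7))
  caln <- fit_cantilever(tabn)
  expect_lt(abs(caln$sensitivity_deg_per_N - s_true), 3 * caln$slope_se)

  # estimator unbiased over 200 replicates (mean slope within 1% of truth)
  slopes <- vapply(1:200, function(i) {
    fit_cantilever(generate_calibration_data(s_true, c(1, 2, 3, 4),
                                             noise_sd_deg = 1, seed = i))$sensitivity_deg_per_N
  }, numeric(1))
  expect_lt(abs(mean(slopes) / s_true - 1), 0.01)

  expect_error(fit_cantilever(data.frame(mass_mg = c(2, 2),
                                         deflection_deg = c(1, 1.2))), "distinct")
  expect_error(fit_cantilever(data.frame(mass_mg = 1, deflection_deg = 1)))
  cal2 <- fit_cantilever(data.frame(mass_mg = c(1, 2, 3),
                                    deflection_deg = c(2, 3, 4)))
  expect_error(deflection_to_dry_mass(0.5, cal2), "below")
})

test_that("proliferation density and epithelial fraction arithmetic", {
  expect_equal(proliferation_density(0, 1)$mean, 0)
  expect_equal(proliferation_density(225, 1.0)$mean, 225)
  expect_error(proliferation_density(10, 0), "positive")
  pd <- proliferation_density(c(200, 250), c(1, 1))
  expect_equal(pd$mean, 225)
  expect_equal(epithelial_fraction(0, 10), 0)
  expect_equal(epithelial_fraction(1, 10), 10)
  expect_error(epithelial_fraction(11, 10), "exceed")
})
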