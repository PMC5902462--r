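# Generators: closed-form truths, determinism, stated-world invariants.

test_that("tube phantom truth matches closed forms", {
  # straight cylinder: V = pi r^2 L over the midline span
  ph <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                      scale_mm_per_px = 0.02)
  expect_equal(ph$truth$volume_mm3, pi * 0.2^2 * 10, tolerance = 1e-6)
  expect_equal(ph$truth$length_mm, 10)
  expect_equal(ph$truth$mean_diameter_mm, 0.4, tolerance = 1e-9)

  # linear taper: tip diameter d (1 + taper), mean diameter at the midpoint
  pht <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                       taper = -0.5)
  expect_equal(utils::tail(pht$truth$diameter_profile$diameter_mm, 1), 0.2,
               tolerance = 1e-6)
  expect_equal(pht$truth$mean_diameter_mm, 0.3, tolerance = 1e-9)

  # sinusoid: length is arclength by construction; volume must match an
  # independent quadrature of the generator's own r(s) at 10x finer step
  sp <- tube_phantom_spec("sinusoid", length_mm = 10, base_diameter_mm = 0.4,
                          bend_amplitude_mm = 0.8, bend_wavelength_mm = 5,
                          taper = -0.2, scale_mm_per_px = 0.02)
  ph2 <- generate_tube_image(sp)
  expect_equal(ph2$truth$length_mm, 10)
  s_fine <- seq(0, 10, length.out = 50001)
  r_fine <- 0.2 * (1 - 0.2 * s_fine / 10)
  v_oracle <- sum((r_fine[-1]^2 + r_fine[-50001]^2) / 2 * diff(s_fine)) * pi
  expect_equal(ph2$truth$volume_mm3, v_oracle, tolerance = 1e-4)
})

test_that("rasterization fidelity: straight-capsule mask area and topology", {
  ph <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                      scale_mm_per_px = 0.02)
  area <- sum(ph$mask) * 0.02^2
  expect_equal(area, 10 * 0.4 + pi * 0.4^2 / 4, tolerance = 0.02)
  # single connected component without holes
  mask2 <- segment_silhouette(ph$image, 0.02)
  expect_identical(mask2, ph$mask)
})

test_that("phantom generation is bit-reproducible and rejects self-overlap", {
  sp <- tube_phantom_spec("spline", length_mm = 9, base_diameter_mm = 0.4,
                          bend_amplitude_mm = 0.6, noise_sd_px = 1, seed = 42)
  a <- generate_tube_image(sp)
  b <- generate_tube_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$volume_mm3, b$truth$volume_mm3)
  # tight bend: radius of curvature A (2 pi / lambda)^2 below one diameter
  sp_bad <- tube_phantom_spec("sinusoid", length_mm = 10,
                              base_diameter_mm = 0.8,
                              bend_amplitude_mm = 1.2, bend_wavelength_mm = 2.5)
  expect_error(generate_tube_image(sp_bad), "self-overlap")
  expect_error(tube_phantom_spec("straight", length_mm = 1,
                                 base_diameter_mm = 0.4), "tubular")
})

test_that("growth cohort with zero noise lies exactly on the response law", {
  sp <- growth_cohort_spec(n_specimens = 6, mass_mg_choices = 0,
                           noise_sd = c(length = 0, volume = 0, diameter = 0),
                           seed = 2)
  coh <- generate_growth_cohort(sp)
  # control behaviour: -18% length, +2% volume, +14% diameter (from the
  # axisymmetric identity (1+dV) = (1+dl)(1+dd)^2)
  expect_equal(coh$L1_mm / coh$L0_mm - 1, rep(-0.18, 6), tolerance = 1e-10)
  expect_equal(coh$V1_mm3 / coh$V0_mm3 - 1, rep(0.02, 6), tolerance = 1e-10)
  dd_expected <- sqrt(1.02 / 0.82) - 1  # 0.1153, the identity's control value
  expect_equal(coh$d1_mm / coh$d0_mm - 1, rep(dd_expected, 6), tolerance = 1e-10)

  # upper anchor of the default law: +200% length at 150 Pa
  sp150 <- growth_cohort_spec(n_specimens = 4, mass_mg_choices = 2,
                              noise_sd = c(length = 0, volume = 0, diameter = 0),
                              seed = 3)
  coh150 <- generate_growth_cohort(sp150)
  dl_pct <- 100 * (coh150$L1_mm / coh150$L0_mm - 1)
  expect_equal(dl_pct, -18 + (218 / 150) * coh150$stress_Pa, tolerance = 1e-8)

  # dry mass and cell count follow the density model
  expect_equal(coh$m_f_mg, 0.104 * coh$V1_mm3)
  expect_equal(coh$N_f, 6.60e5 * coh$V1_mm3)
})

test_that("growth cohort is deterministic per seed and stress uses biomech ops", {
  sp <- growth_cohort_spec(n_specimens = 2, seed = 9)
  expect_identical(generate_growth_cohort(sp), generate_growth_cohort(sp))
  coh <- generate_growth_cohort(growth_cohort_spec(n_specimens = 6, seed = 4))
  expect_equal(coh$stress_Pa,
               applied_stress(buoyant_force(coh$mass_mg), coh$d0_mm))
  expect_true(all(coh$V0_mm3 > 0 & coh$V1_mm3 > 0))
})

test_that("incompressible rescaling leaves volume change at zero", {
  coh <- generate_growth_cohort(growth_cohort_spec(n_specimens = 8, seed = 6))
  eps <- 0.35
  L1 <- coh$L0_mm * (1 + eps)
  d1 <- coh$d0_mm * (1 + eps)^(-1 / 2)
  V1 <- pi * d1^2 / 4 * L1
  dv <- relative_change(coh$V0_mm3, V1)
  expect_true(all(abs(dv) < 0.01))
  expect_equal(dv, rep(0, 8), tolerance = 1e-12)
})

test_that("peristalsis movie truth and guards", {
  sp <- peristalsis_movie_spec(frames = 120L, frame_interval_s = 2,
                               tube_length_mm = 3, scale_mm_per_px = 0.04,
                               wave_frequency_mHz = 18, wave_speed_mm_s = 0.1,
                               seed = 1)
  mv <- generate_peristalsis_movie(sp)
  expect_equal(mv$truth$frequency_mHz, 18)
  expect_equal(mv$truth$speed_mm_s, 0.1)
  expect_equal(mv$truth$n_waves, as.integer(floor(0.018 * 119 * 2)))
  mv2 <- generate_peristalsis_movie(sp)
  expect_identical(mv$stack, mv2$stack)

  # static movie when frequency is zero
  sp0 <- peristalsis_movie_spec(frames = 10L, wave_frequency_mHz = 0,
                                tube_length_mm = 2, scale_mm_per_px = 0.05)
  mv0 <- generate_peristalsis_movie(sp0)
  expect_equal(mv0$truth$frequency_mHz, 0)
  expect_true(all(mv0$stack == array(mv0$stack[, , 1], dim(mv0$stack))))

  # Nyquist: period < 2 frames is rejected with the limit named
  expect_error(peristalsis_movie_spec(frame_interval_s = 40,
                                      wave_frequency_mHz = 15), "Nyquist")
  expect_error(peristalsis_movie_spec(frames = 50L, frame_interval_s = 2,
                                      wave_frequency_mHz = 15), "two wave periods")
})

test_that("calibration generator is exactly linear at zero noise", {
  tab <- generate_calibration_data(2.5e5, c(1, 2, 3, 4))
  slopes <- diff(tab$deflection_deg) / diff(tab$force_N)
  expect_equal(slopes, rep(2.5e5, 3))
  expect_error(generate_calibration_data(2.5e5, c(3, 1)), "unsorted|masses",
               ignore.case = TRUE)
})
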