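# Silhouette -> midline -> morphometry pipeline against generator ground
# truth, plus closed-form degenerate cases.

test_that("segment_silhouette recovers the generator mask and applies rules", {
  ph <- quick_phantom("sinusoid", seed = 2)
  mask <- segment_silhouette(ph$image, 0.025)
  iou <- sum(mask & ph$mask) / sum(mask | ph$mask)
  expect_gte(iou, 0.99)
  expect_error(segment_silhouette(matrix(0, 10, 10), 1), "no object|constant")
  # two blobs: the larger is kept
  img <- matrix(0, 60, 120)
  img[20:40, 10:50] <- 255   # 21 x 41
  img[25:35, 80:100] <- 255  # 11 x 21
  m2 <- segment_silhouette(img, 1)
  expect_true(all(m2[20:40, 10:50]))
  expect_false(any(m2[25:35, 80:100]))
  # holes are filled
  img3 <- matrix(0, 40, 40); img3[10:30, 10:30] <- 255; img3[18:22, 18:22] <- 0
  expect_true(all(segment_silhouette(img3, 1)[18:22, 18:22]))
})

test_that("extract_contour is subpixel-accurate and validates topology", {
  img <- disk_image(radius_px = 100)
  ctr <- unclass(extract_contour(segment_silhouette(img, 1), 1))
  per <- sum(sqrt(rowSums(diff(rbind(ctr, ctr[1, ]))^2)))
  expect_equal(per, 2 * pi * 100, tolerance = 0.01)

  # straight capsule: analytic perimeter 2 L + 2 pi r
  ph <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                      scale_mm_per_px = 0.02)
  ctr2 <- unclass(extract_contour(segment_silhouette(ph$image, 0.02), 0.02))
  per2 <- sum(sqrt(rowSums(diff(rbind(ctr2, ctr2[1, ]))^2)))
  expect_equal(per2, 2 * 10 + 2 * pi * 0.2, tolerance = 0.02)

  # mask clipped at the border is rejected
  mask <- matrix(FALSE, 30, 30); mask[1:10, 5:25] <- TRUE
  expect_error(extract_contour(mask, 1), "border|truncated")
})

test_that("medial axis matches the symmetry axis and generator midline", {
  ph <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                      scale_mm_per_px = 0.02)
  cfg <- morph_config(scale_mm_per_px = 0.02)
  ml <- medial_axis_voronoi(extract_contour(segment_silhouette(ph$image, 0.02),
                                            0.02), cfg)
  expect_equal(max(ml$s), 10, tolerance = 0.02)
  expect_true(all(abs(ml$r - 0.2) <= 0.02))  # r within 1 px everywhere

  # curved phantom: midline within 1 px RMS of the generator midline
  ph2 <- quick_phantom("sinusoid", seed = 5, bend_amplitude_mm = 0.7,
                       scale_mm_per_px = 0.02)
  ml2 <- medial_axis_voronoi(extract_contour(segment_silhouette(ph2$image, 0.02),
                                             0.02), morph_config(0.02))
  d <- gutmorph:::gm_nearest_dist(ml2$x, ml2$y, ph2$midline$x, ph2$midline$y)
  expect_lt(sqrt(mean(d^2)), 0.02)

  # a disk is not tubular
  ctr_disk <- extract_contour(segment_silhouette(disk_image(60), 1), 1)
  expect_error(medial_axis_voronoi(ctr_disk, morph_config(1)), "aspect")
})

test_that("morphometry_from_midline integrates closed forms", {
  s <- seq(0, 10, by = 0.05)
  cyl <- midline(s, s, rep(0, length(s)), rep(0.2, length(s)))
  m <- morphometry_from_midline(cyl)
  expect_equal(m$volume_mm3, pi * 0.2^2 * 10, tolerance = 1e-9)
  expect_equal(m$length_mm, 10)
  expect_equal(m$mean_diameter_mm, 0.4)

  # conical frustum r: 0.2 -> 0.1: V = pi L (r1^2 + r1 r2 + r2^2) / 3
  rf <- seq(0.2, 0.1, length.out = length(s))
  fr <- morphometry_from_midline(midline(s, s, 0 * s, rf))
  expect_equal(fr$volume_mm3, pi * 10 * (0.04 + 0.02 + 0.01) / 3,
               tolerance = 1e-4)

  bad <- data.frame(s = s, x = s, y = 0 * s, r = rep(0.2, length(s)))
  bad$r[5] <- -0.1
  class(bad) <- c("midline", "data.frame")
  expect_error(morphometry_from_midline(bad), "positive")
})

test_that("measure_tube recovers generator truth across random phantoms", {
  for (seed in c(101, 202, 303, 404)) {
    sp <- random_phantom_spec(seed)
    ph <- generate_tube_image(sp)
    m <- measure_tube(ph$image, sp$scale_mm_per_px)
    expect_lt(abs(m$length_mm / ph$truth$length_mm - 1), 0.03)
    expect_lt(abs(m$volume_mm3 / ph$truth$volume_mm3 - 1), 0.03)
    expect_lt(abs(m$mean_diameter_mm - ph$truth$mean_diameter_mm),
              sp$scale_mm_per_px)
  }
})

test_that("measurement is rotation-invariant and scale-covariant", {
  base <- list(midline_kind = "sinusoid", length_mm = 8, base_diameter_mm = 0.4,
               bend_amplitude_mm = 0.5, bend_wavelength_mm = 5,
               scale_mm_per_px = 0.02, seed = 3)
  m0 <- measure_tube(generate_tube_image(do.call(tube_phantom_spec, base))$image, 0.02)
  m35 <- measure_tube(generate_tube_image(do.call(tube_phantom_spec,
           utils::modifyList(base, list(rotation_deg = 35))))$image, 0.02)
  expect_lt(abs(m35$length_mm / m0$length_mm - 1), 0.02)
  expect_lt(abs(m35$mean_diameter_mm / m0$mean_diameter_mm - 1), 0.02)
  expect_lt(abs(m35$volume_mm3 / m0$volume_mm3 - 1), 0.02)

  img <- generate_tube_image(do.call(tube_phantom_spec, base))$image
  m1 <- measure_tube(img, 0.02)
  m2 <- measure_tube(img, 0.04)
  expect_equal(m2$length_mm, 2 * m1$length_mm, tolerance = 1e-6)
  expect_equal(m2$mean_diameter_mm, 2 * m1$mean_diameter_mm, tolerance = 1e-6)
  expect_equal(m2$volume_mm3, 8 * m1$volume_mm3, tolerance = 1e-6)
})

test_that("bezier reconstruction agrees with closed form and flags bad fits", {
  ph <- quick_phantom("straight", length_mm = 10, base_diameter_mm = 0.4,
                      scale_mm_per_px = 0.02)
  ctr <- extract_contour(segment_silhouette(ph$image, 0.02), 0.02)
  b <- bezier_profile_volume(ctr)
  expect_equal(b$volume_mm3, pi * 0.2^2 * 10, tolerance = 0.02)
  expect_equal(b$length_mm, 10, tolerance = 0.02 * 10)
  expect_error(bezier_profile_volume(ctr, n_control = 3), "n_control")
  expect_length(b$flags, 0)
})

test_that("compare_methods computes symmetric relative discrepancies", {
  a <- tube_morphometry(10, 0.4, 1)
  expect_equal(unname(compare_methods(a, a)), c(0, 0, 0))
  b <- tube_morphometry(10, 0.4, 1.1)
  expect_equal(unname(compare_methods(a, b)[["volume"]]), 0.1 / 1.05,
               tolerance = 1e-9)
})
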