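test_that("phantom specs validate their parameters", {
  expect_error(phantom_spec(semi_axes = c(1, -1, 1)), "invalid phantom")
  expect_error(phantom_spec(pixel_pitch = 0), "invalid phantom")
  expect_error(phantom_spec(perturbation_amplitude = 0.6), "invalid phantom")
  expect_error(generate_phantom(phantom_spec(semi_axes = c(0.005, 0.005, 0.005),
                                             pixel_pitch = 0.01)),
               "degenerate phantom")
})

test_that("sphere phantom volume matches 4 pi/3 within 1%", {
  ph <- generate_phantom(phantom_spec(semi_axes = c(1, 1, 1),
                                      pixel_pitch = 0.01,
                                      slice_thickness = 0.01))
  expect_equal(ph$true_volume, 4 * pi / 3)
  v <- cavalieri_volume(slice_series_from_masks(ph$mask_stack,
                                                ph$calibration, 0.01))
  expect_lt(abs(v - 4 * pi / 3) / (4 * pi / 3), 0.01)
})

test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(shape = "perturbed_ellipsoid",
                     semi_axes = c(0.8, 0.6, 0.4), pixel_pitch = 0.02,
                     perturbation_amplitude = 0.1, seed = 99L)
  ph1 <- generate_phantom(sp)
  ph2 <- generate_phantom(sp)
  expect_identical(ph1$true_volume, ph2$true_volume)
  expect_identical(lapply(ph1$mask_stack, `[[`, "bitmap"),
                   lapply(ph2$mask_stack, `[[`, "bitmap"))
})

test_that("zero perturbation reduces to the plain ellipsoid", {
  ax <- c(0.8, 0.6, 0.4)
  sp0 <- phantom_spec(shape = "perturbed_ellipsoid", semi_axes = ax,
                      pixel_pitch = 0.02, perturbation_amplitude = 0, seed = 5L)
  spe <- phantom_spec(shape = "ellipsoid", semi_axes = ax,
                      pixel_pitch = 0.02, seed = 5L)
  ph0 <- generate_phantom(sp0)
  phe <- generate_phantom(spe)
  expect_identical(lapply(ph0$mask_stack, `[[`, "bitmap"),
                   lapply(phe$mask_stack, `[[`, "bitmap"))
  # ground truth switches from the per-slice polygon sum (the slab solid)
  # to the smooth analytic ellipsoid; at t = 0.1 on c = 0.4 the midpoint
  # slab discretization accounts for the ~1% gap
  expect_equal(ph0$true_volume, phe$true_volume, tolerance = 0.01)
})

test_that("contour perturbation is seeded, identity at zero amplitude", {
  theta <- seq(0, 2 * pi, length.out = 65L)[-65L]
  circle <- contour_polygon(100 + 50 * cos(theta), 100 + 50 * sin(theta))
  expect_identical(perturb_contour(circle, 0), circle)
  p1 <- perturb_contour(circle, 2, seed = 7L)
  p2 <- perturb_contour(circle, 2, seed = 7L)
  expect_identical(p1$vertices, p2$vertices)
  expect_false(identical(p1$vertices,
                         perturb_contour(circle, 2, seed = 8L)$vertices))
})

test_that("perturbation noise moves areas by a few percent at 2 px amplitude", {
  theta <- seq(0, 2 * pi, length.out = 129L)[-129L]
  circle <- contour_polygon(150 + 100 * cos(theta), 150 + 100 * sin(theta))
  base_area <- shoelace_area(circle)
  areas <- vapply(1:200, function(s)
    shoelace_area(perturb_contour(circle, 2, seed = s)), numeric(1L))
  expect_lt(sd(areas) / mean(areas), 0.05)
  expect_equal(mean(areas), base_area, tolerance = 0.05)
})

test_that("inter-observer volume spread grows with perturbation amplitude", {
  sds <- vapply(c(0.02, 0.08, 0.2), function(amp) {
    diffs <- vapply(1:8, function(s) {
      spA <- phantom_spec(shape = "perturbed_ellipsoid",
                          semi_axes = c(0.8, 0.7, 0.4), pixel_pitch = 0.02,
                          perturbation_amplitude = amp, seed = 1000L + s)
      spB <- spA; spB$seed <- 2000L + s
      vA <- generate_phantom(spA)$true_volume
      vB <- generate_phantom(spB)$true_volume
      vA - vB
    }, numeric(1L))
    sd(diffs)
  }, numeric(1L))
  expect_true(all(diff(sds) > 0))
})

test_that("rendered slice images round-trip calibration and pixel count", {
  sq <- contour_polygon(c(5, 15, 15, 5), c(5, 5, 15, 15))
  mask <- rasterize_contour(sq, 600, 30)
  cal <- calibrate_from_bar(100, 1) # 0.01 cm/px -> 5 cm bar = 500 px
  img <- render_slice_image(mask, cal, scalebar_cm = 5)
  rec <- measure_rendered_image(img)
  expect_equal(rec$calibration$length_ratio, 0.01)
  expect_equal(rec$mask$pixel_count, mask$pixel_count)
  expect_equal(rec$mask$bitmap, mask$bitmap)
  # bar longer than the image is a render error
  small <- rasterize_contour(sq, 30, 30)
  expect_error(render_slice_image(small, cal, scalebar_cm = 5), "render error")
})

test_that("disc phantom end-to-end: render, calibrate, outline, measure", {
  R <- 0.5 # cm
  p <- 0.01
  theta <- seq(0, 2 * pi, length.out = 257L)[-257L]
  ct <- contour_polygon(300 + (R / p) * cos(theta), 70 + (R / p) * sin(theta))
  mask <- rasterize_contour(ct, 600, 140)
  img <- render_slice_image(mask, calibrate_from_bar(5 / p, 5), scalebar_cm = 5)
  rec <- measure_rendered_image(img)
  area <- cross_section_area(rec$mask, rec$calibration)
  expect_lt(abs(area - pi * R^2) / (pi * R^2), 0.01)
})

test_that("phantom spec YAML round-trips", {
  sp <- phantom_spec(shape = "perturbed_ellipsoid", semi_axes = c(1.2, 1, 0.5),
                     pixel_pitch = 0.02, perturbation_amplitude = 0.05,
                     smoothness = 6L, seed = 12L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, path)
  expect_equal(read_phantom_spec(path), sp)
})
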