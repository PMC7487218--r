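test_that("noiseless morphometrics sit exactly on the generating power law", {
  rec <- generate_morphometrics(10, log_intercept = -0.72, slope = 0.44,
                                body_length_range = c(15, 40), noise_sd = 0,
                                seed = 42)
  fit <- lm(log10(eye_diameter_mm) ~ log10(body_length_mm), data = rec)
  expect_equal(unname(coef(fit)), c(-0.72, 0.44), tolerance = 1e-10)

  # published male coefficients at a 32 mm body predict a 0.876 mm eye
  rec32 <- generate_morphometrics(5, -0.72, 0.44, c(32, 32), 0, seed = 1)
  expect_equal(unique(round(rec32$eye_diameter_mm, 4)), 0.8755,
               tolerance = 1e-4)

  flat <- generate_morphometrics(5, -0.5, 0, c(10, 50), 0, seed = 2)
  expect_equal(flat$eye_diameter_mm, rep(10^-0.5, 10))
})

test_that("morphometric generator applies sex deltas to males and is seeded", {
  rec <- generate_morphometrics(50, -0.75, 0.48, c(13, 58), 0,
                                sex_slope_delta = 0.1,
                                sex_intercept_delta = -0.2, seed = 3)
  f <- lm(log10(eye_diameter_mm) ~ log10(body_length_mm),
          data = rec[rec$sex == "female", ])
  m <- lm(log10(eye_diameter_mm) ~ log10(body_length_mm),
          data = rec[rec$sex == "male", ])
  expect_equal(unname(coef(f)), c(-0.75, 0.48), tolerance = 1e-10)
  expect_equal(unname(coef(m)), c(-0.95, 0.58), tolerance = 1e-10)

  expect_identical(generate_morphometrics(8, -0.7, 0.4, c(10, 40), 0.1, seed = 9),
                   generate_morphometrics(8, -0.7, 0.4, c(10, 40), 0.1, seed = 9))
})

test_that("morphometric generator rejects invalid specifications", {
  expect_error(generate_morphometrics(2, -0.7, 0.4, c(10, 40), 0.1),
               class = "pestavision_input_error")
  expect_error(generate_morphometrics(5, -0.7, 0.4, c(40, 10), 0.1),
               class = "pestavision_input_error")
  expect_error(generate_morphometrics(5, -0.7, 0.4, c(10, 40), -0.1),
               class = "pestavision_input_error")
})

test_that("eye contours lie on the requested circle and are reproducible", {
  pts <- generate_eye_contour(0.5, 50, noise_sd = 0, arc_span = 200)
  expect_equal(sqrt(pts$x^2 + pts$y^2), rep(0.5, 50), tolerance = 1e-12)

  expect_identical(generate_eye_contour(1, 30, 0.02, seed = 5),
                   generate_eye_contour(1, 30, 0.02, seed = 5))
  expect_error(generate_eye_contour(1, 2), class = "pestavision_input_error")
  expect_error(generate_eye_contour(-1, 10), class = "pestavision_input_error")
})

test_that("generated patterns have the requested lobe count and polarity", {
  cases <- list(list(type = "bilobed", n = NULL, want = 2L),
                list(type = "trilobed", n = NULL, want = 3L),
                list(type = "fringed", n = 8L, want = 8L),
                list(type = "fringed", n = 10L, want = 10L))
  for (cs in cases) {
    img <- generate_pattern(cs$type, n_lobes = cs$n, lobe_diameter_mm = 0.8,
                            lobe_spacing_mm = 1.4, body_length_mm = 32,
                            image_px = 128L, canvas_mm = 20)
    expect_identical(count_components(img$pixels > 0.5), cs$want)
    expect_setequal(unique(as.vector(img$pixels)), c(0, 1))
    expect_equal(img$mm_per_pixel, 20 / 128)
  }
})

test_that("pattern generator rejects impossible geometry", {
  # organs darker than background
  expect_error(generate_pattern("bilobed", lobe_diameter_mm = 1,
                                lobe_spacing_mm = 2, body_length_mm = 30,
                                background_level = 0.9, organ_level = 0.1),
               class = "pestavision_input_error")
  # lobes running over the border
  expect_error(generate_pattern("fringed", n_lobes = 12L,
                                lobe_diameter_mm = 1, lobe_spacing_mm = 2,
                                body_length_mm = 20, canvas_mm = 10),
               class = "pestavision_input_error")
  # wrong lobe count for the array type
  expect_error(generate_pattern("bilobed", n_lobes = 4L,
                                lobe_diameter_mm = 1, lobe_spacing_mm = 2,
                                body_length_mm = 30),
               class = "pestavision_input_error")
  # fringed arrays need many lobes
  expect_error(generate_pattern("fringed", n_lobes = 4L,
                                lobe_diameter_mm = 0.3, lobe_spacing_mm = 0.5,
                                body_length_mm = 30),
               class = "pestavision_input_error")
})

test_that("pattern generation is deterministic, also under jitter", {
  a <- generate_pattern("trilobed", lobe_diameter_mm = 0.9,
                        lobe_spacing_mm = 1.2, body_length_mm = 25,
                        jitter_sd_mm = 0.1, seed = 11)
  b <- generate_pattern("trilobed", lobe_diameter_mm = 0.9,
                        lobe_spacing_mm = 1.2, body_length_mm = 25,
                        jitter_sd_mm = 0.1, seed = 11)
  expect_identical(a, b)
})
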