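test_that("circle fit is exact on noiseless arcs and equivariant", {
  three <- tibble::tibble(x = c(1, 0, -1), y = c(0, 1, 0))
  fit <- fit_circle(three)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-12)

  withr::with_seed(21, {
    for (span in c(30, 120, 360)) {
      r <- runif(1, 0.2, 3)
      ctr <- runif(2, -5, 5)
      rot <- runif(1, 0, 2 * pi)
      arc <- generate_eye_contour(r, 60, 0, arc_span = span)
      pts <- tibble::tibble(
        x = ctr[1] + cos(rot) * arc$x - sin(rot) * arc$y,
        y = ctr[2] + sin(rot) * arc$x + cos(rot) * arc$y)
      fit <- fit_circle(pts)
      expect_equal(fit$radius, r, tolerance = 1e-9)
      expect_equal(fit$center, ctr, tolerance = 1e-8)
    }
  })
})

test_that("circle fit recovers the generator radius from noisy contours", {
  pts <- generate_eye_contour(0.5, 200, noise_sd = 0.01, arc_span = 360,
                              seed = 31)
  expect_equal(fit_circle(pts)$radius, 0.5, tolerance = 0.01)
})

test_that("circle fit rejects collinear points", {
  expect_error(fit_circle(tibble::tibble(x = 1:5, y = 2 * (1:5))),
               class = "pestavision_input_error")
})

test_that("minimum resolvable angle follows the facet/radius geometry", {
  expect_equal(interommatidial_angle(1, 1), 0.001)
  expect_equal(min_resolvable_angle(1, 1), 2 * 0.001 * 180 / pi)
  # doubling the radius of curvature halves the angle
  expect_equal(min_resolvable_angle(23.5, 1),
               min_resolvable_angle(23.5, 0.5) / 2)
  # invariant to a simultaneous rescaling of both lengths
  expect_equal(min_resolvable_angle(23.5, 0.5),
               min_resolvable_angle(235, 5))
  expect_error(min_resolvable_angle(-1, 1),
               class = "pestavision_input_error")
})

test_that("species summary orders species by acuity and handles ties", {
  geom <- published_eye_geometry()
  per_ind <- tibble::tibble(
    species = rep(geom$species, each = 2),
    facet_diameter_um = rep(geom$facet_diameter_mean_um, each = 2),
    radius_of_curvature_mm = rep(geom$radius_of_curvature_mean_mm, each = 2))
  out <- species_resolution_summary(per_ind)
  expect_identical(nrow(out), 3L)
  expect_identical(out$species[1], "Deosergestes henseni")
  expect_equal(out$alpha_min_sd_deg, rep(0, 3))
  expect_error(species_resolution_summary(tibble::tibble()),
               class = "pestavision_input_error")
})

test_that("ANOVA F matches a brute-force sum-of-squares computation", {
  withr::with_seed(41, {
    for (i in 1:5) {
      g <- tibble::tibble(
        species = rep(c("a", "b", "c"), each = 4),
        alpha_min_deg = rnorm(12, rep(c(10, 9, 6), each = 4), 1))
      res <- anova_tukey(g)
      expect_equal(res$f, anova_f_brute(g$alpha_min_deg, g$species),
                   tolerance = 1e-10)
      expect_identical(res$df_between, 2L)
      expect_identical(res$df_error, 9L)
    }
  })
})

test_that("identical groups give F near zero and Tukey p near one", {
  block <- c(9.5, 10.2, 10.9, 9.9)
  g <- tibble::tibble(species = rep(c("a", "b", "c"), each = 4),
                      alpha_min_deg = rep(block, 3))
  res <- anova_tukey(g)
  expect_lt(res$f, 1e-20)
  expect_true(all(res$tukey$p_adj > 0.999))
})

test_that("a well-separated extreme pair is declared different", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(500 + s, {
      g <- tibble::tibble(
        species = rep(c("a", "b", "c"), each = 4),
        alpha_min_deg = rnorm(12, rep(c(11, 8.5, 6), each = 4), 1))
    })
    res <- anova_tukey(g)
    extreme <- res$tukey$p_adj[grepl("a", res$tukey$comparison) &
                                 grepl("c", res$tukey$comparison)]
    res$p_value < 0.05 && extreme < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ANOVA type-I error is calibrated near the nominal level", {
  withr::local_seed(97)
  rejections <- vapply(1:1000, function(s) {
    g <- tibble::tibble(species = rep(c("a", "b", "c"), each = 4),
                        alpha_min_deg = rnorm(12, 8, 1))
    anova_tukey(g)$p_value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("degenerate zero-variance groups are rejected with a diagnostic", {
  g <- tibble::tibble(species = rep(c("a", "b"), each = 3),
                      alpha_min_deg = rep(5, 6))
  expect_error(anova_tukey(g), class = "pestavision_numeric_error")
  expect_error(anova_tukey(g[1:3, ]), class = "pestavision_input_error")
})
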