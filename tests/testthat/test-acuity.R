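make_pattern <- function(image_px = 96L, canvas_mm = 12) {
  generate_pattern("trilobed", lobe_diameter_mm = 0.9, lobe_spacing_mm = 1.05,
                   body_length_mm = 25, image_px = image_px,
                   canvas_mm = canvas_mm)
}

test_that("angular size follows the two-arctangent formula and its limits", {
  expect_equal(angular_size(20, 2), 2 * atan(0.5) * 180 / pi)  # s = D
  expect_equal(angular_size(2, 2), 5.7248, tolerance = 1e-4)
  # small-angle regime collapses to s/D in radians
  expect_equal(angular_size(0.1, 10),
               (0.1 / 100) * 180 / pi, tolerance = 1e-4)
  expect_error(angular_size(0, 2), class = "pestavision_input_error")
})

test_that("acuity filter preserves the mean and is an identity at high acuity", {
  img <- make_pattern()
  out <- acuity_filter(img, 2, 5.9)
  expect_equal(mean(out$pixels), mean(img$pixels), tolerance = 1e-9)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))

  sharp <- acuity_filter(img, 2, 1e-4)
  expect_lt(max(abs(sharp$pixels - img$pixels)), 1e-6)

  flat <- as_pattern_image(matrix(0.4, 32, 32), 0.1)
  expect_equal(acuity_filter(flat, 2, 8)$pixels, flat$pixels,
               tolerance = 1e-12)

  expect_error(acuity_filter(img, 2, 0), class = "pestavision_input_error")
  expect_error(acuity_filter(as_pattern_image(matrix(0, 4, 4), 0.1), 2, 5),
               class = "pestavision_input_error")
})

test_that("filtering reduces total variation and blurs harder when closer in angle", {
  img <- make_pattern()
  tv <- function(px) sum(abs(diff(px))) + sum(abs(t(diff(t(px)))))
  for (a in c(2, 5.9, 10.8)) {
    out <- acuity_filter(img, 2, a)
    expect_lt(tv(out$pixels), tv(img$pixels))
  }
})

test_that("discriminability is a bounded pseudometric on aligned images", {
  img <- make_pattern()
  other <- generate_pattern("bilobed", lobe_diameter_mm = 1.2,
                            lobe_spacing_mm = 1.8, body_length_mm = 32,
                            image_px = 96L, canvas_mm = 12)
  expect_identical(discriminability(img, img), 0)
  expect_equal(discriminability(img, other), discriminability(other, img))
  expect_gt(discriminability(img, other), 0)
  expect_lte(discriminability(img, other), 1)

  # translation of the whole pattern is removed by centroid alignment
  shifted <- img
  shifted$pixels <- img$pixels[c(11:96, 1:10), ]
  expect_equal(discriminability(img, shifted), 0, tolerance = 1e-12)

  # mirror image of an asymmetric pattern differs
  asym <- generate_pattern("fringed", n_lobes = 6L, lobe_diameter_mm = 0.3,
                           lobe_spacing_mm = 0.6, body_length_mm = 30,
                           image_px = 96L, canvas_mm = 12,
                           jitter_sd_mm = 0.08, seed = 2)
  mirror <- asym
  mirror$pixels <- asym$pixels[, rev(seq_len(ncol(asym$pixels)))]
  expect_gt(discriminability(asym, mirror), 0)

  # triangle inequality over random generated triples
  third <- generate_pattern("fringed", n_lobes = 8L, lobe_diameter_mm = 0.3,
                            lobe_spacing_mm = 0.42, body_length_mm = 41,
                            image_px = 96L, canvas_mm = 12)
  dab <- discriminability(img, other)
  dbc <- discriminability(other, third)
  dac <- discriminability(img, third)
  expect_lte(dac, dab + dbc + 1e-9)

  # mismatched sampling is refused
  wrong <- make_pattern(canvas_mm = 10)
  expect_error(discriminability(img, wrong),
               class = "pestavision_input_error")
})

test_that("discriminability of a fixed pair never increases with coarser acuity", {
  a <- make_pattern()
  b <- generate_pattern("bilobed", lobe_diameter_mm = 1.2,
                        lobe_spacing_mm = 1.8, body_length_mm = 32,
                        image_px = 96L, canvas_mm = 12)
  idx <- vapply(c(0.5, 1, 2, 4, 5.9, 8.5, 10.8), function(al) {
    discriminability(acuity_filter(a, 2, al), acuity_filter(b, 2, al))
  }, numeric(1))
  expect_true(all(diff(idx) <= 1e-9))
  # and filtering at shrimp acuity is contractive on the unfiltered difference
  expect_gt(discriminability(a, b), idx[length(idx)])
})

test_that("the recognition experiment reports pairs, thresholds and detectability", {
  res <- recognition_experiment(distances_cm = c(2, 4), n_null = 10,
                                image_px = 128L, seed = 77)
  expect_identical(nrow(tibble::as_tibble(res)), 18L)  # 3 viewers x 2 dist x 3 pairs
  expect_true(all(res$index >= 0 & res$index <= 1))
  det <- attr(res, "detectability")
  expect_identical(nrow(det), 18L)
  expect_true(all(det$detectable))

  # moving away never helps: indices at 4 cm do not exceed those at 2 cm
  near <- res[res$distance_cm == 2, ]
  far <- res[res$distance_cm == 4, ]
  key <- function(d) paste(d$viewer, d$target_a, d$target_b)
  far <- far[match(key(near), key(far)), ]
  expect_true(all(far$index <= near$index + 1e-6))

  expect_error(recognition_experiment(resolutions = numeric(0)),
               class = "pestavision_input_error")
})

test_that("a fixed seed reproduces the recognition matrix exactly", {
  a <- recognition_experiment(distances_cm = 2, n_null = 8, image_px = 96L,
                              seed = 5)
  b <- recognition_experiment(distances_cm = 2, n_null = 8, image_px = 96L,
                              seed = 5)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})
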