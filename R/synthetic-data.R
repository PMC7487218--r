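#' Simulate eye-to-body morphometric records
#'
#' Draws per-individual eye diameter and body length records under the
#' allometric power law used throughout the package:
#' `log10(eye) = log_intercept + slope * log10(body_length) + e`,
#' with `e ~ Normal(0, noise_sd)` on the log10 scale. Body lengths are
#' uniform on `body_length_range`. Two groups of `n_per_group` records are
#' produced (females, then males); the male group gets `sex_intercept_delta`
#' and `sex_slope_delta` added to the female coefficients, so a generator
#' with both deltas zero is the no-dimorphism null.
#'
#' @param n_per_group Records per sex (>= 3).
#' @param log_intercept Intercept of the log10-log10 regression (the
#'   allometric prefactor on the log scale; eye and body in mm).
#' @param slope Allometric scaling exponent.
#' @param body_length_range Length-2 numeric, min and max body length (mm).
#' @param noise_sd Residual SD on the log10 scale (>= 0).
#' @param sex_slope_delta,sex_intercept_delta Additive male-minus-female
#'   coefficient differences (default 0: no sexual dimorphism).
#' @param species Species label stored on every record.
#' @param seed Optional integer seed; fixed seeds give identical output.
#'
#' @return A tibble with columns `species`, `sex` ("female"/"male"),
#'   `eye_diameter_mm`, `body_length_mm`, `preservation`.
#' @export
#' @examples
#' generate_morphometrics(8, log_intercept = -0.72, slope = 0.44,
#'                        body_length_range = c(15, 40), noise_sd = 0.04,
#'                        seed = 1)
generate_morphometrics <- function(n_per_group, log_intercept, slope,
                                   body_length_range, noise_sd,
                                   sex_slope_delta = 0,
                                   sex_intercept_delta = 0,
                                   species = "synthetic", seed = NULL) {
  if (!is_number(n_per_group) || n_per_group < 3) {
    abort("`n_per_group` must be a single integer >= 3.",
          class = "pestavision_input_error")
  }
  stop_if_not_nonnegative(noise_sd, "noise_sd")
  if (length(body_length_range) != 2 || any(body_length_range <= 0) ||
      diff(body_length_range) < 0) {
    abort("`body_length_range` must be positive and ordered (min, max).",
          class = "pestavision_input_error")
  }
  local_seed(seed)
  n <- as.integer(n_per_group)
  sex <- rep(c("female", "male"), each = n)
  bl <- runif(2L * n, body_length_range[1], body_length_range[2])
  a <- ifelse(sex == "male", log_intercept + sex_intercept_delta, log_intercept)
  b <- ifelse(sex == "male", slope + sex_slope_delta, slope)
  log_eye <- a + b * log10(bl) + rnorm(2L * n, 0, noise_sd)
  tibble::tibble(
    species = species,
    sex = sex,
    eye_diameter_mm = 10^log_eye,
    body_length_mm = bl,
    preservation = "fresh"
  )
}

#' Generate a noisy circular eye-contour point set
#'
#' Fixture generator for the circle-fitting step of the spatial-resolution
#' module: points evenly spaced along a circular arc with isotropic Gaussian
#' coordinate noise, emulating a traced compound-eye outline.
#'
#' @param radius Arc radius (any length unit, typically mm); > 0.
#' @param n_points Number of points (>= 3).
#' @param noise_sd Isotropic coordinate noise SD, same unit as `radius`.
#' @param arc_span Angular span of the arc in degrees (default 360).
#' @param center Length-2 numeric circle centre (default origin).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `x`, `y`.
#' @export
#' @examples
#' pts <- generate_eye_contour(0.5, 200, noise_sd = 0.01, seed = 7)
#' fit_circle(pts)
generate_eye_contour <- function(radius, n_points, noise_sd = 0,
                                 arc_span = 360, center = c(0, 0),
                                 seed = NULL) {
  stop_if_not_positive(radius, "radius")
  stop_if_not_nonnegative(noise_sd, "noise_sd")
  stop_if_not_positive(arc_span, "arc_span")
  if (!is_number(n_points) || n_points < 3) {
    abort("`n_points` must be >= 3.", class = "pestavision_input_error")
  }
  local_seed(seed)
  n <- as.integer(n_points)
  theta <- seq(0, arc_span * pi / 180, length.out = n)
  tibble::tibble(
    x = center[1] + radius * cos(theta) + rnorm(n, 0, noise_sd),
    y = center[2] + radius * sin(theta) + rnorm(n, 0, noise_sd)
  )
}

lobes_for_type <- function(array_type, n_lobes) {
  if (is.null(n_lobes)) {
    n_lobes <- switch(array_type, bilobed = 2L, trilobed = 3L, fringed = 8L)
  }
  n_lobes <- as.integer(n_lobes)
  ok <- switch(array_type,
    bilobed = n_lobes == 2L,
    trilobed = n_lobes == 3L,
    fringed = n_lobes >= 6L
  )
  if (!ok) {
    abort(sprintf("`n_lobes` = %d is inconsistent with a %s array.",
                  n_lobes, array_type),
          class = "pestavision_input_error")
  }
  n_lobes
}

#' Generate a stylised light-organ pattern image
#'
#' Renders a row of filled circular organ lobes (white on black by default,
#' matching the luminous-organ-on-opaque-carapace polarity) on a square
#' canvas with a recorded physical pixel pitch. Species arrays differ in
#' lobe count and spacing: bilobed (2 lobes), trilobed (3) and fringed
#' (>= 6, many small lobes). Only lobe count, size and spacing are
#' contractual; the silhouettes are deliberately schematic.
#'
#' @param array_type One of `"bilobed"`, `"trilobed"`, `"fringed"`.
#' @param n_lobes Lobe count; defaults to 2/3/8 by `array_type`. Must be 2
#'   for bilobed, 3 for trilobed, >= 6 for fringed.
#' @param lobe_diameter_mm Diameter of one lobe (mm).
#' @param lobe_spacing_mm Centre-to-centre spacing of adjacent lobes (mm);
#'   must exceed `lobe_diameter_mm` so lobes stay disjoint.
#' @param body_length_mm Body length of the bearer (mm); default canvas is
#'   body-scaled so `mm_per_pixel = canvas_mm / image_px`.
#' @param image_px Square image side in pixels (default 256).
#' @param canvas_mm Physical side of the canvas (mm); defaults to
#'   `body_length_mm`. Pass a common value to give several species identical
#'   angular sampling.
#' @param background_level,organ_level Intensities in `[0, 1]`;
#'   `organ_level` must exceed `background_level`.
#' @param species_label Label stored on the image.
#' @param jitter_sd_mm Optional Gaussian jitter SD applied independently to
#'   every lobe centre coordinate (used by the self-noise null); 0 disables.
#' @param diameter_jitter_sd_mm Optional Gaussian jitter SD on each lobe
#'   diameter; 0 disables.
#' @param seed Optional integer seed (only used when jitter is nonzero).
#'
#' @return A `pattern_image`: list with `pixels` (matrix, rows = y),
#'   `mm_per_pixel`, `species_label`, `provenance = "generated"` and the
#'   generating `spec`.
#' @export
#' @examples
#' img <- generate_pattern("trilobed", lobe_diameter_mm = 1,
#'                         lobe_spacing_mm = 1.5, body_length_mm = 25)
#' img
generate_pattern <- function(array_type = c("bilobed", "trilobed", "fringed"),
                             n_lobes = NULL, lobe_diameter_mm,
                             lobe_spacing_mm, body_length_mm,
                             image_px = 256L, canvas_mm = body_length_mm,
                             background_level = 0, organ_level = 1,
                             species_label = NULL, jitter_sd_mm = 0,
                             diameter_jitter_sd_mm = 0, seed = NULL) {
  array_type <- match.arg(array_type)
  n_lobes <- lobes_for_type(array_type, n_lobes)
  stop_if_not_positive(lobe_diameter_mm, "lobe_diameter_mm")
  stop_if_not_positive(lobe_spacing_mm, "lobe_spacing_mm")
  stop_if_not_positive(body_length_mm, "body_length_mm")
  stop_if_not_positive(canvas_mm, "canvas_mm")
  stop_if_not_nonnegative(jitter_sd_mm, "jitter_sd_mm")
  stop_if_not_nonnegative(diameter_jitter_sd_mm, "diameter_jitter_sd_mm")
  if (organ_level <= background_level) {
    abort("`organ_level` must exceed `background_level` (organs are rendered bright on dark).",
          class = "pestavision_input_error")
  }
  if (jitter_sd_mm == 0 && diameter_jitter_sd_mm == 0 &&
      lobe_spacing_mm <= lobe_diameter_mm) {
    abort("`lobe_spacing_mm` must exceed `lobe_diameter_mm` so lobes are disjoint.",
          class = "pestavision_input_error")
  }
  image_px <- as.integer(image_px)
  local_seed(seed)

  cx <- (seq_len(n_lobes) - (n_lobes + 1) / 2) * lobe_spacing_mm
  cy <- rep(0, n_lobes)
  diam <- rep(lobe_diameter_mm, n_lobes)
  if (jitter_sd_mm > 0) {
    cx <- cx + rnorm(n_lobes, 0, jitter_sd_mm)
    cy <- cy + rnorm(n_lobes, 0, jitter_sd_mm)
  }
  if (diameter_jitter_sd_mm > 0) {
    diam <- pmax(diam + rnorm(n_lobes, 0, diameter_jitter_sd_mm),
                 lobe_diameter_mm / 4)
  }
  if (any(abs(cx) + diam / 2 >= canvas_mm / 2) ||
      any(abs(cy) + diam / 2 >= canvas_mm / 2)) {
    abort("lobes overlap the image border; enlarge `canvas_mm` or shrink the array.",
          class = "pestavision_input_error")
  }

  mm_per_pixel <- canvas_mm / image_px
  # pixel-centre physical coordinates, canvas centred on the origin
  coord <- (seq_len(image_px) - (image_px + 1) / 2) * mm_per_pixel
  px <- matrix(background_level, image_px, image_px)
  for (i in seq_len(n_lobes)) {
    dx2 <- (coord - cx[i])^2           # columns: x
    dy2 <- (coord - cy[i])^2           # rows: y
    px[outer(dy2, dx2, `+`) <= (diam[i] / 2)^2] <- organ_level
  }

  structure(
    list(
      pixels = px,
      mm_per_pixel = mm_per_pixel,
      species_label = species_label %||% array_type,
      provenance = "generated",
      spec = list(array_type = array_type, n_lobes = n_lobes,
                  lobe_diameter_mm = lobe_diameter_mm,
                  lobe_spacing_mm = lobe_spacing_mm,
                  body_length_mm = body_length_mm, image_px = image_px,
                  canvas_mm = canvas_mm,
                  background_level = background_level,
                  organ_level = organ_level)
    ),
    class = "pattern_image"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pattern_image <- function(x, ...) {
  cat(sprintf(
    "<pattern_image> %s (%s), %d x %d px, %.4f mm/px, intensities [%.3f, %.3f]\n",
    x$species_label, x$provenance, nrow(x$pixels), ncol(x$pixels),
    x$mm_per_pixel, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @describeIn generate_pattern Raster plot of a pattern image.
#' @param object,x A `pattern_image`.
#' @param ... Unused.
#' @export
autoplot.pattern_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    y = seq_len(nrow(object$pixels)),
    x = seq_len(ncol(object$pixels))
  )
  df$intensity <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$species_label,
                  x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}
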