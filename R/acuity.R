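#' Angular size of an object at a viewing distance
#'
#' `theta = 2 * atan(s / (2 D))` in degrees, with the physical size in mm
#' and the distance in cm.
#'
#' @param physical_size_mm Object size in mm (> 0).
#' @param distance_cm Viewing distance in cm (> 0).
#' @return Angular size in degrees.
#' @export
#' @examples
#' angular_size(2, 2)     # 2 mm seen at 2 cm
angular_size <- function(physical_size_mm, distance_cm) {
  stop_if_not_positive(physical_size_mm, "physical_size_mm")
  stop_if_not_positive(distance_cm, "distance_cm")
  2 * atan(physical_size_mm / (2 * distance_cm * 10)) * 180 / pi
}

degrees_per_pixel <- function(mm_per_pixel, distance_cm) {
  angular_size(mm_per_pixel, distance_cm)
}

# signed FFT frequencies in cycles/degree for an axis of n pixels
fft_freq_deg <- function(n, deg_per_px) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * deg_per_px)
}

#' Acuity-limited rendering of a pattern image
#'
#' Low-pass filters an image in the Fourier domain with a radially symmetric
#' Gaussian modulation transfer function (MTF) parameterised by the viewer's
#' minimum resolvable angle: `MTF(f) = mtf_fraction ^ ((f * alpha_min)^2)`,
#' so the MTF is 1 at zero frequency (mean intensity is conserved) and falls
#' to `mtf_fraction` at the frequency `1 / alpha_min` cycles/degree. The
#' default fraction `exp(-3.56)` follows the convention of published
#' acuity-rendering software. Output intensities are clipped to `[0, 1]`.
#'
#' @param image A `pattern_image` (see [generate_pattern()]), at least
#'   8 x 8 pixels.
#' @param distance_cm Viewing distance in cm; with `image$mm_per_pixel` it
#'   sets the angular sampling (degrees/pixel).
#' @param alpha_min_deg Viewer's minimum resolvable angle in degrees (> 0).
#' @param mtf_fraction MTF value at the resolution-limit frequency, in
#'   (0, 1).
#' @return A `pattern_image` with filtered pixels and added fields
#'   `degrees_per_pixel`, `alpha_min_deg`, `distance_cm`.
#' @export
#' @examples
#' img <- generate_pattern("bilobed", lobe_diameter_mm = 1.2,
#'                         lobe_spacing_mm = 1.8, body_length_mm = 32,
#'                         image_px = 64)
#' blurred <- acuity_filter(img, distance_cm = 2, alpha_min_deg = 5.9)
acuity_filter <- function(image, distance_cm, alpha_min_deg,
                          mtf_fraction = exp(-3.56)) {
  stopifnot(inherits(image, "pattern_image"))
  stop_if_not_positive(alpha_min_deg, "alpha_min_deg")
  stop_if_not_positive(distance_cm, "distance_cm")
  if (mtf_fraction <= 0 || mtf_fraction >= 1) {
    abort("`mtf_fraction` must lie in (0, 1).",
          class = "pestavision_input_error")
  }
  px <- image$pixels
  if (nrow(px) < 8 || ncol(px) < 8) {
    abort("image must be at least 8 x 8 pixels.",
          class = "pestavision_input_error")
  }
  dpp <- degrees_per_pixel(image$mm_per_pixel, distance_cm)
  fy <- fft_freq_deg(nrow(px), dpp)
  fx <- fft_freq_deg(ncol(px), dpp)
  f2 <- outer(fy^2, fx^2, `+`)                  # |f|^2, cycles^2/deg^2
  mtf <- exp(log(mtf_fraction) * f2 * alpha_min_deg^2)
  filt <- Re(fft(fft(px) * mtf, inverse = TRUE)) / length(px)
  out <- image
  out$pixels <- pmin(pmax(filt, 0), 1)
  out$degrees_per_pixel <- dpp
  out$alpha_min_deg <- alpha_min_deg
  out$distance_cm <- distance_cm
  out
}

intensity_centroid <- function(px) {
  w <- pmax(px, 0)
  s <- sum(w)
  if (s == 0) return(c((nrow(px) + 1) / 2, (ncol(px) + 1) / 2))
  c(sum(rowSums(w) * seq_len(nrow(px))) / s,
    sum(colSums(w) * seq_len(ncol(px))) / s)
}

roll_matrix <- function(px, dr, dc) {
  n <- nrow(px); m <- ncol(px)
  px[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(m) - 1 - dc) %% m) + 1]
}

canonical_pattern <- function(px) {
  ctr <- intensity_centroid(px)
  target <- c((nrow(px) + 1) / 2, (ncol(px) + 1) / 2)
  px <- roll_matrix(px, round(target[1] - ctr[1]), round(target[2] - ctr[2]))
  s <- sum(px)
  if (s > 0) px <- px / s
  px
}

#' Discriminability index between two pattern images
#'
#' A normalised L2 distance on centroid-aligned, intensity-normalised
#' images: each image is circularly shifted so its intensity centroid sits
#' at the image centre, scaled to unit total intensity, then to unit L2
#' norm; the index is the Euclidean distance between the two unit vectors
#' divided by `sqrt(2)`. It is 0 for identical patterns, symmetric, obeys
#' the triangle inequality (up to the integer-pixel alignment) and is
#' bounded by 1 for non-negative images.
#'
#' @param image_a,image_b `pattern_image`s with identical dimensions and
#'   angular sampling (same `degrees_per_pixel` when filtered, same
#'   `mm_per_pixel` otherwise).
#' @return A single index in `[0, 1]`.
#' @export
discriminability <- function(image_a, image_b) {
  stopifnot(inherits(image_a, "pattern_image"),
            inherits(image_b, "pattern_image"))
  if (!identical(dim(image_a$pixels), dim(image_b$pixels))) {
    abort("images must have identical pixel dimensions.",
          class = "pestavision_input_error")
  }
  sa <- image_a$degrees_per_pixel %||% image_a$mm_per_pixel
  sb <- image_b$degrees_per_pixel %||% image_b$mm_per_pixel
  if (abs(sa - sb) > 1e-9 * max(sa, sb)) {
    abort("images must share the same angular (or physical) sampling.",
          class = "pestavision_input_error")
  }
  a <- canonical_pattern(image_a$pixels)
  b <- canonical_pattern(image_b$pixels)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    abort("cannot compare an all-zero image.",
          class = "pestavision_input_error")
  }
  sqrt(sum((a / na - b / nb)^2)) / sqrt(2)
}

#' Self-noise discriminability threshold for a generated pattern
#'
#' Builds the null distribution of discriminability between a pattern and
#' geometrically jittered copies of itself (per-lobe position and diameter
#' perturbations), all rendered through the same acuity filter, and returns
#' a high quantile. Patterns scoring below this threshold against a second
#' pattern are no more different from it than the pattern is from its own
#' within-individual variability.
#'
#' @param image A generated `pattern_image` (carries its `spec`).
#' @param distance_cm,alpha_min_deg,mtf_fraction Filter settings (see
#'   [acuity_filter()]).
#' @param n_null Number of jittered copies (default 40).
#' @param probs Null quantile (default 0.95).
#' @param position_jitter_frac Lobe-centre jitter SD as a fraction of lobe
#'   diameter (default 0.1). Scaling positional noise to the lobe's own size
#'   keeps the null comparable across arrays whose features differ in scale
#'   (developmental placement noise grows with the structure it places).
#' @param diameter_jitter_frac Lobe-diameter jitter SD as a fraction of lobe
#'   diameter (default 0.05).
#' @param seed Optional integer seed.
#' @return The threshold (single number).
#' @export
self_noise_threshold <- function(image, distance_cm, alpha_min_deg,
                                 mtf_fraction = exp(-3.56), n_null = 40,
                                 probs = 0.95, position_jitter_frac = 0.1,
                                 diameter_jitter_frac = 0.05, seed = NULL) {
  stopifnot(inherits(image, "pattern_image"))
  if (is.null(image$spec)) {
    abort("self-noise null needs a generated image with its spec.",
          class = "pestavision_input_error")
  }
  local_seed(seed)
  sp <- image$spec
  filtered <- acuity_filter(image, distance_cm, alpha_min_deg, mtf_fraction)
  null_d <- vapply(seq_len(n_null), function(i) {
    jit <- generate_pattern(
      array_type = sp$array_type, n_lobes = sp$n_lobes,
      lobe_diameter_mm = sp$lobe_diameter_mm,
      lobe_spacing_mm = sp$lobe_spacing_mm,
      body_length_mm = sp$body_length_mm, image_px = sp$image_px,
      canvas_mm = sp$canvas_mm, background_level = sp$background_level,
      organ_level = sp$organ_level, species_label = image$species_label,
      jitter_sd_mm = position_jitter_frac * sp$lobe_diameter_mm,
      diameter_jitter_sd_mm = diameter_jitter_frac * sp$lobe_diameter_mm)
    discriminability(filtered,
                     acuity_filter(jit, distance_cm, alpha_min_deg,
                                   mtf_fraction))
  }, numeric(1))
  unname(quantile(null_d, probs))
}

default_pattern_specs <- function() {
  list(
    `Parasergestes armatus` = list(array_type = "bilobed", n_lobes = 2L,
                                   lobe_diameter_mm = 1.2,
                                   lobe_spacing_mm = 1.8,
                                   body_length_mm = 32),
    `Allosergestes sargassi` = list(array_type = "trilobed", n_lobes = 3L,
                                    lobe_diameter_mm = 0.9,
                                    lobe_spacing_mm = 1.05,
                                    body_length_mm = 25),
    `Deosergestes henseni` = list(array_type = "fringed", n_lobes = 8L,
                                  lobe_diameter_mm = 0.3,
                                  lobe_spacing_mm = 0.42,
                                  body_length_mm = 41)
  )
}

#' Conspecific-recognition experiment over viewers, targets and distances
#'
#' Renders every species' light-organ pattern on a common canvas (equal
#' angular sampling), filters each through every viewer's acuity at every
#' viewing distance, and scores all between-target discriminability indices
#' against each viewer's self-noise threshold. Also reports whether each
#' filtered organ cluster remains detectable against the dark background
#' (positive organ-region contrast).
#'
#' @param species_specs Named list of pattern specs (fields `array_type`,
#'   `n_lobes`, `lobe_diameter_mm`, `lobe_spacing_mm`, `body_length_mm`);
#'   defaults to the three study species.
#' @param resolutions Named numeric vector of viewer `alpha_min` in degrees;
#'   defaults to the published per-species estimates.
#' @param distances_cm Viewing distances in cm (default `c(1, 2, 4)`).
#' @param threshold Fixed decision threshold in `[0, 1]`, or `NULL`
#'   (default) to use the self-noise null per viewer/distance (the maximum
#'   across target patterns of their null quantiles).
#' @param image_px,canvas_mm Common rendering canvas (default 192 px over
#'   12 mm).
#' @param n_null,mtf_fraction See [self_noise_threshold()] /
#'   [acuity_filter()].
#' @param seed Optional integer seed for the null draws.
#' @return A `recognition_matrix`: tibble with one row per viewer x distance
#'   x unordered target pair (`viewer`, `alpha_min_deg`, `distance_cm`,
#'   `target_a`, `target_b`, `index`, `threshold`, `distinguishable`), plus
#'   a `detectability` attribute (tibble of per-target filtered organ
#'   contrasts).
#' @export
recognition_experiment <- function(species_specs = default_pattern_specs(),
                                   resolutions = setNames(
                                     species_defaults()$alpha_min_deg,
                                     species_defaults()$species),
                                   distances_cm = c(1, 2, 4),
                                   threshold = NULL, image_px = 192L,
                                   canvas_mm = 12, n_null = 40,
                                   mtf_fraction = exp(-3.56), seed = NULL) {
  if (length(species_specs) == 0 || length(resolutions) == 0 ||
      length(distances_cm) == 0) {
    abort("species specs, resolutions and distances must be non-empty.",
          class = "pestavision_input_error")
  }
  if (is.null(names(species_specs)) || is.null(names(resolutions))) {
    abort("`species_specs` and `resolutions` must be named.",
          class = "pestavision_input_error")
  }
  local_seed(seed)
  patterns <- purrr::imap(species_specs, function(sp, nm) {
    generate_pattern(array_type = sp$array_type, n_lobes = sp$n_lobes,
                     lobe_diameter_mm = sp$lobe_diameter_mm,
                     lobe_spacing_mm = sp$lobe_spacing_mm,
                     body_length_mm = sp$body_length_mm,
                     image_px = image_px, canvas_mm = canvas_mm,
                     species_label = nm)
  })
  targets <- names(patterns)
  pairs <- utils::combn(targets, 2, simplify = FALSE)

  rows <- list()
  detect <- list()
  for (dist in distances_cm) {
    for (v in names(resolutions)) {
      alpha <- resolutions[[v]]
      filtered <- purrr::map(patterns, acuity_filter, distance_cm = dist,
                             alpha_min_deg = alpha,
                             mtf_fraction = mtf_fraction)
      nulls <- NULL
      if (is.null(threshold)) {
        nulls <- purrr::map_dbl(patterns, self_noise_threshold,
                                distance_cm = dist, alpha_min_deg = alpha,
                                mtf_fraction = mtf_fraction, n_null = n_null)
      }
      for (pr in pairs) {
        idx <- discriminability(filtered[[pr[1]]], filtered[[pr[2]]])
        # pair-specific null: the larger of the two compared patterns'
        # own self-noise quantiles (conservative)
        thr <- threshold %||% max(nulls[pr])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          viewer = v, alpha_min_deg = alpha, distance_cm = dist,
          target_a = pr[1], target_b = pr[2], index = idx,
          threshold = thr, distinguishable = idx > thr)
      }
      for (tg in targets) {
        mask <- patterns[[tg]]$pixels > patterns[[tg]]$spec$background_level
        fpx <- filtered[[tg]]$pixels
        detect[[length(detect) + 1L]] <- tibble::tibble(
          viewer = v, alpha_min_deg = alpha, distance_cm = dist,
          target = tg,
          organ_contrast = mean(fpx[mask]) - mean(fpx[!mask]),
          detectable = mean(fpx[mask]) - mean(fpx[!mask]) > 0)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            detectability = dplyr::bind_rows(detect),
            class = c("recognition_matrix", class(out)))
}

#' @export
autoplot.recognition_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- paste(df$target_a, "vs", df$target_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$viewer,
                                   fill = .data$index)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$distinguishable, "distinct", "merged")),
      size = 3, colour = "white") +
    ggplot2::facet_wrap(~distance_cm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "target pair", y = "viewer", fill = "index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
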