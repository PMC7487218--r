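#' Read and write morphometric tables
#'
#' Comma-separated, UTF-8, header row mandatory, `.` decimal; units embedded
#' in the column names (`eye_diameter_mm`, `body_length_mm`).
#'
#' @param path File path.
#' @param records Data frame of morphometric records.
#' @return `read_morphometrics()` returns a tibble; `write_morphometrics()`
#'   returns `path` invisibly.
#' @export
read_morphometrics <- function(path) {
  dat <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_morphometrics(dat, min_n = 1L)
  dat
}

#' @rdname read_morphometrics
#' @export
write_morphometrics <- function(records, path) {
  check_morphometrics(records, min_n = 1L)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a pattern image as 8-bit grayscale PNG with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `mm_per_pixel`, the species label,
#' provenance and the generating spec, so the physical scale survives the
#' round trip (PNG quantises intensities to 8 bits).
#'
#' @param image A `pattern_image`.
#' @param path PNG file path.
#' @return `write_pattern_png()` returns `path` invisibly;
#'   `read_pattern_png()` returns a `pattern_image`.
#' @export
write_pattern_png <- function(image, path) {
  stopifnot(inherits(image, "pattern_image"))
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG files.")
  }
  png::writePNG(image$pixels, path)
  sidecar <- list(mm_per_pixel = image$mm_per_pixel,
                  species_label = image$species_label,
                  provenance = image$provenance, spec = image$spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pattern_png
#' @export
read_pattern_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to read PNG files.")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(pixels = px, mm_per_pixel = meta$mm_per_pixel,
                 species_label = meta$species_label,
                 provenance = meta$provenance, spec = meta$spec),
            class = "pattern_image")
}

#' Default end-to-end pipeline configuration
#'
#' Collects every parameter of the four analysis stages, with defaults set
#' to the study conditions: species mean eye diameters 1.05 / 0.72 / 0.83 mm
#' (*D. henseni*, *A. sargassi*, *P. armatus*), photoreceptor diameter 3 µm,
#' integration time 0.05 s, zero ambient background, emission grid
#' `10^(8:11)` photons/s, viewing distances 1 / 2 / 4 cm and critical alpha
#' 0.016 for the sex ANCOVA.
#'
#' @param seed Top-level seed; all stage randomness flows from it through
#'   named substreams.
#' @param ... Overrides for any config entry.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    species = species_defaults(),
    scaling = published_scaling_coefficients(),
    environment = list(attenuation_per_m = 0.047, background_rate = 0),
    eye_physiology = list(photoreceptor_um = 3, integration_time_s = 0.05),
    emission_photons_per_s = 10^(8:11),
    viewing_distances_cm = c(1, 2, 4),
    alpha_critical = 0.016,
    allometry_n_per_group = 25L,
    allometry_noise_sd = 0.05,
    resolution_n_per_species = 4L,
    pattern_image_px = 192L,
    pattern_canvas_mm = 12,
    n_null = 40L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Published eye-to-body scaling coefficients
#'
#' Per species and sex: sample size, log10-scale intercept and slope of the
#' published allometric fits, shipped as a plain-text reference table and
#' used as generator truth for synthetic morphometrics.
#'
#' @return A tibble with columns `species`, `sex`, `n`, `log_intercept`,
#'   `slope`.
#' @export
published_scaling_coefficients <- function() {
  path <- system.file("extdata", "published_scaling_coefficients.csv",
                      package = "pestavision", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published eye-geometry summary
#'
#' Per species: mean and SD of eye radius of curvature, facet diameter and
#' the published minimum resolvable angle (n = 4 individuals per species).
#'
#' @return A tibble.
#' @export
published_eye_geometry <- function() {
  path <- system.file("extdata", "published_eye_geometry.csv",
                      package = "pestavision", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the four stages on synthetic inputs generated from the
#' configuration: (1) allometry — per-species/sex synthetic morphometrics
#' from the published coefficients, power-law fits and sex ANCOVA;
#' (2) sighting — the species x aperture x emission grid with aggregate
#' means; (3) resolution — synthetic per-individual eye geometries, per-
#' species `alpha_min` summary and the across-species ANOVA/Tukey test;
#' (4) acuity — the recognition experiment at the configured distances.
#' Deterministic under a fixed config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: `config_echo`, `allometry` (fits +
#'   ancova tibbles), `sighting_grid`, `sighting_aggregates`, `resolution`
#'   (summary + anova), `recognition` (decision matrix + detectability).
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(pipeline_config(seed = 1))
#' report$sighting_aggregates
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- allometry on synthetic records drawn from the published coefficients
  allo_seed <- seed_substream(config$seed, "allometry")
  scal <- config$scaling
  records <- purrr::map_dfr(unique(scal$species), function(sp) {
    rows <- scal[scal$species == sp, ]
    body <- config$species$body_length_mm[config$species$species == sp]
    rng <- c(0.6, 1.4) * body
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      rec <- generate_morphometrics(
        n_per_group = config$allometry_n_per_group,
        log_intercept = rows$log_intercept[i], slope = rows$slope[i],
        body_length_range = rng, noise_sd = config$allometry_noise_sd,
        species = sp, seed = allo_seed + i + match(sp, unique(scal$species)) * 101L)
      rec[rec$sex == rows$sex[i], ]
    })
  })
  fits <- purrr::map_dfr(split(records, paste(records$species, records$sex)),
                         function(g) {
    dplyr::bind_cols(tibble::tibble(species = g$species[1], sex = g$sex[1]),
                     glance(fit_power_law(g)))
  })
  ancova <- purrr::map_dfr(split(records, records$species), function(g) {
    dplyr::bind_cols(tibble::tibble(species = g$species[1]),
                     tidy(ancova_sex_comparison(
                       g, alpha_critical = config$alpha_critical)))
  })

  # --- sighting grid
  env <- optical_environment(config$environment$attenuation_per_m,
                             config$environment$background_rate)
  grid <- build_sighting_grid(
    species_eyes = config$species,
    emission_photons_per_s = config$emission_photons_per_s,
    env = env,
    photoreceptor_um = config$eye_physiology$photoreceptor_um,
    integration_time_s = config$eye_physiology$integration_time_s)

  # --- resolution on synthetic per-individual geometries
  res_seed <- seed_substream(config$seed, "resolution")
  geom <- published_eye_geometry()
  withr::with_seed(res_seed, {
    individuals <- purrr::map_dfr(seq_len(nrow(geom)), function(i) {
      n <- config$resolution_n_per_species
      tibble::tibble(
        species = geom$species[i],
        facet_diameter_um = pmax(rnorm(
          n, geom$facet_diameter_mean_um[i], geom$facet_diameter_sd_um[i]), 1),
        radius_of_curvature_mm = pmax(rnorm(
          n, geom$radius_of_curvature_mean_mm[i],
          geom$radius_of_curvature_sd_mm[i]), 0.05))
    })
  })
  res_summary <- species_resolution_summary(individuals)
  res_anova <- anova_tukey(individuals)

  # --- acuity / recognition, using the published alpha_min per viewer
  recog <- recognition_experiment(
    resolutions = setNames(config$species$alpha_min_deg,
                           config$species$species),
    distances_cm = config$viewing_distances_cm,
    image_px = config$pattern_image_px,
    canvas_mm = config$pattern_canvas_mm,
    n_null = config$n_null,
    seed = seed_substream(config$seed, "acuity"))

  structure(
    list(
      config_echo = unclass(config),
      allometry = list(records = records, fits = fits, ancova = ancova),
      sighting_grid = tidy(grid),
      sighting_aggregates = glance(grid),
      resolution = list(individuals = individuals, summary = res_summary,
                        anova = glance(res_anova),
                        tukey = tidy(res_anova)),
      recognition = list(matrix = tibble::as_tibble(recog),
                         detectability = attr(recog, "detectability"))
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  allometry: %d fits, %d ANCOVA rows\n",
              nrow(x$allometry$fits), nrow(x$allometry$ancova)))
  cat(sprintf("  sighting grid: %d rows; grand mean %.3f m\n",
              nrow(x$sighting_grid), x$sighting_aggregates$grand_mean_m))
  cat(sprintf("  resolution: F = %.2f, p = %.3g\n",
              x$resolution$anova$f, x$resolution$anova$p.value))
  cat(sprintf("  recognition: %d of %d pairs distinguishable\n",
              sum(x$recognition$matrix$distinguishable),
              nrow(x$recognition$matrix)))
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
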