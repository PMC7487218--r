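#' Species parameter defaults
#'
#' Mean eye diameters, adult body lengths, eye-contour radii of curvature,
#' mean facet diameters and published minimum resolvable angles for the
#' three sergestid study species. Eye diameters (1.05, 0.72, 0.83 mm for
#' *D. henseni*, *A. sargassi*, *P. armatus*) set the full eye aperture of
#' the sighting model; the half aperture is 50% of these.
#'
#' @return A tibble with one row per species: `species`, `array_type`,
#'   `eye_diameter_mm`, `body_length_mm`, `radius_of_curvature_mm`,
#'   `facet_diameter_um`, `alpha_min_deg` (published estimate).
#' @export
#' @examples
#' species_defaults()
species_defaults <- function() {
  tibble::tibble(
    species = c("Parasergestes armatus", "Allosergestes sargassi",
                "Deosergestes henseni"),
    array_type = c("bilobed", "trilobed", "fringed"),
    eye_diameter_mm = c(0.83, 0.72, 1.05),
    body_length_mm = c(32, 25, 41),
    radius_of_curvature_mm = c(0.3, 0.4, 0.5),
    facet_diameter_um = c(26.0, 27.2, 23.5),
    alpha_min_deg = c(10.8, 8.5, 5.9)
  )
}

# single scalar finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_positive <- function(x, name) {
  if (!all(is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", name),
          class = "pestavision_input_error")
  }
  invisible(x)
}

stop_if_not_nonnegative <- function(x, name) {
  if (!all(is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", name),
          class = "pestavision_input_error")
  }
  invisible(x)
}

# Seed handling: every stochastic generator takes `seed`; a non-NULL seed is
# applied locally so the caller's RNG stream is left untouched.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is_number(seed)) {
      abort("`seed` must be a single integer.",
            class = "pestavision_input_error")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(seed)
}

# Named substreams derived from one top-level pipeline seed. Offsets keep the
# substreams distinct while staying inside the 32-bit integer range.
seed_substream <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offsets <- c(allometry = 11L, sighting = 23L, resolution = 37L,
               acuity = 53L, patterns = 71L)
  if (!stream %in% names(offsets)) {
    abort(sprintf("unknown seed substream '%s'", stream))
  }
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]]
}
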