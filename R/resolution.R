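#' Least-squares circle fit (Kasa algebraic formulation)
#'
#' Fits a circle to 2-D points by linear least squares on the algebraic
#' form `x^2 + y^2 = 2 a x + 2 b y + (r^2 - a^2 - b^2)`. Closed form,
#' translation- and rotation-equivariant, and exact on noiseless circular
#' arcs; used to recover the radius of curvature of a traced eye contour.
#'
#' @param points Data frame or matrix with columns `x`, `y`; >= 3
#'   non-collinear points.
#' @return A `circle_fit` list: `center` (length-2), `radius`,
#'   `rms_residual`, `n`.
#' @export
#' @examples
#' fit_circle(generate_eye_contour(0.5, 50, arc_span = 120))
fit_circle <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) {
    colnames(pts)[1:2] <- c("x", "y")
  }
  x <- pts$x
  y <- pts$y
  if (length(x) < 3 || any(!is.finite(x)) || any(!is.finite(y))) {
    abort(">= 3 finite points are required.",
          class = "pestavision_input_error")
  }
  X <- cbind(2 * x, 2 * y, 1)
  # collinear points make the normal equations singular
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2) {
    abort("points are collinear; no circle can be fitted.",
          class = "pestavision_input_error")
  }
  sol <- lm.fit(X, x^2 + y^2)$coefficients
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean((d - radius)^2)), n = length(x)),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit> center (%.4f, %.4f), radius %.4f, rms residual %.2e (n = %d)\n",
    x$center[1], x$center[2], x$radius, x$rms_residual, x$n))
  invisible(x)
}

#' Interommatidial angle of a compound eye
#'
#' `delta_phi = facet diameter / radius of curvature` in radians, after
#' converting the facet diameter from µm and the radius from mm to a common
#' unit.
#'
#' @param facet_diameter_um Mean facet diameter in µm (> 0).
#' @param radius_of_curvature_mm Mean eye radius of curvature in mm (> 0).
#' @return Interommatidial angle in radians.
#' @export
#' @examples
#' interommatidial_angle(23.5, 0.5)
interommatidial_angle <- function(facet_diameter_um, radius_of_curvature_mm) {
  stop_if_not_positive(facet_diameter_um, "facet_diameter_um")
  stop_if_not_positive(radius_of_curvature_mm, "radius_of_curvature_mm")
  (facet_diameter_um * 1e-6) / (radius_of_curvature_mm * 1e-3)
}

#' Minimum resolvable angle of a compound eye
#'
#' `alpha_min = 2 * delta_phi`, converted from radians to degrees: the
#' smallest angular separation at which two points remain distinguishable
#' under the sampling limit of the ommatidial lattice.
#'
#' @inheritParams interommatidial_angle
#' @return Minimum resolvable angle in degrees.
#' @export
#' @examples
#' min_resolvable_angle(23.5, 0.5)   # ~5.4 degrees
min_resolvable_angle <- function(facet_diameter_um, radius_of_curvature_mm) {
  2 * interommatidial_angle(facet_diameter_um, radius_of_curvature_mm) *
    180 / pi
}

#' Per-species summary of minimum resolvable angle
#'
#' Computes each individual's `alpha_min` from its mean facet diameter and
#' radius of curvature, then summarises mean and SD per species.
#'
#' @param geometries Data frame with columns `species`, `facet_diameter_um`,
#'   `radius_of_curvature_mm` (one row per individual; per-facet replicate
#'   measurements should be averaged per individual beforehand) or a
#'   precomputed `alpha_min_deg` column.
#' @return A tibble with `species`, `n`, `alpha_min_mean_deg`,
#'   `alpha_min_sd_deg`, sorted by ascending mean (best resolution first).
#' @export
species_resolution_summary <- function(geometries) {
  g <- tibble::as_tibble(geometries)
  if (!"species" %in% names(g) || nrow(g) == 0) {
    abort("`geometries` needs a `species` column and >= 1 row.",
          class = "pestavision_input_error")
  }
  if (!"alpha_min_deg" %in% names(g)) {
    g <- dplyr::mutate(g, alpha_min_deg = min_resolvable_angle(
      .data$facet_diameter_um, .data$radius_of_curvature_mm))
  }
  out <- dplyr::summarise(
    dplyr::group_by(g, .data$species),
    n = dplyr::n(),
    alpha_min_mean_deg = mean(.data$alpha_min_deg),
    alpha_min_sd_deg = ifelse(dplyr::n() > 1, sd(.data$alpha_min_deg), 0),
    .groups = "drop")
  dplyr::arrange(out, .data$alpha_min_mean_deg)
}

#' One-way ANOVA with Tukey HSD on minimum resolvable angle
#'
#' Classical one-way ANOVA across species groups followed by Tukey's honest
#' significant difference on all pairwise comparisons (studentized-range
#' quantiles). Both the between-group and error degrees of freedom are
#' reported.
#'
#' @param geometries Data frame with `species` and `alpha_min_deg` columns
#'   (or facet/radius columns as in [species_resolution_summary()]).
#' @return A `resolution_anova` list: `f`, `df_between`, `df_error`,
#'   `p_value`, `tukey` (tibble: comparison, diff, lwr, upr, p_adj). Has a
#'   [tidy()] method returning the Tukey table.
#' @export
anova_tukey <- function(geometries) {
  g <- tibble::as_tibble(geometries)
  if (!"alpha_min_deg" %in% names(g)) {
    g <- dplyr::mutate(g, alpha_min_deg = min_resolvable_angle(
      .data$facet_diameter_um, .data$radius_of_curvature_mm))
  }
  g$species <- factor(g$species)
  if (nlevels(g$species) < 2 || any(table(g$species) < 2)) {
    abort(">= 2 groups with >= 2 observations each are required.",
          class = "pestavision_input_error")
  }
  within_var <- tapply(g$alpha_min_deg, g$species, var)
  if (all(within_var == 0)) {
    abort("degenerate input: zero within-group variance in every group; F is undefined.",
          class = "pestavision_numeric_error")
  }
  fit <- aov(alpha_min_deg ~ species, data = g)
  tab <- anova(fit)
  tk <- TukeyHSD(fit)$species
  structure(
    list(
      f = tab$`F value`[1],
      df_between = tab$Df[1],
      df_error = tab$Df[2],
      p_value = tab$`Pr(>F)`[1],
      tukey = tibble::tibble(
        comparison = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"])
    ),
    class = "resolution_anova"
  )
}

#' @export
print.resolution_anova <- function(x, ...) {
  cat(sprintf("<resolution_anova> F = %.3f (df = %d, %d), p = %.4g\n",
              x$f, x$df_between, x$df_error, x$p_value))
  print(x$tukey)
  invisible(x)
}

#' @export
tidy.resolution_anova <- function(x, ...) x$tukey

#' @export
glance.resolution_anova <- function(x, ...) {
  tibble::tibble(f = x$f, df_between = x$df_between, df_error = x$df_error,
                 p.value = x$p_value)
}
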