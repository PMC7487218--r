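check_morphometrics <- function(records, min_n = 3L) {
  needed <- c("eye_diameter_mm", "body_length_mm")
  if (!all(needed %in% names(records))) {
    abort("records need columns `eye_diameter_mm` and `body_length_mm`.",
          class = "pestavision_input_error")
  }
  if (nrow(records) < min_n) {
    abort(sprintf("at least %d records are required.", min_n),
          class = "pestavision_input_error")
  }
  if (any(!is.finite(records$eye_diameter_mm)) ||
      any(!is.finite(records$body_length_mm)) ||
      any(records$eye_diameter_mm <= 0) || any(records$body_length_mm <= 0)) {
    abort("all measurements must be positive and finite.",
          class = "pestavision_input_error")
  }
  invisible(records)
}

#' Fit an allometric power law to eye and body measurements
#'
#' Ordinary least squares of `log10(eye_diameter)` on `log10(body_length)`,
#' the log-linear form of the power function `eye = a * body^b`. The slope
#' classifies the scaling: < 1 negative allometry (relative eye size shrinks
#' with growth), = 1 isometry, > 1 positive allometry.
#'
#' @param records Data frame with positive `eye_diameter_mm` and
#'   `body_length_mm` columns; >= 3 rows.
#'
#' @return A `power_law_fit`: list with `log_intercept`, `slope`, `n`,
#'   `residual_sd`, `standard_errors` (intercept, slope), `allometry` label
#'   and the underlying `lm` fit. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
#' @examples
#' rec <- generate_morphometrics(20, -0.75, 0.48, c(13, 58), 0, seed = 1)
#' fit_power_law(rec)
fit_power_law <- function(records) {
  check_morphometrics(records)
  fit <- lm(log10(eye_diameter_mm) ~ log10(body_length_mm), data = records)
  cf <- coef(fit)
  # noiseless generator fixtures are a supported input: silence summary.lm's
  # "essentially perfect fit" note
  smry <- suppressWarnings(summary(fit))
  se <- smry$coefficients[, "Std. Error"]
  slope <- unname(cf[2])
  structure(
    list(
      log_intercept = unname(cf[1]),
      slope = slope,
      n = nrow(records),
      residual_sd = smry$sigma,
      standard_errors = unname(se),
      allometry = if (isTRUE(all.equal(slope, 1))) "isometry"
                  else if (slope < 1) "negative allometry"
                  else "positive allometry",
      fit = fit
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> log10(eye) = %.4f + %.4f log10(body)  (n = %d, %s)\n",
    x$log_intercept, x$slope, x$n, x$allometry))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("log_intercept", "slope"),
    estimate = c(x$log_intercept, x$slope),
    std.error = x$standard_errors
  )
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    slope = x$slope,
    log_intercept = x$log_intercept,
    residual_sd = x$residual_sd,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    allometry = x$allometry
  )
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  df <- object$fit$model
  names(df) <- c("log_eye", "log_body")
  ggplot2::ggplot(df, ggplot2::aes(.data$log_body, .data$log_eye)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$log_intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "log10 body length (mm)", y = "log10 eye diameter (mm)",
                  title = sprintf("slope = %.3f (%s)", object$slope,
                                  object$allometry)) +
    ggplot2::theme_minimal()
}

#' Relative eye size per record
#'
#' Appends the eye-to-body size ratio (`eye_diameter_mm / body_length_mm`),
#' the quantity whose decline with body length marks negative allometry.
#'
#' @inheritParams fit_power_law
#' @return The input as a tibble with an added `eye_body_ratio` column.
#' @export
#' @examples
#' rec <- generate_morphometrics(5, -0.72, 0.44, c(15, 40), 0.02, seed = 2)
#' relative_eye_size(rec)
relative_eye_size <- function(records) {
  check_morphometrics(records, min_n = 1L)
  dplyr::mutate(tibble::as_tibble(records),
                eye_body_ratio = .data$eye_diameter_mm / .data$body_length_mm)
}

#' ANCOVA test for sexual dimorphism in eye scaling
#'
#' Nested linear-model F-tests on the log10-log10 data: first the
#' sex-by-body-length interaction (slope homogeneity), then, with a common
#' slope imposed, the sex main effect (intercept difference). The groups are
#' judged dimorphic when the slope test rejects, or when slopes are
#' homogeneous and the intercept test rejects, at `alpha_critical`
#' (default 0.016, a Bonferroni-corrected level for three species).
#'
#' @param males,females Data frames of records for each sex (see
#'   [fit_power_law()] for required columns), or a single data frame with a
#'   `sex` column passed as `males` with `females = NULL`.
#' @param alpha_critical Decision threshold (default 0.016).
#'
#' @return An `ancova_sex` list: `f_slope`, `p_slope`, `f_intercept`,
#'   `p_intercept` (intercept entries are `NA` when slopes already differ),
#'   `alpha_critical`, `dimorphic`, `n`. Has a [tidy()] method.
#' @export
#' @examples
#' f <- generate_morphometrics(25, -0.75, 0.48, c(13, 58), 0.05, seed = 3)
#' ancova_sex_comparison(f)
ancova_sex_comparison <- function(males, females = NULL,
                                  alpha_critical = 0.016) {
  if (is.null(females)) {
    dat <- tibble::as_tibble(males)
    if (!"sex" %in% names(dat)) {
      abort("a single-table call needs a `sex` column.",
            class = "pestavision_input_error")
    }
  } else {
    check_morphometrics(males)
    check_morphometrics(females)
    dat <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(males), sex = "male"),
      dplyr::mutate(tibble::as_tibble(females), sex = "female")
    )
  }
  check_morphometrics(dat, min_n = 6L)
  if (length(unique(dat$sex)) != 2) {
    abort("exactly two sex groups are required.",
          class = "pestavision_input_error")
  }
  spread <- tapply(dat$body_length_mm, dat$sex, function(v) diff(range(v)))
  if (any(spread == 0)) {
    abort("degenerate design: all body lengths equal within a group.",
          class = "pestavision_input_error")
  }
  stop_if_not_positive(alpha_critical, "alpha_critical")

  dat$log_eye <- log10(dat$eye_diameter_mm)
  dat$log_bl <- log10(dat$body_length_mm)
  full <- lm(log_eye ~ log_bl * sex, data = dat)
  common <- lm(log_eye ~ log_bl + sex, data = dat)
  slope_tab <- anova(common, full)
  f_slope <- slope_tab$F[2]
  p_slope <- slope_tab$`Pr(>F)`[2]

  slopes_differ <- p_slope < alpha_critical
  if (slopes_differ) {
    f_int <- NA_real_
    p_int <- NA_real_
  } else {
    pooled <- lm(log_eye ~ log_bl, data = dat)
    int_tab <- anova(pooled, common)
    f_int <- int_tab$F[2]
    p_int <- int_tab$`Pr(>F)`[2]
  }
  structure(
    list(
      f_slope = f_slope, p_slope = p_slope,
      f_intercept = f_int, p_intercept = p_int,
      alpha_critical = alpha_critical,
      dimorphic = slopes_differ || (!is.na(p_int) && p_int < alpha_critical),
      n = nrow(dat)
    ),
    class = "ancova_sex"
  )
}

#' @export
print.ancova_sex <- function(x, ...) {
  cat(sprintf(
    "<ancova_sex> slope: F = %.3f, p = %.4f; intercept: F = %s, p = %s; dimorphic: %s (alpha = %.3f)\n",
    x$f_slope, x$p_slope,
    ifelse(is.na(x$f_intercept), "-", sprintf("%.3f", x$f_intercept)),
    ifelse(is.na(x$p_intercept), "-", sprintf("%.4f", x$p_intercept)),
    x$dimorphic, x$alpha_critical))
  invisible(x)
}

#' @export
tidy.ancova_sex <- function(x, ...) {
  tibble::tibble(
    term = c("slope (sex x body length)", "intercept (sex)"),
    statistic = c(x$f_slope, x$f_intercept),
    p.value = c(x$p_slope, x$p_intercept),
    alpha_critical = x$alpha_critical,
    dimorphic = x$dimorphic
  )
}
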