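## broom-style tidiers for the fitted objects.

#' Tidy a trend model
#'
#' For the GLM path, the coefficient table; for the GAM path, the smooth
#' terms with effective degrees of freedom and approximate p-values.
#'
#' @param x A `trend_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trend_model <- function(x, ...) {
  if (x$family == "glm") {
    co <- summary(x$fit)$coefficients
    tibble::tibble(
      term = rownames(co), estimate = co[, 1], std_error = co[, 2],
      statistic = co[, 3], p_value = co[, 4]
    )
  } else {
    s <- summary(x$fit)$s.table
    tibble::tibble(
      term = rownames(s), edf = s[, "edf"], ref_df = s[, "Ref.df"],
      statistic = s[, 3], p_value = s[, 4]
    )
  }
}

#' @rdname tidy.trend_model
#' @export
glance.trend_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, n_terms = length(x$selected_terms),
    dispersion = x$dispersion, deviance_explained = x$deviance_explained,
    n = stats::nobs(x$fit)
  )
}

#' Tidy a variogram model
#'
#' @param x A `variogram_model`.
#' @param ... Unused.
#' @return One-row tibble with family and parameters.
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, nugget = x$nugget, psill = x$psill, range = x$range,
    sill = x$nugget + x$psill, wsse = x$wsse
  )
}

#' Tidy a spatial mixed-model fit
#'
#' @param x A `spatial_lmm`.
#' @param ... Unused.
#' @return Tibble with the main SES coefficient and its Wald 95% CI.
#' @export
tidy.spatial_lmm <- function(x, ...) {
  tibble::tibble(
    term = x$ses_var, estimate = x$coefficient, std_error = x$se,
    conf_low = x$ci[1], conf_high = x$ci[2]
  )
}

#' @rdname tidy.spatial_lmm
#' @export
glance.spatial_lmm <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n, spatial = x$spatial,
    spatial_range = x$spatial_range, county_variance = x$county_variance,
    residual_sd = x$residual_sd, fallback = x$fallback, method = x$method
  )
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The method-by-split metric table.
#' @export
tidy.cv_report <- function(x, ...) {
  x$metrics
}
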