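## Tract-level aggregation and socioeconomic disparity analysis.

#' Aggregate a cell-level map to census tracts
#'
#' Computes, for each tract rectangle, the area-weighted mean of the
#' intersecting cell values (weights = exact rectangle intersection areas).
#' Tracts intersecting no cell get `NA` and are flagged.
#'
#' @param map Tibble with `cell_id` and one or more value columns.
#' @param tracts Tract tibble with `tract_id`, `xmin`, `xmax`, `ymin`,
#'   `ymax`.
#' @param grid A [grid_spec()] describing the cell geometry.
#' @param cells Tibble with `cell_id`, `x`, `y` centroids (e.g. the
#'   landscape grid).
#' @param value_cols Columns of `map` to aggregate.
#' @return `tracts` with the aggregated columns appended and a logical
#'   `no_overlap` flag.
#' @export
summarize_to_tracts <- function(map, tracts, grid, cells,
                                value_cols = setdiff(names(map), "cell_id")) {
  stopifnot(inherits(grid, "grid_spec"))
  bad <- tracts$xmin >= tracts$xmax | tracts$ymin >= tracts$ymax
  if (any(bad)) {
    stop("geometry error: degenerate tract rectangles: ",
         paste(tracts$tract_id[bad], collapse = ", "))
  }
  agg <- aggregate_cells_to_rects(
    tracts, cells, map,
    cell_size = grid$cell_size, value_cols = value_cols
  )
  res <- agg[match(tracts$tract_id, agg$tract_id), value_cols, drop = FALSE]
  clash <- names(res) %in% names(tracts)
  names(res)[clash] <- paste0(names(res)[clash], "_agg")
  out <- dplyr::bind_cols(tracts, res)
  out$no_overlap <- is.na(res[[1]])
  out
}

#' Compare diversity between disadvantaged and other communities
#'
#' Welch two-sample t-test of each diversity metric between the flagged
#' group (e.g. disadvantaged communities) and the rest.
#'
#' @param tracts Tract tibble.
#' @param metrics Metric columns to compare.
#' @param flag Logical grouping column (default `"dac"`).
#' @return Tibble: metric, group means (SD), group sizes and p-value.
#' @export
compare_groups <- function(tracts, metrics, flag = "dac") {
  g <- tracts[[flag]]
  if (sum(g) < 2 || sum(!g) < 2) {
    stop("test error: each group needs at least 2 tracts")
  }
  purrr::map_dfr(metrics, function(m) {
    a <- tracts[[m]][g]
    b <- tracts[[m]][!g]
    tt <- tryCatch(stats::t.test(a, b), error = function(e) {
      stop("degenerate input for metric '", m, "': ", conditionMessage(e))
    })
    tibble::tibble(
      metric = m,
      mean_flagged = mean(a), sd_flagged = stats::sd(a), n_flagged = length(a),
      mean_other = mean(b), sd_other = stats::sd(b), n_other = length(b),
      p_value = tt$p.value
    )
  })
}

#' Pearson correlations between diversity metrics and tract variables
#'
#' @param tracts Tract tibble.
#' @param metrics Diversity metric columns.
#' @param variables Sociodemographic columns.
#' @return Tibble: metric, variable, Pearson `r`, `n` complete pairs
#'   (constant columns give `NA` with a warning).
#' @export
correlate_diversity <- function(tracts, metrics, variables) {
  out <- tidyr::expand_grid(metric = metrics, variable = variables)
  res <- purrr::pmap_dfr(out, function(metric, variable) {
    x <- tracts[[metric]]
    y <- tracts[[variable]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) {
      return(tibble::tibble(r = NA_real_, n = sum(ok)))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("constant column in pair (", metric, ", ", variable,
              "); correlation undefined")
      return(tibble::tibble(r = NA_real_, n = sum(ok)))
    }
    tibble::tibble(r = stats::cor(x[ok], y[ok]), n = sum(ok))
  })
  dplyr::bind_cols(out, res)
}

#' Spatially correlated linear mixed model for a disparity association
#'
#' Linear mixed model of a diversity metric on one sociodemographic
#' variable, adjusted for population density, with a county random
#' intercept and an exponential spatial correlation structure on tract
#' centroids; fitted by REML. If the spatial fit fails to converge the
#' model falls back to independent residuals with a warning flag.
#'
#' @param tracts Tract tibble with the outcome, SES variable, adjustment
#'   variable(s), `county` and centroid columns.
#' @param ses_var Main fixed-effect column.
#' @param outcome Outcome column.
#' @param adjust Adjustment columns (default population density).
#' @param coords Centroid coordinate columns.
#' @param county Grouping column for the random intercept.
#' @param spatial Include the exponential spatial correlation.
#' @param random_county Include the county random intercept.
#' @param method `"REML"` (default) or `"ML"` (for likelihood-based model
#'   comparison).
#' @return Object of class `spatial_lmm`: coefficient, standard error, 95%
#'   Wald CI, spatial range, variance components, convergence info and the
#'   underlying nlme fit.
#' @export
fit_spatial_lmm <- function(tracts, ses_var, outcome,
                            adjust = "pop_density",
                            coords = c("cx", "cy"), county = "county",
                            spatial = TRUE, random_county = TRUE,
                            method = "REML") {
  if (nrow(tracts) < 30) stop("fit error: need at least 30 tracts")
  if (random_county && length(unique(tracts[[county]])) < 3) {
    stop("fit error: need at least 3 counties for the random intercept")
  }
  dat <- as.data.frame(tracts)
  dat$.county <- factor(dat[[county]])
  dat$.cx <- dat[[coords[1]]]
  dat$.cy <- dat[[coords[2]]]
  fixed <- stats::reformulate(c(ses_var, adjust), response = outcome)

  cor_form <- if (random_county) {
    stats::as.formula("~ .cx + .cy | .county")
  } else {
    stats::as.formula("~ .cx + .cy")
  }
  fit_once <- function(use_spatial) {
    if (random_county) {
      nlme::lme(
        fixed = fixed, data = dat, random = ~ 1 | .county,
        correlation = if (use_spatial) nlme::corExp(form = cor_form) else NULL,
        method = method, control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                                    msMaxIter = 200)
      )
    } else {
      nlme::gls(
        model = fixed, data = dat,
        correlation = if (use_spatial) nlme::corExp(form = cor_form) else NULL,
        method = method,
        control = nlme::glsControl(maxIter = 200, msMaxIter = 200)
      )
    }
  }
  fallback <- FALSE
  fit <- NULL
  if (spatial) {
    fit <- tryCatch(fit_once(TRUE), error = function(e) NULL)
    if (is.null(fit)) {
      warning("spatial correlation fit failed to converge; ",
              "falling back to independent residuals")
      fallback <- TRUE
    }
  }
  if (is.null(fit)) {
    fit <- fit_once(FALSE)
  }
  used_spatial <- spatial && !fallback

  beta <- if (random_county) nlme::fixef(fit) else stats::coef(fit)
  vc <- stats::vcov(fit)
  est <- beta[[ses_var]]
  se <- sqrt(diag(vc))[[ses_var]]
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se
  range_est <- if (used_spatial) {
    as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))[1]
  } else {
    NA_real_
  }
  county_var <- if (random_county) {
    as.numeric(nlme::VarCorr(fit)[1, "Variance"])
  } else {
    NA_real_
  }
  structure(
    list(
      fit = fit, ses_var = ses_var, outcome = outcome,
      coefficient = est, se = se, ci = ci,
      spatial_range = range_est, county_variance = county_var,
      residual_sd = stats::sigma(fit),
      spatial = used_spatial, random_county = random_county,
      fallback = fallback, method = method, n = nrow(dat)
    ),
    class = "spatial_lmm"
  )
}

#' @export
print.spatial_lmm <- function(x, ...) {
  cat(sprintf(
    "<spatial_lmm> %s ~ %s: coefficient %.3f (95%% CI %.3f, %.3f)%s\n",
    x$outcome, x$ses_var, x$coefficient, x$ci[1], x$ci[2],
    if (x$fallback) " [independent-residual fallback]" else ""
  ))
  invisible(x)
}

#' Sensitivity analyses for the disparity models
#'
#' Fits (1) the full model with all retained SES factors (poverty and
#' housing burden are excluded from the full set to avoid collinearity)
#' plus population density, (2) backward elimination from the full model
#' reporting AIC and BIC at each step (ML fits, so likelihoods are
#' comparable across fixed-effect sets), and (3) the single-SES models with
#' the vegetation index added as a confounder.
#'
#' @param tracts Tract tibble.
#' @param ses_set SES columns for the full model (must exclude poverty and
#'   housing burden).
#' @param outcome Outcome column.
#' @param ndvi Vegetation-index column for the confounder analysis.
#' @param adjust Always-kept adjustment column (population density).
#' @param ... Passed to [fit_spatial_lmm()] (coords, county, spatial, ...).
#' @return List with `full` (coefficient tibble), `backward` (step table
#'   with AIC/BIC), `single` and `ndvi_adjusted` (coefficient tibbles).
#' @export
sensitivity_models <- function(tracts,
                               ses_set = c("educational_attainment_pct",
                                           "linguistic_isolation_pct",
                                           "unemployment_pct"),
                               outcome, ndvi = "ndvi_mean",
                               adjust = "pop_density", ...) {
  banned <- c("poverty_pct", "housing_burden_pct")
  if (any(ses_set %in% banned)) {
    stop("the full-model SES set must exclude poverty and housing burden")
  }
  coef_row <- function(fit, term) {
    tibble::tibble(
      term = term, estimate = fit$coefficient,
      se = fit$se, conf_low = fit$ci[1], conf_high = fit$ci[2]
    )
  }
  # full model: report each SES coefficient, adjusting for the others
  full <- purrr::map_dfr(ses_set, function(v) {
    fit <- fit_spatial_lmm(tracts, v, outcome,
      adjust = c(setdiff(ses_set, v), adjust), ...
    )
    coef_row(fit, v)
  })

  # backward elimination on ML AIC (BIC reported alongside)
  steps <- list()
  current <- ses_set
  ic <- function(vars) {
    fit <- fit_spatial_lmm(tracts, vars[1], outcome,
      adjust = c(vars[-1], adjust), method = "ML", ...
    )
    c(AIC = stats::AIC(fit$fit), BIC = stats::BIC(fit$fit))
  }
  current_ic <- ic(current)
  steps[[1]] <- tibble::tibble(
    step = 0L, model = paste(current, collapse = " + "),
    AIC = current_ic["AIC"], BIC = current_ic["BIC"], dropped = NA_character_
  )
  s <- 1L
  while (length(current) > 1) {
    cand <- purrr::map(current, function(v) ic(setdiff(current, v)))
    aics <- vapply(cand, `[`, numeric(1), "AIC")
    if (min(aics) >= current_ic["AIC"]) break
    drop_idx <- which.min(aics)
    dropped <- current[drop_idx]
    current <- setdiff(current, dropped)
    current_ic <- cand[[drop_idx]]
    steps[[s + 1L]] <- tibble::tibble(
      step = s, model = paste(current, collapse = " + "),
      AIC = current_ic["AIC"], BIC = current_ic["BIC"], dropped = dropped
    )
    s <- s + 1L
  }

  single <- purrr::map_dfr(ses_set, function(v) {
    coef_row(fit_spatial_lmm(tracts, v, outcome, adjust = adjust, ...), v)
  })
  ndvi_adjusted <- purrr::map_dfr(ses_set, function(v) {
    coef_row(
      fit_spatial_lmm(tracts, v, outcome, adjust = c(adjust, ndvi), ...), v
    )
  })
  list(
    full = full, backward = dplyr::bind_rows(steps),
    single = single, ndvi_adjusted = ndvi_adjusted
  )
}
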