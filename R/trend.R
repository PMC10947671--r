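## Covariate preparation and quasi-Poisson trend models (GLM / GAM).

#' Fill missing covariate values from spatial neighbors
#'
#' Replaces each missing covariate value with the mean of the non-missing
#' values whose cell centroids lie within `radius_m` of the target centroid
#' (the protocol used for patchy soil-survey attributes). Cells with data
#' are never altered.
#'
#' @param stack Tibble with `x`, `y` centroids and covariate columns.
#' @param predictors Covariate columns to fill (default: all numeric columns
#'   except `x`/`y` and identifiers).
#' @param radius_m Neighborhood radius in metres (default 8000).
#' @return `stack` with missing values filled.
#' @export
fill_missing_covariate <- function(stack, predictors = NULL, radius_m = 8000) {
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(stack)[vapply(stack, is.numeric, logical(1))],
      c("x", "y", "row", "col")
    )
  }
  coords <- as.matrix(stack[, c("x", "y")])
  offenders <- character()
  for (p in predictors) {
    v <- stack[[p]]
    miss <- which(is.na(v))
    for (i in miss) {
      d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
      nb <- which(d <= radius_m & !is.na(v) & seq_along(v) != i)
      if (length(nb) == 0) {
        offenders <- c(offenders, sprintf("%s@%s", p, stack$cell_id[i]))
      } else {
        stack[[p]][i] <- mean(v[nb])
      }
    }
  }
  if (length(offenders) > 0) {
    stop("unfilled cells (no neighbor within radius): ",
         paste(offenders, collapse = ", "))
  }
  stack
}

#' Standardize covariates to mean 0, sd 1
#'
#' @param stack Tibble holding the covariate columns.
#' @param predictors Columns to standardize.
#' @param stats Optional standardization record (tibble `predictor`, `mean`,
#'   `sd`) from a training set; if supplied it is applied as-is, so held-out
#'   data is scaled with training statistics.
#' @return List with `data` (standardized tibble) and `stats`.
#' @export
standardize_covariates <- function(stack, predictors, stats = NULL) {
  if (is.null(stats)) {
    stats <- tibble::tibble(
      predictor = predictors,
      mean = vapply(predictors, function(p) mean(stack[[p]]), numeric(1)),
      sd = vapply(predictors, function(p) stats::sd(stack[[p]]), numeric(1))
    )
    stats$sd[stats$sd == 0] <- 1
  }
  for (i in seq_len(nrow(stats))) {
    p <- stats$predictor[i]
    stack[[p]] <- (stack[[p]] - stats$mean[[i]]) / stats$sd[[i]]
  }
  list(data = stack, stats = stats)
}

#' Screen candidate covariates
#'
#' Two-stage screening: (1) among each collinear pair (`|r| >
#' collinearity`), drop the member with the smaller absolute outcome
#' correlation, processing pairs in descending `|r|` until none remains;
#' (2) drop predictors whose absolute outcome correlation is at most
#' `min_cor`.
#'
#' @param stack Tibble with (standardized) covariate columns.
#' @param y Outcome vector (a diversity metric on the training cells).
#' @param predictors Candidate covariate columns.
#' @param collinearity Pairwise collinearity threshold (default 0.8).
#' @param min_cor Minimum absolute outcome correlation (default 0.1).
#' @return Character vector of retained predictors, with attributes
#'   `dropped_collinear` and `dropped_weak`.
#' @export
screen_covariates <- function(stack, y, predictors,
                              collinearity = 0.8, min_cor = 0.1) {
  keep <- predictors
  dropped_collinear <- character()
  cor_y <- vapply(predictors, function(p) {
    suppressWarnings(stats::cor(stack[[p]], y))
  }, numeric(1))
  cor_y[is.na(cor_y)] <- 0
  repeat {
    if (length(keep) < 2) break
    cm <- abs(suppressWarnings(stats::cor(as.matrix(stack[keep]))))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    if (max(cm) <= collinearity) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]
    b <- keep[idx[2]]
    loser <- if (abs(cor_y[a]) >= abs(cor_y[b])) b else a
    dropped_collinear <- c(dropped_collinear, loser)
    keep <- setdiff(keep, loser)
  }
  dropped_weak <- keep[abs(cor_y[keep]) <= min_cor]
  keep <- setdiff(keep, dropped_weak)
  if (length(keep) < 1) {
    stop("screening error: no predictor survives the correlation screens")
  }
  attr(keep, "dropped_collinear") <- dropped_collinear
  attr(keep, "dropped_weak") <- dropped_weak
  keep
}

#' Fit a quasi-Poisson trend model
#'
#' Log-link quasi-Poisson regression of a diversity metric on screened
#' covariates. The GLM path performs both-direction stepwise selection on
#' quasi-AIC (dispersion estimated from the full model); the GAM path fits
#' penalized univariate smooths plus one two-dimensional Duchon-spline
#' smooth of the coordinates, with smoothing parameters selected by REML
#' under the double-penalty (shrinkage) approach so that irrelevant terms
#' can be shrunk out entirely.
#'
#' @param data Tibble with the response, predictors and `x`, `y` centroids.
#' @param response Response column name (positive values; log link).
#' @param predictors Covariate column names (already standardized).
#' @param family `"gam"` (default) or `"glm"`.
#' @param use_longitude For the GLM path, include the x coordinate as a
#'   predictor (latitude is excluded there; both coordinates enter the GAM
#'   through the spatial smooth).
#' @param k_smooth Basis dimension of univariate smooths.
#' @param k_spatial Basis dimension of the 2-D spatial smooth.
#' @return Object of class `trend_model`.
#' @export
fit_trend <- function(data, response, predictors,
                      family = c("gam", "glm"), use_longitude = TRUE,
                      k_smooth = 5, k_spatial = 25) {
  family <- match.arg(family)
  yv <- data[[response]]
  if (any(yv <= 0)) {
    stop("fit error: response must be strictly positive under the log link")
  }
  # guard: ~10 training rows per candidate term
  max_terms <- max(1L, floor(nrow(data) / 10))
  if (length(predictors) > max_terms) {
    cor_y <- vapply(predictors, function(p) {
      abs(suppressWarnings(stats::cor(data[[p]], yv)))
    }, numeric(1))
    predictors <- names(sort(cor_y, decreasing = TRUE))[seq_len(max_terms)]
    warning("too many terms for the sample size; keeping the ",
            max_terms, " best-correlated predictors")
  }

  if (family == "glm") {
    terms0 <- c(predictors, if (use_longitude) "x")
    if (stats::var(yv) == 0) {
      # degenerate constant response: intercept-only by construction
      fit <- stats::glm(stats::reformulate("1", response = response),
                        data = data, family = stats::quasipoisson())
      return(structure(
        list(family = "glm", fit = fit, response = response,
             selected_terms = character(), dispersion = 0,
             deviance_explained = 0, predictors = predictors),
        class = "trend_model"
      ))
    }
    full_formula <- stats::reformulate(terms0, response = response)
    full <- stats::glm(full_formula, data = data, family = stats::quasipoisson())
    phi <- summary(full)$dispersion
    fit <- stepwise_qaic(data, response, terms0, phi)
    mu <- stats::fitted(fit)
    dev_expl <- 1 - fit$deviance / fit$null.deviance
    obj <- list(
      family = "glm", fit = fit, response = response,
      selected_terms = attr(stats::terms(fit), "term.labels"),
      dispersion = summary(fit)$dispersion,
      deviance_explained = dev_expl
    )
  } else {
    k_smooth <- min(k_smooth, max(3, length(unique(yv)) - 1))
    sm <- vapply(predictors, function(p) {
      sprintf("s(%s, bs = \"cr\", k = %d)", p, k_smooth)
    }, character(1))
    spatial <- sprintf("s(x, y, bs = \"ds\", m = c(1, 0.5), k = %d)",
                       min(k_spatial, max(10, floor(nrow(data) / 4))))
    f <- stats::as.formula(paste(
      response, "~", paste(c(sm, spatial), collapse = " + ")
    ))
    fit <- mgcv::gam(f, data = data, family = stats::quasipoisson(),
                     method = "REML", select = TRUE)
    obj <- list(
      family = "gam", fit = fit, response = response,
      selected_terms = predictors,
      dispersion = fit$scale,
      deviance_explained = summary(fit)$dev.expl
    )
  }
  obj$predictors <- predictors
  structure(obj, class = "trend_model")
}

## Both-direction stepwise minimization of QAIC = deviance / phi + 2 (p + 1),
## with the dispersion phi fixed at its full-model estimate.
stepwise_qaic <- function(data, response, terms_all, phi) {
  qaic <- function(fit) {
    fit$deviance / phi + 2 * (length(stats::coef(fit)) + 1)
  }
  refit <- function(terms) {
    f <- if (length(terms) == 0) {
      stats::reformulate("1", response = response)
    } else {
      stats::reformulate(terms, response = response)
    }
    stats::glm(f, data = data, family = stats::quasipoisson())
  }
  current_terms <- terms_all
  current <- refit(current_terms)
  current_q <- qaic(current)
  repeat {
    candidates <- list()
    for (tm in current_terms) {
      candidates[[paste0("-", tm)]] <- setdiff(current_terms, tm)
    }
    for (tm in setdiff(terms_all, current_terms)) {
      candidates[[paste0("+", tm)]] <- c(current_terms, tm)
    }
    if (length(candidates) == 0) break
    qs <- vapply(candidates, function(tm) qaic(refit(tm)), numeric(1))
    if (min(qs) >= current_q - 1e-8) break
    current_terms <- candidates[[which.min(qs)]]
    current <- refit(current_terms)
    current_q <- qaic(current)
  }
  current
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf(
    "<trend_model> %s (quasi-Poisson, log link): %d terms, dispersion %.3f, deviance explained %.1f%%\n",
    toupper(x$family), length(x$selected_terms), x$dispersion,
    100 * x$deviance_explained
  ))
  invisible(x)
}

#' Predict from a trend model
#'
#' @param object A `trend_model`.
#' @param newdata Tibble with the predictor and coordinate columns.
#' @param ... Unused.
#' @return Tibble with `mu` (response-scale fitted mean) and `se`
#'   (response-scale standard error of the fitted mean).
#' @export
predict.trend_model <- function(object, newdata, ...) {
  pr <- stats::predict(object$fit, newdata = newdata, type = "response",
                       se.fit = TRUE)
  tibble::tibble(mu = as.numeric(pr$fit), se = as.numeric(pr$se.fit))
}

#' Regression kriging
#'
#' Superimposes ordinary-kriged response-scale residuals of a fitted trend
#' model onto its predictions: `prediction = mu(target) + OK(y - mu)(target)`.
#' For the pure-regression variants the residual term is zero. Final
#' predictions are floored at the minimum observed metric so that residual
#' superposition cannot produce implausibly small diversity.
#'
#' @param trend A fitted `trend_model`.
#' @param train Training tibble (rows the trend was fitted on), with `x`,
#'   `y` and the response.
#' @param targets Tibble of all cells to predict (`x`, `y`, predictors).
#' @param krige_residuals If `FALSE`, skip kriging (pure GLM/GAM).
#' @param vg Optional pre-fitted residual `variogram_model`; fitted from the
#'   training residuals when `NULL`.
#' @param n_bins,max_lag Passed to [empirical_variogram()].
#' @return Tibble with `trend`, `trend_se`, `resid_ok`, `ok_variance`,
#'   `prediction` and `se` per target row.
#' @export
regression_krige <- function(trend, train, targets, krige_residuals = TRUE,
                             vg = NULL, n_bins = 15, max_lag = NULL) {
  stopifnot(inherits(trend, "trend_model"))
  mu_train <- predict(trend, train)$mu
  resid <- train[[trend$response]] - mu_train
  pr <- predict(trend, targets)
  if (krige_residuals) {
    if (is.null(vg)) {
      ev <- empirical_variogram(train[, c("x", "y")], resid,
                                n_bins = n_bins, max_lag = max_lag)
      vg <- fit_variogram(ev)
    }
    ok <- ordinary_krige(train[, c("x", "y")], resid,
                         targets[, c("x", "y")], vg)
    resid_ok <- ok$prediction
    ok_var <- ok$ok_variance
  } else {
    resid_ok <- rep(0, nrow(targets))
    ok_var <- rep(0, nrow(targets))
  }
  floor_val <- min(train[[trend$response]])
  prediction <- pmax(pr$mu + resid_ok, floor_val)
  tibble::tibble(
    trend = pr$mu, trend_se = pr$se,
    resid_ok = resid_ok, ok_variance = ok_var,
    prediction = prediction,
    se = prediction_standard_error(pr$se, ok_var)
  )
}
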