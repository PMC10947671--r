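## Ordinary kriging with a global neighborhood.

#' Ordinary kriging
#'
#' Solves the standard ordinary-kriging system (semivariance matrix
#' augmented with the unbiasedness constraint `sum(lambda) = 1`) once for
#' all prediction points, using every observation. With a zero nugget the
#' predictor interpolates the observations exactly with zero variance.
#'
#' @param obs_coords Two-column matrix/data frame of observation coordinates.
#' @param obs_values Observed values.
#' @param pred_coords Two-column matrix/data frame of prediction locations.
#' @param vg A `variogram_model`.
#' @param return_weights If `TRUE`, attach the weight matrix (observations x
#'   prediction points) as attribute `weights`.
#' @return Tibble with `prediction` and `ok_variance` per prediction point.
#' @export
ordinary_krige <- function(obs_coords, obs_values, pred_coords, vg,
                           return_weights = FALSE) {
  stopifnot(inherits(vg, "variogram_model"))
  obs_coords <- as.matrix(obs_coords)
  pred_coords <- as.matrix(pred_coords)
  n <- nrow(obs_coords)
  if (n < 2) stop("ordinary kriging needs at least 2 observations")
  d_obs <- as.matrix(stats::dist(obs_coords))
  if (max(d_obs) == 0) stop("degenerate geometry: all observations coincident")
  gam <- matrix(vg_semivariance(vg, d_obs), n, n)
  G <- rbind(cbind(gam, 1), c(rep(1, n), 0))

  # cross-distances observation -> prediction point
  d_cross <- sqrt(
    outer(obs_coords[, 1], pred_coords[, 1], "-")^2 +
      outer(obs_coords[, 2], pred_coords[, 2], "-")^2
  )
  B <- rbind(matrix(vg_semivariance(vg, d_cross), n), 1)

  sol <- tryCatch(solve(G, B), error = function(e) NULL)
  if (is.null(sol)) {
    diag(G)[seq_len(n)] <- diag(G)[seq_len(n)] + 1e-10
    sol <- tryCatch(solve(G, B), error = function(e) {
      stop("ordinary kriging system is singular even after jitter")
    })
  }
  lambda <- sol[seq_len(n), , drop = FALSE]
  prediction <- as.numeric(crossprod(lambda, obs_values))
  ok_variance <- pmax(0, colSums(sol * B))
  out <- tibble::tibble(prediction = prediction, ok_variance = ok_variance)
  if (return_weights) attr(out, "weights") <- lambda
  out
}

#' Combined prediction standard error
#'
#' Standard error of a regression-kriging prediction under the independence
#' approximation between the trend fit and the kriged residual:
#' `sqrt(trend_se^2 + ok_variance)`.
#'
#' @param trend_se Trend-model prediction standard errors (>= 0).
#' @param ok_variance Ordinary-kriging variances (>= 0).
#' @return Standard errors.
#' @export
prediction_standard_error <- function(trend_se, ok_variance) {
  if (any(trend_se < 0, na.rm = TRUE) || any(ok_variance < 0, na.rm = TRUE)) {
    stop("numerical-contract error: negative variance component")
  }
  sqrt(trend_se^2 + ok_variance)
}
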