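## Semivariogram estimation and parametric fitting.

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins pairwise squared differences into `n_bins` lag classes up to
#' `max_lag` (default: half the maximum pairwise distance) and returns
#' `gamma_hat(h) = sum((z_i - z_j)^2) / (2 N(h))` per bin.
#'
#' @param coords Two-column matrix (or data frame) of projected coordinates.
#' @param values Numeric vector of the field at `coords`.
#' @param n_bins Number of lag bins (default 15).
#' @param max_lag Maximum lag distance; default half the maximum pairwise
#'   distance.
#' @return Tibble of class `empirical_variogram`: `lag` (bin midpoint),
#'   `gamma` and `n_pairs` for non-empty bins.
#' @export
empirical_variogram <- function(coords, values, n_bins = 15, max_lag = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 30) {
    stop("empirical variogram needs at least 30 points")
  }
  d <- stats::dist(coords)
  if (max(d) == 0) {
    stop("degenerate geometry: all points are coincident")
  }
  if (is.null(max_lag)) max_lag <- max(d) / 2
  g <- stats::dist(values)^2 / 2
  dv <- as.numeric(d)
  gv <- as.numeric(g)
  keep <- dv > 0 & dv <= max_lag
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(dv[keep], breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(
    lag = as.numeric(tapply(dv[keep], bin, mean)),
    gamma = as.numeric(tapply(gv[keep], bin, mean)),
    n_pairs = as.integer(tapply(gv[keep], bin, length))
  )
  out <- out[!is.na(out$lag), ]
  class(out) <- c("empirical_variogram", class(out))
  attr(out, "max_lag") <- max_lag
  out
}

vg_families <- c("exponential", "spherical", "gaussian")

## Unit-sill correlation-complement curve of each family; range `a` is the
## family's distance parameter (effective range is 3a for exponential,
## sqrt(3)a for gaussian, a for spherical).
vg_shape <- function(family, h, a) {
  switch(family,
    exponential = 1 - exp(-h / a),
    spherical = ifelse(h < a, 1.5 * h / a - 0.5 * (h / a)^3, 1),
    gaussian = 1 - exp(-(h / a)^2)
  )
}

#' Semivariance of a fitted variogram model
#'
#' `gamma(h) = nugget + psill * f(h / range)` for `h > 0`, and 0 at `h = 0`
#' (the nugget is the jump of the semivariogram at the origin).
#'
#' @param vg A `variogram_model` from [fit_variogram()] or [vg_model()].
#' @param h Distances (>= 0).
#' @return Semivariance values.
#' @export
vg_semivariance <- function(vg, h) {
  stopifnot(inherits(vg, "variogram_model"))
  ifelse(h == 0, 0, vg$nugget + vg$psill * vg_shape(vg$family, h, vg$range))
}

#' Construct a variogram model directly
#'
#' @param family One of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget Nugget variance (>= 0).
#' @param psill Partial sill (>= 0).
#' @param range Range parameter (> 0).
#' @return A list of class `variogram_model`.
#' @export
vg_model <- function(family, nugget, psill, range) {
  family <- match.arg(family, vg_families)
  if (nugget < 0 || psill < 0 || range <= 0) {
    stop("variogram parameters must satisfy nugget >= 0, psill >= 0, range > 0")
  }
  structure(
    list(family = family, nugget = nugget, psill = psill, range = range,
         wsse = NA_real_, bins = NULL),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model> %s: nugget = %.4g, psill = %.4g, range = %.4g\n",
    x$family, x$nugget, x$psill, x$range
  ))
  invisible(x)
}

## Cressie-weighted SSE of one family/parameter set against the bins.
vg_wsse <- function(par, family, bins) {
  g <- par[1] + par[2] * vg_shape(family, bins$lag, par[3])
  g <- pmax(g, 1e-12)
  sum(bins$n_pairs * (bins$gamma - g)^2 / g^2)
}

#' Fit a parametric variogram by weighted least squares
#'
#' Fits exponential, spherical and gaussian models to the empirical bins by
#' minimizing the Cressie-weighted sum of squares
#' `sum(N(h) * (gamma_hat - gamma)^2 / gamma^2)` under non-negativity
#' constraints (multi-start box-constrained optimization), and returns the
#' family with the lowest weighted SSE.
#'
#' @param bins An [empirical_variogram()] result (>= 5 non-empty bins).
#' @param families Candidate families (default all three).
#' @return A `variogram_model` with the fitted parameters, the winning
#'   family, the achieved `wsse` and the bins used.
#' @export
fit_variogram <- function(bins, families = vg_families) {
  if (nrow(bins) < 5) {
    stop("variogram fitting needs at least 5 non-empty bins")
  }
  g_max <- max(bins$gamma)
  g_min <- min(bins$gamma)
  lag_max <- max(bins$lag)
  if (g_max <= 0) {
    # constant field: pure-nugget degenerate model
    return(vg_model("exponential", nugget = 0, psill = 0, range = lag_max))
  }
  best <- NULL
  for (family in families) {
    starts <- expand.grid(
      nugget = c(0, 0.5 * g_min, g_min),
      psill = c(g_max, g_max - g_min, 0.5 * g_max),
      range = lag_max * c(0.05, 0.15, 0.3, 0.6, 1)
    )
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::nlminb(
          start = pmax(as.numeric(starts[s, ]), c(0, 1e-8 * g_max, 1e-3 * lag_max)),
          objective = vg_wsse, family = family, bins = bins,
          lower = c(0, 0, 1e-6 * lag_max),
          upper = c(2 * g_max, 5 * g_max, 10 * lag_max)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$objective < best$objective) {
        best <- list(objective = fit$objective, par = fit$par, family = family)
      }
    }
  }
  if (is.null(best)) {
    stop("variogram error: optimization failed for every family")
  }
  out <- vg_model(best$family,
    nugget = best$par[1], psill = best$par[2],
    range = max(best$par[3], 1e-6 * lag_max)
  )
  out$wsse <- best$objective
  out$bins <- bins
  out
}
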