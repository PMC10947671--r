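## k-fold cross-validation of the five extrapolation models, model
## selection, and composition of the final (optimized) map.

cv_methods <- c("OK", "GLM", "GAM", "GLM_OK", "GAM_OK")

## Pooled prediction-quality metrics. The "relative" errors are expressed as
## percentages of the mean observed value.
prediction_metrics <- function(observed, predicted) {
  mae <- mean(abs(observed - predicted))
  rmse <- sqrt(mean((observed - predicted)^2))
  mo <- mean(observed)
  tibble::tibble(
    correlation = suppressWarnings(stats::cor(observed, predicted)),
    mae = mae, rmae = 100 * mae / mo,
    rmse = rmse, rrmse = 100 * rmse / mo
  )
}

#' 10-fold cross-validation of the extrapolation models
#'
#' Randomly partitions the saturated cells into `k` folds (sizes differing
#' by at most one; every cell held out exactly once), and for each fold
#' refits the entire model chain on the remaining folds — covariate
#' standardization, correlation screening, quasi-Poisson trend, and the
#' residual variogram — before predicting the held-out cells. Validation
#' metrics are computed on the pooled held-out predictions; training
#' metrics (for the pure regression models) are averaged over folds.
#'
#' @param data Tibble of saturated cells: `x`, `y`, the response column and
#'   candidate predictor columns.
#' @param response Response column (a diversity metric; positive).
#' @param predictors Candidate predictor columns.
#' @param methods Subset of `OK`, `GLM`, `GAM`, `GLM_OK`, `GAM_OK`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold partition.
#' @param collinearity,min_cor Screening thresholds (see
#'   [screen_covariates()]).
#' @param n_bins Variogram bins.
#' @return Object of class `cv_report`: `metrics` (method x split),
#'   `predictions` (pooled held-out predictions), `folds`, `seed`,
#'   `response`.
#' @export
cross_validate <- function(data, response, predictors,
                           methods = cv_methods, k = 10, seed = 1,
                           collinearity = 0.8, min_cor = 0.1, n_bins = 15) {
  methods <- match.arg(methods, cv_methods, several.ok = TRUE)
  n <- nrow(data)
  if (n < 5 * k) {
    stop("CV error: need at least 5 cells per fold (", 5 * k, " total)")
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  need_glm <- any(c("GLM", "GLM_OK") %in% methods)
  need_gam <- any(c("GAM", "GAM_OK") %in% methods)

  pred_rows <- list()
  train_metric_rows <- list()
  for (f in seq_len(k)) {
    held_idx <- which(fold == f)
    train <- data[-held_idx, , drop = FALSE]
    test <- data[held_idx, , drop = FALSE]
    y_tr <- train[[response]]

    if ("OK" %in% methods) {
      ev <- empirical_variogram(train[, c("x", "y")], y_tr, n_bins = n_bins)
      vg <- fit_variogram(ev)
      ok <- ordinary_krige(train[, c("x", "y")], y_tr, test[, c("x", "y")], vg)
      pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
        fold = f, method = "OK", row = held_idx,
        observed = test[[response]], predicted = ok$prediction
      )
    }

    if (need_glm || need_gam) {
      std <- standardize_covariates(train, predictors)
      train_s <- std$data
      test_s <- standardize_covariates(test, predictors, stats = std$stats)$data
      selected <- screen_covariates(train_s, y_tr, predictors,
        collinearity = collinearity, min_cor = min_cor
      )
      for (fam in c("glm", "gam")[c(need_glm, need_gam)]) {
        trend <- fit_trend(train_s, response, selected, family = fam)
        base <- toupper(fam)
        mu_tr <- predict(trend, train_s)$mu
        train_metric_rows[[length(train_metric_rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(method = base, fold = f),
          prediction_metrics(y_tr, mu_tr)
        )
        pure <- regression_krige(trend, train_s, test_s,
          krige_residuals = FALSE
        )
        withok <- regression_krige(trend, train_s, test_s,
          krige_residuals = TRUE, n_bins = n_bins
        )
        if (base %in% methods) {
          pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
            fold = f, method = base, row = held_idx,
            observed = test[[response]], predicted = pure$prediction
          )
        }
        if (paste0(base, "_OK") %in% methods) {
          pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
            fold = f, method = paste0(base, "_OK"), row = held_idx,
            observed = test[[response]], predicted = withok$prediction
          )
        }
      }
    }
  }
  predictions <- dplyr::bind_rows(pred_rows)
  val_metrics <- dplyr::group_by(predictions, .data$method)
  val_metrics <- dplyr::reframe(
    val_metrics, prediction_metrics(.data$observed, .data$predicted)
  )
  val_metrics$split <- "validation"
  metrics <- val_metrics
  if (length(train_metric_rows) > 0) {
    tr <- dplyr::bind_rows(train_metric_rows)
    tr <- dplyr::summarise(
      dplyr::group_by(tr, .data$method),
      dplyr::across(
        c("correlation", "mae", "rmae", "rmse", "rrmse"), mean
      ),
      .groups = "drop"
    )
    tr$split <- "training"
    metrics <- dplyr::bind_rows(tr, val_metrics)
  }
  metrics <- dplyr::select(
    metrics, "method", "split", "correlation", "mae", "rmae", "rmse", "rrmse"
  )
  structure(
    list(
      metrics = metrics, predictions = predictions, folds = fold,
      seed = seed, response = response
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> response '%s', %d folds, seed %d\n",
              x$response, max(x$folds), x$seed))
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}

#' Select the best extrapolation model from CV reports
#'
#' Ranks methods by pooled validation RRMSE (primary criterion), breaking
#' ties by higher correlation, then lower RMAE. Given reports for several
#' diversity metrics, also returns the consensus method (majority winner;
#' ties broken by lowest mean RRMSE across metrics).
#'
#' @param ... One or more `cv_report` objects (optionally named by metric),
#'   or a single list of them.
#' @return List with `per_metric` (tibble: metric, method) and `consensus`
#'   (single method id).
#' @export
select_model <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && !inherits(reports[[1]], "cv_report")) {
    reports <- reports[[1]]
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "cv_report")))
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- vapply(reports, function(r) r$response, character(1))
  }
  pick <- function(report) {
    m <- report$metrics[report$metrics$split == "validation", ]
    m <- m[order(m$rrmse, -m$correlation, m$rmae), ]
    m$method[1]
  }
  per_metric <- tibble::tibble(
    metric = names(reports),
    method = vapply(reports, pick, character(1))
  )
  counts <- sort(table(per_metric$method), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) {
    consensus <- top
  } else {
    mean_rrmse <- vapply(top, function(meth) {
      mean(vapply(reports, function(r) {
        m <- r$metrics
        m$rrmse[m$split == "validation" & m$method == meth]
      }, numeric(1)))
    }, numeric(1))
    consensus <- top[which.min(mean_rrmse)]
  }
  list(per_metric = per_metric, consensus = consensus)
}

#' Compose the final (optimized) diversity map
#'
#' Combines model predictions over the whole grid with the observed
#' coverage-standardized estimates: every saturated cell carries its
#' observed estimate, every other cell the selected model's prediction.
#'
#' @param predictions Tibble with `cell_id`, `prediction` and optionally
#'   `se`, `x`, `y` for every grid cell.
#' @param observed Tibble with `cell_id` and `value` for the saturated
#'   cells.
#' @return Tibble of class `final_map`: `cell_id`, `value`, `provenance`
#'   (`"observed"` or `"modeled"`), `se` (NA for observed cells), plus
#'   coordinates when supplied. Attribute `summary` holds mean / median /
#'   min / max / sd by provenance and overall.
#' @export
compose_final_map <- function(predictions, observed) {
  stopifnot(all(c("cell_id", "prediction") %in% names(predictions)))
  stopifnot(all(c("cell_id", "value") %in% names(observed)))
  gap <- setdiff(observed$cell_id, predictions$cell_id)
  if (length(gap) > 0) {
    stop("composition error: observed cells missing from predictions: ",
         paste(utils::head(gap, 5), collapse = ", "))
  }
  out <- predictions
  out$value <- out$prediction
  out$provenance <- "modeled"
  if (!"se" %in% names(out)) out$se <- NA_real_
  idx <- match(observed$cell_id, out$cell_id)
  out$value[idx] <- observed$value
  out$provenance[idx] <- "observed"
  out$se[idx] <- NA_real_
  if (any(is.na(out$value))) {
    stop("composition error: cells with neither prediction nor observation")
  }
  keep <- intersect(c("cell_id", "x", "y", "value", "provenance", "se"),
                    names(out))
  out <- out[, keep]
  summarize_values <- function(v) {
    if (length(v) == 0) {
      return(tibble::tibble(mean = NA_real_, median = NA_real_,
                            min = NA_real_, max = NA_real_, sd = NA_real_))
    }
    tibble::tibble(mean = mean(v), median = stats::median(v),
                   min = min(v), max = max(v), sd = stats::sd(v))
  }
  attr(out, "summary") <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(subset = "observed"),
                     summarize_values(out$value[out$provenance == "observed"])),
    dplyr::bind_cols(tibble::tibble(subset = "modeled"),
                     summarize_values(out$value[out$provenance == "modeled"])),
    dplyr::bind_cols(tibble::tibble(subset = "all"),
                     summarize_values(out$value))
  )
  class(out) <- c("final_map", class(out))
  out
}
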