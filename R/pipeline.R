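## Configuration-driven orchestration of the whole analysis:
## simulate -> clean -> grid -> incidence -> coverage -> diversity ->
## spatial models -> cross-validation -> final maps -> tract disparity.

#' Pipeline configuration
#'
#' Collects every stage threshold (all defaults are the study-protocol
#' values: 40-observer minimum, saturation and standardization coverage
#' 0.80, collinearity 0.8, outcome-correlation screen 0.1, 8 km fill
#' radius, 10-fold CV) together with the synthetic-data configuration.
#'
#' @param synthetic A [sim_config()] describing the synthetic study system.
#' @param n_tracts Number of census tracts to generate.
#' @param min_observers Minimum unique observers per cell (default 40).
#' @param C_threshold Saturation threshold on doubled-effort coverage.
#' @param C_target Coverage at which diversity is standardized.
#' @param collinearity,min_cor Covariate screening thresholds.
#' @param fill_radius_m Neighborhood radius for covariate filling (metres).
#' @param unit Sampling-unit rule (`"observer_day"` or `"observer"`).
#' @param metrics Diversity metrics to map (subset of `D0`, `D1`, `D2`).
#' @param methods Extrapolation models to cross-validate.
#' @param cv_k,cv_seed Cross-validation folds and seed.
#' @param use_covariates If `FALSE`, covariates are ignored and only
#'   ordinary kriging runs (degraded mode).
#' @param ses_vars SES columns for the disparity models.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(),
                            n_tracts = 100,
                            min_observers = 40,
                            C_threshold = 0.80,
                            C_target = 0.80,
                            collinearity = 0.8,
                            min_cor = 0.1,
                            fill_radius_m = 8000,
                            unit = "observer_day",
                            metrics = c("D0", "D1", "D2"),
                            methods = c("OK", "GLM", "GAM", "GLM_OK", "GAM_OK"),
                            cv_k = 10,
                            cv_seed = 1,
                            use_covariates = TRUE,
                            ses_vars = c("unemployment_pct",
                                         "educational_attainment_pct",
                                         "linguistic_isolation_pct",
                                         "poverty_pct")) {
  for (th in list(C_threshold = C_threshold, C_target = C_target,
                  collinearity = collinearity)) {
    if (th <= 0 || th > 1) {
      stop("configuration error: thresholds must lie in (0, 1]")
    }
  }
  if (min_cor < 0 || min_cor >= 1) {
    stop("configuration error: min_cor must lie in [0, 1)")
  }
  structure(
    list(
      synthetic = synthetic, n_tracts = n_tracts,
      min_observers = min_observers, C_threshold = C_threshold,
      C_target = C_target, collinearity = collinearity, min_cor = min_cor,
      fill_radius_m = fill_radius_m, unit = unit, metrics = metrics,
      methods = methods, cv_k = cv_k, cv_seed = cv_seed,
      use_covariates = use_covariates, ses_vars = ses_vars
    ),
    class = "pipeline_config"
  )
}

## Fit one extrapolation method on the full saturated set and predict every
## grid cell. Returns tibble(cell_id, x, y, prediction, se).
fit_predict_method <- function(method, train, targets, response, predictors,
                               config) {
  if (method == "OK") {
    ev <- empirical_variogram(train[, c("x", "y")], train[[response]])
    vg <- fit_variogram(ev)
    ok <- ordinary_krige(train[, c("x", "y")], train[[response]],
                         targets[, c("x", "y")], vg)
    return(dplyr::bind_cols(
      targets[, c("cell_id", "x", "y")],
      tibble::tibble(prediction = ok$prediction,
                     se = sqrt(ok$ok_variance))
    ))
  }
  std <- standardize_covariates(train, predictors)
  train_s <- std$data
  targets_s <- standardize_covariates(targets, predictors, stats = std$stats)$data
  selected <- screen_covariates(train_s, train_s[[response]], predictors,
    collinearity = config$collinearity, min_cor = config$min_cor
  )
  fam <- if (grepl("^GAM", method)) "gam" else "glm"
  trend <- fit_trend(train_s, response, selected, family = fam)
  rk <- regression_krige(trend, train_s, targets_s,
    krige_residuals = grepl("_OK$", method)
  )
  dplyr::bind_cols(
    targets[, c("cell_id", "x", "y")],
    tibble::tibble(prediction = rk$prediction, se = rk$se)
  )
}

#' Run the full pipeline on a synthetic study system
#'
#' Executes every stage end to end and (optionally) writes all intermediate
#' artifacts plus a machine-readable manifest into `out_dir`. With a fixed
#' configuration the run is fully reproducible.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return (Invisibly) a list with the landscape, occurrence counts,
#'   incidence, coverage, diversity, CV reports, selection, final maps,
#'   tract table and disparity results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  ## stage 1: synthetic study system
  landscape <- sim_landscape(config$synthetic)
  occ <- sim_occurrences(landscape)
  tracts <- sim_tracts(landscape, config$n_tracts)
  say("simulate: %d cells, %d records, %d tracts",
      nrow(landscape$grid), nrow(occ), nrow(tracts))

  ## stage 2: clean + grid + incidence
  grid <- grid_spec_of(landscape)
  cleaned <- clean_records(occ)
  rl <- attr(cleaned, "removal_log")
  say("clean: %d -> %d records (%d removed)",
      nrow(occ), nrow(cleaned), rl$n_removed[rl$rule == "total_removed"])
  gridded <- assign_grid(cleaned, grid)
  say("grid: %d records assigned, %d outside extent",
      nrow(gridded), attr(gridded, "n_dropped_outside"))
  inc <- build_incidence(gridded, unit = config$unit)
  inc <- apply_effort_filter(inc, config$min_observers)
  eligible <- inc[inc$eligible & inc$T >= 2, , drop = FALSE]
  say("incidence: %d populated cells, %d eligible (>= %d observers)",
      nrow(inc), nrow(eligible), config$min_observers)

  ## stage 3: coverage + diversity
  cov <- coverage_profile(eligible, C_threshold = config$C_threshold)
  sat <- eligible[cov$saturated, , drop = FALSE]
  if (nrow(sat) == 0) {
    stop("no saturated cells: cannot train the extrapolation models")
  }
  say("coverage: %d saturated cells (C_2T >= %.2f)",
      nrow(sat), config$C_threshold)
  div_long <- estimate_diversity(sat, C_target = config$C_target)
  div <- diversity_table(div_long)

  ## stage 4: assemble training data
  cells <- landscape$grid
  predictors <- setdiff(names(landscape$covariates), "cell_id")
  targets <- dplyr::left_join(cells, landscape$covariates, by = "cell_id")
  if (config$use_covariates) {
    targets <- fill_missing_covariate(targets, predictors,
                                      radius_m = config$fill_radius_m)
  }
  train <- dplyr::inner_join(targets, div, by = "cell_id")

  methods <- config$methods
  if (!config$use_covariates) {
    methods <- intersect(methods, "OK")
    say("covariates disabled: GLM/GAM variants skipped, running OK only")
  }

  ## stage 5: CV + model selection + final maps
  reports <- list()
  final_maps <- list()
  for (metric in config$metrics) {
    reports[[metric]] <- cross_validate(
      train, metric, if (config$use_covariates) predictors else character(),
      methods = methods, k = config$cv_k, seed = config$cv_seed,
      collinearity = config$collinearity, min_cor = config$min_cor
    )
  }
  sel <- select_model(reports)
  say("model selection: consensus %s (%s)", sel$consensus,
      paste(sprintf("%s:%s", sel$per_metric$metric, sel$per_metric$method),
            collapse = ", "))
  for (metric in config$metrics) {
    pred <- fit_predict_method(
      sel$consensus, train, targets, metric,
      if (config$use_covariates) predictors else character(), config
    )
    observed <- tibble::tibble(cell_id = train$cell_id,
                               value = train[[metric]])
    final_maps[[metric]] <- compose_final_map(pred, observed)
  }

  ## stage 6: tract aggregation + disparity
  map_values <- cells["cell_id"]
  for (metric in config$metrics) {
    map_values[[paste0("map_", metric)]] <- final_maps[[metric]]$value
  }
  tracts2 <- summarize_to_tracts(
    map_values, tracts, grid, cells,
    value_cols = paste0("map_", config$metrics)
  )
  ttest <- compare_groups(tracts2, paste0("map_", config$metrics))
  correlations <- correlate_diversity(
    tracts2, paste0("map_", config$metrics), config$ses_vars
  )
  lmm <- purrr::map_dfr(config$ses_vars, function(v) {
    fit <- fit_spatial_lmm(
      tracts2, v, paste0("map_", config$metrics[1]),
      adjust = "population_density"
    )
    tibble::tibble(
      ses_var = v, coefficient = fit$coefficient, se = fit$se,
      conf_low = fit$ci[1], conf_high = fit$ci[2],
      spatial_range = fit$spatial_range, fallback = fit$fallback
    )
  })
  say("disparity: %d SES models fitted on %d tracts",
      nrow(lmm), nrow(tracts2))

  result <- list(
    config = config, landscape = landscape, n_records = nrow(occ),
    removal_log = rl, incidence = inc, coverage = cov,
    diversity = div, cv_reports = reports, selection = sel,
    final_maps = final_maps, tracts = tracts2,
    disparity = list(ttest = ttest, correlations = correlations, lmm = lmm),
    log = log_lines
  )
  if (!is.null(out_dir)) {
    write_run_directory(result, occ, out_dir)
  }
  invisible(result)
}

## Serialize every artifact of a run, plus a manifest, into a directory.
write_run_directory <- function(result, occ, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  config <- result$config

  write_occurrences(occ, p("occurrences.csv"))
  readr::write_csv(result$removal_log, p("cleaning_log.csv"))
  write_incidence(
    result$incidence[, setdiff(names(result$incidence), "eligible")],
    p("incidence_long.csv"), p("cell_summary.csv")
  )
  readr::write_csv(result$coverage, p("coverage.csv"))
  readr::write_csv(result$diversity, p("diversity.csv"))
  cv_tab <- purrr::imap_dfr(result$cv_reports, function(r, metric) {
    dplyr::bind_cols(tibble::tibble(metric = metric), r$metrics)
  })
  readr::write_csv(cv_tab, p("cv_metrics.csv"))
  readr::write_csv(result$selection$per_metric, p("model_selection.csv"))
  for (metric in names(result$final_maps)) {
    fm <- result$final_maps[[metric]]
    readr::write_csv(tibble::as_tibble(fm), p(sprintf("final_map_%s.csv", metric)))
    readr::write_csv(attr(fm, "summary"), p(sprintf("map_summary_%s.csv", metric)))
  }
  readr::write_csv(result$tracts, p("tracts.csv"))
  write_tracts_geojson(result$tracts, p("tracts.geojson"))
  readr::write_csv(result$disparity$ttest, p("disparity_ttest.csv"))
  readr::write_csv(result$disparity$correlations, p("disparity_correlations.csv"))
  readr::write_csv(result$disparity$lmm, p("disparity_lmm.csv"))
  writeLines(result$log, p("run_log.txt"))

  cfg_json <- jsonlite::toJSON(
    result$config[setdiff(names(result$config), "synthetic")],
    auto_unbox = TRUE, digits = NA
  )
  syn_json <- jsonlite::toJSON(unclass(config$synthetic),
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "hillmapr",
    version = as.character(utils::packageVersion("hillmapr")),
    seed = config$synthetic$seed,
    cv_seed = config$cv_seed,
    config = jsonlite::fromJSON(cfg_json),
    synthetic_config = jsonlite::fromJSON(syn_json)
  )
  jsonlite::write_json(manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
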