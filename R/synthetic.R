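## Synthetic landscapes, communities, biased citizen-science occurrence
## records and SES-attributed census tracts with known ground truth.
##
## The generator emulates the data properties the mapping pipeline is built
## for: spatially autocorrelated environmental surfaces and diversity, a
## lognormal species-abundance distribution within each cell, observer counts
## driven by a population-density surface (with a configurable mean number of
## records per observer, default 20), a known corruption fraction to exercise
## record cleaning, and tract-level SES gradients tied to true diversity.

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study system. Defaults describe a
#' plausible urban-California-like landscape at desk scale: a 20 x 20 grid of
#' 5 x 5-km cells, a 400-species regional pool, environmental autocorrelation
#' over ~5 cells, an average of 20 records per observer, and a negative
#' SES-diversity gradient.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param grid_rows,grid_cols Grid dimensions (each >= 2).
#' @param cell_size Cell edge length in metres (> 0; default 5000).
#' @param origin Projected coordinates of the grid's lower-left corner.
#' @param n_species_pool Regional species pool size.
#' @param spatial_range Autocorrelation range (metres) of the exponential
#'   covariance used for all generated surfaces (> 0).
#' @param base_richness Median true cell richness on the response scale.
#' @param coefficients Named numeric vector of log-linear effects of
#'   covariate surfaces on true richness; recorded in the output so recovery
#'   tests can check screening and trend fitting against the truth.
#' @param spatial_sd Standard deviation of the spatially autocorrelated
#'   Gaussian component of log-richness.
#' @param noise_sd Standard deviation of the independent log-scale noise.
#' @param sad_sigma Lognormal species-abundance-distribution shape (log-scale
#'   sd); larger values give heavier rare-species tails.
#' @param observer_rate Expected observers per cell at average population
#'   density (0 switches effort off entirely).
#' @param effort_mean_records Mean records per observer (> 0; default 20).
#' @param records_family `"poisson"` or `"nbinom"`: distribution of records
#'   per observer (the real effort distribution is characterized only by its
#'   mean, so the family is configurable).
#' @param nb_size Negative-binomial size parameter when
#'   `records_family = "nbinom"`.
#' @param corrupt_frac Fraction of records corrupted (missing coordinates,
#'   incomplete taxonomy, or cultivated flag), independent of species.
#' @param ses_effect Slope of true tract-mean richness per unit (percentage
#'   point) of the primary SES variable; negative values emulate lower
#'   diversity in lower-SES neighborhoods. 0 decouples SES from diversity.
#' @param ses_noise_sd Measurement noise added to the primary SES variable.
#' @param n_counties Number of (contiguous, block-shaped) counties.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       grid_rows = 20, grid_cols = 20,
                       cell_size = 5000, origin = c(0, 0),
                       n_species_pool = 400,
                       spatial_range = 25000,
                       base_richness = 80,
                       coefficients = c(
                         temperature = 0.20, precipitation = 0.15,
                         ndvi = 0.25, tree_canopy = 0.10,
                         road_density = -0.10, soil_ph = 0.08
                       ),
                       spatial_sd = 0.15,
                       noise_sd = 0.05,
                       sad_sigma = 1.5,
                       observer_rate = 45,
                       effort_mean_records = 20,
                       records_family = c("poisson", "nbinom"),
                       nb_size = 5,
                       corrupt_frac = 0.05,
                       ses_effect = -2,
                       ses_noise_sd = 0,
                       n_counties = 6) {
  if (grid_rows < 2 || grid_cols < 2) {
    stop("configuration error: grid dimensions must each be >= 2")
  }
  if (cell_size <= 0) stop("configuration error: cell_size must be > 0")
  if (spatial_range <= 0) stop("configuration error: spatial_range must be > 0")
  if (effort_mean_records <= 0) {
    stop("configuration error: effort_mean_records must be > 0")
  }
  if (corrupt_frac < 0 || corrupt_frac >= 1) {
    stop("configuration error: corrupt_frac must be in [0, 1)")
  }
  structure(
    list(
      seed = seed, grid_rows = grid_rows, grid_cols = grid_cols,
      cell_size = cell_size, origin = origin,
      n_species_pool = n_species_pool, spatial_range = spatial_range,
      base_richness = base_richness, coefficients = coefficients,
      spatial_sd = spatial_sd, noise_sd = noise_sd, sad_sigma = sad_sigma,
      observer_rate = observer_rate,
      effort_mean_records = effort_mean_records,
      records_family = match.arg(records_family), nb_size = nb_size,
      corrupt_frac = corrupt_frac, ses_effect = ses_effect,
      ses_noise_sd = ses_noise_sd, n_counties = n_counties
    ),
    class = "sim_config"
  )
}

## Simulate `n_fields` zero-mean, unit-variance Gaussian random fields with
## exponential covariance exp(-d / range) on the given coordinates, via one
## Cholesky factor shared across fields.
simulate_grf <- function(coords, range, n_fields = 1) {
  d <- as.matrix(stats::dist(coords))
  sigma <- exp(-d / range)
  diag(sigma) <- diag(sigma) + 1e-10
  L <- chol(sigma)
  z <- matrix(stats::rnorm(nrow(coords) * n_fields), nrow = nrow(coords))
  crossprod(L, z)
}

covariate_names <- function() {
  c(
    "temperature", "precipitation", "elevation", "evapotranspiration",
    "ndvi", "tree_canopy", "developed_open", "herbaceous",
    "road_density", "soil_ph", "soil_organic_matter"
  )
}

#' Generate a synthetic landscape with known true diversity
#'
#' Builds the grid, a stack of spatially autocorrelated covariate surfaces
#' (climate, vegetation index, land-cover fractions, road density, soil
#' properties), a population-density surface, and the true per-cell
#' community: a lognormal species-abundance distribution over a cell-specific
#' species subset, from which the true Hill numbers `D0 >= D1 >= D2 >= 1`
#' are computed exactly. True log-richness is a recorded linear combination
#' of covariates plus a spatially autocorrelated Gaussian field plus
#' independent noise, so trend-recovery tests know the generating model.
#'
#' @param config A [sim_config()].
#' @return A list of class `hillmapr_landscape` with elements `grid`
#'   (cell centroids), `covariates` (wide tibble keyed by `cell_id`),
#'   `truth` (per-cell true `D0`, `D1`, `D2` and `pop_density`), `sad`
#'   (per-cell species identities and relative abundances), `coefficients`
#'   (the generating effects) and `config`.
#' @export
sim_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- config$grid_rows
  cols <- config$grid_cols
  n <- rows * cols
  grid <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  grid <- dplyr::mutate(grid,
    cell_id = sprintf("c%03d_%03d", .data$row, .data$col),
    x = config$origin[1] + (.data$col - 0.5) * config$cell_size,
    y = config$origin[2] + (.data$row - 0.5) * config$cell_size
  )
  grid <- dplyr::select(grid, "cell_id", "row", "col", "x", "y")

  coords <- as.matrix(grid[, c("x", "y")])
  covs <- covariate_names()
  fields <- simulate_grf(coords, config$spatial_range, length(covs) + 2)
  covariates <- tibble::as_tibble(as.data.frame(fields[, seq_along(covs)]))
  names(covariates) <- covs
  covariates <- dplyr::bind_cols(grid["cell_id"], covariates)

  beta <- config$coefficients
  missing_covs <- setdiff(names(beta), covs)
  if (length(missing_covs) > 0) {
    stop("configuration error: unknown covariates in coefficients: ",
         paste(missing_covs, collapse = ", "))
  }
  eta <- log(config$base_richness) +
    as.matrix(covariates[names(beta)]) %*% beta +
    config$spatial_sd * fields[, length(covs) + 1] +
    stats::rnorm(n, 0, config$noise_sd)
  S_true <- pmin(config$n_species_pool, pmax(2L, as.integer(round(exp(eta)))))

  pop_density <- exp(0.8 * fields[, length(covs) + 2])
  pop_density <- pop_density / mean(pop_density)

  sad <- lapply(seq_len(n), function(i) {
    sp <- sort(sample.int(config$n_species_pool, S_true[i]))
    ab <- stats::rlnorm(S_true[i], meanlog = 0, sdlog = config$sad_sigma)
    list(species = sp, p = ab / sum(ab))
  })
  d1 <- vapply(sad, function(s) exp(-sum(s$p * log(s$p))), numeric(1))
  d2 <- vapply(sad, function(s) 1 / sum(s$p^2), numeric(1))

  truth <- dplyr::mutate(grid,
    D0 = as.numeric(S_true), D1 = d1, D2 = d2,
    pop_density = pop_density
  )
  structure(
    list(
      grid = grid, covariates = covariates, truth = truth, sad = sad,
      coefficients = beta, config = config
    ),
    class = "hillmapr_landscape"
  )
}

#' @export
print.hillmapr_landscape <- function(x, ...) {
  cat(sprintf(
    "<hillmapr_landscape> %d x %d grid (%d cells), %d covariates, species pool %d\n",
    x$config$grid_rows, x$config$grid_cols, nrow(x$grid),
    ncol(x$covariates) - 1, x$config$n_species_pool
  ))
  invisible(x)
}

#' Simulate biased citizen-science occurrence records
#'
#' Draws, for every cell, an observer count with mean proportional to the
#' population-density surface; each observer contributes a Poisson (or
#' negative-binomial) number of records with species sampled from the cell's
#' lognormal abundance distribution, a uniform location within the cell, and
#' a single recording date. A configurable fraction of records is corrupted
#' (missing coordinates, genus-level taxonomy, or a cultivated flag) to
#' exercise the cleaning rules; the injected corruption is recorded in the
#' `.corrupted` column so cleaning tests have an exact ledger.
#'
#' @param landscape A [sim_landscape()] result.
#' @param config The same [sim_config()] (grid geometry must match).
#' @return A tibble with Darwin-Core-style columns `scientificName`,
#'   `decimalLatitude`, `decimalLongitude` (projected metres: the synthetic
#'   world is planar), `recordedBy`, `eventDate`, `establishmentMeans`,
#'   `taxonRank`, plus ground-truth bookkeeping columns `.cell_true` and
#'   `.corrupted`.
#' @export
sim_occurrences <- function(landscape, config = landscape$config) {
  stopifnot(inherits(landscape, "hillmapr_landscape"))
  if (config$grid_rows != landscape$config$grid_rows ||
      config$grid_cols != landscape$config$grid_cols ||
      config$cell_size != landscape$config$cell_size) {
    stop("configuration error: landscape and config disagree on grid geometry")
  }
  set.seed(config$seed + 1L)
  truth <- landscape$truth
  n_cells <- nrow(truth)
  n_obs_cell <- stats::rpois(n_cells, config$observer_rate * truth$pop_density)
  total_obs <- sum(n_obs_cell)
  if (total_obs == 0) {
    return(tibble::tibble(
      scientificName = character(), decimalLatitude = numeric(),
      decimalLongitude = numeric(), recordedBy = character(),
      eventDate = as.Date(character()), establishmentMeans = character(),
      taxonRank = character(), .cell_true = character(),
      .corrupted = logical()
    ))
  }
  obs_cell_idx <- rep.int(seq_len(n_cells), n_obs_cell)
  n_rec_obs <- switch(config$records_family,
    poisson = stats::rpois(total_obs, config$effort_mean_records),
    nbinom = stats::rnbinom(total_obs,
      size = config$nb_size, mu = config$effort_mean_records
    )
  )
  keep <- n_rec_obs > 0
  dates <- as.Date("2019-01-01") +
    sample.int(as.integer(as.Date("2022-12-31") - as.Date("2019-01-01")) + 1L,
      total_obs,
      replace = TRUE
    ) - 1L
  rec_obs_idx <- rep.int(seq_len(total_obs), n_rec_obs)
  rec_cell_idx <- obs_cell_idx[rec_obs_idx]
  n_rec <- length(rec_obs_idx)

  # species draws: loop cells (vectorized within cell)
  species <- integer(n_rec)
  for (ci in unique(rec_cell_idx)) {
    sel <- which(rec_cell_idx == ci)
    sad <- landscape$sad[[ci]]
    species[sel] <- sad$species[
      sample.int(length(sad$p), length(sel), replace = TRUE, prob = sad$p)
    ]
  }
  half <- config$cell_size / 2
  rx <- truth$x[rec_cell_idx] + stats::runif(n_rec, -half, half)
  ry <- truth$y[rec_cell_idx] + stats::runif(n_rec, -half, half)

  out <- tibble::tibble(
    scientificName = sprintf("species_%04d", species),
    decimalLatitude = ry,
    decimalLongitude = rx,
    recordedBy = sprintf("obs_%06d", rec_obs_idx),
    eventDate = dates[rec_obs_idx],
    establishmentMeans = "wild",
    taxonRank = "species",
    .cell_true = truth$cell_id[rec_cell_idx],
    .corrupted = FALSE
  )

  if (config$corrupt_frac > 0 && n_rec > 0) {
    hit <- which(stats::runif(n_rec) < config$corrupt_frac)
    kind <- sample.int(3L, length(hit), replace = TRUE)
    out$.corrupted[hit] <- TRUE
    coord_hit <- hit[kind == 1L]
    out$decimalLatitude[coord_hit] <- NA_real_
    out$decimalLongitude[coord_hit] <- NA_real_
    out$taxonRank[hit[kind == 2L]] <- "genus"
    out$establishmentMeans[hit[kind == 3L]] <- "cultivated"
  }
  out
}

## Integer factorization of n_tracts into a rows x cols layout closest to the
## grid aspect ratio.
tract_layout <- function(n_tracts, grid_rows, grid_cols) {
  divs <- which(n_tracts %% seq_len(n_tracts) == 0)
  best <- divs[which.min(abs(log((divs^2) / n_tracts) -
    log(grid_rows / grid_cols)))]
  c(rows = best, cols = n_tracts / best)
}

#' Generate SES-attributed census tracts tiling the landscape
#'
#' Tiles the grid extent with `n_tracts` rectangular tracts, aggregates true
#' diversity and population density into them (area-weighted), and attaches
#' SES attributes on 0-100 percent scales. The primary SES variable
#' (unemployment) is constructed so that true tract-mean richness has a known
#' linear association with it (slope = `ses_effect` diversity units per
#' percentage point); the remaining SES variables are independent noise. A
#' composite score flags the worst quartile of tracts as disadvantaged
#' communities (DAC), exactly `ceiling(0.25 * n_tracts)` of them.
#'
#' @inheritParams sim_occurrences
#' @param n_tracts Number of tracts (>= 2, <= number of cells).
#' @return A tibble with tract rectangles (`xmin`, `xmax`, `ymin`, `ymax`),
#'   centroids, county labels, true mean diversity (`mean_D0`, `mean_D1`,
#'   `mean_D2`), SES percent variables, `pop_characteristics_score`,
#'   `composite_score`, `dac`, `population_density` and `ndvi_mean`.
#' @export
sim_tracts <- function(landscape, n_tracts, config = landscape$config) {
  stopifnot(inherits(landscape, "hillmapr_landscape"))
  n_cells <- nrow(landscape$grid)
  if (n_tracts < 2) stop("configuration error: n_tracts must be >= 2")
  if (n_tracts > n_cells) {
    stop("configuration error: n_tracts exceeds the number of cells")
  }
  set.seed(config$seed + 2L)
  lay <- tract_layout(n_tracts, config$grid_rows, config$grid_cols)
  width <- config$grid_cols * config$cell_size / lay["cols"]
  height <- config$grid_rows * config$cell_size / lay["rows"]
  tr <- tidyr::expand_grid(tr_row = seq_len(lay["rows"]), tr_col = seq_len(lay["cols"]))
  tr <- dplyr::mutate(tr,
    tract_id = sprintf("t%04d", dplyr::row_number()),
    xmin = config$origin[1] + (.data$tr_col - 1) * width,
    xmax = config$origin[1] + .data$tr_col * width,
    ymin = config$origin[2] + (.data$tr_row - 1) * height,
    ymax = config$origin[2] + .data$tr_row * height,
    cx = (.data$xmin + .data$xmax) / 2,
    cy = (.data$ymin + .data$ymax) / 2
  )

  # county blocks: split tract columns into ~n_counties contiguous stripes,
  # wrapping to a second row of stripes if needed
  k <- max(1L, config$n_counties)
  stripe <- ceiling(lay["cols"] * lay["rows"] / k)
  tr$county <- sprintf("county_%02d", 1L +
    ((as.integer(factor(tr$tract_id)) - 1L) %/% stripe))

  cell_values <- dplyr::select(
    landscape$truth, "cell_id", "D0", "D1", "D2", "pop_density"
  )
  cell_values$ndvi <- landscape$covariates$ndvi
  agg <- aggregate_cells_to_rects(
    tr, landscape$grid, cell_values,
    cell_size = config$cell_size,
    value_cols = c("D0", "D1", "D2", "pop_density", "ndvi")
  )
  tr <- dplyr::left_join(tr, agg, by = "tract_id")
  tr <- dplyr::rename(tr,
    mean_D0 = "D0", mean_D1 = "D1", mean_D2 = "D2",
    population_density = "pop_density", ndvi_mean = "ndvi"
  )

  n <- nrow(tr)
  d_centered <- tr$mean_D0 - mean(tr$mean_D0)
  if (config$ses_effect != 0) {
    ses_primary <- 50 + d_centered / config$ses_effect +
      stats::rnorm(n, 0, config$ses_noise_sd)
  } else {
    ses_primary <- stats::rnorm(n, 50, 12)
  }
  tr$unemployment_pct <- pmin(100, pmax(0, ses_primary))
  tr$educational_attainment_pct <- stats::runif(n, 5, 95)
  tr$linguistic_isolation_pct <- stats::runif(n, 0, 60)
  tr$poverty_pct <- stats::runif(n, 2, 80)
  tr$housing_burden_pct <- stats::runif(n, 5, 70)
  tr$pop_characteristics_score <- pmin(100, pmax(0,
    rowMeans(cbind(
      tr$unemployment_pct, tr$educational_attainment_pct,
      tr$linguistic_isolation_pct, tr$poverty_pct, tr$housing_burden_pct
    )) + stats::rnorm(n, 0, 5)
  ))
  tr$composite_score <- tr$pop_characteristics_score + stats::rnorm(n, 0, 3)
  n_dac <- ceiling(0.25 * n)
  tr$dac <- rank(-tr$composite_score, ties.method = "first") <= n_dac
  tr
}

#' Simulate a tract table from an explicit disparity-generating model
#'
#' Direct generative model for testing the spatial mixed-model machinery:
#' `outcome = b0 + beta_ses * ses + beta_pop * pop_density + county effect +
#' spatially correlated residual (exponential correlation) + nugget`.
#' Counties are contiguous spatial blocks.
#'
#' @param n_tracts Number of tracts.
#' @param n_counties Number of counties (>= 2).
#' @param beta_ses Generating SES slope (outcome units per percentage point).
#' @param beta_pop Generating population-density slope.
#' @param b0 Intercept.
#' @param sigma_county SD of county random intercepts.
#' @param sigma_spatial SD of the spatially correlated residual component.
#' @param range_spatial Exponential correlation range of the residual field,
#'   in the same units as the unit-square-scaled coordinates.
#' @param sigma_nugget SD of the independent residual.
#' @param within_county If `TRUE`, the spatial residual field is drawn
#'   independently per county (block-diagonal covariance), matching the
#'   grouped exponential correlation structure the mixed model fits; if
#'   `FALSE` one field spans the whole domain, crossing county borders.
#' @param seed Integer seed.
#' @return Tibble with `tract_id`, `cx`, `cy`, `county`, `ses`,
#'   `pop_density`, `ndvi_mean`, `outcome` plus the extra independent SES
#'   columns used by sensitivity analyses.
#' @export
sim_tract_disparity <- function(n_tracts = 300, n_counties = 10,
                                beta_ses = -0.61, beta_pop = 0.5, b0 = 150,
                                sigma_county = 5, sigma_spatial = 6,
                                range_spatial = 0.15, sigma_nugget = 4,
                                within_county = TRUE, seed = 1) {
  set.seed(seed)
  cx <- stats::runif(n_tracts)
  cy <- stats::runif(n_tracts)
  county_idx <- pmin(n_counties, 1L + floor(cx * n_counties))
  county_re <- stats::rnorm(n_counties, 0, sigma_county)
  spatial <- rep(0, n_tracts)
  if (sigma_spatial > 0) {
    if (within_county) {
      for (cty in seq_len(n_counties)) {
        idx <- which(county_idx == cty)
        if (length(idx) > 0) {
          spatial[idx] <- sigma_spatial * as.numeric(
            simulate_grf(cbind(cx[idx], cy[idx]), range_spatial, 1)
          )
        }
      }
    } else {
      spatial <- sigma_spatial * as.numeric(
        simulate_grf(cbind(cx, cy), range_spatial, 1)
      )
    }
  }
  ses <- pmin(100, pmax(0, stats::rnorm(n_tracts, 50, 15)))
  pop_density <- stats::rlnorm(n_tracts, 0, 0.5)
  outcome <- b0 + beta_ses * ses + beta_pop * pop_density +
    county_re[county_idx] + spatial + stats::rnorm(n_tracts, 0, sigma_nugget)
  tibble::tibble(
    tract_id = sprintf("t%04d", seq_len(n_tracts)),
    cx = cx, cy = cy,
    county = sprintf("county_%02d", county_idx),
    ses = ses,
    educational_attainment_pct = stats::runif(n_tracts, 5, 95),
    linguistic_isolation_pct = stats::runif(n_tracts, 0, 60),
    unemployment_pct = ses,
    pop_density = pop_density,
    ndvi_mean = stats::rnorm(n_tracts),
    outcome = outcome
  )
}
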