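# Tract aggregation, group comparison, correlations, spatial mixed models.

test_that("tract aggregation is exact for simple geometries", {
  g <- grid_spec(origin = c(0, 0), cell_size = 10, rows = 1, cols = 2)
  cells <- tibble::tibble(cell_id = c("a", "b"), x = c(5, 15), y = c(5, 5))
  map <- tibble::tibble(cell_id = c("a", "b"), v = c(100, 200))
  # tract identical to one cell
  tr1 <- tibble::tibble(tract_id = "t1", xmin = 0, xmax = 10,
                        ymin = 0, ymax = 10)
  out1 <- summarize_to_tracts(map, tr1, g, cells, "v")
  expect_equal(out1$v, 100)
  # tract covering both cells equally
  tr2 <- tibble::tibble(tract_id = "t2", xmin = 0, xmax = 20,
                        ymin = 0, ymax = 10)
  expect_equal(summarize_to_tracts(map, tr2, g, cells, "v")$v, 150)
  # no overlap: flagged missing
  tr3 <- tibble::tibble(tract_id = "t3", xmin = 50, xmax = 60,
                        ymin = 0, ymax = 10)
  out3 <- summarize_to_tracts(map, tr3, g, cells, "v")
  expect_true(out3$no_overlap)
  expect_true(is.na(out3$v))
  # degenerate rectangle: geometry error naming the tract
  tr4 <- tibble::tibble(tract_id = "bad", xmin = 5, xmax = 5,
                        ymin = 0, ymax = 10)
  expect_error(summarize_to_tracts(map, tr4, g, cells, "v"), "bad")
})

test_that("random tract rectangles match a brute-force intersection oracle", {
  set.seed(40)
  land <- sim_landscape(sim_config(seed = 40, grid_rows = 6, grid_cols = 6,
                                   cell_size = 10))
  g <- grid_spec_of(land)
  map <- tibble::tibble(cell_id = land$grid$cell_id, v = rnorm(36))
  tr <- tibble::tibble(
    tract_id = sprintf("t%d", 1:15),
    xmin = runif(15, 0, 40), ymin = runif(15, 0, 40)
  )
  tr$xmax <- tr$xmin + runif(15, 3, 25)
  tr$ymax <- tr$ymin + runif(15, 3, 25)
  got <- summarize_to_tracts(map, tr, g, land$grid, "v")
  for (i in 1:15) {
    num <- 0
    den <- 0
    for (j in seq_len(36)) {
      cx <- land$grid$x[j]
      cy <- land$grid$y[j]
      w <- max(0, min(tr$xmax[i], cx + 5) - max(tr$xmin[i], cx - 5)) *
        max(0, min(tr$ymax[i], cy + 5) - max(tr$ymin[i], cy - 5))
      num <- num + w * map$v[j]
      den <- den + w
    }
    expect_equal(got$v[i], num / den, tolerance = 1e-12)
  }
  # conservation: a constant surface aggregates to the constant
  const <- tibble::tibble(cell_id = land$grid$cell_id, v = 3.5)
  expect_true(all(abs(
    summarize_to_tracts(const, tr, g, land$grid, "v")$v - 3.5
  ) < 1e-12))
})

test_that("the DAC comparison has correct type-I error and power", {
  set.seed(41)
  # permuted labels on one sample: uniform p-values
  x <- rnorm(120, 100, 10)
  rejections <- 0
  n_shuffles <- 1000
  for (i in seq_len(n_shuffles)) {
    lab <- sample(rep(c(TRUE, FALSE), each = 60))
    p <- stats::t.test(x[lab], x[!lab])$p.value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_shuffles, 0.03)
  expect_lte(rejections / n_shuffles, 0.07)

  # true difference 20, sd 5, n = 50/50: decisive in every seed
  for (s in 1:20) {
    set.seed(s)
    tr <- tibble::tibble(
      dac = rep(c(TRUE, FALSE), each = 50),
      m = c(rnorm(50, 80, 5), rnorm(50, 100, 5))
    )
    out <- compare_groups(tr, "m")
    expect_lt(out$p_value, 0.001)
  }

  # degenerate inputs
  tr0 <- tibble::tibble(dac = rep(c(TRUE, FALSE), each = 10), m = 1)
  expect_error(compare_groups(tr0, "m"), "degenerate")
  tr1 <- tibble::tibble(dac = c(TRUE, rep(FALSE, 9)), m = rnorm(10))
  expect_error(compare_groups(tr1, "m"), "test error")
})

test_that("correlation tables hit the analytic limits and sampling bounds", {
  tr <- tibble::tibble(a = rnorm(100))
  tr$b <- tr$a
  tr$c <- -tr$a
  tr$const <- 1
  out <- correlate_diversity(tr, "a", c("b", "c"))
  expect_equal(out$r, c(1, -1))
  expect_warning(correlate_diversity(tr, "a", "const"), "constant")

  set.seed(42)
  n <- 400
  rho <- -0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  got <- correlate_diversity(tibble::tibble(d = y, s = x), "d", "s")
  expect_lt(abs(got$r - rho), 2 / sqrt(n))
  expect_equal(got$n, n)
})

test_that("the spatial LMM matches OLS when both extra structures are off", {
  d <- sim_tract_disparity(n_tracts = 200, sigma_county = 0,
                           sigma_spatial = 0, seed = 5)
  fit <- fit_spatial_lmm(d, "ses", "outcome", spatial = FALSE,
                         random_county = FALSE)
  ols <- stats::lm(outcome ~ ses + pop_density, data = d)
  expect_lt(abs(fit$coefficient - stats::coef(ols)[["ses"]]), 1e-4)
  expect_lt(abs(fit$se - summary(ols)$coefficients["ses", 2]), 1e-4)
})

test_that("the spatial LMM recovers a generating slope", {
  hits <- 0
  for (s in 1:5) {
    d <- sim_tract_disparity(n_tracts = 250, beta_ses = -0.61, seed = 100 + s)
    fit <- fit_spatial_lmm(d, "ses", "outcome")
    if (abs(fit$coefficient - (-0.61)) <= 2 * fit$se) hits <- hits + 1
    expect_true(all(diff(c(fit$ci[1], fit$coefficient, fit$ci[2])) > 0))
  }
  expect_gte(hits, 4)
  expect_error(fit_spatial_lmm(sim_tract_disparity(20), "ses", "outcome"),
               "30 tracts")
})

test_that("the disparity module recovers the generator's SES slope end to end", {
  land <- sim_landscape(sim_config(seed = 50, grid_rows = 14, grid_cols = 14,
                                   ses_effect = -2))
  tr <- sim_tracts(land, 196)
  fit <- fit_spatial_lmm(tr, "unemployment_pct", "mean_D0",
                         adjust = "population_density")
  # the SES column is an exact linear transform of tract-mean diversity, so
  # the fitted SE is ~0; recovery is judged on a tight relative tolerance
  expect_lt(abs(fit$coefficient - (-2)) / 2, 0.01)
  expect_lt(fit$ci[2], 0) # the negative gradient is detected
})

test_that("sensitivity analyses behave under known generating structures", {
  d <- sim_tract_disparity(n_tracts = 220, beta_ses = -0.5,
                           sigma_spatial = 3, seed = 9)
  sens <- sensitivity_models(
    d,
    ses_set = c("unemployment_pct", "educational_attainment_pct",
                "linguistic_isolation_pct"),
    outcome = "outcome"
  )
  # independent extra SES columns: full-model coefficient close to single
  single_u <- sens$single[sens$single$term == "unemployment_pct", ]
  full_u <- sens$full[sens$full$term == "unemployment_pct", ]
  expect_lt(abs(full_u$estimate - single_u$estimate), 2 * single_u$se)
  # the null SES variables do not enter significantly
  null_terms <- sens$single[sens$single$term != "unemployment_pct", ]
  expect_true(all(null_terms$conf_low < 0 & null_terms$conf_high > 0))
  # backward selection drops a null variable first, never the real one
  expect_false(any(sens$backward$dropped == "unemployment_pct", na.rm = TRUE))
  expect_gte(nrow(sens$backward), 2)
  # NDVI independent of the outcome: adjusted coefficients barely move
  ndvi_u <- sens$ndvi_adjusted[sens$ndvi_adjusted$term == "unemployment_pct", ]
  expect_lt(abs(ndvi_u$estimate - single_u$estimate), 0.5 * single_u$se)
  expect_error(
    sensitivity_models(d, ses_set = c("poverty_pct"), outcome = "outcome"),
    "exclude"
  )
})
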