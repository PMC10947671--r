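# Covariate preparation and quasi-Poisson trend models.

test_that("missing covariates are filled with the neighborhood mean", {
  stack <- tibble::tibble(
    cell_id = c("a", "b", "c", "d"),
    x = c(0, 5000, 10000, 40000), y = 0,
    v = c(2, NA, 4, 9)
  )
  filled <- fill_missing_covariate(stack, "v", radius_m = 8000)
  expect_equal(filled$v[2], 3) # mean of the two in-radius neighbors
  # no missing values: identity
  expect_identical(fill_missing_covariate(filled, "v", radius_m = 8000),
                   filled)
  # isolated missing cell: error naming the offender
  stack2 <- tibble::tibble(cell_id = c("a", "b"), x = c(0, 50000), y = 0,
                           v = c(1, NA))
  expect_error(fill_missing_covariate(stack2, "v", radius_m = 8000),
               "v@b")
})

test_that("random masks are filled identically to a brute-force scan", {
  set.seed(17)
  land <- sim_landscape(sim_config(seed = 17, grid_rows = 8, grid_cols = 8))
  stack <- dplyr::left_join(land$grid, land$covariates, by = "cell_id")
  stack$soil_ph[sample(64, 12)] <- NA
  filled <- fill_missing_covariate(stack, "soil_ph", radius_m = 8000)
  for (i in which(is.na(stack$soil_ph))) {
    d <- sqrt((stack$x - stack$x[i])^2 + (stack$y - stack$y[i])^2)
    nb <- d <= 8000 & !is.na(stack$soil_ph) & seq_len(64) != i
    expect_equal(filled$soil_ph[i], mean(stack$soil_ph[nb]))
  }
})

test_that("standardization gives mean 0 / sd 1 and reuses training stats", {
  set.seed(2)
  d <- tibble::tibble(a = rnorm(50, 3, 2), b = runif(50, 10, 20))
  std <- standardize_covariates(d, c("a", "b"))
  expect_equal(colMeans(std$data), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(vapply(std$data, sd, numeric(1)), c(a = 1, b = 1),
               tolerance = 1e-12)
  held <- standardize_covariates(tibble::tibble(a = 3, b = 15),
                                 c("a", "b"), stats = std$stats)$data
  expect_equal(unname(held$a), (3 - mean(d$a)) / sd(d$a))
})

test_that("screening drops collinear and weakly correlated predictors", {
  set.seed(5)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.95 * x1 + 0.1 * rnorm(n) # collinear with x1
  x3 <- rnorm(n) # weak
  y <- 2 * x1 + rnorm(n, 0, 0.5)
  d <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)
  kept <- screen_covariates(d, y, c("x1", "x2", "x3"))
  expect_true("x1" %in% kept)
  expect_true("x2" %in% attr(kept, "dropped_collinear"))
  expect_true("x3" %in% attr(kept, "dropped_weak"))
  expect_error(screen_covariates(d, rnorm(n), "x3"), "screening error")
})

test_that("the generating covariates survive screening on synthetic data", {
  land <- sim_landscape(sim_config(seed = 23, grid_rows = 12, grid_cols = 12))
  stack <- dplyr::left_join(land$grid, land$covariates, by = "cell_id")
  preds <- setdiff(names(land$covariates), "cell_id")
  std <- standardize_covariates(stack, preds)
  kept <- screen_covariates(std$data, log(land$truth$D0), preds)
  strong <- names(land$coefficients[abs(land$coefficients) >= 0.15])
  expect_true(all(strong %in% kept))
})

test_that("the quasi-Poisson GLM recovers a generating log-linear model", {
  set.seed(6)
  n <- 300
  d <- tibble::tibble(
    x1 = rnorm(n), x = runif(n), y = runif(n)
  )
  d$resp <- exp(1 + 0.5 * d$x1) * exp(rnorm(n, 0, 0.02))
  fit <- fit_trend(d, "resp", "x1", family = "glm", use_longitude = FALSE)
  co <- summary(fit$fit)$coefficients
  expect_lt(abs(co["(Intercept)", 1] - 1), 2 * co["(Intercept)", 2] + 1e-3)
  expect_lt(abs(co["x1", 1] - 0.5), 2 * co["x1", 2] + 1e-3)
  expect_gt(fit$deviance_explained, 0.9)
  expect_error(fit_trend(dplyr::mutate(d, resp = resp - 10), "resp", "x1",
                         family = "glm"), "positive")
})

test_that("a constant response collapses to the intercept-only model", {
  set.seed(8)
  d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60),
                      x = runif(60), y = runif(60), resp = 7)
  fit <- fit_trend(d, "resp", c("x1", "x2"), family = "glm",
                   use_longitude = FALSE)
  expect_equal(length(fit$selected_terms), 0)
  expect_lt(abs(fit$deviance_explained), 1e-8)
})

test_that("double-penalty REML shrinks pure-noise smooths", {
  # pure-noise covariates: the double penalty must cut the covariate edf
  # well below the no-selection fit in every replicate, eliminating a good
  # share of smooths outright (edf < 0.5)
  ratios <- numeric(0)
  eliminated <- 0
  total <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
      x = runif(n), y = runif(n)
    )
    d$resp <- exp(rnorm(n, 2, 0.25))
    fit <- fit_trend(d, "resp", c("x1", "x2", "x3"), family = "gam")
    edf <- summary(fit$fit)$s.table[, "edf"]
    cov_edf <- edf[!grepl("x,y", names(edf))]
    f0 <- resp ~ s(x1, bs = "cr", k = 5) + s(x2, bs = "cr", k = 5) +
      s(x3, bs = "cr", k = 5) + s(x, y, bs = "ds", m = c(1, 0.5), k = 25)
    plain <- mgcv::gam(f0, data = d, family = stats::quasipoisson(),
                       method = "REML", select = FALSE)
    plain_edf <- summary(plain)$s.table[1:3, "edf"]
    ratios <- c(ratios, sum(cov_edf) / sum(plain_edf))
    eliminated <- eliminated + sum(cov_edf < 0.5)
    total <- total + length(cov_edf)
  }
  expect_true(all(ratios < 1))
  expect_lt(mean(ratios), 0.7)
  expect_gte(eliminated, total / 3)
})

test_that("regression kriging composes trend and residual exactly", {
  set.seed(9)
  land <- sim_landscape(sim_config(seed = 9, grid_rows = 8, grid_cols = 8))
  d <- dplyr::left_join(land$grid, land$covariates, by = "cell_id")
  d$resp <- land$truth$D0
  fit <- fit_trend(d, "resp", c("ndvi", "temperature"), family = "glm",
                   use_longitude = FALSE)
  # pure regression: the kriged-residual term is zero
  pure <- regression_krige(fit, d, d, krige_residuals = FALSE)
  expect_true(all(pure$resid_ok == 0))
  expect_equal(pure$prediction, pmax(predict(fit, d)$mu, min(d$resp)))
  # zero-nugget residual kriging reproduces the observations at the cells
  ev <- empirical_variogram(d[, c("x", "y")],
                            d$resp - predict(fit, d)$mu)
  vg <- fit_variogram(ev)
  vg0 <- vg_model(vg$family, nugget = 0, psill = max(vg$psill, 1e-3),
                  range = vg$range)
  rk <- regression_krige(fit, d, d, vg = vg0)
  expect_equal(rk$prediction, d$resp, tolerance = 1e-6)
  # pure-nugget residual variogram degrades, at new locations, to the
  # regression plus one constant (the residual mean)
  vgn <- vg_model("exponential", nugget = 2, psill = 0, range = 1)
  train <- d[1:48, ]
  held <- d[49:64, ]
  fit2 <- fit_trend(train, "resp", c("ndvi", "temperature"), family = "glm",
                    use_longitude = FALSE)
  rkn <- regression_krige(fit2, train, held, vg = vgn)
  shift <- rkn$prediction - predict(fit2, held)$mu
  expect_lt(diff(range(shift)), 1e-8)
  expect_equal(shift[1], mean(train$resp - predict(fit2, train)$mu),
               tolerance = 1e-8)
})
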