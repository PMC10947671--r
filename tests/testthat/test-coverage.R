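# Coverage estimation and coverage-standardized Hill numbers.

test_that("coverage estimator reproduces hand-evaluated values", {
  # Y = [3,2,1,1], T = 4: U = 7, Q1 = 2, Q2 = 1, A = 6/8
  expect_equal(sample_coverage(c(3, 2, 1, 1), 4), 1 - (2 / 7) * 0.75,
               tolerance = 1e-12)
  # doubled effort: A^(t* + 1) with t* = 4
  expect_equal(sample_coverage(c(3, 2, 1, 1), 4, t_extra = 4),
               1 - (2 / 7) * 0.75^5, tolerance = 1e-12)
  # no singletons: complete coverage at any extrapolation
  expect_identical(sample_coverage(c(2, 2, 3), 3), 1)
  expect_identical(sample_coverage(c(2, 2, 3), 3, t_extra = 10), 1)
  expect_error(sample_coverage(c(1, 1), 1), "insufficient")
})

test_that("coverage is monotone in extra effort and bounded in [0, 1]", {
  set.seed(42)
  for (i in 1:20) {
    M <- rand_incidence_matrix(sample(3:10, 1), sample(3:12, 1))
    if (nrow(M) == 0) next
    y <- mat_to_y(M)
    Tt <- ncol(M)
    cv <- vapply(seq(0, 3 * Tt, by = 0.5),
                 function(t_extra) sample_coverage(y, Tt, t_extra), numeric(1))
    expect_true(all(diff(cv) >= -1e-12))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("saturation classification applies the >= rule at the threshold", {
  y <- c(3, 2, 1, 1)
  inc <- tibble::tibble(
    cell_id = "c", T = 4L, n_observers = 4L, y = list(y)
  )
  c2t <- sample_coverage(y, 4, t_extra = 4)
  expect_true(coverage_profile(inc, C_threshold = c2t)$saturated)
  expect_false(coverage_profile(inc, C_threshold = c2t + 1e-9)$saturated)
  # Q1 = 0 cell is saturated under any threshold <= 1
  inc0 <- tibble::tibble(cell_id = "c", T = 3L, n_observers = 3L,
                         y = list(c(2, 2, 3)))
  prof <- coverage_profile(inc0, C_threshold = 1)
  expect_true(prof$saturated)
  expect_identical(prof$C_T, 1)
})

test_that("effort inversion hits the target and is minimal", {
  y <- c(3, 2, 1, 1)
  # fixed point: the coverage at observed effort inverts to T
  ct <- sample_coverage(y, 4)
  expect_equal(effort_for_coverage(y, 4, C_target = ct), 4, tolerance = 1e-3)
  # tiny target: minimal positive effort
  expect_equal(effort_for_coverage(y, 4, C_target = 1e-6), 1)
  set.seed(99)
  for (i in 1:30) {
    M <- rand_incidence_matrix(sample(4:12, 1), sample(3:12, 1))
    if (nrow(M) < 2) next
    y <- mat_to_y(M)
    Tt <- ncol(M)
    ms <- suppressWarnings(effort_for_coverage(y, Tt, 0.8))
    capped <- ms >= 2 * Tt - 1e-9 &&
      coverage_at_effort(y, Tt, 2 * Tt) < 0.8
    if (capped) next
    expect_gte(coverage_at_effort(y, Tt, ms), 0.8 - 1e-5)
    if (ms > 1) {
      expect_lt(coverage_at_effort(y, Tt, max(1, ms - 1e-2)), 0.8 + 1e-5)
    }
  }
})

test_that("rarefied Hill numbers agree exactly with subset enumeration", {
  set.seed(7)
  for (i in 1:15) {
    Tt <- sample(4:9, 1)
    M <- rand_incidence_matrix(Tt, sample(3:12, 1))
    if (nrow(M) < 2) next
    y <- mat_to_y(M)
    for (m in unique(c(2, ceiling(Tt / 2), Tt - 1))) {
      oracle <- enum_hill_oracle(M, m)
      expect_equal(hill_incidence(y, Tt, m, 0), unname(oracle["D0"]),
                   tolerance = 1e-10)
      expect_equal(hill_incidence(y, Tt, m, 1), unname(oracle["D1"]),
                   tolerance = 1e-10)
      expect_equal(hill_incidence(y, Tt, m, 2), unname(oracle["D2"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("textbook rarefaction cases come out exactly", {
  # two units, species A in both, B in one: expected richness of one unit
  expect_equal(hill_incidence(c(2, 1), 2, m = 1, q = 0), 1.5)
  # single species: unit diversity at every order and any coverage target
  for (yv in list(1, 3, 6)) {
    d <- suppressWarnings(diversity_at_coverage(yv, 6, C_target = 0.8))
    expect_equal(d$D_hat, rep(1, 3))
  }
  # equal incidence counts across S species at m = T collapse to S
  expect_equal(
    vapply(0:2, function(q) hill_incidence(rep(3, 4), 6, 6, q), numeric(1)),
    rep(4, 3)
  )
})

test_that("standardized estimates preserve Hill ordering and the unit floor", {
  set.seed(13)
  for (i in 1:40) {
    M <- rand_incidence_matrix(sample(3:12, 1), sample(1:15, 1))
    if (nrow(M) == 0) next
    y <- mat_to_y(M)
    for (ct in c(0.6, 0.8, 0.95)) {
      d <- suppressWarnings(diversity_at_coverage(y, ncol(M), C_target = ct))
      expect_true(all(diff(d$D_hat) <= 1e-12))
      expect_true(all(d$D_hat >= 1 - 1e-12))
      expect_true(d$mode[1] %in% c("interpolated", "observed", "extrapolated"))
    }
  }
})

test_that("diversity at 80% and 90% coverage rank cells almost identically", {
  # mirrors the protocol's internal consistency argument for the 80% rule
  set.seed(2024)
  cells <- lapply(1:40, function(i) {
    S <- sample(20:60, 1)
    p <- rlnorm(S, 0, 1.5)
    p <- p / sum(p)
    Tt <- sample(40:80, 1)
    M <- matrix(rbinom(S * Tt, 1, rep(pmin(1, 12 * p), Tt)), nrow = S)
    M <- M[rowSums(M) > 0, , drop = FALSE]
    list(y = rowSums(M), T = Tt)
  })
  d80 <- vapply(cells, function(cl) {
    suppressWarnings(diversity_at_coverage(cl$y, cl$T, q = 0, C_target = 0.8))$D_hat
  }, numeric(1))
  d90 <- vapply(cells, function(cl) {
    suppressWarnings(diversity_at_coverage(cl$y, cl$T, q = 0, C_target = 0.9))$D_hat
  }, numeric(1))
  expect_gt(stats::cor(d80, d90, method = "spearman"), 0.9)
})
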