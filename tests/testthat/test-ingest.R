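# Record cleaning, grid assignment, incidence building, effort filter.

test_that("cleaning drops exactly the records violating a rule", {
  rec <- make_records(
    species = c("a", "b", "c", "d", "e"),
    x = c(1, 2, NA, 4, 5), y = c(1, 2, 3, NA, 5),
    observer = "o1"
  )
  out <- clean_records(rec)
  expect_equal(nrow(out), 3)
  log <- attr(out, "removal_log")
  expect_equal(log$n_removed[log$rule == "missing_coordinates"], 2)

  # all complete and wild: identity
  rec2 <- make_records("a", 1, 1, "o1")
  expect_equal(nrow(clean_records(rec2)), 1)

  # non-wild and genus-level records are removed
  rec3 <- make_records(c("a", "b", "c"), 1:3, 1:3, "o1",
                       wild = c("wild", "cultivated", "wild"),
                       rank = c("species", "species", "genus"))
  expect_equal(nrow(clean_records(rec3)), 1)

  expect_error(clean_records(tibble::tibble(a = 1)), "schema")
})

test_that("cleaning is idempotent and matches the injected corruption ledger", {
  land <- sim_landscape(sim_config(seed = 21, grid_rows = 6, grid_cols = 6,
                                   observer_rate = 12, corrupt_frac = 0.2))
  occ <- sim_occurrences(land)
  cleaned <- clean_records(occ)
  log <- attr(cleaned, "removal_log")
  expect_equal(log$n_removed[log$rule == "total_removed"], sum(occ$.corrupted))
  twice <- clean_records(cleaned)
  expect_equal(nrow(twice), nrow(cleaned))
  log2 <- attr(twice, "removal_log")
  expect_equal(log2$n_removed[log2$rule == "total_removed"], 0)
})

test_that("grid assignment follows the half-open convention", {
  g <- grid_spec(origin = c(0, 0), cell_size = 10, rows = 3, cols = 3)
  rec <- make_records(
    species = c("origin", "edge_x", "interior", "outside"),
    x = c(0, 10, 25, 31), y = c(0, 5, 25, 5),
    observer = "o1"
  )
  out <- assign_grid(rec, g)
  # origin belongs to the first cell; an x = 10 edge point to the next column
  expect_equal(out$cell_col[out$scientificName == "origin"], 1L)
  expect_equal(out$cell_row[out$scientificName == "origin"], 1L)
  expect_equal(out$cell_col[out$scientificName == "edge_x"], 2L)
  expect_equal(out$cell_id[out$scientificName == "interior"], "c003_003")
  # outside the extent: dropped and logged (conservation)
  expect_false("outside" %in% out$scientificName)
  expect_equal(nrow(out) + attr(out, "n_dropped_outside"), nrow(rec))
})

test_that("assignment agrees with the generator's cell ledger", {
  land <- sim_landscape(sim_config(seed = 8, grid_rows = 5, grid_cols = 7,
                                   observer_rate = 8, corrupt_frac = 0))
  occ <- sim_occurrences(land)
  out <- assign_grid(clean_records(occ), grid_spec_of(land))
  expect_equal(attr(out, "n_dropped_outside"), 0)
  expect_identical(out$cell_id, out$.cell_true)
})

test_that("incidence building collapses abundance within sampling units", {
  # one observer, one date, one species recorded 7 times
  rec <- make_records(rep("a", 7), 1, 1, "o1")
  rec$cell_id <- "c001_001"
  inc <- build_incidence(rec)
  expect_equal(inc$T, 1L)
  expect_equal(unname(inc$y[[1]]), 1L)
  expect_equal(inc$U, 1)

  # two units; A in both, B in unit 1 only
  rec2 <- make_records(c("A", "B", "A"), 1, 1, c("o1", "o1", "o2"))
  rec2$cell_id <- "c001_001"
  inc2 <- build_incidence(rec2)
  expect_equal(inc2$T, 2L)
  expect_equal(sort(unname(inc2$y[[1]])), c(1L, 2L))
  expect_equal(inc2$Q1, 1L)
  expect_equal(inc2$Q2, 1L)

  # empty input
  expect_equal(nrow(build_incidence(rec2[0, ])), 0)
})

test_that("incidence frequencies match a brute-force recount", {
  set.seed(31)
  n <- 400
  rec <- make_records(
    species = sprintf("sp%02d", sample(1:15, n, replace = TRUE)),
    x = runif(n), y = runif(n),
    observer = sprintf("o%02d", sample(1:12, n, replace = TRUE)),
    date = as.Date("2020-01-01") + sample(0:5, n, replace = TRUE)
  )
  rec$cell_id <- "c001_001"
  inc <- build_incidence(rec, unit = "observer_day")
  # brute force over explicit unit keys
  key <- paste(rec$recordedBy, rec$eventDate)
  units <- unique(key)
  y_bf <- vapply(sort(unique(rec$scientificName)), function(sp) {
    sum(vapply(units, function(u) {
      any(rec$scientificName == sp & key == u)
    }, logical(1)))
  }, integer(1))
  expect_equal(inc$T, length(units))
  expect_equal(inc$y[[1]][names(y_bf)], y_bf)
  # invariants
  expect_lte(inc$Q1 + inc$Q2, inc$S_obs)
  expect_gte(inc$U, inc$S_obs)
  expect_lte(max(inc$y[[1]]), inc$T)

  # observer rule merges an observer's dates into one unit
  inc_obs <- build_incidence(rec, unit = "observer")
  expect_equal(inc_obs$T, length(unique(rec$recordedBy)))
  expect_lte(max(inc_obs$y[[1]]), inc_obs$T)
})

test_that("incidence invariants hold on fuzzed inputs", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(20:150, 1)
    rec <- make_records(
      species = sprintf("sp%02d", sample(1:10, n, replace = TRUE)),
      x = runif(n), y = runif(n),
      observer = sprintf("o%02d", sample(1:8, n, replace = TRUE)),
      date = as.Date("2020-01-01") + sample(0:3, n, replace = TRUE)
    )
    rec$cell_id <- sample(c("a", "b"), n, replace = TRUE)
    inc <- build_incidence(rec)
    expect_true(all(inc$Q1 + inc$Q2 <= inc$S_obs))
    expect_true(all(inc$U >= inc$S_obs))
    expect_true(all(vapply(seq_len(nrow(inc)),
                           function(j) max(inc$y[[j]]) <= inc$T[j],
                           logical(1))))
  }
})

test_that("the minimum-observer rule is a strict >= threshold", {
  inc <- tibble::tibble(
    cell_id = c("a", "b", "c"), T = c(50L, 45L, 10L),
    n_observers = c(39L, 40L, 10L),
    S_obs = 1L, U = 1, Q1 = 0L, Q2 = 0L, y = list(1, 1, 1)
  )
  out <- apply_effort_filter(inc, min_observers = 40)
  expect_equal(out$eligible, c(FALSE, TRUE, FALSE))
  expect_true(all(apply_effort_filter(inc, min_observers = 1)$eligible))
})

test_that("occurrence and incidence files round-trip losslessly", {
  land <- sim_landscape(sim_config(seed = 3, grid_rows = 4, grid_cols = 4,
                                   observer_rate = 10))
  occ <- sim_occurrences(land)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, tmp)
  back <- read_occurrences(tmp)
  expect_equal(as.data.frame(back[occurrence_cols <- names(occ)]),
               as.data.frame(occ))

  inc <- build_incidence(assign_grid(clean_records(occ), grid_spec_of(land)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence(inc, f1, f2)
  inc2 <- read_incidence(f1, f2)
  expect_equal(inc2$T, inc$T)
  expect_equal(inc2$Q1, inc$Q1)
  for (j in seq_len(nrow(inc))) {
    expect_equal(sort(inc2$y[[j]]), sort(inc$y[[j]]))
  }
})
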