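# Independent oracles used across the suite. These recompute expected
# values from first principles (enumeration, Monte-Carlo subsampling,
# direct linear algebra) without going through the package's estimator
# code paths.

# Random species-by-unit incidence matrix for a small cell.
rand_incidence_matrix <- function(Tt, S, p_range = c(0.1, 0.9)) {
  p <- runif(S, p_range[1], p_range[2])
  M <- matrix(rbinom(S * Tt, 1, rep(p, Tt)), nrow = S)
  M[rowSums(M) > 0, , drop = FALSE]
}

# Hill numbers of a frequency-count vector Qk (k = 1..m): the functional
# the rarefaction estimators target, applied to (possibly averaged) counts.
hill_of_counts <- function(Qk) {
  k <- seq_along(Qk)
  U <- sum(k * Qk)
  p <- k / U
  c(
    D0 = sum(Qk),
    D1 = exp(-sum(ifelse(Qk > 0, p * log(p) * Qk, 0))),
    D2 = U^2 / sum(k^2 * Qk)
  )
}

# Exact enumeration oracle: average frequency counts over ALL m-unit
# subsets of the T units, then take Hill numbers of the averaged counts.
enum_hill_oracle <- function(M, m) {
  Tt <- ncol(M)
  subs <- utils::combn(Tt, m)
  Qk <- rep(0, m)
  for (j in seq_len(ncol(subs))) {
    cnt <- rowSums(M[, subs[, j], drop = FALSE])
    for (k in seq_len(m)) Qk[k] <- Qk[k] + sum(cnt == k)
  }
  hill_of_counts(Qk / ncol(subs))
}

# Monte-Carlo subsampling oracle with batch-based standard errors.
# Drawing `n_draws` uniform subsets is realized as a multinomial over the
# enumerated distinct subsets (identical distribution, much faster).
mc_hill_oracle <- function(M, m, n_draws = 1e5, n_batches = 100) {
  Tt <- ncol(M)
  subs <- utils::combn(Tt, m)
  n_sub <- ncol(subs)
  # frequency-count vector of each distinct subset
  Qmat <- matrix(0, nrow = n_sub, ncol = m)
  for (j in seq_len(n_sub)) {
    cnt <- rowSums(M[, subs[, j], drop = FALSE])
    for (k in seq_len(m)) Qmat[j, k] <- sum(cnt == k)
  }
  per_batch <- n_draws / n_batches
  batch_est <- matrix(NA_real_, nrow = n_batches, ncol = 3)
  total_counts <- rep(0, n_sub)
  for (b in seq_len(n_batches)) {
    draws <- as.numeric(stats::rmultinom(1, per_batch, rep(1 / n_sub, n_sub)))
    total_counts <- total_counts + draws
    batch_est[b, ] <- hill_of_counts(colSums(Qmat * draws) / per_batch)
  }
  est <- hill_of_counts(colSums(Qmat * total_counts) / n_draws)
  se <- apply(batch_est, 2, stats::sd) / sqrt(n_batches)
  list(est = est, se = se)
}

# Independent ordinary-kriging solve: assemble and solve the augmented
# system with explicit loops for a single prediction point.
ok_oracle <- function(obs_coords, obs_values, pred_point, gamma_fun) {
  n <- nrow(obs_coords)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt(sum((obs_coords[i, ] - obs_coords[j, ])^2))
        A[i, j] <- gamma_fun(d)
      }
    }
    A[i, n + 1] <- 1
    A[n + 1, i] <- 1
  }
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    d <- sqrt(sum((obs_coords[i, ] - pred_point)^2))
    b[i] <- gamma_fun(d)
  }
  b[n + 1] <- 1
  sol <- solve(A, b)
  list(
    prediction = sum(sol[seq_len(n)] * obs_values),
    variance = sum(sol * b),
    weights = sol[seq_len(n)]
  )
}

# Incidence frequencies of a matrix cell.
mat_to_y <- function(M) rowSums(M)

# Small helper: occurrence tibble from explicit fields.
make_records <- function(species, x, y, observer, date = as.Date("2020-06-01"),
                         wild = "wild", rank = "species") {
  tibble::tibble(
    scientificName = species,
    decimalLatitude = y,
    decimalLongitude = x,
    recordedBy = observer,
    eventDate = date,
    establishmentMeans = wild,
    taxonRank = rank
  )
}
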