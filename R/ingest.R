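## Record cleaning, grid assignment and incidence building.

#' Grid specification
#'
#' Defines the equal-area analysis grid: origin (lower-left corner in
#' projected coordinates), cell size in metres, dimensions, and the
#' projected CRS label. Cells are half-open intervals `[low, high)` in both
#' axes, indexed by row then column; a point on a shared edge belongs to the
#' higher-index cell.
#'
#' @param origin Numeric length-2: projected x, y of the grid lower-left.
#' @param cell_size Cell edge length in metres (default 5000).
#' @param rows,cols Grid dimensions.
#' @param crs CRS label. Synthetic data is already planar; for real use an
#'   equal-area projection (e.g. a California Albers variant) is expected.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 5000, rows, cols,
                      crs = "synthetic-planar") {
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (rows < 1 || cols < 1) stop("grid dimensions must be >= 1")
  structure(
    list(origin = origin, cell_size = cell_size, rows = as.integer(rows),
         cols = as.integer(cols), crs = crs),
    class = "grid_spec"
  )
}

#' Grid specification of a synthetic landscape
#' @param landscape A [sim_landscape()] result.
#' @return A [grid_spec()].
#' @export
grid_spec_of <- function(landscape) {
  stopifnot(inherits(landscape, "hillmapr_landscape"))
  cfg <- landscape$config
  grid_spec(
    origin = cfg$origin, cell_size = cfg$cell_size,
    rows = cfg$grid_rows, cols = cfg$grid_cols
  )
}

occurrence_columns <- c(
  "scientificName", "decimalLatitude", "decimalLongitude",
  "recordedBy", "eventDate", "establishmentMeans", "taxonRank"
)

check_occurrence_schema <- function(records) {
  missing <- setdiff(occurrence_columns, names(records))
  if (length(missing) > 0) {
    stop("schema error: missing occurrence columns: ",
         paste(missing, collapse = ", "))
  }
  invisible(records)
}

#' Clean occurrence records
#'
#' Applies the eligibility rules for research-grade wild-plant records:
#' drops records with a missing species name, a missing coordinate,
#' incomplete taxonomy (rank above species), or a non-wild establishment
#' flag. The per-rule removal counts are attached as the `removal_log`
#' attribute (a record violating several rules is counted under each).
#' Cleaning is idempotent.
#'
#' @param records Occurrence tibble with Darwin-Core-style columns.
#' @return The retained records, with attribute `removal_log`.
#' @export
clean_records <- function(records) {
  check_occurrence_schema(records)
  miss_sp <- is.na(records$scientificName) | records$scientificName == ""
  miss_coord <- is.na(records$decimalLatitude) | is.na(records$decimalLongitude)
  incomplete_tax <- is.na(records$taxonRank) | records$taxonRank != "species"
  not_wild <- is.na(records$establishmentMeans) |
    records$establishmentMeans != "wild"
  drop <- miss_sp | miss_coord | incomplete_tax | not_wild
  out <- records[!drop, , drop = FALSE]
  attr(out, "removal_log") <- tibble::tibble(
    rule = c("missing_species", "missing_coordinates",
             "incomplete_taxonomy", "not_wild", "total_removed"),
    n_removed = c(sum(miss_sp), sum(miss_coord), sum(incomplete_tax),
                  sum(not_wild), sum(drop))
  )
  out
}

#' Assign cleaned records to grid cells
#'
#' Computes the half-open cell index of every record from its projected
#' coordinates (`decimalLongitude` = x, `decimalLatitude` = y for planar
#' data) and drops records outside the grid extent (count attached as the
#' `n_dropped_outside` attribute).
#'
#' @param records Cleaned occurrence tibble.
#' @param grid A [grid_spec()].
#' @return Records with added `cell_row`, `cell_col`, `cell_id` columns.
#' @export
assign_grid <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  check_occurrence_schema(records)
  col <- floor((records$decimalLongitude - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((records$decimalLatitude - grid$origin[2]) / grid$cell_size) + 1L
  inside <- !is.na(row) & !is.na(col) &
    row >= 1L & row <= grid$rows & col >= 1L & col <= grid$cols
  out <- records[inside, , drop = FALSE]
  out$cell_row <- row[inside]
  out$cell_col <- col[inside]
  out$cell_id <- sprintf("c%03d_%03d", out$cell_row, out$cell_col)
  attr(out, "n_dropped_outside") <- sum(!inside)
  out
}

#' Build per-cell incidence data
#'
#' Collapses abundance-style records to incidence: the sampling unit is a
#' distinct (observer, date) pair by default (or a distinct observer), `T`
#' is the number of units in the cell, and each species' incidence frequency
#' `Y_i` counts the units in which it occurs at least once. Duplicate
#' records of a species within one unit collapse to a single incidence.
#'
#' @param records Occurrence tibble with a `cell_id` column (see
#'   [assign_grid()]).
#' @param unit Sampling-unit rule: `"observer_day"` (default) or
#'   `"observer"`.
#' @return Nested tibble with one row per cell: `cell_id`, `T`,
#'   `n_observers`, `S_obs`, `U`, `Q1`, `Q2` and the list-column `y` of
#'   named incidence-frequency vectors.
#' @export
build_incidence <- function(records, unit = c("observer_day", "observer")) {
  unit <- match.arg(unit)
  if (!"cell_id" %in% names(records)) {
    stop("records must carry `cell_id`; run assign_grid() first")
  }
  empty <- tibble::tibble(
    cell_id = character(), T = integer(), n_observers = integer(),
    S_obs = integer(), U = numeric(), Q1 = integer(), Q2 = integer(),
    y = list()
  )
  if (nrow(records) == 0) {
    return(empty)
  }
  records$.unit <- if (unit == "observer_day") {
    paste(records$recordedBy, records$eventDate, sep = "@")
  } else {
    records$recordedBy
  }
  per_cell <- dplyr::group_by(records, .data$cell_id)
  inc <- dplyr::summarise(
    per_cell,
    T = dplyr::n_distinct(.data$.unit),
    n_observers = dplyr::n_distinct(.data$recordedBy),
    y = list({
      pairs <- unique(data.frame(sp = .data$scientificName, u = .data$.unit))
      tab <- table(pairs$sp)
      stats::setNames(as.integer(tab), names(tab))
    }),
    .groups = "drop"
  )
  dplyr::mutate(
    inc,
    S_obs = vapply(.data$y, length, integer(1)),
    U = vapply(.data$y, sum, numeric(1)),
    Q1 = vapply(.data$y, function(v) sum(v == 1L), integer(1)),
    Q2 = vapply(.data$y, function(v) sum(v == 2L), integer(1))
  )[, names(empty)]
}

#' Mark cells meeting the minimum-observer effort rule
#'
#' Cells with at least `min_observers` unique observers are eligible for the
#' coverage analysis; the rest are left to be filled by spatial
#' extrapolation.
#'
#' @param inc Nested incidence tibble from [build_incidence()].
#' @param min_observers Minimum unique observers per cell (default 40).
#' @return `inc` with a logical `eligible` column.
#' @export
apply_effort_filter <- function(inc, min_observers = 40) {
  dplyr::mutate(inc, eligible = .data$n_observers >= min_observers)
}
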