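## Plain-text readers/writers: Darwin-Core-style occurrence CSV, long-format
## incidence CSV + cell summary, tract GeoJSON. Writers round-trip
## losslessly with the corresponding readers.

#' Write / read occurrence records as Darwin-Core-style CSV
#'
#' @param records Occurrence tibble.
#' @param path CSV path.
#' @return `write_occurrences()` returns `path` invisibly;
#'   `read_occurrences()` returns the occurrence tibble.
#' @export
write_occurrences <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @param col_mapping Optional named character vector mapping the standard
#'   column names to the file's column names, e.g.
#'   `c(scientificName = "species")`.
#' @export
read_occurrences <- function(path, col_mapping = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!is.null(col_mapping)) {
    for (std in names(col_mapping)) {
      names(out)[names(out) == col_mapping[[std]]] <- std
    }
  }
  if ("eventDate" %in% names(out)) {
    out$eventDate <- as.Date(out$eventDate)
  }
  check_occurrence_schema(out)
  out
}

#' Write / read per-cell incidence data
#'
#' The sparse long file holds one row per (cell, species) with the incidence
#' frequency `y`; the summary file holds per-cell totals
#' (`T`, `S_obs`, `U`, `Q1`, `Q2`, `n_observers`).
#'
#' @param inc Nested incidence tibble from [build_incidence()].
#' @param long_path,summary_path CSV paths.
#' @return `write_incidence()` returns the paths invisibly;
#'   `read_incidence()` rebuilds the nested incidence tibble.
#' @export
write_incidence <- function(inc, long_path, summary_path) {
  long <- purrr::map2_dfr(inc$cell_id, inc$y, function(id, y) {
    tibble::tibble(cell_id = id, species_id = names(y), y = as.integer(y))
  })
  readr::write_csv(long, long_path)
  readr::write_csv(
    inc[, c("cell_id", "T", "n_observers", "S_obs", "U", "Q1", "Q2")],
    summary_path
  )
  invisible(c(long_path, summary_path))
}

#' @rdname write_incidence
#' @export
read_incidence <- function(long_path, summary_path) {
  long <- readr::read_csv(long_path, show_col_types = FALSE, progress = FALSE)
  summ <- readr::read_csv(summary_path, show_col_types = FALSE, progress = FALSE)
  ys <- lapply(split(long, long$cell_id), function(d) {
    stats::setNames(as.integer(d$y), d$species_id)
  })
  summ$y <- ys[summ$cell_id]
  summ[, c("cell_id", "T", "n_observers", "S_obs", "U", "Q1", "Q2", "y")]
}

#' Write / read tract tables as GeoJSON
#'
#' Tracts are axis-aligned rectangles; every non-geometry column is stored
#' as a feature property.
#'
#' @param tracts Tract tibble with `xmin`, `xmax`, `ymin`, `ymax`.
#' @param path GeoJSON path.
#' @return `write_tracts_geojson()` returns `path` invisibly;
#'   `read_tracts_geojson()` returns the tract tibble.
#' @export
write_tracts_geojson <- function(tracts, path) {
  props <- setdiff(names(tracts), c("xmin", "xmax", "ymin", "ymax"))
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- list(
      c(tracts$xmin[i], tracts$ymin[i]), c(tracts$xmax[i], tracts$ymin[i]),
      c(tracts$xmax[i], tracts$ymax[i]), c(tracts$xmin[i], tracts$ymax[i]),
      c(tracts$xmin[i], tracts$ymin[i])
    )
    list(
      type = "Feature",
      properties = as.list(tracts[i, props, drop = FALSE]),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tracts_geojson
#' @export
read_tracts_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    dplyr::bind_cols(
      tibble::as_tibble(props),
      tibble::tibble(xmin = min(xs), xmax = max(xs),
                     ymin = min(ys), ymax = max(ys))
    )
  })
  rows
}
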