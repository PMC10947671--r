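## Exact rectangle geometry used for grid/tract bookkeeping. Cells are
## axis-aligned squares centred on their centroids; tracts are axis-aligned
## rectangles, so intersection areas are closed-form.

## Area-weighted aggregation of per-cell values into rectangles.
## `rects`: tibble with tract_id, xmin, xmax, ymin, ymax.
## `grid`: tibble with cell_id, x, y (centroids).
## `cell_values`: tibble keyed by cell_id with `value_cols`.
## Returns one row per tract_id with the area-weighted means (NA when a
## tract intersects no cell).
aggregate_cells_to_rects <- function(rects, grid, cell_values, cell_size,
                                     value_cols) {
  half <- cell_size / 2
  vals <- dplyr::left_join(grid, cell_values, by = "cell_id")
  vm <- as.matrix(vals[, value_cols, drop = FALSE])
  out <- matrix(NA_real_, nrow = nrow(rects), ncol = length(value_cols))
  for (i in seq_len(nrow(rects))) {
    ox <- pmax(
      0,
      pmin(rects$xmax[i], vals$x + half) - pmax(rects$xmin[i], vals$x - half)
    )
    oy <- pmax(
      0,
      pmin(rects$ymax[i], vals$y + half) - pmax(rects$ymin[i], vals$y - half)
    )
    w <- ox * oy
    if (sum(w) > 0) {
      out[i, ] <- colSums(vm * w, na.rm = FALSE) / sum(w)
    }
  }
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- value_cols
  dplyr::bind_cols(rects["tract_id"], res)
}
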