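# The 1-km2 analysis grid. Cells are axis-aligned squares; membership is
# half-open with points and segments lying exactly on a shared boundary
# assigned to the cell with the smaller (col, row) index, so every location
# belongs to exactly one cell and totals are conserved.

#' Build the analysis grid over a study area
#'
#' Lays a square lattice of `cell_size`-meter cells over the bounding box of
#' the study-area polygon and keeps every cell whose center lies inside the
#' polygon, so the cell count approximates the polygon area in km2.
#'
#' @param study_area a polygon feature (`list(rings = list(outer, ...))`), a
#'   plain ring matrix, or a `poly_layer` with one feature.
#' @param cell_size cell side length in meters (default 1000).
#' @param origin optional c(x0, y0) lattice origin; defaults to the bounding
#'   box lower-left snapped to `cell_size`.
#' @return object of class `panther_grid` with a `cells` data.frame
#'   (cell_id, col, row, xc, yc).
#' @export
build_grid <- function(study_area, cell_size = 1000, origin = NULL) {
  feat <- as_feature(study_area)
  outer <- feat$rings[[1]]
  if (nrow(outer) < 3 || feature_area(feat) <= 0) {
    stop("study area polygon is empty or invalid")
  }
  if (feature_area(feat) <= cell_size^2) {
    stop("study area polygon must exceed one cell in area")
  }
  bb <- apply(outer, 2, range)
  if (is.null(origin)) {
    origin <- c(floor(bb[1, 1] / cell_size) * cell_size,
                floor(bb[1, 2] / cell_size) * cell_size)
  }
  n_cols <- ceiling((bb[2, 1] - origin[1]) / cell_size)
  n_rows <- ceiling((bb[2, 2] - origin[2]) / cell_size)
  cols <- rep(seq_len(n_cols), times = n_rows)
  rows <- rep(seq_len(n_rows), each = n_cols)
  xc <- origin[1] + (cols - 0.5) * cell_size
  yc <- origin[2] + (rows - 0.5) * cell_size
  keep <- point_in_feature(xc, yc, feat, include_boundary = TRUE)
  cells <- data.frame(cell_id = (rows[keep] - 1L) * n_cols + cols[keep],
                      col = cols[keep], row = rows[keep],
                      xc = xc[keep], yc = yc[keep])
  structure(list(x0 = origin[1], y0 = origin[2], cell_size = cell_size,
                 n_cols = n_cols, n_rows = n_rows, cells = cells),
            class = "panther_grid")
}

#' @export
print.panther_grid <- function(x, ...) {
  cat("Analysis grid:", nrow(x$cells), "cells of",
      x$cell_size / 1000, "km,", x$n_cols, "x", x$n_rows, "lattice\n")
  invisible(x)
}

# Rectangular grid without a study-area polygon (used by the synthetic
# landscape, where the study area is the full square extent).
rect_grid <- function(extent_m, cell_size = 1000, origin = c(0, 0)) {
  n <- as.integer(round(extent_m / cell_size))
  cols <- rep(seq_len(n), times = n)
  rows <- rep(seq_len(n), each = n)
  cells <- data.frame(cell_id = (rows - 1L) * n + cols, col = cols, row = rows,
                      xc = origin[1] + (cols - 0.5) * cell_size,
                      yc = origin[2] + (rows - 0.5) * cell_size)
  structure(list(x0 = origin[1], y0 = origin[2], cell_size = cell_size,
                 n_cols = n, n_rows = n, cells = cells),
            class = "panther_grid")
}

# Map coordinates to (col, row); coordinates exactly on an interior lattice
# line fall to the lower/left cell (smaller index). Returns NA outside the
# lattice bounding box.
grid_col_row <- function(grid, x, y) {
  s <- grid$cell_size
  fx <- (x - grid$x0) / s
  fy <- (y - grid$y0) / s
  col <- floor(fx) + 1L
  row <- floor(fy) + 1L
  on_vline <- fx == floor(fx) & col > 1L
  on_hline <- fy == floor(fy) & row > 1L
  col[on_vline] <- col[on_vline] - 1L
  row[on_hline] <- row[on_hline] - 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(col = col, row = row)
}

# Cell id for coordinates (NA when outside the lattice or not an included
# study-area cell).
cell_at <- function(grid, x, y) {
  cr <- grid_col_row(grid, x, y)
  id <- (cr$row - 1L) * grid$n_cols + cr$col
  id[!(id %in% grid$cells$cell_id)] <- NA_integer_
  id
}

cell_bounds <- function(grid, cell_id) {
  col <- (cell_id - 1L) %% grid$n_cols + 1L
  row <- (cell_id - 1L) %/% grid$n_cols + 1L
  s <- grid$cell_size
  list(xmin = grid$x0 + (col - 1) * s, ymin = grid$y0 + (row - 1) * s,
       xmax = grid$x0 + col * s, ymax = grid$y0 + row * s)
}
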