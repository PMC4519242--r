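# Habitat mapping and area accounting: convert per-cell probabilities into
# a habitat map, summarize by zones, and apply the carrying-capacity
# arithmetic.

#' Classify the probability surface into a habitat map
#'
#' Cells with `P >= threshold` (or strictly greater with
#' `strict = TRUE`) are habitat; with 1-km2 cells the habitat area in km2
#' equals the habitat cell count.
#'
#' @param table FeatureTable with fitted `P`.
#' @param threshold probability cutoff in (0, 1).
#' @param strict use strict inequality `P > threshold`?
#' @return object of class `habitat_map`: the per-cell data.frame (cell_id,
#'   P, habitat) plus `habitat_km2` and the threshold.
#' @export
classify_map <- function(table, threshold, strict = FALSE) {
  stopifnot("P" %in% names(table))
  habitat <- if (strict) table$P > threshold else table$P >= threshold
  cells <- data.frame(cell_id = table$cell_id, P = table$P,
                      habitat = as.integer(habitat))
  if (!is.null(table$xc)) { cells$xc <- table$xc; cells$yc <- table$yc }
  structure(list(cells = cells, habitat_km2 = sum(habitat),
                 threshold = threshold, strict = strict),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("Habitat map: %d of %d cells habitat (%.0f km2) at P %s %.3f\n",
              x$habitat_km2, nrow(x$cells), x$habitat_km2,
              if (x$strict) ">" else ">=", x$threshold))
  invisible(x)
}

#' Summarize habitat by zones
#'
#' Assigns each cell (by center) to a zone polygon and reports, per zone,
#' the habitat area, its share of all habitat, and the mean P. Cells
#' outside every zone are reported as "other". Overlapping zones are an
#' error.
#'
#' @param map a [classify_map()] result with cell coordinates.
#' @param zones named list of zone polygons (feature / ring matrix), or a
#'   `poly_layer` with a `name` property.
#' @return data.frame with zone, habitat_km2, share, mean_P, n_cells.
#' @export
zone_summary <- function(map, zones) {
  cells <- map$cells
  if (is.null(cells$xc)) stop("map cells carry no coordinates")
  if (inherits(zones, "poly_layer")) {
    nm <- zones$props$name %||% paste0("zone", seq_along(zones$features))
    zones <- setNames(zones$features, nm)
  }
  member <- matrix(FALSE, nrow(cells), length(zones))
  for (j in seq_along(zones)) {
    member[, j] <- point_in_feature(cells$xc, cells$yc, as_feature(zones[[j]]))
  }
  if (any(rowSums(member) > 1)) stop("overlapping zones")
  zone <- rep("other", nrow(cells))
  for (j in seq_along(zones)) zone[member[, j]] <- names(zones)[j]
  total_habitat <- sum(cells$habitat)
  res <- lapply(c(names(zones), "other"), function(z) {
    i <- zone == z
    data.frame(zone = z, n_cells = sum(i),
               habitat_km2 = sum(cells$habitat[i]),
               share = if (total_habitat > 0) sum(cells$habitat[i]) / total_habitat else NA,
               mean_P = if (any(i)) mean(cells$P[i]) else NA_real_)
  })
  do.call(rbind, res)
}

#' Carrying-capacity arithmetic
#'
#' Expected number of adults supported by a habitat area at a given
#' maximum adult density.
#'
#' @param habitat_km2 habitat area in km2.
#' @param density_per_100km2 adults per 100 km2 (default 2.80, the maximum
#'   adult puma density reported in the western-range literature).
#' @return expected number of adults.
#' @export
capacity <- function(habitat_km2, density_per_100km2 = 2.80) {
  if (habitat_km2 < 0 || density_per_100km2 < 0) stop("inputs must be >= 0")
  habitat_km2 * density_per_100km2 / 100
}

#' Category area and percent table
#'
#' @param areas named numeric vector of category areas (km2), or a
#'   categorized cover `poly_layer` whose feature areas are summed.
#' @param total total area (km2) for the percent column.
#' @return data.frame with category, area_km2, percent (unrounded) and
#'   percent_display (1 decimal).
#' @export
area_table <- function(areas, total) {
  if (total <= 0) stop("total area must be positive")
  if (inherits(areas, "poly_layer")) {
    a <- vapply(areas$features, feature_area, numeric(1)) / 1e6
    areas <- tapply(a, areas$props$category, sum)
    areas <- setNames(as.numeric(areas), names(areas))
  }
  if (any(areas < 0)) stop("category areas must be >= 0")
  pct <- 100 * areas / total
  out <- data.frame(category = names(areas), area_km2 = as.numeric(areas),
                    percent = as.numeric(pct),
                    percent_display = round(as.numeric(pct), 1))
  out[order(-out$area_km2), ]
}
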