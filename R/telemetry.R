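# Telemetry handling: filter fixes to resident breeding adults, build 100%
# minimum-convex-polygon home ranges, label per-cell presence, and compare
# home-range habitat quality between the sexes.

#' Telemetry filter rules
#'
#' Defaults: fixes from January 2004 through December 2013, animals at
#' least 3 years old at the fix (age in continuous years of 365.25 days),
#' and animals retained only when at least 50 fixes survive filtering.
#'
#' @param window_start,window_end inclusive date window.
#' @param min_age_years minimum age at the fix.
#' @param min_fixes minimum surviving fixes per animal.
#' @return object of class `filter_rules`.
#' @export
filter_rules <- function(window_start = "2004-01-01",
                         window_end = "2013-12-31",
                         min_age_years = 3, min_fixes = 50) {
  ws <- as.Date(window_start); we <- as.Date(window_end)
  if (!(ws < we)) stop("window start must precede window end")
  if (min_fixes < 1) stop("min_fixes must be at least 1")
  structure(list(window_start = ws, window_end = we,
                 min_age_years = min_age_years, min_fixes = min_fixes),
            class = "filter_rules")
}

#' Filter telemetry fixes
#'
#' Keeps fixes inside the date window, inside the study area, and taken at
#' or above the minimum age; then drops animals left with fewer than
#' `min_fixes` fixes.
#'
#' @param fixes data.frame with animal_id, sex, birth_date, fix_datetime,
#'   x, y.
#' @param rules a [filter_rules()] object.
#' @param study_area optional polygon (feature, ring matrix, or
#'   single-feature `poly_layer`); when `NULL` no spatial filter is applied.
#' @return filtered fixes with attribute `animal_counts` (fixes per
#'   retained animal).
#' @export
filter_fixes <- function(fixes, rules = filter_rules(), study_area = NULL) {
  fd <- as.Date(fixes$fix_datetime)
  bd <- as.Date(fixes$birth_date)
  keep <- fd >= rules$window_start & fd <= rules$window_end
  age <- as.numeric(fd - bd) / 365.25
  keep <- keep & age >= rules$min_age_years
  if (!is.null(study_area)) {
    feat <- as_feature(study_area)
    keep <- keep & point_in_feature(fixes$x, fixes$y, feat)
  }
  out <- fixes[keep, , drop = FALSE]
  counts <- table(out$animal_id)
  retained <- names(counts)[counts >= rules$min_fixes]
  out <- out[out$animal_id %in% retained, , drop = FALSE]
  if (nrow(out) == 0) message("no fixes survive filtering")
  attr(out, "animal_counts") <- counts[retained]
  out
}

#' Minimum convex polygon home range for one animal
#'
#' 100% MCP: the convex hull of the animal's fixes.
#'
#' @param fixes data.frame of one animal's fixes (x, y in meters), or a
#'   two-column matrix.
#' @return object of class `home_range`: animal_id, sex, n_fixes, ring
#'   (hull matrix), area_km2.
#' @export
mcp_home_range <- function(fixes) {
  if (is.matrix(fixes)) fixes <- data.frame(x = fixes[, 1], y = fixes[, 2])
  x <- fixes$x; y <- fixes$y
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3) stop("degenerate home range: fewer than 3 non-collinear fixes")
  ring <- convex_hull_ring(x, y)
  if (polygon_area(ring) == 0) stop("degenerate home range: collinear fixes")
  structure(list(animal_id = fixes$animal_id[1] %||% NA,
                 sex = as.character(fixes$sex[1] %||% NA),
                 n_fixes = length(x), ring = ring,
                 area_km2 = polygon_area(ring) / 1e6),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat("MCP home range", if (!is.na(x$animal_id)) paste0("(", x$animal_id, ")"),
      ":", x$n_fixes, "fixes,", round(x$area_km2, 2), "km2\n")
  invisible(x)
}

#' Home ranges for all animals in a fix table
#'
#' @param fixes filtered fix data.frame.
#' @return list of `home_range` objects, named by animal id.
#' @export
home_ranges <- function(fixes) {
  by_animal <- split(fixes, fixes$animal_id)
  lapply(by_animal, mcp_home_range)
}

#' Label per-cell presence from filtered fixes
#'
#' A cell is "present" when at least one filtered fix falls inside it
#' (lower-left rule on shared boundaries); all other cells are "absent".
#'
#' @param grid a `panther_grid`.
#' @param fixes filtered fix data.frame.
#' @return data.frame with cell_id and presence (0/1).
#' @export
label_presence <- function(grid, fixes) {
  cid <- cell_at(grid, fixes$x, fixes$y)
  if (anyNA(cid)) {
    warning(sum(is.na(cid)), " fixes fall outside the grid and are ignored")
    cid <- cid[!is.na(cid)]
  }
  presence <- as.integer(grid$cells$cell_id %in% cid)
  data.frame(cell_id = grid$cells$cell_id, presence = presence)
}

#' Mean predicted presence probability within home ranges
#'
#' Averages the model's per-cell P over the grid-cell centers contained in
#' each animal's MCP, reports sex-group medians, and compares the groups
#' with a Wilcoxon rank-sum test (exact when the combined sample is at most
#' 20 and untied; otherwise the tie-corrected normal approximation).
#'
#' @param ranges list of `home_range` objects (see [home_ranges()]).
#' @param table FeatureTable with fitted `P` column.
#' @param grid a `panther_grid`.
#' @return object of class `home_range_P`: per-animal data.frame, group
#'   medians, and the rank-sum p-value.
#' @export
home_range_P <- function(ranges, table, grid) {
  stopifnot("P" %in% names(table))
  tab <- merge(grid$cells, table[, c("cell_id", "P")], by = "cell_id")
  per <- lapply(ranges, function(hr) {
    inside <- point_in_polygon(tab$xc, tab$yc, hr$ring, include_boundary = TRUE)
    data.frame(animal_id = hr$animal_id, sex = hr$sex, n_fixes = hr$n_fixes,
               area_km2 = hr$area_km2, n_cells = sum(inside),
               mean_P = if (any(inside)) mean(tab$P[inside]) else NA_real_)
  })
  per <- do.call(rbind, per)
  if (anyNA(per$mean_P)) {
    warning("home ranges containing no cell centers are excluded: ",
            paste(per$animal_id[is.na(per$mean_P)], collapse = ", "))
  }
  ok <- per[!is.na(per$mean_P), ]
  med <- tapply(ok$mean_P, ok$sex, median)
  pval <- NA_real_
  if (length(unique(ok$sex)) == 2) {
    g <- split(ok$mean_P, ok$sex)
    n <- length(g[[1]]) + length(g[[2]])
    has_ties <- anyDuplicated(ok$mean_P) > 0
    if (length(unique(ok$mean_P)) == 1) {
      pval <- 1  # identical groups: no evidence of a shift
    } else {
      pval <- wilcox.test(g[[1]], g[[2]],
                          exact = (n <= 20 && !has_ties),
                          correct = FALSE)$p.value
    }
  }
  structure(list(per_animal = per, medians = med, p_value = pval),
            class = "home_range_P")
}

#' @export
print.home_range_P <- function(x, ...) {
  cat("Home-range mean P for", nrow(x$per_animal), "animals\n")
  print(round(x$medians, 3))
  cat("Wilcoxon rank-sum p =", signif(x$p_value, 3), "\n")
  invisible(x)
}
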