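# Seasonal water-depth surfaces: interpolate daily gauge stages across the
# grid, subtract ground elevation, and average within season. Depth is
# positive above ground and negative when the water table is below the
# surface.

#' Season definition for depth averaging
#'
#' The wet season is June through October; the dry season November through
#' May. A dry season spans the year boundary and is labeled by its ending
#' year, so for an averaging period `start:end` the dry records run from
#' November of `start - 1` through May of `end`.
#'
#' @param wet_months,dry_months integer month sets; must partition 1..12.
#' @param start_year,end_year averaging period (calendar years).
#' @return object of class `season_config`.
#' @export
season_config <- function(wet_months = 6:10, dry_months = c(11:12, 1:5),
                          start_year = 2004, end_year = 2005) {
  if (!setequal(c(wet_months, dry_months), 1:12) ||
      length(intersect(wet_months, dry_months)) > 0) {
    stop("wet and dry months must partition the 12 months")
  }
  structure(list(wet_months = wet_months, dry_months = dry_months,
                 start_year = start_year, end_year = end_year),
            class = "season_config")
}

# Dates (of the gauge records) belonging to a season within the averaging
# period.
season_dates <- function(dates, season, which = c("wet", "dry")) {
  which <- match.arg(which)
  dates <- as.Date(dates)
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  if (which == "wet") {
    mo %in% season$wet_months & yr >= season$start_year & yr <= season$end_year
  } else {
    # dry season labeled by ending year: Nov (y-1) .. May (y)
    lab <- ifelse(mo >= 11, yr + 1L, yr)
    mo %in% season$dry_months & lab >= season$start_year & lab <= season$end_year
  }
}

#' Inverse-distance-weighted stage interpolation
#'
#' Interpolates gauge stages for one day at arbitrary points with
#' inverse-distance weighting (power `p`). The estimate is exact at gauge
#' locations. Gauges with no record on the date are skipped.
#'
#' @param gauges data.frame with station_id, x, y, date, stage_m.
#' @param date the day to interpolate (coerced with `as.Date`).
#' @param points two-column matrix or data.frame of x, y.
#' @param p inverse-distance power (default 2).
#' @return numeric vector of stages at the points.
#' @export
interpolate_stage <- function(gauges, date, points, p = 2) {
  date <- as.Date(date)
  day <- gauges[as.Date(gauges$date) == date & is.finite(gauges$stage_m), ]
  if (nrow(day) == 0) stop("no gauge data available on ", format(date))
  points <- as.matrix(points)
  idw_weights(points, cbind(day$x, day$y), p) %*% day$stage_m
}

# Row-stochastic IDW weight matrix from points to stations; rows for points
# coinciding with a station put full weight on that station.
idw_weights <- function(points, stations, p = 2) {
  d2 <- outer(points[, 1], stations[, 1], "-")^2 +
        outer(points[, 2], stations[, 2], "-")^2
  w <- 1 / (sqrt(d2)^p)
  hit <- d2 < 1e-12
  if (any(hit)) {
    w[which(rowSums(hit) > 0), ] <- 0
    w[hit] <- 1
  }
  w / rowSums(w)
}

#' Seasonal water-depth surface
#'
#' For each grid cell, water depth is sampled at a regular subgrid of
#' points: depth(point, day) = interpolated stage - ground elevation, and
#' the cell value is the mean over the points and all in-season days of the
#' averaging period.
#'
#' @param gauges data.frame (station_id, x, y, date, stage_m).
#' @param elevation ground elevation `panther_raster` (meters, same datum
#'   as stages).
#' @param grid a `panther_grid`.
#' @param season a [season_config()].
#' @param n_sub per-cell sample subgrid dimension (default 3, i.e. 9 points).
#' @param p IDW power.
#' @return data.frame with cell_id, wet_depth, dry_depth (m). Cells over
#'   elevation nodata are NA.
#' @export
seasonal_depth <- function(gauges, elevation, grid, season = season_config(),
                           n_sub = 3, p = 2) {
  offs <- (seq_len(n_sub) - 0.5) / n_sub  # e.g. 1/6, 3/6, 5/6
  s <- grid$cell_size
  b <- cell_bounds(grid, grid$cells$cell_id)
  n_cells <- nrow(grid$cells)
  ox <- rep(offs * s, times = n_sub)
  oy <- rep(offs * s, each = n_sub)
  px <- rep(b$xmin, each = n_sub^2) + rep(ox, times = n_cells)
  py <- rep(b$ymin, each = n_sub^2) + rep(oy, times = n_cells)
  elev <- raster_sample(elevation, px, py)

  gauges$date <- as.Date(gauges$date)
  one_season <- function(which) {
    sel <- season_dates(gauges$date, season, which) & is.finite(gauges$stage_m)
    g <- gauges[sel, ]
    if (nrow(g) == 0) stop("no in-season gauge records for ", which, " season")
    # group days by the set of stations reporting, so the IDW weight matrix
    # is computed once per availability pattern
    stations <- unique(g[, c("station_id", "x", "y")])
    day_split <- split(g, g$date)
    pattern <- vapply(day_split, function(d)
      paste(sort(d$station_id), collapse = "|"), character(1))
    mean_stage <- numeric(length(px))
    n_days_total <- length(day_split)
    for (pat in unique(pattern)) {
      days <- day_split[pattern == pat]
      ids <- sort(days[[1]]$station_id)
      st <- stations[match(ids, stations$station_id), ]
      W <- idw_weights(cbind(px, py), cbind(st$x, st$y), p)
      stage_mat <- vapply(days, function(d) d$stage_m[match(ids, d$station_id)],
                          numeric(length(ids)))
      stage_mat <- matrix(stage_mat, nrow = length(ids))
      mean_stage <- mean_stage +
        as.vector(W %*% rowMeans(stage_mat)) * (length(days) / n_days_total)
    }
    depth_pts <- mean_stage - elev
    cell_idx <- rep(seq_len(n_cells), each = n_sub^2)
    as.vector(tapply(depth_pts, cell_idx, mean))
  }
  data.frame(cell_id = grid$cells$cell_id,
             wet_depth = one_season("wet"),
             dry_depth = one_season("dry"))
}
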