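# Per-cell landscape covariates. The model uses 15 explanatory variables:
# the 10 land-cover fractions plus forest edge, dry- and wet-season water
# depth, human population density, and road density.

#' Canonical land-cover categories and covariate names
#'
#' The ten aggregated land-cover categories, keyed by their column
#' abbreviations: FW_Wet (open freshwater wetland), Wet_For (wetland
#' forest), Ag (agriculture), SW_Wet (saltwater wetland), Grass
#' (grassland/dry prairie), Wet_Shrub (wet shrub), Urban, Up_For (upland
#' forest), Water (open water), Up_Shrub (upland shrub).
#'
#' @return named character vector mapping abbreviation to description.
#' @export
panther_categories <- function() {
  c(FW_Wet = "open freshwater wetland", Wet_For = "wetland forest",
    Ag = "agriculture", SW_Wet = "saltwater wetland", Grass = "grassland",
    Wet_Shrub = "wet shrub", Urban = "urban", Up_For = "upland forest",
    Water = "open water", Up_Shrub = "upland shrub")
}

#' Names of the 15 model covariates
#' @return character vector of FeatureTable covariate column names.
#' @export
covariate_names <- function() {
  c(names(panther_categories()),
    "For_Edge", "dry_depth", "wet_depth", "Pop_Dens", "Rd_Dens")
}

#' Forest-edge classification rules
#'
#' Splits the ten cover categories into forest, edge-forming, and
#' non-edge-forming sets. Forest edge is the boundary between a forest
#' polygon and an edge-forming polygon; urban, agriculture, and saltwater
#' wetland do not form edge. The upland-forest/wetland-forest boundary also
#' counts as forest edge when `forest_forest = TRUE`.
#'
#' @param forest categories counted as forest.
#' @param edge_forming categories forming natural edge against forest.
#' @param non_edge categories never forming edge.
#' @param forest_forest count upland/wetland forest contact as edge?
#' @return object of class `edge_rules`.
#' @export
edge_rules <- function(forest = c("Up_For", "Wet_For"),
                       edge_forming = c("Grass", "Water", "Up_Shrub",
                                        "Wet_Shrub", "FW_Wet"),
                       non_edge = c("Urban", "Ag", "SW_Wet"),
                       forest_forest = TRUE) {
  all_cats <- names(panther_categories())
  sets <- list(forest = forest, edge_forming = edge_forming, non_edge = non_edge)
  if (anyDuplicated(unlist(sets))) stop("edge rule sets must be disjoint")
  if (!setequal(unlist(sets), all_cats)) {
    stop("edge rule sets must cover all 10 categories")
  }
  structure(c(sets, list(forest_forest = forest_forest)), class = "edge_rules")
}

# Candidate grid cells overlapping a bounding box (clamped to the lattice).
bbox_cells <- function(grid, xmin, ymin, xmax, ymax) {
  s <- grid$cell_size
  c0 <- max(1L, floor((xmin - grid$x0) / s) + 1L)
  c1 <- min(grid$n_cols, ceiling((xmax - grid$x0) / s))
  r0 <- max(1L, floor((ymin - grid$y0) / s) + 1L)
  r1 <- min(grid$n_rows, ceiling((ymax - grid$y0) / s))
  if (c1 < c0 || r1 < r0) return(integer(0))
  cols <- rep(c0:c1, times = r1 - r0 + 1L)
  rows <- rep(r0:r1, each = c1 - c0 + 1L)
  (rows - 1L) * grid$n_cols + cols
}

#' Per-cell land-cover fractions
#'
#' Intersects cover polygons with the analysis grid: the fraction of a cell
#' in a category is the intersected area of that category's polygons divided
#' by the cell area. Fully tessellated cells have fractions summing to 1.
#'
#' @param grid a `panther_grid`.
#' @param layer a `poly_layer` whose props carry a `category` column (or a
#'   `code` column plus `category_map`).
#' @param category_map optional named map raw code -> category.
#' @return data.frame with cell_id and one fraction column per category.
#' @export
cover_fractions <- function(grid, layer, category_map = NULL) {
  if (!is.null(category_map)) layer <- apply_category_map(layer, category_map)
  cats <- names(panther_categories())
  if (is.null(layer$props$category)) stop("cover layer has no 'category' property")
  unknown <- setdiff(unique(layer$props$category), cats)
  if (length(unknown)) stop("unknown cover categories: ", paste(unknown, collapse = ", "))

  area <- matrix(0, nrow(grid$cells), length(cats),
                 dimnames = list(NULL, cats))
  id_index <- integer(grid$n_cols * grid$n_rows)
  id_index[grid$cells$cell_id] <- seq_len(nrow(grid$cells))

  ras <- attr(layer, "raster")
  if (!is.null(ras) && grid$cell_size %% ras$cellsize == 0) {
    # raster-backed tessellation: each subcell lies wholly in one grid cell
    sub <- ras$cellsize
    n <- ras$ncol
    cols <- rep(seq_len(n), each = ras$nrow)
    rows <- rep(seq_len(ras$nrow), times = n)
    xc <- ras$x0 + (cols - 0.5) * sub
    yc <- ras$y0 + (rows - 0.5) * sub
    cid <- cell_at(grid, xc, yc)
    cat_idx <- match(as.vector(ras$values), cats)
    ok <- !is.na(cid) & !is.na(cat_idx)
    tab <- table(factor(id_index[cid[ok]], levels = seq_len(nrow(grid$cells))),
                 factor(cats[cat_idx[ok]], levels = cats))
    area <- area + matrix(tab, nrow = nrow(tab)) * sub^2
  } else {
    for (i in seq_along(layer$features)) {
      f <- layer$features[[i]]
      cat_i <- layer$props$category[i]
      outer <- f$rings[[1]]
      if (nrow(outer) < 3 || !all(is.finite(outer))) {
        stop("invalid geometry in cover polygon ", i)
      }
      bb <- apply(outer, 2, range)
      for (cid in bbox_cells(grid, bb[1, 1], bb[1, 2], bb[2, 1], bb[2, 2])) {
        ci <- id_index[cid]
        if (ci == 0) next
        b <- cell_bounds(grid, cid)
        a <- feature_rect_area(f, b$xmin, b$ymin, b$xmax, b$ymax)
        if (a > 0) area[ci, cat_i] <- area[ci, cat_i] + a
      }
    }
  }
  frac <- area / grid$cell_size^2
  if (any(rowSums(frac) > 1 + 1e-6)) {
    stop("ambiguous boundary: overlapping cover polygons of different categories")
  }
  out <- data.frame(cell_id = grid$cells$cell_id)
  out[cats] <- as.data.frame(frac)
  out
}

#' Per-cell forest edge length
#'
#' Total length (km) of shared boundaries between forest polygons and
#' edge-forming polygons, plus upland/wetland forest contacts, clipped to
#' each grid cell. Segments lying exactly on a grid line are assigned to the
#' lower-left cell. Boundaries between polygons of the same category never
#' count.
#'
#' @param grid a `panther_grid`.
#' @param layer a categorized `poly_layer` forming a planar tessellation.
#' @param rules an [edge_rules()] object.
#' @param validate check for overlapping polygons of different categories?
#' @return data.frame with cell_id and For_Edge (km); attribute
#'   `total_km` gives the un-gridded layer total.
#' @export
forest_edge <- function(grid, layer, rules = edge_rules(), validate = TRUE) {
  cats <- layer$props$category
  if (is.null(cats)) stop("cover layer has no 'category' property")
  qualifies <- function(a, b) {
    (a %in% rules$forest && b %in% rules$edge_forming) ||
    (b %in% rules$forest && a %in% rules$edge_forming) ||
    (rules$forest_forest && a %in% rules$forest && b %in% rules$forest && a != b)
  }

  ras <- attr(layer, "raster")
  if (!is.null(ras) && grid$cell_size %% ras$cellsize == 0) {
    # subcell faces never cross a grid line, so each face belongs wholly to
    # the cell of its midpoint (lower-left rule on grid-line faces)
    segs <- raster_edge_segments(ras, qualifies)
    edge_km <- numeric(nrow(grid$cells))
    id_index <- integer(grid$n_cols * grid$n_rows)
    id_index[grid$cells$cell_id] <- seq_len(nrow(grid$cells))
    total <- 0
    if (nrow(segs)) {
      mx <- (segs$x1 + segs$x2) / 2
      my <- (segs$y1 + segs$y2) / 2
      cid <- cell_at(grid, mx, my)
      ok <- !is.na(cid)
      total <- sum(segs$length)
      acc <- rowsum(segs$length[ok], id_index[cid[ok]])
      edge_km[as.integer(rownames(acc))] <- acc[, 1]
    }
    out <- data.frame(cell_id = grid$cells$cell_id, For_Edge = edge_km / 1000)
    attr(out, "total_km") <- total / 1000
    return(out)
  }
  if (!is.null(ras)) {
    segs <- raster_edge_segments(ras, qualifies)
  } else {
    if (validate) {
      frac <- try(cover_fractions(grid, layer), silent = TRUE)
      if (inherits(frac, "try-error")) {
        stop("ambiguous boundary: overlapping cover polygons of different categories")
      }
    }
    segs <- shared_boundaries(layer$features, cats, qualifies)
  }

  edge_km <- numeric(nrow(grid$cells))
  id_index <- integer(grid$n_cols * grid$n_rows)
  id_index[grid$cells$cell_id] <- seq_len(nrow(grid$cells))
  total <- 0
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      ts <- segment_grid_breaks(segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i],
                                grid$x0, grid$y0, grid$cell_size)
      mx <- segs$x1[i] + (head(ts, -1) + ts[-1]) / 2 * (segs$x2[i] - segs$x1[i])
      my <- segs$y1[i] + (head(ts, -1) + ts[-1]) / 2 * (segs$y2[i] - segs$y1[i])
      lens <- diff(ts) * segs$length[i]
      cid <- cell_at(grid, mx, my)
      ok <- !is.na(cid)
      total <- total + sum(lens)
      if (any(ok)) {
        ci <- id_index[cid[ok]]
        for (k in seq_along(ci)) edge_km[ci[k]] <- edge_km[ci[k]] + lens[k]
      }
    }
  }
  out <- data.frame(cell_id = grid$cells$cell_id, For_Edge = edge_km / 1000)
  attr(out, "total_km") <- total / 1000
  out
}

# Vectorized qualifying-boundary extraction for a raster-backed category
# tessellation: boundaries are the faces between adjacent subcells whose
# categories qualify.
raster_edge_segments <- function(ras, qualifies) {
  v <- ras$values
  s <- ras$cellsize
  cats <- sort(unique(as.vector(v)))
  qual <- outer(cats, cats, Vectorize(function(a, b) qualifies(a, b)))
  dimnames(qual) <- list(cats, cats)
  segs <- list()
  # vertical faces between [r, c] and [r, c+1]
  if (ncol(v) > 1) {
    a <- v[, -ncol(v), drop = FALSE]; b <- v[, -1, drop = FALSE]
    hit <- which(qual[cbind(match(a, cats), match(b, cats))] &
                   a != b)
    if (length(hit)) {
      r <- (hit - 1) %% nrow(v) + 1
      c <- (hit - 1) %/% nrow(v) + 1
      x <- ras$x0 + c * s
      y0v <- ras$y0 + (r - 1) * s
      segs[[length(segs) + 1]] <- data.frame(x1 = x, y1 = y0v, x2 = x, y2 = y0v + s,
                                             length = s)
    }
  }
  # horizontal faces between [r, c] and [r+1, c]
  if (nrow(v) > 1) {
    a <- v[-nrow(v), , drop = FALSE]; b <- v[-1, , drop = FALSE]
    hit <- which(qual[cbind(match(a, cats), match(b, cats))] & a != b)
    if (length(hit)) {
      r <- (hit - 1) %% (nrow(v) - 1) + 1
      c <- (hit - 1) %/% (nrow(v) - 1) + 1
      y <- ras$y0 + r * s
      x0v <- ras$x0 + (c - 1) * s
      segs[[length(segs) + 1]] <- data.frame(x1 = x0v, y1 = y, x2 = x0v + s, y2 = y,
                                             length = s)
    }
  }
  if (!length(segs)) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0)))
  }
  do.call(rbind, segs)
}

#' Per-cell area-weighted human population density
#'
#' `density(cell) = sum_b density(b) * area(cell intersect b) / cell_area`;
#' area not covered by any block contributes zero. Block density is taken
#' from a `density` property, or computed as `population / block area`.
#'
#' @param grid a `panther_grid`.
#' @param blocks a `poly_layer` of census blocks with `density`
#'   (people/km2) or `population` properties.
#' @return data.frame with cell_id and Pop_Dens (people/km2).
#' @export
human_density <- function(grid, blocks) {
  dens <- blocks$props$density
  if (is.null(dens)) {
    pop <- blocks$props$population
    if (is.null(pop)) stop("blocks need a 'density' or 'population' property")
    if (any(pop < 0)) stop("negative population in census blocks")
    a_km2 <- vapply(blocks$features, feature_area, numeric(1)) / 1e6
    dens <- ifelse(a_km2 > 0, pop / a_km2, 0)
  }
  if (any(dens < 0)) stop("negative population density in census blocks")
  out <- numeric(nrow(grid$cells))
  id_index <- integer(grid$n_cols * grid$n_rows)
  id_index[grid$cells$cell_id] <- seq_len(nrow(grid$cells))
  for (i in seq_along(blocks$features)) {
    f <- blocks$features[[i]]
    bb <- apply(f$rings[[1]], 2, range)
    for (cid in bbox_cells(grid, bb[1, 1], bb[1, 2], bb[2, 1], bb[2, 2])) {
      ci <- id_index[cid]
      if (ci == 0) next
      b <- cell_bounds(grid, cid)
      a <- feature_rect_area(f, b$xmin, b$ymin, b$xmax, b$ymax)
      if (a > 0) out[ci] <- out[ci] + dens[i] * a / grid$cell_size^2
    }
  }
  data.frame(cell_id = grid$cells$cell_id, Pop_Dens = out)
}

#' Per-cell road density
#'
#' Sums the length (km) of road segments clipped to each cell, skipping
#' excluded road classes (by default four-wheel-drive tracks, bike trails,
#' and pedestrian trails). Segments on a shared cell boundary count once,
#' in the lower-left cell.
#'
#' @param grid a `panther_grid`.
#' @param roads a `line_layer` with a `class` property.
#' @param excluded_classes road classes to ignore.
#' @return data.frame with cell_id and Rd_Dens (km of road per km2 cell).
#' @export
road_density <- function(grid, roads,
                         excluded_classes = c("four-wheel drive", "bike trail",
                                              "pedestrian trail")) {
  out <- numeric(nrow(grid$cells))
  id_index <- integer(grid$n_cols * grid$n_rows)
  id_index[grid$cells$cell_id] <- seq_len(nrow(grid$cells))
  cls <- roads$props$class %||% rep("road", length(roads$features))
  for (i in seq_along(roads$features)) {
    if (cls[i] %in% excluded_classes) next
    m <- as.matrix(roads$features[[i]]$coords)
    for (k in seq_len(nrow(m) - 1)) {
      x1 <- m[k, 1]; y1 <- m[k, 2]; x2 <- m[k + 1, 1]; y2 <- m[k + 1, 2]
      len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      if (len == 0) next
      ts <- segment_grid_breaks(x1, y1, x2, y2, grid$x0, grid$y0, grid$cell_size)
      mx <- x1 + (head(ts, -1) + ts[-1]) / 2 * (x2 - x1)
      my <- y1 + (head(ts, -1) + ts[-1]) / 2 * (y2 - y1)
      cid <- cell_at(grid, mx, my)
      ok <- !is.na(cid)
      if (any(ok)) {
        ci <- id_index[cid[ok]]
        lens <- diff(ts)[ok] * len
        for (j in seq_along(ci)) out[ci[j]] <- out[ci[j]] + lens[j]
      }
    }
  }
  data.frame(cell_id = grid$cells$cell_id, Rd_Dens = out / 1000)
}

#' Pairwise covariate correlation diagnostics
#'
#' Squared Pearson correlations for requested covariate pairs, e.g. forest
#' edge against total forest cover, or wet- against dry-season depth.
#'
#' @param table FeatureTable data.frame.
#' @param pairs list of length-2 character vectors of column names; a name
#'   may also be a formula-like sum "a+b" which is evaluated by adding
#'   columns (e.g. `"Up_For+Wet_For"` for total forest).
#' @return data.frame with var1, var2, r_squared.
#' @export
feature_diagnostics <- function(table,
                                pairs = list(c("For_Edge", "Up_For+Wet_For"),
                                             c("wet_depth", "dry_depth"))) {
  if (nrow(table) < 3) stop("need at least 3 cells for diagnostics")
  get_col <- function(nm) {
    parts <- strsplit(nm, "+", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(table))
    if (length(miss)) stop("unknown covariate: ", paste(miss, collapse = ", "))
    rowSums(table[, parts, drop = FALSE])
  }
  res <- lapply(pairs, function(p) {
    x <- get_col(p[1]); y <- get_col(p[2])
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero-variance covariate in pair ", p[1], " ~ ", p[2])
      r2 <- NA_real_
    } else {
      r2 <- cor(x, y)^2
    }
    data.frame(var1 = p[1], var2 = p[2], r_squared = r2)
  })
  do.call(rbind, res)
}

#' Assemble the per-cell feature table
#'
#' Joins cover fractions, forest edge, seasonal water depths, human density,
#' and road density into the 15-covariate FeatureTable.
#'
#' @param grid a `panther_grid`.
#' @param cover categorized cover `poly_layer`.
#' @param gauges gauge data.frame (station_id, x, y, date, stage_m).
#' @param elevation ground-elevation `panther_raster`.
#' @param blocks census-block `poly_layer`.
#' @param roads road `line_layer`.
#' @param rules an [edge_rules()] object.
#' @param season a [season_config()].
#' @param excluded_road_classes passed to [road_density()].
#' @return FeatureTable data.frame (cell_id, col, row, xc, yc, 15 covariates).
#' @export
build_features <- function(grid, cover, gauges, elevation, blocks, roads,
                           rules = edge_rules(), season = season_config(),
                           excluded_road_classes = c("four-wheel drive",
                                                     "bike trail",
                                                     "pedestrian trail")) {
  tab <- grid$cells
  tab <- merge(tab, cover_fractions(grid, cover), by = "cell_id", sort = TRUE)
  tab <- merge(tab, forest_edge(grid, cover, rules), by = "cell_id")
  depths <- seasonal_depth(gauges, elevation, grid, season)
  tab <- merge(tab, depths, by = "cell_id")
  tab <- merge(tab, human_density(grid, blocks), by = "cell_id")
  tab <- merge(tab, road_density(grid, roads, excluded_road_classes),
               by = "cell_id")
  tab[order(tab$cell_id), ]
}
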