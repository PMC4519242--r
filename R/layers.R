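# Lightweight vector-layer and raster containers with plain-text (GeoJSON /
# ESRI ASCII grid) serialization.

#' Construct a polygon layer
#'
#' @param features list of polygon features; each feature is
#'   `list(rings = list(outer, hole1, ...), props = list(...))` where rings
#'   are two-column matrices.
#' @param props optional data.frame of per-feature properties; defaults to
#'   binding the features' own `props`.
#' @return object of class `poly_layer`.
#' @export
poly_layer <- function(features, props = NULL) {
  if (is.null(props)) {
    plist <- lapply(features, function(f) as.data.frame(f$props %||% list(),
                                                        stringsAsFactors = FALSE))
    nonempty <- plist[vapply(plist, ncol, 1L) > 0]
    props <- if (length(nonempty) == length(features)) do.call(rbind, plist)
             else data.frame(row.names = seq_along(features))
  }
  structure(list(features = features, props = props), class = "poly_layer")
}

#' @export
print.poly_layer <- function(x, ...) {
  cat("Polygon layer:", length(x$features), "features;",
      paste(names(x$props), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a polyline layer
#'
#' @param features list of `list(coords = matrix, props = list(...))`.
#' @param props optional data.frame of per-feature properties.
#' @return object of class `line_layer`.
#' @export
line_layer <- function(features, props = NULL) {
  if (is.null(props)) {
    plist <- lapply(features, function(f) as.data.frame(f$props %||% list(),
                                                        stringsAsFactors = FALSE))
    nonempty <- plist[vapply(plist, ncol, 1L) > 0]
    props <- if (length(nonempty) == length(features)) do.call(rbind, plist)
             else data.frame(row.names = seq_along(features))
  }
  structure(list(features = features, props = props), class = "line_layer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Axis-aligned rectangle polygon feature
#'
#' @param xmin,ymin,xmax,ymax bounds in meters.
#' @param ... named properties attached to the feature.
#' @return a polygon feature usable in [poly_layer()].
#' @export
rect_feature <- function(xmin, ymin, xmax, ymax, ...) {
  list(rings = list(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))),
       props = list(...))
}

# Coerce ring matrix / feature / single-feature layer to a feature.
as_feature <- function(x) {
  if (inherits(x, "poly_layer")) {
    if (length(x$features) != 1) stop("expected a single-polygon layer")
    return(x$features[[1]])
  }
  if (is.list(x) && !is.null(x$rings)) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(list(rings = list(as.matrix(x)), props = list()))
  stop("cannot interpret object as a polygon feature")
}

# Attach a `category` column by mapping each feature's raw `code` through a
# named map; unmapped codes are rejected.
apply_category_map <- function(layer, category_map) {
  codes <- as.character(layer$props$code)
  if (is.null(codes)) stop("cover layer has no 'code' property")
  unmapped <- setdiff(unique(codes), names(category_map))
  if (length(unmapped)) {
    stop("unmapped cover codes: ", paste(unmapped, collapse = ", "))
  }
  layer$props$category <- unname(category_map[codes])
  layer
}

## ---- GeoJSON ----

ring_to_coords <- function(ring) {
  ring <- as.matrix(ring)
  ring <- rbind(ring, ring[1, ])  # GeoJSON rings are explicitly closed
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a vector layer to GeoJSON
#'
#' @param layer a `poly_layer` or `line_layer`.
#' @param path output file path.
#' @export
write_geojson <- function(layer, path) {
  is_poly <- inherits(layer, "poly_layer")
  feats <- lapply(seq_along(layer$features), function(i) {
    f <- layer$features[[i]]
    geom <- if (is_poly) {
      list(type = "Polygon", coordinates = lapply(f$rings, ring_to_coords))
    } else {
      m <- as.matrix(f$coords)
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2])))
    }
    props <- if (nrow(layer$props)) as.list(layer$props[i, , drop = FALSE]) else list()
    list(type = "Feature", geometry = geom, properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_geojson()]
#'
#' Supports Polygon and LineString geometries with scalar properties.
#'
#' @param path GeoJSON file path.
#' @return a `poly_layer` or `line_layer`.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$type, "FeatureCollection"))
  types <- vapply(obj$features, function(f) f$geometry$type, character(1))
  to_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  }
  feats <- lapply(obj$features, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    if (f$geometry$type == "Polygon") {
      rings <- lapply(f$geometry$coordinates, function(r) {
        m <- to_mat(r)
        m[-nrow(m), , drop = FALSE]  # drop closing vertex
      })
      list(rings = rings, props = props)
    } else {
      list(coords = to_mat(f$geometry$coordinates), props = props)
    }
  })
  if (all(types == "Polygon")) poly_layer(feats) else line_layer(feats)
}

## ---- Raster (ESRI ASCII grid) ----

#' Construct a raster
#'
#' Values are stored as a matrix indexed `[row, col]` with row 1 the
#' southernmost row, so y increases with the row index.
#'
#' @param values numeric matrix.
#' @param x0,y0 lower-left corner in meters.
#' @param cellsize cell size in meters.
#' @return object of class `panther_raster`.
#' @export
make_raster <- function(values, x0 = 0, y0 = 0, cellsize = 1) {
  structure(list(values = values, x0 = x0, y0 = y0, cellsize = cellsize,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "panther_raster")
}

#' @export
print.panther_raster <- function(x, ...) {
  cat("Raster:", x$nrow, "x", x$ncol, "cells of", x$cellsize, "m\n")
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#' @param raster a `panther_raster`.
#' @param path output path (.asc).
#' @export
write_asc <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$ncol),
               paste("nrows", raster$nrow),
               paste("xllcorner", raster$x0),
               paste("yllcorner", raster$y0),
               paste("cellsize", raster$cellsize),
               "NODATA_value -9999"), con)
  v <- raster$values
  v[is.na(v)] <- -9999
  for (r in rev(seq_len(raster$nrow))) {  # ASCII grids list the top row first
    writeLines(paste(format(v[r, ], trim = TRUE, scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path input path (.asc).
#' @return a `panther_raster`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  nod <- hdr[["nodata_value"]]
  if (!is.null(nod)) m[m == nod] <- NA
  make_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

# Bilinear sample of raster values at points; values are treated as cell
# centers. Points outside the raster are clamped to the border cells.
raster_sample <- function(raster, x, y) {
  gx <- (x - raster$x0) / raster$cellsize - 0.5
  gy <- (y - raster$y0) / raster$cellsize - 0.5
  gx <- pmin(pmax(gx, 0), raster$ncol - 1)
  gy <- pmin(pmax(gy, 0), raster$nrow - 1)
  c0 <- pmin(floor(gx), raster$ncol - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(gy), raster$nrow - 2); r0 <- pmax(r0, 0)
  fx <- gx - c0; fy <- gy - r0
  v <- raster$values
  idx <- function(r, c) v[cbind(r + 1, c + 1)]
  (1 - fx) * (1 - fy) * idx(r0, c0) + fx * (1 - fy) * idx(r0, c0 + 1) +
    (1 - fx) * fy * idx(r0 + 1, c0) + fx * fy * idx(r0 + 1, c0 + 1)
}
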