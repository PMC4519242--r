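# Planar geometry primitives used by the gridding and feature-engineering
# stages. All coordinates are planar meters; polygons are matrices with two
# columns (x, y), implicitly closed (last vertex joins the first).

#' Signed and absolute polygon area
#'
#' Shoelace area of a single ring. `signed = TRUE` returns the signed area
#' (positive for counter-clockwise vertex order).
#'
#' @param ring numeric matrix with columns x, y; implicitly closed.
#' @param signed return the signed area instead of its absolute value?
#' @return area in squared input units.
#' @export
polygon_area <- function(ring, signed = FALSE) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  a <- sum(x * y[j] - x[j] * y) / 2
  if (signed) a else abs(a)
}

# Area of a polygon feature given as list(rings = list(outer, hole1, ...)).
feature_area <- function(feature) {
  rings <- feature$rings
  a <- polygon_area(rings[[1]])
  if (length(rings) > 1) {
    a <- a - sum(vapply(rings[-1], polygon_area, numeric(1)))
  }
  a
}

#' Point-in-polygon test
#'
#' Vectorized even-odd (ray casting) test for a single ring. Points lying
#' exactly on the boundary are classified inside when
#' `include_boundary = TRUE`.
#'
#' @param px,py point coordinates (equal-length vectors).
#' @param ring polygon ring, matrix with columns x, y.
#' @param include_boundary count boundary points as inside?
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring, include_boundary = TRUE) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  x1 <- ring[, 1]; y1 <- ring[, 2]
  j <- c(2:n, 1L)
  x2 <- ring[j, 1]; y2 <- ring[j, 2]
  for (k in seq_len(n)) {
    ax <- x1[k]; ay <- y1[k]; bx <- x2[k]; by <- y2[k]
    # edge crossing test for a ray in +x direction
    crosses <- ((ay > py) != (by > py))
    if (any(crosses)) {
      xint <- ax + (py[crosses] - ay) * (bx - ax) / (by - ay)
      flip <- xint > px[crosses]
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    # collinear and within the segment's bounding box
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    tol <- 1e-9 * max(1, abs(ax), abs(ay), abs(bx), abs(by))
    on_seg <- abs(cross) <= tol &
      px >= pmin(ax, bx) - tol & px <= pmax(ax, bx) + tol &
      py >= pmin(ay, by) - tol & py <= pmax(ay, by) + tol
    on_edge <- on_edge | on_seg
  }
  if (include_boundary) inside | on_edge else inside & !on_edge
}

# Point-in-feature honouring holes.
point_in_feature <- function(px, py, feature, include_boundary = TRUE) {
  inside <- point_in_polygon(px, py, feature$rings[[1]], include_boundary)
  if (length(feature$rings) > 1) {
    for (h in feature$rings[-1]) {
      in_hole <- point_in_polygon(px, py, h, include_boundary = FALSE)
      inside <- inside & !in_hole
    }
  }
  inside
}

#' Clip a polygon ring to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the rectangle
#' `[xmin, xmax] x [ymin, ymax]`. The result may contain degenerate
#' (zero-area) connector edges for non-convex inputs; these do not affect
#' the shoelace area, which is exact for simple input rings.
#'
#' @param ring matrix with columns x, y.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return clipped ring matrix (possibly with zero rows).
#' @export
clip_polygon_rect <- function(ring, xmin, ymin, xmax, ymax) {
  poly <- as.matrix(ring)
  clip_halfplane <- function(poly, inside_fun, intersect_fun) {
    n <- nrow(poly)
    if (n == 0) return(poly)
    out_x <- numeric(0); out_y <- numeric(0)
    px <- poly[n, 1]; py <- poly[n, 2]
    p_in <- inside_fun(px, py)
    for (i in seq_len(n)) {
      cx <- poly[i, 1]; cy <- poly[i, 2]
      c_in <- inside_fun(cx, cy)
      if (c_in) {
        if (!p_in) {
          ip <- intersect_fun(px, py, cx, cy)
          out_x <- c(out_x, ip[1]); out_y <- c(out_y, ip[2])
        }
        out_x <- c(out_x, cx); out_y <- c(out_y, cy)
      } else if (p_in) {
        ip <- intersect_fun(px, py, cx, cy)
        out_x <- c(out_x, ip[1]); out_y <- c(out_y, ip[2])
      }
      px <- cx; py <- cy; p_in <- c_in
    }
    cbind(out_x, out_y, deparse.level = 0)
  }
  poly <- clip_halfplane(poly, function(x, y) x >= xmin, function(x1, y1, x2, y2) {
    t <- (xmin - x1) / (x2 - x1); c(xmin, y1 + t * (y2 - y1))
  })
  poly <- clip_halfplane(poly, function(x, y) x <= xmax, function(x1, y1, x2, y2) {
    t <- (xmax - x1) / (x2 - x1); c(xmax, y1 + t * (y2 - y1))
  })
  poly <- clip_halfplane(poly, function(x, y) y >= ymin, function(x1, y1, x2, y2) {
    t <- (ymin - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymin)
  })
  poly <- clip_halfplane(poly, function(x, y) y <= ymax, function(x1, y1, x2, y2) {
    t <- (ymax - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymax)
  })
  poly
}

# Area of feature (outer minus holes) intersected with a rectangle.
feature_rect_area <- function(feature, xmin, ymin, xmax, ymax) {
  a <- polygon_area(clip_polygon_rect(feature$rings[[1]], xmin, ymin, xmax, ymax))
  if (length(feature$rings) > 1) {
    for (h in feature$rings[-1]) {
      a <- a - polygon_area(clip_polygon_rect(h, xmin, ymin, xmax, ymax))
    }
  }
  a
}

#' Clip a segment to an axis-aligned rectangle
#'
#' Liang-Barsky clipping. Returns the clipped segment endpoints or `NULL`
#' when the segment misses the rectangle.
#'
#' @param x1,y1,x2,y2 segment endpoints.
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return 2 x 2 matrix of clipped endpoints, or `NULL`.
#' @export
clip_segment_rect <- function(x1, y1, x2, y2, xmin, ymin, xmax, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  rbind(c(x1 + t0 * dx, y1 + t0 * dy),
        c(x1 + t1 * dx, y1 + t1 * dy))
}

# Split the segment (x1,y1)-(x2,y2) at every crossing of the lattice lines
# x = x0 + k*s and y = y0 + k*s; returns the ordered parameter breakpoints
# in [0, 1] including both ends.
segment_grid_breaks <- function(x1, y1, x2, y2, x0, y0, s) {
  ts <- c(0, 1)
  dx <- x2 - x1; dy <- y2 - y1
  if (dx != 0) {
    ks <- seq(ceiling((min(x1, x2) - x0) / s), floor((max(x1, x2) - x0) / s))
    if (length(ks)) ts <- c(ts, (x0 + ks * s - x1) / dx)
  }
  if (dy != 0) {
    ks <- seq(ceiling((min(y1, y2) - y0) / s), floor((max(y1, y2) - y0) / s))
    if (length(ks)) ts <- c(ts, (y0 + ks * s - y1) / dy)
  }
  ts <- sort(unique(pmin(1, pmax(0, ts))))
  ts
}

# Extract all boundary segments from a list of polygon features, with the
# owning feature index. Rings contribute all their edges (outer and holes).
feature_edges <- function(features) {
  xs1 <- ys1 <- xs2 <- ys2 <- numeric(0)
  fid <- integer(0)
  for (i in seq_along(features)) {
    for (ring in features[[i]]$rings) {
      ring <- as.matrix(ring)
      n <- nrow(ring)
      j <- c(2:n, 1L)
      xs1 <- c(xs1, ring[, 1]); ys1 <- c(ys1, ring[, 2])
      xs2 <- c(xs2, ring[j, 1]); ys2 <- c(ys2, ring[j, 2])
      fid <- c(fid, rep(i, n))
    }
  }
  keep <- !(xs1 == xs2 & ys1 == ys2)
  data.frame(x1 = xs1[keep], y1 = ys1[keep], x2 = xs2[keep], y2 = ys2[keep],
             feature = fid[keep])
}

# Find collinear overlap pieces between boundary segments of features with
# different qualifying categories. `qualifies(catA, catB)` decides whether a
# shared boundary between the two categories counts. Returns a data.frame of
# segment pieces (x1, y1, x2, y2, length).
shared_boundaries <- function(features, categories, qualifies, tol = 1e-6) {
  ed <- feature_edges(features)
  if (nrow(ed) == 0) return(data.frame(x1 = numeric(0), y1 = numeric(0),
                                       x2 = numeric(0), y2 = numeric(0),
                                       length = numeric(0)))
  dx <- ed$x2 - ed$x1; dy <- ed$y2 - ed$y1
  len <- sqrt(dx^2 + dy^2)
  ux <- dx / len; uy <- dy / len
  # canonical direction: first nonzero component positive
  flip <- ux < -tol | (abs(ux) <= tol & uy < 0)
  ux[flip] <- -ux[flip]; uy[flip] <- -uy[flip]
  # signed offset of the supporting line from the origin
  off <- ed$x1 * uy - ed$y1 * ux
  key <- paste(round(ux, 9), round(uy, 9), round(off, 6))
  t1 <- ed$x1 * ux + ed$y1 * uy
  t2 <- ed$x2 * ux + ed$y2 * uy
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  out <- vector("list", 0)
  for (idx in split(seq_len(nrow(ed)), key)) {
    if (length(idx) < 2) next
    cats <- categories[ed$feature[idx]]
    ii <- order(lo[idx])
    idx <- idx[ii]
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        ia <- idx[a]; ib <- idx[b]
        if (lo[ib] >= hi[ia] - tol) break
        if (ed$feature[ia] == ed$feature[ib]) next
        ca <- categories[ed$feature[ia]]; cb <- categories[ed$feature[ib]]
        if (!qualifies(ca, cb)) next
        s0 <- max(lo[ia], lo[ib]); s1 <- min(hi[ia], hi[ib])
        if (s1 - s0 <= tol) next
        uxx <- ux[ia]; uyy <- uy[ia]; o <- off[ia]
        out[[length(out) + 1]] <- c(uxx * s0 + uyy * o, uyy * s0 - uxx * o,
                                    uxx * s1 + uyy * o, uyy * s1 - uxx * o,
                                    s1 - s0)
      }
    }
  }
  if (!length(out)) return(data.frame(x1 = numeric(0), y1 = numeric(0),
                                      x2 = numeric(0), y2 = numeric(0),
                                      length = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4], length = m[, 5])
}

# Convex hull of points as a counter-clockwise ring matrix.
convex_hull_ring <- function(x, y) {
  idx <- grDevices::chull(x, y)
  ring <- cbind(x[idx], y[idx])
  if (polygon_area(ring, signed = TRUE) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}
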