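# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The default synthetic landscape (the study conditions) and its model.
default_land <- function() cached("land", synth_landscape(synthetic_config()))
default_model <- function() cached(
  "model", habitat_model(data = default_land()$table))

# A small landscape for cheap end-to-end checks.
small_config <- function(seed = 1) {
  synthetic_config(extent_km = 20, n_animals = 5, fixes_per_animal = 120,
                   movement_radius_km = 8, n_gauges = 6, seed = seed)
}
small_land <- function() cached("small_land", synth_landscape(small_config()))

# Random axis-aligned tessellation of the square [0, size]^2 by recursive
# binary splitting; returns a poly_layer with `n` rectangles labeled with
# random categories.
bsp_tessellation <- function(n, size = 4000, categories = names(panther_categories()),
                             seed = 1) {
  set.seed(seed)
  rects <- list(c(0, 0, size, size))
  while (length(rects) < n) {
    i <- sample.int(length(rects), 1)
    r <- rects[[i]]
    w <- r[3] - r[1]; h <- r[4] - r[2]
    if (w < 200 && h < 200) next
    if (w >= h) {
      cut <- runif(1, r[1] + w * 0.25, r[1] + w * 0.75)
      a <- c(r[1], r[2], cut, r[4]); b <- c(cut, r[2], r[3], r[4])
    } else {
      cut <- runif(1, r[2] + h * 0.25, r[2] + h * 0.75)
      a <- c(r[1], r[2], r[3], cut); b <- c(r[1], cut, r[3], r[4])
    }
    rects[[i]] <- a
    rects[[length(rects) + 1]] <- b
  }
  cats <- sample(categories, length(rects), replace = TRUE)
  feats <- lapply(seq_along(rects), function(i) {
    r <- rects[[i]]
    rect_feature(r[1], r[2], r[3], r[4], code = cats[i])
  })
  poly_layer(feats, data.frame(code = cats, category = cats,
                               stringsAsFactors = FALSE))
}

# Split every rectangle of a BSP tessellation into two triangles (exercises
# non-axis-aligned clipping); keeps categories.
triangulate_layer <- function(layer) {
  feats <- list(); cats <- character(0)
  for (i in seq_along(layer$features)) {
    r <- layer$features[[i]]$rings[[1]]
    xmin <- min(r[, 1]); xmax <- max(r[, 1])
    ymin <- min(r[, 2]); ymax <- max(r[, 2])
    cc <- layer$props$category[i]
    feats[[length(feats) + 1]] <- list(
      rings = list(cbind(c(xmin, xmax, xmax), c(ymin, ymin, ymax))),
      props = list(code = cc))
    feats[[length(feats) + 1]] <- list(
      rings = list(cbind(c(xmin, xmax, xmin), c(ymin, ymax, ymax))),
      props = list(code = cc))
    cats <- c(cats, cc, cc)
  }
  poly_layer(feats, data.frame(code = cats, category = cats,
                               stringsAsFactors = FALSE))
}

# Monte-Carlo per-cell category-fraction oracle: uniform points in each
# cell, classified by point-in-feature.
mc_cover_oracle <- function(grid, layer, n_points = 1e5, seed = 42) {
  set.seed(seed)
  cats <- names(panther_categories())
  out <- matrix(0, nrow(grid$cells), length(cats), dimnames = list(NULL, cats))
  for (ci in seq_len(nrow(grid$cells))) {
    b <- pantherscape:::cell_bounds(grid, grid$cells$cell_id[ci])
    px <- runif(n_points, b$xmin, b$xmax)
    py <- runif(n_points, b$ymin, b$ymax)
    hit <- rep(FALSE, n_points)
    for (i in seq_along(layer$features)) {
      inside <- pantherscape:::point_in_feature(px, py, layer$features[[i]],
                                                include_boundary = FALSE) & !hit
      if (any(inside)) {
        cc <- layer$props$category[i]
        out[ci, cc] <- out[ci, cc] + sum(inside)
        hit <- hit | inside
      }
    }
  }
  out / n_points
}

# Brute-force O(n^3)-style hull oracle: a point is a hull vertex iff it is
# not strictly inside the hull of the others; here we verify by testing that
# every input point is inside the reported hull and every hull vertex is an
# input point on the boundary of all half-planes.
brute_hull_extreme <- function(x, y) {
  n <- length(x)
  extreme <- logical(n)
  for (i in seq_len(n)) {
    # point i is extreme iff some line through it and another point has all
    # points on one side
    is_ext <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      cr <- (x - x[i]) * dy - (y - y[i]) * dx
      if (all(cr <= 1e-9) || all(cr >= -1e-9)) { is_ext <- TRUE; break }
    }
    extreme[i] <- is_ext
  }
  extreme
}
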