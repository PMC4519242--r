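# Landscape covariates: cover fractions, forest edge, human density, road
# density, and the pairwise diagnostics.

grid1 <- pantherscape:::rect_grid(1000)   # one cell
grid2 <- pantherscape:::rect_grid(2000)   # 2 x 2 cells

cover_layer <- function(...) {
  feats <- list(...)
  cats <- vapply(feats, function(f) f$props$code, character(1))
  poly_layer(feats, data.frame(code = cats, category = cats,
                               stringsAsFactors = FALSE))
}

test_that("cover fractions recover known splits", {
  # cell entirely inside one wetland-forest polygon
  layer <- cover_layer(rect_feature(-500, -500, 1500, 1500, code = "Wet_For"))
  fr <- cover_fractions(grid1, layer)
  expect_equal(fr$Wet_For, 1)
  expect_equal(fr$Urban, 0)
  # 50/50 split upland forest / urban
  layer <- cover_layer(rect_feature(0, 0, 500, 1000, code = "Up_For"),
                       rect_feature(500, 0, 1000, 1000, code = "Urban"))
  fr <- cover_fractions(grid1, layer)
  expect_equal(fr$Up_For, 0.5)
  expect_equal(fr$Urban, 0.5)
  expect_equal(sum(fr[1, names(panther_categories())]), 1, tolerance = 1e-9)
})

test_that("cover fractions match the Monte-Carlo oracle on random tessellations", {
  layer <- bsp_tessellation(20, size = 2000, seed = 3)
  fr <- cover_fractions(grid2, layer)
  mc <- mc_cover_oracle(grid2, layer, n_points = 1e5)
  for (cc in names(panther_categories())) {
    expect_lt(max(abs(fr[[cc]] - mc[, cc])), 0.01)
  }
  # triangulated version exercises non-axis-aligned clipping
  tri <- triangulate_layer(layer)
  fr2 <- cover_fractions(grid2, tri)
  for (cc in names(panther_categories())) {
    expect_equal(fr2[[cc]], fr[[cc]], tolerance = 1e-9)
  }
})

test_that("cover conservation: per-cell areas sum to layer-wide category areas", {
  layer <- bsp_tessellation(15, size = 2000, seed = 11)
  fr <- cover_fractions(grid2, layer)
  per_cat <- colSums(fr[, names(panther_categories())]) * 1e6
  truth <- tapply(vapply(layer$features, pantherscape:::feature_area, numeric(1)),
                  layer$props$category, sum)
  for (cc in names(truth)) {
    expect_equal(unname(per_cat[cc]), unname(truth[cc]), tolerance = 1e-6)
  }
})

test_that("cover fractions are invariant to feature order and reject overlaps", {
  layer <- bsp_tessellation(12, size = 2000, seed = 5)
  perm <- sample(seq_along(layer$features))
  shuffled <- poly_layer(layer$features[perm],
                         layer$props[perm, , drop = FALSE])
  expect_equal(cover_fractions(grid2, shuffled),
               cover_fractions(grid2, layer))
  overlap <- cover_layer(rect_feature(0, 0, 1000, 1000, code = "Urban"),
                         rect_feature(0, 0, 1000, 1000, code = "Grass"))
  expect_error(cover_fractions(grid1, overlap), "ambiguous boundary")
})

test_that("category map application rejects unmapped codes", {
  layer <- poly_layer(list(rect_feature(0, 0, 1000, 1000, code = "6170")),
                      data.frame(code = "6170", stringsAsFactors = FALSE))
  fr <- cover_fractions(grid1, layer, category_map = c("6170" = "Wet_For"))
  expect_equal(fr$Wet_For, 1)
  expect_error(cover_fractions(grid1, layer, category_map = c("9999" = "Urban")),
               "unmapped")
})

test_that("forest edge follows the edge-forming rules on toy layouts", {
  half <- function(a, b) cover_layer(rect_feature(0, 0, 500, 1000, code = a),
                                     rect_feature(500, 0, 1000, 1000, code = b))
  # forest | grassland: one shared 1-km segment
  expect_equal(forest_edge(grid1, half("Wet_For", "Grass"))$For_Edge, 1)
  # forest | agriculture: not edge-forming
  expect_equal(forest_edge(grid1, half("Wet_For", "Ag"))$For_Edge, 0)
  # upland forest | wetland forest: counts as forest edge
  expect_equal(forest_edge(grid1, half("Up_For", "Wet_For"))$For_Edge, 1)
  # same category twice: never edge
  expect_equal(forest_edge(grid1, half("Wet_For", "Wet_For"))$For_Edge, 0)
  # saltwater wetland is non-edge-forming
  expect_equal(forest_edge(grid1, half("Wet_For", "SW_Wet"))$For_Edge, 0)
})

test_that("a nested inclusion contributes its perimeter", {
  # 0.2 x 0.2 km grassland island inside a forest cell -> 0.8 km of edge
  outer <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  hole <- cbind(c(400, 600, 600, 400), c(400, 400, 600, 600))
  forest <- list(rings = list(outer, hole), props = list(code = "Wet_For"))
  island <- list(rings = list(hole), props = list(code = "Grass"))
  layer <- poly_layer(list(forest, island),
                      data.frame(code = c("Wet_For", "Grass"),
                                 category = c("Wet_For", "Grass"),
                                 stringsAsFactors = FALSE))
  expect_equal(forest_edge(grid1, layer)$For_Edge, 0.8)
})

test_that("edge additivity: per-cell edge sums to the un-gridded total", {
  land <- small_land()
  fe <- forest_edge(land$grid, land$cover)
  expect_equal(sum(fe$For_Edge), attr(fe, "total_km"), tolerance = 1e-9)
  # raster fast path agrees with the generic polygon path
  generic <- land$cover
  attr(generic, "raster") <- NULL
  fe2 <- forest_edge(land$grid, generic, validate = FALSE)
  expect_equal(fe$For_Edge, fe2$For_Edge, tolerance = 1e-9)
})

test_that("raster and generic cover paths agree", {
  land <- small_land()
  fr <- cover_fractions(land$grid, land$cover)
  generic <- land$cover
  attr(generic, "raster") <- NULL
  fr2 <- cover_fractions(land$grid, generic)
  for (cc in names(panther_categories())) {
    expect_equal(fr[[cc]], fr2[[cc]], tolerance = 1e-9)
  }
})

test_that("human density is the area-weighted block average", {
  # block of density 200 covering 25% of the cell
  blocks <- poly_layer(list(rect_feature(0, 0, 500, 500)),
                       data.frame(density = 200))
  expect_equal(human_density(grid1, blocks)$Pop_Dens, 50)
  # uniform density over the whole grid
  blocks <- poly_layer(list(rect_feature(0, 0, 2000, 2000)),
                       data.frame(density = 7))
  expect_equal(human_density(grid2, blocks)$Pop_Dens, rep(7, 4))
  # population is converted through block area
  blocks <- poly_layer(list(rect_feature(0, 0, 2000, 2000)),
                       data.frame(population = 1200))
  expect_equal(human_density(grid2, blocks)$Pop_Dens, rep(300, 4))
  expect_error(
    human_density(grid1, poly_layer(list(rect_feature(0, 0, 10, 10)),
                                    data.frame(population = -5))),
    "negative")
})

test_that("human density matches Monte-Carlo sampling on a random mosaic", {
  layer <- bsp_tessellation(15, size = 2000, seed = 9)
  dens <- stats::setNames(runif(length(layer$features), 0, 1000),
                          NULL)
  blocks <- poly_layer(layer$features, data.frame(density = dens))
  hd <- human_density(grid2, blocks)
  set.seed(21)
  for (ci in 1:4) {
    b <- pantherscape:::cell_bounds(grid2, grid2$cells$cell_id[ci])
    px <- runif(1e5, b$xmin, b$xmax); py <- runif(1e5, b$ymin, b$ymax)
    val <- numeric(1e5)
    for (i in seq_along(blocks$features)) {
      inside <- pantherscape:::point_in_feature(px, py, blocks$features[[i]],
                                                include_boundary = FALSE)
      val[inside] <- dens[i]
    }
    expect_lt(abs(hd$Pop_Dens[ci] - mean(val)), 0.01 * max(mean(val), 1))
  }
})

test_that("road density clips, excludes classes, and breaks boundary ties", {
  roads <- line_layer(list(list(coords = cbind(c(0, 1000), c(0, 1000)),
                                props = list(class = "highway"))))
  expect_equal(road_density(grid1, roads)$Rd_Dens, sqrt(2), tolerance = 1e-9)
  bike <- line_layer(list(list(coords = cbind(c(0, 1000), c(0, 1000)),
                               props = list(class = "bike trail"))))
  expect_equal(road_density(grid1, bike)$Rd_Dens, 0)
  # road along the shared boundary of two cells -> lower-left cell only
  mid <- line_layer(list(list(coords = cbind(c(1000, 1000), c(0, 2000)),
                              props = list(class = "local"))))
  rd <- road_density(grid2, mid)
  expect_equal(rd$Rd_Dens[rd$cell_id == 1], 1)
  expect_equal(rd$Rd_Dens[rd$cell_id == 2], 0)
  expect_equal(rd$Rd_Dens[rd$cell_id == 3], 1)
  expect_equal(sum(rd$Rd_Dens), 2)  # counted once
  # empty input -> zeros
  none <- line_layer(list(), data.frame(class = character(0)))
  expect_equal(road_density(grid1, none)$Rd_Dens, 0)
})

test_that("feature diagnostics report squared correlations", {
  tab <- data.frame(For_Edge = c(1, 2, 3, 4), Up_For = c(1, 2, 3, 4) / 2,
                    Wet_For = c(0.5, 1, 1.5, 2) / 2,
                    wet_depth = c(0.3, -1, 2, 0), dry_depth = c(0, 0, 0, 0))
  d <- feature_diagnostics(tab, pairs = list(c("For_Edge", "Up_For+Wet_For")))
  expect_equal(d$r_squared, 1)
  expect_warning(
    d2 <- feature_diagnostics(tab, pairs = list(c("wet_depth", "dry_depth"))),
    "zero-variance")
  expect_true(is.na(d2$r_squared))
  # y = 2x + small noise
  set.seed(1)
  tab2 <- data.frame(For_Edge = 1:50, Up_For = 2 * (1:50) + rnorm(50, 0, 0.1))
  d3 <- feature_diagnostics(tab2, pairs = list(c("For_Edge", "Up_For")))
  expect_gt(d3$r_squared, 0.99)
  # orthogonal patterns
  tab3 <- data.frame(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(feature_diagnostics(tab3, pairs = list(c("a", "b")))$r_squared, 0)
})
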