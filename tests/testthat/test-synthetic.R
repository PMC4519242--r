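# The synthetic landscape generator: determinism, composition, planted
# signal, and the error contracts.

test_that("configuration validation catches bad inputs", {
  expect_error(synthetic_config(extent_km = 4), "landscape too small")
  mix <- synthetic_config()$cover_mix
  mix["Urban"] <- mix["Urban"] + 0.05
  expect_error(synthetic_config(cover_mix = mix), "sum to 1")
  expect_error(synthetic_config(n_animals = 0), "n_animals")
  expect_error(synthetic_config(fixes_per_animal = 10), "fixes_per_animal")
  expect_error(synthetic_config(preference_coefs = c(Bananas = 1)),
               "unknown covariates")
})

test_that("cover generation hits the target mix and is deterministic", {
  cfg <- small_config()
  cov1 <- generate_cover(cfg)
  cov2 <- generate_cover(cfg)
  expect_identical(attr(cov1, "raster")$values, attr(cov2, "raster")$values)
  realized <- attr(cov1, "realized_mix")
  expect_true(all(abs(realized - cfg$cover_mix) <= 0.05))
  # tessellation: per-cell fractions sum to 1
  grid <- pantherscape:::rect_grid(cfg$extent_km * 1000)
  fr <- cover_fractions(grid, cov1)
  expect_true(all(abs(rowSums(fr[, names(panther_categories())]) - 1) < 1e-9))
  # urban concentrated in the north-west corner, saltwater on the south edge
  ras <- attr(cov1, "raster")
  v <- ras$values
  n <- nrow(v)
  urban_rows <- which(v == "Urban", arr.ind = TRUE)
  expect_gt(mean(urban_rows[, "row"] > 0.6 * n), 0.9)
  expect_gt(mean(urban_rows[, "col"] < 0.4 * n), 0.9)
  salt_rows <- which(v == "SW_Wet", arr.ind = TRUE)
  expect_gt(mean(salt_rows[, "row"] < 0.25 * n), 0.9)
})

test_that("a degenerate single-category mixture tessellates trivially", {
  mix <- setNames(rep(0, 10), names(panther_categories()))
  mix["FW_Wet"] <- 1
  cfg <- synthetic_config(extent_km = 10, cover_mix = mix, n_gauges = 4)
  cov <- generate_cover(cfg)
  expect_equal(unname(attr(cov, "realized_mix")["FW_Wet"]), 1)
})

test_that("hydrology spans the expected depth range with correlated seasons", {
  cfg <- small_config()
  h <- generate_hydrology(cfg)
  expect_identical(h$gauges, generate_hydrology(cfg)$gauges)
  # gauges inside and outside the extent
  L <- cfg$extent_km * 1000
  expect_true(any(h$gauges$x < 0 | h$gauges$x > L))
  expect_true(any(h$gauges$x > 0 & h$gauges$x < L))
  # true depths span approximately -5.2 .. +2.6 m
  depths <- c(h$truth$true_wet_depth, h$truth$true_dry_depth)
  expect_lt(abs(min(depths) - (-5.2)) , 0.6)
  expect_lt(abs(max(depths) - 2.6), 0.6)
  # wet runs deeper than dry by the seasonal stage offset
  expect_equal(mean(h$truth$true_wet_depth - h$truth$true_dry_depth), 0.3,
               tolerance = 1e-9)
  # derived per-cell seasonal depths are highly correlated
  land <- small_land()
  r2 <- feature_diagnostics(land$table,
                            pairs = list(c("wet_depth", "dry_depth")))$r_squared
  expect_gte(r2, 0.9)
})

test_that("anthropogenic surfaces form an urban gradient with excluded trails", {
  cfg <- small_config()
  a <- generate_anthropogenic(cfg)
  expect_true(any(a$roads$props$class %in%
                    c("four-wheel drive", "bike trail", "pedestrian trail")))
  land <- small_land()
  # urban corner cells are orders of magnitude denser than the interior
  corner <- land$table$Pop_Dens[land$table$xc < 3000 & land$table$yc > 17000]
  interior <- land$table$Pop_Dens[land$table$xc > 10000 & land$table$yc < 10000]
  expect_gt(max(corner), 100 * max(stats::median(interior), 1))
  # wilderness config: no people, no roads
  mix <- cfg$cover_mix
  mix["FW_Wet"] <- mix["FW_Wet"] + mix["Urban"]
  mix["Urban"] <- 0
  wcfg <- synthetic_config(extent_km = 20, cover_mix = mix, n_gauges = 6)
  w <- generate_anthropogenic(wcfg)
  expect_true(all(w$blocks$props$population == 0))
  expect_equal(length(w$roads$features), 0)
})

test_that("telemetry under a null preference structure is uniform", {
  cfg <- synthetic_config(extent_km = 20, n_animals = 1,
                          fixes_per_animal = 2000,
                          preference_coefs = c(Wet_For = 0),
                          depth_quad_weight = 0, intercept = 0,
                          movement_radius_km = 5, n_gauges = 6, seed = 1)
  land <- synth_landscape(cfg)
  expect_true(all(abs(land$truth$w - land$truth$w[1]) < 1e-12))
  # fixes should be uniform over the movement-accessible cells
  cc <- land$truth$centers[1]
  d2 <- (land$table$xc - land$table$xc[cc])^2 +
        (land$table$yc - land$table$yc[cc])^2
  cand <- which(d2 <= (cfg$movement_radius_km * 1000)^2)
  cid <- pantherscape:::cell_at(land$grid, land$fixes$x, land$fixes$y)
  counts <- table(factor(cid, levels = land$table$cell_id[cand]))
  gof <- suppressWarnings(stats::chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("planted effects separate presence from absence cells as signed", {
  land <- default_land()
  tab <- land$table
  pres <- tab$presence == 1
  coefs <- land$truth$coefs
  for (v in names(coefs)[coefs != 0]) {
    diff <- mean(tab[[v]][pres]) - mean(tab[[v]][!pres])
    expect_true(sign(diff) == sign(coefs[v]),
                label = paste("signed separation for", v))
  }
  # the two designated nulls exist and have zero effect
  expect_equal(unname(coefs[land$truth$null_covariates]), c(0, 0))
  # presence cells sit nearer the depth optimum
  expect_lt(mean(abs(tab$dry_depth[pres] - (-0.6))),
            mean(abs(tab$dry_depth[!pres] - (-0.6))))
})

test_that("the full landscape is a pure function of the config", {
  l1 <- synth_landscape(small_config())
  l2 <- synth_landscape(small_config())
  expect_identical(l1$table, l2$table)
  expect_identical(l1$fixes, l2$fixes)
  expect_identical(l1$truth$w, l2$truth$w)
  # a different seed changes the outputs
  l3 <- synth_landscape(small_config(seed = 2))
  expect_false(identical(l1$fixes, l3$fixes))
})

test_that("landscape files round-trip through plain-text formats", {
  land <- small_land()
  dir <- tempfile("land")
  save_landscape(land, dir)
  expect_true(all(file.exists(file.path(dir, c("cover.geojson", "gauges.csv",
                                               "elevation.asc", "blocks.geojson",
                                               "roads.geojson", "telemetry.csv",
                                               "truth.json", "features.csv")))))
  cov <- read_geojson(file.path(dir, "cover.geojson"))
  expect_equal(length(cov$features), length(land$cover$features))
  expect_equal(sum(vapply(cov$features, pantherscape:::feature_area, numeric(1))),
               (20000)^2)
  fx <- read.csv(file.path(dir, "telemetry.csv"))
  expect_equal(nrow(fx), nrow(land$fixes))
  unlink(dir, recursive = TRUE)
})
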