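# Synthetic landscape generator with known ground truth. Emulates the real
# study system: a mostly-wetland landscape with 10 cover categories at
# realistic proportions, a smooth hydrologic surface observed through
# gauging stations, an urban/road gradient concentrated in one corner,
# saltwater wetland along one edge, and telemetry from simulated animals
# whose utilization follows planted covariate effects (forest edge and
# wetland forest positive, human density / roads / agriculture negative,
# water depth peaked near -0.6 m). Every output is a pure function of the
# configuration, including its seed.

#' Synthetic landscape configuration
#'
#' Defaults reproduce the study conditions: a 60-km square landscape of
#' 1-km2 cells, cover mix at the real study area's category proportions,
#' 20 monitored animals with 150 fixes each, and planted preference
#' effects with a depth optimum of -0.6 m. `Grass` and `Up_Shrub` are the
#' designated null covariates (effect exactly 0) used by
#' importance-recovery tests.
#'
#' @param extent_km side of the square landscape (km).
#' @param cover_mix named category fractions summing to 1.
#' @param n_animals number of simulated animals.
#' @param fixes_per_animal fixes per animal (>= 50 so every animal passes
#'   the telemetry filter).
#' @param preference_coefs named linear effects on standardized covariates;
#'   unnamed covariates have effect 0.
#' @param depth_optimum_m water depth (m) of peak utilization.
#' @param depth_quad_weight curvature of the quadratic depth response.
#' @param intercept baseline log-odds shift of utilization.
#' @param movement_radius_km radius of the disc each animal samples fixes
#'   from around its home-range center.
#' @param subcell_m resolution of the cover/elevation subgrid (must divide
#'   1000).
#' @param n_gauges number of gauging stations (>= 4; two are placed outside
#'   the extent to buffer edge effects).
#' @param hydro_years calendar years of daily stage records.
#' @param seed integer seed determining all outputs.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(extent_km = 60,
                             cover_mix = c(FW_Wet = 0.343, Wet_For = 0.147,
                                           Ag = 0.097, SW_Wet = 0.088,
                                           Grass = 0.076, Wet_Shrub = 0.082,
                                           Urban = 0.069, Up_For = 0.054,
                                           Water = 0.023, Up_Shrub = 0.021),
                             n_animals = 20, fixes_per_animal = 330,
                             preference_coefs = c(Wet_For = 4.5, For_Edge = 4.5,
                                                  Pop_Dens = -5, Ag = -4,
                                                  Rd_Dens = -3),
                             depth_optimum_m = -0.6,
                             depth_quad_weight = 1.5,
                             intercept = -3.5,
                             movement_radius_km = 18,
                             subcell_m = 250, n_gauges = 12,
                             hydro_years = 2004:2005, seed = 1) {
  if (extent_km < 5) stop("landscape too small")
  cats <- names(panther_categories())
  if (!setequal(names(cover_mix), cats)) {
    stop("cover_mix must name exactly the 10 cover categories")
  }
  cover_mix <- cover_mix[cats]
  if (abs(sum(cover_mix) - 1) > 1e-9) stop("cover_mix fractions must sum to 1")
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (fixes_per_animal < 50) stop("fixes_per_animal must be >= 50")
  if (1000 %% subcell_m != 0) stop("subcell_m must divide 1000")
  if (n_gauges < 4) stop("need at least 4 gauges")
  coefs <- setNames(rep(0, length(covariate_names())), covariate_names())
  unknown <- setdiff(names(preference_coefs), names(coefs))
  if (length(unknown)) stop("unknown covariates in preference_coefs: ",
                            paste(unknown, collapse = ", "))
  coefs[names(preference_coefs)] <- preference_coefs
  structure(list(extent_km = extent_km, cell_km = 1, cover_mix = cover_mix,
                 n_animals = n_animals, fixes_per_animal = fixes_per_animal,
                 preference_coefs = coefs,
                 null_covariates = c("Grass", "Up_Shrub"),
                 depth_optimum_m = depth_optimum_m,
                 depth_quad_weight = depth_quad_weight,
                 intercept = intercept,
                 movement_radius_km = movement_radius_km,
                 subcell_m = subcell_m, n_gauges = n_gauges,
                 hydro_years = hydro_years, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Urban zone: the north-west corner; saltwater strip: the south edge.
urban_zone <- function(config) {
  L <- config$extent_km * 1000
  list(xmax = 0.30 * L, ymin = 0.70 * L)
}
salt_strip <- function(config) {
  L <- config$extent_km * 1000
  list(ymax = 0.10 * L)
}

#' Generate the synthetic cover layer
#'
#' Seeded Voronoi agglomeration: category-labeled seed points are scattered
#' over the extent (urban seeds confined to the north-west corner,
#' saltwater-wetland seeds to the south edge), every subcell is assigned to
#' its nearest seed, and whole patches are then greedily reassigned until
#' the realized category fractions are within 2 percentage points of the
#' target mix. The layer is a gap-free, overlap-free tessellation of
#' axis-aligned rectangles (horizontal runs of same-category subcells) and
#' carries the subcell category raster as attribute `raster`.
#'
#' @param config a [synthetic_config()].
#' @return categorized `poly_layer` with attributes `raster` and
#'   `realized_mix`.
#' @export
generate_cover <- function(config) {
  set.seed(config$seed + 101L)
  L <- config$extent_km * 1000
  s <- config$subcell_m
  N <- as.integer(L / s)
  cats <- names(config$cover_mix)
  mix <- config$cover_mix

  n_seeds <- max(40L, as.integer(round(config$extent_km^2 / 3)))
  alloc <- floor(mix * n_seeds)
  rem <- n_seeds - sum(alloc)
  if (rem > 0) {
    frac_part <- mix * n_seeds - alloc
    alloc[order(-frac_part)[seq_len(rem)]] <- alloc[order(-frac_part)[seq_len(rem)]] + 1
  }
  alloc[mix > 0 & alloc == 0] <- 1L
  uz <- urban_zone(config); ss <- salt_strip(config)
  seed_cat <- rep(cats, times = alloc)
  sx <- runif(length(seed_cat), 0, L)
  sy <- runif(length(seed_cat), 0, L)
  is_u <- seed_cat == "Urban"
  sx[is_u] <- runif(sum(is_u), 0, uz$xmax)
  sy[is_u] <- runif(sum(is_u), uz$ymin, L)
  is_s <- seed_cat == "SW_Wet"
  sy[is_s] <- runif(sum(is_s), 0, ss$ymax)

  xc <- rep((seq_len(N) - 0.5) * s, times = N)
  yc <- rep((seq_len(N) - 0.5) * s, each = N)
  best <- rep.int(Inf, N * N)
  assign_seed <- integer(N * N)
  for (k in seq_along(sx)) {
    d2 <- (xc - sx[k])^2 + (yc - sy[k])^2
    hit <- d2 < best
    best[hit] <- d2[hit]
    assign_seed[hit] <- k
  }
  patch_cat <- seed_cat

  # greedy patch rebalancing toward the target mix
  in_uz <- sx <= uz$xmax & sy >= uz$ymin
  in_ss <- sy <= ss$ymax
  patch_size <- tabulate(assign_seed, nbins = length(sx))
  for (iter in seq_len(500)) {
    realized <- vapply(cats, function(cc)
      sum(patch_size[patch_cat == cc]), numeric(1)) / (N * N)
    err <- realized - mix
    if (max(abs(err)) <= 0.02) break
    over <- cats[which.max(err)]
    under <- cats[which.min(err)]
    cand <- which(patch_cat == over & patch_size > 0)
    if (under == "Urban") cand <- cand[in_uz[cand]]
    if (under == "SW_Wet") cand <- cand[in_ss[cand]]
    if (over %in% c("Urban", "SW_Wet")) cand <- cand  # always removable
    if (!length(cand)) break
    need <- min(err[over], -err[under]) * N * N
    pick <- cand[which.min(abs(patch_size[cand] - need))]
    if (patch_size[pick] > 2 * max(need, 1)) break  # flip would overshoot badly
    patch_cat[pick] <- under
  }

  # vals indexed [row, col] with row 1 at the south; element (r, c) is the
  # subcell centered at ((c - 0.5) s, (r - 0.5) s)
  vals <- matrix(patch_cat[assign_seed], nrow = N, byrow = TRUE)
  ras <- make_raster(vals, 0, 0, s)

  feats <- list(); codes <- character(0)
  for (r in seq_len(N)) {
    rl <- rle(vals[r, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (i in seq_along(rl$values)) {
      feats[[length(feats) + 1]] <- rect_feature((starts[i] - 1) * s, (r - 1) * s,
                                                 ends[i] * s, r * s,
                                                 code = rl$values[i])
      codes <- c(codes, rl$values[i])
    }
  }
  layer <- poly_layer(feats, data.frame(code = codes, category = codes,
                                        stringsAsFactors = FALSE))
  attr(layer, "raster") <- ras
  realized <- vapply(cats, function(cc) mean(vals == cc), numeric(1))
  attr(layer, "realized_mix") <- realized
  layer
}

# Continuous generative fields for the hydrology stage (shared between the
# generator and its ground truth).
hydro_fields <- function(config) {
  L <- config$extent_km * 1000
  uzc <- c(0.15 * L, 0.85 * L)  # urban corner is the dry end
  f_raw <- function(x, y) {
    g_corner <- exp(-sqrt((x - uzc[1])^2 + (y - uzc[2])^2) / (0.35 * L))
    g_sin <- 0.5 * (1 + sin(2 * pi * x / L * 1.7 + 0.5) *
                        sin(2 * pi * y / L * 1.3 + 1.1))
    g_grad <- 1 - y / L
    0.55 * g_corner + 0.30 * g_sin + 0.15 * g_grad
  }
  # normalize over cell centers so the depth extremes are realized
  n <- config$extent_km
  cx <- rep((seq_len(n) - 0.5) * 1000, times = n)
  cy <- rep((seq_len(n) - 0.5) * 1000, each = n)
  fr <- f_raw(cx, cy)
  lo <- min(fr); hi <- max(fr)
  wet_mean <- 0.45; dry_mean <- 0.15
  m <- (5 * wet_mean + 7 * dry_mean) / 12  # annual mean stage
  elev <- function(x, y) {
    f <- (f_raw(x, y) - lo) / (hi - lo)
    m - 2.6 + 7.8 * f  # true annual-mean depth runs +2.6 .. -5.2
  }
  base <- function(x, y) 0.08 * sin(2 * pi * x / L + 1) * cos(2 * pi * y / L)
  list(elev = elev, base = base, wet_mean = wet_mean, dry_mean = dry_mean)
}

#' Generate the synthetic hydrology inputs
#'
#' A smooth ground-elevation surface (corner gradient plus low-frequency
#' undulation) and daily stage records at gauging stations placed inside
#' and just outside the extent. Stages carry a seasonal offset (wet-season
#' mean 0.3 m above the dry-season mean) plus small daily noise, so the
#' derived per-cell mean depths span approximately -5.2 to +2.6 m.
#'
#' @param config a [synthetic_config()].
#' @return list with `elevation` (a `panther_raster`), `gauges`
#'   (data.frame: station_id, x, y, date, stage_m), and `truth` (per-cell
#'   true wet/dry depths at cell centers).
#' @export
generate_hydrology <- function(config) {
  set.seed(config$seed + 202L)
  L <- config$extent_km * 1000
  s <- config$subcell_m
  N <- as.integer(L / s)
  hf <- hydro_fields(config)

  gx <- rep((seq_len(N) - 0.5) * s, times = N)
  gy <- rep((seq_len(N) - 0.5) * s, each = N)
  elev_vals <- matrix(hf$elev(gx, gy), nrow = N, byrow = TRUE)
  elevation <- make_raster(elev_vals, 0, 0, s)

  n_in <- config$n_gauges - 2L
  k <- ceiling(sqrt(n_in))
  pos <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n_in), ]
  gxs <- (pos$i - 0.5) / k * L + runif(n_in, -L / (4 * k), L / (4 * k))
  gys <- (pos$j - 0.5) / k * L + runif(n_in, -L / (4 * k), L / (4 * k))
  gxs <- c(gxs, -0.05 * L, 1.05 * L)
  gys <- c(gys, 0.5 * L, 0.5 * L)
  ids <- sprintf("G%02d", seq_along(gxs))

  dates <- seq(as.Date(paste0(min(config$hydro_years), "-01-01")),
               as.Date(paste0(max(config$hydro_years), "-12-31")), by = "day")
  mo <- as.integer(format(dates, "%m"))
  seasonal <- ifelse(mo %in% 6:10, hf$wet_mean, hf$dry_mean)
  recs <- lapply(seq_along(gxs), function(g) {
    data.frame(station_id = ids[g], x = gxs[g], y = gys[g], date = dates,
               stage_m = seasonal + hf$base(gxs[g], gys[g]) +
                 rnorm(length(dates), 0, 0.05))
  })
  gauges <- do.call(rbind, recs)

  n <- config$extent_km
  cx <- rep((seq_len(n) - 0.5) * 1000, times = n)
  cy <- rep((seq_len(n) - 0.5) * 1000, each = n)
  truth <- data.frame(
    cell_id = seq_len(n * n),
    true_wet_depth = hf$wet_mean + hf$base(cx, cy) - hf$elev(cx, cy),
    true_dry_depth = hf$dry_mean + hf$base(cx, cy) - hf$elev(cx, cy))
  list(elevation = elevation, gauges = gauges, truth = truth)
}

#' Generate synthetic census blocks and roads
#'
#' Census-block densities decay from the urban corner (peak about 8000
#' people per km2) to a sparse rural baseline; the road network combines
#' highways crossing the wild interior, a dense local grid in the urban
#' corner, and a few excluded-class trails (four-wheel drive, bike,
#' pedestrian). When the cover mix has no urban fraction the landscape is
#' wilderness: all block populations are zero and no roads are generated.
#'
#' @param config a [synthetic_config()].
#' @return list with `blocks` (poly_layer with population and density) and
#'   `roads` (line_layer with class codes).
#' @export
generate_anthropogenic <- function(config) {
  set.seed(config$seed + 303L)
  L <- config$extent_km * 1000
  wilderness <- config$cover_mix[["Urban"]] == 0
  uzc <- c(0.15 * L, 0.85 * L)

  bs <- 2000  # 2-km census blocks
  nb <- ceiling(L / bs)
  feats <- list(); pop <- numeric(0); dens <- numeric(0)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    x0 <- (i - 1) * bs; y0 <- (j - 1) * bs
    cx <- x0 + bs / 2; cy <- y0 + bs / 2
    d <- sqrt((cx - uzc[1])^2 + (cy - uzc[2])^2)
    dn <- if (wilderness) 0 else 8000 * exp(-(d / 5000)^2) + 0.2
    feats[[length(feats) + 1]] <- rect_feature(x0, y0, min(x0 + bs, L),
                                               min(y0 + bs, L))
    dens <- c(dens, dn)
    pop <- c(pop, round(dn * (min(x0 + bs, L) - x0) * (min(y0 + bs, L) - y0) / 1e6))
  }
  blocks <- poly_layer(feats, data.frame(population = pop, density = dens))

  rfeats <- list(); rclass <- character(0)
  add_road <- function(coords, cls) {
    rfeats[[length(rfeats) + 1]] <<- list(coords = coords, props = list(class = cls))
    rclass <<- c(rclass, cls)
  }
  if (!wilderness) {
    add_road(cbind(c(0, L), c(0.55, 0.55) * L), "highway")
    add_road(cbind(c(0.45, 0.45) * L, c(0, L)), "highway")
    add_road(cbind(c(0, 0.6 * L), c(0.85 * L, 0.3 * L)), "primary")
    uz <- urban_zone(config)
    for (x in seq(500, uz$xmax - 500, by = 500)) {
      add_road(cbind(c(x, x), c(uz$ymin, L)), "local")
    }
    for (y in seq(uz$ymin + 500, L - 500, by = 500)) {
      add_road(cbind(c(0, uz$xmax), c(y, y)), "local")
    }
    add_road(cbind(c(0.6, 0.8) * L, c(0.2, 0.35) * L), "four-wheel drive")
    add_road(cbind(c(0.55, 0.75) * L, c(0.5, 0.6) * L), "bike trail")
    add_road(cbind(c(0.3, 0.4) * L, c(0.3, 0.25) * L), "pedestrian trail")
  }
  roads <- if (length(rfeats)) {
    line_layer(rfeats, data.frame(class = rclass, stringsAsFactors = FALSE))
  } else {
    line_layer(list(), data.frame(class = character(0)))
  }
  list(blocks = blocks, roads = roads)
}

#' Simulate telemetry from planted preferences
#'
#' Per-cell utilization weight `w = plogis(intercept + sum(beta_j z_j) -
#' q (dry_depth - optimum)^2)` on standardized covariates. Each animal's
#' home-range center is drawn proportional to `w`; its fixes are drawn
#' (independently, proportional to `w`) from the cells within the movement
#' radius of the center, uniformly within the chosen cell. Fixes carry
#' animal id, sex, birth date (at least 3 years before the first fix), and
#' timestamps within 2004-2013.
#'
#' @param config a [synthetic_config()].
#' @param features FeatureTable computed on the synthetic landscape.
#' @return list with `fixes` (telemetry data.frame) and `truth`
#'   (utilization weights, realized coefficients, centers).
#' @export
simulate_telemetry <- function(config, features) {
  set.seed(config$seed + 404L)
  vars <- covariate_names()
  Z <- scale(features[, vars])
  Z[, apply(features[, vars], 2, sd) == 0] <- 0
  beta <- config$preference_coefs[vars]
  lp <- as.vector(Z %*% beta)
  lp <- lp - config$depth_quad_weight *
    (features$dry_depth - config$depth_optimum_m)^2
  lp <- lp - mean(lp) + config$intercept
  w <- stats::plogis(lp)
  if (all(w <= 0)) stop("no habitable cells")

  n_cells <- nrow(features)
  centers <- sample.int(n_cells, config$n_animals, replace = FALSE, prob = w)
  r <- config$movement_radius_km * 1000
  fixes <- list()
  for (a in seq_len(config$n_animals)) {
    cc <- centers[a]
    d2 <- (features$xc - features$xc[cc])^2 + (features$yc - features$yc[cc])^2
    cand <- which(d2 <= r^2)
    cells <- cand[sample.int(length(cand), config$fixes_per_animal,
                             replace = TRUE, prob = w[cand])]
    x <- features$xc[cells] + runif(length(cells), -500, 500)
    y <- features$yc[cells] + runif(length(cells), -500, 500)
    start <- as.Date("2004-01-01") + floor(runif(1, 0, 365 * 8))
    span <- floor(runif(1, 365, 365 * 3))
    days <- sort(sample.int(span, config$fixes_per_animal, replace = TRUE))
    fix_date <- pmin(start + days, as.Date("2013-12-31"))
    birth <- start - round(3 * 365.25) - floor(runif(1, 0, 1500))
    fixes[[a]] <- data.frame(
      animal_id = sprintf("A%02d", a),
      sex = sample(c("F", "M"), 1, prob = c(0.6, 0.4)),
      birth_date = birth, fix_datetime = fix_date, x = x, y = y)
  }
  truth <- list(w = w, coefs = beta, null_covariates = config$null_covariates,
                depth_optimum_m = config$depth_optimum_m,
                centers = centers)
  list(fixes = do.call(rbind, fixes), truth = truth)
}

#' Generate the full synthetic landscape
#'
#' Runs cover, hydrology, and anthropogenic generation, assembles the
#' feature table on the analysis grid, simulates telemetry, and labels
#' presence. Everything is a pure function of the configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with config, grid, cover, elevation, gauges, blocks,
#'   roads, fixes, truth, and `table` (FeatureTable with presence labels).
#' @export
synth_landscape <- function(config = synthetic_config()) {
  L <- config$extent_km * 1000
  cover <- generate_cover(config)
  hydro <- generate_hydrology(config)
  anthro <- generate_anthropogenic(config)
  grid <- rect_grid(L)
  season <- season_config(start_year = min(config$hydro_years),
                          end_year = max(config$hydro_years))
  features <- build_features(grid, cover, hydro$gauges, hydro$elevation,
                             anthro$blocks, anthro$roads, season = season)
  tel <- simulate_telemetry(config, features)
  pres <- label_presence(grid, tel$fixes)
  table <- merge(features, pres, by = "cell_id")
  table <- table[order(table$cell_id), ]
  truth <- c(tel$truth, list(hydro = hydro$truth))
  list(config = config, grid = grid, cover = cover,
       elevation = hydro$elevation, gauges = hydro$gauges,
       blocks = anthro$blocks, roads = anthro$roads,
       fixes = tel$fixes, truth = truth, table = table)
}

#' Write a synthetic landscape to plain-text files
#'
#' cover/blocks/roads as GeoJSON, elevation as ESRI ASCII grid, gauges and
#' telemetry as CSV, ground truth as JSON.
#'
#' @param landscape a [synth_landscape()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geojson(landscape$cover, file.path(dir, "cover.geojson"))
  write_asc(landscape$elevation, file.path(dir, "elevation.asc"))
  write.csv(landscape$gauges, file.path(dir, "gauges.csv"), row.names = FALSE)
  write_geojson(landscape$blocks, file.path(dir, "blocks.geojson"))
  if (length(landscape$roads$features)) {
    write_geojson(landscape$roads, file.path(dir, "roads.geojson"))
  }
  write.csv(landscape$fixes, file.path(dir, "telemetry.csv"), row.names = FALSE)
  jsonlite::write_json(landscape$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(landscape$table, file.path(dir, "features.csv"), row.names = FALSE)
  invisible(dir)
}
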