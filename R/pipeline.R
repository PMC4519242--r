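# End-to-end pipeline orchestration: synthesize (or load) inputs, engineer
# features, label presence, fit and validate the model, run the sensitivity
# analysis, and map habitat — as one configured, reproducible run.

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] describing the landscape to
#'   generate, or `NULL` to run from files in `input_dir` (as written by
#'   [save_landscape()]).
#' @param input_dir directory of input files when `synthetic` is `NULL`.
#' @param model a [model_config()]; its seed governs the modelling stages.
#' @param filter a [filter_rules()].
#' @param strata named P ranges for the sensitivity analysis.
#' @param sweep_covariates covariates to sweep (default the planted-effect
#'   set plus dry-season depth).
#' @param cv_folds folds for cross validation.
#' @param importance_permutations permutations per variable for accuracy
#'   importance.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), input_dir = NULL,
                       model = model_config(), filter = filter_rules(),
                       strata = default_strata(),
                       sweep_covariates = c("Pop_Dens", "Rd_Dens", "For_Edge",
                                            "Wet_For", "Ag", "dry_depth"),
                       cv_folds = 10, importance_permutations = 10) {
  if (is.null(synthetic) && is.null(input_dir)) {
    stop("either a synthetic config or an input directory is required")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir, model = model,
                 filter = filter, strata = strata,
                 sweep_covariates = sweep_covariates, cv_folds = cv_folds,
                 importance_permutations = importance_permutations),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full habitat-modelling pipeline
#'
#' Executes the stages in dependency order (synth/load, features,
#' telemetry filtering and presence labeling, model fit, threshold, cross
#' validation, variable importance, sensitivity sweeps, habitat map) and
#' returns a manifest of stage outputs and summary metrics. Re-running
#' with the same configuration reproduces all numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for artifact files (feature table CSV,
#'   reports as JSON).
#' @return object of class `pantherscape_run`: manifest plus the fitted
#'   objects.
#' @export
run_pantherscape <- function(config = run_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stages <- character(0)
  timing <- numeric(0)
  tick <- function(name) {
    stages <<- c(stages, name)
    timing[name] <<- proc.time()[["elapsed"]]
  }

  if (!is.null(config$synthetic)) {
    land <- run_stage("synth", synth_landscape(config$synthetic))
    grid <- land$grid
    table <- land$table
    fixes <- land$fixes
    truth <- land$truth
    tick("synth"); tick("features")  # synth_landscape covers both
  } else {
    land <- NULL
    loaded <- run_stage("load", {
      d <- config$input_dir
      need <- c("features.csv", "telemetry.csv")
      miss <- need[!file.exists(file.path(d, need))]
      if (length(miss)) stop("missing input files: ", paste(miss, collapse = ", "))
      list(table = read.csv(file.path(d, "features.csv")),
           fixes = read.csv(file.path(d, "telemetry.csv")))
    })
    table <- loaded$table
    fixes <- loaded$fixes
    truth <- NULL
    n <- round(sqrt(nrow(table)))
    grid <- rect_grid(n * 1000)
    tick("load"); tick("features")
  }

  filtered <- run_stage("telemetry", {
    f <- filter_fixes(fixes, config$filter)
    if (nrow(f) == 0) stop("no telemetry fixes survive filtering")
    f
  })
  table$presence <- NULL
  table <- merge(table, label_presence(grid, filtered), by = "cell_id")
  table <- table[order(table$cell_id), ]
  tick("telemetry")

  model <- run_stage("fit", habitat_model(data = table, config = config$model))
  table$P <- model$oob_p
  tick("fit")

  cv <- run_stage("cv", cross_validate(table, config$model, k = config$cv_folds))
  tick("cv")

  imp <- run_stage("importance",
                   variable_importance(model, config$importance_permutations))
  tick("importance")

  strata <- run_stage("strata", build_strata(table, config$strata))
  curves <- run_stage("sensitivity", {
    lapply(setNames(nm = config$sweep_covariates), function(v)
      suppressWarnings(sweep_response(model, strata, v)))
  })
  effects <- report_effects(curves)
  tick("sensitivity")

  map <- run_stage("map", classify_map(table, model$threshold$threshold))
  tick("map")

  ranges <- run_stage("home_ranges", {
    hr <- home_ranges(filtered)
    suppressWarnings(home_range_P(hr, table, grid))
  })
  tick("home_ranges")

  smry <- summary(model)
  metrics <- list(
    n_cells = nrow(table), prevalence = mean(table$presence),
    threshold = model$threshold$threshold,
    oob = unclass(smry$out_of_bag)[c("pcc", "sensitivity", "specificity",
                                     "kappa", "auc")],
    resubstitution = unclass(smry$resubstitution)[c("pcc", "sensitivity",
                                                    "specificity", "kappa",
                                                    "auc")],
    cv = unclass(cv$pooled)[c("pcc", "sensitivity", "specificity", "kappa",
                              "auc")],
    habitat_km2 = map$habitat_km2,
    top_variables = head(imp$variable, 5),
    median_home_range_P = median(ranges$per_animal$mean_P, na.rm = TRUE))

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)

  manifest <- list(config_hash = config_hash, stages = stages,
                   metrics = metrics)
  run <- structure(list(manifest = manifest, model = model, cv = cv,
                        importance = imp, strata = strata, curves = curves,
                        effects = effects, map = map, home_ranges = ranges,
                        table = table, landscape = land,
                        timing_s = diff(c(t0, timing))),
                   class = "pantherscape_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(table, file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(importance = as.data.frame(imp),
                              effects = effects),
                         file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.pantherscape_run <- function(x, ...) {
  m <- x$manifest$metrics
  cat("pantherscape run:", length(x$manifest$stages), "stages,",
      m$n_cells, "cells, prevalence", round(m$prevalence, 3), "\n")
  cat(sprintf("OOB PCC %.1f | CV PCC %.1f | resub PCC %.1f | OOB AUC %.3f\n",
              m$oob$pcc, m$cv$pcc, m$resubstitution$pcc, m$oob$auc))
  cat("threshold", round(m$threshold, 3), "| habitat", m$habitat_km2, "km2\n")
  cat("top variables:", paste(m$top_variables, collapse = ", "), "\n")
  invisible(x)
}
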