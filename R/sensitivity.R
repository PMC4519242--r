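# Stratified one-at-a-time sensitivity analysis: model response curves
# computed within excellent / medium / poor habitat strata, holding the
# other covariates at stratum-specific averages. This respects the fact
# that in real landscapes no cell has all covariates at their central
# tendency at once.

#' Default sensitivity strata
#'
#' Closed P ranges: excellent `[0.85, 0.95]`, medium `[0.45, 0.55]`,
#' poor `[0.05, 0.15]`.
#' @return named list of length-2 numeric ranges.
#' @export
default_strata <- function() {
  list(excellent = c(0.85, 0.95), medium = c(0.45, 0.55), poor = c(0.05, 0.15))
}

#' Build sensitivity strata
#'
#' For each stratum, collects the cells whose predicted P lies in the
#' (closed) range and averages every covariate over the members.
#'
#' @param table FeatureTable with fitted `P`.
#' @param ranges named list of P ranges (see [default_strata()]).
#' @param covariates covariate columns (default the 15 model covariates).
#' @return object of class `sensitivity_strata`: per-stratum member index,
#'   cell count, and covariate mean vector; empty strata are flagged.
#' @export
build_strata <- function(table, ranges = default_strata(),
                         covariates = intersect(covariate_names(), names(table))) {
  stopifnot("P" %in% names(table))
  strata <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    member <- which(table$P >= r[1] & table$P <= r[2])
    list(name = nm, range = r, members = member, n = length(member),
         empty = length(member) == 0,
         means = if (length(member))
           colMeans(table[member, covariates, drop = FALSE])
         else setNames(rep(NA_real_, length(covariates)), covariates))
  })
  names(strata) <- names(ranges)
  if (all(vapply(strata, `[[`, logical(1), "empty"))) {
    stop("model range too narrow: all sensitivity strata are empty")
  }
  structure(list(strata = strata, covariates = covariates),
            class = "sensitivity_strata")
}

#' @export
print.sensitivity_strata <- function(x, ...) {
  for (s in x$strata) {
    cat(sprintf("%-10s P in [%.2f, %.2f]: %d cells%s\n", s$name,
                s$range[1], s$range[2], s$n, if (s$empty) " (empty)" else ""))
  }
  invisible(x)
}

#' Sweep one covariate through the model within each stratum
#'
#' Builds synthetic predictor rows equal to the stratum's covariate mean
#' vector with the target covariate replaced by a grid of values spanning
#' the observed range, and predicts P along the sweep. Cover fractions are
#' swept without renormalizing the sibling fractions (one-at-a-time
#' design).
#'
#' @param model a `habitat_model`.
#' @param strata a [build_strata()] result.
#' @param covariate covariate name to sweep.
#' @param n_points sweep resolution (default 50).
#' @param range optional sweep range; defaults to the observed range of the
#'   covariate in the training data.
#' @return object of class `response_curve`: data.frame (covariate,
#'   stratum, x, P) with the per-stratum baseline predictions as attribute.
#' @export
sweep_response <- function(model, strata, covariate, n_points = 50,
                           range = NULL) {
  if (!covariate %in% model$feature_names) {
    stop("covariate not in model: ", covariate)
  }
  if (is.null(range)) range <- base::range(model$data[[covariate]])
  xs <- seq(range[1], range[2], length.out = n_points)
  out <- list(); baselines <- c()
  for (s in strata$strata) {
    if (s$empty) {
      warning("stratum ", s$name, " is empty; skipped")
      next
    }
    row <- as.data.frame(as.list(s$means))[, model$feature_names, drop = FALSE]
    sweep_rows <- row[rep(1, n_points), , drop = FALSE]
    sweep_rows[[covariate]] <- xs
    p <- predict(model, sweep_rows)
    baselines[s$name] <- predict(model, row)
    out[[s$name]] <- data.frame(covariate = covariate, stratum = s$name,
                                x = xs, P = p)
  }
  curves <- do.call(rbind, out)
  rownames(curves) <- NULL
  attr(curves, "baselines") <- baselines
  class(curves) <- c("response_curve", "data.frame")
  curves
}

#' Effect-size table from response curves
#'
#' For each covariate x stratum curve: the response range `delta_P`
#' (max - min), the direction of the trend ("positive", "negative", or
#' "none" for a flat curve), and the sweep location of the maximum. Also
#' identifies, per covariate, the stratum of maximal effect.
#'
#' @param curves one `response_curve` or a list of them.
#' @param flat_tol curves with delta_P at or below this are "none".
#' @return data.frame with covariate, stratum, delta_P, direction,
#'   x_at_max, max_effect (logical, largest delta_P for that covariate).
#' @export
report_effects <- function(curves, flat_tol = 0.02) {
  if (inherits(curves, "response_curve")) curves <- list(curves)
  rows <- list()
  for (cu in curves) {
    for (s in unique(cu$stratum)) {
      d <- cu[cu$stratum == s, ]
      delta <- max(d$P) - min(d$P)
      dir <- if (delta <= flat_tol) "none"
             else if (d$x[which.max(d$P)] > d$x[which.min(d$P)]) "positive"
             else "negative"
      rows[[length(rows) + 1]] <- data.frame(
        covariate = d$covariate[1], stratum = s, delta_P = delta,
        direction = dir, x_at_max = d$x[which.max(d$P)])
    }
  }
  out <- do.call(rbind, rows)
  out$max_effect <- FALSE
  for (v in unique(out$covariate)) {
    i <- which(out$covariate == v)
    out$max_effect[i[which.max(out$delta_P[i])]] <- TRUE
  }
  out
}

#' Plot response curves
#'
#' One line per stratum over the sweep range.
#'
#' @param x a `response_curve`.
#' @param ... passed to `matplot`.
#' @export
plot.response_curve <- function(x, ...) {
  strata <- unique(x$stratum)
  xs <- unique(x$x)
  m <- vapply(strata, function(s) x$P[x$stratum == s], numeric(length(xs)))
  matplot(xs, m, type = "l", lty = 1, lwd = 2, ylim = c(0, 1),
          xlab = x$covariate[1], ylab = "P", ...)
  legend("topright", legend = strata, col = seq_along(strata), lty = 1,
         bty = "n")
  invisible(x)
}
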