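# The presence-absence habitat classifier. The ensemble learner is the
# randomForest package (classification forest); this module owns the
# out-of-bag bookkeeping, the equal-sensitivity/specificity threshold, the
# accuracy metrics, cross validation, and permutation importance.

#' Random-forest model configuration
#'
#' Defaults follow standard practice for presence-absence landscape models:
#' 500 classification trees with 3 variables tried at each split.
#'
#' @param n_trees number of trees.
#' @param vars_per_split variables tried per split (mtry).
#' @param seed integer seed governing tree randomness, fold assignment, and
#'   importance permutations.
#' @param threshold_rule only "sens_eq_spec" is implemented.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_trees = 500, vars_per_split = 3, seed = 1,
                         threshold_rule = "sens_eq_spec") {
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (vars_per_split < 1 || vars_per_split > length(covariate_names())) {
    stop("vars_per_split out of range")
  }
  threshold_rule <- match.arg(threshold_rule, "sens_eq_spec")
  structure(list(n_trees = n_trees, vars_per_split = vars_per_split,
                 seed = as.integer(seed), threshold_rule = threshold_rule),
            class = "model_config")
}

#' Fit the random-forest presence model
#'
#' Fits a classification random forest of presence (1) versus absence (0)
#' on the 15 landscape covariates, stores resubstitution and out-of-bag
#' probabilities of presence, and selects the classification threshold
#' where sensitivity equals specificity (computed on out-of-bag
#' probabilities). The fit is deterministic given `config$seed`.
#'
#' @param formula model formula, e.g. `presence ~ .`; the default uses all
#'   15 covariates.
#' @param data FeatureTable data.frame with a `presence` column (0/1) and
#'   the covariates.
#' @param config a [model_config()].
#' @return object of class `habitat_model` with components `forest`,
#'   `oob_p`, `resub_p`, `threshold`, `labels`, `feature_names`, `config`.
#' @export
habitat_model <- function(formula = NULL, data, config = model_config()) {
  if (is.null(formula)) {
    vars <- intersect(covariate_names(), names(data))
  } else {
    tf <- terms(formula, data = data)
    vars <- attr(tf, "term.labels")
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) stop("missing covariates: ",
                                 paste(missing_vars, collapse = ", "))
  X <- data[, vars, drop = FALSE]
  bad <- which(!stats::complete.cases(X))
  if (length(bad)) {
    stop("missing covariate values in cells: ",
         paste(head(data$cell_id[bad] %||% bad, 10), collapse = ", "))
  }
  y <- data$presence
  if (is.null(y)) stop("data must contain a 'presence' column")
  if (length(unique(y)) < 2) stop("degenerate response: only one class present")
  yf <- factor(y, levels = c(0, 1))
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = X, y = yf, ntree = config$n_trees, mtry = config$vars_per_split,
    importance = TRUE, keep.forest = TRUE, keep.inbag = TRUE)
  oob_p <- rf$votes[, "1"]
  resub_p <- predict(rf, X, type = "prob")[, "1"]
  thr <- select_threshold(y, oob_p)
  structure(list(forest = rf, feature_names = vars, config = config,
                 labels = y, oob_p = unname(oob_p), resub_p = unname(resub_p),
                 threshold = thr, data = X,
                 cell_id = data$cell_id %||% seq_along(y)),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("Random-forest habitat model:", x$forest$ntree, "trees,",
      x$forest$mtry, "vars/split,", length(x$labels), "cells (",
      sum(x$labels == 1), "present )\n")
  cat("Threshold (sens = spec, OOB):", round(x$threshold$threshold, 3), "\n")
  invisible(x)
}

#' @export
summary.habitat_model <- function(object, ...) {
  t <- object$threshold$threshold
  out <- list(
    threshold = object$threshold,
    out_of_bag = accuracy_metrics(object$labels, object$oob_p, t,
                                  mode = "out_of_bag"),
    resubstitution = accuracy_metrics(object$labels, object$resub_p, t,
                                      mode = "resubstitution"))
  class(out) <- "summary.habitat_model"
  out
}

#' @export
print.summary.habitat_model <- function(x, ...) {
  cat("Threshold (sens = spec):", round(x$threshold$threshold, 3), "\n\n")
  for (m in c("out_of_bag", "resubstitution")) {
    r <- x[[m]]
    cat(sprintf("%-15s PCC %5.1f  sens %5.1f  spec %5.1f  kappa %5.3f  AUC %5.3f\n",
                m, r$pcc, r$sensitivity, r$specificity, r$kappa, r$auc))
  }
  invisible(x)
}

#' Predict presence probability for new cells
#'
#' @param object a `habitat_model`.
#' @param newdata data.frame with the model covariates; when omitted the
#'   out-of-bag probabilities for the training cells are returned.
#' @param type "prob" for probability of presence, "class" for the 0/1
#'   classification at the fitted threshold.
#' @param ... unused.
#' @return numeric vector of probabilities, or integer 0/1 vector.
#' @export
predict.habitat_model <- function(object, newdata = NULL,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- if (is.null(newdata)) object$oob_p
       else unname(predict(object$forest,
                           newdata[, object$feature_names, drop = FALSE],
                           type = "prob")[, "1"])
  if (type == "prob") p else as.integer(p >= object$threshold$threshold)
}

#' Residuals of the habitat model
#'
#' Response residuals `presence - P` on out-of-bag probabilities.
#' @param object a `habitat_model`.
#' @param ... unused.
#' @export
residuals.habitat_model <- function(object, ...) {
  object$labels - object$oob_p
}

#' Plot variable importance of a fitted habitat model
#'
#' Horizontal bar chart of standardized permutation (accuracy) and Gini
#' importance, ranked by combined score.
#'
#' @param x a `habitat_model`.
#' @param importance optional precomputed [variable_importance()] report.
#' @param ... passed to `barplot`.
#' @export
plot.habitat_model <- function(x, importance = NULL, ...) {
  imp <- importance %||% variable_importance(x, n_permutations = 3)
  imp <- imp[order(imp$combined), ]
  m <- t(as.matrix(imp[, c("acc_std", "gini_std")]))
  colnames(m) <- imp$variable
  barplot(m, beside = TRUE, horiz = TRUE, las = 1,
          col = c("black", "grey70"),
          xlab = "standardized importance", ...)
  legend("bottomright", fill = c("black", "grey70"),
         legend = c("accuracy", "Gini"), bty = "n")
  invisible(imp)
}

#' Classification accuracy metrics
#'
#' Classifies `P >= threshold` as present and reports PCC, sensitivity and
#' specificity (percent), Cohen's kappa (chance-corrected agreement from
#' the confusion-matrix marginals), and AUC (Mann-Whitney rank statistic
#' with midranks for ties).
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param threshold classification cutoff.
#' @param mode evaluation-mode tag carried in the report.
#' @return object of class `accuracy_report`.
#' @export
accuracy_metrics <- function(labels, probabilities, threshold,
                             mode = c("resubstitution", "out_of_bag", "cv10")) {
  mode <- match.arg(mode)
  stopifnot(length(labels) == length(probabilities))
  if (length(labels) == 0) stop("no observations")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  structure(list(pcc = 100 * po,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 kappa = kappa,
                 auc = auc_rank(labels, probabilities),
                 threshold = threshold, n = n, mode = mode,
                 confusion = c(tp = tp, fn = fn, fp = fp, tn = tn)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("[%s] PCC %.1f%%  sens %.1f%%  spec %.1f%%  kappa %.3f  AUC %.3f (t = %.3f, n = %d)\n",
              x$mode, x$pcc, x$sensitivity, x$specificity, x$kappa, x$auc,
              x$threshold, x$n))
  invisible(x)
}

# AUC as the Mann-Whitney statistic with midranks.
auc_rank <- function(labels, probabilities) {
  r <- rank(probabilities)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select the equal-sensitivity/specificity threshold
#'
#' Candidate thresholds are the sorted unique predicted probabilities;
#' the selected threshold minimizes |sensitivity - specificity|, with ties
#' broken toward the smaller threshold (favoring sensitivity).
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities.
#' @return object of class `threshold_result`: threshold, sensitivity,
#'   specificity (percent), and the candidate trace.
#' @export
select_threshold <- function(labels, probabilities) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  cand <- sort(unique(probabilities))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  # classify P >= t: cumulative counts over the sorted candidates
  sens <- vapply(cand, function(t) sum(probabilities >= t & labels == 1), 0) / n1
  spec <- vapply(cand, function(t) sum(probabilities < t & labels == 0), 0) / n0
  gap <- abs(sens - spec)
  i <- which.min(gap)  # which.min takes the first (smallest t) on ties
  structure(list(threshold = cand[i], sensitivity = 100 * sens[i],
                 specificity = 100 * spec[i],
                 trace = data.frame(threshold = cand, sensitivity = 100 * sens,
                                    specificity = 100 * spec)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold %.3f: sensitivity %.1f%%, specificity %.1f%%\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' k-fold cross validation of the habitat model
#'
#' Randomly partitions the cells into `k` near-equal folds (seeded), trains
#' on k-1 folds, and predicts the held-out fold, so every cell is predicted
#' exactly once. The classification threshold is re-derived inside each
#' training set (from its out-of-bag probabilities) to avoid leakage;
#' metrics are computed on the pooled held-out predictions using each
#' fold's own threshold, and a pooled threshold is also reported.
#'
#' @param data FeatureTable with `presence` and covariates.
#' @param config a [model_config()].
#' @param k number of folds (default 10).
#' @return object of class `cv_report`: pooled `accuracy_report`, per-fold
#'   metrics, fold assignment, pooled probabilities, pooled threshold.
#' @export
cross_validate <- function(data, config = model_config(), k = 10) {
  n <- nrow(data)
  if (n < k) stop("need at least k observations")
  vars <- intersect(covariate_names(), names(data))
  y <- data$presence
  set.seed(config$seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  attempt <- 0
  while (any(vapply(seq_len(k), function(f)
    length(unique(y[folds != f])) < 2, logical(1)))) {
    attempt <- attempt + 1
    if (attempt > 50) stop("cannot form folds with both classes in training")
    message("refolding: single-class training fold (attempt ", attempt, ")")
    set.seed(config$seed + 1000 + attempt)
    folds <- sample(rep(seq_len(k), length.out = n))
  }
  pooled_p <- numeric(n)
  pred_class <- integer(n)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    set.seed(config$seed + f)
    rf <- randomForest::randomForest(
      x = data[tr, vars, drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
      ntree = config$n_trees, mtry = config$vars_per_split)
    thr_f <- select_threshold(y[tr], unname(rf$votes[, "1"]))$threshold
    p_hold <- unname(predict(rf, data[!tr, vars, drop = FALSE],
                             type = "prob")[, "1"])
    pooled_p[!tr] <- p_hold
    pred_class[!tr] <- as.integer(p_hold >= thr_f)
    fold_metrics[[f]] <- data.frame(
      fold = f, threshold = thr_f, n = sum(!tr),
      pcc = 100 * mean((p_hold >= thr_f) == (y[!tr] == 1)))
  }
  # pooled confusion using the per-fold thresholds
  tp <- sum(pred_class == 1 & y == 1); fn <- sum(pred_class == 0 & y == 1)
  fp <- sum(pred_class == 1 & y == 0); tn <- sum(pred_class == 0 & y == 0)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  pooled_threshold <- select_threshold(y, pooled_p)$threshold
  pooled <- structure(list(
    pcc = 100 * po,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    kappa = if (pe == 1) 0 else (po - pe) / (1 - pe),
    auc = auc_rank(y, pooled_p),
    threshold = pooled_threshold, n = n, mode = "cv10",
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn)), class = "accuracy_report")
  structure(list(pooled = pooled,
                 per_fold = do.call(rbind, fold_metrics),
                 folds = folds, probabilities = pooled_p,
                 pooled_threshold = pooled_threshold, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$k, "fold cross validation (pooled held-out predictions)\n")
  print(x$pooled)
  invisible(x)
}

#' Permutation and Gini variable importance
#'
#' Accuracy importance is the mean loss in out-of-bag classification
#' accuracy over seeded permutations of each covariate column (out-of-bag
#' rows only, majority vote over the trees not trained on the row); Gini
#' importance is the forest's mean decrease in node impurity. Both are
#' standardized so the top variable scores 1; the combined rank orders
#' variables by the sum of the two standardized scores.
#'
#' @param model a `habitat_model`.
#' @param n_permutations permutations per variable.
#' @return object of class `importance_report` (data.frame with variable,
#'   acc_importance, gini_importance, acc_std, gini_std, combined, rank).
#' @export
variable_importance <- function(model, n_permutations = 10) {
  rf <- model$forest
  X <- model$data
  y <- model$labels
  inbag <- rf$inbag  # rows x trees bootstrap counts
  oob <- inbag == 0
  votes_total <- rowSums(oob)
  oob_acc <- function(Xp) {
    ind <- predict(rf, Xp, predict.all = TRUE)$individual
    votes1 <- rowSums((ind == "1") & oob)
    pred <- as.integer(votes1 / pmax(votes_total, 1) >= 0.5)
    mean(pred[votes_total > 0] == y[votes_total > 0])
  }
  base_acc <- oob_acc(X)
  acc_imp <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    loss <- numeric(n_permutations)
    for (r in seq_len(n_permutations)) {
      set.seed(model$config$seed + 7919 * j + r)
      Xp <- X
      Xp[[j]] <- X[[j]][sample(nrow(X))]
      loss[r] <- base_acc - oob_acc(Xp)
    }
    acc_imp[j] <- mean(loss)
  }
  gini <- rf$importance[, "MeanDecreaseGini"]
  std <- function(v) if (max(v) > 0) v / max(v) else v
  out <- data.frame(variable = colnames(X),
                    acc_importance = acc_imp,
                    gini_importance = unname(gini),
                    acc_std = std(pmax(acc_imp, 0)),
                    gini_std = std(unname(gini)))
  out$combined <- out$acc_std + out$gini_std
  out$rank <- rank(-out$combined, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' @export
print.importance_report <- function(x, ...) {
  df <- as.data.frame(x)
  df[, c("acc_importance", "gini_importance", "acc_std", "gini_std",
         "combined")] <-
    round(df[, c("acc_importance", "gini_importance", "acc_std", "gini_std",
                 "combined")], 4)
  print(df)
  invisible(x)
}
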