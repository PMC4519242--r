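# The classifier surroundings: accuracy metrics, threshold selection,
# cross validation, and variable importance.

# Brute-force oracles ------------------------------------------------------

confusion_oracle <- function(labels, probs, t) {
  pred <- ifelse(probs >= t, 1, 0)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  n <- length(labels)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  list(pcc = 100 * po, sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       kappa = (po - pe) / (1 - pe))
}

auc_pair_oracle <- function(labels, probs) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

test_that("accuracy metrics match hand-computed confusion examples", {
  # TP = 40, FN = 10, FP = 5, TN = 45
  labels <- c(rep(1, 50), rep(0, 50))
  probs <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 5), rep(0.1, 45))
  r <- accuracy_metrics(labels, probs, 0.5)
  expect_equal(r$pcc, 85)
  expect_equal(r$sensitivity, 80)
  expect_equal(r$specificity, 90)
  expect_equal(r$kappa, 0.70)
  # perfect classification
  p2 <- c(rep(1, 50), rep(0, 50))
  r2 <- accuracy_metrics(labels, p2, 0.5)
  expect_equal(r2$pcc, 100)
  expect_equal(r2$kappa, 1)
  expect_equal(r2$auc, 1)
  # AUC with 3 of 4 concordant pairs
  r3 <- accuracy_metrics(c(1, 1, 0, 0), c(0.9, 0.3, 0.5, 0.1), 0.5)
  expect_equal(r3$auc, 0.75)
  expect_error(accuracy_metrics(c(1, 1), c(0.2, 0.3), 0.5), "both classes")
})

test_that("metrics equal brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    probs <- round(runif(n), 2)  # rounding induces ties for the AUC midranks
    t <- runif(1)
    r <- accuracy_metrics(labels, probs, t)
    o <- confusion_oracle(labels, probs, t)
    expect_equal(r$pcc, o$pcc)
    expect_equal(r$sensitivity, o$sens)
    expect_equal(r$specificity, o$spec)
    expect_equal(r$kappa, o$kappa)
    expect_equal(r$auc, auc_pair_oracle(labels, probs))
  }
})

test_that("AUC is invariant to strictly increasing transforms", {
  set.seed(5)
  labels <- sample(0:1, 200, replace = TRUE, prob = c(0.6, 0.4))
  probs <- runif(200)
  a1 <- accuracy_metrics(labels, probs, 0.5)$auc
  a2 <- accuracy_metrics(labels, stats::plogis(5 * probs - 2), 0.5)$auc
  expect_equal(a1, a2)
})

test_that("threshold selection enumerates candidates and favors sensitivity", {
  r <- select_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.2))
  expect_equal(r$threshold, 0.8)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  # symmetric interleaved scores: perfect balance attainable
  r2 <- select_threshold(c(0, 1, 0, 1), c(0.1, 0.4, 0.6, 0.9))
  expect_equal(abs(r2$sensitivity - r2$specificity), 0)
})

test_that("the selected threshold balances sens and spec within 100/min(n1,n0)", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    probs <- runif(n)  # continuous: no cross-class ties
    r <- select_threshold(labels, probs)
    bound <- 100 / min(sum(labels == 1), sum(labels == 0))
    expect_lte(abs(r$sensitivity - r$specificity), bound + 1e-9)
  }
})

test_that("thresholding well-separated data approximates prevalence", {
  land <- default_land()
  m <- default_model()
  frac_present <- mean(m$oob_p >= m$threshold$threshold)
  expect_lt(abs(frac_present - mean(land$table$presence)), 0.05)
})

test_that("the fit is deterministic and rejects degenerate inputs", {
  land <- small_land()
  cfg <- model_config(n_trees = 100, seed = 7)
  m1 <- habitat_model(data = land$table, config = cfg)
  m2 <- habitat_model(data = land$table, config = cfg)
  expect_identical(m1$oob_p, m2$oob_p)
  expect_identical(m1$threshold$threshold, m2$threshold$threshold)
  expect_true(all(m1$oob_p >= 0 & m1$oob_p <= 1))
  bad <- land$table
  bad$presence <- 0
  expect_error(habitat_model(data = bad), "degenerate response")
  bad2 <- land$table
  bad2$Pop_Dens[5] <- NA
  expect_error(habitat_model(data = bad2), "missing covariate values")
})

test_that("permuted labels give chance-level OOB AUC and near-zero kappa", {
  land <- default_land()
  tab <- land$table[seq_len(2000), ]
  set.seed(1)
  tab$presence <- sample(tab$presence)
  m <- habitat_model(data = tab, config = model_config(n_trees = 300, seed = 1))
  auc <- pantherscape:::auc_rank(m$labels, m$oob_p)
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
  r <- accuracy_metrics(m$labels, m$oob_p, m$threshold$threshold,
                        mode = "out_of_bag")
  expect_lt(abs(r$kappa), 0.05)
})

test_that("cross validation partitions the data and stays near OOB accuracy", {
  land <- small_land()
  cfg <- model_config(n_trees = 150, seed = 3)
  cv <- cross_validate(land$table, cfg, k = 10)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(length(cv$probabilities), nrow(land$table))
  expect_true(all(table(cv$folds) >= floor(nrow(land$table) / 10)))
  m <- habitat_model(data = land$table, config = cfg)
  oob_pcc <- accuracy_metrics(m$labels, m$oob_p, m$threshold$threshold,
                              mode = "out_of_bag")$pcc
  expect_lt(abs(cv$pooled$pcc - oob_pcc), 3)
  # leave-one-out partition property on a small subset
  sub <- land$table[sample(seq_len(nrow(land$table)), 20), ]
  if (length(unique(sub$presence)) == 2) {
    cv2 <- cross_validate(sub, model_config(n_trees = 50, seed = 2), k = 20)
    expect_equal(length(cv2$probabilities), 20)
    expect_equal(sort(unique(cv2$folds)), 1:20)
  }
})

test_that("constant covariates get near-zero importance", {
  land <- small_land()
  tab <- land$table
  tab$Water <- 0.2  # constant column
  m <- habitat_model(data = tab, config = model_config(n_trees = 150, seed = 4))
  imp <- variable_importance(m, n_permutations = 2)
  water <- imp[imp$variable == "Water", ]
  expect_lt(abs(water$acc_importance), 1e-6)
  expect_lt(water$gini_std, 0.02)
  expect_equal(max(imp$acc_std), 1)
  expect_equal(max(imp$gini_std), 1)
  expect_setequal(imp$rank, seq_len(nrow(imp)))
})
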