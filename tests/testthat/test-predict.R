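test_that("group centroids are coordinate-wise means", {
  x <- rbind(rep(2, 30), rep(4, 30), rep(6, 30))
  colnames(x) <- panss_items()
  cent <- group_centroids(x, c("A", "A", "B"))
  expect_equal(unname(cent["A", ]), rep(3, 30))
  expect_equal(unname(cent["B", ]), rep(6, 30))  # single patient: own vector
  expect_equal(unname(attr(cent, "sizes")), c(2L, 1L))

  # independent column-mean oracle on a synthetic cohort
  sim <- generate_cohort(default_params(n_patients = 60), seed = 4)
  xs <- panss_matrix(sim$cohort)
  cs <- group_centroids(xs, sim$labels$group)
  for (g in rownames(cs)) {
    oracle <- apply(xs[sim$labels$group == g, , drop = FALSE], 2, mean)
    expect_equal(unname(cs[g, ]), unname(oracle))
  }
  expect_error(group_centroids(xs, rep("unassigned", 60)), "no assigned")
})

test_that("nearest-centroid assignment uses Euclidean distance with tie logging", {
  cent <- rbind(A = rep(2, 30), B = rep(5, 30))
  class(cent) <- c("centroids", class(cent))
  x <- rbind(rep(2, 30), rep(5, 30), rep(3.5, 30))  # third is equidistant
  colnames(x) <- panss_items()
  expect_message(asg <- assign_by_centroid(x, cent), "tie")
  expect_equal(asg$group, c("A", "B", "A"))
  expect_equal(attr(asg, "ties"), 1)
})

test_that("GAF dichotomization is strict at the threshold", {
  expect_false(dichotomize_outcome(65))
  expect_true(dichotomize_outcome(65.1))
  expect_warning(out <- dichotomize_outcome(c(NA_real_, NA_real_)), "missing")
  expect_true(all(is.na(out)))
})

test_that("the penalized logistic model behaves in its limits", {
  # monotone probabilities in a single positive-effect feature
  x <- matrix(seq(-2, 2, length.out = 40), ncol = 1)
  colnames(x) <- "f"
  y <- x[, 1] > 0
  m <- fit_outcome_model(x, y, strength = 1)
  p <- predict_prob(m, x)
  expect_true(all(diff(p) > 0))

  # refitting the same data reproduces the model exactly; under the
  # inverse-penalty convention duplicating every row is equivalent to
  # doubling the regularization strength
  expect_identical(fit_outcome_model(x, y, strength = 1)$coefficients,
                   m$coefficients)
  m2 <- fit_outcome_model(rbind(x, x), c(y, y), strength = 0.5)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-6)

  # saturated-model limit: group indicators recover empirical rates
  set.seed(30)
  n <- 3000
  grp <- sample(c("A", "B", "C"), n, replace = TRUE)
  rate <- c(A = 0.75, B = 0.20, C = 0.35)
  yy <- runif(n) < rate[grp]
  xx <- build_features(matrix(0, n, 30, dimnames = list(NULL, panss_items())),
                       "group_onehot", assignment = grp)
  mm <- fit_outcome_model(xx, yy, strength = 1000)
  for (g in c("A", "B", "C")) {
    onerow <- matrix(0, 1, 3,
                     dimnames = list(NULL, paste0("group_", c("A", "B", "C"))))
    onerow[1, paste0("group_", g)] <- 1
    expect_equal(predict_prob(mm, onerow), mean(yy[grp == g]),
                 tolerance = 0.05)
  }

  expect_error(fit_outcome_model(x, rep(TRUE, 40)), "single class")
})

test_that("evaluation metrics match brute-force confusion arithmetic", {
  # perfect classifier
  y <- c(TRUE, TRUE, FALSE, FALSE)
  rep_perfect <- evaluate_model(c(0.9, 0.8, 0.1, 0.2), y)
  expect_equal(rep_perfect$accuracy, 1)
  expect_equal(rep_perfect$precision, 1)
  expect_equal(rep_perfect$recall, 1)
  expect_equal(rep_perfect$pr_auc, 1)

  # hand-computed confusion: TP=6 FP=3 FN=6 TN=15
  scores <- c(rep(0.9, 6), rep(0.8, 3), rep(0.1, 6), rep(0.2, 15))
  labels <- c(rep(TRUE, 6), rep(FALSE, 3), rep(TRUE, 6), rep(FALSE, 15))
  r <- evaluate_model(scores, labels)
  expect_equal(unname(r$confusion), c(6L, 3L, 6L, 15L))
  expect_equal(r$precision, 6 / 9)
  expect_equal(r$recall, 6 / 12)
  expect_equal(r$accuracy, 21 / 30)

  # always-good classifier: precision and PR-AUC equal prevalence exactly
  y2 <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  always <- evaluate_model(rep(0.99, 5), y2)
  expect_identical(always$precision, mean(y2))
  expect_identical(always$pr_auc, mean(y2))
  expect_identical(always$baseline, mean(y2))

  # exhaustive property over all label sets of size <= 8
  brute <- function(scores, y) {
    pred <- scores >= 0.5
    tp <- sum(pred & y); fp <- sum(pred & !y)
    fn <- sum(!pred & y); tn <- sum(!pred & !y)
    c(acc = (tp + tn) / length(y),
      prec = if (tp + fp == 0) 0 else tp / (tp + fp),
      rec = if (tp + fn == 0) 0 else tp / (tp + fn))
  }
  set.seed(44)
  for (n in 1:8) {
    for (mask in 0:(2^n - 1)) {
      y <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1))
      scores <- round(runif(n), 2)
      r <- evaluate_model(scores, y)
      o <- brute(scores, y)
      expect_identical(r$accuracy, unname(o["acc"]))
      expect_identical(r$precision, unname(o["prec"]))
      expect_identical(r$recall, unname(o["rec"]))
    }
  }
})

test_that("stratified folds partition the patients", {
  set.seed(2)
  y <- runif(37) < 0.4
  folds <- panssmapper:::stratified_folds(y, k = 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(length(folds), 37)
  # each patient in exactly one test fold; classes spread across folds
  expect_true(all(table(folds, y) >= 1))
})

test_that("k-means recovers planted zero-variance clusters and is seeded", {
  x <- rbind(matrix(1, 10, 30), matrix(4, 10, 30), matrix(7, 10, 30))
  colnames(x) <- panss_items()
  lab <- kmeans_partition(x, k = 3, seed = 5)
  expect_equal(length(unique(lab)), 3)
  expect_true(all(tapply(seq_len(30), lab, function(i) {
    nrow(unique(x[i, , drop = FALSE])) == 1
  })))
  expect_identical(kmeans_partition(x, k = 3, seed = 5), lab)

  sim <- generate_cohort(default_params(n_patients = 120), seed = 3)
  xs <- panss_matrix(sim$cohort)
  km <- kmeans_partition(xs, k = 3, seed = 1)
  km_pca <- kmeans_partition(xs, k = 3, on_pca = TRUE, seed = 1)
  # the partitions partly overlap the planted groups: dominant diagonal
  # after best matching
  for (partition in list(km, km_pca)) {
    cp <- compare_partitions(sim$labels$group, partition)
    expect_gt(cp$matched_fraction, 1 / 3)
  }
})

test_that("partition comparison matches the ARI formula oracle", {
  p <- rep(c("A", "B", "C"), each = 10)
  expect_equal(compare_partitions(p, p)$ari, 1)
  expect_equal(compare_partitions(p, rep("X", 30))$ari, 0)

  # direct formula oracle on the diagonal contingency table
  ari_oracle <- function(tab) {
    n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    a <- sum(choose(rowSums(tab), 2)); b <- sum(choose(colSums(tab), 2))
    exp_idx <- a * b / choose(n, 2)
    (sum_ij - exp_idx) / ((a + b) / 2 - exp_idx)
  }
  q <- rep(c("x", "y", "z"), each = 10)
  res <- compare_partitions(p, q)
  expect_equal(res$ari, ari_oracle(table(p, q)), tolerance = 1e-12)
  expect_equal(unname(res$matching), c("x", "y", "z"))
  expect_equal(res$matched_fraction, 1)

  expect_error(compare_partitions(p, q[1:10]), "different patient sets")
})

test_that("the prediction experiment runs both feature sets and schemes", {
  p <- headline_params(n = 80)
  s1 <- generate_cohort(p, seed = 101)
  s2 <- generate_cohort(p, seed = 102, id_prefix = "v")
  x1 <- panss_matrix(s1$cohort); x2 <- panss_matrix(s2$cohort)
  res <- run_prediction_experiment(x1, s1$cohort$gaf, s1$labels$group,
                                   x2, s2$cohort$gaf, s2$labels$group,
                                   predict_config(seed = 7))
  for (feature in c("panss_items", "group_onehot")) {
    for (scheme in c("train_test", "fivefold_cv")) {
      r <- res$reports[[feature]][[scheme]]
      expect_s3_class(r, "prediction_report")
      expect_true(r$pr_auc >= 0 && r$pr_auc <= 1)
      # precision/recall consistent with confusion counts
      cf <- r$confusion
      if (cf["tp"] + cf["fp"] > 0) {
        expect_equal(r$precision, unname(cf["tp"] / (cf["tp"] + cf["fp"])))
      }
    }
  }
  expect_named(res$difference, c("train_test_pr_auc", "fivefold_cv_pr_auc"))
})
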