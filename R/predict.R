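#' Prediction configuration
#'
#' @param gaf_threshold GAF cut for good vs. poor functional outcome:
#'   good is strictly greater than the threshold (default 65).
#' @param regularization_strength Inverse-penalty strength of the
#'   L2-penalized logistic regression (default 1; larger means weaker
#'   penalty, following the inverse-regularization convention of the
#'   standard machine-learning stack).
#' @param feature_set One of `"panss_items"`, `"group_onehot"`,
#'   `"kmeans_onehot"`, `"kmeans_pca_onehot"`.
#' @param scheme `"train_test"` (fit on cohort 1, evaluate on cohort 2)
#'   or `"fivefold_cv"` (label-stratified fivefold cross-validation on
#'   the pooled data).
#' @param seed Integer seed for fold shuffling and k-means.
#' @return A `predict_config` list.
#' @export
predict_config <- function(gaf_threshold = 65, regularization_strength = 1,
                           feature_set = c("panss_items", "group_onehot",
                                           "kmeans_onehot",
                                           "kmeans_pca_onehot"),
                           scheme = c("train_test", "fivefold_cv"),
                           seed = 1L) {
  feature_set <- match.arg(feature_set)
  scheme <- match.arg(scheme)
  if (regularization_strength <= 0) {
    stop("regularization_strength must be > 0", call. = FALSE)
  }
  structure(list(gaf_threshold = gaf_threshold,
                 regularization_strength = regularization_strength,
                 feature_set = feature_set, scheme = scheme,
                 seed = as.integer(seed)),
            class = "predict_config")
}

#' Group centroids in symptom space
#'
#' The centroid of a group is the coordinate-wise mean of its members'
#' 30-item symptom vectors. Unassigned patients are excluded.
#'
#' @param symptoms Symptom matrix, rows aligned with `assignment`.
#' @param assignment A `group_assignment` or label vector.
#' @return A `centroids` object: matrix (groups x items) with group
#'   sizes in the `sizes` attribute.
#' @export
group_centroids <- function(symptoms, assignment) {
  symptoms <- as.matrix(symptoms)
  labels <- assignment_labels(assignment, nrow(symptoms))
  groups <- sort(setdiff(unique(labels), "unassigned"))
  if (length(groups) == 0) stop("no assigned groups", call. = FALSE)
  cent <- t(vapply(groups, function(g) {
    idx <- which(labels == g)
    if (length(idx) == 0) stop("empty group: ", g, call. = FALSE)
    colMeans(symptoms[idx, , drop = FALSE])
  }, numeric(ncol(symptoms))))
  rownames(cent) <- groups
  attr(cent, "sizes") <- vapply(groups, function(g) sum(labels == g),
                                integer(1))
  class(cent) <- c("centroids", class(cent))
  cent
}

#' Nearest-centroid group assignment
#'
#' Assigns each patient to the group whose centroid is closest in raw
#' (unstandardized) Euclidean distance over the 30 PANSS items; this is
#' how a stratification learned in one cohort is replicated in another.
#' Exact ties go to the lexicographically first group label and are
#' counted in the `ties` attribute.
#'
#' @param symptoms Symptom matrix of the cohort to assign.
#' @param centroids A [group_centroids()] result (or plain matrix with
#'   group row names).
#' @return A `group_assignment` tibble.
#' @export
assign_by_centroid <- function(symptoms, centroids) {
  symptoms <- as.matrix(symptoms)
  cent <- unclass(centroids)
  if (nrow(cent) < 2) stop("need centroids for >= 2 groups", call. = FALSE)
  groups <- rownames(cent)
  ord <- order(groups)  # lexicographic tie preference
  d2 <- outer(rowSums(symptoms^2), rep(1, nrow(cent))) -
    2 * symptoms %*% t(cent) +
    outer(rep(1, nrow(symptoms)), rowSums(cent^2))
  d2 <- d2[, ord, drop = FALSE]
  pick <- apply(d2, 1, which.min)
  ties <- sum(apply(d2, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1))
  if (ties > 0) message(ties, " centroid tie(s) resolved to the first label")
  ids <- rownames(symptoms)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(symptoms)))
  out <- tibble::tibble(patient_id = ids, group = groups[ord][pick])
  attr(out, "ties") <- ties
  class(out) <- c("group_assignment", class(out))
  out
}

#' Dichotomize functional outcome at a GAF threshold
#'
#' Good outcome is GAF strictly greater than the threshold; GAF equal
#' to the threshold is poor. Missing GAF yields `NA` (such patients are
#' excluded from prediction by the callers, which log the count).
#'
#' @param gaf Numeric vector of GAF scores.
#' @param threshold Cut point (default 65).
#' @return Logical vector: `TRUE` = good outcome.
#' @export
dichotomize_outcome <- function(gaf, threshold = 65) {
  if (all(is.na(gaf))) warning("all GAF values missing")
  gaf > threshold
}

#' Build a design matrix for outcome prediction
#'
#' @param symptoms Symptom matrix.
#' @param feature_set See [predict_config()].
#' @param assignment Group assignment (required for `group_onehot`);
#'   unassigned patients receive all-zero indicator rows and should be
#'   dropped by the caller.
#' @param kmeans_labels Integer labels (required for the k-means
#'   feature sets).
#' @return Numeric design matrix.
#' @export
build_features <- function(symptoms,
                           feature_set = c("panss_items", "group_onehot",
                                           "kmeans_onehot",
                                           "kmeans_pca_onehot"),
                           assignment = NULL, kmeans_labels = NULL) {
  feature_set <- match.arg(feature_set)
  symptoms <- as.matrix(symptoms)
  if (feature_set == "panss_items") return(symptoms)
  if (feature_set == "group_onehot") {
    labels <- assignment_labels(assignment, nrow(symptoms))
    groups <- sort(setdiff(unique(labels), "unassigned"))
    m <- vapply(groups, function(g) as.numeric(labels == g),
                numeric(nrow(symptoms)))
    colnames(m) <- paste0("group_", groups)
    rownames(m) <- rownames(symptoms)
    return(m)
  }
  if (is.null(kmeans_labels)) stop("kmeans_labels required", call. = FALSE)
  ks <- sort(unique(kmeans_labels))
  m <- vapply(ks, function(k) as.numeric(kmeans_labels == k),
              numeric(nrow(symptoms)))
  colnames(m) <- paste0("cluster_", ks)
  rownames(m) <- rownames(symptoms)
  m
}

#' Fit the L2-penalized logistic outcome model
#'
#' Ridge-penalized logistic regression with unpenalized intercept. The
#' penalty follows the inverse convention: the effective per-observation
#' penalty weight is `1 / (strength * n)`, so strength 1 matches the
#' default of the standard machine-learning stack and large strengths
#' approach the unpenalized fit.
#'
#' @param features Numeric design matrix.
#' @param labels Logical (or 0/1) outcome labels; both classes must be
#'   present.
#' @param strength Inverse regularization strength (> 0).
#' @return An `outcome_model` with `coefficients`, `intercept`, and a
#'   scoring function accessible via [predict_prob()].
#' @export
fit_outcome_model <- function(features, labels, strength = 1) {
  x <- as.matrix(features)
  y <- as.numeric(labels)
  ok <- !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  # the solver requires >= 2 columns; pad one-feature designs with a zero
  # column whose coefficient is necessarily zero under the ridge penalty
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, `.zero_pad` = 0)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 1 / (strength * nrow(x)),
                        standardize = FALSE, thresh = 1e-10, maxit = 1e6)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != ".zero_pad"]
  structure(list(coefficients = beta,
                 intercept = as.numeric(fit$a0),
                 strength = strength, n_train = nrow(x)),
            class = "outcome_model")
}

#' Predicted good-outcome probabilities
#'
#' @param model An `outcome_model`.
#' @param features Design matrix with the model's columns.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(model, features) {
  eta <- as.matrix(features) %*% model$coefficients + model$intercept
  as.numeric(1 / (1 + exp(-eta)))
}

#' Evaluate binary outcome predictions
#'
#' Hard predictions at probability 0.5 give the confusion counts,
#' accuracy, precision (`TP / (TP + FP)`, 0 with a flag when no
#' positive prediction exists) and recall. The precision-recall curve is
#' swept over the unique predicted scores and summarized by average
#' precision (step interpolation: `sum (R_i - R_{i-1}) * P_i`). The
#' baseline is the positive-class prevalence, which is exactly the
#' precision (and average precision) of the classifier that always
#' predicts a good outcome.
#'
#' @param scores Predicted probabilities (or an `outcome_model` plus
#'   `features`).
#' @param labels Logical true labels.
#' @param features Optional design matrix when `scores` is a model.
#' @return A `prediction_report` list.
#' @export
evaluate_model <- function(scores, labels, features = NULL) {
  if (inherits(scores, "outcome_model")) {
    scores <- predict_prob(scores, features)
  }
  ok <- !is.na(labels) & !is.na(scores)
  scores <- scores[ok]; y <- as.logical(labels[ok])
  if (length(y) == 0) stop("empty evaluation set", call. = FALSE)
  pred <- scores >= 0.5
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  precision_flag <- (tp + fp) == 0
  precision <- if (precision_flag) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 0 else tp / (tp + fn)
  accuracy <- (tp + tn) / length(y)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  pr <- t(vapply(thresholds, function(t) {
    p <- scores >= t
    tp_t <- sum(p & y); fp_t <- sum(p & !y)
    c(recall = if (sum(y) == 0) 0 else tp_t / sum(y),
      precision = if (tp_t + fp_t == 0) 1 else tp_t / (tp_t + fp_t))
  }, numeric(2)))
  pr_curve <- tibble::tibble(threshold = thresholds,
                             recall = pr[, "recall"],
                             precision = pr[, "precision"])
  rec <- c(0, pr_curve$recall)
  pr_auc <- sum(diff(rec) * pr_curve$precision)

  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 precision_undefined = precision_flag,
                 pr_curve = pr_curve, pr_auc = pr_auc,
                 baseline = mean(y), n = length(y)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "Prediction report (n = %d): accuracy %.3f, precision %.3f, recall %.3f, PR-AUC %.3f (baseline %.3f)\n",
    x$n, x$accuracy, x$precision, x$recall, x$pr_auc, x$baseline))
  invisible(x)
}

# label-stratified fold indices; every patient lands in exactly one fold
stratified_folds <- function(y, k = 5L, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' k-means partition of the symptom space
#'
#' Lloyd's algorithm with k-means++ initialization and `restarts`
#' seeded restarts, keeping the solution with the lowest within-cluster
#' sum of squares. With `on_pca = TRUE` clustering runs on the
#' two-dimensional principal-component lens coordinates instead of the
#' raw 30-item space.
#'
#' @param symptoms Symptom matrix.
#' @param k Number of clusters (default 3, matching the three patient
#'   groups).
#' @param on_pca Cluster the 2-d PCA scores instead of raw items.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return Integer vector of cluster labels (1..k).
#' @export
kmeans_partition <- function(symptoms, k = 3L, on_pca = FALSE, seed = 1L,
                             restarts = 10L) {
  x <- as.matrix(symptoms)
  if (on_pca) x <- pca_lens(x, dims = 2L)
  if (nrow(x) < k) stop("need at least k rows", call. = FALSE)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_init(x, k)
    km <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  as.integer(best$cluster)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  # duplicate centers (possible on zero-variance data) get a tiny jitter so
  # stats::kmeans accepts them
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(x), sd = 1e-8)
  }
  centers
}

#' Compare two partitions of the same patients
#'
#' Produces the full contingency table, the adjusted Rand index, and
#' the best one-to-one label matching (the permutation of the smaller
#' partition's labels maximizing the matched count).
#'
#' @param p1,p2 Label vectors over the same patients (same length and,
#'   if named, the same names).
#' @return List with `table`, `ari`, `matching` (named vector: label of
#'   `p1` -> best-matching label of `p2`) and `matched_fraction`.
#' @export
compare_partitions <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("partitions cover different patient sets", call. = FALSE)
  }
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!identical(names(p1), names(p2))) {
      if (!setequal(names(p1), names(p2))) {
        stop("partitions cover different patient sets", call. = FALSE)
      }
      p2 <- p2[names(p1)]
    }
  }
  tab <- table(p1, p2)
  ari <- mclust::adjustedRandIndex(p1, p2)
  l1 <- rownames(tab); l2 <- colnames(tab)
  if (length(l1) <= length(l2) && length(l1) <= 7) {
    perms <- all_permutations(seq_along(l2), length(l1))
    scores <- vapply(perms, function(pm) {
      sum(tab[cbind(seq_along(l1), pm)])
    }, numeric(1))
    best <- perms[[which.max(scores)]]
    matching <- stats::setNames(l2[best], l1)
    matched <- max(scores) / sum(tab)
  } else {
    matching <- NULL
    matched <- NA_real_
  }
  list(table = tab, ari = ari, matching = matching,
       matched_fraction = matched)
}

# all injective maps of 1..m into `pool` (m <= length(pool)), as a list
all_permutations <- function(pool, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(pool)) {
    rest <- all_permutations(pool[-i], m - 1)
    out <- c(out, lapply(rest, function(r) c(pool[i], r)))
  }
  out
}

#' Run the paired outcome-prediction experiment
#'
#' Mirrors the replication design: an outcome model is trained on
#' cohort 1 and evaluated on cohort 2 (`train_test`), and additionally
#' under label-stratified fivefold cross-validation on the pooled
#' cohorts (`fivefold_cv`), for both feature sets -- the raw 30 PANSS
#' items and the one-hot group membership. Patients without a GAF score
#' are excluded (counts logged); unassigned patients are excluded from
#' the group-feature models only.
#'
#' @param symptoms1,symptoms2 Symptom matrices of the two cohorts.
#' @param gaf1,gaf2 GAF vectors aligned with the matrices.
#' @param assignment1,assignment2 Group assignments (cohort 2 typically
#'   from [assign_by_centroid()]).
#' @param config A [predict_config()] (its `feature_set` field is
#'   ignored; both are run).
#' @return Nested list `reports[[feature]][[scheme]]` of
#'   `prediction_report`s, plus `excluded` counts.
#' @export
run_prediction_experiment <- function(symptoms1, gaf1, assignment1,
                                      symptoms2, gaf2, assignment2,
                                      config = predict_config()) {
  y1 <- dichotomize_outcome(gaf1, config$gaf_threshold)
  y2 <- dichotomize_outcome(gaf2, config$gaf_threshold)
  lab1 <- assignment_labels(assignment1, nrow(symptoms1))
  lab2 <- assignment_labels(assignment2, nrow(symptoms2))
  excluded <- c(missing_gaf = sum(is.na(c(y1, y2))),
                unassigned = sum(c(lab1, lab2) == "unassigned"))

  reports <- list()
  for (feature in c("panss_items", "group_onehot")) {
    if (feature == "panss_items") {
      x1 <- symptoms1; x2 <- symptoms2
      keep1 <- !is.na(y1); keep2 <- !is.na(y2)
    } else {
      groups <- sort(setdiff(unique(c(lab1, lab2)), "unassigned"))
      onehot <- function(lab) {
        m <- vapply(groups, function(g) as.numeric(lab == g),
                    numeric(length(lab)))
        colnames(m) <- paste0("group_", groups)
        m
      }
      x1 <- onehot(lab1); x2 <- onehot(lab2)
      keep1 <- !is.na(y1) & lab1 != "unassigned"
      keep2 <- !is.na(y2) & lab2 != "unassigned"
    }
    x1k <- as.matrix(x1)[keep1, , drop = FALSE]
    x2k <- as.matrix(x2)[keep2, , drop = FALSE]
    y1k <- y1[keep1]; y2k <- y2[keep2]

    model <- fit_outcome_model(x1k, y1k, config$regularization_strength)
    tt <- evaluate_model(model, y2k, features = x2k)

    xall <- rbind(x1k, x2k)
    yall <- c(y1k, y2k)
    folds <- stratified_folds(yall, k = 5L, seed = config$seed)
    cv_scores <- rep(NA_real_, length(yall))
    for (f in 1:5) {
      tr <- folds != f
      m <- fit_outcome_model(xall[tr, , drop = FALSE], yall[tr],
                             config$regularization_strength)
      cv_scores[!tr] <- predict_prob(m, xall[!tr, , drop = FALSE])
    }
    cv <- evaluate_model(cv_scores, yall)
    reports[[feature]] <- list(train_test = tt, fivefold_cv = cv)
  }
  list(reports = reports, excluded = excluded,
       difference = list(
       train_test_pr_auc = reports$group_onehot$train_test$pr_auc -
         reports$panss_items$train_test$pr_auc,
       fivefold_cv_pr_auc = reports$group_onehot$fivefold_cv$pr_auc -
         reports$panss_items$fivefold_cv$pr_auc))
}
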