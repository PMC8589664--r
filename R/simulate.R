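#' Default parameters for the synthetic cohort generator
#'
#' The defaults encode the study conditions the analysis assumes: three
#' patient groups whose mixing proportions follow the reported group
#' sizes 21/30/43 (out of 94 stratified patients); per-group mean item
#' scores set at the level of the Wallwork factors, with group B highest
#' on positive and excited symptoms, group C highest on negative
#' symptoms, and group A mild throughout; group-linked functional
#' outcomes with A > C > B good-outcome probability; and a metabolite
#' panel in which glutathione peroxidase activity rises A < B < C
#' (means 23.3, 25.5, 28.1 umol/min/gHb) while 2-aminobutyrate falls
#' A > B > C (21.4, 17.9, 16.8 uM). Group-specific correlation structure
#' is planted among the amino acids: an arginine-ornithine-citrulline
#' (urea-cycle) block in group A only, a glutamate hub in group C only,
#' and a glycine-serine correlation shared by all groups.
#'
#' @param n_patients Number of patients to simulate (default 100).
#' @param item_noise_sd Standard deviation of the Gaussian noise added to
#'   the factor-level mean before rounding to the 1-7 item scale
#'   (default 1.0).
#' @param seed Integer seed stored with the parameters (default 1).
#' @return A `generator_params` list; see [generate_cohort()].
#' @export
default_params <- function(n_patients = 100, item_noise_sd = 1.0, seed = 1L) {
  factors <- c("positive", "negative", "disorganized", "excited", "depressed")
  factor_means <- rbind(
    A = c(2.8, 1.8, 2.0, 2.2, 2.0),
    B = c(4.2, 3.5, 3.8, 3.8, 3.0),
    C = c(2.8, 4.0, 3.0, 2.4, 3.2)
  )
  colnames(factor_means) <- factors

  mets <- c("GPx", "GR", "Trx", "GSH", "aminobutyrate_2",
            "glutamate", "glutamine", "glycine", "serine",
            "arginine", "ornithine", "citrulline", "methionine")
  metabolite_means <- rbind(
    A = c(23.3, 7.5, 28, 2.40, 21.4, 60, 550, 230, 110, 80, 60, 30, 25),
    B = c(25.5, 7.5, 28, 2.20, 17.9, 60, 550, 230, 110, 80, 60, 30, 25),
    C = c(28.1, 7.5, 28, 2.30, 16.8, 60, 550, 230, 110, 80, 60, 30, 25)
  )
  colnames(metabolite_means) <- mets
  metabolite_sds <- c(GPx = 8, GR = 2, Trx = 8, GSH = 0.4, aminobutyrate_2 = 5,
                      glutamate = 5, glutamine = 5, glycine = 5, serine = 5,
                      arginine = 5, ornithine = 5, citrulline = 5,
                      methionine = 5)

  base_corr <- diag(length(mets))
  dimnames(base_corr) <- list(mets, mets)
  set_r <- function(m, a, b, r) {
    m[a, b] <- r; m[b, a] <- r; m
  }
  # shared edge in every group
  shared <- set_r(base_corr, "glycine", "serine", 0.6)
  # group A: urea-cycle block
  corr_A <- shared
  for (pair in list(c("arginine", "ornithine"), c("arginine", "citrulline"),
                    c("ornithine", "citrulline"))) {
    corr_A <- set_r(corr_A, pair[1], pair[2], 0.7)
  }
  # group C: correlated amino-acid block around glutamate
  corr_C <- shared
  block <- c("glutamate", "glutamine", "glycine", "serine", "methionine")
  for (a in block) {
    for (b in block) {
      if (a < b && corr_C[a, b] == 0) corr_C <- set_r(corr_C, a, b, 0.5)
    }
  }
  corr_B <- shared

  diagnoses <- c("schizophrenia", "schizophreniform", "brief_psychotic_episode",
                 "other")
  diagnosis_probs <- rbind(
    A = c(0.30, 0.40, 0.20, 0.10),
    B = c(0.80, 0.00, 0.00, 0.20),
    C = c(0.60, 0.15, 0.10, 0.15)
  )
  colnames(diagnosis_probs) <- diagnoses

  params <- list(
    n_patients = as.integer(n_patients),
    group_probs = c(A = 21, B = 30, C = 43) / 94,
    factor_means = factor_means,
    baseline_item_mean = 2.5,
    item_noise_sd = item_noise_sd,
    outcome_good_prob = c(A = 0.75, B = 0.20, C = 0.35),
    gaf_means = c(A = 72, B = 55, C = 60),
    gaf_sds = c(A = 10, B = 10, C = 10),
    metabolite_means = metabolite_means,
    metabolite_sds = metabolite_sds,
    within_group_metabolite_corr = list(A = corr_A, B = corr_B, C = corr_C),
    diagnosis_probs = diagnosis_probs,
    age_mean = 25.1, age_sd = 4.5,
    male_prob = 0.76,
    missing_rate = 0,
    seed = as.integer(seed)
  )
  class(params) <- "generator_params"
  validate_generator_params(params)
  params
}

#' @rdname default_params
#' @param params A `generator_params` list.
#' @export
validate_generator_params <- function(params) {
  p <- params$group_probs
  if (length(p) != 3 || abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
    stop("group_probs must be 3 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  if (params$n_patients < 3) stop("n_patients must be >= 3", call. = FALSE)
  if (params$item_noise_sd < 0) stop("item_noise_sd must be >= 0", call. = FALSE)
  fm <- params$factor_means
  if (any(fm < 1 | fm > 7)) stop("factor means must lie in [1, 7]", call. = FALSE)
  for (g in names(params$within_group_metabolite_corr)) {
    m <- params$within_group_metabolite_corr[[g]]
    if (max(abs(m - t(m))) > 1e-8 || max(abs(diag(m) - 1)) > 1e-12) {
      stop("correlation matrix for group ", g,
           " must be symmetric with unit diagonal", call. = FALSE)
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix for group ", g,
           " is not positive semi-definite", call. = FALSE)
    }
  }
  invisible(params)
}

# Draw n samples from N(0, corr) via eigendecomposition (handles PSD-but-
# singular matrices, unlike plain Cholesky).
rmvn_corr <- function(n, corr) {
  e <- eigen(corr, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(corr)), n, ncol(corr))
  out <- z %*% t(e$vectors %*% diag(sqrt(vals), ncol(corr)))
  colnames(out) <- colnames(corr)
  out
}

#' Generate a synthetic early-psychosis cohort
#'
#' Simulates a cohort with three planted symptom profiles. Group
#' membership is drawn from `group_probs`; each PANSS item score is
#' `clamp(round(factor_mean[group, factor(item)] + N(0, item_noise_sd)), 1, 7)`,
#' where items outside the five Wallwork factors use a shared baseline
#' mean. GAF is drawn from the group's Gaussian and truncated to
#' [0, 100]; `working`, `living_independently` and `remission` are
#' Bernoulli with the group's good-outcome probability; metabolites are
#' multivariate Gaussian with the group's mean vector and planted
#' correlation structure (negative draws clamped at 0). The true group
#' labels are returned separately and never written into the cohort.
#'
#' @param params A `generator_params` list from [default_params()].
#' @param seed Integer seed; defaults to `params$seed`.
#' @param id_prefix Prefix for patient identifiers.
#' @return A list with elements `cohort` (a `cohort_table`) and `labels`
#'   (tibble with `patient_id` and true `group` in A/B/C).
#' @export
generate_cohort <- function(params = default_params(), seed = params$seed,
                            id_prefix = "pt") {
  validate_generator_params(params)
  set.seed(seed)
  n <- params$n_patients
  groups <- sample(names(params$group_probs), n, replace = TRUE,
                   prob = params$group_probs)

  mapping <- wallwork_mapping()
  item_factor <- rep(NA_character_, 30)
  names(item_factor) <- panss_items()
  for (f in names(mapping)) item_factor[mapping[[f]]] <- f

  item_means <- matrix(params$baseline_item_mean, nrow = 3, ncol = 30,
                       dimnames = list(rownames(params$factor_means),
                                       panss_items()))
  for (item in panss_items()) {
    f <- item_factor[[item]]
    if (!is.na(f)) item_means[, item] <- params$factor_means[, f]
  }

  scores <- item_means[groups, , drop = FALSE] +
    matrix(stats::rnorm(n * 30, sd = params$item_noise_sd), n, 30)
  scores <- pmin(pmax(round(scores), 1), 7)

  age <- pmax(stats::rnorm(n, params$age_mean, params$age_sd), 16)
  sex <- ifelse(stats::runif(n) < params$male_prob, "male", "female")
  gaf <- pmin(pmax(stats::rnorm(n, params$gaf_means[groups],
                                params$gaf_sds[groups]), 0), 100)
  sofas <- pmin(pmax(gaf + stats::rnorm(n, 0, 5), 0), 100)
  good_p <- params$outcome_good_prob[groups]
  working <- stats::runif(n) < good_p
  living <- stats::runif(n) < good_p
  remission <- stats::runif(n) < good_p
  diagnosis <- vapply(groups, function(g) {
    sample(colnames(params$diagnosis_probs), 1,
           prob = params$diagnosis_probs[g, ])
  }, character(1))

  mets <- colnames(params$metabolite_means)
  met_values <- matrix(NA_real_, n, length(mets),
                       dimnames = list(NULL, mets))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    z <- rmvn_corr(length(idx), params$within_group_metabolite_corr[[g]])
    draw <- sweep(z, 2, params$metabolite_sds[mets], `*`)
    draw <- sweep(draw, 2, params$metabolite_means[g, mets], `+`)
    met_values[idx, ] <- pmax(draw, 0)
  }

  if (params$missing_rate > 0) {
    for (col in seq_along(mets)) {
      drop <- stats::runif(n) < params$missing_rate
      met_values[drop, col] <- NA_real_
    }
    gaf[stats::runif(n) < params$missing_rate] <- NA_real_
  }

  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  cohort <- tibble::tibble(
    patient_id = ids, age = age, sex = sex, gaf = gaf, sofas = sofas,
    working = working, living_independently = living, remission = remission,
    diagnosis = diagnosis
  )
  cohort <- cbind(cohort[, "patient_id", drop = FALSE],
                  tibble::as_tibble(as.data.frame(scores)),
                  cohort[, -1],
                  tibble::as_tibble(as.data.frame(met_values)))
  list(cohort = as_cohort(cohort),
       labels = tibble::tibble(patient_id = ids, group = groups))
}

#' Geometric fixtures for Mapper validation
#'
#' `generate_circle()` samples points uniformly on the unit circle with
#' isotropic Gaussian noise; `generate_blobs()` samples isotropic
#' Gaussian blobs around given centers. Both are fixtures with known
#' topology (a loop; k separated components) used to validate the Mapper
#' construction.
#'
#' @param n Number of points (circle; must be >= 10).
#' @param noise_sd Isotropic Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return `generate_circle()`: an n x 2 matrix. `generate_blobs()`: a
#'   list with `points` (matrix) and `labels` (integer blob index).
#' @export
generate_circle <- function(n, noise_sd = 0, seed = 1L) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  set.seed(seed)
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(x = cos(theta), y = sin(theta)) +
    matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2)
}

#' @rdname generate_circle
#' @param n_per_blob Points per blob.
#' @param centers Matrix (or list of numeric vectors) of blob centers.
#' @param sd Isotropic standard deviation within each blob.
#' @export
generate_blobs <- function(n_per_blob, centers, sd = 1, seed = 1L) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- as.matrix(centers)
  if (nrow(centers) < 2) stop("need at least 2 centers", call. = FALSE)
  set.seed(seed)
  k <- nrow(centers)
  d <- ncol(centers)
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rep(centers[i, ], each = n_per_blob), n_per_blob, d) +
      matrix(stats::rnorm(n_per_blob * d, sd = sd), n_per_blob, d)
  }))
  colnames(pts) <- paste0("x", seq_len(d))
  list(points = pts, labels = rep(seq_len(k), each = n_per_blob))
}
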