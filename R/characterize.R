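#' Wallwork five-factor item mapping
#'
#' The consensus assignment of PANSS items to the five Wallwork factors:
#' positive (P1, P3, P5, G9), negative (N1, N2, N3, N4, N6, G7),
#' disorganized (P2, N5, G11), excited (P4, P7, G8, G14) and depressed
#' (G2, G3, G6). Ten items (P6, N7, G1, G4, G5, G10, G12, G13, G15,
#' G16) load on no factor. The mapping is exported so every report can
#' state exactly which items were summed.
#'
#' @return Named list of character vectors.
#' @export
wallwork_mapping <- function() {
  list(
    positive     = c("P1", "P3", "P5", "G9"),
    negative     = c("N1", "N2", "N3", "N4", "N6", "G7"),
    disorganized = c("P2", "N5", "G11"),
    excited      = c("P4", "P7", "G8", "G14"),
    depressed    = c("G2", "G3", "G6")
  )
}

#' Wallwork five-factor scores
#'
#' Each factor score is the sum of its constituent item scores (the
#' conventional scale for PANSS subscores), so a factor with m items
#' ranges from m to 7m.
#'
#' @param symptoms A symptom matrix (patients x 30 items) or a
#'   `cohort_table`.
#' @return Tibble with `patient_id` and the five factor-score columns.
#' @export
wallwork_factors <- function(symptoms) {
  if (inherits(symptoms, "cohort_table")) {
    symptoms <- panss_matrix(symptoms, complete_only = FALSE)
  }
  symptoms <- as.matrix(symptoms)
  mapping <- wallwork_mapping()
  ids <- rownames(symptoms)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(symptoms)))
  out <- tibble::tibble(patient_id = ids)
  for (f in names(mapping)) {
    out[[f]] <- rowSums(symptoms[, mapping[[f]], drop = FALSE])
  }
  out
}

# Survival function of the Kolmogorov distribution,
# Q(x) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 x^2), clamped to [0, 1].
kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test on ordinal data
#'
#' Computes `D = max |ECDF_a(x) - ECDF_b(x)|` with both empirical CDFs
#' evaluated at the pooled support, which handles the ties that are
#' inevitable on 1-7 ordinal scores. The two-sided p-value uses the
#' asymptotic Kolmogorov distribution at `sqrt(n_eff) * D` with
#' effective sample size `n_eff = |a||b| / (|a| + |b|)`. With heavy
#' ties the asymptotic p is conservative relative to a tie-aware exact
#' computation; this is the documented behaviour of the classical test
#' on ordinal data.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  support <- sort(unique(c(a, b)))
  ecdf_a <- vapply(support, function(x) mean(a <= x), numeric(1))
  ecdf_b <- vapply(support, function(x) mean(b <= x), numeric(1))
  d <- max(abs(ecdf_a - ecdf_b))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  list(statistic = d, p.value = kolmogorov_sf(sqrt(n_eff) * d))
}

#' Group-specific PANSS items by group-vs-rest KS tests
#'
#' For each of the 30 items and each group, the distribution of the
#' item's scores in the group is compared with its distribution in the
#' pooled remaining groups by the two-sample KS test. P-values are
#' Bonferroni-corrected over the whole family (default: 30 items x
#' number of groups = 90 comparisons; set `family = 30` to correct
#' within each group only) and an item is flagged as group-specific
#' when the corrected p falls below `alpha`. Unassigned patients are
#' excluded.
#'
#' @param symptoms Symptom matrix (patients x 30), rows aligned with
#'   `assignment`.
#' @param assignment A `group_assignment` (or character vector of
#'   labels aligned with the rows of `symptoms`).
#' @param alpha Significance level after correction (default 0.05).
#' @param family Bonferroni family size; `NULL` (default) uses
#'   30 x number of tested groups.
#' @return Tibble: item, group, statistic, p, p_corrected, flag.
#' @export
group_specific_items <- function(symptoms, assignment, alpha = 0.05,
                                 family = NULL) {
  labels <- assignment_labels(assignment, nrow(symptoms))
  keep <- labels != "unassigned"
  symptoms <- as.matrix(symptoms)[keep, , drop = FALSE]
  labels <- labels[keep]
  groups <- sort(unique(labels))
  groups <- groups[vapply(groups, function(g) sum(labels == g) >= 2,
                          logical(1))]
  skipped <- setdiff(sort(unique(labels)), groups)
  if (length(skipped)) {
    warning("group(s) with < 2 members skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(groups) < 2) stop("need >= 2 groups with >= 2 members each",
                               call. = FALSE)
  if (is.null(family)) family <- 30L * length(groups)
  rows <- list()
  for (item in panss_items()) {
    for (g in groups) {
      ks <- ks_two_sample(symptoms[labels == g, item],
                          symptoms[labels != g, item])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        item = item, group = g, statistic = ks$statistic, p = ks$p.value,
        p_corrected = min(1, ks$p.value * family))
    }
  }
  out <- do.call(rbind, rows)
  out$flag <- out$p_corrected < alpha
  attr(out, "family") <- family
  out
}

assignment_labels <- function(assignment, n) {
  if (is.data.frame(assignment)) {
    labels <- assignment$group
  } else {
    labels <- as.character(assignment)
  }
  if (length(labels) != n) {
    stop("assignment length does not match the number of patients",
         call. = FALSE)
  }
  labels
}

#' Compare outcomes across groups
#'
#' Categorical outcomes (`working`, `living_independently`, `remission`,
#' `diagnosis`) are tested with the chi-square test of independence on
#' the group x category table (no continuity correction); continuous
#' outcomes (`gaf`, `sofas`, and the five Wallwork factor scores) with
#' one-way ANOVA across groups plus pairwise two-sample t-tests (equal
#' variances). Per-group effect summaries (proportions or mean and
#' standard error) accompany every test. Unassigned patients are
#' excluded; outcomes that are entirely missing are skipped with a
#' warning.
#'
#' @param cohort A `cohort_table`.
#' @param assignment A `group_assignment` aligned with `cohort` by
#'   `patient_id`.
#' @param alpha Flagging threshold (default 0.05).
#' @return List with `categorical` (tibble: outcome, statistic, df, p,
#'   flag), `continuous` (tibble: outcome, anova F, p, flag),
#'   `pairwise` (tibble of pairwise t-tests), and `group_summary`
#'   (per-group means/proportions with standard errors).
#' @export
compare_outcomes <- function(cohort, assignment, alpha = 0.05) {
  labels <- assignment$group[match(cohort$patient_id, assignment$patient_id)]
  keep <- !is.na(labels) & labels != "unassigned"
  data <- cohort[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop("need outcomes for at least 2 groups", call. = FALSE)
  }
  fs <- wallwork_factors(data)
  for (f in setdiff(names(fs), "patient_id")) data[[f]] <- fs[[f]]

  cat_rows <- list(); cont_rows <- list(); pair_rows <- list()
  summ_rows <- list()

  for (outcome in c("working", "living_independently", "remission",
                    "diagnosis")) {
    if (!outcome %in% names(data)) next
    v <- data[[outcome]]
    if (all(is.na(v))) { warning("outcome ", outcome, " all missing; skipped"); next }
    tab <- table(labels[!is.na(v)], v[!is.na(v)])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    cat_rows[[outcome]] <- tibble::tibble(
      outcome = outcome, statistic = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value, flag = ct$p.value < alpha)
    if (is.logical(v)) {
      for (g in sort(unique(labels))) {
        vg <- v[labels == g & !is.na(v)]
        summ_rows[[paste(outcome, g)]] <- tibble::tibble(
          outcome = outcome, group = g, n = length(vg),
          estimate = mean(vg), se = stats::sd(vg) / sqrt(length(vg)))
      }
    }
  }

  for (outcome in c("gaf", "sofas", "positive", "negative", "disorganized",
                    "excited", "depressed")) {
    if (!outcome %in% names(data)) next
    v <- data[[outcome]]
    if (all(is.na(v))) { warning("outcome ", outcome, " all missing; skipped"); next }
    ok <- !is.na(v)
    fit <- stats::aov(v[ok] ~ factor(labels[ok]))
    an <- summary(fit)[[1]]
    cont_rows[[outcome]] <- tibble::tibble(
      outcome = outcome, statistic = an[["F value"]][1],
      df1 = an[["Df"]][1], df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1],
      flag = an[["Pr(>F)"]][1] < alpha)
    gs <- sort(unique(labels))
    for (g in gs) {
      vg <- v[labels == g & ok]
      summ_rows[[paste(outcome, g)]] <- tibble::tibble(
        outcome = outcome, group = g, n = length(vg),
        estimate = mean(vg), se = stats::sd(vg) / sqrt(length(vg)))
    }
    for (i in seq_along(gs)) {
      for (j in seq_along(gs)) {
        if (i >= j) next
        vi <- v[labels == gs[i] & ok]; vj <- v[labels == gs[j] & ok]
        if (stats::var(vi) == 0 && stats::var(vj) == 0) {
          # degenerate samples with zero pooled variance: report the mean
          # difference without a test
          pair_rows[[paste(outcome, gs[i], gs[j])]] <- tibble::tibble(
            outcome = outcome, group1 = gs[i], group2 = gs[j],
            estimate = mean(vi) - mean(vj), statistic = NA_real_,
            p = NA_real_, flag = FALSE)
          next
        }
        tt <- stats::t.test(vi, vj, var.equal = TRUE)
        pair_rows[[paste(outcome, gs[i], gs[j])]] <- tibble::tibble(
          outcome = outcome, group1 = gs[i], group2 = gs[j],
          estimate = unname(diff(rev(tt$estimate))),
          statistic = unname(tt$statistic), p = tt$p.value,
          flag = tt$p.value < alpha)
      }
    }
  }

  list(categorical = do.call(rbind, unname(cat_rows)),
       continuous = do.call(rbind, unname(cont_rows)),
       pairwise = do.call(rbind, unname(pair_rows)),
       group_summary = do.call(rbind, unname(summ_rows)))
}
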