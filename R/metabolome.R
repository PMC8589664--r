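#' Covariate-adjusted group contrast for one metabolite
#'
#' Ordinary least squares of `metabolite ~ group + age + sex` (sex coded
#' female = 1), followed by all pairwise group contrasts with t-tests on
#' the coefficient differences. Complete-case analysis: patients missing
#' the metabolite, age or sex are dropped and the count reported.
#'
#' @param cohort A `cohort_table` containing the metabolite column plus
#'   `age` and `sex`.
#' @param assignment Group assignment aligned by `patient_id`.
#' @param metabolite Name of the metabolite column.
#' @return Tibble of pairwise contrasts: group1, group2, estimate
#'   (mean difference group1 - group2, adjusted), se, statistic, df, p;
#'   attributes `n_used`, `n_dropped` and `fit` (the `lm` object).
#' @export
adjusted_group_contrast <- function(cohort, assignment, metabolite) {
  if (!metabolite %in% names(cohort)) {
    stop("metabolite column not found: ", metabolite, call. = FALSE)
  }
  labels <- assignment$group[match(cohort$patient_id, assignment$patient_id)]
  df <- data.frame(y = cohort[[metabolite]],
                   group = labels,
                   age = cohort$age,
                   sex = as.numeric(cohort$sex == "female"))
  df <- df[!is.na(df$group) & df$group != "unassigned", , drop = FALSE]
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  groups <- sort(unique(df$group))
  sizes <- table(df$group)
  if (length(groups) < 2 || any(sizes < 3)) {
    stop("need >= 2 groups with >= 3 measured members each", call. = FALSE)
  }
  df$group <- factor(df$group, levels = groups)
  fit <- stats::lm(y ~ group + age + sex, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  rdf <- fit$df.residual
  # coefficient vector picking out the adjusted mean of group g
  coef_vec <- function(g) {
    v <- stats::setNames(numeric(length(cf)), names(cf))
    if (g != groups[1]) v[paste0("group", g)] <- 1
    v
  }
  rows <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i >= j) next
      v <- coef_vec(groups[i]) - coef_vec(groups[j])
      est <- sum(v * cf)
      se <- sqrt(drop(t(v) %*% vc %*% v))
      tstat <- est / se
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = metabolite, group1 = groups[i], group2 = groups[j],
        estimate = est, se = se, statistic = tstat, df = rdf,
        p = 2 * stats::pt(-abs(tstat), rdf))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- nrow(df)
  attr(out, "n_dropped") <- n0 - nrow(df)
  attr(out, "fit") <- fit
  out
}

#' Pearson correlation with significance
#'
#' Product-moment correlation on complete pairs; the two-sided p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors (>= 3 complete pairs, nonzero variance).
#' @return List with `r`, `p.value` and `n` (complete pairs used).
#' @export
pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in one of the samples", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = n)
}

#' Within-group metabolite correlation network
#'
#' Tests every unordered metabolite pair within one patient group;
#' pairs whose Pearson correlation differs significantly from zero
#' (raw p below `alpha`; the threshold is deliberately uncorrected,
#' matching the exploratory convention for such networks, with an
#' optional Benjamini-Hochberg filter via `use_fdr`) become network
#' edges. Missing values are handled by pairwise deletion; the n used
#' is recorded per edge.
#'
#' @param cohort A `cohort_table` with metabolite columns.
#' @param assignment Group assignment aligned by `patient_id`.
#' @param group Group label to analyse.
#' @param alpha Edge threshold on p (default 0.05).
#' @param metabolites Metabolite columns (default: all).
#' @param use_fdr Threshold Benjamini-Hochberg-adjusted p instead of
#'   raw p.
#' @return A `correlation_network`: list with `group`, `edges` tibble
#'   (metabolite pair in lexicographic order, r, p, n), full `r_matrix`
#'   and `p_matrix`, `alpha`, `n_members`.
#' @export
correlation_network <- function(cohort, assignment, group, alpha = 0.05,
                                metabolites = NULL, use_fdr = FALSE) {
  if (is.null(metabolites)) metabolites <- metabolite_names(cohort)
  if (length(metabolites) < 2) stop("need >= 2 metabolites", call. = FALSE)
  labels <- assignment$group[match(cohort$patient_id, assignment$patient_id)]
  members <- which(!is.na(labels) & labels == group)
  panel <- as.matrix(cohort[members, metabolites, drop = FALSE])
  measured <- rowSums(!is.na(panel)) > 0
  if (sum(measured) < 4) {
    stop("group ", group, " has fewer than 4 members with panel data",
         call. = FALSE)
  }
  m <- length(metabolites)
  r_mat <- diag(1, m); p_mat <- matrix(NA_real_, m, m)
  dimnames(r_mat) <- dimnames(p_mat) <- list(metabolites, metabolites)
  diag(p_mat) <- 0
  rows <- list()
  ord <- order(metabolites)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a >= b) next
      x <- panel[, a]; y <- panel[, b]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
        r_mat[a, b] <- r_mat[b, a] <- NA_real_
        next
      }
      res <- pearson_with_p(x, y)
      r_mat[a, b] <- r_mat[b, a] <- res$r
      p_mat[a, b] <- p_mat[b, a] <- res$p.value
      pair <- sort(c(metabolites[a], metabolites[b]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite1 = pair[1], metabolite2 = pair[2],
        r = res$r, p = res$p.value, n = res$n)
    }
  }
  all_pairs <- do.call(rbind, rows)
  if (!is.null(all_pairs)) {
    all_pairs$p_fdr <- stats::p.adjust(all_pairs$p, method = "BH")
    keep <- if (use_fdr) all_pairs$p_fdr < alpha else all_pairs$p < alpha
    edges <- all_pairs[keep, , drop = FALSE]
    edges <- edges[order(edges$metabolite1, edges$metabolite2), , drop = FALSE]
  } else {
    edges <- tibble::tibble(metabolite1 = character(0),
                            metabolite2 = character(0), r = numeric(0),
                            p = numeric(0), n = integer(0),
                            p_fdr = numeric(0))
  }
  structure(list(group = group, edges = edges, r_matrix = r_mat,
                 p_matrix = p_mat, alpha = alpha,
                 n_members = sum(measured), use_fdr = use_fdr),
            class = "correlation_network")
}

#' Classify correlation edges by the groups in which they appear
#'
#' Takes one correlation network per group (all over the same
#' metabolite panel) and labels every edge found in at least one group
#' with the exact set of groups containing it -- the set-valued color
#' legend of a multi-group correlation figure ({A}, {B}, {C}, {A,C},
#' and so on).
#'
#' @param networks Named list of `correlation_network`s (names =
#'   group labels; defaults to each network's own `group` field).
#' @return Tibble: metabolite1, metabolite2, `groups`
#'   (comma-separated sorted labels) and one logical column per group.
#' @export
classify_edges_by_group <- function(networks) {
  if (length(networks) < 2) stop("need >= 2 networks", call. = FALSE)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- vapply(networks, function(nw) nw$group, character(1))
  }
  mets <- lapply(networks, function(nw) rownames(nw$r_matrix))
  if (length(unique(lapply(mets, sort))) != 1) {
    stop("networks cover different metabolite sets", call. = FALSE)
  }
  edge_keys <- lapply(networks, function(nw) {
    if (nrow(nw$edges) == 0) return(character(0))
    paste(nw$edges$metabolite1, nw$edges$metabolite2, sep = "\r")
  })
  all_keys <- sort(unique(unlist(edge_keys, use.names = FALSE)))
  if (length(all_keys) == 0) {
    return(tibble::tibble(metabolite1 = character(0),
                          metabolite2 = character(0),
                          groups = character(0)))
  }
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- tibble::tibble(metabolite1 = parts[, 1], metabolite2 = parts[, 2])
  present <- vapply(names(networks), function(g) all_keys %in% edge_keys[[g]],
                    logical(length(all_keys)))
  present <- matrix(present, nrow = length(all_keys),
                    dimnames = list(NULL, names(networks)))
  out$groups <- apply(present, 1, function(row) {
    paste(sort(colnames(present)[row]), collapse = ",")
  })
  for (g in colnames(present)) out[[paste0("in_", g)]] <- present[, g]
  out
}
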