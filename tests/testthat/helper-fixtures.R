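# Shared fixtures, all built in code.

# A tiny hand-written cohort: 3 patients with distinct, non-constant
# symptom vectors and complete outcomes.
tiny_cohort <- function() {
  items <- panss_items()
  base <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                         age = c(24, 31, 19.5),
                         sex = c("male", "female", "male"),
                         gaf = c(70, 55, NA),
                         sofas = c(68, 50, 61),
                         working = c(TRUE, FALSE, NA),
                         living_independently = c(TRUE, FALSE, TRUE),
                         remission = c(TRUE, FALSE, FALSE),
                         diagnosis = c("schizophreniform", "schizophrenia", NA))
  scores <- rbind(rep(c(1L, 2L), 15),
                  rep(c(3L, 5L), 15),
                  rep(c(2L, 4L, 6L), 10))
  colnames(scores) <- items
  out <- cbind(base[, "patient_id", drop = FALSE],
               tibble::as_tibble(as.data.frame(scores)), base[, -1])
  as_cohort(out)
}

# A symptom matrix with three noise-free planted profiles, useful when a
# deterministic, perfectly separable stratification input is needed.
planted_symptoms <- function(n_per_group = 10) {
  p <- default_params(item_noise_sd = 0)
  sim <- generate_cohort_raw_profiles(p, n_per_group)
  sim
}

generate_cohort_raw_profiles <- function(p, n_per_group) {
  mapping <- wallwork_mapping()
  item_means <- matrix(p$baseline_item_mean, 3, 30,
                       dimnames = list(c("A", "B", "C"), panss_items()))
  for (f in names(mapping)) {
    item_means[, mapping[[f]]] <- p$factor_means[, f]
  }
  profiles <- pmin(pmax(round(item_means), 1), 7)
  x <- profiles[rep(c("A", "B", "C"), each = n_per_group), ]
  rownames(x) <- sprintf("pt%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(c("A", "B", "C"), each = n_per_group))
}

# Build a mapper_graph by hand from a list of member-index vectors and an
# explicit edge list; nerve consistency is the caller's responsibility.
toy_graph <- function(nodes, n, edges = NULL) {
  ids <- sprintf("n%d", seq_along(nodes))
  if (is.null(edges)) {
    edges <- panssmapper:::nerve_edges(nodes, ids, n)
  } else {
    edges <- tibble::tibble(from = ids[edges[, 1]], to = ids[edges[, 2]],
                            shared = rep(1L, nrow(edges)))
  }
  panssmapper:::new_mapper_graph(
    nodes = nodes,
    node_info = tibble::tibble(node = ids,
                               rectangle = seq_along(nodes),
                               cluster = 1L, size = lengths(nodes)),
    edges = edges, n = n, patient_ids = as.character(seq_len(n)),
    lens = NULL, config = mapper_config())
}

# Parameters of the outcome-prediction experiment: generator defaults
# (noisy items, recoverable groups) with the GAF means set so that the
# good-outcome probabilities are exactly (0.75, 0.20, 0.35) and the
# outcome depends on the true group only.
headline_params <- function(n = 100) {
  p <- default_params(n_patients = n)
  p$gaf_means[] <- 65 + stats::qnorm(c(0.75, 0.20, 0.35)) * 10
  p
}
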