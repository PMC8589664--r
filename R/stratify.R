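#' Stratification configuration
#'
#' @param min_component_patients Components of the Mapper graph whose
#'   distinct-patient count falls below this threshold are excluded and
#'   their patients left unassigned (default 5, which removes isolated
#'   fragments the size of the ones excluded in practice while keeping
#'   real groups).
#' @param n_groups Number of patient groups to extract (default 3).
#' @param split_method How to split a connected component that must be
#'   divided: `"fast_greedy"` (default) cuts the modularity dendrogram
#'   into exactly k parts, which is deterministic and fast enough for
#'   the dense graphs produced at the standard resolution and gain;
#'   `"edge_betweenness"` removes highest-betweenness edges until the
#'   component falls apart (deterministic tie-break: lexicographically
#'   smallest edge) and is intended for small graphs, since its cost
#'   grows quickly with edge count; `"manual"` uses `manual_cut`.
#' @param manual_cut A list of node-id character vectors that partition
#'   the component to split (only with `split_method = "manual"`).
#' @return A `stratify_config` list.
#' @export
stratify_config <- function(min_component_patients = 5L, n_groups = 3L,
                            split_method = c("fast_greedy",
                                             "edge_betweenness", "manual"),
                            manual_cut = NULL) {
  split_method <- match.arg(split_method)
  if (min_component_patients < 1) stop("min_component_patients must be >= 1",
                                       call. = FALSE)
  if (n_groups < 1) stop("n_groups must be >= 1", call. = FALSE)
  structure(list(min_component_patients = as.integer(min_component_patients),
                 n_groups = as.integer(n_groups),
                 split_method = split_method, manual_cut = manual_cut),
            class = "stratify_config")
}

#' Connected components of a Mapper graph, with small ones excluded
#'
#' Components are measured by their distinct-patient count; those below
#' `min_component_patients` are excluded (their patients end up
#' unassigned, mirroring the handling of isolated nodes). Retained
#' components are ordered by descending patient count.
#'
#' @param graph A `mapper_graph`.
#' @param min_component_patients Exclusion threshold.
#' @return List with `retained` (list of node-id character vectors,
#'   largest first), `excluded_nodes` (character vector), and
#'   `component` (named integer: component index per node).
#' @export
extract_components <- function(graph, min_component_patients = 5L) {
  if (length(graph$nodes) == 0) stop("empty graph", call. = FALSE)
  ig <- mapper_igraph(graph)
  comp <- igraph::components(ig)
  membership <- comp$membership
  node_ids <- graph$node_info$node
  node_index <- match(names(membership), node_ids)
  patients_of_comp <- function(ci) {
    unique(unlist(graph$nodes[node_index[membership == ci]], use.names = FALSE))
  }
  comp_ids <- seq_len(comp$no)
  patient_counts <- vapply(comp_ids, function(ci) length(patients_of_comp(ci)),
                           integer(1))
  keep <- comp_ids[patient_counts >= min_component_patients]
  keep <- keep[order(-patient_counts[keep], keep)]
  retained <- lapply(keep, function(ci) names(membership)[membership == ci])
  excluded <- names(membership)[membership %in% setdiff(comp_ids, keep)]
  list(retained = retained, excluded_nodes = excluded,
       component = membership)
}

#' Split a connected component of the Mapper graph into k parts
#'
#' With `method = "fast_greedy"` (default) the modularity dendrogram of
#' the component is cut into exactly k communities. With
#' `method = "edge_betweenness"` the highest-betweenness edge is
#' removed repeatedly (recomputing betweenness after each removal,
#' breaking ties by the lexicographically smallest edge) until the
#' component has k connected parts; exact but only practical on small
#' graphs. With `method = "manual"` the supplied node sets are
#' validated as a partition of the component and returned unchanged.
#' Parts are returned ordered by descending distinct-patient count.
#'
#' @param graph A `mapper_graph`.
#' @param component Character vector of node ids forming one connected
#'   component.
#' @param k Number of parts (>= 2).
#' @param method `"fast_greedy"`, `"edge_betweenness"` or `"manual"`.
#' @param manual_cut List of node-id vectors (for `"manual"`).
#' @return List of k character vectors of node ids.
#' @export
split_component <- function(graph, component, k = 2L,
                            method = c("fast_greedy", "edge_betweenness",
                                       "manual"),
                            manual_cut = NULL) {
  method <- match.arg(method)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(component)) {
    stop("cannot split ", length(component), " nodes into ", k, " parts",
         call. = FALSE)
  }
  if (method == "manual") {
    if (is.null(manual_cut)) stop("manual_cut required", call. = FALSE)
    flat <- unlist(manual_cut, use.names = FALSE)
    if (anyDuplicated(flat) || !setequal(flat, component)) {
      stop("manual_cut is not a partition of the component", call. = FALSE)
    }
    return(manual_cut)
  }
  ig <- igraph::induced_subgraph(mapper_igraph(graph), vids = component)
  if (method == "fast_greedy") {
    fg <- igraph::cluster_fast_greedy(ig, weights = NULL)
    memb <- igraph::cut_at(fg, no = k)
    names(memb) <- igraph::V(ig)$name
  } else {
    while (igraph::components(ig)$no < k) {
      eb <- igraph::edge_betweenness(ig, directed = FALSE, weights = NA)
      top <- which(eb == max(eb))
      if (length(top) > 1) {
        ends <- igraph::ends(ig, igraph::E(ig)[top])
        key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
                     sep = "\r")
        top <- top[order(key)][1]
      }
      ig <- igraph::delete_edges(ig, igraph::E(ig)[top])
    }
    memb <- igraph::components(ig)$membership
  }
  parts <- split(names(memb), memb)
  sizes <- vapply(parts, function(p) component_patient_count(graph, p),
                  integer(1))
  unname(parts[order(-sizes)])
}

component_patient_count <- function(graph, node_set) {
  idx <- match(node_set, graph$node_info$node)
  length(unique(unlist(graph$nodes[idx], use.names = FALSE)))
}

#' Assign patients to groups by node-majority vote
#'
#' A patient may belong to several Mapper nodes. The patient's group is
#' the label carried by the majority of the labeled nodes containing the
#' patient; an exact tie, or membership only in excluded (unlabeled)
#' nodes, leaves the patient unassigned.
#'
#' @param graph A `mapper_graph`.
#' @param node_groups Named character vector: node id -> group label.
#'   Nodes absent from the vector are treated as excluded.
#' @return A `group_assignment` tibble with columns `patient_id` and
#'   `group` (a planted label or `"unassigned"`); the node ids
#'   contributing to each patient are stored in the `provenance`
#'   attribute.
#' @export
assign_patients <- function(graph, node_groups) {
  by_patient <- node_membership_by_patient(graph)
  labels <- rep("unassigned", graph$n)
  provenance <- vector("list", graph$n)
  node_ids <- graph$node_info$node
  for (pi_chr in names(by_patient)) {
    pi <- as.integer(pi_chr)
    nidx <- by_patient[[pi_chr]]
    ids <- node_ids[nidx]
    provenance[[pi]] <- ids
    lab <- node_groups[ids[ids %in% names(node_groups)]]
    if (length(lab) == 0) next
    tab <- sort(table(lab), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next  # exact tie
    labels[pi] <- names(tab)[1]
  }
  out <- tibble::tibble(patient_id = graph$patient_ids, group = labels)
  attr(out, "provenance") <- stats::setNames(provenance, graph$patient_ids)
  class(out) <- c("group_assignment", class(out))
  out
}

#' Stratify a cohort from its Mapper graph
#'
#' End-to-end grouping: connected components are extracted and small
#' ones excluded; if fewer retained components than `n_groups` exist,
#' the largest part is split (by edge betweenness, or manually) until
#' `n_groups` parts remain; if more, only the `n_groups` largest are
#' kept and the rest left unassigned, with a warning. Groups are then
#' named by descending mean positive-factor score of their patients --
#' `B` (highest positive symptoms), then `C`, then `A` -- with ties on
#' the positive factor broken by descending negative-factor mean, so
#' that labels are anchored to symptom content and comparable across
#' cohorts. Finally patients are assigned by node-majority vote.
#'
#' @param graph A `mapper_graph`.
#' @param symptoms The symptom matrix the graph was built from (used to
#'   name groups by factor content).
#' @param config A [stratify_config()].
#' @return A `group_assignment` tibble (see [assign_patients()]); the
#'   node labeling is stored in the `node_groups` attribute.
#' @export
stratify_groups <- function(graph, symptoms, config = stratify_config()) {
  comp <- extract_components(graph, config$min_component_patients)
  parts <- comp$retained
  if (length(parts) == 0) {
    warning("no component meets min_component_patients; all patients unassigned")
    out <- tibble::tibble(patient_id = graph$patient_ids,
                          group = rep("unassigned", graph$n))
    class(out) <- c("group_assignment", class(out))
    return(out)
  }
  if (length(parts) > config$n_groups) {
    warning(length(parts), " components retained but n_groups = ",
            config$n_groups, "; smallest components left unassigned")
    parts <- parts[seq_len(config$n_groups)]
  }
  while (length(parts) < config$n_groups) {
    sizes <- vapply(parts, function(p) component_patient_count(graph, p),
                    integer(1))
    splittable <- which(vapply(parts, length, integer(1)) >= 2)
    if (length(splittable) == 0) {
      warning("cannot reach n_groups = ", config$n_groups,
              "; no component has >= 2 nodes left to split")
      break
    }
    target <- splittable[which.max(sizes[splittable])]
    # cut the largest part into as many pieces as still needed, bounded by
    # its node count
    k_cut <- min(config$n_groups - length(parts) + 1L,
                 length(parts[[target]]))
    pieces <- split_component(graph, parts[[target]], k = k_cut,
                              method = config$split_method,
                              manual_cut = config$manual_cut)
    parts <- c(parts[-target], pieces)
  }
  node_groups <- name_groups(graph, symptoms, parts)
  out <- assign_patients(graph, node_groups)
  attr(out, "node_groups") <- node_groups
  out
}

# Label node-set parts by symptom content: descending mean positive-factor
# score -> B, C, A (ties broken by descending negative-factor mean).
name_groups <- function(graph, symptoms, parts) {
  fs <- wallwork_factors(symptoms)
  pos <- fs$positive
  neg <- fs$negative
  stats_of <- function(node_set) {
    idx <- match(node_set, graph$node_info$node)
    pts <- unique(unlist(graph$nodes[idx], use.names = FALSE))
    c(pos = mean(pos[pts]), neg = mean(neg[pts]))
  }
  profile <- t(vapply(parts, stats_of, numeric(2)))
  ord <- order(-profile[, "pos"], -profile[, "neg"])
  label_scheme <- if (length(parts) == 3) c("B", "C", "A") else
    paste0("G", seq_along(parts))
  node_groups <- character(0)
  for (j in seq_along(ord)) {
    p <- parts[[ord[j]]]
    node_groups[p] <- label_scheme[j]
  }
  node_groups
}

#' Sensitivity of the stratification to the B/C boundary
#'
#' Identifies boundary nodes (nodes of one group adjacent to the other)
#' between two groups and flips each one's label in turn, recomputing
#' the patient assignment, the per-group mean Wallwork factor profile,
#' and (when a cohort is supplied) the per-group mean GAF. The base
#' (unflipped) configuration is always the first row.
#'
#' @param graph A `mapper_graph`.
#' @param node_groups Named character vector of node labels (e.g. the
#'   `node_groups` attribute of [stratify_groups()]).
#' @param symptoms Symptom matrix for factor profiles.
#' @param cohort Optional `cohort_table` for outcome summaries.
#' @param groups Length-2 character vector: the boundary to probe
#'   (default `c("B", "C")`).
#' @param shift Maximum number of boundary nodes to flip (each flipped
#'   alone); 0 returns only the base row.
#' @return A tibble with one row per configuration (base first):
#'   flipped node, its old and new label, group sizes, per-group factor
#'   means and mean GAF. The full assignments are attached as the
#'   `assignments` attribute.
#' @export
boundary_sensitivity <- function(graph, node_groups, symptoms, cohort = NULL,
                                 groups = c("B", "C"), shift = Inf) {
  ig <- mapper_igraph(graph)
  ends <- igraph::as_edgelist(ig)
  lab <- function(v) ifelse(v %in% names(node_groups), node_groups[v], NA)
  l1 <- lab(ends[, 1]); l2 <- lab(ends[, 2])
  cross <- !is.na(l1) & !is.na(l2) &
    ((l1 == groups[1] & l2 == groups[2]) | (l1 == groups[2] & l2 == groups[1]))
  boundary_nodes <- sort(unique(c(ends[cross, 1], ends[cross, 2])))
  if (length(boundary_nodes) == 0 && shift > 0) {
    warning("no boundary between groups ", groups[1], " and ", groups[2])
  }
  if (is.finite(shift)) {
    boundary_nodes <- utils::head(boundary_nodes, shift)
  }
  if (shift == 0) boundary_nodes <- character(0)

  summarize_config <- function(ng, flipped = NA_character_,
                               from = NA_character_, to = NA_character_) {
    asg <- assign_patients(graph, ng)
    fs <- wallwork_factors(symptoms)
    row <- tibble::tibble(flipped_node = flipped, from = from, to = to)
    for (g in sort(unique(ng))) {
      members <- which(asg$group == g)
      row[[paste0("n_", g)]] <- length(members)
      for (f in c("positive", "negative", "disorganized", "excited",
                  "depressed")) {
        row[[paste0(f, "_", g)]] <-
          if (length(members)) mean(fs[[f]][members]) else NA_real_
      }
      if (!is.null(cohort)) {
        gafs <- cohort$gaf[match(asg$patient_id[members], cohort$patient_id)]
        row[[paste0("gaf_", g)]] <-
          if (length(members)) mean(gafs, na.rm = TRUE) else NA_real_
      }
    }
    list(row = row, assignment = asg)
  }

  base <- summarize_config(node_groups)
  rows <- list(base$row)
  assignments <- list(base = base$assignment)
  for (nd in boundary_nodes) {
    ng <- node_groups
    from <- ng[[nd]]
    to <- setdiff(groups, from)[1]
    ng[[nd]] <- to
    res <- summarize_config(ng, flipped = nd, from = from, to = to)
    rows[[length(rows) + 1L]] <- res$row
    assignments[[nd]] <- res$assignment
  }
  out <- do.call(rbind, rows)
  attr(out, "assignments") <- assignments
  out
}
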