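#' Derive a stage seed from the pipeline seed
#'
#' All randomness flows from one top-level seed; each stochastic stage
#' (generator, fold shuffling, k-means, ...) receives a seed derived
#' deterministically from it, so that whole-pipeline runs are exactly
#' reproducible while stages remain decoupled.
#'
#' @param seed Top-level integer seed.
#' @param stage Stage name.
#' @return An integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, simulate2 = 2L, mapper = 3L, stratify = 4L,
               predict = 5L, kmeans = 6L, kmeans_pca = 7L, metabolome = 8L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML layout with sections `simulate`,
#' `mapper`, `stratify`, `predict` and `paths`, plus the top-level
#' `seed`. [read_pipeline_config()] merges a YAML file over these
#' defaults and validates every numeric parameter against its range.
#'
#' @return A `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(n_patients = 100L, item_noise_sd = 1.0),
    mapper = list(resolution = 60L, gain = 7, lens_dims = 2L,
                  distance = "normalized_pearson",
                  cluster_histogram_bins = 10L, scale_items = FALSE),
    stratify = list(min_component_patients = 5L, n_groups = 3L,
                    split_method = "fast_greedy"),
    predict = list(gaf_threshold = 65, regularization_strength = 1),
    paths = list(cohort1 = NULL, cohort2 = NULL, out_dir = "panssmapper-out")
  ), class = "pipeline_config")
}

#' @rdname default_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(unclass(default_config()), user)
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
  config
}

#' @rdname default_config
#' @param config A `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  # constructors perform the range checks
  do.call(mapper_config, config$mapper)
  do.call(stratify_config, config$stratify)
  do.call(predict_config, c(config$predict, list(seed = config$seed)))
  if (config$simulate$n_patients < 3) {
    stop("simulate.n_patients must be >= 3", call. = FALSE)
  }
  if (config$simulate$item_noise_sd < 0) {
    stop("simulate.item_noise_sd must be >= 0", call. = FALSE)
  }
  invisible(config)
}

#' Export a Mapper graph to GraphML and JSON
#'
#' The JSON export lists, for each node, its id, the member patient
#' ids and the mean Wallwork factor scores of its members; edges carry
#' the endpoint ids and the shared-member count.
#'
#' @param graph A `mapper_graph`.
#' @param symptoms Symptom matrix (for mean factor scores).
#' @param graphml_path,json_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the JSON-ready list.
#' @export
export_mapper_graph <- function(graph, symptoms, graphml_path = NULL,
                                json_path = NULL) {
  fs <- wallwork_factors(symptoms)
  factor_cols <- setdiff(names(fs), "patient_id")
  nodes <- lapply(seq_along(graph$nodes), function(i) {
    members <- graph$nodes[[i]]
    means <- lapply(factor_cols, function(f) mean(fs[[f]][members]))
    names(means) <- factor_cols
    list(id = graph$node_info$node[i],
         member_patient_ids = graph$patient_ids[members],
         mean_factor_scores = means)
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(i) {
    list(from = graph$edges$from[i], to = graph$edges$to[i],
         shared = graph$edges$shared[i])
  })
  obj <- list(n_patients = graph$n, nodes = nodes, edges = edges)
  if (!is.null(json_path)) {
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(mapper_igraph(graph), graphml_path,
                        format = "graphml")
  }
  invisible(obj)
}

#' Run the full stratification pipeline
#'
#' Orchestrates the whole analysis in the order of the study design:
#' obtain two cohorts (read from `paths`, or simulated when no paths
#' are configured), build the Mapper graph of cohort 1, stratify it
#' into groups, characterize the groups (factor scores, group-specific
#' items, outcome comparisons), replicate the grouping in cohort 2 by
#' nearest-centroid assignment, run the paired outcome-prediction
#' experiment (items vs. groups, train/test and fivefold CV) together
#' with the k-means comparators, and -- when metabolite columns are
#' present -- the per-group correlation networks and adjusted
#' contrasts. Every stage output is serialized under `out_dir` and all
#' effective parameters are logged to `log.json`. Two runs with the
#' same configuration and seed produce identical outputs.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param out_dir Output directory; overrides `config$paths$out_dir`.
#'   `NULL` disables writing.
#' @return A list bundle with every stage's result.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- config$paths$out_dir
  seed <- config$seed

  if (!is.null(config$paths$cohort1)) {
    cohort1 <- read_cohort(config$paths$cohort1)
    truth1 <- NULL
  } else {
    params <- default_params(n_patients = config$simulate$n_patients,
                             item_noise_sd = config$simulate$item_noise_sd)
    sim <- generate_cohort(params, seed = derive_seed(seed, "simulate"))
    cohort1 <- sim$cohort
    truth1 <- sim$labels
  }
  if (!is.null(config$paths$cohort2)) {
    cohort2 <- read_cohort(config$paths$cohort2)
    truth2 <- NULL
  } else {
    params <- default_params(n_patients = config$simulate$n_patients,
                             item_noise_sd = config$simulate$item_noise_sd)
    sim2 <- generate_cohort(params, seed = derive_seed(seed, "simulate2"),
                            id_prefix = "v")
    cohort2 <- sim2$cohort
    truth2 <- sim2$labels
  }

  x1 <- panss_matrix(cohort1)
  x2 <- panss_matrix(cohort2)
  mcfg <- do.call(mapper_config, config$mapper)
  scfg <- do.call(stratify_config, config$stratify)
  pcfg <- do.call(predict_config, c(config$predict, list(seed = seed)))

  graph <- build_mapper_graph(x1, mcfg)
  assignment1 <- stratify_groups(graph, x1, scfg)
  characterization <- list(
    factors = wallwork_factors(x1),
    items = group_specific_items(x1, assignment1),
    outcomes = compare_outcomes(cohort1, assignment1))
  centroids <- group_centroids(x1, assignment1)
  assignment2 <- assign_by_centroid(x2, centroids)
  prediction <- run_prediction_experiment(
    x1, cohort1$gaf[match(rownames(x1), cohort1$patient_id)], assignment1,
    x2, cohort2$gaf[match(rownames(x2), cohort2$patient_id)], assignment2,
    pcfg)

  km <- kmeans_partition(x1, k = scfg$n_groups,
                         seed = derive_seed(seed, "kmeans"))
  km_pca <- kmeans_partition(x1, k = scfg$n_groups, on_pca = TRUE,
                             seed = derive_seed(seed, "kmeans_pca"))
  assigned <- assignment1$group != "unassigned"
  comparators <- list(
    kmeans = compare_partitions(assignment1$group[assigned], km[assigned]),
    kmeans_pca = compare_partitions(assignment1$group[assigned],
                                    km_pca[assigned]))

  metabolome <- NULL
  mets <- metabolite_names(cohort1)
  if (length(mets) >= 2) {
    groups <- sort(setdiff(unique(assignment1$group), "unassigned"))
    networks <- lapply(groups, function(g) {
      correlation_network(cohort1, assignment1, g)
    })
    names(networks) <- groups
    contrasts <- lapply(mets, function(m) {
      tryCatch(adjusted_group_contrast(cohort1, assignment1, m),
               error = function(e) NULL)
    })
    names(contrasts) <- mets
    metabolome <- list(networks = networks,
                       edge_classes = classify_edges_by_group(networks),
                       contrasts = contrasts[!vapply(contrasts, is.null,
                                                     logical(1))])
  }

  bundle <- list(config = config, cohort1 = cohort1, cohort2 = cohort2,
                 truth1 = truth1, truth2 = truth2,
                 graph = graph, assignment1 = assignment1,
                 centroids = centroids, assignment2 = assignment2,
                 characterization = characterization,
                 prediction = prediction, comparators = comparators,
                 metabolome = metabolome)
  if (!is.null(out_dir)) write_pipeline_bundle(bundle, x1, out_dir)
  bundle
}

write_pipeline_bundle <- function(bundle, symptoms1, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(bundle$cohort1, file.path(out_dir, "cohort1.csv"))
  write_cohort(bundle$cohort2, file.path(out_dir, "cohort2.csv"))
  if (!is.null(bundle$truth1)) {
    readr::write_csv(bundle$truth1, file.path(out_dir, "cohort1_true_labels.csv"))
  }
  if (!is.null(bundle$truth2)) {
    readr::write_csv(bundle$truth2, file.path(out_dir, "cohort2_true_labels.csv"))
  }
  export_mapper_graph(bundle$graph, symptoms1,
                      graphml_path = file.path(out_dir, "mapper_graph.graphml"),
                      json_path = file.path(out_dir, "mapper_graph.json"))
  readr::write_csv(tibble::as_tibble(bundle$assignment1),
                   file.path(out_dir, "assignment_cohort1.csv"))
  readr::write_csv(tibble::as_tibble(bundle$assignment2),
                   file.path(out_dir, "assignment_cohort2.csv"))
  readr::write_csv(bundle$characterization$factors,
                   file.path(out_dir, "factor_scores_cohort1.csv"))
  readr::write_csv(bundle$characterization$items,
                   file.path(out_dir, "group_specific_items.csv"))
  report_json <- list(
    outcomes = lapply(bundle$characterization$outcomes, function(x) x),
    prediction = lapply(bundle$prediction$reports, function(feature) {
      lapply(feature, function(rep) {
        rep$pr_curve <- NULL
        unclass(rep)
      })
    }),
    prediction_difference = bundle$prediction$difference,
    comparator_ari = list(
      kmeans = bundle$comparators$kmeans$ari,
      kmeans_pca = bundle$comparators$kmeans_pca$ari))
  jsonlite::write_json(report_json, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (feature in names(bundle$prediction$reports)) {
    for (scheme in names(bundle$prediction$reports[[feature]])) {
      readr::write_csv(
        bundle$prediction$reports[[feature]][[scheme]]$pr_curve,
        file.path(out_dir, sprintf("pr_curve_%s_%s.csv", feature, scheme)))
    }
  }
  if (!is.null(bundle$metabolome)) {
    readr::write_csv(bundle$metabolome$edge_classes,
                     file.path(out_dir, "metabolite_edges.csv"))
    for (g in names(bundle$metabolome$networks)) {
      rmat <- bundle$metabolome$networks[[g]]$r_matrix
      utils::write.csv(rmat,
                       file.path(out_dir, sprintf("correlation_matrix_%s.csv", g)))
    }
  }
  log <- list(timestamp = format(Sys.time(), tz = "UTC"),
              parameters = unclass(bundle$config))
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
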