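#' Mapper configuration
#'
#' Parameters of the Mapper construction. `resolution` is the number of
#' cover intervals per lens dimension and `gain` controls the overlap
#' between adjacent intervals: each interval has length
#' `stride * gain`, so the overlap fraction between neighbours is
#' `1 - 1/gain`. The defaults (resolution 60, gain 7, two
#' principal-component lens dimensions, normalized Pearson correlation
#' distance) are the settings under which the stratification was
#' developed.
#'
#' @param resolution Integer >= 1, intervals per lens dimension.
#' @param gain Numeric > 1; gain of 1 would give zero overlap and is
#'   disallowed so that edge formation remains possible.
#' @param lens_dims Number of principal components used as the lens.
#' @param distance `"normalized_pearson"` (`sqrt(2 * (1 - r))`, a true
#'   metric on standardized vectors; the default for symptom profiles),
#'   `"one_minus_r"`, or `"euclidean"` (for low-dimensional geometric
#'   point clouds, where profile correlation is degenerate).
#' @param cluster_histogram_bins Bins of the merge-height histogram used
#'   by the preimage clustering gap heuristic (>= 2).
#' @param scale_items Use z-scored PCA for the lens instead of
#'   covariance PCA. All PANSS items share the 1-7 scale, so the default
#'   is centering only.
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(resolution = 60L, gain = 7,
                          lens_dims = 2L,
                          distance = c("normalized_pearson", "one_minus_r",
                                       "euclidean"),
                          cluster_histogram_bins = 10L,
                          scale_items = FALSE) {
  distance <- match.arg(distance)
  if (resolution < 1) stop("resolution must be >= 1", call. = FALSE)
  if (gain <= 1) stop("gain must be > 1", call. = FALSE)
  if (cluster_histogram_bins < 2) stop("cluster_histogram_bins must be >= 2",
                                       call. = FALSE)
  structure(list(resolution = as.integer(resolution), gain = gain,
                 lens_dims = as.integer(lens_dims), distance = distance,
                 cluster_histogram_bins = as.integer(cluster_histogram_bins),
                 scale_items = scale_items),
            class = "mapper_config")
}

#' Normalized Pearson correlation distance
#'
#' Pairwise distance between patients' symptom vectors:
#' `d(x, y) = sqrt(2 * (1 - r(x, y)))` where `r` is the Pearson
#' correlation across the 30 items. This is the Euclidean metric on
#' row-standardized vectors (up to a global scale) and hence a true
#' metric, unlike `1 - r`, which is available via `method`.
#'
#' @param symptoms Numeric matrix, patients in rows.
#' @param method `"normalized_pearson"` or `"one_minus_r"`.
#' @return An n x n symmetric distance matrix with zero diagonal;
#'   entries lie in [0, 2].
#' @export
normalized_pearson_distance <- function(symptoms,
                                        method = c("normalized_pearson",
                                                   "one_minus_r")) {
  method <- match.arg(method)
  symptoms <- as.matrix(symptoms)
  if (ncol(symptoms) < 2) stop("need at least 2 columns", call. = FALSE)
  rv <- apply(symptoms, 1, stats::var)
  if (any(rv == 0)) {
    who <- rownames(symptoms)[rv == 0]
    if (is.null(who)) who <- which(rv == 0)
    stop("constant symptom vector (zero variance across items) for: ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(symptoms))
  d <- switch(method,
              normalized_pearson = sqrt(pmax(2 * (1 - r), 0)),
              one_minus_r = pmax(1 - r, 0))
  diag(d) <- 0
  d
}

#' Principal-component lens
#'
#' Projects the column-centered symptom matrix onto its top principal
#' components. A deterministic sign convention is applied: each
#' component's loading vector is flipped so that its largest-magnitude
#' entry is positive.
#'
#' @param symptoms Numeric matrix, patients in rows.
#' @param dims Number of components (default 2).
#' @param scale_items Standardize columns before the decomposition.
#' @return An n x dims matrix of lens coordinates.
#' @export
pca_lens <- function(symptoms, dims = 2L, scale_items = FALSE) {
  x <- as.matrix(symptoms)
  if (nrow(x) < dims + 1) {
    stop("need at least dims + 1 rows for a ", dims, "-dimensional lens",
         call. = FALSE)
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (scale_items) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    xc <- sweep(xc, 2, sds, `/`)
  }
  sv <- svd(xc)
  if (sv$d[dims] <= max(sv$d) * 1e-8) {
    stop("data rank is below the requested number of lens dimensions",
         call. = FALSE)
  }
  v <- sv$v[, seq_len(dims), drop = FALSE]
  for (j in seq_len(dims)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  lens <- xc %*% v
  colnames(lens) <- paste0("PC", seq_len(dims))
  rownames(lens) <- rownames(x)
  lens
}

#' Overlapping hypercube cover of the lens range
#'
#' Per lens dimension the range [min, max] is divided into `resolution`
#' strides of length `s = (max - min) / resolution`; interval `i` is
#' centered at `min + (i + 0.5) * s` with length `s * gain`, so adjacent
#' intervals overlap by the fraction `1 - 1/gain`. Cover elements are
#' the Cartesian products of the per-dimension intervals; each point is
#' assigned to every element containing it (points at the range maximum
#' fall in the last interval). A dimension with zero range collapses to
#' one full-range interval with a warning.
#'
#' @param lens Lens coordinate matrix from [pca_lens()].
#' @param resolution Intervals per dimension.
#' @param gain Overlap control (> 1).
#' @return A `mapper_cover` list: `rectangles` (data frame of interval
#'   indices per dimension), `members` (list of point-index vectors, one
#'   per rectangle), and the per-dimension geometry.
#' @export
build_cover <- function(lens, resolution, gain) {
  lens <- as.matrix(lens)
  if (resolution < 1) stop("resolution must be >= 1", call. = FALSE)
  if (gain <= 1) stop("gain must be > 1", call. = FALSE)
  n <- nrow(lens)
  d <- ncol(lens)
  geom <- vector("list", d)
  idx_per_dim <- vector("list", d)
  for (j in seq_len(d)) {
    lo <- min(lens[, j]); hi <- max(lens[, j])
    if (hi - lo <= 0) {
      warning("lens dimension ", j,
              " has zero range; using a single full-range interval")
      geom[[j]] <- list(min = lo, max = hi, stride = 0, length = 0,
                        n_intervals = 1L, degenerate = TRUE)
      idx_per_dim[[j]] <- lapply(seq_len(n), function(i) 0L)
      next
    }
    s <- (hi - lo) / resolution
    len <- s * gain
    # interval i (0-based) covers [lo + (i + 0.5) s - len/2, ... + len/2]
    t <- (lens[, j] - lo) / s - 0.5
    i_lo <- pmax(ceiling(t - gain / 2), 0L)
    i_hi <- pmin(floor(t + gain / 2), resolution - 1L)
    geom[[j]] <- list(min = lo, max = hi, stride = s, length = len,
                      n_intervals = as.integer(resolution),
                      degenerate = FALSE)
    idx_per_dim[[j]] <- mapply(function(a, b) seq.int(a, b),
                               i_lo, i_hi, SIMPLIFY = FALSE)
  }
  # linear rectangle key from per-dimension interval indices
  sizes <- vapply(geom, function(g) g$n_intervals, integer(1))
  mult <- cumprod(c(1L, sizes[-d]))
  point_keys <- vector("list", n)
  for (i in seq_len(n)) {
    combos <- idx_per_dim[[1]][[i]] * mult[1]
    if (d > 1) {
      for (j in 2:d) {
        combos <- as.vector(outer(combos, idx_per_dim[[j]][[i]] * mult[j], `+`))
      }
    }
    point_keys[[i]] <- combos
  }
  counts <- lengths(point_keys)
  long_point <- rep.int(seq_len(n), counts)
  long_key <- unlist(point_keys, use.names = FALSE)
  members <- split(long_point, long_key)
  keys <- as.integer(names(members))
  rect <- matrix(0L, length(keys), d)
  rem <- keys
  for (j in seq_len(d)) {
    rect[, j] <- rem %% sizes[j]
    rem <- rem %/% sizes[j]
  }
  colnames(rect) <- paste0("i", seq_len(d))
  structure(list(rectangles = cbind(data.frame(rect_id = keys), rect),
                 members = unname(members),
                 geometry = geom, resolution = as.integer(resolution),
                 gain = gain, n_points = n),
            class = "mapper_cover")
}

#' Cluster the preimage of one cover element
#'
#' Single-linkage clustering of the points in one cover rectangle,
#' restricted to the global distance matrix, cut by the first-gap
#' heuristic: merge heights are histogrammed into `bins` bins spanning
#' [smallest merge height, preimage diameter] and the dendrogram is cut
#' at the lower edge of the first empty bin -- the gap separating
#' within-cluster merges from between-cluster separations. Anchoring
#' the bin width to the preimage diameter (rather than the largest
#' merge height alone) keeps chance gaps among a handful of
#' near-continuum merge heights from shattering a single cluster. If no
#' gap exists (including the case of all pairwise distances equal), all
#' members form one cluster. Clusters are returned ordered by their
#' smallest member index.
#'
#' @param member_indices Integer vector of point indices (nonempty).
#' @param distances Full distance matrix.
#' @param bins Number of histogram bins (default 10).
#' @return List of integer vectors partitioning `member_indices`.
#' @export
cluster_preimage <- function(member_indices, distances, bins = 10L) {
  m <- length(member_indices)
  if (m == 0) stop("empty member set", call. = FALSE)
  if (m == 1) return(list(member_indices))
  sub <- distances[member_indices, member_indices, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  h <- hc$height
  diam <- max(sub)
  labels <- if (diam <= 0 || diam - min(h) <= 0) {
    rep(1L, m)
  } else {
    breaks <- seq(min(h), diam, length.out = bins + 1)
    counts <- graphics::hist(h, breaks = breaks, plot = FALSE)$counts
    gap <- which(counts == 0)
    if (length(gap) == 0) {
      rep(1L, m)
    } else {
      stats::cutree(hc, h = breaks[gap[1]])
    }
  }
  parts <- split(member_indices, labels)
  parts <- parts[order(vapply(parts, min, numeric(1)))]
  unname(parts)
}

#' Build the Mapper graph of a symptom matrix
#'
#' Composes the full construction: normalized Pearson distances, the
#' principal-component lens, the overlapping cover, single-linkage
#' clustering within each cover element's preimage, and the nerve:
#' one node per preimage cluster, an edge between two nodes whenever
#' they share at least one patient (the shared count is stored on the
#' edge). Node identifiers are `r<rectangle>_c<rank>` and are stable for
#' a given input and configuration.
#'
#' @param symptoms Numeric matrix, patients x items. Row names (patient
#'   ids) are preserved in the graph.
#' @param config A [mapper_config()].
#' @return A `mapper_graph`: list with `nodes` (list of patient-index
#'   vectors), `node_info` (tibble: node, rectangle, cluster, size),
#'   `edges` (tibble: from, to, shared), `n` patients, `patient_ids`,
#'   `lens`, and the `config`.
#' @export
build_mapper_graph <- function(symptoms, config = mapper_config()) {
  x <- as.matrix(symptoms)
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) {
    return(new_mapper_graph(nodes = list(1L),
                            node_info = tibble::tibble(node = "r0_c1",
                                                       rectangle = 0L,
                                                       cluster = 1L, size = 1L),
                            edges = empty_edges(), n = 1L, patient_ids = ids,
                            lens = NULL, config = config))
  }
  d <- if (config$distance == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    normalized_pearson_distance(x, method = config$distance)
  }
  lens <- pca_lens(x, dims = config$lens_dims,
                   scale_items = config$scale_items)
  cover <- build_cover(lens, config$resolution, config$gain)
  nodes <- list()
  node_rect <- integer(0)
  node_rank <- integer(0)
  for (k in seq_along(cover$members)) {
    parts <- cluster_preimage(cover$members[[k]], d,
                              bins = config$cluster_histogram_bins)
    for (j in seq_along(parts)) {
      nodes[[length(nodes) + 1L]] <- parts[[j]]
      node_rect <- c(node_rect, cover$rectangles$rect_id[k])
      node_rank <- c(node_rank, j)
    }
  }
  node_ids <- sprintf("r%d_c%d", node_rect, node_rank)
  node_info <- tibble::tibble(node = node_ids, rectangle = node_rect,
                              cluster = node_rank,
                              size = lengths(nodes))
  edges <- nerve_edges(nodes, node_ids, n)
  new_mapper_graph(nodes = nodes, node_info = node_info, edges = edges,
                   n = n, patient_ids = ids, lens = lens, config = config)
}

empty_edges <- function() {
  tibble::tibble(from = character(0), to = character(0), shared = integer(0))
}

# Nerve of the node member sets via a sparse patient x node incidence matrix.
nerve_edges <- function(nodes, node_ids, n) {
  if (length(nodes) < 2) return(empty_edges())
  inc <- Matrix::sparseMatrix(
    i = unlist(nodes, use.names = FALSE),
    j = rep.int(seq_along(nodes), lengths(nodes)),
    x = 1, dims = c(n, length(nodes))
  )
  shared <- Matrix::crossprod(inc)
  tri <- Matrix::triu(shared, k = 1)
  sm <- Matrix::summary(tri)
  sm <- sm[sm$x > 0, , drop = FALSE]
  ord <- order(sm$i, sm$j)
  tibble::tibble(from = node_ids[sm$i[ord]], to = node_ids[sm$j[ord]],
                 shared = as.integer(sm$x[ord]))
}

new_mapper_graph <- function(nodes, node_info, edges, n, patient_ids, lens,
                             config) {
  structure(list(nodes = nodes, node_info = node_info, edges = edges,
                 n = n, patient_ids = patient_ids, lens = lens,
                 config = config),
            class = "mapper_graph")
}

#' Convert a Mapper graph to an igraph object
#'
#' Nodes carry their size as a vertex attribute; edges carry the
#' shared-member count as a weight.
#'
#' @param graph A `mapper_graph`.
#' @return An `igraph` graph.
#' @export
mapper_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges,
    directed = FALSE,
    vertices = data.frame(name = graph$node_info$node,
                          size = graph$node_info$size)
  )
  g
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("Mapper graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges over ", x$n, " patients\n", sep = "")
  invisible(x)
}

# patient index -> indices of nodes containing the patient
node_membership_by_patient <- function(graph) {
  idx <- rep.int(seq_along(graph$nodes), lengths(graph$nodes))
  split(idx, unlist(graph$nodes, use.names = FALSE))
}
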