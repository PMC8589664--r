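test_that("normalized Pearson distance matches a direct covariance oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  # brute-force Pearson on the 4-vectors
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  d <- normalized_pearson_distance(rbind(x, y))
  expect_equal(d[1, 2], sqrt(2 * (1 - r_oracle)), tolerance = 1e-12)

  same <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5))
  expect_equal(normalized_pearson_distance(same)[1, 2], 0)

  anti <- rbind(c(1, 2, 3, 4), c(9, 8, 7, 6))  # y = -x + c
  expect_equal(normalized_pearson_distance(anti)[1, 2], 2)

  const <- rbind(p_ok = c(1, 2, 3, 4), p_const = c(2, 2, 2, 2))
  expect_error(normalized_pearson_distance(const), "p_const")

  expect_equal(normalized_pearson_distance(anti, method = "one_minus_r")[1, 2], 2)
})

test_that("the distance satisfies the metric axioms", {
  set.seed(31)
  x <- matrix(sample(1:7, 20 * 30, replace = TRUE), 20, 30)
  d <- normalized_pearson_distance(x)
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d, t(d), tolerance = 1e-9)
  expect_true(all(diag(d) == 0))
  for (rep in 1:200) {
    ijk <- sample(20, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("PCA lens is an isometry on rank-2 data and deterministic", {
  set.seed(5)
  coords <- matrix(rnorm(40), 20, 2)
  basis <- qr.Q(qr(matrix(rnorm(60), 30, 2)))  # orthonormal 30x2
  x <- coords %*% t(basis)
  lens <- pca_lens(x, dims = 2)
  d0 <- stats::dist(coords)
  d1 <- stats::dist(lens)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)

  # duplicate rows map to identical lens values
  xd <- rbind(x, x[3, ])
  lens_d <- pca_lens(xd, dims = 2)
  expect_equal(lens_d[3, ], lens_d[21, ], tolerance = 1e-12)

  # variance ordering of the components
  full <- pca_lens(matrix(rnorm(300), 30, 10), dims = 2)
  expect_gte(stats::var(full[, 1]), stats::var(full[, 2]))

  # rank deficiency is an error
  expect_error(pca_lens(matrix(rep(1:10, 3), 10, 3), dims = 2), "rank")
})

test_that("cover geometry follows the stride/gain convention", {
  lens <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  cov <- build_cover(lens, resolution = 4, gain = 2)
  g <- cov$geometry[[1]]
  expect_equal(g$stride, 0.25)
  expect_equal(g$length, 0.5)
  # centers at min + (i + 0.5) * stride
  centers <- 0 + (0:3 + 0.5) * g$stride
  expect_equal(centers, c(0.125, 0.375, 0.625, 0.875))
  # overlap fraction between adjacent intervals = 1 - 1/gain
  overlap <- (g$length - g$stride) / g$length
  expect_equal(overlap, 1 - 1 / 2, tolerance = 1e-9)
  g7 <- build_cover(lens, resolution = 10, gain = 7)$geometry[[1]]
  expect_equal((g7$length - g7$stride) / g7$length, 1 - 1 / 7,
               tolerance = 1e-9)

  # every point lies in at least one rectangle, for random lenses
  for (seed in 1:3) {
    set.seed(seed)
    l2 <- cbind(rnorm(57), rnorm(57))
    cv <- build_cover(l2, resolution = 8, gain = 3)
    covered <- sort(unique(unlist(cv$members)))
    expect_equal(covered, 1:57)
  }

  # degenerate dimension collapses to one interval with a warning
  expect_warning(cz <- build_cover(cbind(1:9, rep(2, 9)), 5, 3), "zero range")
  expect_true(all(vapply(cz$members, length, integer(1)) >= 1))
})

test_that("preimage clustering follows the dendrogram gap heuristic", {
  # singleton
  d1 <- matrix(0, 1, 1)
  expect_equal(cluster_preimage(1L, d1), list(1L))

  # two tight bundles far apart: oracle = connected components at the gap
  pts <- c(0, 0.01, 0.02, 5, 5.01, 5.02)
  d <- as.matrix(stats::dist(pts))
  parts <- cluster_preimage(1:6, d, bins = 10)
  expect_equal(length(parts), 2)
  expect_equal(parts[[1]], 1:3)
  expect_equal(parts[[2]], 4:6)

  # equidistant points: no gap exists, one cluster
  deq <- matrix(1, 4, 4); diag(deq) <- 0
  expect_equal(cluster_preimage(1:4, deq), list(1:4))

  # subsets of a larger distance matrix are handled via global indices
  big <- as.matrix(stats::dist(c(0, 100, 0.4, 0.5, 9, 9.1)))
  parts2 <- cluster_preimage(c(3L, 4L, 5L, 6L), big, bins = 10)
  expect_equal(parts2, list(c(3L, 4L), c(5L, 6L)))
})

test_that("mapper graph separates far blobs and closes the circle loop", {
  cfg_blob <- mapper_config(resolution = 10, gain = 3, distance = "euclidean")
  for (seed in 1:3) {
    b <- generate_blobs(50, rbind(c(0, 0), c(10, 0)), sd = 1, seed = seed)
    g <- build_mapper_graph(b$points, cfg_blob)
    comp <- extract_components(g, min_component_patients = 5)
    expect_equal(length(comp$retained), 2)
    # no edge joins members of different blobs
    node_blob <- vapply(g$nodes, function(m) {
      u <- unique(b$labels[m]); if (length(u) == 1) u else NA_integer_
    }, integer(1))
    expect_true(all(!is.na(node_blob)))
    i <- match(g$edges$from, g$node_info$node)
    j <- match(g$edges$to, g$node_info$node)
    expect_true(all(node_blob[i] == node_blob[j]))
  }

  cfg_circ <- mapper_config(resolution = 20, gain = 3, distance = "euclidean")
  for (seed in 1:3) {
    z <- generate_circle(500, noise_sd = 0.05, seed = seed)
    g <- build_mapper_graph(z, cfg_circ)
    ig <- mapper_igraph(g)
    comp <- igraph::components(ig)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(ig, which(comp$membership == big))
    # cycle rank >= 1 on the largest component
    expect_gte(igraph::ecount(sub) - igraph::vcount(sub) + 1, 1)
  }
})

test_that("a single-patient input yields one node and no edges", {
  x <- matrix(1:30, 1, 30, dimnames = list("solo", panss_items()))
  g <- build_mapper_graph(x)
  expect_equal(length(g$nodes), 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(g$patient_ids, "solo")
})

test_that("nerve edges equal nonempty member intersections and conserve membership", {
  sim <- generate_cohort(default_params(n_patients = 80), seed = 13)
  x <- panss_matrix(sim$cohort)
  g <- build_mapper_graph(x, mapper_config(resolution = 15, gain = 3))
  # membership conservation
  expect_equal(sort(unique(unlist(g$nodes))), 1:80)
  # brute-force nerve oracle
  expected <- list()
  for (i in seq_along(g$nodes)) {
    for (j in seq_along(g$nodes)) {
      if (i >= j) next
      inter <- length(intersect(g$nodes[[i]], g$nodes[[j]]))
      if (inter > 0) {
        expected[[length(expected) + 1]] <-
          c(g$node_info$node[i], g$node_info$node[j], inter)
      }
    }
  }
  exp_df <- do.call(rbind, expected)
  expect_equal(nrow(g$edges), nrow(exp_df))
  expect_equal(g$edges$from, exp_df[, 1])
  expect_equal(g$edges$to, exp_df[, 2])
  expect_equal(g$edges$shared, as.integer(exp_df[, 3]))
})

test_that("edge count is monotone in gain on fixed data", {
  sim <- generate_cohort(default_params(n_patients = 60), seed = 21)
  x <- panss_matrix(sim$cohort)
  counts <- vapply(c(1.5, 2, 3, 5, 7), function(gain) {
    nrow(build_mapper_graph(x, mapper_config(resolution = 10,
                                             gain = gain))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
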