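test_that("pearson_with_p matches exact arithmetic and a permutation oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_p(x, 2 * x + 3)$r, 1)
  res <- pearson_with_p(x, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 0.8, tolerance = 1e-12)

  # exact permutation oracle over all orderings at n <= 6
  perm_p <- function(x, y) {
    r_obs <- abs(stats::cor(x, y))
    perms <- combinat_perms(length(y))
    rs <- apply(perms, 1, function(idx) abs(stats::cor(x, y[idx])))
    mean(rs >= r_obs - 1e-12)
  }
  combinat_perms <- function(n) {
    if (n == 1) return(matrix(1))
    sub <- combinat_perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    }))
  }
  set.seed(23)
  for (rep in 1:5) {
    x6 <- rnorm(6); y6 <- rnorm(6)
    p_exact <- perm_p(x6, y6)
    p_t <- pearson_with_p(x6, y6)$p.value
    # agreement within the permutation distribution's discreteness (1/720
    # granularity, plus distributional mismatch at tiny n)
    expect_lt(abs(p_t - p_exact), 0.12)
  }

  expect_error(pearson_with_p(1:2, 2:3), ">= 3")
  expect_error(pearson_with_p(c(1, 1, 1, 1), 1:4), "zero variance")
})

test_that("adjusted contrasts are shift-invariant and match the orthogonal-design t-test", {
  set.seed(61)
  n <- 60
  co <- tibble::tibble(patient_id = paste0("m", 1:n))
  scores <- matrix(rep(2:4, length.out = n * 30), n, 30,
                   dimnames = list(NULL, panss_items()))
  co <- cbind(co, tibble::as_tibble(as.data.frame(scores)))
  # balanced covariates, orthogonal to the group indicator
  co$age <- rep(c(20, 30), n / 2)
  co$sex <- rep(c("male", "female", "female", "male"), n / 4)
  co$gaf <- 60; co$sofas <- 60
  co$working <- NA; co$living_independently <- NA; co$remission <- NA
  co$diagnosis <- NA_character_
  co$met <- rnorm(n, mean = rep(c(10, 14), each = n / 2), sd = 2)
  co <- as_cohort(co)
  asg <- tibble::tibble(patient_id = co$patient_id,
                        group = rep(c("A", "B"), each = n / 2))

  ct <- adjusted_group_contrast(co, asg, "met")
  tt <- stats::t.test(co$met[1:30], co$met[31:60], var.equal = TRUE)
  expect_equal(ct$estimate, unname(diff(rev(tt$estimate))), tolerance = 1e-9)

  # adding a constant changes only the intercept
  co2 <- co; co2$met <- co$met + 100
  ct2 <- adjusted_group_contrast(co2, asg, "met")
  expect_equal(ct2$estimate, ct$estimate, tolerance = 1e-9)
  expect_equal(ct2$p, ct$p, tolerance = 1e-9)

  # single-sex group makes the design singular only if sex is constant
  co3 <- co; co3$sex <- "male"
  expect_error(adjusted_group_contrast(co3, asg, "met"), "collinear")
})

test_that("planted correlations become network edges and absent ones do not", {
  set.seed(71)
  n <- 80
  co <- tibble::tibble(patient_id = paste0("m", 1:n))
  scores <- matrix(rep(2:4, length.out = n * 30), n, 30,
                   dimnames = list(NULL, panss_items()))
  co <- cbind(co, tibble::as_tibble(as.data.frame(scores)))
  co$age <- 25; co$sex <- "male"; co$gaf <- 60; co$sofas <- 60
  co$working <- NA; co$living_independently <- NA; co$remission <- NA
  co$diagnosis <- NA_character_
  z <- rnorm(n)
  co$metA <- 10 + z
  co$metB <- 5 + 0.9 * z + rnorm(n, sd = sqrt(1 - 0.81))  # rho = 0.9
  co$metC <- rnorm(n)                                     # independent
  co <- as_cohort(co)
  asg <- tibble::tibble(patient_id = co$patient_id,
                        group = rep(c("G1", "G2"), each = n / 2))

  nw <- correlation_network(co, asg, "G1")
  expect_s3_class(nw, "correlation_network")
  expect_true(any(nw$edges$metabolite1 == "metA" &
                    nw$edges$metabolite2 == "metB"))
  expect_true(all(nw$edges$p < nw$alpha))
  # matrix symmetry with unit diagonal, exactly
  expect_identical(nw$r_matrix, t(nw$r_matrix))
  expect_identical(unname(diag(nw$r_matrix)), rep(1, 3))

  # invariance to per-metabolite affine rescaling and column order
  co_scaled <- co
  co_scaled$metA <- 3 * co$metA - 7
  nw_s <- correlation_network(co_scaled, asg, "G1")
  expect_equal(abs(nw_s$r_matrix), abs(nw$r_matrix), tolerance = 1e-12)
  nw_perm <- correlation_network(co, asg, "G1",
                                 metabolites = c("metC", "metA", "metB"))
  expect_equal(nw_perm$r_matrix["metA", "metB"], nw$r_matrix["metA", "metB"])

  expect_error(correlation_network(co[1:3, ], asg[1:3, ], "G1"), "fewer than 4")
})

test_that("edges are classified by the exact set of groups containing them", {
  mk_net <- function(group, edges) {
    r <- diag(1, 3); dimnames(r) <- list(c("m1", "m2", "m3"),
                                         c("m1", "m2", "m3"))
    structure(list(group = group,
                   edges = tibble::tibble(
                     metabolite1 = vapply(edges, `[`, "", 1),
                     metabolite2 = vapply(edges, `[`, "", 2),
                     r = rep(0.9, length(edges)), p = rep(0.001, length(edges)),
                     n = rep(20L, length(edges))),
                   r_matrix = r, p_matrix = r, alpha = 0.05),
              class = "correlation_network")
  }
  nets <- list(A = mk_net("A", list(c("m1", "m2"), c("m1", "m3"))),
               B = mk_net("B", list(c("m1", "m2"))),
               C = mk_net("C", list(c("m1", "m2"), c("m2", "m3"))))
  out <- classify_edges_by_group(nets)
  get <- function(a, b) out$groups[out$metabolite1 == a & out$metabolite2 == b]
  expect_equal(get("m1", "m2"), "A,B,C")
  expect_equal(get("m1", "m3"), "A")
  expect_equal(get("m2", "m3"), "C")
})

test_that("the generator's planted group-specific edges are recovered", {
  p <- default_params(n_patients = 300)
  sim <- generate_cohort(p, seed = 15)
  asg <- sim$labels
  nets <- lapply(c("A", "B", "C"), function(g) {
    correlation_network(sim$cohort, asg, g)
  })
  names(nets) <- c("A", "B", "C")
  out <- classify_edges_by_group(nets)
  urea <- out[out$metabolite1 == "arginine" & out$metabolite2 == "ornithine", ]
  expect_equal(urea$groups, "A")
  shared <- out[out$metabolite1 == "glycine" & out$metabolite2 == "serine", ]
  expect_equal(shared$groups, "A,B,C")
})
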