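test_that("euclidean_mst handles forced geometries and guards input", {
  mst <- euclidean_mst(c(0, 1, 3))
  expect_equal(nrow(mst), 2L)
  expect_equal(attr(mst, "total_weight"), 3)
  expect_setequal(paste(mst$i, mst$j), c("1 2", "2 3"))

  expect_error(euclidean_mst(matrix(1, 1, 2)), "at least 2")
  expect_error(euclidean_mst(c(0, NA)), "finite")
})

test_that("MST weight matches exhaustive spanning-tree enumeration (n <= 7)", {
  for (n in c(4L, 5L, 7L)) {
    for (rep_i in 1:2) {
      set.seed(n * 10 + rep_i)
      pts <- matrix(runif(n * 2), n, 2)
      mst <- euclidean_mst(pts)
      expect_equal(nrow(mst), n - 1L)
      expect_equal(attr(mst, "total_weight"), exhaustive_mst_weight(pts),
                   tolerance = 1e-12)
    }
  }
})

test_that("MST weight matches an independent implementation on larger sets", {
  set.seed(7)
  pts <- matrix(rnorm(60 * 3), 60, 3)
  g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(pts)),
                                           mode = "undirected",
                                           weighted = TRUE)
  ref <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(attr(euclidean_mst(pts), "total_weight"), ref,
               tolerance = 1e-10)
})

test_that("cross_edge_count matches forced cases and an edge-scan oracle", {
  mst <- euclidean_mst(c(0, 1, 10, 11))
  expect_equal(cross_edge_count(mst, c("X", "X", "Y", "Y")), 1L)

  mst_path <- euclidean_mst(c(0, 1, 2, 3))
  expect_equal(cross_edge_count(mst_path, c("X", "Y", "X", "Y")), 3L)

  set.seed(3)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  labels <- rep(c("a", "b"), 5)
  mst10 <- euclidean_mst(pts)
  recount <- sum(mapply(function(i, j) labels[i] != labels[j],
                        mst10$i, mst10$j))
  expect_equal(cross_edge_count(mst10, labels), recount)
  expect_error(cross_edge_count(mst10, rep("a", 10)), "both samples")
})

test_that("hp_divergence reproduces hand-evaluated estimator values", {
  r <- hp_divergence(c(0, 1), c(10, 11))
  expect_equal(r$cross_edges, 1L)
  expect_equal(r$divergence, 0.5)   # 1 - 1*4/(2*2*2)
  expect_equal(r$separability, 0.75)

  # perfectly interleaved points over-mix: raw estimate < 0 clamps to 0
  r2 <- hp_divergence(c(0, 2), c(1, 3))
  expect_equal(r2$cross_edges, 3L)
  expect_equal(r2$divergence, 0)
  expect_equal(r2$separability, 0.5)

  expect_error(hp_divergence(matrix(1:4, 2), matrix(1:6, 2)),
               "dimension mismatch")
  expect_error(hp_divergence(matrix(1, 1, 1), matrix(1:2, 2)), "at least 2")
})

test_that("separability is invariant to rigid motion and uniform rescaling", {
  set.seed(11)
  A <- matrix(rnorm(40 * 3), 40, 3)
  B <- matrix(rnorm(30 * 3, mean = 0.8), 30, 3)
  base <- hp_divergence(A, B)$separability
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))  # random rotation/reflection
  shift <- c(5, -3, 2)
  tf <- function(X) sweep(3.7 * X %*% Q, 2L, shift, "+")
  expect_equal(hp_divergence(tf(A), tf(B))$separability, base)
})

test_that("hpd null and separated calibrations hit the stated endpoints", {
  # light version of the full 20-seed acceptance calibration
  seps <- vapply(1:3, function(s) {
    set.seed(s)
    hp_divergence(matrix(rnorm(200 * 15), 200, 15),
                  matrix(rnorm(200 * 15), 200, 15))$separability
  }, numeric(1))
  expect_true(all(seps >= 0.5 & seps < 0.56))

  set.seed(4)
  far <- hp_divergence(matrix(rnorm(200 * 15), 200, 15),
                       matrix(rnorm(200 * 15, mean = 20), 200, 15))
  expect_equal(far$cross_edges, 1L)
  expect_equal(far$separability, 1, tolerance = 0.01)
})

test_that("hpd_feature_curve is consistent with hp_divergence", {
  cohorts <- simulate_cohorts(planted_hub_spec(), seed = 13)
  fs <- select_top_features(correlation_difference(
    cohort_correlation(cohorts$case), cohort_correlation(cohorts$control)))
  fm <- build_feature_matrix(cohorts$case, cohorts$control, fs,
                             n_subsets_per_cohort = 150L, g = 6L, seed = 13)
  curve <- hpd_feature_curve(fm)
  expect_equal(nrow(curve), 15L)
  expect_true(all(curve$separability >= 0.5 & curve$separability <= 1))

  is_case <- fm$labels == "case"
  full <- hp_divergence(fm$values[is_case, ], fm$values[!is_case, ])
  expect_equal(curve$separability[15], full$separability)
  # added features of comparable strength do not reduce separability
  expect_gte(curve$separability[15], curve$separability[1])
})
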