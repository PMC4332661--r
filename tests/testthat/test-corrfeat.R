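test_that("cohort_correlation matches hand-evaluated Pearson values", {
  tab <- tiny_table(4, override = list(
    lh_bankssts = c(2.1, 2.3, 2.5, 2.7),
    lh_cuneus = c(3.0, 2.9, 2.8, 2.7),
    lh_entorhinal = 2.0 + 0.5 * c(2.1, 2.3, 2.5, 2.7)))  # positive affine
  cm <- cohort_correlation(tab)
  expect_equal(cm$values["lh_bankssts", "lh_cuneus"], -1)
  expect_equal(cm$values["lh_bankssts", "lh_entorhinal"], 1)
  expect_equal(cm$n_subjects, 4L)
  expect_true(isSymmetric(cm$values))
  expect_equal(unname(diag(cm$values)), rep(1, 70))
})

test_that("cohort_correlation rejects degenerate input", {
  const <- tiny_table(5, override = list(rh_insula = 2.5))
  expect_error(cohort_correlation(const), "rh_insula")
  expect_error(cohort_correlation(tiny_table(2)), "at least 3")
})

test_that("correlation_difference is |case - control|, symmetric, guarded", {
  cm1 <- cohort_correlation(tiny_table(10, seed = 1))
  cm2 <- cohort_correlation(tiny_table(10, "control", seed = 2))
  D <- correlation_difference(cm1, cm2)
  expect_true(isSymmetric(unclass(D)))
  expect_equal(unname(diag(D)), rep(0, 70))
  expect_equal(D[3, 9], abs(cm1$values[3, 9] - cm2$values[3, 9]))
  expect_equal(max(abs(correlation_difference(cm1, cm1))), 0)

  cm3 <- cm2
  cm3$atlas$region_names <- rev(cm3$atlas$region_names)
  expect_error(correlation_difference(cm1, cm3), "atlas mismatch")
})

test_that("select_top_features matches the brute-force oracle (p <= 8)", {
  for (p in c(5L, 6L, 8L)) {
    regions <- paste0("r", seq_len(p))
    for (rep_i in 1:5) {
      set.seed(p * 100 + rep_i)
      M <- matrix(runif(p * p), p, p)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      k <- min(4L, p)
      fs <- select_top_features(M, k = k, atlas = regions)
      oracle <- brute_force_top_pairs(M, regions, k)
      expect_equal(fs$region_i, oracle$region_i)
      expect_equal(fs$region_j, oracle$region_j)
      expect_equal(fs$score, oracle$score)
      expect_true(all(diff(fs$score) <= 0))
    }
  }
})

test_that("select_top_features tie-break and guards are deterministic", {
  M <- matrix(1, 4, 4); diag(M) <- 0
  fs <- select_top_features(M, k = 3, atlas = paste0("r", 1:4))
  expect_equal(fs$region_i, c("r1", "r1", "r1"))
  expect_equal(fs$region_j, c("r2", "r3", "r4"))
  expect_error(select_top_features(M, k = 0, atlas = paste0("r", 1:4)), "k")
  expect_error(select_top_features(M, k = 7, atlas = paste0("r", 1:4)), "k")
  # default k on the full atlas yields exactly 15 pairs
  D <- correlation_difference(cohort_correlation(tiny_table(10, seed = 3)),
                              cohort_correlation(tiny_table(10, "control",
                                                            seed = 4)))
  expect_equal(nrow(select_top_features(D)), 15L)
})

test_that("candidate feature counts follow the unique-entry formula", {
  expect_equal(count_candidate_features(include_diagonal = TRUE), 2485L)
  expect_equal(count_candidate_features(include_diagonal = FALSE), 2415L)
  expect_equal(count_candidate_features(paste0("r", 1:3)), 3L)
})

test_that("sample_subsets draws valid deterministic subsets", {
  tab <- tiny_table(10, "control", seed = 8)
  draws <- sample_subsets(tab, "control", g = 6, n_subsets = 500, seed = 42)
  expect_length(draws, 500L)
  expect_true(all(vapply(draws, function(d)
    length(d) == 6L && !anyDuplicated(d) && all(d %in% tab$subject_ids),
    logical(1))))
  expect_identical(draws,
                   sample_subsets(tab, "control", 6, 500, seed = 42))
  expect_error(sample_subsets(tiny_table(6), "case", g = 7,
                              n_subsets = 1, seed = 1), "fewer than g")
})

test_that("subset_feature_vector matches direct Pearson evaluation at n = 6", {
  a_vals <- c(2.0, 2.1, 2.2, 2.3, 2.4, 2.5)
  b_vals <- c(1.0, 1.2, 1.1, 1.4, 1.3, 1.5)
  tab <- tiny_table(6, override = list(lh_fusiform = a_vals,
                                       rh_lingual = b_vals,
                                       rh_cuneus = 2 * a_vals + 1))
  feats <- pairs_features(c("lh_fusiform", "lh_fusiform"),
                          c("rh_lingual", "rh_cuneus"))
  v <- subset_feature_vector(tab, tab$subject_ids, feats)
  expect_length(v, 2L)
  expect_equal(v[1], oracle_pearson(a_vals, b_vals))
  expect_equal(v[1], 31 / 35)  # frozen hand evaluation
  expect_equal(v[2], 1.0)      # exactly proportional pair

  const <- tiny_table(6, override = list(lh_fusiform = 2.5))
  expect_error(subset_feature_vector(const, const$subject_ids, feats),
               "lh_fusiform")
  expect_true(is.na(subset_feature_vector(const, const$subject_ids, feats,
                                          na_feature = TRUE)[1]))
})

test_that("build_feature_matrix has the stated shape, bounds and provenance", {
  cohorts <- simulate_cohorts(planted_hub_spec(), seed = 3)
  fs <- select_top_features(correlation_difference(
    cohort_correlation(cohorts$case), cohort_correlation(cohorts$control)))
  fm <- build_feature_matrix(cohorts$case, cohorts$control, fs,
                             n_subsets_per_cohort = 500L, g = 6L, seed = 9)
  expect_equal(dim(fm$values), c(1000L, 15L))
  expect_equal(sum(fm$labels == "case"), 500L)
  expect_true(all(fm$values >= -1 & fm$values <= 1))
  expect_length(fm$provenance, 1000L)
  expect_true(all(fm$provenance[[1]] %in% cohorts$case$subject_ids))
  expect_true(all(fm$provenance[[1000]] %in% cohorts$control$subject_ids))

  # planted features carry signal: case rows exceed control rows on average
  hub_cols <- grepl("rh_temporalpole", colnames(fm$values))
  expect_true(any(hub_cols))
  expect_gt(mean(fm$values[fm$labels == "case", hub_cols]),
            mean(fm$values[fm$labels == "control", hub_cols]))

  tiny <- build_feature_matrix(cohorts$case, cohorts$control, fs,
                               n_subsets_per_cohort = 1L, g = 6L, seed = 1)
  expect_equal(nrow(tiny$values), 2L)
})
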