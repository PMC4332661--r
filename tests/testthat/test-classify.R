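make_labeled_fm <- function(n_per_class, k = 5L, shift = 0, seed = 1) {
  set.seed(seed)
  vals <- rbind(matrix(rnorm(n_per_class * k, mean = shift), ncol = k),
                matrix(rnorm(n_per_class * k), ncol = k))
  vals <- pmin(pmax(vals / 4, -1), 1)
  as_feature_matrix(vals, rep(c("case", "control"), each = n_per_class))
}

test_that("split_experiment1 partitions rows with stratification", {
  fm <- make_labeled_fm(500)
  plan <- split_experiment1(fm, 700, 300, seed = 2)
  expect_length(plan$train_rows, 700L)
  expect_length(plan$test_rows, 300L)
  expect_length(intersect(plan$train_rows, plan$test_rows), 0L)
  expect_equal(sum(fm$labels[plan$train_rows] == "case"), 350L)
  expect_identical(plan, split_experiment1(fm, 700, 300, seed = 2))
  expect_error(split_experiment1(fm, 900, 300, seed = 1), "row count")
  expect_error(split_experiment1(fm, 1000, 0, seed = 1), "non-empty")
})

test_that("split_experiment2 builds subject-disjoint pools and row counts", {
  cohorts <- simulate_cohorts(planted_hub_spec(), seed = 21)
  fs <- select_top_features(correlation_difference(
    cohort_correlation(cohorts$case), cohort_correlation(cohorts$control)))
  exp2 <- split_experiment2(cohorts$case, cohorts$control, fs,
                            n_train_rows = 100L, n_test_rows = 60L,
                            seed = 5)
  pools <- exp2$plan
  expect_length(pools$train_subject_pool, 40L + 24L)
  expect_length(pools$test_subject_pool, 24L + 15L)
  expect_length(intersect(pools$train_subject_pool,
                          pools$test_subject_pool), 0L)
  expect_equal(nrow(exp2$train$values), 100L)
  expect_equal(nrow(exp2$test$values), 60L)
  expect_true(audit_subject_disjoint(exp2$train, exp2$test, pools))

  # audit catches a corrupted plan
  bad_plan <- pools
  bad_plan$train_subject_pool <- c(bad_plan$train_subject_pool,
                                   bad_plan$test_subject_pool[1])
  expect_error(audit_subject_disjoint(exp2$train, exp2$test, bad_plan),
               "overlap")
  bad_plan2 <- pools
  bad_plan2$train_subject_pool <- bad_plan2$train_subject_pool[-1]
  expect_error(audit_subject_disjoint(exp2$train, exp2$test, bad_plan2),
               "outside the training pool")

  expect_error(split_experiment2(cohorts$case, cohorts$control, fs,
                                 n_train_case_subjects = 64L, seed = 1),
               "leave subjects")
  expect_error(split_experiment2(cohorts$case, cohorts$control, fs,
                                 n_train_control_subjects = 35L, seed = 1),
               "at least g")
})

test_that("fit_sparse_linear shrinks, separates, and standardizes", {
  fm <- make_labeled_fm(100, shift = 4, seed = 3)
  # penalty -> infinity limit: all weights zero
  m_inf <- fit_sparse_linear(fm, penalty_grid = 1e6, cv_folds = 3, seed = 1)
  expect_true(all(m_inf$weights == 0))

  # separable toy: perfect training accuracy
  m <- fit_sparse_linear(fm, cv_folds = 3, seed = 1)
  expect_true(all(is.finite(m$weights)))
  expect_true(m$penalty %in% m$cv_results$penalty)
  pred <- predict(m, fm, type = "class")
  expect_equal(mean(pred == fm$labels), 1.0)

  # predictions invariant under affine rescaling of an input feature
  fm2 <- fm
  fm2$values[, 2] <- 100 * fm2$values[, 2] - 7
  m2 <- fit_sparse_linear(fm2, cv_folds = 3, seed = 1)
  expect_equal(predict(m2, fm2), predict(m, fm), tolerance = 1e-6)

  # constant feature dropped with a warning
  fm3 <- fm
  fm3$values[, 5] <- 0.5
  expect_warning(m3 <- fit_sparse_linear(fm3, cv_folds = 3, seed = 1),
                 "constant feature")
  expect_equal(unname(m3$weights[5]), 0)

  one_class <- as_feature_matrix(fm$values, rep("case", 200))
  expect_error(fit_sparse_linear(one_class), "per class")
})

test_that("permuted labels yield chance-level test AUC", {
  aucs <- vapply(1:20, function(s) {
    fm <- make_labeled_fm(60, k = 10, shift = 2, seed = s)
    set.seed(1000 + s)
    fm$labels <- sample(fm$labels)
    plan <- split_experiment1(fm, 80, 40, seed = s)
    m <- fit_sparse_linear(feature_matrix_rows(fm, plan$train_rows),
                           cv_folds = 3, seed = s)
    test <- feature_matrix_rows(fm, plan$test_rows)
    roc_with_bootstrap(m, test, n_boot = 5, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("roc_with_bootstrap has sound curve geometry and bounds", {
  # a perfectly informative feature (label indicator) plus pure noise
  set.seed(100)
  vals <- cbind(c(rep(1, 50), rep(0, 50)) + rnorm(100, sd = 1e-4),
                rnorm(100, sd = 1e-4))
  fm <- as_feature_matrix(vals, rep(c("case", "control"), each = 50))
  m <- fit_sparse_linear(fm, penalty_grid = c(1e-3, 1e-2), cv_folds = 3,
                         seed = 1)
  roc <- roc_with_bootstrap(m, fm, n_boot = 100, seed = 2)
  expect_equal(roc$auc, 1.0)
  expect_equal(tpr_at_fpr(roc, 0.1), 1.0)
  expect_equal(roc$n_boot, 100L)
  expect_length(roc$boot_auc, 100L)

  # endpoints, monotonicity, bracketing
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[1], 0)
  expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(roc$lower <= roc$tpr_grid & roc$tpr_grid <= roc$upper))

  noisy <- make_labeled_fm(80, shift = 1, seed = 9)
  m2 <- fit_sparse_linear(noisy, cv_folds = 3, seed = 1)
  roc2 <- roc_with_bootstrap(m2, noisy, n_boot = 30, seed = 3)
  expect_true(all(diff(roc2$curve$tpr) >= 0))
  expect_true(roc2$auc >= 0 && roc2$auc <= 1)
  expect_true(all(roc2$lower <= roc2$tpr_grid &
                    roc2$tpr_grid <= roc2$upper))

  one_class <- as_feature_matrix(noisy$values, rep("case", 160))
  expect_error(roc_with_bootstrap(m2, one_class), "both classes")
})

test_that("pca_embed orders variance and handles degenerate rank", {
  fm <- make_labeled_fm(100, k = 15, shift = 1, seed = 5)
  emb <- pca_embed(fm, 2)
  expect_equal(dim(emb), c(200L, 2L))
  sdev <- attr(emb, "sdev")
  expect_true(sdev[1] >= sdev[2])
  expect_identical(attr(emb, "labels"), fm$labels)

  line <- as_feature_matrix(cbind(1:20, 2 * (1:20) + 3) / 50,
                            rep(c("case", "control"), 10))
  emb_line <- pca_embed(line, 2)
  expect_lt(attr(emb_line, "sdev")[2], 1e-8)
  expect_error(pca_embed(fm, 16), "exceeds")
})
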