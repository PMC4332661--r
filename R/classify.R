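#' Random stratified row split (Experiment 1 protocol)
#'
#' Splits a subset-feature matrix into training and test rows uniformly at
#' random, preserving the cohort balance of the matrix (the study default is
#' 700 training and 300 test rows out of 1000). Because subjects recur across
#' subset rows, the same subjects typically contribute to both sides — this is
#' the overlapping-subjects protocol.
#'
#' @param fm a `feature_matrix`.
#' @param n_train,n_test row counts; must sum to `nrow(fm$values)`.
#' @param seed integer seed.
#' @return a `split_plan`: list with `train_rows`, `test_rows`,
#'   `experiment = 1`, `seed`.
#' @export
split_experiment1 <- function(fm, n_train = 700L, n_test = 300L, seed) {
  n <- nrow(fm$values)
  if (n_train + n_test != n) {
    stop("n_train + n_test (", n_train + n_test,
         ") must equal row count (", n, ")", call. = FALSE)
  }
  if (n_train < 1L || n_test < 1L) {
    stop("both train and test sets must be non-empty", call. = FALSE)
  }
  set.seed(as.integer(seed))
  train_rows <- integer(0)
  frac <- n_train / n
  for (lab in unique(fm$labels)) {
    rows <- which(fm$labels == lab)
    take <- round(length(rows) * frac)
    train_rows <- c(train_rows, sample(rows, take))
  }
  # fix rounding drift so counts are exact
  if (length(train_rows) != n_train) {
    pool <- setdiff(seq_len(n), train_rows)
    if (length(train_rows) < n_train) {
      train_rows <- c(train_rows,
                      sample(pool, n_train - length(train_rows)))
    } else {
      train_rows <- sample(train_rows, n_train)
    }
  }
  train_rows <- sort(train_rows)
  structure(list(train_rows = train_rows,
                 test_rows = setdiff(seq_len(n), train_rows),
                 experiment = 1L, seed = seed),
            class = "split_plan")
}

#' Row subset of a feature matrix
#' @param fm a `feature_matrix`.
#' @param rows row indices to keep.
#' @return a `feature_matrix` restricted to those rows.
#' @export
feature_matrix_rows <- function(fm, rows) {
  structure(list(values = fm$values[rows, , drop = FALSE],
                 labels = fm$labels[rows],
                 provenance = fm$provenance[rows],
                 features = fm$features),
            class = "feature_matrix")
}

#' Subject-disjoint train/test generation (Experiment 2 protocol)
#'
#' Draws disjoint subject pools per cohort (study defaults: 40 of the 64 case
#' subjects and 24 of the 39 controls for training, the remainder for test),
#' then generates training subset rows exclusively from the training pools and
#' test rows exclusively from the held-out subjects, so no subject contributes
#' feature vectors on both sides of the split. Row totals default to 700/300,
#' split evenly across cohorts with any odd remainder going to the case
#' cohort. The disjointness audit is a hard assertion.
#'
#' @param case_table,control_table single-cohort `thickness_table`s.
#' @param features a `feature_set`.
#' @param n_train_case_subjects,n_train_control_subjects training pool sizes.
#' @param n_train_rows,n_test_rows subset-row totals per partition.
#' @param g subset size.
#' @param seed master seed.
#' @return list with `train` and `test` (`feature_matrix`s) and `plan`
#'   (a `split_plan` with the subject pools).
#' @export
split_experiment2 <- function(case_table, control_table, features,
                              n_train_case_subjects = 40L,
                              n_train_control_subjects = 24L,
                              n_train_rows = 700L, n_test_rows = 300L,
                              g = 6L, seed) {
  n_case <- nrow(case_table$values)
  n_ctrl <- nrow(control_table$values)
  if (n_train_case_subjects >= n_case ||
      n_train_control_subjects >= n_ctrl) {
    stop("training pools must leave subjects for the test pools",
         call. = FALSE)
  }
  pools_ok <- min(n_train_case_subjects, n_train_control_subjects,
                  n_case - n_train_case_subjects,
                  n_ctrl - n_train_control_subjects) >= g
  if (!pools_ok) {
    stop("every subject pool must have at least g = ", g, " subjects",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, 21L))
  train_case_ids <- sample(case_table$subject_ids, n_train_case_subjects)
  train_ctrl_ids <- sample(control_table$subject_ids,
                           n_train_control_subjects)
  test_case_ids <- setdiff(case_table$subject_ids, train_case_ids)
  test_ctrl_ids <- setdiff(control_table$subject_ids, train_ctrl_ids)

  slice <- function(tab, ids) {
    keep <- tab$subject_ids %in% ids
    thickness_table(tab$values[keep, , drop = FALSE], tab$subject_ids[keep],
                    tab$cohort_labels[keep], atlas = tab$atlas)
  }
  per_cohort <- function(total) {
    c(case = ceiling(total / 2), control = floor(total / 2))
  }
  train <- build_feature_matrix(slice(case_table, train_case_ids),
                                slice(control_table, train_ctrl_ids),
                                features, per_cohort(n_train_rows), g,
                                derive_seed(seed, 22L))
  test <- build_feature_matrix(slice(case_table, test_case_ids),
                               slice(control_table, test_ctrl_ids),
                               features, per_cohort(n_test_rows), g,
                               derive_seed(seed, 23L))
  plan <- structure(
    list(train_rows = seq_len(nrow(train$values)),
         test_rows = seq_len(nrow(test$values)),
         experiment = 2L, seed = seed,
         train_subject_pool = sort(c(train_case_ids, train_ctrl_ids)),
         test_subject_pool = sort(c(test_case_ids, test_ctrl_ids))),
    class = "split_plan")
  audit_subject_disjoint(train, test, plan)
  list(train = train, test = test, plan = plan)
}

#' Audit subject-disjointness of a train/test pair
#'
#' Hard assertion that the train and test subject pools are disjoint and that
#' every row's provenance subjects lie inside the partition's pool.
#'
#' @param train,test `feature_matrix`s with provenance.
#' @param plan a `split_plan` with subject pools.
#' @return `TRUE` invisibly; stops on any violation.
#' @export
audit_subject_disjoint <- function(train, test, plan) {
  overlap <- intersect(plan$train_subject_pool, plan$test_subject_pool)
  if (length(overlap) > 0L) {
    stop("subject pools overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  in_pool <- function(prov, pool) {
    all(vapply(prov, function(ids) all(ids %in% pool), logical(1L)))
  }
  if (!in_pool(train$provenance, plan$train_subject_pool)) {
    stop("training row built from a subject outside the training pool",
         call. = FALSE)
  }
  if (!in_pool(test$provenance, plan$test_subject_pool)) {
    stop("test row built from a subject outside the test pool",
         call. = FALSE)
  }
  invisible(TRUE)
}

# rank-based (Mann-Whitney) AUC of scores for binary labels; positive = case
auc_score <- function(scores, labels) {
  pos <- labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lab in unique(labels)) {
    rows <- which(labels == lab)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' Fit a sparsity-constrained linear classifier
#'
#' L1-penalized logistic regression (via glmnet) on internally standardized
#' features, with the penalty constant chosen by stratified k-fold
#' cross-validation maximizing mean validation AUC over a log-spaced grid,
#' then refit on the full training set at the selected penalty. Ties on CV
#' AUC go to the larger (sparser) penalty. Constant features are dropped with
#' a warning. `"case"` is the positive class.
#'
#' @param train a `feature_matrix` of training rows (both classes present).
#' @param penalty_grid candidate L1 penalties; default 20 values log-spaced
#'   over `[1e-3, 1e2]`.
#' @param cv_folds number of CV folds (default 5).
#' @param seed integer seed (fold assignment).
#' @return a `sparse_linear_model`: weights and intercept on the standardized
#'   scale, per-feature `center`/`scale`, selected `penalty`, and the CV AUC
#'   table (`cv_results`).
#' @export
fit_sparse_linear <- function(train,
                              penalty_grid = 10^seq(-3, 2, length.out = 20L),
                              cv_folds = 5L, seed = 1L) {
  x <- train$values
  y <- factor(train$labels, levels = c("control", "case"))
  if (any(table(y) < 2L)) {
    stop("need at least 2 training rows per class", call. = FALSE)
  }
  if (length(penalty_grid) < 1L) stop("empty penalty grid", call. = FALSE)
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  keep <- scale_ > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, center[keep]),
              2L, scale_[keep], "/")
  lambda <- sort(unique(penalty_grid), decreasing = TRUE)

  set.seed(as.integer(seed))
  fold <- stratified_folds(train$labels, cv_folds)
  cv_auc <- matrix(NA_real_, cv_folds, length(lambda))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- glmnet::glmnet(xs[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 1,
                          lambda = lambda, standardize = FALSE)
    pred <- stats::predict(fit, xs[!tr, , drop = FALSE], s = lambda,
                           type = "link")
    cv_auc[f, ] <- apply(pred, 2L, auc_score,
                         labels = train$labels[!tr])
  }
  mean_auc <- colMeans(cv_auc)
  best <- which.max(mean_auc)  # lambda sorted decreasing: ties -> sparser
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda[best]))
  weights <- numeric(ncol(x))
  names(weights) <- colnames(x)
  weights[keep] <- beta[-1L]
  structure(
    list(weights = weights, intercept = beta[1L],
         center = center, scale = scale_, kept = keep,
         penalty = lambda[best], cv_folds = cv_folds,
         cv_results = data.frame(penalty = lambda, mean_auc = mean_auc),
         positive_class = "case"),
    class = "sparse_linear_model"
  )
}

#' @export
print.sparse_linear_model <- function(x, ...) {
  cat(sprintf(
    "sparse_linear_model: penalty=%.4g, %d/%d nonzero weights (%d-fold CV)\n",
    x$penalty, sum(x$weights != 0), length(x$weights), x$cv_folds))
  invisible(x)
}

#' Predict from a sparse linear model
#'
#' @param object a `sparse_linear_model`.
#' @param newdata a `feature_matrix` or numeric matrix with the training
#'   feature columns.
#' @param type `"score"` (linear decision value, higher = more case-like) or
#'   `"class"`.
#' @param ... unused.
#' @return numeric scores or a character vector of class labels.
#' @export
predict.sparse_linear_model <- function(object, newdata,
                                        type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  k <- object$kept
  xs <- sweep(sweep(x[, k, drop = FALSE], 2L, object$center[k]),
              2L, object$scale[k], "/")
  score <- drop(xs %*% object$weights[k]) + object$intercept
  if (type == "score") return(score)
  ifelse(score > 0, "case", "control")
}

# empirical ROC of scores vs labels on a threshold sweep
roc_points <- function(scores, labels) {
  pos <- labels == "case"
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  # collapse tied scores to one operating point
  last <- c(diff(scores[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve with bootstrap confidence bounds
#'
#' Sweeps the model's test-set scores over all thresholds, computes the AUC by
#' the trapezoid rule, and attaches per-FPR-grid-point percentile confidence
#' bounds from stratified bootstrap resamples of the test rows (study
#' default: 100 replicates).
#'
#' @param model a `sparse_linear_model`.
#' @param test a `feature_matrix` of test rows (both classes present).
#' @param n_boot bootstrap replicate count.
#' @param seed integer seed.
#' @param conf_level confidence level for the percentile bounds.
#' @param fpr_grid FPR grid for the interpolated curve and its bounds.
#' @return a `roc_result`: full `curve` (fpr/tpr), `auc`, `fpr_grid`,
#'   `tpr_grid`, `lower`/`upper` bounds, `boot_auc`, `n_boot`.
#' @export
roc_with_bootstrap <- function(model, test, n_boot = 100L, seed = 1L,
                               conf_level = 0.95,
                               fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(unique(test$labels)) < 2L) {
    stop("test set must contain both classes", call. = FALSE)
  }
  scores <- stats::predict(model, test)
  labels <- test$labels
  pts <- roc_points(scores, labels)
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  interp <- function(p) {
    stats::approx(p$fpr, p$tpr, xout = fpr_grid, ties = max, rule = 2)$y
  }
  tpr_grid <- interp(pts)
  set.seed(as.integer(seed))
  idx_by_class <- split(seq_along(labels), labels)
  boot_tpr <- matrix(NA_real_, n_boot, length(fpr_grid))
  boot_auc <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_class, function(ii)
      sample(ii, length(ii), replace = TRUE)), use.names = FALSE)
    pb <- roc_points(scores[idx], labels[idx])
    boot_tpr[b, ] <- interp(pb)
    boot_auc[b] <- trapezoid_auc(pb$fpr, pb$tpr)
  }
  alpha <- (1 - conf_level) / 2
  lower <- apply(boot_tpr, 2L, stats::quantile, probs = alpha)
  upper <- apply(boot_tpr, 2L, stats::quantile, probs = 1 - alpha)
  # bounds must bracket the point estimate
  lower <- pmin(lower, tpr_grid)
  upper <- pmax(upper, tpr_grid)
  structure(
    list(curve = pts, auc = auc, fpr_grid = fpr_grid, tpr_grid = tpr_grid,
         lower = lower, upper = upper, boot_auc = boot_auc,
         n_boot = n_boot, conf_level = conf_level),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC=%.3f (%d bootstrap replicates)\n",
              x$auc, x$n_boot))
  invisible(x)
}

#' Interpolated TPR at a fixed FPR
#' @param roc a `roc_result`.
#' @param fpr target false positive rate(s) in `[0, 1]`.
#' @return linearly interpolated true positive rate(s).
#' @export
tpr_at_fpr <- function(roc, fpr) {
  stats::approx(roc$curve$fpr, roc$curve$tpr, xout = fpr,
                ties = max, rule = 2)$y
}

#' Principal-component embedding of a feature matrix
#'
#' Projects the (internally centered) subset rows onto the top principal
#' axes; the 2-D embedding of the 15 within-subset correlations is the
#' standard visual check that the two cohorts' subset clouds separate.
#'
#' @param fm a `feature_matrix`.
#' @param dims number of components (default 2, <= feature count).
#' @return matrix of row scores (rows x dims) with attributes `"labels"` and
#'   `"sdev"` (component standard deviations, non-increasing).
#' @export
pca_embed <- function(fm, dims = 2L) {
  k <- ncol(fm$values)
  if (dims > k) stop("dims (", dims, ") exceeds feature count (", k, ")",
                     call. = FALSE)
  if (nrow(fm$values) < dims) stop("need at least dims rows", call. = FALSE)
  pc <- stats::prcomp(fm$values, center = TRUE, scale. = FALSE)
  out <- pc$x[, seq_len(dims), drop = FALSE]
  attr(out, "labels") <- fm$labels
  attr(out, "sdev") <- pc$sdev[seq_len(dims)]
  out
}
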