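#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis. Defaults are
#' the study constants: 15 features, subsets of 6, 500 subsets per cohort
#' (1000 rows), a 700/300 train/test row split, subject pools of 40/24 for
#' the subject-disjoint protocol, 5 CV folds, 100 bootstrap replicates.
#'
#' @param case_path,control_path optional thickness-table TSV paths; when
#'   `NULL` the synthetic planted-hub generator is used.
#' @param dialect input table dialect (see [read_thickness_table()]).
#' @param synthetic a `synthetic_spec` for simulated input.
#' @param k number of selected features.
#' @param g subset size.
#' @param n_subsets_per_cohort subset draws per cohort.
#' @param n_train_rows,n_test_rows experiment row split; their sum must equal
#'   `2 * n_subsets_per_cohort`.
#' @param n_train_case_subjects,n_train_control_subjects experiment-2 pools.
#' @param penalty_grid,cv_folds,n_boot classifier settings.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(case_path = NULL, control_path = NULL,
                            dialect = "plain",
                            synthetic = planted_hub_spec(),
                            k = 15L, g = 6L,
                            n_subsets_per_cohort = 500L,
                            n_train_rows = 700L, n_test_rows = 300L,
                            n_train_case_subjects = 40L,
                            n_train_control_subjects = 24L,
                            penalty_grid = 10^seq(-3, 2, length.out = 20L),
                            cv_folds = 5L, n_boot = 100L) {
  stopifnot(k >= 1L, g >= 3L, n_subsets_per_cohort >= 1L,
            cv_folds >= 2L, n_boot >= 1L)
  if (n_train_rows + n_test_rows != 2L * n_subsets_per_cohort) {
    stop("n_train_rows + n_test_rows (", n_train_rows + n_test_rows,
         ") must equal 2 * n_subsets_per_cohort (",
         2L * n_subsets_per_cohort, ")", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON (or YAML)
#'
#' JSON is read with jsonlite; files ending in `.yaml`/`.yml` are read with
#' the yaml package when it is installed. Unknown fields are an error.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

pipeline_input <- function(config, seed) {
  if (!is.null(config$case_path)) {
    list(case = read_thickness_table(config$case_path, config$dialect,
                                     cohort_label = "case"),
         control = read_thickness_table(config$control_path, config$dialect,
                                        cohort_label = "control"),
         source = "files")
  } else {
    c(simulate_cohorts(config$synthetic, seed), list(source = "synthetic"))
  }
}

#' Run the full separability pipeline
#'
#' Sequences the whole analysis from a [pipeline_config()] and a master seed:
#' cohort correlation matrices and their absolute difference, top-k feature
#' selection, the labeled subset-feature matrix, the cumulative
#' Henze-Penrose separability curve, the 2-D PCA embedding, and the two
#' classification experiments (overlapping and subject-disjoint) with
#' bootstrap ROC. Deterministic given the master seed (stage seeds via
#' [derive_seed()]). With `out_dir` set, writes TSV/CSV/JSON outputs, PNG
#' figures, and a run log.
#'
#' @param config a `pipeline_config`.
#' @param seed master integer seed.
#' @param out_dir optional output directory (created if missing).
#' @return a `pipeline_report` list: `features`, `curve`, `embedding`,
#'   `experiment1` / `experiment2` (model, ROC, AUC, TPR at FPR 0.1), and
#'   correlation matrices.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("stage input: ", if (is.null(config$case_path)) "synthetic cohorts"
       else "thickness tables")
  input <- pipeline_input(config, seed)
  note("  case n=", nrow(input$case$values),
       " control n=", nrow(input$control$values))

  note("stage correlation: per-cohort Pearson matrices + |difference|")
  cm_case <- cohort_correlation(input$case)
  cm_ctrl <- cohort_correlation(input$control)
  dm <- correlation_difference(cm_case, cm_ctrl)

  note("stage features: top-", config$k,
       " pairs by absolute correlation difference ",
       "(per-pair Euclidean distance)")
  features <- select_top_features(dm, k = config$k)

  note("stage feature matrix: ", config$n_subsets_per_cohort,
       " subsets of ", config$g, " per cohort")
  fm <- build_feature_matrix(input$case, input$control, features,
                             config$n_subsets_per_cohort, config$g,
                             derive_seed(seed, 31L))

  note("stage separability: cumulative Henze-Penrose curve")
  curve <- hpd_feature_curve(fm)
  note(sprintf("  final separability = %.4f",
               curve$separability[nrow(curve)]))

  embedding <- pca_embed(fm, 2L)

  note("stage experiment 1: overlapping-subject ",
       config$n_train_rows, "/", config$n_test_rows, " row split")
  plan1 <- split_experiment1(fm, config$n_train_rows, config$n_test_rows,
                             derive_seed(seed, 41L))
  train1 <- feature_matrix_rows(fm, plan1$train_rows)
  test1 <- feature_matrix_rows(fm, plan1$test_rows)
  model1 <- fit_sparse_linear(train1, config$penalty_grid, config$cv_folds,
                              derive_seed(seed, 42L))
  roc1 <- roc_with_bootstrap(model1, test1, config$n_boot,
                             derive_seed(seed, 43L))

  note("stage experiment 2: subject-disjoint pools ",
       config$n_train_case_subjects, "/", config$n_train_control_subjects)
  exp2 <- split_experiment2(input$case, input$control, features,
                            config$n_train_case_subjects,
                            config$n_train_control_subjects,
                            config$n_train_rows, config$n_test_rows,
                            config$g, derive_seed(seed, 44L))
  note("  subject-disjointness audit passed")
  model2 <- fit_sparse_linear(exp2$train, config$penalty_grid,
                              config$cv_folds, derive_seed(seed, 45L))
  roc2 <- roc_with_bootstrap(model2, exp2$test, config$n_boot,
                             derive_seed(seed, 46L))
  note(sprintf("  AUC experiment1=%.3f experiment2=%.3f", roc1$auc, roc2$auc))

  report <- structure(
    list(seed = seed,
         correlations = list(case = cm_case, control = cm_ctrl,
                             difference = dm),
         features = features,
         feature_matrix = fm,
         curve = curve,
         embedding = embedding,
         experiment1 = list(model = model1, roc = roc1, auc = roc1$auc,
                            tpr_at_fpr_0.1 = tpr_at_fpr(roc1, 0.1)),
         experiment2 = list(model = model2, roc = roc2, auc = roc2$auc,
                            tpr_at_fpr_0.1 = tpr_at_fpr(roc2, 0.1),
                            plan = exp2$plan),
         log = log_lines),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Machine-readable summary of a pipeline report
#' @param report a `pipeline_report`.
#' @return a plain list suitable for JSON serialization.
#' @export
report_summary <- function(report) {
  list(
    seed = report$seed,
    features = as.data.frame(report$features),
    separability_curve = as.data.frame(report$curve),
    final_separability =
      report$curve$separability[nrow(report$curve)],
    experiment1 = list(auc = report$experiment1$auc,
                       tpr_at_fpr_0.1 = report$experiment1$tpr_at_fpr_0.1,
                       penalty = report$experiment1$model$penalty),
    experiment2 = list(auc = report$experiment2$auc,
                       tpr_at_fpr_0.1 = report$experiment2$tpr_at_fpr_0.1,
                       penalty = report$experiment2$model$penalty,
                       train_subject_pool =
                         report$experiment2$plan$train_subject_pool,
                       test_subject_pool =
                         report$experiment2$plan$test_subject_pool)
  )
}

# correlation heatmap on the study's fixed [-0.1, 1] color scale
plot_correlation_heatmap <- function(V, main, zlim = c(-0.1, 1)) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101L)
  graphics::image(seq_len(ncol(V)), seq_len(nrow(V)),
                  t(pmin(pmax(V, zlim[1L]), zlim[2L])),
                  zlim = zlim, col = pal, main = main,
                  xlab = "region", ylab = "region", useRaster = TRUE)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_feature_set(report$features, fp("features.tsv"))
  utils::write.table(as.data.frame(report$curve),
                     fp("separability_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_matrix(report$feature_matrix, fp("feature_matrix.csv"))
  emb <- data.frame(label = attr(report$embedding, "labels"),
                    report$embedding)
  utils::write.table(emb, fp("pca_embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (e in c("experiment1", "experiment2")) {
    roc <- report[[e]]$roc
    utils::write.table(
      data.frame(fpr = roc$fpr_grid, tpr = roc$tpr_grid,
                 lower = roc$lower, upper = roc$upper),
      fp(paste0("roc_", e, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    model <- report[[e]]$model
    jsonlite::write_json(
      list(weights = as.list(model$weights), intercept = model$intercept,
           penalty = model$penalty, cv_folds = model$cv_folds),
      fp(paste0("model_", e, ".json")), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report_summary(report), fp("results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(report$log, fp("run_log.txt"))
  try({
    grDevices::png(fp("correlation_heatmaps.png"), 1200, 400)
    graphics::par(mfrow = c(1, 3))
    plot_correlation_heatmap(report$correlations$control$values,
                             "control correlations")
    plot_correlation_heatmap(report$correlations$case$values,
                             "case correlations")
    plot_correlation_heatmap(report$correlations$difference,
                             "|case - control|")
    grDevices::dev.off()

    grDevices::png(fp("separability_curve.png"), 600, 450)
    graphics::plot(report$curve$n_features, report$curve$separability,
                   type = "b", ylim = c(0.5, 1), xlab = "features used",
                   ylab = "HP separability",
                   main = "cumulative separability")
    graphics::abline(h = 0.9, lty = 2)
    grDevices::dev.off()

    grDevices::png(fp("pca_embedding.png"), 600, 450)
    cols <- ifelse(attr(report$embedding, "labels") == "case", 2L, 4L)
    graphics::plot(report$embedding, col = cols, pch = 16, cex = 0.6,
                   xlab = "PC1", ylab = "PC2", main = "PCA embedding")
    graphics::legend("topright", c("case", "control"), col = c(2L, 4L),
                     pch = 16)
    grDevices::dev.off()

    grDevices::png(fp("roc_curves.png"), 600, 450)
    r1 <- report$experiment1$roc; r2 <- report$experiment2$roc
    graphics::plot(r1$curve$fpr, r1$curve$tpr, type = "l", col = 2L,
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = "ROC: overlapping vs subject-disjoint")
    graphics::lines(r2$curve$fpr, r2$curve$tpr, col = 4L)
    graphics::abline(0, 1, lty = 3)
    graphics::legend("bottomright",
                     sprintf("experiment %d (AUC %.2f)", 1:2,
                             c(r1$auc, r2$auc)),
                     col = c(2L, 4L), lty = 1)
    grDevices::dev.off()
  }, silent = TRUE)
  invisible(out_dir)
}
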