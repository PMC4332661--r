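# Programmatic fixtures: small thickness tables built in code.

dk70 <- load_atlas("dk70")

# table of n subjects with random positive thickness; selected regions can be
# overridden with explicit per-subject values
tiny_table <- function(n, cohort = "case", override = list(), seed = 1,
                       prefix = cohort) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 70, mean = 2.5, sd = 0.15), n, 70)
  colnames(vals) <- dk70$region_names
  for (reg in names(override)) vals[, reg] <- override[[reg]]
  thickness_table(vals, sprintf("%s%02d", prefix, seq_len(n)),
                  rep(cohort, n), atlas = dk70)
}

# a feature_set-shaped data.frame from explicit region pairs
pairs_features <- function(region_i, region_j) {
  data.frame(rank = seq_along(region_i), region_i = region_i,
             region_j = region_j, score = NA_real_,
             stringsAsFactors = FALSE)
}

# small scaled-down pipeline config for fast end-to-end tests
small_config <- function(...) {
  pipeline_config(n_subsets_per_cohort = 30L, n_train_rows = 40L,
                  n_test_rows = 20L, n_boot = 10L, cv_folds = 3L,
                  n_train_case_subjects = 40L,
                  n_train_control_subjects = 24L, ...)
}

# feature_matrix wrapper around a plain matrix + labels
as_feature_matrix <- function(values, labels, provenance = NULL) {
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  structure(list(values = values, labels = labels,
                 provenance = provenance,
                 features = pairs_features(colnames(values),
                                           colnames(values))),
            class = "feature_matrix")
}
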