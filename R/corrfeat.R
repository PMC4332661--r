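#' Cohort interregional correlation matrix
#'
#' Pearson correlation, across the subjects of one table, between every pair
#' of regional thickness values — the standard structural-covariance matrix.
#'
#' @param table a `thickness_table` with at least 3 subjects.
#' @return a `correlation_matrix` object: 70 x 70 symmetric `values` with unit
#'   diagonal, `n_subjects`, and the `atlas`.
#' @export
cohort_correlation <- function(table) {
  X <- table$values
  if (nrow(X) < 3L) {
    stop("need at least 3 subjects to correlate, got ", nrow(X),
         call. = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  V <- stats::cor(X)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  structure(list(values = V, n_subjects = nrow(X), atlas = table$atlas),
            class = "correlation_matrix")
}

#' Absolute cross-cohort correlation difference
#'
#' Entrywise `|r_case - r_control|`. The per-pair Euclidean distance between
#' two scalars reduces to this absolute difference, which is the difference
#' map the feature selection ranks.
#'
#' @param case_cm,control_cm `correlation_matrix` objects on the same atlas.
#' @return symmetric matrix with zero diagonal, attribute `"atlas"`.
#' @export
correlation_difference <- function(case_cm, control_cm) {
  if (!atlas_identical(case_cm$atlas, control_cm$atlas)) {
    stop("atlas mismatch between correlation matrices", call. = FALSE)
  }
  D <- abs(case_cm$values - control_cm$values)
  diag(D) <- 0
  attr(D, "atlas") <- case_cm$atlas
  D
}

#' Select the top-k difference features
#'
#' Ranks all off-diagonal region pairs by the cross-cohort correlation
#' difference and keeps the `k` largest (default 15). Ties are broken
#' lexicographically on the canonical (i, j) pair order, so the selection is
#' deterministic.
#'
#' @param diff difference matrix from [correlation_difference()] (or any
#'   symmetric matrix with an `"atlas"` attribute / atlas-ordered dimnames).
#' @param k number of features to keep.
#' @param atlas region atlas; defaults to the matrix's `"atlas"` attribute.
#' @return a `feature_set`: data.frame with `rank`, `region_i`, `region_j`
#'   (i < j in canonical order), `score` (non-increasing).
#' @export
select_top_features <- function(diff, k = 15L, atlas = attr(diff, "atlas")) {
  if (is.null(atlas)) stop("atlas is required", call. = FALSE)
  rn <- region_names_of(atlas)
  p <- length(rn)
  if (!is.matrix(diff) || any(dim(diff) != p)) {
    stop("diff must be a ", p, " x ", p, " matrix", call. = FALSE)
  }
  n_pairs <- p * (p - 1L) / 2L
  if (k <= 0L || k > n_pairs) {
    stop("k must be in [1, ", n_pairs, "], got ", k, call. = FALSE)
  }
  ut <- which(upper.tri(diff), arr.ind = TRUE)  # row < col, column-major
  score <- diff[ut]
  ord <- order(-score, ut[, 1L], ut[, 2L])[seq_len(k)]
  structure(
    data.frame(rank = seq_len(k),
               region_i = rn[ut[ord, 1L]],
               region_j = rn[ut[ord, 2L]],
               score = score[ord],
               stringsAsFactors = FALSE),
    class = c("feature_set", "data.frame"),
    atlas = atlas
  )
}

#' Count candidate correlation features
#'
#' Number of unique entries of a p-region correlation matrix: `p(p-1)/2`
#' off-diagonal pairs, plus `p` diagonal entries when `include_diagonal` is
#' `TRUE` (70 regions give 2415 and 2485 respectively; both conventions are
#' in circulation, so both are exposed).
#'
#' @param atlas region atlas.
#' @param include_diagonal count the (constant) diagonal self-correlations?
#' @return integer count.
#' @export
count_candidate_features <- function(atlas = load_atlas("dk70"),
                                     include_diagonal = FALSE) {
  p <- length(region_names_of(atlas))
  (p * (p - 1L)) %/% 2L + if (include_diagonal) p else 0L
}

#' Draw random subject subsets from one cohort
#'
#' Each draw takes `g` distinct subjects uniformly without replacement;
#' subjects recur freely across draws. Deterministic given `seed`.
#'
#' @param table a `thickness_table`.
#' @param cohort `"case"` or `"control"`.
#' @param g subset size (default 6).
#' @param n_subsets number of draws.
#' @param seed integer seed.
#' @return list of `n_subsets` character vectors of subject IDs, with
#'   attribute `"cohort"`.
#' @export
sample_subsets <- function(table, cohort, g = 6L, n_subsets, seed) {
  ids <- table$subject_ids[table$cohort_labels == cohort]
  if (length(ids) < g) {
    stop("cohort '", cohort, "' has ", length(ids),
         " subjects, fewer than g = ", g, call. = FALSE)
  }
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(n_subsets), function(i) sample(ids, g))
  attr(draws, "cohort") <- cohort
  draws
}

#' Within-subset feature vector
#'
#' For one subset of `g` subjects, the Pearson correlation across those
#' subjects of each selected region pair — one k-vector per subset.
#'
#' @param table a `thickness_table` containing the subset's subjects.
#' @param subject_ids character vector of subset member IDs.
#' @param features a `feature_set`.
#' @param na_feature if `TRUE`, a zero-variance region within the subset
#'   yields `NA` for affected features instead of an error.
#' @return numeric vector of length `nrow(features)`, entries in `[-1, 1]`.
#' @export
subset_feature_vector <- function(table, subject_ids, features,
                                  na_feature = FALSE) {
  miss <- setdiff(subject_ids, table$subject_ids)
  if (length(miss) > 0L) {
    stop("subset subjects not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sub <- table$values[subject_ids, , drop = FALSE]
  regions <- unique(c(features$region_i, features$region_j))
  sds <- apply(sub[, regions, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0) && !na_feature) {
    stop("zero within-subset variance for region(s): ",
         paste(regions[sds == 0], collapse = ", "), call. = FALSE)
  }
  C <- suppressWarnings(stats::cor(sub[, regions, drop = FALSE]))
  C[!is.finite(C)] <- NA_real_
  C[cbind(match(features$region_i, regions),
          match(features$region_j, regions))]
}

#' Build the labeled subset-feature matrix
#'
#' Draws `n_subsets_per_cohort` subsets of `g` subjects from each cohort and
#' computes the k within-subset correlations for each, concatenated into one
#' labeled matrix (the study default, 500 subsets of six per cohort with
#' k = 15, gives a 1000 x 15 matrix). Row provenance (the subject IDs behind
#' each row) is retained for subject-disjointness audits.
#'
#' @param case_table,control_table single-cohort `thickness_table`s.
#' @param features a `feature_set`.
#' @param n_subsets_per_cohort draws per cohort; a single count or a named
#'   vector `c(case = ..., control = ...)`.
#' @param g subset size.
#' @param seed master seed (cohort draws use [derive_seed()] offsets 11, 12).
#' @param na_feature propagate `NA` features (rows with any `NA` are dropped
#'   with a message) instead of erroring on degenerate subsets.
#' @return a `feature_matrix`: list with `values` (rows x k, entries in
#'   `[-1, 1]`), `labels`, `provenance` (list of ID vectors), `features`.
#' @export
build_feature_matrix <- function(case_table, control_table, features,
                                 n_subsets_per_cohort = 500L, g = 6L, seed,
                                 na_feature = FALSE) {
  n_per <- if (length(n_subsets_per_cohort) == 1L) {
    c(case = n_subsets_per_cohort, control = n_subsets_per_cohort)
  } else n_subsets_per_cohort
  draws_case <- sample_subsets(case_table, "case", g, n_per[["case"]],
                               derive_seed(seed, 11L))
  draws_ctrl <- sample_subsets(control_table, "control", g, n_per[["control"]],
                               derive_seed(seed, 12L))
  fv <- function(tab, draws) {
    t(vapply(draws, function(ids)
      subset_feature_vector(tab, ids, features, na_feature = na_feature),
      numeric(nrow(features))))
  }
  values <- rbind(fv(case_table, draws_case), fv(control_table, draws_ctrl))
  labels <- rep(c("case", "control"), c(n_per[["case"]], n_per[["control"]]))
  provenance <- c(draws_case, draws_ctrl)
  if (anyNA(values)) {
    bad <- apply(values, 1L, anyNA)
    message("dropping ", sum(bad), " subset row(s) with undefined features")
    values <- values[!bad, , drop = FALSE]
    labels <- labels[!bad]
    provenance <- provenance[!bad]
  }
  colnames(values) <- paste(features$region_i, features$region_j, sep = "|")
  structure(list(values = values, labels = labels, provenance = provenance,
                 features = features),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "subset rows x",
      ncol(x$values), "features (",
      sum(x$labels == "case"), "case /", sum(x$labels == "control"),
      "control )\n")
  invisible(x)
}

#' Write a feature set as TSV
#' @param features a `feature_set`.
#' @param path output path.
#' @export
write_feature_set <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV plus a provenance sidecar
#'
#' The CSV has a `label` column then the k feature columns; the sidecar JSON
#' (`<path>.provenance.json`) maps each row to the subject IDs it was built
#' from.
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(label = fm$labels, fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fm$provenance, paste0(path, ".provenance.json"))
  invisible(path)
}
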