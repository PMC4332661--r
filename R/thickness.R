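#' Construct a cortical thickness table
#'
#' The pipeline's sole input container: a subjects x 70-region matrix of mean
#' cortical thickness (mm) with per-subject cohort labels, aligned to a
#' [load_atlas()] region order.
#'
#' @param values numeric matrix, subjects x regions, thickness in mm.
#' @param subject_ids unique character IDs, one per row.
#' @param cohort_labels per-subject label, each `"case"` or `"control"`.
#' @param atlas a `region_atlas`; columns of `values` must follow its order.
#' @param drop_incomplete if `TRUE`, subjects with any missing region value
#'   are removed (with a message); otherwise missing values are an error.
#' @return a `thickness_table` object.
#' @export
thickness_table <- function(values, subject_ids, cohort_labels,
                            atlas = load_atlas("dk70"),
                            drop_incomplete = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(subject_ids)) {
    stop("subject_ids length must equal row count", call. = FALSE)
  }
  if (length(cohort_labels) == 1L) {
    cohort_labels <- rep(cohort_labels, nrow(values))
  }
  if (nrow(values) != length(cohort_labels)) {
    stop("cohort_labels length must equal row count", call. = FALSE)
  }
  if (!all(cohort_labels %in% c("case", "control"))) {
    stop("cohort labels must be 'case' or 'control'", call. = FALSE)
  }
  if (ncol(values) != length(atlas$region_names)) {
    stop("column count (", ncol(values), ") must equal atlas size (",
         length(atlas$region_names), ")", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject IDs: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    if (drop_incomplete) {
      bad <- apply(values, 1L, anyNA)
      message("dropping ", sum(bad), " subject(s) with missing region values: ",
              paste(subject_ids[bad], collapse = ", "))
      values <- values[!bad, , drop = FALSE]
      subject_ids <- subject_ids[!bad]
      cohort_labels <- cohort_labels[!bad]
    } else {
      stop("missing thickness values (set drop_incomplete = TRUE to drop ",
           "affected subjects)", call. = FALSE)
    }
  }
  nonpos <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0L) {
    i <- nonpos[1L, 1L]; j <- nonpos[1L, 2L]
    stop("non-positive or non-finite thickness for subject '", subject_ids[i],
         "', region '", atlas$region_names[j], "' (", values[i, j], ")",
         call. = FALSE)
  }
  dimnames(values) <- list(subject_ids, atlas$region_names)
  structure(
    list(values = values, subject_ids = subject_ids,
         cohort_labels = cohort_labels, atlas = atlas),
    class = "thickness_table"
  )
}

#' @export
print.thickness_table <- function(x, ...) {
  tab <- table(x$cohort_labels)
  cat("thickness_table:", nrow(x$values), "subjects x",
      ncol(x$values), "regions\n")
  cat("  cohorts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

thickness_colname <- function(region, dialect) {
  switch(dialect,
         aparcstats2table = paste0(region, "_thickness"),
         plain = region,
         stop("unknown dialect '", dialect, "'", call. = FALSE))
}

#' Read a cortical thickness table
#'
#' Parses tab-separated thickness tables in either the FreeSurfer
#' `aparcstats2table` dialect (first column subject ID, thickness columns named
#' `"<hemi>_<region>_thickness"`) or a plain dialect (header `subject_id`,
#' bare region columns, optional `cohort` column). Columns are re-aligned to
#' the canonical atlas order regardless of file order; non-atlas columns (for
#' example `lh_MeanThickness_thickness`) are ignored with a warning.
#'
#' @param path path to a tab-separated file.
#' @param dialect `"aparcstats2table"` or `"plain"`.
#' @param cohort_label cohort for all subjects in the file (`"case"` or
#'   `"control"`); required unless a plain-dialect file carries a `cohort`
#'   column.
#' @param atlas region atlas to align against.
#' @param drop_incomplete drop subjects with missing region values instead of
#'   erroring.
#' @return a [thickness_table()].
#' @export
read_thickness_table <- function(path,
                                 dialect = c("aparcstats2table", "plain"),
                                 cohort_label = NULL,
                                 atlas = load_atlas("dk70"),
                                 drop_incomplete = FALSE) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("file has fewer than 2 columns", call. = FALSE)
  id_col <- if (dialect == "plain") "subject_id" else names(df)[1L]
  if (dialect == "plain" && !("subject_id" %in% names(df))) {
    stop("plain dialect requires a 'subject_id' column", call. = FALSE)
  }
  ids <- as.character(df[[id_col]])

  wanted <- vapply(atlas$region_names, thickness_colname, "",
                   dialect = dialect)
  missing_cols <- atlas$region_names[!(wanted %in% names(df))]
  if (length(missing_cols) > 0L) {
    stop("missing region column(s): ",
         paste(vapply(utils::head(missing_cols, 5L), thickness_colname, "",
                      dialect = dialect), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(id_col, wanted, "cohort"))
  if (length(extra) > 0L) {
    warning("ignoring ", length(extra), " non-atlas column(s): ",
            paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }

  vals <- as.matrix(df[, wanted, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("non-numeric thickness values in file", call. = FALSE)
  }
  cohorts <- if (!is.null(cohort_label)) {
    cohort_label
  } else if ("cohort" %in% names(df)) {
    as.character(df[["cohort"]])
  } else {
    stop("cohort_label is required (file has no 'cohort' column)",
         call. = FALSE)
  }
  thickness_table(vals, ids, cohorts, atlas = atlas,
                  drop_incomplete = drop_incomplete)
}

#' Write a thickness table
#'
#' Writes the plain tab-separated dialect (`subject_id`, `cohort`, then the 70
#' region columns in canonical order); [read_thickness_table()] on the output
#' reproduces the values bit-exactly.
#'
#' @param table a `thickness_table`.
#' @param path output path.
#' @export
write_thickness_table <- function(table, path) {
  vals <- apply(table$values, 2L, sprintf, fmt = "%.17g")  # bit-exact
  df <- data.frame(subject_id = table$subject_ids,
                   cohort = table$cohort_labels,
                   vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate two single-cohort thickness tables
#'
#' @param case_table,control_table `thickness_table`s on the same atlas with
#'   disjoint subject IDs.
#' @return one `thickness_table` with cohort labels preserved.
#' @export
concat_cohorts <- function(case_table, control_table) {
  if (!inherits(case_table, "thickness_table") ||
      !inherits(control_table, "thickness_table")) {
    stop("inputs must be thickness_table objects", call. = FALSE)
  }
  if (nrow(case_table$values) == 0L || nrow(control_table$values) == 0L) {
    stop("cannot concatenate an empty cohort table", call. = FALSE)
  }
  if (!atlas_identical(case_table$atlas, control_table$atlas)) {
    stop("atlas mismatch between cohort tables", call. = FALSE)
  }
  shared <- intersect(case_table$subject_ids, control_table$subject_ids)
  if (length(shared) > 0L) {
    stop("overlapping subject IDs across cohorts: ",
         paste(utils::head(shared, 5L), collapse = ", "), call. = FALSE)
  }
  thickness_table(rbind(case_table$values, control_table$values),
                  c(case_table$subject_ids, control_table$subject_ids),
                  c(case_table$cohort_labels, control_table$cohort_labels),
                  atlas = case_table$atlas)
}

#' Extract the single-cohort slice of a thickness table
#' @param table a `thickness_table`.
#' @param cohort `"case"` or `"control"`.
#' @return a `thickness_table` restricted to that cohort.
#' @export
cohort_slice <- function(table, cohort) {
  keep <- table$cohort_labels == cohort
  if (!any(keep)) stop("no subjects in cohort '", cohort, "'", call. = FALSE)
  thickness_table(table$values[keep, , drop = FALSE],
                  table$subject_ids[keep], table$cohort_labels[keep],
                  atlas = table$atlas)
}
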