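#' Euclidean minimum spanning tree
#'
#' MST of the complete Euclidean graph on a point set, by Prim's algorithm on
#' the full distance matrix (O(N^2), ample for the pooled subset samples this
#' package handles). Ties between equal distances are broken deterministically
#' by smallest point index, so the returned tree is reproducible; with
#' continuous features exact ties are measure-zero and every MST has the same
#' total weight regardless.
#'
#' @param points numeric matrix (N x d) or vector (treated as 1-D), finite.
#' @return data.frame of `n - 1` edges with columns `i`, `j` (point indices,
#'   `i < j`) and `weight`; attribute `"total_weight"`.
#' @export
euclidean_mst <- function(points) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (!all(is.finite(points))) {
    stop("points must have finite coordinates", call. = FALSE)
  }
  D <- as.matrix(stats::dist(points))
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  min_d <- D[1L, ]
  parent <- rep(1L, n)
  min_d[1L] <- Inf
  edges_i <- integer(n - 1L)
  edges_j <- integer(n - 1L)
  edges_w <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    v <- which.min(min_d)  # ties -> smallest index
    edges_i[k] <- min(parent[v], v)
    edges_j[k] <- max(parent[v], v)
    edges_w[k] <- min_d[v]
    in_tree[v] <- TRUE
    min_d[v] <- Inf
    upd <- !in_tree & D[v, ] < min_d
    min_d[upd] <- D[v, upd]
    parent[upd] <- v
  }
  out <- data.frame(i = edges_i, j = edges_j, weight = edges_w)
  attr(out, "total_weight") <- sum(edges_w)
  out
}

#' Count cross-sample MST edges (Friedman-Rafsky statistic)
#'
#' Number of MST edges whose endpoints come from different samples. Few cross
#' edges mean the two samples occupy distinct parts of feature space.
#'
#' @param mst edge list from [euclidean_mst()].
#' @param labels per-point sample label (two levels, both present).
#' @return integer cross-edge count.
#' @export
cross_edge_count <- function(mst, labels) {
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both samples", call. = FALSE)
  }
  sum(labels[mst$i] != labels[mst$j])
}

#' Henze-Penrose divergence and separability of two samples
#'
#' Friedman-Rafsky MST estimate of the Henze-Penrose divergence: with C cross
#' edges in the pooled Euclidean MST of samples of sizes m and n,
#' `D = max(0, 1 - C (m + n) / (2 m n))`, clamped at 0 because a divergence is
#' non-negative (well-mixed samples can push the raw value below 0). The
#' separability score `S = (1 + D) / 2` lives in `[0.5, 1]`: 0.5 means the
#' samples cannot be told apart, 1 means they are completely separable.
#'
#' @param case_points,control_points numeric matrices with equal column count
#'   (>= 2 rows each).
#' @return an `hpd_result`: list with `m`, `n`, `cross_edges`, `divergence`,
#'   `separability`.
#' @export
hp_divergence <- function(case_points, control_points) {
  if (is.vector(case_points)) case_points <- matrix(case_points, ncol = 1L)
  if (is.vector(control_points)) {
    control_points <- matrix(control_points, ncol = 1L)
  }
  if (ncol(case_points) != ncol(control_points)) {
    stop("dimension mismatch between samples", call. = FALSE)
  }
  m <- nrow(case_points)
  n <- nrow(control_points)
  if (m < 2L || n < 2L) {
    stop("each sample needs at least 2 points", call. = FALSE)
  }
  pooled <- rbind(case_points, control_points)
  labels <- rep(c("case", "control"), c(m, n))
  C <- cross_edge_count(euclidean_mst(pooled), labels)
  D <- max(0, 1 - C * (m + n) / (2 * m * n))
  structure(
    list(m = m, n = n, cross_edges = C, divergence = D,
         separability = (1 + D) / 2),
    class = "hpd_result"
  )
}

#' @export
print.hpd_result <- function(x, ...) {
  cat(sprintf("hpd_result: m=%d n=%d cross_edges=%d D=%.4f S=%.4f\n",
              x$m, x$n, x$cross_edges, x$divergence, x$separability))
  invisible(x)
}

#' Cumulative feature-separability curve
#'
#' Separability of case vs control subset rows as features are added in rank
#' order: for j = 1..k, the Henze-Penrose separability computed on the first j
#' feature columns. The final value equals [hp_divergence()] on the full
#' matrix.
#'
#' @param fm a `feature_matrix`.
#' @return a `separability_curve`: data.frame with `n_features`,
#'   `cross_edges`, `divergence`, `separability`.
#' @export
hpd_feature_curve <- function(fm) {
  k <- ncol(fm$values)
  is_case <- fm$labels == "case"
  rows <- lapply(seq_len(k), function(j) {
    r <- hp_divergence(fm$values[is_case, seq_len(j), drop = FALSE],
                       fm$values[!is_case, seq_len(j), drop = FALSE])
    data.frame(n_features = j, cross_edges = r$cross_edges,
               divergence = r$divergence, separability = r$separability)
  })
  structure(do.call(rbind, rows),
            class = c("separability_curve", "data.frame"))
}
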