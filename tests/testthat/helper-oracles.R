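# Independent test-side oracles. These deliberately reimplement, by a
# different route, the quantities the package computes.

# minimum spanning-tree weight by exhaustive enumeration of all n^(n-2)
# labeled trees via Prufer sequences (Cayley's formula)
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- 0L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

exhaustive_mst_weight <- function(points) {
  n <- nrow(points)
  D <- as.matrix(dist(points))
  if (n == 2L) return(D[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[r, ], n)
    w <- sum(D[e])
    if (w < best) best <- w
  }
  best
}

# brute-force feature ranking: enumerate every off-diagonal pair, sort by
# descending score with lexicographic (i, j) tie-break
brute_force_top_pairs <- function(diff, region_names, k) {
  p <- length(region_names)
  rows <- do.call(rbind, lapply(seq_len(p - 1L), function(i) {
    data.frame(i = i, j = (i + 1L):p, score = diff[i, (i + 1L):p])
  }))
  rows <- rows[order(-rows$score, rows$i, rows$j), ]
  data.frame(region_i = region_names[rows$i[seq_len(k)]],
             region_j = region_names[rows$j[seq_len(k)]],
             score = rows$score[seq_len(k)],
             stringsAsFactors = FALSE)
}

# separately implemented nearest-PD repair (eigenvalue clipping + unit
# diagonal), used to check the perturbation build_covariance reports
oracle_nearest_pd <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  lam[lam < eps] <- eps
  S <- matrix(0, nrow(R), ncol(R))
  for (k in seq_along(lam)) {
    S <- S + lam[k] * tcrossprod(e$vectors[, k])
  }
  d <- sqrt(diag(S))
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    S[i, j] <- S[i, j] / (d[i] * d[j])
  }
  S
}

# hand evaluation of the Pearson formula (no stats::cor)
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
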