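# Independent oracles used across the suite. All are deliberately naive:
# full matrices, double loops, full sorts, graph-library flood fills --
# the implementation under test must agree with them, never call them.

# every upper-triangle pair via stats::cor on the full matrix, i-major
oracle_pairs <- function(values, method = "pearson") {
  cm <- stats::cor(t(values), method = method)
  n <- nrow(values)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(i = idx[, 1L], j = idx[, 2L], r = cm[idx])
}

# exhaustive double-loop degree centrality at a fixed threshold
oracle_dc_threshold <- function(values, thr, method = "pearson") {
  cm <- stats::cor(t(values), method = method)
  n <- nrow(values)
  binary <- integer(n); weighted <- double(n); retained <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (cm[i, j] > thr) {
      binary[i] <- binary[i] + 1L; binary[j] <- binary[j] + 1L
      weighted[i] <- weighted[i] + cm[i, j]
      weighted[j] <- weighted[j] + cm[i, j]
      retained <- retained + 1L
    }
  }
  list(binary = binary, weighted = weighted, retained = retained)
}

# full-sort top-k of a pairs data frame (descending r, stable)
oracle_topk <- function(pairs, k) {
  pairs[order(-pairs$r, pairs$i, pairs$j)[seq_len(k)], , drop = FALSE]
}

# accumulate binary/weighted maps from an explicit set of retained pairs
oracle_accumulate <- function(pairs, n) {
  binary <- integer(n); weighted <- double(n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]; r <- pairs$r[k]
    binary[i] <- binary[i] + 1L; binary[j] <- binary[j] + 1L
    weighted[i] <- weighted[i] + r; weighted[j] <- weighted[j] + r
  }
  list(binary = binary, weighted = weighted)
}

# flood fill over the thresholded indicator via igraph components:
# vertices = admissible in-mask voxels, edges = 26-adjacency
oracle_flood_fill <- function(target, r_with_target, coords, grid_shape,
                              thr) {
  admissible <- r_with_target > thr
  admissible[target] <- TRUE
  keep <- which(admissible)
  if (length(keep) == 1L) return(target)
  cc <- coords[keep, , drop = FALSE]
  edges <- integer(0)
  for (a in seq_along(keep)) for (b in seq_along(keep)) {
    if (a < b && all(abs(cc[a, ] - cc[b, ]) <= 1L))
      edges <- c(edges, a, b)
  }
  g <- igraph::make_graph(edges, n = length(keep), directed = FALSE)
  comp <- igraph::components(g)$membership
  sort(keep[comp == comp[match(target, keep)]])
}

# random time-series matrix with a fixed seed
random_ts <- function(n, t, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * t), nrow = n)
}

# wrap a plain matrix as a minimal voxel_ts on a 1D line of voxels
as_line_ts <- function(values) {
  n <- nrow(values)
  structure(list(values = values,
                 coords = cbind(x = seq_len(n), y = rep(1L, n),
                                z = rep(1L, n)),
                 grid_shape = c(n, 1L, 1L),
                 reference = NULL, n_removed = 0L),
            class = "voxel_ts")
}
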