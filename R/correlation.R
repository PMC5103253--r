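# Streaming pairwise-correlation engine.
#
# Correlations are computed over the upper triangle of voxel pairs as a
# blocked stream: rows are standardized once (mean 0, unit L2 norm) so that
# Pearson r is a plain dot product, then blocks of `block_size` rows are
# multiplied against the full standardized matrix. Peak extra memory is
# O(block_size * N); the N x N matrix is never formed. Spearman is Pearson
# on within-row ranks (ties get average ranks).

# Center each row and scale to unit L2 norm so row_i . row_j = Pearson r.
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x * x))
  if (any(nrm == 0))
    stop("zero-variance row encountered; remove constant series upstream",
         call. = FALSE)
  x / nrm
}

# Replace each row by its ranks; ties receive the average of their range.
rank_rows <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

# Rows of `values` prepared so that dot products are the requested
# correlation coefficient.
prepare_rows <- function(values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (method == "spearman") values <- rank_rows(values)
  standardize_rows(values)
}

# Stream every upper-triangle pair (i < j) exactly once, in i-major order,
# as chunks. `fun(i, j, r)` is called once per block with parallel integer
# and double vectors; chunk boundaries depend on block_size but the
# concatenated (i, j, r) sequence does not.
stream_correlations <- function(std, block_size, fun) {
  n <- nrow(std)
  stopifnot(block_size >= 1L)
  b0 <- 1L
  while (b0 < n) {
    b1 <- min(b0 + block_size - 1L, n - 1L)
    rows <- b0:b1
    cmat <- std[rows, , drop = FALSE] %*% t(std)   # |rows| x N
    # upper-triangle template for this block, i-major
    idx_i <- rep.int(rows, n - rows)
    idx_j <- sequence(n - rows, from = rows + 1L)
    r <- cmat[cbind(idx_i - b0 + 1L, idx_j)]
    fun(idx_i, idx_j, r)
    b0 <- b1 + 1L
  }
  invisible(NULL)
}

#' All pairwise voxel correlations as a data frame
#'
#' Convenience collector over the blocked streaming engine: returns every
#' unordered voxel pair i < j with its correlation, in i-major order.
#' Intended for small N (the data frame has N(N-1)/2 rows); the degree
#' centrality and lFCD routines never call this, they consume the stream
#' blockwise instead.
#'
#' @param ts a \code{voxel_ts} object (or a plain numeric matrix of row
#'   time series).
#' @param method correlation type, \code{"pearson"} or \code{"spearman"}.
#' @param block_size rows per streamed block; results do not depend on it.
#' @return data.frame with integer columns \code{i}, \code{j} and double
#'   column \code{r}.
#' @export
correlation_pairs <- function(ts, method = c("pearson", "spearman"),
                              block_size = 1024L) {
  values <- if (inherits(ts, "voxel_ts")) ts$values else as.matrix(ts)
  std <- prepare_rows(values, method)
  n <- nrow(std)
  out_i <- integer(0); out_j <- integer(0); out_r <- double(0)
  stream_correlations(std, block_size, function(i, j, r) {
    out_i <<- c(out_i, i); out_j <<- c(out_j, j); out_r <<- c(out_r, r)
  })
  data.frame(i = out_i, j = out_j, r = out_r)
}
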