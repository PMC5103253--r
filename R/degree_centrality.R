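#' Voxel-wise degree centrality
#'
#' Treats every in-mask voxel as a node of an undirected graph whose edges
#' are suprathreshold pairwise correlations, and returns for each voxel its
#' binary degree (number of retained connections) and weighted degree (sum
#' of retained correlation values). Two thresholding modes are available,
#' mutually exclusive:
#'
#' \describe{
#'   \item{threshold}{retain every pair with r strictly greater than
#'     \code{threshold} (default 0).}
#'   \item{sparsity}{retain the top \code{sparsity}\% strongest of all
#'     N(N-1)/2 unique pairs. \code{sparsity = 0.1} means 0.1\%. Selection
#'     uses a two-level adaptive histogram (50 primary bins over
#'     \code{[floor_threshold, 1]}, 100 secondary bins over the boundary
#'     bin) so the run never stores more than the plausibly-top-k records;
#'     the full correlation matrix is never materialised. The retained
#'     count can exceed the target when values at the selection boundary
#'     fall within one secondary sub-bin of each other -- ties are broken
#'     with a precision of 1/(50*100) of the primary span.}
#' }
#'
#' The target count in sparsity mode is \code{ceiling(sparsity/100 * M)}
#' with M = N(N-1)/2, so at least the requested fraction is always
#' retained.
#'
#' @param ts a \code{voxel_ts} object from [load_masked_timeseries()], or a
#'   plain N x T numeric matrix.
#' @param threshold correlation cutoff (< 1); pairs must exceed it
#'   strictly, so a cutoff below -1 admits every pair. Ignored if
#'   \code{sparsity} is given.
#' @param sparsity percentage P in (0, 100] of connections to keep.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param block_size rows per streamed correlation block; affects memory
#'   only, never the result.
#' @param primary_bins,secondary_bins histogram resolution for sparsity
#'   mode.
#' @param floor_threshold lower edge of the primary histogram span
#'   (sparsity mode). Connections at or below it can never be retained;
#'   lowering it below 0 widens the bins (precision degrades
#'   proportionally).
#' @return An object of class \code{centrality_result}: list with
#'   \code{binary} and \code{weighted} per-voxel vectors, \code{mode},
#'   \code{retained_connections}, \code{final_threshold} (smallest retained
#'   r in sparsity mode, the user cutoff otherwise), \code{k_target}
#'   (sparsity mode), \code{n_voxels}, \code{method}.
#' @examples
#' fx <- synthetic_bold(grid_shape = c(4, 4, 1), n_timepoints = 40,
#'                      blocks = list(cuboid_block(1:2, 1:2, 1),
#'                                    cuboid_block(3:4, 3:4, 1)),
#'                      signal_weight = 1, noise_sd = 0, seed = 7)
#' ts <- load_masked_timeseries(fx$bold, fx$mask)
#' degree_centrality(ts, threshold = 0.6)
#' @export
degree_centrality <- function(ts, threshold = NULL, sparsity = NULL,
                              method = c("pearson", "spearman"),
                              block_size = 1024L,
                              primary_bins = 50L, secondary_bins = 100L,
                              floor_threshold = 0) {
  method <- match.arg(method)
  if (!is.null(threshold) && !is.null(sparsity))
    stop("threshold and sparsity are mutually exclusive", call. = FALSE)
  values <- if (inherits(ts, "voxel_ts")) ts$values else as.matrix(ts)
  n <- nrow(values)
  if (n < 2L) stop("need at least 2 voxels", call. = FALSE)
  std <- prepare_rows(values, method)

  if (is.null(sparsity)) {
    if (is.null(threshold)) threshold <- 0
    if (!is.finite(threshold) || threshold >= 1)
      stop("threshold must be finite and < 1", call. = FALSE)
    res <- dc_accumulate_threshold(std, threshold, block_size)
    out <- list(binary = res$binary, weighted = res$weighted,
                mode = "threshold",
                retained_connections = res$retained,
                final_threshold = threshold,
                k_target = NA_integer_)
  } else {
    if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 100)
      stop("sparsity must be a percentage in (0, 100]", call. = FALSE)
    m <- n * (n - 1) / 2
    k_target <- as.integer(ceiling(sparsity / 100 * m))
    h <- ah_new(k_target, floor_threshold = floor_threshold,
                primary_bins = primary_bins,
                secondary_bins = secondary_bins)
    stream_correlations(std, block_size, function(i, j, r)
      ah_insert(h, i, j, r))
    if (ah_stored_count(h) == 0L) {
      warning("sparsity shortfall: no correlation exceeds the floor ",
              "threshold (", floor_threshold, "); maps are empty",
              call. = FALSE)
      sel <- list(i = integer(0), j = integer(0), r = double(0),
                  final_threshold = NA_real_)
    } else {
      sel <- ah_finalize(h)
    }
    binary <- tabulate(sel$i, nbins = n) + tabulate(sel$j, nbins = n)
    weighted <- rowsum_safe(sel$r, sel$i, n) + rowsum_safe(sel$r, sel$j, n)
    out <- list(binary = binary, weighted = weighted,
                mode = "sparsity",
                retained_connections = length(sel$r),
                final_threshold = sel$final_threshold,
                k_target = k_target)
  }
  out$n_voxels <- n
  out$method <- method
  out$sparsity <- if (is.null(sparsity)) NA_real_ else sparsity
  class(out) <- "centrality_result"
  out
}

# weighted-degree accumulation for threshold mode, blockwise
dc_accumulate_threshold <- function(std, threshold, block_size) {
  n <- nrow(std)
  binary <- double(n); weighted <- double(n); retained <- 0
  stream_correlations(std, block_size, function(i, j, r) {
    keep <- r > threshold
    if (!any(keep)) return(invisible(NULL))
    i <- i[keep]; j <- j[keep]; r <- r[keep]
    binary <<- binary + tabulate(i, nbins = n) + tabulate(j, nbins = n)
    weighted <<- weighted + rowsum_safe(r, i, n) + rowsum_safe(r, j, n)
    retained <<- retained + length(r)
  })
  list(binary = binary, weighted = weighted, retained = retained)
}

# sum of x by integer group g into a dense length-n vector
rowsum_safe <- function(x, g, n) {
  out <- double(n)
  if (length(x)) {
    s <- rowsum(x, g, reorder = FALSE)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("Voxel-wise degree centrality (", x$method, ", ", x$mode,
      " mode)\n", sep = "")
  if (x$mode == "sparsity")
    cat(sprintf("  sparsity: %g%%  (target %d connections)\n",
                x$sparsity, x$k_target))
  cat(sprintf("  voxels: %d   retained connections: %d\n",
              x$n_voxels, x$retained_connections))
  cat(sprintf("  final threshold: r > %.6f\n", x$final_threshold))
  cat(sprintf("  binary DC:   min %g, max %g, mean %.3f\n",
              min(x$binary), max(x$binary), mean(x$binary)))
  cat(sprintf("  weighted DC: min %.3f, max %.3f, mean %.3f\n",
              min(x$weighted), max(x$weighted), mean(x$weighted)))
  invisible(x)
}

#' @export
summary.centrality_result <- function(object, ...) {
  print(object)
  cat("\nBinary degree distribution:\n")
  print(summary(object$binary))
  invisible(object)
}
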