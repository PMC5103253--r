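#' Synthetic 4D volume with known block-correlation structure
#'
#' Generates a 4D "BOLD-like" volume in which disjoint blocks of voxels
#' share a latent Gaussian signal. A voxel in the block assigned latent
#' \eqn{g_k} receives the series \eqn{w\,g_k + (1-w)\,\varepsilon_v} with
#' independent Gaussian noise \eqn{\varepsilon_v \sim N(0, \sigma^2)};
#' latents are unit variance. The expected within-block Pearson
#' correlation is therefore analytically known,
#' \deqn{E[r] \approx \frac{w^2}{w^2 + (1-w)^2 \sigma^2},}
#' and is returned as \code{expected_r} so tests can calibrate thresholds.
#' Voxels listed in \code{noise_voxels} are in-mask but carry pure noise;
#' everything else is outside the mask. Identical seeds give bit-identical
#' volumes.
#'
#' This emulates only the correlation structure that the connectivity
#' metrics consume -- it has none of real fMRI's temporal autocorrelation,
#' drift, or physiological structure.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param n_timepoints number of timepoints T (>= 3).
#' @param blocks list of integer matrices (one per block, columns x, y, z,
#'   1-based) of the voxel coordinates sharing each latent signal; blocks
#'   must be disjoint. [cuboid_block()] builds rectangular ones.
#' @param signal_weight mixing weight w in [0, 1].
#' @param noise_sd noise standard deviation (>= 0).
#' @param noise_voxels optional coordinate matrix of in-mask pure-noise
#'   voxels (e.g. a shell around the blocks).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return list with \code{bold} (4D array), \code{mask} (3D 0/1 array),
#'   \code{expected_r}, and \code{spec} (the arguments, for provenance).
#' @examples
#' fx <- synthetic_bold(grid_shape = c(6, 6, 6), n_timepoints = 50,
#'                      blocks = list(cuboid_block(1:3, 1:3, 1:3)),
#'                      signal_weight = 0.7, noise_sd = 1, seed = 42)
#' fx$expected_r
#' @export
synthetic_bold <- function(grid_shape, n_timepoints, blocks,
                           signal_weight = 1, noise_sd = 0,
                           noise_voxels = NULL, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            n_timepoints >= 3L,
            signal_weight >= 0, signal_weight <= 1, noise_sd >= 0)
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "integer"
    if (ncol(b) != 3L) stop("block coordinates must have 3 columns",
                            call. = FALSE)
    if (any(b < 1L) || any(t(b) > grid_shape))
      stop("block voxel outside grid", call. = FALSE)
    b
  })
  flat <- function(b) b[, 1L] + grid_shape[1L] * (b[, 2L] - 1L) +
    grid_shape[1L] * grid_shape[2L] * (b[, 3L] - 1L)
  all_flat <- unlist(lapply(blocks, flat))
  if (anyDuplicated(all_flat))
    stop("blocks overlap", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  t_len <- as.integer(n_timepoints)
  bold <- array(0, dim = c(grid_shape, t_len))
  mask <- array(0, dim = grid_shape)
  nvol <- prod(grid_shape)
  w <- signal_weight
  for (b in blocks) {
    g <- stats::rnorm(t_len)                    # unit-variance latent
    fb <- flat(b)
    mask[fb] <- 1
    for (v in fb) {
      eps <- stats::rnorm(t_len, sd = noise_sd)
      bold[v + nvol * (0:(t_len - 1L))] <- w * g + (1 - w) * eps
    }
  }
  if (!is.null(noise_voxels)) {
    nv <- as.matrix(noise_voxels)
    storage.mode(nv) <- "integer"
    fb <- flat(nv)
    if (any(fb %in% all_flat))
      stop("noise_voxels overlap a block", call. = FALSE)
    mask[fb] <- 1
    for (v in fb) {
      bold[v + nvol * (0:(t_len - 1L))] <-
        stats::rnorm(t_len, sd = max(noise_sd, 1))
    }
  }
  expected_r <- if (w == 0) 0 else
    w^2 / (w^2 + (1 - w)^2 * noise_sd^2)
  list(bold = bold, mask = mask, expected_r = expected_r,
       spec = list(grid_shape = grid_shape, n_timepoints = t_len,
                   blocks = blocks, signal_weight = w,
                   noise_sd = noise_sd, seed = seed))
}

#' Rectangular block of voxel coordinates
#'
#' @param x,y,z integer coordinate ranges (1-based, inclusive).
#' @return integer matrix with columns x, y, z, one row per voxel.
#' @export
cuboid_block <- function(x, y, z) {
  g <- expand.grid(x = as.integer(x), y = as.integer(y),
                   z = as.integer(z))
  as.matrix(g)
}
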