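#' Extract masked voxel time series from a 4D NIfTI volume
#'
#' Reads a 4D functional volume and a 3D brain mask sharing the same grid,
#' and returns one time-series row per in-mask voxel. Rows follow a fixed
#' raster order of the mask -- x slowest, z fastest -- so that voxel indices
#' are reproducible across runs regardless of how the files were produced.
#' Any nonzero mask voxel counts as in-mask.
#'
#' In-mask voxels whose time series is constant are removed with a warning:
#' Pearson and Spearman correlation are undefined for zero-variance series,
#' and downstream maps write such voxels as 0.
#'
#' @param bold path to a 4D NIfTI file (or a 4D array / \code{niftiImage}).
#' @param mask path to a 3D NIfTI mask on the same grid (or a 3D array).
#' @return An object of class \code{voxel_ts}: a list with \code{values}
#'   (N x T matrix), \code{coords} (N x 3 integer matrix of 1-based voxel
#'   coordinates), \code{grid_shape}, \code{reference} (the source image,
#'   carried so output maps inherit its header), and \code{n_removed}.
#' @examples
#' fx <- synthetic_bold(grid_shape = c(4, 4, 2), n_timepoints = 10,
#'                      blocks = list(cuboid_block(1:2, 1:2, 1:2)), seed = 1)
#' ts <- load_masked_timeseries(fx$bold, fx$mask)
#' dim(ts$values)
#' @export
load_masked_timeseries <- function(bold, mask) {
  img <- if (is.character(bold)) RNifti::readNifti(bold) else bold
  msk <- if (is.character(mask)) RNifti::readNifti(mask) else mask
  dim_img <- dim(img)
  if (length(dim_img) != 4L)
    stop("functional input must be 4D (X x Y x Z x T), got ",
         length(dim_img), "D", call. = FALSE)
  dim_msk <- dim(msk)
  if (length(dim_msk) != 3L || !all(dim_msk == dim_img[1:3]))
    stop("mask grid ", paste(dim_msk, collapse = "x"),
         " does not match volume grid ",
         paste(dim_img[1:3], collapse = "x"), call. = FALSE)
  n_t <- dim_img[4L]
  if (n_t < 3L)
    stop("need at least 3 timepoints for correlation, got ", n_t,
         call. = FALSE)

  inmask <- which(msk != 0, arr.ind = TRUE)
  if (nrow(inmask) == 0L)
    stop("mask is empty: no nonzero voxels", call. = FALSE)
  # fixed raster order: x slowest, z fastest
  ord <- order(inmask[, 1L], inmask[, 2L], inmask[, 3L])
  coords <- inmask[ord, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  storage.mode(coords) <- "integer"

  flat <- coords[, 1L] +
    dim_img[1L] * (coords[, 2L] - 1L) +
    dim_img[1L] * dim_img[2L] * (coords[, 3L] - 1L)
  vol <- as.array(img)
  dim(vol) <- c(prod(dim_img[1:3]), n_t)
  values <- vol[flat, , drop = FALSE]
  storage.mode(values) <- "double"

  rng <- matrixStats_range(values)
  flat_rows <- rng[, 2L] == rng[, 1L]
  n_removed <- sum(flat_rows)
  if (n_removed > 0L) {
    warning(n_removed, " in-mask voxel(s) have constant time series; ",
            "removed from the computation (written as 0 in output maps)",
            call. = FALSE)
    values <- values[!flat_rows, , drop = FALSE]
    coords <- coords[!flat_rows, , drop = FALSE]
  }
  if (nrow(values) < 2L)
    stop("fewer than 2 usable in-mask voxels", call. = FALSE)

  structure(list(values = values,
                 coords = coords,
                 grid_shape = dim_img[1:3],
                 reference = if (inherits(img, "niftiImage")) img else NULL,
                 n_removed = n_removed),
            class = "voxel_ts")
}

# rowwise min/max without forming two passes' worth of copies
matrixStats_range <- function(x) {
  cbind(apply(x, 1L, min), apply(x, 1L, max))
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat("Masked voxel time series\n")
  cat("  grid:     ", paste(x$grid_shape, collapse = " x "), "\n")
  cat("  voxels:   ", nrow(x$values),
      if (x$n_removed > 0L) sprintf(" (%d constant voxels removed)",
                                    x$n_removed) else "", "\n", sep = "")
  cat("  timepoints:", ncol(x$values), "\n")
  invisible(x)
}

#' Write a per-voxel scalar map back to NIfTI
#'
#' Places \code{values[i]} at the voxel coordinate of row \code{i} of the
#' time-series object; all other voxels (out of mask, or removed as
#' constant) are 0. The grid and header affine of the source 4D image are
#' preserved and data are stored as float32.
#'
#' @param values numeric vector, one value per time-series row.
#' @param ts a \code{voxel_ts} object.
#' @param path output file path (\code{.nii} or \code{.nii.gz}); if
#'   \code{NULL} the 3D array is returned instead of written.
#' @return The output path (or the 3D array if \code{path} is NULL),
#'   invisibly when written.
#' @export
write_map <- function(values, ts, path = NULL) {
  stopifnot(inherits(ts, "voxel_ts"))
  n <- nrow(ts$values)
  if (n == 0L) stop("time-series object has no voxels", call. = FALSE)
  if (length(values) != n)
    stop("length(values) = ", length(values),
         " but time series has ", n, " voxels", call. = FALSE)
  out <- array(0, dim = ts$grid_shape)
  out[ts$coords] <- values
  if (is.null(path)) return(out)
  img <- if (!is.null(ts$reference)) RNifti::asNifti(out, ts$reference)
         else RNifti::asNifti(out)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 3D map and return in-mask values in raster order
#'
#' Companion to [write_map()]: extracts per-voxel values from a 3D map at
#' the coordinates of a \code{voxel_ts} object (or of any mask), in the
#' same fixed raster order used everywhere in the package.
#'
#' @param path path to a 3D NIfTI file (or a 3D array).
#' @param ts a \code{voxel_ts} object giving the coordinates.
#' @return numeric vector of length N.
#' @export
read_map <- function(path, ts) {
  stopifnot(inherits(ts, "voxel_ts"))
  img <- if (is.character(path)) RNifti::readNifti(path) else path
  if (length(dim(img)) != 3L || !all(dim(img) == ts$grid_shape))
    stop("map grid does not match time-series grid", call. = FALSE)
  as.array(img)[ts$coords]
}
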