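#' Concordance correlation coefficient between two spatial maps
#'
#' Lin-style concordance correlation with population (1/n) moments:
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(a,b)}
#'   {\mathrm{var}(a) + \mathrm{var}(b) + (\bar a - \bar b)^2}}
#' Unlike Pearson r, concordance penalises location and scale shifts: it
#' equals 1 only when the two maps are identical, and satisfies
#' \eqn{|\rho_c| \le |r|}. It is the standard statistic for agreement
#' between two implementations' voxel maps.
#'
#' @param a,b numeric vectors of per-voxel values over the same mask (use
#'   [read_map()] to extract them from NIfTI files in matching order).
#' @return scalar in [-1, 1]. If both maps are constant and equal the
#'   maps agree exactly and 1 is returned; if both are constant but
#'   unequal the statistic is undefined and \code{NaN} is returned with a
#'   warning.
#' @examples
#' concordance(c(0, 1, 2, 3), c(1, 2, 3, 4))   # shift penalised: 0.714
#' @export
concordance <- function(a, b) {
  if (length(a) != length(b))
    stop("maps differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 voxels", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("maps must be finite", call. = FALSE)
  if (all(a == b)) return(1)
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  if (va == 0 && vb == 0) {
    # two flat, unequal maps: no correlation component exists
    warning("both maps are constant and unequal; concordance undefined",
            call. = FALSE)
    return(NaN)
  }
  2 * cab / (va + vb + (ma - mb)^2)
}
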