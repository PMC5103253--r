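# Two-level adaptive histogram for memory-bounded top-k selection of
# correlation records.
#
# Primary structure: `primary_bins` equal-width bins spanning
# [floor_threshold, 1]. A record (i, j, r) is admitted only if
# r > admission_threshold. Whenever the bins strictly above the lowest
# retained bin already hold at least k_target records, the lowest bin is
# discarded and the admission threshold rises by exactly one bin width --
# so memory stays bounded by the records that can still matter, never
# O(N^2). At finalization whole bins are taken from high to low; the
# boundary bin that would overshoot the target is re-histogrammed into
# `secondary_bins` equal-width sub-bins over its own range and consumed
# likewise. Everything in the last admitted sub-bin is kept, so the result
# can exceed k_target, but only by values closer together than one sub-bin
# width: ties are broken with a precision of
# (1 - floor_threshold) / (primary_bins * secondary_bins) of the span.
#
# The histogram is a mutable environment; inserts are vectorized but a
# record-at-a-time path with identical semantics is used by the unit tests.

ah_new <- function(k_target, floor_threshold = 0, primary_bins = 50L,
                   secondary_bins = 100L) {
  stopifnot(k_target >= 1, primary_bins >= 2L, secondary_bins >= 2L,
            floor_threshold < 1)
  h <- new.env(parent = emptyenv())
  h$floor <- floor_threshold
  h$nbins <- as.integer(primary_bins)
  h$secondary_bins <- as.integer(secondary_bins)
  h$width <- (1 - floor_threshold) / primary_bins
  h$k_target <- k_target
  h$lowest <- 1L                      # index of lowest retained bin
  h$counts <- integer(primary_bins)
  # per-bin record storage: lists of chunks, concatenated at finalization
  h$bin_i <- vector("list", primary_bins)
  h$bin_j <- vector("list", primary_bins)
  h$bin_r <- vector("list", primary_bins)
  h$admission_threshold <- floor_threshold
  h$n_seen <- 0L                      # records offered (for shortfall info)
  h
}

# bin index for value r; top edge closed so r = 1 lands in the top bin
ah_bin_of <- function(h, r) {
  b <- floor((r - h$floor) / h$width) + 1
  as.integer(pmin(b, h$nbins))
}

# Insert a batch of records. Admission is strict: r > admission_threshold.
# After insertion the lowest retained bin is discarded (and the admission
# threshold raised by one bin width) for as long as the bins strictly above
# it already hold >= k_target records.
ah_insert <- function(h, i, j, r) {
  h$n_seen <- h$n_seen + length(r)
  keep <- r > h$admission_threshold
  if (any(keep)) {
    i <- i[keep]; j <- j[keep]; r <- r[keep]
    b <- ah_bin_of(h, r)
    for (bb in unique(b)) {
      sel <- b == bb
      h$bin_i[[bb]] <- c(h$bin_i[[bb]], list(i[sel]))
      h$bin_j[[bb]] <- c(h$bin_j[[bb]], list(j[sel]))
      h$bin_r[[bb]] <- c(h$bin_r[[bb]], list(r[sel]))
      h$counts[bb] <- h$counts[bb] + sum(sel)
    }
  }
  ah_prune(h)
  invisible(h)
}

ah_prune <- function(h) {
  while (h$lowest < h$nbins) {
    above <- sum(h$counts[(h$lowest + 1L):h$nbins])
    if (above < h$k_target) break
    b <- h$lowest
    h$bin_i[b] <- list(NULL); h$bin_j[b] <- list(NULL)
    h$bin_r[b] <- list(NULL)
    h$counts[b] <- 0L
    h$lowest <- b + 1L
    h$admission_threshold <- h$admission_threshold + h$width
  }
  invisible(h)
}

ah_stored_count <- function(h) sum(h$counts)

# Finalize: return the retained record set meeting (or minimally
# exceeding) k_target, plus the realised threshold (min retained r).
ah_finalize <- function(h) {
  total <- ah_stored_count(h)
  if (total == 0L)
    stop("adaptive histogram is empty: no correlation exceeded the floor ",
         "threshold", call. = FALSE)
  gather <- function(bins) list(
    i = unlist(lapply(h$bin_i[bins], unlist), use.names = FALSE),
    j = unlist(lapply(h$bin_j[bins], unlist), use.names = FALSE),
    r = unlist(lapply(h$bin_r[bins], unlist), use.names = FALSE))
  if (total < h$k_target) {
    warning("sparsity shortfall: only ", total, " connections above the ",
            "floor threshold, fewer than the ", h$k_target, " requested",
            call. = FALSE)
    rec <- gather(h$lowest:h$nbins)
    return(list(i = rec$i, j = rec$j, r = rec$r,
                final_threshold = min(rec$r), shortfall = TRUE))
  }
  # whole primary bins, high to low, while they fit under the target
  taken <- integer(0)
  cum <- 0L
  b <- h$nbins
  while (b >= h$lowest && cum + h$counts[b] <= h$k_target) {
    if (h$counts[b] > 0L) taken <- c(taken, b)
    cum <- cum + h$counts[b]
    b <- b - 1L
  }
  out <- if (length(taken)) gather(taken) else list(i = integer(0),
                                                    j = integer(0),
                                                    r = double(0))
  if (cum < h$k_target) {
    # b is the boundary bin: re-histogram its records into secondary
    # sub-bins over the bin's own range and consume high to low
    stopifnot(b >= h$lowest, h$counts[b] > 0L)
    rec <- gather(b)
    lo <- h$floor + (b - 1L) * h$width
    sw <- h$width / h$secondary_bins
    sub <- pmin(as.integer(floor((rec$r - lo) / sw)) + 1L,
                h$secondary_bins)
    for (s in h$secondary_bins:1L) {
      sel <- sub == s
      ns <- sum(sel)
      if (ns == 0L) next
      out$i <- c(out$i, rec$i[sel])
      out$j <- c(out$j, rec$j[sel])
      out$r <- c(out$r, rec$r[sel])
      cum <- cum + ns
      if (cum >= h$k_target) break
    }
  }
  list(i = out$i, j = out$j, r = out$r,
       final_threshold = min(out$r), shortfall = FALSE)
}
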