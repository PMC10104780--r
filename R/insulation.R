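#' Diamond-window insulation profile
#'
#' For each bin, the mean balanced contact frequency in the window x window
#' "diamond" of contacts crossing the bin (upstream block x downstream
#' block), expressed as log2 of the ratio to the chromosome-wide mean
#' diamond score. Bins within a window of a chromosome end, and bins whose
#' diamond contains no valid cell, are NA. Boundaries (e.g. cohesin/CTCF
#' insulation at cut sites) score as local minima.
#'
#' @param mat A balanced \code{ContactMatrix}.
#' @param window Diamond half-width in bp; must be a multiple of the bin
#'   size and at least 2 bins.
#' @return A \code{ScalarTrack} labelled "insulation".
#' @export
insulation_profile <- function(mat, window = 100000) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (all(is.na(mat$weights))) stop("matrix is not balanced; run ice_balance()")
  if (window %% mat$bin_size != 0)
    stop("window must be a multiple of the bin size")
  w <- as.integer(window / mat$bin_size)
  if (w < 2) stop("window must span at least 2 bins")
  off <- chrom_offsets(mat$bins)
  vals <- rep(NA_real_, nrow(mat$bins))
  for (k in seq_len(nrow(off))) {
    ch <- off$chrom[k]; first <- off$first[k]; n <- off$n[k]
    if (n < 2 * w + 1) next
    M <- dense_chrom(mat, ch, balanced = TRUE)
    raw <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
      blk <- M[(i - w):(i - 1), (i + 1):(i + w)]
      if (any(is.finite(blk))) raw[i] <- mean(blk, na.rm = TRUE)
    }
    m <- mean(raw, na.rm = TRUE)
    if (is.finite(m) && m > 0)
      vals[first:(first + n - 1L)] <- log2(raw / m)
  }
  scalar_track(mat$bins, vals, "insulation")
}
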