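#' Downsample a contact matrix to an exact number of valid pairs
#'
#' Multivariate-hypergeometric thinning: draws \code{target_pairs} pairs
#' without replacement from the pixel counts, so the downsampled matrix has
#' exactly \code{target_pairs} total valid pairs and each pixel's expected
#' count is \code{count * target_pairs / total_valid_pairs}. Used to equalize
#' replicate read depth before pooling.
#'
#' @param mat A \code{ContactMatrix}.
#' @param target_pairs Target total (<= \code{total_valid_pairs}).
#' @param seed Integer RNG seed for reproducibility.
#' @return A \code{ContactMatrix} with thinned counts (zero pixels dropped);
#'   weights are dropped.
#' @export
downsample <- function(mat, target_pairs, seed = 1) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (target_pairs > mat$total_valid_pairs)
    stop("target_pairs exceeds total_valid_pairs")
  px <- mat$pixels
  if (target_pairs == mat$total_valid_pairs) return(mat)
  new_counts <- with_seed_local(seed,
                                rmvhyper(as.numeric(px$count), target_pairs))
  px$count <- new_counts
  px <- px[px$count > 0, , drop = FALSE]
  contact_matrix(mat$bins, px)
}

# Sequential-conditional multivariate hypergeometric draw: allocate k items
# without replacement across urns with sizes `counts`.
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- numeric(n)
  remaining <- sum(counts)
  left <- k
  for (i in seq_len(n)) {
    if (left == 0) break
    ci <- counts[i]
    remaining <- remaining - ci
    x <- stats::rhyper(1, ci, remaining, left)
    out[i] <- x
    left <- left - x
  }
  out
}
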