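#' Iterative-correction (ICE) balancing of a contact matrix
#'
#' Computes per-bin multiplicative weights so that every non-filtered bin has
#' the same balanced marginal (normalized to 1), with the first
#' \code{ignore_diags} diagonals of each cis block masked from the marginals
#' (default 2: the main diagonal and the first off-diagonal). Bins whose log
#' coverage falls more than \code{mad_max} median absolute deviations below
#' the median, and bins with zero coverage, are filtered (weight NA).
#'
#' @param mat A \code{ContactMatrix}.
#' @param ignore_diags Number of leading cis diagonals to mask (>= 0).
#' @param mad_max Coverage filter stringency in MADs of log marginal.
#' @param tol Convergence tolerance on the relative marginal deviation.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return The matrix with \code{weights} filled in (NA = filtered bin).
#' @export
ice_balance <- function(mat, ignore_diags = 2, mad_max = 5, tol = 1e-5,
                        max_iter = 1000) {
  stopifnot(inherits(mat, "ContactMatrix"), ignore_diags >= 0)
  nb <- nrow(mat$bins)
  px <- mat$pixels
  if (nrow(px) == 0) stop("cannot balance an empty matrix")
  # mask leading diagonals (within-chromosome only)
  same_chrom <- mat$bins$chrom[px$bin1_id] == mat$bins$chrom[px$bin2_id]
  d <- px$bin2_id - px$bin1_id
  keep <- !(same_chrom & d < ignore_diags)
  px <- px[keep, , drop = FALSE]
  if (nrow(px) == 0) stop("no pixels left after masking diagonals")
  i <- px$bin1_id; j <- px$bin2_id; v <- as.numeric(px$count)
  # raw coverage with off-diagonal pixels counted on both bins
  offd <- i != j
  agg0 <- rowsum(c(v, v[offd]), c(i, j[offd]))
  cov <- numeric(nb)
  cov[as.integer(rownames(agg0))] <- agg0[, 1]
  good <- cov > 0
  if (any(good) && is.finite(mad_max)) {
    lc <- log(cov[good])
    med <- stats::median(lc)
    madv <- stats::mad(lc)
    if (madv > 0) good[good] <- lc >= med - mad_max * madv
  }
  if (!any(good)) stop("all bins filtered by coverage")
  b <- ifelse(good, 1, NA_real_)
  use <- good[i] & good[j]
  ii <- i[use]; jj <- j[use]; vv <- v[use]
  dup <- ii != jj
  ridx <- c(ii, jj[dup])
  last_dev <- Inf
  for (it in seq_len(max_iter)) {
    bv <- vv * b[ii] * b[jj]
    s <- numeric(nb)
    agg <- rowsum(c(bv, bv[dup]), ridx)
    s[as.integer(rownames(agg))] <- agg[, 1]
    sg <- s[good]
    m <- mean(sg)
    if (m == 0) stop("balancing degenerate: zero total after filtering")
    last_dev <- max(abs(sg / m - 1))
    if (last_dev < tol) break
    b[good] <- b[good] / sqrt(sg / m)
  }
  if (last_dev >= tol)
    stop(sprintf("ICE did not converge in %d iterations (residual %.3g)",
                 max_iter, last_dev))
  # scale so each balanced marginal equals 1
  bv <- vv * b[ii] * b[jj]
  agg <- rowsum(c(bv, bv[dup]), ridx)
  s <- numeric(nb)
  s[as.integer(rownames(agg))] <- agg[, 1]
  b[good] <- b[good] / sqrt(mean(s[good]))
  mat$weights <- b
  mat
}
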