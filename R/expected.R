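#' Cis distance-decay expected profile
#'
#' For each chromosome and each diagonal (genomic separation s = diagonal
#' index x bin size), the mean balanced contact frequency over element pairs
#' whose two bins are both non-filtered. Diagonals with no valid element are
#' undefined (NA), not zero.
#'
#' @param mat A balanced \code{ContactMatrix} (weights present).
#' @return An \code{ExpectedProfile}: data.frame with columns \code{chrom},
#'   \code{diag}, \code{s} (bp), \code{sum_balanced}, \code{n_valid},
#'   \code{expected}.
#' @export
expected_cis <- function(mat) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (all(is.na(mat$weights))) stop("matrix is not balanced; run ice_balance()")
  off <- chrom_offsets(mat$bins)
  res <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    first <- off$first[k]; n <- off$n[k]; ch <- off$chrom[k]
    w <- mat$weights[first:(first + n - 1L)]
    valid <- !is.na(w)
    sel <- mat$pixels$bin1_id >= first & mat$pixels$bin1_id < first + n &
      mat$pixels$bin2_id >= first & mat$pixels$bin2_id < first + n
    px <- mat$pixels[sel, , drop = FALSE]
    i <- px$bin1_id - first + 1L
    j <- px$bin2_id - first + 1L
    bal <- px$count * w[i] * w[j]
    dpix <- j - i
    sums <- numeric(n)
    if (length(dpix) > 0) {
      ok <- !is.na(bal)
      agg <- rowsum(bal[ok], dpix[ok])
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    # number of valid (both-unfiltered) element pairs on each diagonal:
    # for diagonal d, sum over i of valid[i] * valid[i + d]
    vnum <- as.numeric(valid)
    nval <- vapply(0:(n - 1L), function(d) {
      if (d == 0) sum(vnum) else sum(vnum[1:(n - d)] * vnum[(1 + d):n])
    }, 0)
    res[[k]] <- data.frame(chrom = ch, diag = 0:(n - 1L),
                           s = (0:(n - 1L)) * mat$bin_size,
                           sum_balanced = sums, n_valid = nval,
                           expected = ifelse(nval > 0, sums / nval, NA_real_),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("ExpectedProfile", "data.frame")
  out
}

#' Observed/expected transform of cis contact matrices
#'
#' Divides each balanced cis contact by the chromosome's expected value at
#' the same genomic separation, yielding per-chromosome dense O/E matrices.
#' Filtered bins are NA rows/columns. By construction the mean O/E over
#' valid entries of every diagonal is 1.
#'
#' @param mat A balanced \code{ContactMatrix}.
#' @param expected An \code{ExpectedProfile} from [expected_cis()] (computed
#'   from \code{mat} if omitted).
#' @return An \code{OEMatrix}: list with \code{bins} and per-chromosome dense
#'   matrices in \code{chroms} (named list).
#' @export
observed_over_expected <- function(mat, expected = NULL) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (is.null(expected)) expected <- expected_cis(mat)
  off <- chrom_offsets(mat$bins)
  mats <- list()
  for (k in seq_len(nrow(off))) {
    ch <- off$chrom[k]; first <- off$first[k]; n <- off$n[k]
    M <- dense_chrom(mat, ch, balanced = TRUE)
    ex <- expected[expected$chrom == ch, ]
    ev <- ex$expected[match(0:(n - 1L), ex$diag)]
    D <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
    hasdata <- is.finite(M) & M > 0
    if (any(hasdata & (is.na(ev[D]) | ev[D] == 0)))
      stop(sprintf("chromosome %s: observations at separations with zero/undefined expected", ch))
    E <- matrix(ev[D], n, n)
    OE <- M / E
    mats[[ch]] <- OE
  }
  obj <- list(bins = mat$bins, chroms = mats, bin_size = mat$bin_size)
  class(obj) <- "OEMatrix"
  obj
}

#' @export
print.OEMatrix <- function(x, ...) {
  cat(sprintf("OEMatrix: %d chromosome(s), %d bins at %s bp\n",
              length(x$chroms), nrow(x$bins),
              format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Contact-probability scaling P(s) and its log-log derivative
#'
#' Averages the balanced distance-decay profile into log-spaced separation
#' bins (geometric, \code{bins_per_decade} per decade of genomic distance),
#' pooling chromosomes by summing balanced signal and valid element counts.
#' The derivative d log P / d log s is estimated by central finite
#' differences on the log-binned curve, with one-sided differences at the
#' curve ends.
#'
#' @param mat A balanced \code{ContactMatrix}.
#' @param bins_per_decade Log-bin density (default 8).
#' @param min_separation Smallest separation retained, bp (default: one bin;
#'   the masked leading diagonals carry no signal anyway).
#' @param expected Optional precomputed [expected_cis()] profile.
#' @return A \code{ScalingCurve}: data.frame with \code{s} (geometric bin
#'   center, bp), \code{p} (mean contact probability) and \code{deriv}.
#' @export
contact_scaling <- function(mat, bins_per_decade = 8, min_separation = NULL,
                            expected = NULL) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (is.null(expected)) expected <- expected_cis(mat)
  if (is.null(min_separation)) min_separation <- mat$bin_size
  ex <- expected[expected$s >= min_separation & expected$n_valid > 0, ]
  if (nrow(ex) == 0) stop("no diagonals at or beyond min_separation")
  lo <- log10(min(ex$s)); hi <- log10(max(ex$s))
  nb <- max(1L, ceiling((hi - lo) * bins_per_decade))
  edges <- 10^seq(lo, hi, length.out = nb + 1L)
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-9)
  bi <- findInterval(ex$s, edges, rightmost.closed = TRUE)
  sums <- rowsum(ex$sum_balanced, bi)
  nval <- rowsum(ex$n_valid, bi)
  # geometric mean separation of the diagonals in each log-bin
  smid <- exp(rowsum(log(ex$s) * ex$n_valid, bi)[, 1] / nval[, 1])
  p <- sums[, 1] / nval[, 1]
  keep <- is.finite(p) & p > 0
  s <- smid[keep]; p <- p[keep]
  if (length(p) < 3) stop("fewer than 3 log-bins with data")
  ls <- log(s); lp <- log(p)
  n <- length(p)
  deriv <- numeric(n)
  deriv[1] <- (lp[2] - lp[1]) / (ls[2] - ls[1])
  deriv[n] <- (lp[n] - lp[n - 1]) / (ls[n] - ls[n - 1])
  if (n > 2)
    deriv[2:(n - 1)] <- (lp[3:n] - lp[1:(n - 2)]) / (ls[3:n] - ls[1:(n - 2)])
  out <- data.frame(s = s, p = p, deriv = deriv)
  class(out) <- c("ScalingCurve", "data.frame")
  out
}
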