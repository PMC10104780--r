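#' Saddle plot of O/E stratified by compartment eigenvector quantile
#'
#' Ranks valid bins by EV1, excludes the outer \code{trim_percentile}
#' percent of ranked values at each end, splits the remainder into
#' \code{n_quantiles} equal-count groups (sizes differ by at most one bin),
#' and averages cis O/E over all bin pairs per group pair. Row/column 1 is
#' the most negative EV1 (strongest B), row/column \code{n_quantiles} the
#' strongest A.
#'
#' @param oe An \code{OEMatrix}.
#' @param ev1 A \code{ScalarTrack} of EV1 values on the same bins.
#' @param n_quantiles Number of quantile groups (default 30).
#' @param trim_percentile Percent excluded from each tail of the ranked EV1
#'   distribution (default 0.2, i.e. 0.2%).
#' @param per_chrom Trim and rank per chromosome instead of genome-wide
#'   (default FALSE: genome-wide).
#' @return A \code{SaddleResult}: list with \code{matrix}
#'   (n_quantiles x n_quantiles mean O/E), \code{counts}, \code{edges}
#'   (EV1 group boundaries) and strength curves \code{A_strength},
#'   \code{B_strength} from [saddle_strength()].
#' @export
saddle <- function(oe, ev1, n_quantiles = 30, trim_percentile = 0.2,
                   per_chrom = FALSE) {
  stopifnot(inherits(oe, "OEMatrix"), inherits(ev1, "ScalarTrack"))
  if (!same_bins(oe$bins, ev1$bins))
    stop("EV1 track is on a different bin table")
  v <- ev1$values
  group <- rep(NA_integer_, length(v))
  assign_groups <- function(idx) {
    vv <- v[idx]
    ord <- order(vv)
    nv <- length(ord)
    ntrim <- floor(nv * trim_percentile / 100)
    keep <- ord[(ntrim + 1):(nv - ntrim)]
    nk <- length(keep)
    if (nk < n_quantiles)
      stop("fewer valid bins than quantile groups after trimming")
    g <- floor((seq_len(nk) - 1) * n_quantiles / nk) + 1L
    group[idx[keep]] <<- g
    invisible(NULL)
  }
  valid <- which(!is.na(v))
  if (length(valid) < n_quantiles)
    stop("fewer valid bins than quantile groups")
  if (per_chrom) {
    for (ch in unique(oe$bins$chrom)) {
      idx <- valid[oe$bins$chrom[valid] == ch]
      if (length(idx) >= n_quantiles) assign_groups(idx)
    }
  } else assign_groups(valid)
  sums <- matrix(0, n_quantiles, n_quantiles)
  cnts <- matrix(0, n_quantiles, n_quantiles)
  off <- chrom_offsets(oe$bins)
  for (k in seq_len(nrow(off))) {
    ch <- off$chrom[k]; first <- off$first[k]; n <- off$n[k]
    g <- group[first:(first + n - 1L)]
    inb <- which(!is.na(g))
    if (length(inb) == 0) next
    M <- oe$chroms[[ch]][inb, inb, drop = FALSE]
    G <- matrix(0, length(inb), n_quantiles)
    G[cbind(seq_along(inb), g[inb])] <- 1
    W <- is.finite(M) + 0
    M0 <- M; M0[!is.finite(M0)] <- 0
    sums <- sums + t(G) %*% M0 %*% G
    cnts <- cnts + t(G) %*% W %*% G
  }
  S <- ifelse(cnts > 0, sums / cnts, NA_real_)
  edges <- tapply(v[!is.na(group)], group[!is.na(group)], min)
  extent <- floor(n_quantiles / 2)
  st <- saddle_strength_matrix(S, extent)
  obj <- list(matrix = S, counts = cnts, edges = edges,
              n_quantiles = n_quantiles,
              A_strength = st$A, B_strength = st$B)
  class(obj) <- "SaddleResult"
  obj
}

#' @export
print.SaddleResult <- function(x, ...) {
  cat(sprintf("SaddleResult: %dx%d; strength at corner k=1: A %.3f, B %.3f\n",
              x$n_quantiles, x$n_quantiles, x$A_strength[1], x$B_strength[1]))
  invisible(x)
}

#' Cumulative saddle (compartmentalization) strength
#'
#' For k = 1..extent, the mean O/E of the k x k A-A corner (bottom-right:
#' highest EV1 quantiles) or B-B corner (top-left) divided by the mean of
#' the two corresponding k x k A-B/B-A corners. A value of 1 means no
#' compartmentalization.
#'
#' @param saddle A \code{SaddleResult} (or a bare saddle matrix).
#' @param extent Corner depth; at most n_quantiles / 2 (default: that bound).
#' @return list(A = numeric(extent), B = numeric(extent)).
#' @export
saddle_strength <- function(saddle, extent = NULL) {
  S <- if (inherits(saddle, "SaddleResult")) saddle$matrix else saddle
  nq <- nrow(S)
  if (is.null(extent)) extent <- floor(nq / 2)
  if (extent > nq / 2) stop("extent exceeds n_quantiles / 2")
  saddle_strength_matrix(S, extent)
}

saddle_strength_matrix <- function(S, extent) {
  nq <- nrow(S)
  A <- numeric(extent); B <- numeric(extent)
  for (k in seq_len(extent)) {
    hi <- (nq - k + 1):nq; lo <- 1:k
    aa <- mean(S[hi, hi], na.rm = TRUE)
    bb <- mean(S[lo, lo], na.rm = TRUE)
    ab <- mean(c(S[lo, hi], S[hi, lo]), na.rm = TRUE)
    A[k] <- aa / ab
    B[k] <- bb / ab
  }
  list(A = A, B = B)
}
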