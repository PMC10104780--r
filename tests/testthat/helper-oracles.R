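# Independent brute-force oracles and small fixture builders shared by the
# test files. Everything here is deliberately naive (dense loops) so it can
# serve as a cross-check for the package's sparse implementations.

dense_chrom_test <- function(mat, ch) dsb3d:::dense_chrom(mat, ch, balanced = TRUE)

# dense symmetric matrix from a ContactMatrix's pixels (raw counts)
dense_counts <- function(mat) {
  n <- nrow(mat$bins)
  M <- matrix(0, n, n)
  px <- mat$pixels
  if (nrow(px) > 0) {
    M[cbind(px$bin1_id, px$bin2_id)] <- px$count
    M[cbind(px$bin2_id, px$bin1_id)] <- px$count
  }
  M
}

# brute-force Sinkhorn balancing of a dense symmetric matrix with the same
# diagonal mask / bin filter as ice_balance; iterates to near fixed point
sinkhorn_oracle <- function(M, good, ignore_diags = 0, n_iter = 10000,
                            tol = 1e-13) {
  n <- nrow(M)
  mask <- abs(row(M) - col(M)) >= ignore_diags
  W <- M * mask
  W[!good, ] <- 0
  W[, !good] <- 0
  b <- ifelse(good, 1, NA_real_)
  for (it in seq_len(n_iter)) {
    s <- as.numeric(W %*% ifelse(is.na(b), 0, b)) * ifelse(is.na(b), 0, b)
    m <- mean(s[good])
    if (max(abs(s[good] / m - 1)) < tol) break
    b[good] <- b[good] / sqrt(s[good] / m)
  }
  s <- as.numeric(W %*% ifelse(is.na(b), 0, b)) * ifelse(is.na(b), 0, b)
  b[good] <- b[good] / sqrt(mean(s[good]))
  b
}

# dense per-diagonal mean over valid bin pairs (one chromosome)
diag_means_oracle <- function(B, valid) {
  n <- nrow(B)
  vapply(0:(n - 1), function(d) {
    vals <- c()
    for (i in 1:(n - d)) {
      j <- i + d
      if (valid[i] && valid[j]) vals <- c(vals, B[i, j])
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, 0)
}

# hand-built OEMatrix on a single-chromosome bin table
oe_from_matrix <- function(M, bin_size = 25000, chrom = "chr1") {
  n <- nrow(M)
  bins <- bin_table(stats::setNames(n * bin_size, chrom), bin_size)
  structure(list(bins = bins, chroms = stats::setNames(list(M), chrom),
                 bin_size = bin_size), class = "OEMatrix")
}

# minimal CompartmentResult with given EV1 values
comp_from_ev <- function(bins, ev) {
  labels <- rep("unassigned", length(ev))
  labels[!is.na(ev) & ev > 0] <- "A"
  labels[!is.na(ev) & ev < 0] <- "B"
  structure(list(ev1 = scalar_track(bins, ev, "EV1"), labels = labels,
                 phasing_correlation = NA_real_),
            class = "CompartmentResult")
}

# maximal-overlap junction oracle: find the longest read prefix matching the
# bait reference and the earliest read suffix matching the prey reference,
# then classify from the gap between them
junction_oracle <- function(read, bait_ref, prey_ref) {
  n <- nchar(read)
  b_star <- 0L
  for (i in seq_len(min(n, nchar(bait_ref)))) {
    if (substr(read, i, i) == substr(bait_ref, i, i)) b_star <- i else break
  }
  p_star <- NA_integer_
  for (p in seq_len(n)) {
    L <- n - p + 1L
    if (L > nchar(prey_ref)) next
    if (substr(read, p, n) == substr(prey_ref, 1, L)) { p_star <- p; break }
  }
  if (is.na(p_star)) return(list(class = NA_character_))
  gap <- p_star - b_star
  if (gap == 1) list(class = "blunt", mh_length = 0L)
  else if (gap <= 0) list(class = "MH", mh_length = 1L - gap)
  else list(class = "insertion",
            insertion_seq = substr(read, b_star + 1L, p_star - 1L))
}

# junction table with prescribed per-bin raw counts on chr1
jt_from_counts <- function(counts, bins, bait_only = 5000) {
  idx <- rep(seq_along(counts), counts)
  recs <- data.frame(prey_chrom = "chr1",
                     prey_pos = bins$start[idx] + 100,
                     prey_strand = "+", seq = strrep("A", 40),
                     bait_end = 20, prey_start = 21,
                     stringsAsFactors = FALSE)
  junction_table(recs, list(chrom = "chr1", pos = 0, strand = "+"),
                 bait_only_count = bait_only)
}

# deterministic power-law contact matrix: counts = round(K * d^-alpha) for
# d >= 1 (no diagonal), unit weights, one chromosome
powerlaw_matrix <- function(n_bins = 400, bin_size = 25000, alpha = 1,
                            K = 1e4) {
  bins <- bin_table(c(chr1 = n_bins * bin_size), bin_size)
  ij <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  d <- ij[, 2] - ij[, 1]
  cnt <- round(K * d^(-alpha))
  keep <- cnt > 0
  m <- contact_matrix(bins, data.frame(bin1_id = ij[keep, 1],
                                       bin2_id = ij[keep, 2],
                                       count = cnt[keep]))
  m$weights <- rep(1, n_bins)
  m
}
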