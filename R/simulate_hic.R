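#' Configuration for the synthetic Hi-C generator
#'
#' Defines a toy genome and the planted structure a simulated contact map
#' carries: power-law distance decay, plaid (block) compartments with a
#' condition-dependent set of B-to-A flips, focal DSB-pair clustering,
#' CTCF-anchored convergent loops and optional one-sided extrusion lines.
#'
#' @param chrom_sizes Named chromosome lengths (bp). Default: 4 x 50 Mb.
#' @param bin_size Bin width (bp, default 25 kb).
#' @param alpha Distance-decay exponent: intensity ~ s^-alpha (default 1).
#' @param kappa Compartment contrast; the checkerboard factor is
#'   \code{1 + kappa * c_i * c_j} with c = +/-1 (default 0 = none).
#' @param block_bins Compartment block width in bins (default 10).
#' @param flip_bins Integer bin ids (B bins) flipped to A in the damage
#'   condition only.
#' @param cut_sites \code{SiteCatalog} of cut sites; cis pairs get a focal
#'   Gaussian boost of height \code{beta} (damage condition only).
#' @param beta Cluster boost (>= 1, default 1 = none).
#' @param cluster_sigma_bins Gaussian shoulder width of the focal boost
#'   (default 1).
#' @param cluster_core_bins Flat-core Chebyshev radius of the focal boost in
#'   bins (default 2, i.e. a 5 x 5 core -- 125 kb at 25-kb bins -- so the
#'   planted height equals the mean enrichment over the central score
#'   block).
#' @param anchors Oriented \code{SiteCatalog} of CTCF anchors; convergent
#'   cis pairs within \code{loop_range} get a boost \code{lambda}.
#' @param lambda Loop-dot boost (>= 1, default 1).
#' @param loop_sigma_bins Gaussian shoulder width of loop dots; 0 (the
#'   default) gives hard-edged dots, keeping the tight loop-score ring
#'   (25-100 kb) free of planted signal.
#' @param loop_core_bins Flat-core radius of loop dots in bins (default 2).
#' @param loop_range c(min, max) anchor separation for loops (bp).
#' @param line_boost One-sided extrusion-line boost along the motif
#'   direction (>= 1, default 1 = none).
#' @param line_len_bins Extent of the extrusion line in bins (default 8).
#' @param n_pairs Expected total read-pair count N (Poisson; default 1e6).
#' @param seed Master seed.
#' @return A validated \code{HicSimConfig} list.
#' @export
hic_sim_config <- function(chrom_sizes = c(chr1 = 5e7, chr2 = 5e7,
                                           chr3 = 5e7, chr4 = 5e7),
                           bin_size = 25000, alpha = 1, kappa = 0,
                           block_bins = 10, flip_bins = integer(0),
                           cut_sites = NULL, beta = 1,
                           cluster_sigma_bins = 1, cluster_core_bins = 2,
                           anchors = NULL,
                           lambda = 1, loop_sigma_bins = 0,
                           loop_core_bins = 2,
                           loop_range = c(25000, 1e6), line_boost = 1,
                           line_len_bins = 8, n_pairs = 1e6, seed = 1) {
  stopifnot(beta >= 1, lambda >= 1, line_boost >= 1, n_pairs > 0,
            kappa >= 0, kappa < 1, alpha > 0, block_bins >= 1)
  bins <- bin_table(chrom_sizes, bin_size)
  comp <- compartment_vector_blocks(bins, block_bins)
  if (length(flip_bins) > 0) {
    if (any(comp[flip_bins] != -1))
      stop("flip_bins must be drawn from B-labelled (c = -1) bins")
  }
  cfg <- list(chrom_sizes = chrom_sizes, bin_size = bin_size, bins = bins,
              alpha = alpha, kappa = kappa, block_bins = block_bins,
              comp = comp, flip_bins = flip_bins, cut_sites = cut_sites,
              beta = beta, cluster_sigma_bins = cluster_sigma_bins,
              cluster_core_bins = cluster_core_bins,
              anchors = anchors, lambda = lambda,
              loop_sigma_bins = loop_sigma_bins,
              loop_core_bins = loop_core_bins, loop_range = loop_range,
              line_boost = line_boost, line_len_bins = line_len_bins,
              n_pairs = n_pairs, seed = seed)
  class(cfg) <- "HicSimConfig"
  cfg
}

# Alternating +1/-1 blocks per chromosome (+1 = A-like, -1 = B-like).
compartment_vector_blocks <- function(bins, block_bins) {
  comp <- numeric(nrow(bins))
  off <- chrom_offsets(bins)
  for (k in seq_len(nrow(off))) {
    n <- off$n[k]
    blocks <- rep(c(1, -1), length.out = ceiling(n / block_bins))
    comp[off$first[k]:(off$first[k] + n - 1L)] <-
      rep(blocks, each = block_bins)[1:n]
  }
  comp
}

#' Planted compartment state of a simulation condition
#'
#' @param cfg A \code{HicSimConfig}.
#' @param condition "control" or "damage" (damage applies the flip set).
#' @return list(c = per-bin +/-1 vector, labels = "A"/"B").
#' @export
sim_compartment_truth <- function(cfg, condition = c("control", "damage")) {
  condition <- match.arg(condition)
  cvec <- cfg$comp
  if (condition == "damage" && length(cfg$flip_bins) > 0)
    cvec[cfg$flip_bins] <- 1
  list(c = cvec, labels = ifelse(cvec > 0, "A", "B"))
}

# Expected (unnormalized) cis intensity matrix for one chromosome.
sim_intensity_chrom <- function(cfg, chrom, condition) {
  off <- chrom_offsets(cfg$bins)
  row <- off[off$chrom == chrom, ]
  n <- row$n; first <- row$first
  cvec <- sim_compartment_truth(cfg, condition)$c[first:(first + n - 1L)]
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- pmax(D, 1)^(-cfg$alpha)  # clean power law off-diagonal; diag = 1
  M <- M * (1 + cfg$kappa * outer(cvec, cvec))
  bump <- function(M, a, b, height, sigma, core) {
    # symmetric focal boost at (a, b)/(b, a): flat multiplicative core of
    # Chebyshev radius `core` bins with Gaussian shoulders of width sigma
    if (height <= 1) return(M)
    r <- core + 3L * ceiling(sigma)
    ii <- max(1, a - r):min(n, a + r)
    jj <- max(1, b - r):min(n, b + r)
    cheb <- outer(abs(ii - a), abs(jj - b), pmax)
    G <- if (sigma > 0) exp(-pmax(cheb - core, 0)^2 / (2 * sigma^2))
         else (cheb <= core) + 0
    M[ii, jj] <- M[ii, jj] * (1 + (height - 1) * G)
    M[jj, ii] <- M[jj, ii] * (1 + (height - 1) * t(G))
    M
  }
  if (!is.null(cfg$cut_sites) && cfg$beta > 1 && condition == "damage") {
    pr <- cis_pairs(cfg$cut_sites)
    pr <- pr[pr$chrom == chrom, , drop = FALSE]
    for (r in seq_len(nrow(pr))) {
      a <- floor(pr$pos1[r] / cfg$bin_size) + 1L
      b <- floor(pr$pos2[r] / cfg$bin_size) + 1L
      M <- bump(M, a, b, cfg$beta, cfg$cluster_sigma_bins,
                cfg$cluster_core_bins)
    }
  }
  if (!is.null(cfg$anchors) && cfg$lambda > 1) {
    pr <- convergent_pairs(cfg$anchors, cfg$loop_range[1], cfg$loop_range[2])
    pr <- pr[pr$chrom == chrom, , drop = FALSE]
    for (r in seq_len(nrow(pr))) {
      a <- floor(pr$pos1[r] / cfg$bin_size) + 1L
      b <- floor(pr$pos2[r] / cfg$bin_size) + 1L
      M <- bump(M, a, b, cfg$lambda, cfg$loop_sigma_bins,
                cfg$loop_core_bins)
    }
  }
  if (!is.null(cfg$anchors) && cfg$line_boost > 1) {
    an <- cfg$anchors[cfg$anchors$chrom == chrom, , drop = FALSE]
    L <- cfg$line_len_bins
    for (r in seq_len(nrow(an))) {
      a <- floor(an$pos[r] / cfg$bin_size) + 1L
      if (an$strand[r] == "+") {
        jj <- (a + 1L):min(n, a + L)
      } else {
        jj <- max(1, a - L):(a - 1L)
      }
      jj <- jj[jj >= 1 & jj <= n & jj != a]
      M[a, jj] <- M[a, jj] * cfg$line_boost
      M[jj, a] <- M[jj, a] * cfg$line_boost
    }
  }
  M
}

#' Simulate a binned Hi-C contact map
#'
#' Draws Poisson pixel counts from a cis intensity
#' \code{p_ij ~ s^-alpha * (1 + kappa c_i c_j) * loop(i,j) * cluster(i,j)},
#' where the compartment vector c has the configured flip set switched to A
#' in the damage condition and the focal cluster boost applies in the
#' damage condition only. The expected total count is \code{n_pairs}.
#' Byte-identical for a fixed (config seed, condition, rep) triple.
#'
#' @param cfg A \code{HicSimConfig}.
#' @param condition "control" or "damage".
#' @param rep_index Replicate stream index (default 1).
#' @return An unbalanced \code{ContactMatrix}.
#' @export
simulate_contact_map <- function(cfg, condition = c("control", "damage"),
                                 rep_index = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "HicSimConfig"))
  off <- chrom_offsets(cfg$bins)
  # total intensity over all chromosomes' upper triangles, for normalization
  chroms <- off$chrom
  intens <- lapply(chroms, function(ch)
    sim_intensity_chrom(cfg, ch, condition))
  tot <- sum(vapply(intens, function(M) sum(M[upper.tri(M, diag = TRUE)]), 0))
  sd_stream <- derive_seed(cfg$seed,
                           1000 * rep_index +
                             ifelse(condition == "damage", 1, 0))
  pixels <- with_seed_local(sd_stream, {
    out <- vector("list", length(chroms))
    for (k in seq_along(chroms)) {
      M <- intens[[k]]
      n <- nrow(M)
      ut <- upper.tri(M, diag = TRUE)
      lam <- cfg$n_pairs * M[ut] / tot
      cnt <- stats::rpois(length(lam), lam)
      nz <- cnt > 0
      ij <- which(ut, arr.ind = TRUE)
      out[[k]] <- data.frame(
        bin1_id = off$first[k] + ij[nz, 1] - 1L,
        bin2_id = off$first[k] + ij[nz, 2] - 1L,
        count = cnt[nz])
    }
    do.call(rbind, out)
  })
  contact_matrix(cfg$bins, pixels)
}

#' Simulate replicate contact maps for both conditions
#'
#' Independent Poisson draws from the same condition intensity, one RNG
#' stream per (condition, replicate).
#'
#' @param cfg A \code{HicSimConfig}.
#' @param n_reps Replicates per condition (default 2).
#' @param conditions Conditions to simulate.
#' @return Named list (per condition) of lists of \code{ContactMatrix}.
#' @export
simulate_replicates <- function(cfg, n_reps = 2,
                                conditions = c("control", "damage")) {
  stopifnot(n_reps >= 1)
  out <- lapply(conditions, function(cond)
    lapply(seq_len(n_reps), function(r)
      simulate_contact_map(cfg, cond, rep_index = r)))
  names(out) <- conditions
  out
}

#' Per-bin gene-density track aligned to the planted compartments
#'
#' A-like blocks get high density, B-like blocks low density, plus optional
#' noise: the phasing covariate the compartment caller needs. The control
#' (unflipped) compartment profile is used, as gene density does not change
#' with damage.
#'
#' @param cfg A \code{HicSimConfig}.
#' @param high,low Density values for A/B blocks (defaults 10 and 1).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Seed for the noise (default cfg seed).
#' @return A \code{ScalarTrack} labelled "gene_density".
#' @export
sim_gene_density <- function(cfg, high = 10, low = 1, noise_sd = 0,
                             seed = NULL) {
  vals <- ifelse(cfg$comp > 0, high, low)
  if (noise_sd > 0) {
    if (is.null(seed)) seed <- derive_seed(cfg$seed, 999)
    vals <- with_seed_local(seed,
                            pmax(vals + stats::rnorm(length(vals), 0, noise_sd), 0))
  }
  scalar_track(cfg$bins, vals, "gene_density")
}
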