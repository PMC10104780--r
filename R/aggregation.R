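#' All cis pairs of a site catalog
#'
#' Every unordered pair of distinct sites on the same chromosome, emitted
#' once with the lower coordinate first.
#'
#' @param sites A \code{SiteCatalog}.
#' @return data.frame with \code{chrom}, \code{pos1}, \code{pos2}
#'   (pos1 < pos2), \code{name1}, \code{name2}.
#' @export
cis_pairs <- function(sites) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    sub <- sites[sites$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    idx <- utils::combn(n, 2)
    out[[ch]] <- data.frame(chrom = ch,
                            pos1 = sub$pos[idx[1, ]],
                            pos2 = sub$pos[idx[2, ]],
                            name1 = sub$name[idx[1, ]],
                            name2 = sub$name[idx[2, ]],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos1 = numeric(),
                      pos2 = numeric(), name1 = character(),
                      name2 = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_pileup <- function(sum_lin, cnt_lin, sum_log, cnt_log, resolution, flank,
                       n_used, n_dropped) {
  mean_linear <- ifelse(cnt_lin > 0, sum_lin / cnt_lin, NA_real_)
  mean_log2 <- ifelse(cnt_log > 0, sum_log / cnt_log, NA_real_)
  obj <- list(mean_linear = mean_linear, mean_log2 = mean_log2,
              resolution = resolution, flank = flank,
              n_used = n_used, n_dropped = n_dropped,
              enrichment_score = NA_real_)
  class(obj) <- "PileupResult"
  obj
}

#' @export
print.PileupResult <- function(x, ...) {
  cat(sprintf(
    "PileupResult: %dx%d at %s bp (flank %s bp), %d snippets (%d dropped), score %.3f\n",
    nrow(x$mean_linear), ncol(x$mean_linear),
    format(x$resolution, big.mark = ","), format(x$flank, big.mark = ","),
    x$n_used, x$n_dropped, x$enrichment_score))
  invisible(x)
}

#' Aggregate O/E pileup at cis site pairs
#'
#' Snips an O/E window of +/- \code{flank} around each (site1, site2) bin
#' pair and averages per cell over snippets. Both the linear-O/E mean and
#' the mean of log2(O/E) are kept (scores use the linear mean; log2 is for
#' display). A pair is dropped (and counted) when either site is within
#' \code{flank} of a chromosome end or the pair separation is not greater
#' than \code{2 * flank} (the window would cross the diagonal). Cells with
#' missing O/E are skipped per cell; a snippet with a missing center cell is
#' dropped.
#'
#' @param oe An \code{OEMatrix} (conventionally at 25-kb bins for DSB-pair
#'   aggregation).
#' @param pairs data.frame from [cis_pairs()].
#' @param flank Half-window in bp (default 1 Mb, i.e. a 2 Mb window).
#' @return A \code{PileupResult} with the default cluster-enrichment score
#'   filled in.
#' @export
pairwise_pileup <- function(oe, pairs, flank = 1e6) {
  stopifnot(inherits(oe, "OEMatrix"))
  res <- oe$bin_size
  f <- as.integer(round(flank / res))
  d <- 2L * f + 1L
  sum_lin <- matrix(0, d, d); cnt_lin <- matrix(0, d, d)
  sum_log <- matrix(0, d, d); cnt_log <- matrix(0, d, d)
  off <- chrom_offsets(oe$bins)
  n_used <- 0L; n_dropped <- 0L
  for (r in seq_len(nrow(pairs))) {
    ch <- pairs$chrom[r]
    row <- off[off$chrom == ch, ]
    if (nrow(row) == 0) { n_dropped <- n_dropped + 1L; next }
    n <- row$n
    i <- floor(pairs$pos1[r] / res) + 1L
    j <- floor(pairs$pos2[r] / res) + 1L
    sep <- pairs$pos2[r] - pairs$pos1[r]
    if (i - f < 1 || j + f > n || i + f > n || j - f < 1 ||
        sep <= 2 * flank) { n_dropped <- n_dropped + 1L; next }
    W <- oe$chroms[[ch]][(i - f):(i + f), (j - f):(j + f)]
    if (!is.finite(W[f + 1L, f + 1L])) { n_dropped <- n_dropped + 1L; next }
    ok <- is.finite(W)
    sum_lin[ok] <- sum_lin[ok] + W[ok]
    cnt_lin <- cnt_lin + ok
    pos <- ok & W > 0
    sum_log[pos] <- sum_log[pos] + log2(W[pos])
    cnt_log <- cnt_log + pos
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable snippets")
  p <- new_pileup(sum_lin, cnt_lin, sum_log, cnt_log, res, flank,
                  n_used, n_dropped)
  p$enrichment_score <- cluster_enrichment_score(p,
                                                 outer_radius = min(1e6, flank))
  p
}

#' DSB cluster-enrichment score of a pileup
#'
#' Ratio of the mean linear O/E over the central \code{center_bins} x
#' \code{center_bins} block to the mean over the surrounding ring: cells
#' whose center lies beyond the central block but within
#' \code{outer_radius} of the pileup center (Chebyshev distance on cell
#' centers; ties at the radius included). With 25-kb bins and the defaults
#' this is the 125-kb center against the 125 kb - 1 Mb surround.
#'
#' @param pileup A \code{PileupResult} (or a bare linear-O/E matrix plus
#'   \code{resolution}).
#' @param center_bins Width of the central block in bins (odd; default 5).
#' @param outer_radius Ring outer radius in bp (default 1 Mb).
#' @param resolution Required when \code{pileup} is a bare matrix.
#' @param log_space Compute the ratio on mean log2(O/E) instead (sensitivity
#'   option; default FALSE).
#' @return The enrichment score (a single number; 1 = no enrichment).
#' @export
cluster_enrichment_score <- function(pileup, center_bins = 5,
                                     outer_radius = 1e6, resolution = NULL,
                                     log_space = FALSE) {
  if (inherits(pileup, "PileupResult")) {
    M <- if (log_space) pileup$mean_log2 else pileup$mean_linear
    resolution <- pileup$resolution
  } else {
    M <- pileup
    if (is.null(resolution)) stop("resolution required for a bare matrix")
  }
  d <- nrow(M)
  if (d %% 2 != 1) stop("pileup matrix must have odd dimension")
  ctr <- (d + 1L) / 2L
  rad <- floor(center_bins / 2)
  cheb <- pmax(abs(row(M) - ctr), abs(col(M) - ctr))
  ring_rad <- outer_radius / resolution
  if (d < 2 * ring_rad + 1) stop("pileup smaller than the requested ring")
  center <- cheb <= rad
  ring <- cheb > rad & cheb <= ring_rad
  if (!any(ring)) stop("empty ring")
  mean(M[center], na.rm = TRUE) / mean(M[ring], na.rm = TRUE)
}

#' Constrained-resampling null for the cluster-enrichment score
#'
#' Repeatedly replaces the damaged-site catalog with random control loci
#' drawn from bins that are (1) at least \code{min_dist} from every motif in
#' \code{all_motifs}, (2) matched per chromosome in number, and (3) matched
#' in undamaged-control compartment label, then recomputes the
#' cluster-enrichment score for each draw. Constraints (2) and (3) are
#' enforced jointly by sampling within (chromosome, label) strata.
#'
#' @param sites Damaged-site \code{SiteCatalog} (e.g. the top cut sites).
#' @param all_motifs \code{SiteCatalog} of every recognition motif.
#' @param compartments \code{CompartmentResult} of the undamaged control
#'   (typically at 250-kb bins) supplying the matching labels.
#' @param oe \code{OEMatrix} on which scores are computed (pileup bins).
#' @param n_resamples Number of draws (default 100).
#' @param seed Master seed; each resample uses an independently derived
#'   stream.
#' @param min_dist Exclusion radius around motifs in bp (default 125 kb).
#' @param flank Pileup half-window in bp (default 1 Mb).
#' @return A \code{ResampleNull}: list with \code{scores}, \code{mean},
#'   \code{sd}, \code{n_resamples}, the per-resample \code{loci}, and the
#'   derived sub-seeds in \code{seeds}.
#' @export
matched_control_null <- function(sites, all_motifs, compartments, oe,
                                 n_resamples = 100, seed = 1,
                                 min_dist = 125000, flank = 1e6) {
  bins <- oe$bins
  centers <- floor((bins$start + bins$end) / 2)
  # distance from each candidate bin center to the nearest motif
  dist <- rep(Inf, nrow(bins))
  for (ch in unique(bins$chrom)) {
    mp <- sort(all_motifs$pos[all_motifs$chrom == ch])
    bi <- which(bins$chrom == ch)
    if (length(mp) == 0) next
    k <- findInterval(centers[bi], mp)
    dlo <- ifelse(k >= 1, centers[bi] - mp[pmax(k, 1)], Inf)
    dhi <- ifelse(k < length(mp), mp[pmin(k + 1, length(mp))] - centers[bi], Inf)
    dist[bi] <- pmin(dlo, dhi)
  }
  comp_at <- function(chrom, pos) {
    id <- bin_of(compartments$ev1$bins, chrom, pos)
    ifelse(is.na(id), "unassigned", compartments$labels[id])
  }
  cand_lab <- comp_at(bins$chrom, centers)
  site_lab <- comp_at(sites$chrom, sites$pos)
  strata <- paste(sites$chrom, site_lab)
  need <- table(strata)
  cand_key <- paste(bins$chrom, cand_lab)
  eligible <- dist >= min_dist
  for (st in names(need)) {
    avail <- sum(eligible & cand_key == st)
    if (avail < need[[st]])
      stop(sprintf("stratum '%s': %d candidate bins for %d sites",
                   st, avail, need[[st]]))
  }
  scores <- numeric(n_resamples)
  loci <- vector("list", n_resamples)
  seeds <- vapply(seq_len(n_resamples), function(r) derive_seed(seed, r), 0)
  for (r in seq_len(n_resamples)) {
    picks <- with_seed_local(seeds[r], {
      unlist(lapply(names(need), function(st) {
        pool_idx <- which(eligible & cand_key == st)
        pool_idx[sample.int(length(pool_idx), need[[st]])]
      }))
    })
    cat_r <- site_catalog(bins$chrom[picks], centers[picks],
                          name = sprintf("ctl%03d_%02d", r, seq_along(picks)))
    loci[[r]] <- data.frame(chrom = cat_r$chrom, pos = cat_r$pos,
                            label = cand_lab[picks], dist = dist[picks],
                            stringsAsFactors = FALSE)
    p <- pairwise_pileup(oe, cis_pairs(cat_r), flank = flank)
    scores[r] <- p$enrichment_score
  }
  obj <- list(n_resamples = n_resamples, scores = scores,
              mean = mean(scores), sd = stats::sd(scores),
              loci = loci, seeds = seeds)
  class(obj) <- "ResampleNull"
  obj
}

#' @export
print.ResampleNull <- function(x, ...) {
  cat(sprintf("ResampleNull: %d resamples, score %.3f +/- %.3f\n",
              x$n_resamples, x$mean, x$sd))
  invisible(x)
}

#' Oriented CTCF anchor pileup with flame-line scores
#'
#' On-diagonal aggregate of O/E around oriented motif anchors; snippets at
#' minus-strand anchors are reflected so every motif points rightward
#' (downstream = increasing coordinate in the aggregate). The "flame" lines
#' left by one-sided loop extrusion are quantified as the mean O/E along the
#' row/column emanating from the center (the two cells nearest the diagonal
#' excluded) minus the mean of the off-line background.
#'
#' @param oe An \code{OEMatrix} (conventionally 5-kb bins).
#' @param anchors Oriented \code{SiteCatalog} (strand "+" or "-").
#' @param flank Half-window in bp (default 100 kb; 41 x 41 at 5 kb).
#' @return A \code{PileupResult} with \code{line_downstream},
#'   \code{line_upstream} and \code{line_background} fields.
#' @export
ctcf_pileup <- function(oe, anchors, flank = 1e5) {
  stopifnot(inherits(oe, "OEMatrix"))
  if (any(anchors$strand == "*")) stop("anchors must be oriented (+/-)")
  res <- oe$bin_size
  f <- as.integer(round(flank / res))
  d <- 2L * f + 1L
  sum_lin <- matrix(0, d, d); cnt_lin <- matrix(0, d, d)
  sum_log <- matrix(0, d, d); cnt_log <- matrix(0, d, d)
  off <- chrom_offsets(oe$bins)
  n_used <- 0L; n_dropped <- 0L
  for (r in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[r]
    row <- off[off$chrom == ch, ]
    if (nrow(row) == 0) { n_dropped <- n_dropped + 1L; next }
    n <- row$n
    i <- floor(anchors$pos[r] / res) + 1L
    if (i - f < 1 || i + f > n) { n_dropped <- n_dropped + 1L; next }
    W <- oe$chroms[[ch]][(i - f):(i + f), (i - f):(i + f)]
    if (anchors$strand[r] == "-") W <- W[d:1, d:1]
    ok <- is.finite(W)
    sum_lin[ok] <- sum_lin[ok] + W[ok]
    cnt_lin <- cnt_lin + ok
    pos <- ok & W > 0
    sum_log[pos] <- sum_log[pos] + log2(W[pos])
    cnt_log <- cnt_log + pos
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable snippets")
  p <- new_pileup(sum_lin, cnt_lin, sum_log, cnt_log, res, flank,
                  n_used, n_dropped)
  M <- p$mean_linear
  ctr <- f + 1L
  line_cells_down <- if (ctr + 2 <= d)
    c(M[ctr, (ctr + 2):d], M[(ctr + 2):d, ctr]) else numeric(0)
  line_cells_up <- if (ctr - 2 >= 1)
    c(M[ctr, 1:(ctr - 2)], M[1:(ctr - 2), ctr]) else numeric(0)
  on_line <- row(M) == ctr | col(M) == ctr
  bg <- mean(M[!on_line], na.rm = TRUE)
  p$line_downstream <- mean(line_cells_down, na.rm = TRUE) - bg
  p$line_upstream <- mean(line_cells_up, na.rm = TRUE) - bg
  p$line_background <- bg
  p$enrichment_score <- NA_real_
  p
}

#' Convergent CTCF-CTCF loop aggregation and loop score
#'
#' Enumerates all cis pairs of a "+" anchor upstream of a "-" anchor
#' (convergent orientation) separated by \code{min_sep}-\code{max_sep},
#' aggregates O/E windows centered on each pair, and scores looping as the
#' mean of the central 5 x 5 block over the mean of the remaining cells
#' within \code{ring_radius} of the center. Windows may cross the diagonal
#' (short-range pairs); snippets are dropped only at chromosome ends.
#'
#' @param oe An \code{OEMatrix} (conventionally 25-kb bins).
#' @param anchors Oriented \code{SiteCatalog}.
#' @param min_sep,max_sep Pair separation bounds in bp (defaults 25 kb and
#'   1 Mb).
#' @param flank Half-window in bp (default 100 kb).
#' @param ring_radius Score ring outer radius in bp (default 100 kb).
#' @return list(pileup = PileupResult, loop_score = numeric,
#'   n_loops = number of qualifying pairs).
#' @export
convergent_loop_score <- function(oe, anchors, min_sep = 25000,
                                  max_sep = 1e6, flank = 1e5,
                                  ring_radius = 1e5) {
  stopifnot(inherits(oe, "OEMatrix"))
  pairs <- convergent_pairs(anchors, min_sep, max_sep)
  if (nrow(pairs) == 0) stop("no convergent anchor pairs in range")
  res <- oe$bin_size
  f <- as.integer(round(flank / res))
  d <- 2L * f + 1L
  sum_lin <- matrix(0, d, d); cnt_lin <- matrix(0, d, d)
  sum_log <- matrix(0, d, d); cnt_log <- matrix(0, d, d)
  off <- chrom_offsets(oe$bins)
  n_used <- 0L; n_dropped <- 0L
  for (r in seq_len(nrow(pairs))) {
    ch <- pairs$chrom[r]
    row <- off[off$chrom == ch, ]
    if (nrow(row) == 0) { n_dropped <- n_dropped + 1L; next }
    n <- row$n
    i <- floor(pairs$pos1[r] / res) + 1L
    j <- floor(pairs$pos2[r] / res) + 1L
    if (i - f < 1 || j + f > n) { n_dropped <- n_dropped + 1L; next }
    W <- oe$chroms[[ch]][(i - f):(i + f), (j - f):(j + f)]
    ok <- is.finite(W)
    sum_lin[ok] <- sum_lin[ok] + W[ok]
    cnt_lin <- cnt_lin + ok
    pos <- ok & W > 0
    sum_log[pos] <- sum_log[pos] + log2(W[pos])
    cnt_log <- cnt_log + pos
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no usable snippets")
  p <- new_pileup(sum_lin, cnt_lin, sum_log, cnt_log, res, flank,
                  n_used, n_dropped)
  score <- cluster_enrichment_score(p, center_bins = 5,
                                    outer_radius = ring_radius)
  p$enrichment_score <- score
  list(pileup = p, loop_score = score, n_loops = nrow(pairs))
}

#' Enumerate convergent anchor pairs in cis
#'
#' @param anchors Oriented \code{SiteCatalog}.
#' @param min_sep,max_sep Separation bounds in bp.
#' @return data.frame(chrom, pos1, pos2) with pos1 on a "+" anchor upstream
#'   of a "-" anchor at pos2.
#' @export
convergent_pairs <- function(anchors, min_sep = 25000, max_sep = 1e6) {
  out <- list()
  for (ch in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == ch, , drop = FALSE]
    plus <- sub$pos[sub$strand == "+"]
    minus <- sub$pos[sub$strand == "-"]
    if (length(plus) == 0 || length(minus) == 0) next
    grid <- expand.grid(p = plus, m = minus)
    sep <- grid$m - grid$p
    keep <- sep >= min_sep & sep <= max_sep
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, pos1 = grid$p[keep],
                            pos2 = grid$m[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos1 = numeric(),
                      pos2 = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Anchored differential interaction track
#'
#' For one anchor bin, the per-bin difference of cis O/E between two
#' conditions: O/E(damage)[anchor, j] - O/E(control)[anchor, j] for every
#' bin j on the anchor chromosome (other chromosomes NA). Bins within
#' \code{mask_radius} of the anchor can be masked, mirroring the greyed-out
#' local-diagonal region of anchored plots.
#'
#' @param oe_damage,oe_control \code{OEMatrix} objects on identical bins
#'   (conventionally 1-Mb bins).
#' @param anchor list(chrom, pos) of the anchor locus (0-based bp).
#' @param mask_radius Radius in bp around the anchor to set NA (default 0).
#' @return A \code{ScalarTrack} labelled "anchored_differential".
#' @export
anchored_differential <- function(oe_damage, oe_control, anchor,
                                  mask_radius = 0) {
  stopifnot(inherits(oe_damage, "OEMatrix"), inherits(oe_control, "OEMatrix"))
  if (!same_bins(oe_damage$bins, oe_control$bins))
    stop("conditions are on different bin tables")
  bins <- oe_damage$bins
  aid <- bin_of(bins, anchor$chrom, anchor$pos)
  if (is.na(aid)) stop("anchor position outside the bin table")
  off <- chrom_offsets(bins)
  row <- off[off$chrom == anchor$chrom, ]
  local <- aid - row$first + 1L
  vd <- oe_damage$chroms[[anchor$chrom]][local, ]
  vc <- oe_control$chroms[[anchor$chrom]][local, ]
  if (all(!is.finite(vd)) || all(!is.finite(vc)))
    stop("anchor bin is filtered in one of the conditions")
  vals <- rep(NA_real_, nrow(bins))
  vals[row$first:(row$first + row$n - 1L)] <- vd - vc
  if (mask_radius > 0) {
    ctr <- floor((bins$start[aid] + bins$end[aid]) / 2)
    centers <- floor((bins$start + bins$end) / 2)
    vals[bins$chrom == anchor$chrom &
           abs(centers - ctr) <= mask_radius] <- NA_real_
  }
  scalar_track(bins, vals, "anchored_differential")
}
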