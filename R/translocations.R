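#' Classify a junction as blunt, microhomology or insertion
#'
#' Uses the alignment coordinates on the read: with
#' \code{gap = prey_start - bait_end}, \code{gap == 1} is a blunt joint
#' (bait and prey alignments abut), \code{gap <= 0} is a microhomology of
#' \code{1 - gap} bases (shared by both alignments), and \code{gap >= 2} is
#' an insertion of the intervening read bases. Microhomology is the
#' signature of alternative end-joining; blunt joints indicate classical
#' NHEJ. When bait/prey reference sequences are supplied the microhomology
#' length is cross-checked against sequence identity between the bait
#' continuation and the prey preface.
#'
#' @param records data.frame of junction records (see [junction_table()]),
#'   or a \code{JunctionTable}.
#' @param bait_ref,prey_refs Optional references for the cross-check:
#'   \code{bait_ref} a character string whose prefix the read's bait segment
#'   follows; \code{prey_refs} a character vector parallel to the records
#'   giving, for each junction, the prey-side reference beginning at the
#'   aligned prey base.
#' @return The records with columns \code{class} ("blunt"/"MH"/"insertion"),
#'   \code{mh_length} (0 for blunt, NA for insertion) and
#'   \code{insertion_seq} (NA unless insertion).
#' @export
classify_junction <- function(records, bait_ref = NULL, prey_refs = NULL) {
  if (inherits(records, "JunctionTable")) records <- records$records
  records <- as.data.frame(records)
  if (nrow(records) == 0) {
    records$class <- character(0)
    records$mh_length <- integer(0)
    records$insertion_seq <- character(0)
    return(records)
  }
  if (any(records$prey_start > nchar(records$seq)))
    stop("malformed record: prey_start after read end")
  gap <- records$prey_start - records$bait_end
  cls <- ifelse(gap == 1, "blunt", ifelse(gap <= 0, "MH", "insertion"))
  mh <- ifelse(gap == 1, 0L, ifelse(gap <= 0, 1L - gap, NA_integer_))
  ins <- rep(NA_character_, nrow(records))
  is_ins <- gap >= 2
  ins[is_ins] <- substr(records$seq[is_ins], records$bait_end[is_ins] + 1L,
                        records$prey_start[is_ins] - 1L)
  if (!is.null(bait_ref) && !is.null(prey_refs)) {
    for (r in which(cls == "MH")) {
      k <- mh[r]
      bait_cont <- substr(bait_ref, records$bait_end[r] - k + 1L,
                          records$bait_end[r])
      prey_pref <- substr(prey_refs[r], 1L, k)
      if (nchar(bait_cont) == k && nchar(prey_pref) == k &&
          bait_cont != prey_pref)
        warning(sprintf(
          "record %d: %d-nt microhomology not supported by references", r, k))
    }
  }
  records$class <- cls
  records$mh_length <- as.integer(mh)
  records$insertion_seq <- ins
  records
}

#' Summarize junction classes
#'
#' Counts and fractions over \{blunt, MH 1-5, MH >= 6, insertion\}. The
#' boundary between the two microhomology buckets is exposed as
#' \code{mh_split}: lengths < \code{mh_split} fall in the lower bucket,
#' lengths >= \code{mh_split} in the upper (default 6, so "MH 1-5" vs
#' "MH > 6" partition all microhomology junctions).
#'
#' @param records Classified records from [classify_junction()].
#' @param mh_split Lower bound of the long-microhomology bucket (default 6).
#' @return A \code{JunctionClassCounts}: list with \code{counts},
#'   \code{fractions} (NA when there are no junctions), \code{n} and the
#'   coarse three-way fractions \code{blunt}/\code{mh}/\code{insertion}.
#' @export
junction_class_summary <- function(records, mh_split = 6) {
  if (inherits(records, "JunctionTable")) records <- records$records
  if (!"class" %in% names(records))
    records <- classify_junction(records)
  n <- nrow(records)
  counts <- c("blunt" = sum(records$class == "blunt"),
              "MH 1-5" = sum(records$class == "MH" &
                               records$mh_length < mh_split),
              "MH >= 6" = sum(records$class == "MH" &
                                records$mh_length >= mh_split),
              "insertion" = sum(records$class == "insertion"))
  fractions <- if (n > 0) counts / n else
    stats::setNames(rep(NA_real_, 4), names(counts))
  obj <- list(counts = counts, fractions = fractions, n = n,
              blunt = unname(fractions["blunt"]),
              mh = unname(fractions["MH 1-5"] + fractions["MH >= 6"]),
              insertion = unname(fractions["insertion"]),
              mh_split = mh_split)
  class(obj) <- "JunctionClassCounts"
  obj
}

#' @export
print.JunctionClassCounts <- function(x, ...) {
  cat(sprintf("JunctionClassCounts (n = %d):\n", x$n))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Classify prey loci by distance to the nearest cut-site motif
#'
#' Distance is measured from the prey junction base to the nearest motif
#' center. Below \code{proximal_max} is "proximal" (recurrent breaks at cut
#' sites, allowing for end resection), above \code{distal_min} is "distal"
#' (spontaneous breaks), anything between is "intermediate" (reported but
#' excluded from the two-class summary).
#'
#' @param records Junction records or a \code{JunctionTable}.
#' @param motifs \code{SiteCatalog} of all recognition motifs (not only the
#'   frequently cut subset).
#' @param proximal_max,distal_min Class bounds in bp (defaults 500 and
#'   10,000).
#' @return The records with \code{motif_dist} and \code{prey_class} columns.
#' @export
classify_prey_distance <- function(records, motifs, proximal_max = 500,
                                   distal_min = 10000) {
  if (inherits(records, "JunctionTable")) records <- records$records
  if (nrow(motifs) == 0) stop("empty motif catalog")
  dist <- rep(Inf, nrow(records))
  for (ch in unique(records$prey_chrom)) {
    mp <- sort(motifs$pos[motifs$chrom == ch])
    ri <- which(records$prey_chrom == ch)
    if (length(mp) == 0) next
    p <- records$prey_pos[ri]
    k <- findInterval(p, mp)
    dlo <- ifelse(k >= 1, p - mp[pmax(k, 1)], Inf)
    dhi <- ifelse(k < length(mp), mp[pmin(k + 1, length(mp))] - p, Inf)
    dist[ri] <- pmin(dlo, dhi)
  }
  records$motif_dist <- dist
  records$prey_class <- ifelse(dist < proximal_max, "proximal",
                               ifelse(dist > distal_min, "distal",
                                      "intermediate"))
  records
}

#' Bin junctions into a genome-wide frequency table
#'
#' Counts junctions in fixed windows and normalizes on two scales: per
#' bait-only read (comparable across libraries of different depth) and per
#' 1,000 total events (junctions + bait-only reads).
#'
#' @param jt A \code{JunctionTable}.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param bin_size Window size in bp (default 100 kb).
#' @param condition Optional condition label carried through.
#' @return A \code{FrequencyTable}: list with \code{bins} (all genome bins),
#'   per-bin \code{raw}, \code{per_bait} and \code{per_1000}, plus
#'   \code{bait_only_count}, \code{total_events}, \code{bait} and
#'   \code{condition}. When there are no bait-only reads \code{per_bait} is
#'   NA and \code{per_bait_defined} is FALSE.
#' @export
frequency_table <- function(jt, chrom_sizes, bin_size = 1e5,
                            condition = NA_character_) {
  stopifnot(inherits(jt, "JunctionTable"))
  bins <- bin_table(chrom_sizes, bin_size)
  ids <- bin_of(bins, jt$records$prey_chrom, jt$records$prey_pos)
  if (anyNA(ids)) stop("junction outside the genome bins")
  raw <- numeric(nrow(bins))
  if (length(ids) > 0) {
    tab <- table(ids)
    raw[as.integer(names(tab))] <- as.numeric(tab)
  }
  per_bait_defined <- jt$bait_only_count > 0
  if (!per_bait_defined)
    warning("no bait-only reads: per-bait normalization undefined")
  obj <- list(bins = bins,
              raw = raw,
              per_bait = if (per_bait_defined) raw / jt$bait_only_count
                         else rep(NA_real_, length(raw)),
              per_1000 = 1000 * raw / jt$total_events,
              bait_only_count = jt$bait_only_count,
              total_events = jt$total_events,
              bait = jt$bait, condition = condition,
              per_bait_defined = per_bait_defined)
  class(obj) <- "FrequencyTable"
  obj
}

#' @export
print.FrequencyTable <- function(x, ...) {
  cat(sprintf(
    "FrequencyTable: %d junctions in %d bins; %d bait-only; %d events\n",
    sum(x$raw), nrow(x$bins), x$bait_only_count, x$total_events))
  invisible(x)
}

#' Differential translocation frequencies between two conditions
#'
#' Restricts to bins with at least \code{min_events} raw junctions summed
#' over the two conditions, computes the per-bin log2 fold change of
#' normalized frequencies (with a pseudocount of \code{pseudocount} raw
#' events added to both conditions before normalizing, display only), and
#' tests the genome-wide shift with a paired Wilcoxon signed-rank test on
#' the raw normalized differences across retained bins. Intra- and
#' inter-chromosomal subtotals are reported relative to the bait chromosome.
#'
#' @param tableA,tableB \code{FrequencyTable}s on the same bin grid
#'   (A = numerator condition).
#' @param min_events Combined raw-event filter per bin (default 10).
#' @param scale Which normalization to compare: "per_bait" (default) or
#'   "per_1000".
#' @param pseudocount Raw-event pseudocount for the fold-change display
#'   (default 0.5).
#' @param paired Use the paired signed-rank test (default TRUE; FALSE gives
#'   the rank-sum test).
#' @return A \code{DifferentialTable}: list with the retained-bin data.frame
#'   \code{table} (chrom, start, end, rawA, rawB, normA, normB, log2fc),
#'   \code{p_value}, \code{n_bins}, and \code{intra}/\code{inter} subtotal
#'   lists.
#' @export
differential_translocation <- function(tableA, tableB, min_events = 10,
                                       scale = c("per_bait", "per_1000"),
                                       pseudocount = 0.5, paired = TRUE) {
  scale <- match.arg(scale)
  stopifnot(inherits(tableA, "FrequencyTable"),
            inherits(tableB, "FrequencyTable"))
  if (!same_bins(tableA$bins, tableB$bins))
    stop("frequency tables are on different bin grids")
  if (scale == "per_bait" &&
      (!tableA$per_bait_defined || !tableB$per_bait_defined))
    stop("per-bait scale undefined (no bait-only reads); use per_1000")
  keep <- which(tableA$raw + tableB$raw >= min_events)
  if (length(keep) == 0) stop("no bins pass the event filter")
  denomA <- if (scale == "per_bait") tableA$bait_only_count else
    tableA$total_events / 1000
  denomB <- if (scale == "per_bait") tableB$bait_only_count else
    tableB$total_events / 1000
  normA <- tableA[[scale]][keep]
  normB <- tableB[[scale]][keep]
  log2fc <- log2(((tableA$raw[keep] + pseudocount) / denomA) /
                   ((tableB$raw[keep] + pseudocount) / denomB))
  diffs <- normA - normB
  p_value <- if (all(diffs == 0)) NA_real_ else
    suppressWarnings(stats::wilcox.test(normA, normB,
                                        paired = paired)$p.value)
  bait_chrom <- tableA$bait$chrom
  sub <- function(sel) list(
    n_bins = sum(sel),
    rawA = sum(tableA$raw[keep][sel]), rawB = sum(tableB$raw[keep][sel]),
    normA = sum(normA[sel]), normB = sum(normB[sel]))
  is_intra <- tableA$bins$chrom[keep] == bait_chrom
  obj <- list(table = data.frame(chrom = tableA$bins$chrom[keep],
                                 start = tableA$bins$start[keep],
                                 end = tableA$bins$end[keep],
                                 rawA = tableA$raw[keep],
                                 rawB = tableB$raw[keep],
                                 normA = normA, normB = normB,
                                 log2fc = log2fc,
                                 stringsAsFactors = FALSE),
              p_value = p_value, n_bins = length(keep),
              min_events = min_events, scale = scale,
              intra = sub(is_intra), inter = sub(!is_intra))
  class(obj) <- "DifferentialTable"
  obj
}

#' @export
print.DifferentialTable <- function(x, ...) {
  cat(sprintf(
    "DifferentialTable: %d bins (>=%d events), Wilcoxon p = %.3g\n",
    x$n_bins, x$min_events, x$p_value))
  invisible(x)
}

#' Map an insertion sequence to the prey or bait flank
#'
#' Exact-match search of the insert and its reverse complement in the
#' reference window around the prey locus, then around the bait. Most
#' inserts in damage-induced junction libraries copy sequence from the
#' vicinity of the prey, often from the antiparallel strand.
#'
#' @param insertion_seq Insert (20-30 nt).
#' @param prey_flank_ref,bait_flank_ref Reference windows (character;
#'   \code{bait_flank_ref} optional).
#' @return list(matched, source ("prey"/"bait"/NA), strand ("sense"/
#'   "antiparallel"/NA), offset (1-based position of the match in the
#'   searched window, NA if unmatched)).
#' @export
map_insertion <- function(insertion_seq, prey_flank_ref,
                          bait_flank_ref = NULL) {
  L <- nchar(insertion_seq)
  if (L < 20 || L > 30)
    stop("insertion length outside the reportable 20-30 nt range")
  search_one <- function(ref, src) {
    if (is.null(ref)) return(NULL)
    if (nchar(ref) < L) stop("flank shorter than the insert")
    fw <- Biostrings::matchPattern(insertion_seq, Biostrings::DNAString(ref))
    if (length(fw) > 0)
      return(list(matched = TRUE, source = src, strand = "sense",
                  offset = Biostrings::start(fw)[1]))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(insertion_seq)))
    rv <- Biostrings::matchPattern(rc, Biostrings::DNAString(ref))
    if (length(rv) > 0)
      return(list(matched = TRUE, source = src, strand = "antiparallel",
                  offset = Biostrings::start(rv)[1]))
    NULL
  }
  hit <- search_one(prey_flank_ref, "prey")
  if (is.null(hit)) hit <- search_one(bait_flank_ref, "bait")
  if (is.null(hit))
    hit <- list(matched = FALSE, source = NA_character_,
                strand = NA_character_, offset = NA_integer_)
  hit
}

#' Annotate prey loci by genomic region
#'
#' Assigns each prey to Promoter (within \code{promoter_flank} of a TSS,
#' taking precedence), Gene Body (inside a gene interval) or Intergenic.
#'
#' @param records Junction records or a \code{JunctionTable}.
#' @param genes data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{strand} ("+"/"-"); the TSS is the
#'   strand-appropriate end.
#' @param promoter_flank Promoter half-width around the TSS in bp
#'   (default 3000).
#' @return The records with a \code{region} column.
#' @export
annotate_prey <- function(records, genes, promoter_flank = 3000) {
  if (inherits(records, "JunctionTable")) records <- records$records
  region <- rep("Intergenic", nrow(records))
  if (is.null(genes) || nrow(genes) == 0) {
    warning("empty gene model: all prey Intergenic")
    records$region <- region
    return(records)
  }
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  prey <- GenomicRanges::GRanges(records$prey_chrom,
                                 IRanges::IRanges(records$prey_pos + 1L,
                                                  width = 1L))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  prom <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(tss + 1L - promoter_flank, 1L),
                                                  tss + 1L + promoter_flank))
  in_body <- GenomicRanges::countOverlaps(prey, body) > 0
  in_prom <- GenomicRanges::countOverlaps(prey, prom) > 0
  region[in_body] <- "Gene Body"
  region[in_prom] <- "Promoter"
  records$region <- region
  records
}
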