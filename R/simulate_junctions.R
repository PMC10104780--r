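#' Configuration for the synthetic HTGTS junction generator
#'
#' @param bait list(chrom, pos, strand) of the bait locus.
#' @param prey_loci data.frame(chrom, pos) of prey break sites.
#' @param mixture Named numeric: weights for \code{blunt}, \code{mh},
#'   \code{insertion}; must sum to 1.
#' @param mh_lengths Integer vector of candidate microhomology lengths
#'   (default 1:8).
#' @param mh_weights Sampling weights over \code{mh_lengths} (default
#'   geometric-ish decay).
#' @param ins_lengths Candidate insertion lengths (default 2:30; the
#'   reporting pipeline caps insertions at 30 bp).
#' @param bait_len,prey_len Aligned bases from bait/prey per read
#'   (defaults 40).
#' @param n_junctions,n_bait_only Library composition.
#' @param insertion_source "random" (default) or "prey_antiparallel"
#'   (inserts copied from the reverse complement of the prey flank; lengths
#'   clamped to 20-30 so they are mappable).
#' @param seed Master seed.
#' @return A validated \code{JunctionSimConfig}.
#' @export
junction_sim_config <- function(bait = list(chrom = "chr2", pos = 13271320,
                                            strand = "+"),
                                prey_loci = NULL,
                                mixture = c(blunt = 0.18, mh = 0.69,
                                            insertion = 0.13),
                                mh_lengths = 1:8,
                                mh_weights = NULL,
                                ins_lengths = 2:30,
                                bait_len = 40, prey_len = 40,
                                n_junctions = 1000, n_bait_only = 500,
                                insertion_source = c("random",
                                                     "prey_antiparallel"),
                                seed = 7) {
  insertion_source <- match.arg(insertion_source)
  stopifnot(abs(sum(mixture) - 1) < 1e-8,
            all(c("blunt", "mh", "insertion") %in% names(mixture)),
            all(ins_lengths >= 1), all(ins_lengths <= 30),
            all(mh_lengths >= 1), n_junctions >= 0, n_bait_only >= 0)
  if (is.null(prey_loci))
    prey_loci <- data.frame(
      chrom = c("chr2", "chr2", "chr5", "chr8", "chr11"),
      pos = c(45000000, 90000000, 30000000, 60000000, 20000000))
  if (is.null(mh_weights)) mh_weights <- 0.6^seq_along(mh_lengths)
  mh_weights <- mh_weights / sum(mh_weights)
  cfg <- list(bait = bait, prey_loci = prey_loci, mixture = mixture,
              mh_lengths = mh_lengths, mh_weights = mh_weights,
              ins_lengths = ins_lengths, bait_len = bait_len,
              prey_len = prey_len, n_junctions = n_junctions,
              n_bait_only = n_bait_only,
              insertion_source = insertion_source, seed = seed)
  class(cfg) <- "JunctionSimConfig"
  cfg
}

# Random DNA with no two adjacent identical bases. The constraint keeps the
# planted junction coordinates identifiable: a maximal-overlap scan of the
# read against the references recovers exactly the planted class.
random_dna_distinct <- function(n) {
  bases <- c("A", "C", "G", "T")
  idx <- integer(n)
  idx[1] <- sample.int(4, 1)
  if (n > 1) {
    step <- sample.int(3, n - 1, replace = TRUE)  # offset among the 3 others
    for (i in 2:n) idx[i] <- (idx[i - 1] - 1L + step[i - 1L]) %% 4L + 1L
  }
  paste(bases[idx], collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substr1 <- function(x, i, j) substr(x, i, j)

#' Simulate an HTGTS junction library with known class composition
#'
#' Builds each read as bait prefix + (shared microhomology | nothing |
#' insertion) + prey suffix, with the alignment coordinates set from the
#' construction, so classification can be validated by round trip. Prey
#' references are mutated locally where a junction requires sequence
#' homology with the bait. Bait-only reads are appended. Reference
#' sequences avoid adjacent repeated bases and junction-flank coincidences
#' so the planted class is the unique maximal-overlap reading of each read.
#'
#' @param cfg A \code{JunctionSimConfig}.
#' @return list(junctions = JunctionTable, truth = data.frame (class,
#'   mh_length, insertion_seq, prey_ref, prey_flank per junction),
#'   bait_ref = character).
#' @export
simulate_junction_library <- function(cfg) {
  stopifnot(inherits(cfg, "JunctionSimConfig"))
  with_seed_local(cfg$seed, {
    B <- cfg$bait_len; P <- cfg$prey_len
    bait_ref <- random_dna_distinct(B + 20)
    n <- cfg$n_junctions
    classes <- sample(c("blunt", "MH", "insertion"), n, replace = TRUE,
                      prob = cfg$mixture[c("blunt", "mh", "insertion")])
    prey_idx <- sample(nrow(cfg$prey_loci), n, replace = TRUE)
    # wide antiparallel flank used when inserts are copied from the prey
    prey_flanks <- vapply(seq_len(nrow(cfg$prey_loci)),
                          function(i) random_dna(120), "")
    recs <- vector("list", n)
    truth <- vector("list", n)
    bases <- c("A", "C", "G", "T")
    next_bait <- substr1(bait_ref, B + 1, B + 1)
    for (r in seq_len(n)) {
      cl <- classes[r]
      prey_ref <- random_dna_distinct(P + 10)
      mh_k <- NA_integer_; ins <- NA_character_
      if (cl == "blunt") {
        # forbid chance homology at the joint
        repeat {
          b1 <- substr1(prey_ref, 1, 1)
          if (b1 != substr1(bait_ref, B, B) && b1 != next_bait) break
          prey_ref <- paste0(sample(bases, 1), substr1(prey_ref, 2, nchar(prey_ref)))
        }
        read <- paste0(substr1(bait_ref, 1, B), substr1(prey_ref, 1, P))
        bait_end <- B; prey_start <- B + 1L
        mh_k <- 0L
      } else if (cl == "MH") {
        k <- sample(cfg$mh_lengths, 1, prob = cfg$mh_weights)
        # plant the shared bases: prey preface = bait continuation
        shared <- substr1(bait_ref, B - k + 1, B)
        tail_ref <- substr1(prey_ref, k + 1, nchar(prey_ref))
        repeat {
          b1 <- substr1(tail_ref, 1, 1)
          if (b1 != next_bait && b1 != substr1(shared, k, k)) break
          tail_ref <- paste0(sample(bases, 1),
                             substr1(tail_ref, 2, nchar(tail_ref)))
        }
        prey_ref <- paste0(shared, tail_ref)
        read <- paste0(substr1(bait_ref, 1, B),
                       substr1(prey_ref, k + 1, P))
        bait_end <- B; prey_start <- B - k + 1L
        mh_k <- as.integer(k)
      } else {
        if (cfg$insertion_source == "prey_antiparallel") {
          # resample the copied window until the joint constraints hold, so
          # the insert stays an exact reverse-complement copy of the flank
          repeat {
            L <- sample(20:30, 1)
            start <- sample(nchar(prey_flanks[prey_idx[r]]) - L, 1)
            ins <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(substr1(prey_flanks[prey_idx[r]],
                                            start, start + L - 1))))
            if (substr1(ins, 1, 1) != next_bait) break
          }
        } else {
          L <- sample(cfg$ins_lengths, 1)
          ins <- random_dna(L)
          repeat {
            if (substr1(ins, 1, 1) != next_bait) break
            ins <- paste0(sample(bases, 1), substr1(ins, 2, nchar(ins)))
          }
        }
        repeat {
          b1 <- substr1(prey_ref, 1, 1)
          if (b1 != substr1(ins, nchar(ins), nchar(ins))) break
          prey_ref <- paste0(sample(bases, 1),
                             substr1(prey_ref, 2, nchar(prey_ref)))
        }
        read <- paste0(substr1(bait_ref, 1, B), ins, substr1(prey_ref, 1, P))
        bait_end <- B; prey_start <- B + nchar(ins) + 1L
      }
      pl <- cfg$prey_loci[prey_idx[r], ]
      recs[[r]] <- data.frame(prey_chrom = pl$chrom, prey_pos = pl$pos,
                              prey_strand = "+", seq = read,
                              bait_end = bait_end, prey_start = prey_start,
                              stringsAsFactors = FALSE)
      truth[[r]] <- data.frame(class = cl, mh_length = mh_k,
                               insertion_seq = ins, prey_ref = prey_ref,
                               prey_flank = prey_flanks[prey_idx[r]],
                               stringsAsFactors = FALSE)
    }
    records <- if (n > 0) do.call(rbind, recs) else
      data.frame(prey_chrom = character(), prey_pos = numeric(),
                 prey_strand = character(), seq = character(),
                 bait_end = integer(), prey_start = integer())
    jt <- junction_table(records, cfg$bait,
                         bait_only_count = cfg$n_bait_only)
    list(junctions = jt,
         truth = if (n > 0) do.call(rbind, truth) else NULL,
         bait_ref = bait_ref)
  })
}

#' Build a site catalog by motif scan or from planted positions
#'
#' In scan mode, finds every exact occurrence of the recognition motif
#' (default the AsiSI site GCGATCGC) in the given sequences; palindromic
#' motifs (equal to their reverse complement, checked at runtime) yield one
#' site per position, others are scanned on both strands. In planted mode,
#' returns the supplied positions with rank scores emulating an END-seq
#' cleavage ranking.
#'
#' @param genome For scan mode: a named character vector or
#'   \code{Biostrings::DNAStringSet} (or FASTA path) of sequences. For
#'   planted mode: a data.frame(chrom, pos) of sites.
#' @param mode "motif_scan" or "planted".
#' @param motif Recognition sequence (non-degenerate ACGT; default
#'   "GCGATCGC").
#' @param scores Optional scores for planted mode (default: descending
#'   ranks).
#' @return A \code{SiteCatalog} (positions 0-based motif starts).
#' @export
make_site_catalog <- function(genome, mode = c("motif_scan", "planted"),
                              motif = "GCGATCGC", scores = NULL) {
  mode <- match.arg(mode)
  if (mode == "planted") {
    df <- as.data.frame(genome)
    if (is.null(scores)) scores <- rev(seq_len(nrow(df)))
    return(site_catalog(df$chrom, df$pos, strand = "*", score = scores,
                        name = sprintf("site%03d", seq_len(nrow(df)))))
  }
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be ACGT only")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  pal <- motif == as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  out <- list()
  for (i in seq_along(genome)) {
    ch <- names(genome)[i]
    fw <- Biostrings::start(Biostrings::matchPattern(motif, genome[[i]]))
    pos <- fw - 1L
    strand <- rep("+", length(pos))
    if (!pal) {
      rcm <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
      rv <- Biostrings::start(Biostrings::matchPattern(rcm, genome[[i]]))
      pos <- c(pos, rv - 1L)
      strand <- c(strand, rep("-", length(rv)))
    } else strand <- rep("*", length(pos))
    if (length(pos) > 0)
      out[[ch]] <- data.frame(chrom = ch, pos = pos, strand = strand,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(site_catalog(character(), numeric()))
  df <- do.call(rbind, out)
  df <- df[order(match(df$chrom, names(genome)), df$pos), ]
  site_catalog(df$chrom, df$pos, strand = df$strand,
               score = rev(seq_len(nrow(df))),
               name = sprintf("motif%04d", seq_len(nrow(df))))
}
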