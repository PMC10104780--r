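#' Mouse-like toy genome preset with 97 frequently cut sites
#'
#' A synthetic 19-chromosome genome whose cut-site catalog reproduces two
#' published constraints of the frequently cut AsiSI sites in MEF cells:
#' 97 sites in total, forming exactly 304 cis pairs. The per-chromosome
#' counts (12, 11, 10, 8, 8, 7, 6, 5, 4, 4, 4, 4, 4, 3, 3, 1, 1, 1, 1) are
#' a synthetic stand-in constructed to satisfy those constraints (the real
#' per-chromosome table is not redistributed here). Sites are evenly spaced
#' along each chromosome, keeping every cis pair usable at a 1-Mb pileup
#' flank.
#'
#' @param chrom_size Length of every chromosome in bp (default 60 Mb).
#' @return list(sites = SiteCatalog of the 97 sites,
#'   chrom_sizes = named vector).
#' @export
mouse_like_cut_sites <- function(chrom_size = 6e7) {
  counts <- c(12, 11, 10, 8, 8, 7, 6, 5, 4, 4, 4, 4, 4, 3, 3, 1, 1, 1, 1)
  chroms <- paste0("chr", seq_along(counts))
  chrom_sizes <- stats::setNames(rep(chrom_size, length(counts)), chroms)
  rows <- list()
  for (k in seq_along(counts)) {
    n <- counts[k]
    lo <- 4e6; hi <- chrom_size - 4e6
    pos <- if (n == 1) (lo + hi) / 2 else seq(lo, hi, length.out = n)
    rows[[k]] <- data.frame(chrom = chroms[k], pos = floor(pos),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  sites <- site_catalog(df$chrom, df$pos, strand = "*",
                        score = rev(seq_len(nrow(df))),
                        name = sprintf("DSB%02d", seq_len(nrow(df))),
                        chrom_sizes = chrom_sizes)
  list(sites = sites, chrom_sizes = chrom_sizes)
}
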