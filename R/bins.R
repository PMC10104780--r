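#' Build a uniform genomic bin table
#'
#' Tiles each chromosome with consecutive, non-overlapping bins of a fixed
#' size. The terminal bin of a chromosome may be shorter than \code{bin_size}.
#' All coordinates are 0-based, half-open. Bin ids are 1-based, dense, and
#' ordered by (chromosome, start) in the order chromosomes appear in
#' \code{chrom_sizes}.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{bin_id}, carrying \code{bin_size} and \code{chrom_sizes} as
#'   attributes.
#' @export
bin_table <- function(chrom_sizes, bin_size) {
  stopifnot(length(chrom_sizes) > 0, !is.null(names(chrom_sizes)),
            bin_size >= 1, all(chrom_sizes >= 1))
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$bin_id <- seq_len(nrow(bins))
  attr(bins, "bin_size") <- as.numeric(bin_size)
  attr(bins, "chrom_sizes") <- chrom_sizes
  class(bins) <- c("BinTable", "data.frame")
  bins
}

#' @export
print.BinTable <- function(x, ...) {
  cat(sprintf("BinTable: %d bins, %d chromosome(s), bin size %s bp\n",
              nrow(x), length(unique(x$chrom)),
              format(attr(x, "bin_size"), big.mark = ",")))
  invisible(x)
}

bin_size_of <- function(bins) attr(bins, "bin_size")

chrom_sizes_of <- function(bins) {
  cs <- attr(bins, "chrom_sizes")
  if (!is.null(cs)) return(cs)
  tapply(bins$end, bins$chrom, max)[unique(bins$chrom)]
}

#' Locate the bin containing a genomic position
#'
#' @param bins A bin table from [bin_table()].
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @return Integer bin id(s) (NA where the position falls outside the table).
#' @export
bin_of <- function(bins, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- rep(NA_integer_, n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- bins[bins$chrom == ch, ]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos[sel], sub$start)
    ok <- idx >= 1 & pos[sel] < sub$end[pmax(idx, 1)] & pos[sel] >= 0
    out[sel[ok]] <- sub$bin_id[idx[ok]]
  }
  out
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end)
}

# per-chromosome first bin id and bin count, in table order
chrom_offsets <- function(bins) {
  chroms <- unique(bins$chrom)
  first <- vapply(chroms, function(ch) min(bins$bin_id[bins$chrom == ch]), 0)
  n <- vapply(chroms, function(ch) sum(bins$chrom == ch), 0)
  data.frame(chrom = chroms, first = as.integer(first), n = as.integer(n),
             stringsAsFactors = FALSE)
}
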