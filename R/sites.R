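#' Construct a catalog of genomic point features
#'
#' Holds point features such as AsiSI cut sites (with an END-seq-style rank
#' score) or oriented CTCF motif anchors. Positions are 0-based.
#'
#' @param chrom,pos,strand,score,name Parallel vectors; \code{strand} in
#'   \code{c("+", "-", "*")} ("*" = unoriented).
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return A \code{SiteCatalog} data.frame.
#' @export
site_catalog <- function(chrom, pos, strand = "*", score = NA_real_,
                         name = NA_character_, chrom_sizes = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = chrom, pos = as.numeric(pos),
                   strand = rep_len(strand, n),
                   score = rep_len(as.numeric(score), n),
                   name = rep_len(as.character(name), n),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$strand %in% c("+", "-", "*")))
  if (!is.null(chrom_sizes)) {
    if (any(!df$chrom %in% names(chrom_sizes)))
      stop("site on unknown chromosome")
    if (any(df$pos < 0 | df$pos >= chrom_sizes[df$chrom]))
      stop("site position outside chromosome bounds")
  }
  if (anyDuplicated(df[, c("chrom", "pos", "strand")]))
    stop("duplicate (chrom, pos, strand) entries")
  class(df) <- c("SiteCatalog", "data.frame")
  df
}

#' Read point features from a BED file
#'
#' BED intervals (0-based half-open) collapse to point sites at the interval
#' midpoint \code{floor((start + end) / 2)}; columns 4-6 (name, score,
#' strand), when present, are carried through.
#'
#' @param path BED file.
#' @param chrom_sizes Optional named vector for bounds checking.
#' @return A \code{SiteCatalog}.
#' @export
read_sites <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  name <- if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
  score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  site_catalog(df$chrom, floor((df$start + df$end) / 2), strand, score, name,
               chrom_sizes = chrom_sizes)
}

#' Write a site catalog as BED (1-bp features)
#' @param sites A \code{SiteCatalog}.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$pos, sites$pos + 1,
                   ifelse(is.na(sites$name), ".", sites$name),
                   ifelse(is.na(sites$score), 0, sites$score),
                   ifelse(sites$strand == "*", ".", sites$strand))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(sites)
}

sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos + 1L, width = 1L),
                         strand = ifelse(sites$strand == "*", "*", sites$strand))
}
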