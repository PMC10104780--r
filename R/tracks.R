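#' Construct a per-bin scalar track
#'
#' @param bins A bin table from [bin_table()].
#' @param values Numeric vector, one value per bin (NA = missing).
#' @param label Semantic name, e.g. "gene_density", "EV1", "insulation",
#'   "compartment".
#' @return A \code{ScalarTrack}.
#' @export
scalar_track <- function(bins, values, label = "value") {
  stopifnot(inherits(bins, "BinTable"), length(values) == nrow(bins))
  obj <- list(bins = bins, values = values, label = label)
  class(obj) <- "ScalarTrack"
  obj
}

#' @export
print.ScalarTrack <- function(x, ...) {
  cat(sprintf("ScalarTrack '%s': %d bins, %d missing\n",
              x$label, length(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read a bedGraph into a per-bin track
#'
#' Intervals are averaged into the target bins with length weighting; bins
#' with no covering interval are NA. bedGraph coordinates are 0-based
#' half-open and are used as-is.
#'
#' @param path bedGraph file (chrom, start, end, value; header/track lines
#'   starting with "track" or "#" are skipped).
#' @param bins Target bin table.
#' @param label Track label.
#' @return A \code{ScalarTrack}.
#' @export
read_track <- function(path, bins, label = "value") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: chrom start end value")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  track_from_intervals(df, bins, label)
}

# shared by read_track and the simulators
track_from_intervals <- function(df, bins, label = "value") {
  sizes <- chrom_sizes_of(bins)
  known <- df$chrom %in% names(sizes)
  if (any(known)) {
    over <- df$end[known] > sizes[df$chrom[known]]
    if (any(over)) stop("interval extends beyond chromosome end")
  }
  df <- df[known, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               value = df$value)
  bgr <- GenomicRanges::GRanges(bins$chrom,
                                IRanges::IRanges(bins$start + 1L, bins$end))
  hits <- GenomicRanges::findOverlaps(bgr, gr)
  vals <- rep(NA_real_, nrow(bins))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(bgr[qi], gr[si]))
    num <- rowsum(w * df$value[si], qi)
    den <- rowsum(w, qi)
    vals[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  }
  scalar_track(bins, vals, label)
}

#' Re-bin a track onto another bin table
#'
#' Length-weighted averaging of the track's bin intervals into the target
#' bins (missing source bins are dropped first).
#'
#' @param track A \code{ScalarTrack}.
#' @param bins Target bin table.
#' @return A \code{ScalarTrack} on \code{bins}.
#' @export
average_track <- function(track, bins) {
  keep <- !is.na(track$values)
  df <- data.frame(chrom = track$bins$chrom[keep],
                   start = track$bins$start[keep],
                   end = track$bins$end[keep],
                   value = track$values[keep])
  track_from_intervals(df, bins, track$label)
}

#' Write a track as bedGraph (missing bins omitted)
#' @param track A \code{ScalarTrack}.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  keep <- !is.na(track$values)
  df <- data.frame(track$bins$chrom, track$bins$start, track$bins$end,
                   track$values)[keep, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(track)
}
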