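#' Construct a sparse binned contact matrix
#'
#' Stores the upper triangle of a symmetric, binned Hi-C contact matrix as
#' pixel triples \code{(bin1_id, bin2_id, count)} together with its bin table
#' and (optionally) per-bin balancing weights. Pixels with
#' \code{bin1_id > bin2_id} are mirrored into the upper triangle; duplicate
#' coordinates are an error.
#'
#' @param bins A bin table from [bin_table()].
#' @param pixels data.frame with integer columns \code{bin1_id},
#'   \code{bin2_id} and non-negative \code{count}.
#' @param weights Optional numeric vector of per-bin balancing weights
#'   (NA = filtered bin). Defaults to all-NA (unbalanced).
#' @return A \code{ContactMatrix} object.
#' @export
contact_matrix <- function(bins, pixels, weights = NULL) {
  stopifnot(inherits(bins, "BinTable"))
  pixels <- as.data.frame(pixels)
  stopifnot(all(c("bin1_id", "bin2_id", "count") %in% names(pixels)))
  if (nrow(pixels) > 0) {
    if (any(pixels$count < 0)) stop("negative pixel counts")
    if (any(pixels$bin1_id < 1 | pixels$bin2_id > nrow(bins)))
      stop("pixel bin ids outside bin table")
    flip <- pixels$bin1_id > pixels$bin2_id
    if (any(flip)) {
      tmp <- pixels$bin1_id[flip]
      pixels$bin1_id[flip] <- pixels$bin2_id[flip]
      pixels$bin2_id[flip] <- tmp
    }
    key <- paste(pixels$bin1_id, pixels$bin2_id)
    if (anyDuplicated(key)) stop("duplicate pixel coordinates")
    pixels <- pixels[order(pixels$bin1_id, pixels$bin2_id), , drop = FALSE]
    rownames(pixels) <- NULL
  }
  pixels$bin1_id <- as.integer(pixels$bin1_id)
  pixels$bin2_id <- as.integer(pixels$bin2_id)
  pixels$count <- as.numeric(pixels$count)
  if (is.null(weights)) weights <- rep(NA_real_, nrow(bins))
  stopifnot(length(weights) == nrow(bins))
  obj <- list(bins = bins,
              pixels = pixels[, c("bin1_id", "bin2_id", "count")],
              weights = weights,
              bin_size = bin_size_of(bins),
              total_valid_pairs = sum(pixels$count))
  class(obj) <- "ContactMatrix"
  obj
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf(
    "ContactMatrix: %d bins (%s bp), %d pixels, %s valid pairs, %s\n",
    nrow(x$bins), format(x$bin_size, big.mark = ","), nrow(x$pixels),
    format(x$total_valid_pairs, big.mark = ","),
    if (all(is.na(x$weights))) "unbalanced" else "balanced"))
  invisible(x)
}

#' Read a contact matrix from cooler-dump-compatible TSVs
#'
#' Expects a bin-table TSV (\code{chrom start end}) and a pixel TSV
#' (\code{bin1_id bin2_id count}) in the dialect written by
#' \command{cooler dump}: tab-separated, with or without a header line, pixel
#' ids 0-based row indices into the bin table. Internally ids are converted
#' to 1-based.
#'
#' @param pixels_path Path to the pixel TSV.
#' @param bins_path Path to the bin TSV.
#' @param resolution Optional coarser resolution (bp); when given and coarser
#'   than the file's bin size, counts are summed exactly into the coarser
#'   bins via [coarsen()].
#' @return A \code{ContactMatrix}.
#' @export
read_contact_matrix <- function(pixels_path, bins_path, resolution = NULL) {
  btab <- read_tsv_flex(bins_path, c("chrom", "start", "end"),
                        numeric_cols = c("start", "end"))
  sizes <- tapply(btab$end, btab$chrom, max)[unique(btab$chrom)]
  widths <- btab$end - btab$start
  bsize <- max(widths)
  bins <- bin_table(sizes, bsize)
  if (nrow(bins) != nrow(btab) || !all(bins$start == btab$start) ||
      !all(bins$chrom == btab$chrom))
    stop("bin table is not a uniform tiling at its modal bin size")
  ptab <- read_tsv_flex(pixels_path, c("bin1_id", "bin2_id", "count"),
                        numeric_cols = c("bin1_id", "bin2_id", "count"))
  if (nrow(ptab) > 0) {
    if (any(ptab$count < 0)) stop("negative counts in pixel file")
    if (any(ptab$bin1_id < 0 | ptab$bin2_id >= nrow(bins)))
      stop("pixel ids do not match the bin table")
    ptab$bin1_id <- as.integer(ptab$bin1_id) + 1L
    ptab$bin2_id <- as.integer(ptab$bin2_id) + 1L
  }
  m <- contact_matrix(bins, ptab)
  if (!is.null(resolution) && resolution > bsize) {
    if (resolution %% bsize != 0)
      stop("requested resolution is not a multiple of the file bin size")
    m <- coarsen(m, resolution)
  }
  m
}

# Tolerates an optional header line; enforces the expected column count.
read_tsv_flex <- function(path, col_names, numeric_cols) {
  first <- readLines(path, n = 1)
  has_header <- length(first) == 1 &&
    any(grepl(paste(col_names, collapse = "|"), first))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "#")
  if (ncol(df) < length(col_names))
    stop(sprintf("%s: expected %d columns (%s)", path, length(col_names),
                 paste(col_names, collapse = ", ")))
  df <- df[, seq_along(col_names), drop = FALSE]
  names(df) <- col_names
  for (cc in numeric_cols) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(df[[cc]])) stop(sprintf("%s: non-numeric values in %s", path, cc))
  }
  df
}

#' Write a contact matrix as cooler-dump-compatible TSVs
#'
#' @param mat A \code{ContactMatrix}.
#' @param pixels_path,bins_path Output paths. Pixel ids are written 0-based.
#' @param header Write header lines (default TRUE).
#' @export
write_contact_matrix <- function(mat, pixels_path, bins_path, header = TRUE) {
  stopifnot(inherits(mat, "ContactMatrix"))
  btab <- mat$bins[, c("chrom", "start", "end")]
  utils::write.table(btab, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  ptab <- mat$pixels
  ptab$bin1_id <- ptab$bin1_id - 1L
  ptab$bin2_id <- ptab$bin2_id - 1L
  utils::write.table(ptab, pixels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(mat)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Exact summation of counts: each coarse pixel is the sum of all fine pixels
#' whose (mirrored) coordinates fall in the coarse bin pair. Conserves
#' \code{total_valid_pairs} exactly. Balancing weights are dropped.
#'
#' @param mat A \code{ContactMatrix}.
#' @param new_bin_size Target bin size, a multiple of the current one.
#' @return A \code{ContactMatrix} at the coarser resolution.
#' @export
coarsen <- function(mat, new_bin_size) {
  stopifnot(inherits(mat, "ContactMatrix"))
  if (new_bin_size %% mat$bin_size != 0)
    stop("new_bin_size must be a multiple of the current bin size")
  sizes <- chrom_sizes_of(mat$bins)
  nb <- bin_table(sizes, new_bin_size)
  map <- bin_of(nb, mat$bins$chrom,
                mat$bins$start)  # fine-bin start lies inside its coarse bin
  px <- mat$pixels
  if (nrow(px) == 0) return(contact_matrix(nb, px))
  b1 <- map[px$bin1_id]
  b2 <- map[px$bin2_id]
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  agg <- rowsum(px$count, group = paste(lo, hi))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  out <- data.frame(bin1_id = as.integer(key[, 1]),
                    bin2_id = as.integer(key[, 2]),
                    count = as.numeric(agg[, 1]))
  contact_matrix(nb, out)
}

#' Pool replicate contact matrices
#'
#' Pixelwise sum of counts across matrices defined on identical bin tables;
#' \code{total_valid_pairs} is additive. Weights are dropped (re-balance the
#' pooled matrix).
#'
#' @param mats List of \code{ContactMatrix} objects.
#' @return A pooled \code{ContactMatrix}.
#' @export
pool <- function(mats) {
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, TRUE, "ContactMatrix")))
  bins <- mats[[1]]$bins
  for (m in mats[-1])
    if (!same_bins(bins, m$bins)) stop("bin tables differ between replicates")
  px <- do.call(rbind, lapply(mats, `[[`, "pixels"))
  if (nrow(px) == 0) return(contact_matrix(bins, px))
  agg <- rowsum(px$count, group = paste(px$bin1_id, px$bin2_id))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  out <- data.frame(bin1_id = as.integer(key[, 1]),
                    bin2_id = as.integer(key[, 2]),
                    count = as.numeric(agg[, 1]))
  contact_matrix(bins, out)
}

# Dense symmetric (optionally balanced) cis matrix for one chromosome.
# Filtered bins (NA weight) become NA rows/columns when balanced = TRUE.
dense_chrom <- function(mat, chrom, balanced = FALSE) {
  off <- chrom_offsets(mat$bins)
  row <- off[off$chrom == chrom, ]
  if (nrow(row) == 0) stop(sprintf("unknown chromosome '%s'", chrom))
  first <- row$first; n <- row$n
  sel <- mat$pixels$bin1_id >= first & mat$pixels$bin1_id < first + n &
    mat$pixels$bin2_id >= first & mat$pixels$bin2_id < first + n
  px <- mat$pixels[sel, , drop = FALSE]
  M <- matrix(0, n, n)
  if (nrow(px) > 0) {
    i <- px$bin1_id - first + 1L
    j <- px$bin2_id - first + 1L
    M[cbind(i, j)] <- px$count
    M[cbind(j, i)] <- px$count
  }
  if (balanced) {
    w <- mat$weights[first:(first + n - 1L)]
    M <- M * outer(w, w)
  }
  M
}
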