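#' Construct a table of HTGTS translocation junctions
#'
#' Each record is one bait-to-prey junction; bait-only reads (reads running
#' through the bait break without a translocation) are counted in the header
#' and used as the normalization denominator downstream.
#'
#' @param records data.frame with columns \code{prey_chrom}, \code{prey_pos}
#'   (0-based), \code{prey_strand}, \code{seq} (read sequence),
#'   \code{bait_end} (last read base aligned to bait, 1-based),
#'   \code{prey_start} (first read base aligned to prey, 1-based).
#' @param bait list(chrom, pos, strand) of the bait locus (pos 0-based).
#' @param bait_only_count Number of bait-only reads.
#' @return A \code{JunctionTable}; \code{total_events} = junctions +
#'   bait-only reads.
#' @export
junction_table <- function(records, bait, bait_only_count = 0) {
  records <- as.data.frame(records)
  need <- c("prey_chrom", "prey_pos", "prey_strand", "seq",
            "bait_end", "prey_start")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("junction records missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(is.list(bait), all(c("chrom", "pos") %in% names(bait)))
  if (nrow(records) > 0) {
    if (any(records$bait_end < 1 | records$bait_end > nchar(records$seq)))
      stop("bait_end outside read")
    if (any(records$prey_start < 1)) stop("prey_start before read start")
    if (any(records$prey_start > nchar(records$seq)))
      stop("prey_start after read end")
    records$intra <- records$prey_chrom == bait$chrom
  } else records$intra <- logical(0)
  obj <- list(records = records, bait = bait,
              bait_only_count = as.integer(bait_only_count),
              total_events = nrow(records) + as.integer(bait_only_count))
  class(obj) <- "JunctionTable"
  obj
}

#' @export
print.JunctionTable <- function(x, ...) {
  cat(sprintf(
    "JunctionTable: %d junctions + %d bait-only = %d events; bait %s:%s\n",
    nrow(x$records), x$bait_only_count, x$total_events,
    x$bait$chrom, format(x$bait$pos, big.mark = ",")))
  invisible(x)
}

#' Read a TLX-style junction TSV
#'
#' Accepts a minimal TLX dialect: a tab-separated file with header columns
#' \code{Qname Rname Junction Strand B_Qend Qstart Seq}, where \code{Rname}/
#' \code{Junction} give the prey locus (Junction 1-based, converted to
#' 0-based on ingest), \code{B_Qend} is the last read base aligned to the
#' bait and \code{Qstart} the first aligned to the prey (both 1-based on the
#' read). Rows with \code{Rname == "*"} are bait-only reads. The bait locus
#' is read from a comment line \code{#bait=chrom:pos:strand} when present,
#' else taken from the \code{bait} argument. Exact duplicate rows are
#' retained (deduplication is the upstream pipeline's job).
#'
#' @param path TLX-style TSV.
#' @param bait Optional list(chrom, pos, strand); overrides nothing if the
#'   file carries a \code{#bait=} line.
#' @param chrom_sizes Optional named vector; junction rows on chromosomes not
#'   in it are skipped, with the skip count in attribute \code{n_skipped}
#'   and a warning.
#' @return A \code{JunctionTable}.
#' @export
read_junctions <- function(path, bait = NULL, chrom_sizes = NULL) {
  lines <- readLines(path)
  bline <- grep("^#bait=", lines, value = TRUE)
  if (length(bline) > 0) {
    f <- strsplit(sub("^#bait=", "", bline[1]), ":")[[1]]
    bait <- list(chrom = f[1], pos = as.numeric(f[2]),
                 strand = if (length(f) >= 3) f[3] else "+")
  }
  if (is.null(bait)) stop("bait locus not given and no #bait= header line")
  lines <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("Qname", "Rname", "Junction", "Strand", "B_Qend", "Qstart", "Seq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("TLX file missing column(s): ", paste(miss, collapse = ", "))
  is_bait_only <- df$Rname == "*" | is.na(df$Junction)
  jx <- df[!is_bait_only, , drop = FALSE]
  n_skipped <- 0L
  if (!is.null(chrom_sizes) && nrow(jx) > 0) {
    keep <- jx$Rname %in% names(chrom_sizes)
    n_skipped <- sum(!keep)
    if (n_skipped > 0)
      warning(sprintf("%d junction(s) on unknown chromosomes skipped",
                      n_skipped))
    jx <- jx[keep, , drop = FALSE]
  }
  records <- data.frame(prey_chrom = jx$Rname,
                        prey_pos = as.numeric(jx$Junction) - 1,
                        prey_strand = as.character(jx$Strand),
                        seq = as.character(jx$Seq),
                        bait_end = as.integer(jx$B_Qend),
                        prey_start = as.integer(jx$Qstart),
                        stringsAsFactors = FALSE)
  out <- junction_table(records, bait, bait_only_count = sum(is_bait_only))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a junction table in the minimal TLX dialect
#' @param jt A \code{JunctionTable}.
#' @param path Output path.
#' @export
write_junctions <- function(jt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bait=%s:%s:%s", jt$bait$chrom, jt$bait$pos,
                     if (is.null(jt$bait$strand)) "+" else jt$bait$strand), con)
  r <- jt$records
  df <- data.frame(Qname = sprintf("J%06d", seq_len(nrow(r))),
                   Rname = r$prey_chrom, Junction = r$prey_pos + 1,
                   Strand = r$prey_strand, B_Qend = r$bait_end,
                   Qstart = r$prey_start, Seq = r$seq)
  if (jt$bait_only_count > 0) {
    df <- rbind(df, data.frame(
      Qname = sprintf("B%06d", seq_len(jt$bait_only_count)),
      Rname = "*", Junction = NA, Strand = "*", B_Qend = NA, Qstart = NA,
      Seq = "*"))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jt)
}
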