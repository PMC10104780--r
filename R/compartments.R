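#' A/B compartment eigenvector phased by gene density
#'
#' Per chromosome, takes the leading eigenvector (largest eigenvalue) of the
#' centered O/E matrix (O/E - 1) with filtered rows/columns removed and
#' re-inserted as NA, scales it by the square root of its eigenvalue, and
#' flips its sign so the correlation with gene density is non-negative.
#' Bins with EV1 > 0 are labelled A, EV1 < 0 labelled B; missing (or exactly
#' zero) bins are unassigned.
#'
#' @param oe An \code{OEMatrix} from [observed_over_expected()] (conventionally
#'   at 250-kb bins).
#' @param gene_density A \code{ScalarTrack} on the same bins used for phasing.
#' @param min_valid_bins Chromosomes with fewer valid bins get an all-NA EV1
#'   (with a warning); default 10.
#' @return A \code{CompartmentResult}: list with \code{ev1} (ScalarTrack),
#'   \code{labels} (character vector "A"/"B"/"unassigned" per bin) and
#'   \code{phasing_correlation} (named per-chromosome).
#' @export
compartment_eigenvector <- function(oe, gene_density, min_valid_bins = 10) {
  stopifnot(inherits(oe, "OEMatrix"), inherits(gene_density, "ScalarTrack"))
  if (!same_bins(oe$bins, gene_density$bins))
    stop("gene density track is on a different bin table")
  off <- chrom_offsets(oe$bins)
  ev <- rep(NA_real_, nrow(oe$bins))
  phasing <- stats::setNames(rep(NA_real_, nrow(off)), off$chrom)
  for (k in seq_len(nrow(off))) {
    ch <- off$chrom[k]; first <- off$first[k]; n <- off$n[k]
    M <- oe$chroms[[ch]]
    valid <- which(rowSums(is.finite(M)) > 0)
    if (length(valid) < min_valid_bins) {
      warning(sprintf("chromosome %s: only %d valid bins; EV1 left missing",
                      ch, length(valid)))
      next
    }
    E <- M[valid, valid, drop = FALSE] - 1
    E[!is.finite(E)] <- 0
    eg <- eigen(E, symmetric = TRUE)
    v <- eg$vectors[, 1]
    lam <- eg$values[1]
    v <- v * sqrt(max(lam, 0))
    gd <- gene_density$values[first:(first + n - 1L)][valid]
    if (stats::sd(v) > 0 && sum(is.finite(gd)) > 2 &&
        stats::sd(gd, na.rm = TRUE) > 0) {
      r <- stats::cor(v, gd, use = "complete.obs")
      if (is.finite(r)) {
        if (r < 0) { v <- -v; r <- -r }
        if (r == 0) warning(sprintf(
          "chromosome %s: zero correlation with gene density; sign kept", ch))
        phasing[ch] <- r
      }
    }
    ev[first + valid - 1L] <- v
  }
  labels <- rep("unassigned", length(ev))
  labels[!is.na(ev) & ev > 0] <- "A"
  labels[!is.na(ev) & ev < 0] <- "B"
  obj <- list(ev1 = scalar_track(oe$bins, ev, "EV1"), labels = labels,
              phasing_correlation = phasing)
  class(obj) <- "CompartmentResult"
  obj
}

#' @export
print.CompartmentResult <- function(x, ...) {
  cat(sprintf("CompartmentResult: %d bins (A %d / B %d / unassigned %d)\n",
              length(x$labels), sum(x$labels == "A"), sum(x$labels == "B"),
              sum(x$labels == "unassigned")))
  invisible(x)
}

#' Detect compartment flips between two conditions
#'
#' Classifies every bin by its compartment transition between condition 1 and
#' condition 2 (A->A, A->B, B->A, B->B) and flags transitions that are
#' replicate-consistent: the same transition in every pairing of a
#' condition-1 replicate with a condition-2 replicate. Headline fractions are
#' computed over consistently-assigned bins only, using the pooled-condition
#' labels when pooled results are supplied and the first replicates
#' otherwise.
#'
#' @param cond1_reps,cond2_reps Lists of \code{CompartmentResult}, one per
#'   replicate, on identical bins.
#' @param pooled1,pooled2 Optional \code{CompartmentResult} of the pooled
#'   libraries, used for the headline transition labels.
#' @return A \code{FlipTable}: list with per-bin \code{transition}
#'   (character, NA where either condition is unassigned),
#'   \code{consistent} (logical), and \code{fractions} over
#'   \{A->A, A->B, B->A, B->B\} (summing to 1 over consistent assigned bins).
#' @export
detect_flips <- function(cond1_reps, cond2_reps,
                         pooled1 = NULL, pooled2 = NULL) {
  stopifnot(length(cond1_reps) >= 1, length(cond2_reps) >= 1)
  bins <- cond1_reps[[1]]$ev1$bins
  all_res <- c(cond1_reps, cond2_reps, Filter(Negate(is.null),
                                              list(pooled1, pooled2)))
  for (r in all_res)
    if (!same_bins(bins, r$ev1$bins)) stop("bin tables differ between inputs")
  lab1 <- if (is.null(pooled1)) cond1_reps[[1]]$labels else pooled1$labels
  lab2 <- if (is.null(pooled2)) cond2_reps[[1]]$labels else pooled2$labels
  assigned <- lab1 %in% c("A", "B") & lab2 %in% c("A", "B")
  transition <- rep(NA_character_, nrow(bins))
  transition[assigned] <- paste0(lab1[assigned], "->", lab2[assigned])
  consistent <- rep(TRUE, nrow(bins))
  for (r1 in cond1_reps) for (r2 in cond2_reps) {
    ok <- r1$labels %in% c("A", "B") & r2$labels %in% c("A", "B")
    tr <- rep(NA_character_, nrow(bins))
    tr[ok] <- paste0(r1$labels[ok], "->", r2$labels[ok])
    consistent <- consistent & !is.na(tr) & (is.na(transition) | tr == transition)
  }
  use <- assigned & consistent
  classes <- c("A->A", "A->B", "B->A", "B->B")
  fr <- vapply(classes, function(cl) mean(transition[use] == cl), 0)
  obj <- list(bins = bins, transition = transition, consistent = consistent,
              fractions = fr, n_consistent_assigned = sum(use))
  class(obj) <- "FlipTable"
  obj
}

#' @export
print.FlipTable <- function(x, ...) {
  cat("FlipTable fractions over consistent assigned bins:\n")
  print(round(x$fractions, 4))
  invisible(x)
}
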