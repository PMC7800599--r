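# Colocalization of peak sets: the ">= 10 bp shared bases" overlap relation,
# asymmetric overlap fractions, and Euler-Venn membership counts.

.as_intervals <- function(x) {
  if (is(x, "GRanges")) return(granges(x, use.mcols = FALSE))
  stopf("peak sets must be GRanges")
}

#' Which reference peaks overlap a query set
#'
#' A reference peak overlaps the query set when some query interval on the
#' same chromosome shares at least `min_overlap` bases with it. The 10 bp
#' default is the standard rule for calling two factors' sites colocalized.
#'
#' @param reference,query `GRanges` of peak intervals.
#' @param min_overlap Minimum shared bases (default 10).
#' @return Logical vector over `reference`.
#' @export
peaks_overlapping <- function(reference, query, min_overlap = 10) {
  reference <- .as_intervals(reference)
  query <- .as_intervals(query)
  countOverlaps(reference, query, minoverlap = min_overlap, ignore.strand = TRUE) > 0
}

#' Fraction of reference peaks overlapped by a query set
#'
#' Note the statistic is asymmetric: `overlap_fraction(A, B)` need not equal
#' `overlap_fraction(B, A)`; pipelines report both directions.
#'
#' @inheritParams peaks_overlapping
#' @return A number in `[0, 1]`.
#' @export
overlap_fraction <- function(reference, query, min_overlap = 10) {
  if (length(reference) == 0) stopf("reference peak set is empty")
  mean(peaks_overlapping(reference, query, min_overlap))
}

#' Euler-Venn membership counts of two or three peak sets
#'
#' Classifies each peak of each set by which other sets it overlaps (at least
#' `min_overlap` shared bases). Counts are peak counts, not merged-interval
#' counts: peak sets of different factors cannot be partitioned into shared
#' physical regions without a merging rule, so every Venn region that
#' involves a given set is counted over that set's own peaks. Regions
#' involving the reference set (the first argument) therefore sum exactly to
#' the reference set's size; regions not involving it (e.g. "B only") are the
#' analogous membership counts with that set as its own reference.
#'
#' @param setA Reference peak set (`GRanges`).
#' @param setB,setC Query peak sets (`setC` optional).
#' @param min_overlap Minimum shared bases (default 10).
#' @param names Character vector naming the sets (default A, B, C).
#' @return An object of class `overlap_result` with elements `counts` (named
#'   integer vector over the Venn regions), `membership` (logical matrix over
#'   reference peaks), `fractions` (asymmetric pairwise overlap fractions),
#'   `sizes` and `min_overlap`.
#' @export
venn_counts <- function(setA, setB, setC = NULL, min_overlap = 10,
                        names = c("A", "B", "C")) {
  three <- !is.null(setC)
  sets <- if (three) list(setA, setB, setC) else list(setA, setB)
  nm <- names[seq_along(sets)]
  ov <- function(r, q) peaks_overlapping(r, q, min_overlap)

  # pairwise fractions, both directions
  fr <- list()
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i != j)
    fr[[sprintf("%s_in_%s", nm[i], nm[j])]] <-
      if (length(sets[[i]])) mean(ov(sets[[i]], sets[[j]])) else NA_real_

  if (!three) {
    inB <- ov(setA, setB)
    inA <- ov(setB, setA)
    counts <- c(sum(!inB), sum(!inA), sum(inB))
    names(counts) <- c(sprintf("%s_only", nm[1]), sprintf("%s_only", nm[2]),
                       sprintf("%s_and_%s", nm[1], nm[2]))
    membership <- cbind(inB)
    colnames(membership) <- nm[2]
  } else {
    aB <- ov(setA, setB); aC <- ov(setA, setC)
    bA <- ov(setB, setA); bC <- ov(setB, setC)
    cA <- ov(setC, setA); cB <- ov(setC, setB)
    counts <- c(sum(!aB & !aC),            # A only
                sum(!bA & !bC),            # B only
                sum(!cA & !cB),            # C only
                sum(aB & !aC),             # A&B (from A)
                sum(aC & !aB),             # A&C (from A)
                sum(bC & !bA),             # B&C (from B)
                sum(aB & aC))              # A&B&C (from A)
    names(counts) <- c(sprintf("%s_only", nm),
                       sprintf("%s_and_%s", nm[1], nm[2]),
                       sprintf("%s_and_%s", nm[1], nm[3]),
                       sprintf("%s_and_%s", nm[2], nm[3]),
                       paste(nm, collapse = "_and_"))
    membership <- cbind(aB, aC)
    colnames(membership) <- nm[2:3]
  }
  structure(list(counts = counts, membership = membership,
                 fractions = unlist(fr),
                 sizes = stats::setNames(lengths(sets), nm),
                 reference = nm[1], min_overlap = min_overlap),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Peak-set overlap (>= %d bp rule), reference set '%s'\n",
              x$min_overlap, x$reference))
  cat("Set sizes: ", paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  cat("Venn region counts (per-peak membership):\n")
  print(x$counts)
  cat("Pairwise overlap fractions (row set overlapped by column set):\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Result table for an overlap analysis
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return A data.frame of Venn region counts and fractions.
#' @method as.data.frame overlap_result
#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(region = names(x$counts), count = as.integer(x$counts),
             stringsAsFactors = FALSE)
}
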