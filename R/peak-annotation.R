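# Peak annotation: turn peak calls into +/-100 bp peak regions, assign each
# region to one genome category by the fixed priority with a minimum-overlap
# rule, and summarize the category distribution.

#' Anchor position of peaks
#'
#' The anchor is the reported summit when a summit offset is present,
#' otherwise the floor of the interval midpoint (a deterministic, dialect
#' independent tie-break).
#'
#' @param peaks `GRanges` of peak records (optionally with a `summit` column,
#'   0-based offset from peak start).
#' @return Integer vector of 1-based anchor positions.
#' @export
peak_anchor <- function(peaks) {
  mid <- start(peaks) + width(peaks) %/% 2L
  if (!is.null(peaks$summit)) {
    s <- peaks$summit
    mid <- ifelse(!is.na(s), start(peaks) + as.integer(s), mid)
  }
  as.integer(mid)
}

#' Peak region around an anchor
#'
#' The peak region is the +/-`flank` bp window around the anchor (default
#' 100 bp each side, a 201 bp region away from chromosome edges), clipped to
#' the chromosome.
#'
#' @param chrom Chromosome names.
#' @param anchor 1-based anchor positions.
#' @param sizes Named chromosome lengths.
#' @param flank Flank size in bp.
#' @return A `GRanges` of clipped regions, with an `anchor` metadata column.
#' @export
peak_region <- function(chrom, anchor, sizes, flank = 100) {
  sizes <- chrom_sizes(sizes)
  chrom <- as.character(chrom)
  if (!all(chrom %in% names(sizes)))
    stopf("unknown chromosome(s): %s", paste(unique(setdiff(chrom, names(sizes))), collapse = ", "))
  L <- sizes[chrom]
  if (any(anchor < 1 | anchor > L)) stopf("anchor outside chromosome bounds")
  gr <- GRanges(chrom, IRanges(pmax(anchor - flank, 1), pmin(anchor + flank, L)),
                seqinfo = .seqinfo_from_sizes(sizes))
  mcols(gr)$anchor <- as.integer(anchor)
  gr
}

# Overlap base counts of each region with each partition category.
# Returns an n x 4 matrix (columns in priority order).
.category_overlaps <- function(regions, partition) {
  ov <- findOverlaps(regions, partition, ignore.strand = TRUE)
  w <- width(pintersect(regions[queryHits(ov)], partition[subjectHits(ov)]))
  cat <- as.integer(partition$category[subjectHits(ov)])
  m <- matrix(0L, nrow = length(regions), ncol = length(CATEGORIES),
              dimnames = list(NULL, CATEGORIES))
  if (length(ov)) {
    # accumulate (a region can hit several intervals of one category)
    key <- (queryHits(ov) - 1L) * 4L + cat
    acc <- rowsum(as.numeric(w), key)
    k <- as.integer(rownames(acc))
    m[cbind((k - 1L) %/% 4L + 1L, (k - 1L) %% 4L + 1L)] <- acc[, 1]
  }
  m
}

.assign_category <- function(ovm, min_overlap) {
  cat <- rep("INTERGENIC", nrow(ovm))
  for (cc in rev(c("TSS", "TES", "GENE_BODY")))  # apply lowest priority first
    cat[ovm[, cc] >= min_overlap] <- cc
  factor(cat, levels = CATEGORIES)
}

#' Annotate one peak region
#'
#' Computes the overlap in bases between a region and each partition category
#' and assigns the highest-priority gene-linked category (TSS, then TES, then
#' GENE_BODY) whose total overlap reaches `min_overlap` bases; a region
#' reaching the threshold in none of them is INTERGENIC.
#'
#' @param region A length-1 `GRanges`.
#' @param partition Partition from [build_partition()].
#' @param min_overlap Minimum overlap in bp (default 10).
#' @return A list with elements `category` (factor) and `overlap_bp` (named
#'   integer vector over the four categories).
#' @export
annotate_peak <- function(region, partition, min_overlap = 10) {
  if (length(region) != 1) stopf("annotate_peak takes a single region; see annotate_peaks")
  if (!as.character(seqnames(region)) %in% seqlevels(partition))
    stopf("region chromosome %s not in partition", as.character(seqnames(region)))
  ovm <- .category_overlaps(region, partition)
  list(category = .assign_category(ovm, min_overlap)[1],
       overlap_bp = stats::setNames(as.integer(ovm[1, ]), CATEGORIES))
}

#' Annotate a set of peaks
#'
#' Batch form of [annotate_peak()]: derives each peak's anchor and
#' +/-`flank` bp region, then assigns categories. Input order is preserved.
#'
#' @param peaks `GRanges` of peak records (see [read_bed()]).
#' @param partition Partition from [build_partition()].
#' @param sizes Named chromosome lengths.
#' @param flank Region flank in bp (default 100).
#' @param min_overlap Minimum overlap in bp (default 10).
#' @return A `GRanges` of peak regions with metadata columns `name`, `anchor`,
#'   `category` and per-category overlap bases (`tss_bp`, `tes_bp`,
#'   `gene_body_bp`, `intergenic_bp`); parameters are stored in
#'   `S4Vectors::metadata()`.
#' @export
annotate_peaks <- function(peaks, partition, sizes, flank = 100, min_overlap = 10) {
  sizes <- chrom_sizes(sizes)
  chrom <- as.character(seqnames(peaks))
  unknown <- !(chrom %in% names(sizes))
  if (any(unknown)) {
    who <- if (!is.null(peaks$name)) peaks$name[unknown][1] else sprintf("peak %d", which(unknown)[1])
    stopf("peak '%s' on unknown chromosome %s", who, chrom[unknown][1])
  }
  anchors <- peak_anchor(peaks)
  regions <- peak_region(chrom, anchors, sizes, flank)
  ovm <- .category_overlaps(regions, partition)
  mcols(regions) <- DataFrame(
    name = if (!is.null(peaks$name)) peaks$name else sprintf("peak_%d", seq_along(peaks)),
    anchor = anchors,
    category = .assign_category(ovm, min_overlap),
    tss_bp = ovm[, "TSS"], tes_bp = ovm[, "TES"],
    gene_body_bp = ovm[, "GENE_BODY"], intergenic_bp = ovm[, "INTERGENIC"])
  metadata(regions) <- c(metadata(partition),
                         list(flank = flank, min_overlap = min_overlap))
  regions
}

#' Category distribution of annotated peaks
#'
#' @param annotated Output of [annotate_peaks()], or a factor/character vector
#'   of categories.
#' @return An object of class `category_distribution`: a data.frame with
#'   columns `category`, `count`, `percentage`, carrying the annotation
#'   parameters as attributes.
#' @export
category_distribution <- function(annotated) {
  params <- list()
  if (is(annotated, "GRanges")) {
    params <- metadata(annotated)
    annotated <- annotated$category
  }
  cats <- factor(as.character(annotated), levels = CATEGORIES)
  if (length(cats) == 0) stopf("cannot summarize an empty peak set")
  counts <- as.vector(table(cats))
  df <- data.frame(category = CATEGORIES, count = counts,
                   percentage = 100 * counts / sum(counts))
  structure(df, class = c("category_distribution", "data.frame"),
            total = sum(counts), params = params)
}

#' @export
print.category_distribution <- function(x, ...) {
  cat(sprintf("Peak category distribution (%d peaks):\n", attr(x, "total")))
  df <- as.data.frame(x)
  df$percentage <- sprintf("%.1f%%", df$percentage)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.category_distribution <- function(x, main = "Peak category distribution", ...) {
  barplot(x$percentage, names.arg = x$category, ylab = "% of peaks", main = main, ...)
  invisible(x)
}
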