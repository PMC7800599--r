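# Genome model: chromosome sizes, gene models, the four-way genome partition
# (TSS / TES / GENE_BODY / INTERGENIC) and the two random control-site
# samplers used for meta-profile backgrounds.

#' Read a chrom.sizes file
#'
#' Reads the standard two-column whitespace-separated chromosome sizes dialect
#' (name, length in bp).
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("chrom.sizes file must have two columns (name, length)")
  chrom_sizes(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

#' Validate a chromosome-sizes vector
#'
#' @param sizes Named numeric vector: chromosome name -> length in bp.
#' @return The validated vector (lengths coerced to whole numbers).
#' @export
chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || any(names(sizes) == "") || anyDuplicated(names(sizes)))
    stopf("chromosome names must be unique and non-empty")
  if (any(is.na(sizes)) || any(sizes < 1) || any(sizes != floor(sizes)))
    stopf("chromosome lengths must be positive integers")
  stats::setNames(as.numeric(sizes), names(sizes))
}

#' Write a chrom.sizes file
#'
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  sizes <- chrom_sizes(sizes)
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

.seqinfo_from_sizes <- function(sizes) {
  Seqinfo(seqnames = names(sizes), seqlengths = as.integer(sizes))
}

#' Construct gene models
#'
#' Builds a `GRanges` of gene records (1-based closed coordinates, the
#' Bioconductor convention) with a `gene_id` metadata column.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 1-based closed start/end coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param gene_id Unique gene identifiers.
#' @return A `GRanges` with a `gene_id` column.
#' @export
gene_models <- function(chrom, start, end, strand, gene_id) {
  if (anyDuplicated(gene_id)) stopf("gene_id values must be unique")
  if (any(start > end)) stopf("gene start must not exceed end")
  if (!all(strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$gene_id <- as.character(gene_id)
  gr
}

#' Read gene models from GFF3 or GTF
#'
#' Imports an annotation file and keeps records of one feature type
#' (`"gene"` by default); other feature types are ignored with a message
#' reporting how many were dropped.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param feature_type Feature type to keep (column 3).
#' @return A `GRanges` with a `gene_id` column.
#' @export
read_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) {
    drop <- sum(as.character(gr$type) != feature_type)
    if (drop > 0) message(sprintf("read_genes: ignored %d non-'%s' feature records", drop, feature_type))
    gr <- gr[as.character(gr$type) == feature_type]
  }
  id <- gr$gene_id %||% gr$ID %||% gr$Name
  if (is.null(id)) stopf("no gene_id/ID/Name attribute found in %s", path)
  strand(gr)[strand(gr) == "*"] <- "+"
  gene_models(as.character(seqnames(gr)), start(gr), end(gr),
              as.character(strand(gr)), as.character(id))
}

#' Write gene models as GFF3
#'
#' @param genes `GRanges` from [gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(source = "promoterscope", type = "gene", ID = genes$gene_id,
                          gene_id = genes$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

.check_genes <- function(genes, sizes) {
  chr <- as.character(seqnames(genes))
  unknown <- !(chr %in% names(sizes))
  if (any(unknown))
    stopf("gene(s) on unknown chromosome: %s",
          paste(genes$gene_id[unknown], collapse = ", "))
  L <- sizes[chr]
  bad <- start(genes) < 1 | end(genes) > L
  if (any(bad))
    stopf("gene(s) outside chromosome bounds: %s",
          paste(genes$gene_id[bad], collapse = ", "))
  invisible(TRUE)
}

# Window around a 0-based boundary coordinate, oriented by strand:
# on '+' the window covers [b - up, b + down); on '-' it covers
# [b - down, b + up). Returned as 1-based closed GRanges, clipped to the
# chromosome; empty windows are dropped.
.boundary_windows <- function(chrom, b0, plus, up, down, sizes) {
  lo0 <- ifelse(plus, b0 - up, b0 - down)
  hi0 <- ifelse(plus, b0 + down, b0 + up)
  lo0 <- pmax(lo0, 0)
  hi0 <- pmin(hi0, sizes[chrom])
  keep <- hi0 > lo0
  GRanges(chrom[keep], IRanges(lo0[keep] + 1, hi0[keep]))
}

#' Partition a genome into TSS, TES, gene-body and intergenic regions
#'
#' Divides every base of the genome into exactly one of four categories:
#' `TSS` (a window around the strand-aware transcription start), `TES` (a
#' window around the strand-aware transcription end), `GENE_BODY` (the gene
#' span outside its TSS/TES windows) and `INTERGENIC` (everything else).
#' Where windows of different genes (or the TSS and TES of one short gene)
#' overlap, each base takes the highest-priority category under the fixed
#' order TSS > TES > GENE_BODY > INTERGENIC.
#'
#' @param genes `GRanges` of gene models (see [gene_models()]).
#' @param sizes Named chromosome lengths, as from [chrom_sizes()].
#' @param tss_window,tes_window Length-2 non-negative `(upstream, downstream)`
#'   window sizes in bp, applied strand-aware around the gene start/end
#'   boundary. Default 200 bp each side.
#' @return A sorted, disjoint `GRanges` tiling the genome exactly, with a
#'   `category` metadata column; the windows used are stored in
#'   `S4Vectors::metadata()`.
#' @examples
#' sizes <- c(chrA = 3000)
#' g <- gene_models("chrA", 1001, 2000, "+", "g1")
#' part <- build_partition(g, sizes, c(100, 100), c(100, 100))
#' genome_category_fractions(part)
#' @export
build_partition <- function(genes, sizes, tss_window = c(200, 200), tes_window = c(200, 200)) {
  sizes <- chrom_sizes(sizes)
  if (length(tss_window) != 2 || length(tes_window) != 2 ||
      any(c(tss_window, tes_window) < 0))
    stopf("tss_window and tes_window must be length-2 non-negative (upstream, downstream)")
  si <- .seqinfo_from_sizes(sizes)
  genome_gr <- GRanges(names(sizes), IRanges(1, as.integer(sizes)), seqinfo = si)

  if (length(genes) == 0) {
    part <- genome_gr
    mcols(part)$category <- factor(rep("INTERGENIC", length(part)), levels = CATEGORIES)
  } else {
    .check_genes(genes, sizes)
    chr <- as.character(seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    s0 <- start(genes) - 1   # 0-based start boundary
    e0 <- end(genes)         # 0-based end boundary (one past last base)
    tss_b0 <- ifelse(plus, s0, e0)
    tes_b0 <- ifelse(plus, e0, s0)

    fix <- function(gr) { seqlevels(gr) <- seqlevels(si); seqinfo(gr) <- si; gr }
    tss <- fix(reduce(.boundary_windows(chr, tss_b0, plus, tss_window[1], tss_window[2], sizes)))
    tes <- fix(reduce(.boundary_windows(chr, tes_b0, plus, tes_window[1], tes_window[2], sizes)))
    body <- fix(reduce(GRanges(chr, ranges(genes))))
    tes <- setdiff(tes, tss)
    body <- setdiff(body, union(tss, tes))
    inter <- setdiff(genome_gr, reduce(c(tss, tes, body)))

    cat_of <- function(gr, cat) {
      mcols(gr)$category <- factor(rep(cat, length(gr)), levels = CATEGORIES)
      gr
    }
    part <- c(cat_of(tss, "TSS"), cat_of(tes, "TES"),
              cat_of(body, "GENE_BODY"), cat_of(inter, "INTERGENIC"))
    part <- sort(part, ignore.strand = TRUE)
  }
  metadata(part) <- list(tss_window = tss_window, tes_window = tes_window)
  part
}

#' Fraction of genome bases in each category
#'
#' @param partition A partition from [build_partition()].
#' @return Named numeric vector over the four categories, summing to 1.
#' @export
genome_category_fractions <- function(partition) {
  genome <- sum(as.numeric(seqlengths(partition)))
  bp <- tapply(as.numeric(width(partition)), partition$category, sum, default = 0)
  stats::setNames(as.vector(bp[CATEGORIES]) / genome, CATEGORIES)
}

#' Write a genome partition as BED4
#'
#' Writes (chrom, start, end, category) lines, 0-based half-open, preceded by
#' comment lines recording the windows used.
#'
#' @param partition A partition from [build_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- metadata(partition)
  writeLines(sprintf("# tss_window=%s tes_window=%s",
                     paste(md$tss_window, collapse = ","),
                     paste(md$tes_window, collapse = ",")), con)
  writeLines(sprintf("%s\t%d\t%d\t%s", as.character(seqnames(partition)),
                     start(partition) - 1L, end(partition),
                     as.character(partition$category)), con)
  invisible(path)
}

#' Construct a site set
#'
#' A site set is a named collection of single-base genomic anchors (1-based
#' positions), the unit around which peak regions and meta-profile windows are
#' built.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based anchor positions.
#' @param name Name of the set.
#' @param flank Optional flank (bp) associated with the set's derived regions.
#' @param ... Additional per-site metadata columns (e.g. `gene_id`, `category`).
#' @return A data.frame of class `site_set` with columns `chrom`, `pos`, and
#'   any metadata; attributes `set_name` and `flank`.
#' @export
site_set <- function(chrom, pos, name, flank = NULL, ...) {
  if (!nzchar(name)) stopf("site set name must be non-empty")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos), ...,
                   stringsAsFactors = FALSE)
  structure(df, class = c("site_set", "data.frame"), set_name = name, flank = flank)
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set '%s': %d sites on %d chromosome(s)\n",
              attr(x, "set_name") %||% "?", nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Strand-aware TSS anchor positions of genes
#'
#' @param genes `GRanges` of gene models.
#' @return Integer vector of 1-based TSS positions (gene start on `+`, gene
#'   end on `-`).
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Sample random promoters
#'
#' Draws `n` distinct gene TSS anchor positions uniformly without replacement,
#' the promoter control set for meta-profiles.
#'
#' @param genes `GRanges` of gene models.
#' @param n Number of promoters to draw.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A [site_set()] named `"random_promoters"` with a `gene_id` column.
#' @export
sample_random_promoters <- function(genes, n, seed) {
  n <- check_count(n)
  pos <- gene_tss(genes)
  chr <- as.character(seqnames(genes))
  keep <- !duplicated(paste(chr, pos))
  chr <- chr[keep]; pos <- pos[keep]; ids <- genes$gene_id[keep]
  if (n > length(pos))
    stopf("requested %d promoters but only %d distinct promoters available", n, length(pos))
  idx <- with_seed(seed, sample.int(length(pos), n))
  site_set(chr[idx], pos[idx], "random_promoters", gene_id = ids[idx])
}

#' Sample random genomic sites
#'
#' Draws `n` anchor positions uniformly over the genome: a chromosome is
#' chosen with probability proportional to its usable length, then a position
#' uniform over it. Every anchor is at least `margin` bp from both chromosome
#' ends; chromosomes shorter than `2 * margin` are excluded.
#'
#' @param sizes Named chromosome lengths.
#' @param n Number of sites.
#' @param seed Integer seed.
#' @param margin Minimum distance (bp) from chromosome ends; defaults to
#'   100 bp, the default peak-region flank, so derived regions never run off
#'   a chromosome.
#' @return A [site_set()] named `"random_sites"`.
#' @export
sample_random_sites <- function(sizes, n, seed, margin = 100) {
  sizes <- chrom_sizes(sizes)
  n <- check_count(n)
  usable <- sizes - 2 * margin
  usable <- usable[usable >= 1]
  if (length(usable) == 0)
    stopf("no chromosome can host sites with margin %d", margin)
  with_seed(seed, {
    chr <- sample(names(usable), n, replace = TRUE, prob = usable)
    pos <- floor(runif(n) * usable[chr]) + margin + 1
  })
  site_set(chr, as.integer(pos), "random_sites")
}
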