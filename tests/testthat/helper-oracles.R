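# Independent brute-force oracles and random-instance generators used across
# the suite. The oracles work per base on plain vectors and never touch the
# package's interval machinery.

suppressPackageStartupMessages(library(GenomicRanges))

CATS <- c("TSS", "TES", "GENE_BODY", "INTERGENIC")

# Per-base category labels of one chromosome, by brute force: walk every gene,
# mark its windows base by base, and resolve each base to the highest-priority
# category among all genes covering it. Coordinates in `genes` are 1-based
# closed; returns an integer vector of length L (1=TSS .. 4=INTERGENIC).
oracle_labels <- function(genes, L, tss_w = c(200, 200), tes_w = c(200, 200)) {
  lab <- rep(4L, L)
  mark <- function(lo0, hi0, code) {
    lo0 <- max(lo0, 0); hi0 <- min(hi0, L)
    if (hi0 > lo0) {
      idx <- (lo0 + 1):hi0
      lab[idx] <<- pmin(lab[idx], code)
    }
  }
  for (i in seq_len(nrow(genes))) {
    s0 <- genes$start[i] - 1; e0 <- genes$end[i]
    plus <- genes$strand[i] == "+"
    mark(s0, e0, 3L)  # gene body (lowest gene-linked priority)
  }
  for (i in seq_len(nrow(genes))) {
    s0 <- genes$start[i] - 1; e0 <- genes$end[i]
    plus <- genes$strand[i] == "+"
    tes_b <- if (plus) e0 else s0
    if (plus) mark(tes_b - tes_w[1], tes_b + tes_w[2], 2L)
    else mark(tes_b - tes_w[2], tes_b + tes_w[1], 2L)
  }
  for (i in seq_len(nrow(genes))) {
    s0 <- genes$start[i] - 1; e0 <- genes$end[i]
    plus <- genes$strand[i] == "+"
    tss_b <- if (plus) s0 else e0
    if (plus) mark(tss_b - tss_w[1], tss_b + tss_w[2], 1L)
    else mark(tss_b - tss_w[2], tss_b + tss_w[1], 1L)
  }
  lab
}

# Annotate one 1-based closed region against a per-base label vector with the
# minimum-overlap threshold and the fixed priority.
oracle_annotate <- function(labels, start1, end1, min_overlap = 10) {
  counts <- tabulate(labels[start1:end1], nbins = 4)
  for (k in 1:3) if (counts[k] >= min_overlap) return(CATS[k])
  "INTERGENIC"
}

# All-pairs overlap flags: reference interval i is flagged when some query
# interval on the same chromosome shares >= k bases with it.
oracle_overlap_flags <- function(ref, qry, k = 10) {
  vapply(seq_len(nrow(ref)), function(i) {
    same <- qry$chrom == ref$chrom[i]
    if (!any(same)) return(FALSE)
    ov <- pmin(qry$end[same], ref$end[i]) - pmax(qry$start[same], ref$start[i]) + 1
    any(ov >= k)
  }, TRUE)
}

# Random non-degenerate gene table on one chromosome.
random_genes <- function(n, L, min_len = 50, max_len = 2000) {
  s <- sample.int(L - max_len - 1, n)
  len <- sample(min_len:max_len, n, replace = TRUE)
  data.frame(chrom = "chrZ", start = s, end = pmin(s + len, L),
             strand = sample(c("+", "-"), n, replace = TRUE),
             gene_id = sprintf("g%04d", seq_len(n)), stringsAsFactors = FALSE)
}

genes_gr <- function(df) gene_models(df$chrom, df$start, df$end, df$strand, df$gene_id)

# Random interval table (1-based closed) for overlap tests; widths are at
# least 10 bp, like real peak calls, so a set always overlaps itself under
# the >= 10 bp rule.
random_intervals <- function(n, L, chroms = c("c1", "c2"), max_len = 400) {
  s <- sample.int(L - max_len - 10, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = s,
             end = s + 9L + sample.int(max_len, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

intervals_gr <- function(df) GRanges(df$chrom, IRanges(df$start, df$end))

# Small feasible simulation config for fast tests.
small_config <- function(seed = 42, ...) {
  simulation_config(seed = seed, chrom_lengths = c(c1 = 8e5, c2 = 6e5),
                    n_genes = 400, n_peaks = 300, ...)
}
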