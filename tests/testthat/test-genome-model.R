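test_that("single-gene partition matches the worked example", {
  sizes <- c(chrA = 3000)
  g <- gene_models("chrA", 1001, 2000, "+", "g1")   # 0-based [1000, 2000)
  part <- build_partition(g, sizes, c(100, 100), c(100, 100))
  df <- data.frame(start0 = start(part) - 1, end0 = end(part),
                   category = as.character(part$category))
  expect_equal(df$start0, c(0, 900, 1100, 1900, 2100))
  expect_equal(df$end0, c(900, 1100, 1900, 2100, 3000))
  expect_equal(df$category, c("INTERGENIC", "TSS", "GENE_BODY", "TES", "INTERGENIC"))
  frac <- genome_category_fractions(part)
  expect_equal(unname(frac), c(200, 200, 800, 1800) / 3000)
  expect_equal(sum(frac), 1, tolerance = 1e-12)
})

test_that("minus-strand genes get strand-aware TSS/TES windows", {
  sizes <- c(chrA = 3000)
  g <- gene_models("chrA", 1001, 2000, "-", "g1")
  part <- build_partition(g, sizes, c(100, 50), c(100, 50))
  tss <- part[part$category == "TSS"]
  tes <- part[part$category == "TES"]
  # TSS is at the gene END on '-': 0-based [2000 - 50, 2000 + 100)
  expect_equal(c(start(tss) - 1, end(tss)), c(1950, 2100))
  # TES at the gene start: 0-based [1000 - 50, 1000 + 100)
  expect_equal(c(start(tes) - 1, end(tes)), c(950, 1100))
})

test_that("an empty gene set yields a fully intergenic genome", {
  sizes <- c(chrA = 5000, chrB = 1000)
  part <- build_partition(gene_models(character(), integer(), integer(),
                                      character(), character()), sizes)
  expect_equal(as.character(part$category), rep("INTERGENIC", 2))
  expect_equal(sum(width(part)), 6000)
  expect_equal(unname(genome_category_fractions(part)), c(0, 0, 0, 1))
})

test_that("partition of overlapping random genes matches the per-base oracle and tiles exactly", {
  set.seed(71)
  for (rep in 1:5) {
    L <- 20000
    genes <- random_genes(20, L)
    part <- build_partition(genes_gr(genes), c(chrZ = L))
    # tiling: sorted, disjoint, exhaustive
    expect_equal(sum(width(part)), L)
    expect_true(all(start(part)[-1] == end(part)[-length(part)] + 1))
    # per-base equivalence with the brute-force labeler
    lab <- oracle_labels(genes, L)
    got <- rep(NA_integer_, L)
    for (i in seq_along(part))
      got[start(part)[i]:end(part)[i]] <- as.integer(part$category[i])
    expect_identical(got, lab)
    # fractions agree with oracle base counts exactly
    expect_equal(unname(genome_category_fractions(part)),
                 as.vector(tabulate(lab, 4) / L))
  }
})

test_that("partition rejects genes off the genome", {
  sizes <- c(chrA = 1000)
  expect_error(build_partition(gene_models("chrB", 1, 10, "+", "gX"), sizes), "gX")
  expect_error(build_partition(gene_models("chrA", 500, 2000, "+", "gY"), sizes), "gY")
})

test_that("random promoter sampling is exhaustive, deterministic and uniform", {
  set.seed(5)
  genes <- genes_gr(random_genes(30, 50000))
  # exhaustive draw returns every distinct promoter
  all30 <- sample_random_promoters(genes, 30, seed = 9)
  expect_setequal(all30$pos, gene_tss(genes))
  # determinism
  s1 <- sample_random_promoters(genes, 5, seed = 123)
  s2 <- sample_random_promoters(genes, 5, seed = 123)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # over-ask rejects with counts
  expect_error(sample_random_promoters(genes, 31, seed = 1), "30")
  # inclusion frequency ~ n/N across seeds (binomial check); all-'+' genes
  # with distinct starts guarantee 300 distinct promoters
  df2 <- random_genes(300, 5e5); df2$strand <- "+"
  genes2 <- genes_gr(df2)
  hits <- integer(300)
  n_draw <- 100; n_seeds <- 200
  for (sd in seq_len(n_seeds)) {
    s <- sample_random_promoters(genes2, n_draw, seed = sd)
    idx <- match(s$gene_id, genes2$gene_id)
    hits[idx] <- hits[idx] + 1L
  }
  p <- n_draw / 300
  se <- sqrt(p * (1 - p) / n_seeds)
  # per-gene 3-SE band holds for nearly all genes, and globally on average
  expect_gt(mean(abs(hits / n_seeds - p) <= 3 * se), 0.99)
  expect_lt(abs(mean(hits / n_seeds) - p), 3 * se / sqrt(300))
})

test_that("random genomic sites respect margins and proportional allocation", {
  # a chromosome too short for the margin is excluded; all excluded -> error
  expect_error(sample_random_sites(c(c1 = 10000), 5, seed = 1, margin = 5000), "margin")
  # margins respected
  s <- sample_random_sites(c(c1 = 10000, c2 = 3000), 500, seed = 2, margin = 1000)
  L <- c(c1 = 10000, c2 = 3000)
  expect_true(all(s$pos > 1000 & s$pos <= L[s$chrom] - 1000))
  # proportional to usable length: chromosomes L and 2L at margin 0
  s2 <- sample_random_sites(c(a = 50000, b = 100000), 30000, seed = 3, margin = 0)
  frac_b <- mean(s2$chrom == "b")
  se <- sqrt(2/3 * 1/3 / 30000)
  expect_lt(abs(frac_b - 2/3), 3 * se)
  # determinism
  expect_identical(as.data.frame(sample_random_sites(L, 50, seed = 7)),
                   as.data.frame(sample_random_sites(L, 50, seed = 7)))
})

test_that("chrom.sizes and partition BED writers round-trip / are well formed", {
  sizes <- c(chr2L = 23011544, chr4 = 1351857)
  f <- withr::local_tempfile()
  write_chrom_sizes(sizes, f)
  expect_equal(read_chrom_sizes(f), sizes)
  part <- build_partition(gene_models("chr4", 1001, 8000, "+", "g1"), sizes)
  f2 <- withr::local_tempfile()
  write_partition_bed(part, f2)
  bed <- read.table(f2, comment.char = "#", sep = "\t")
  expect_equal(nrow(bed), length(part))
  expect_equal(bed$V2, start(part) - 1)   # 0-based starts on disk
  expect_equal(bed$V4, as.character(part$category))
})

test_that("gene annotation reader keeps only gene features and reports ids", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tgene\t101\t500\t.\t+\t.\tID=gA",
               "chrA\tsrc\tmRNA\t101\t500\t.\t+\t.\tID=tA;Parent=gA",
               "chrA\tsrc\texon\t101\t200\t.\t+\t.\tParent=tA",
               "chrA\tsrc\tgene\t900\t1500\t.\t-\t.\tID=gB"), f)
  expect_message(g <- read_genes(f), "ignored 2")
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(start(g), c(101, 900))
  expect_equal(as.character(strand(g)), c("+", "-"))
})
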