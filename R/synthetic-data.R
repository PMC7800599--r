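# Synthetic data with planted ground truth: genomes with annotated genes,
# peak sets with known category composition, signal tracks with localized
# enrichment bumps or histone-depletion dips, colocalized partner peak sets,
# and qPCR Ct tables with planted fold changes.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate the
#' study conditions the pipeline was built for: a promoter-heavy binding
#' profile (73.2% of peaks at TSS regions), 4,709 binding sites, a 21-gene
#' qPCR panel with 7 genes down at least 20%, 3 up and 11 unchanged, a
#' reference gene at fold change 1 and an RNAi target depleted 8-fold. The
#' genome itself is a scaled-down multi-chromosome annotation (4 chromosomes,
#' ~19 Mb, 5,000 genes) sized so that every planted peak can sit at the
#' center of a distinct category interval and every size-matched promoter
#' control set can be drawn without replacement.
#'
#' @param seed Integer seed; every generator is a deterministic function of
#'   (config, seed).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param n_genes Number of genes to place.
#' @param gene_length,gene_gap Uniform `(min, max)` ranges (bp) for gene
#'   lengths and inter-gene gaps.
#' @param tss_window,tes_window Partition windows, as in [build_partition()].
#' @param n_peaks Number of peaks to plant.
#' @param peak_fractions Target category fractions (named over TSS, TES,
#'   GENE_BODY, INTERGENIC; must sum to 1).
#' @param flank Peak-region flank in bp.
#' @param min_overlap Annotation minimum overlap in bp.
#' @param signal_bin Signal-track resolution in bp (background drawn per bin).
#' @param background_mean,noise_sd Background signal level and per-bin
#'   Gaussian noise sd (track values are truncated at 0).
#' @param bump_amplitude,bump_width Planted Gaussian bump height and width
#'   (sd, bp) at enriched/depleted sites.
#' @param qpcr_fold_changes Named vector of planted fold changes for the
#'   assayed panel.
#' @param qpcr_replicates Replicates per condition.
#' @param ct_noise_sd Per-well Gaussian Ct noise sd (cycles).
#' @param reference_gene,target_gene qPCR reference gene and RNAi target ids.
#' @param target_fold Planted fold change of the RNAi target (default 1/8,
#'   an 8-fold knockdown).
#' @param efficiency qPCR amplification efficiency (fold per cycle).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr2L = 6e6, chr2R = 5.5e6,
                                                chr3L = 4.5e6, chrX = 3e6),
                              n_genes = 5000,
                              gene_length = c(1000, 3000),
                              gene_gap = c(400, 1600),
                              tss_window = c(200, 200),
                              tes_window = c(200, 200),
                              n_peaks = 4709,
                              peak_fractions = c(TSS = 0.732, TES = 0.05,
                                                 GENE_BODY = 0.15, INTERGENIC = 0.068),
                              flank = 100,
                              min_overlap = 10,
                              signal_bin = 25,
                              background_mean = 10,
                              noise_sd = 1,
                              bump_amplitude = 5,
                              bump_width = 300,
                              qpcr_fold_changes = stats::setNames(
                                c(rep(0.5, 7), rep(1.5, 3), rep(1.0, 11)),
                                sprintf("g%02d", 1:21)),
                              qpcr_replicates = 3,
                              ct_noise_sd = 0.05,
                              reference_gene = "Ras",
                              target_gene = "CG9890",
                              target_fold = 1 / 8,
                              efficiency = 2) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_sizes(chrom_lengths),
              n_genes = check_count(n_genes, "n_genes"),
              gene_length = gene_length, gene_gap = gene_gap,
              tss_window = tss_window, tes_window = tes_window,
              n_peaks = check_count(n_peaks, "n_peaks"),
              peak_fractions = peak_fractions, flank = flank,
              min_overlap = min_overlap, signal_bin = signal_bin,
              background_mean = background_mean, noise_sd = noise_sd,
              bump_amplitude = bump_amplitude, bump_width = bump_width,
              qpcr_fold_changes = qpcr_fold_changes,
              qpcr_replicates = check_count(qpcr_replicates, "qpcr_replicates"),
              ct_noise_sd = ct_noise_sd, reference_gene = reference_gene,
              target_gene = target_gene, target_fold = target_fold,
              efficiency = efficiency)
  if (abs(sum(cfg$peak_fractions) - 1) > 1e-9)
    stopf("peak_fractions must sum to 1")
  if (!identical(sort(names(cfg$peak_fractions)), sort(CATEGORIES)))
    stopf("peak_fractions must be named over: %s", paste(CATEGORIES, collapse = ", "))
  if (any(cfg$peak_fractions < 0)) stopf("peak_fractions must be non-negative")
  if (any(cfg$gene_length < 1) || cfg$gene_length[1] > cfg$gene_length[2])
    stopf("gene_length must be a valid (min, max) range")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: seed %d, %d chromosomes (%.1f Mb), %d genes, %d peaks\n",
              x$seed, length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              x$n_genes, x$n_peaks))
  cat("  peak fractions:", paste(sprintf("%s=%.3f", names(x$peak_fractions),
                                         x$peak_fractions), collapse = ", "), "\n")
  cat(sprintf("  signal: bin %d bp, background %.1f +/- %.1f, bump %.1f (sd %d bp)\n",
              x$signal_bin, x$background_mean, x$noise_sd, x$bump_amplitude,
              as.integer(x$bump_width)))
  cat(sprintf("  qPCR: %d genes, %d replicates, Ct noise %.2f, reference %s\n",
              length(x$qpcr_fold_changes), x$qpcr_replicates, x$ct_noise_sd,
              x$reference_gene))
  invisible(x)
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes sequentially on each chromosome (counts
#' proportional to chromosome length), with uniform gene lengths and
#' inter-gene gaps and random strands. The first gap on every chromosome is
#' forced to at least `4 * (tss + tes window)` bp so unambiguous intergenic
#' planting regions always exist.
#'
#' @param config A [simulation_config()].
#' @param seed Seed override (default `config$seed`).
#' @return List with elements `chrom_sizes` (named lengths) and `genes`
#'   (`GRanges` of gene models).
#' @export
generate_genome <- function(config, seed = config$seed) {
  sizes <- config$chrom_lengths
  n <- config$n_genes
  if (n == 0)
    return(list(chrom_sizes = sizes, genes = gene_models(character(), integer(),
                                                         integer(), character(), character())))
  # allocate gene counts per chromosome, largest remainder
  alloc <- .largest_remainder(n, sizes / sum(sizes))
  big_gap <- 4 * (sum(config$tss_window) + sum(config$tes_window))
  with_seed(seed, {
    out <- list()
    gi <- 0L
    for (k in seq_along(sizes)) {
      ch <- names(sizes)[k]
      nk <- alloc[k]
      if (nk == 0) next
      gaps <- runif(nk, config$gene_gap[1], config$gene_gap[2])
      # guarantee one wide inter-gene gap per chromosome (unambiguous
      # intergenic planting space); falls back to the leading gap when a
      # chromosome holds a single gene
      gaps[min(2L, nk)] <- max(gaps[min(2L, nk)], big_gap)
      lens <- round(runif(nk, config$gene_length[1], config$gene_length[2]))
      starts0 <- cumsum(gaps + c(0, lens[-nk]))  # 0-based starts
      ends0 <- starts0 + lens
      need <- ends0[nk] + config$gene_gap[1]
      if (need > sizes[[ch]])
        stopf("cannot place %d genes on %s: need %.0f bp, have %.0f", nk, ch, need, sizes[[ch]])
      out[[ch]] <- data.frame(chrom = ch, start = floor(starts0) + 1L,
                              end = floor(ends0),
                              strand = sample(c("+", "-"), nk, replace = TRUE),
                              gene_id = sprintf("gene%05d", gi + seq_len(nk)))
      gi <- gi + nk
    }
    df <- do.call(rbind, out)
  })
  genes <- gene_models(df$chrom, df$start, df$end, df$strand, df$gene_id)
  list(chrom_sizes = sizes, genes = genes)
}

# Integer counts from fractions by largest-remainder rounding (exact total).
.largest_remainder <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Plant peaks with known category labels
#'
#' Plants exactly `round-to-count` peaks per category (largest-remainder
#' rounding of `fractions * n`), each at the center of a distinct partition
#' interval wide enough to contain the whole +/-`flank` peak region. A region
#' fully inside one category interval overlaps that category by
#' `2 * flank + 1` bases and every other category by 0, so annotation under
#' the priority rule is unambiguous by construction.
#'
#' @param partition Partition from [build_partition()].
#' @param n Number of peaks.
#' @param fractions Target category fractions (named over the four
#'   categories, summing to 1).
#' @param flank Peak-region flank (default 100 bp).
#' @param seed Integer seed.
#' @return A [site_set()] named `"planted_peaks"` with a `category` truth
#'   column, in shuffled order.
#' @export
plant_peaks <- function(partition, n, fractions, flank = 100, seed = 1L) {
  n <- check_count(n)
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")
  fractions <- fractions[CATEGORIES]
  counts <- stats::setNames(.largest_remainder(n, fractions), CATEGORIES)
  width_needed <- 2 * flank + 1
  with_seed(seed, {
    picks <- lapply(CATEGORIES, function(cc) {
      k <- counts[[cc]]
      if (k == 0) return(NULL)
      cand <- partition[partition$category == cc & width(partition) >= width_needed]
      if (length(cand) == 0)
        stopf("category %s has no interval of width >= %d to plant in", cc, width_needed)
      if (length(cand) < k)
        stopf("category %s: %d plantable intervals for %d requested peaks",
              cc, length(cand), k)
      sel <- cand[sample.int(length(cand), k)]
      data.frame(chrom = as.character(seqnames(sel)),
                 pos = start(sel) + width(sel) %/% 2L,
                 category = cc, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, picks)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
  })
  site_set(df$chrom, df$pos, "planted_peaks", flank = flank, category = df$category)
}

#' Convert a site set to peak records
#'
#' Represents each anchor as a single-base peak record (so the anchor of the
#' record is the site itself), suitable for [write_bed()] and
#' [annotate_peaks()].
#'
#' @param sites A [site_set()].
#' @param prefix Name prefix for the records.
#' @return A `GRanges` of peak records.
#' @export
as_peak_records <- function(sites, prefix = "peak") {
  gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  mcols(gr) <- DataFrame(name = sprintf("%s_%05d", prefix, seq_len(nrow(sites))),
                         score = rep(NA_real_, nrow(sites)),
                         summit = rep(NA_integer_, nrow(sites)))
  gr
}

#' Plant a colocalized partner peak set
#'
#' Builds a second site set of size `n` of which exactly
#' `round(fraction * n_reference)` sites coincide with reference sites (their
#' +/-`flank` regions are identical, hence overlap by at least any
#' `min_overlap <= 2 * flank + 1`), while the remaining sites are placed at
#' least `2 * flank + 1` bp from every reference anchor so they overlap none.
#'
#' @param reference A [site_set()] of reference anchors.
#' @param sizes Named chromosome lengths.
#' @param fraction Fraction of reference sites to be covered (default 0.6).
#' @param n Size of the partner set (default: size of the reference set).
#' @param flank Peak-region flank (default 100 bp).
#' @param seed Integer seed.
#' @return A [site_set()] named `"planted_partner"`.
#' @export
plant_colocalized_sites <- function(reference, sizes, fraction = 0.6,
                                    n = nrow(reference), flank = 100, seed = 1L) {
  sizes <- chrom_sizes(sizes)
  k <- round(fraction * nrow(reference))
  if (k > n) stopf("partner set of size %d cannot cover %d reference sites", n, k)
  clear <- 2 * flank + 1
  with_seed(seed, {
    shared_idx <- sample.int(nrow(reference), k)
    extra <- list()
    need <- n - k
    tries <- 0L
    while (need > 0) {
      tries <- tries + 1L
      if (tries > 1000) stopf("could not place disjoint partner sites")
      cand <- sample_random_sites(sizes, need * 2 + 10, seed = NULL, margin = flank)
      far <- !vapply(seq_len(nrow(cand)), function(i) {
        same <- reference$chrom == cand$chrom[i]
        any(abs(reference$pos[same] - cand$pos[i]) < clear)
      }, TRUE)
      cand <- cand[far, , drop = FALSE]
      if (nrow(cand) > 0) {
        take <- utils::head(cand, need)
        extra[[length(extra) + 1]] <- take
        need <- need - nrow(take)
      }
    }
  })
  shared <- reference[shared_idx, c("chrom", "pos"), drop = FALSE]
  extra_df <- if (length(extra)) do.call(rbind, lapply(extra, function(d) d[c("chrom", "pos")]))
              else shared[0, ]
  df <- rbind(shared, extra_df)
  site_set(df$chrom, df$pos, "planted_partner", flank = flank)
}

#' Generate a signal track with planted bumps or dips
#'
#' Background is drawn per `signal_bin` bp bin as
#' `Normal(background_mean, noise_sd)`; at every site a Gaussian bump of
#' height `bump_amplitude` and width `bump_width` (sd, bp) is added
#' (`mode = "enrich"`) or subtracted (`mode = "deplete"`, the
#' histone-H3-like nucleosome-depletion dip). Values are truncated at 0.
#'
#' @param sizes Named chromosome lengths.
#' @param sites A [site_set()] of planted anchors (may have zero rows).
#' @param config A [simulation_config()] (signal parameters are read from it).
#' @param mode `"enrich"` or `"deplete"`.
#' @param seed Seed override (default `config$seed`).
#' @return A [signal_track()].
#' @export
generate_signal_track <- function(sizes, sites, config, mode = c("enrich", "deplete"),
                                  seed = config$seed) {
  mode <- match.arg(mode)
  sizes <- chrom_sizes(sizes)
  bin <- check_count(config$signal_bin, "signal_bin")
  a <- config$bump_amplitude * ifelse(mode == "enrich", 1, -1)
  w <- config$bump_width
  vals <- with_seed(seed, {
    lapply(names(sizes), function(ch) {
      L <- sizes[[ch]]
      nb <- ceiling(L / bin)
      v <- rnorm(nb, config$background_mean, config$noise_sd)
      here <- sites[sites$chrom == ch, , drop = FALSE]
      if (nrow(here) > 0 && config$bump_amplitude != 0) {
        centers0 <- (seq_len(nb) - 0.5) * bin   # 0-based bin centers
        reach <- ceiling(4 * w / bin)
        for (p in here$pos) {
          cbin <- ceiling((p - 0.5) / bin)
          lo <- max(1L, cbin - reach); hi <- min(nb, cbin + reach)
          d <- centers0[lo:hi] - (p - 0.5)
          v[lo:hi] <- v[lo:hi] + a * exp(-d^2 / (2 * w^2))
        }
      }
      v <- pmax(v, 0)
      window(Rle(rep(v, each = bin)), 1, L)
    })
  })
  names(vals) <- names(sizes)
  signal_track(vals, sizes)
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' For each panel gene a control-condition delta-Ct (vs the reference gene)
#' is drawn once; the knockdown delta-Ct is shifted by
#' `-log(fold) / log(efficiency)` so that the delta-delta-Ct analysis
#' recovers the planted fold change exactly at zero noise. Each
#' (condition, replicate) pair also carries a shared plate offset, so
#' normalization invariance is exercised, and every well gets independent
#' Gaussian Ct noise. The reference gene is planted at fold change 1 and the
#' RNAi target gene at `config$target_fold`.
#'
#' @param config A [simulation_config()].
#' @param seed Seed override (default `config$seed`).
#' @return A [ct_table()] with attribute `truth` (data.frame of gene and
#'   planted fold change).
#' @export
generate_qpcr <- function(config, seed = config$seed) {
  folds <- c(config$qpcr_fold_changes,
             stats::setNames(config$target_fold, config$target_gene))
  genes <- c(names(folds), config$reference_gene)
  eff <- config$efficiency
  nrep <- config$qpcr_replicates
  df <- with_seed(seed, {
    base_ref <- 18
    dct_ctrl <- stats::setNames(runif(length(folds), -1, 6), names(folds))
    rows <- list()
    for (cond in CONDITIONS) {
      for (r in seq_len(nrep)) {
        offset <- rnorm(1, 0, 0.3)   # shared pipetting/plate offset
        ct_ref <- base_ref + offset + rnorm(1, 0, config$ct_noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, replicate = sprintf("rep%d", r),
          gene = config$reference_gene, ct = ct_ref)
        dct <- dct_ctrl
        if (cond == "knockdown") dct <- dct - log(folds) / log(eff)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, replicate = sprintf("rep%d", r),
          gene = names(folds),
          ct = base_ref + offset + dct + rnorm(length(folds), 0, config$ct_noise_sd))
      }
    }
    do.call(rbind, rows)
  })
  ct <- ct_table(df, config$reference_gene)
  attr(ct, "truth") <- data.frame(gene = names(folds), fold_change = as.numeric(folds),
                                  stringsAsFactors = FALSE)
  ct
}
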