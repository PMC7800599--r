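# Full-pipeline orchestration: simulate or ingest data, annotate peaks,
# colocalize peak sets, compute meta-profile bundles, classify qPCR
# responses; every stage writes parameter-stamped tables and the run is
# summarized in a JSON manifest.

.log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Write the default synthetic input bundle
#'
#' Generates and writes to `out_dir`: `chrom.sizes`, `genes.gff3`,
#' `peaks.bed` (+ `peaks_truth.tsv`), a colocalized partner set
#' `partner_peaks.bed`, `track_factor.wig` (enrichment bumps at the planted
#' peaks), `track_histone.wig` (depletion dips at the same sites) and
#' `qpcr.tsv` (+ `qpcr_truth.tsv`).
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param coloc_fraction Planted colocalization rate of the partner set
#'   (default 0.6).
#' @return Named list of the written file paths, invisibly.
#' @export
simulate_inputs <- function(config = simulation_config(), out_dir = ".",
                            coloc_fraction = 0.6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  genome <- generate_genome(config)
  partition <- build_partition(genome$genes, genome$chrom_sizes,
                               config$tss_window, config$tes_window)
  sites <- plant_peaks(partition, config$n_peaks, config$peak_fractions,
                       flank = config$flank, seed = config$seed + 1L)
  partner <- plant_colocalized_sites(sites, genome$chrom_sizes,
                                     fraction = coloc_fraction,
                                     flank = config$flank, seed = config$seed + 2L)
  track_f <- generate_signal_track(genome$chrom_sizes, sites, config,
                                   mode = "enrich", seed = config$seed + 3L)
  track_h <- generate_signal_track(genome$chrom_sizes, sites, config,
                                   mode = "deplete", seed = config$seed + 4L)
  qpcr <- generate_qpcr(config, seed = config$seed + 5L)

  write_chrom_sizes(genome$chrom_sizes, p("chrom.sizes"))
  write_genes(genome$genes, p("genes.gff3"))
  write_bed(as_peak_records(sites), p("peaks.bed"))
  write_result_tsv(data.frame(name = sprintf("peak_%05d", seq_len(nrow(sites))),
                              chrom = sites$chrom, pos = sites$pos,
                              category = sites$category),
                   p("peaks_truth.tsv"), params = list(seed = config$seed))
  write_bed(as_peak_records(partner, prefix = "partner"), p("partner_peaks.bed"))
  write_wig(track_f, p("track_factor.wig"))
  write_wig(track_h, p("track_histone.wig"))
  write_ct_table(qpcr, p("qpcr.tsv"))
  write_result_tsv(attr(qpcr, "truth"), p("qpcr_truth.tsv"),
                   params = list(seed = config$seed))
  invisible(list(chrom_sizes = p("chrom.sizes"), genes = p("genes.gff3"),
                 peaks = p("peaks.bed"), peaks_truth = p("peaks_truth.tsv"),
                 partner_peaks = p("partner_peaks.bed"),
                 track_factor = p("track_factor.wig"),
                 track_histone = p("track_histone.wig"),
                 qpcr = p("qpcr.tsv"), qpcr_truth = p("qpcr_truth.tsv")))
}

#' Run the full peak-characterization analysis
#'
#' Executes the four analysis stages in order -- annotate, colocalize,
#' metaprofile, qpcr -- each reading declared files and writing
#' parameter-stamped TSV tables, and writes a JSON run manifest. When
#' `inputs` is `NULL` the synthetic bundle from [simulate_inputs()] is
#' generated first. A missing qPCR input skips the expression stage with a
#' logged notice; any stage failure aborts naming the stage.
#'
#' @param out_dir Output directory.
#' @param config A [simulation_config()]; also supplies annotation and
#'   profile parameters.
#' @param inputs Optional named list of input paths (as returned by
#'   [simulate_inputs()]); entries: `chrom_sizes`, `genes`, `peaks`,
#'   optionally `partner_peaks`, `track_factor`, `track_histone`, `qpcr`.
#' @param flank,min_overlap Peak-region and overlap parameters (defaults from
#'   `config`).
#' @param profile_flank,profile_bin Meta-profile geometry (default 5000 / 50).
#' @return An object of class `run_manifest` (also written as
#'   `manifest.json`).
#' @export
run_full_analysis <- function(out_dir, config = simulation_config(), inputs = NULL,
                              flank = config$flank, min_overlap = config$min_overlap,
                              profile_flank = 5000, profile_bin = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  outputs <- character()
  emit <- function(df, name, params) {
    path <- file.path(out_dir, name)
    write_result_tsv(df, path, params)
    outputs[[length(outputs) + 1]] <<- path
    path
  }
  stage <- function(name, expr) {
    .log(logcon, "stage %s: start", name)
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }

  if (is.null(inputs)) {
    .log(logcon, "no inputs given: generating synthetic bundle (seed %d)", config$seed)
    inputs <- stage("simulate", simulate_inputs(config, file.path(out_dir, "inputs")))
  }

  # --- stage 1: annotate ------------------------------------------------
  ann_dist <- NULL
  annotated <- stage("annotate", {
    sizes <- read_chrom_sizes(inputs[["chrom_sizes"]])
    genes <- read_genes(inputs[["genes"]])
    peaks <- read_bed(inputs[["peaks"]])
    partition <- build_partition(genes, sizes, config$tss_window, config$tes_window)
    ann <- annotate_peaks(peaks, partition, sizes, flank = flank, min_overlap = min_overlap)
    # `stage()` evaluates this expression in the enclosing frame, so a plain
    # assignment lands in run_full_analysis' environment
    ann_dist <- category_distribution(ann)
    emit(data.frame(chrom = as.character(seqnames(ann)), start = start(ann) - 1L,
                    end = end(ann), name = ann$name, category = as.character(ann$category),
                    anchor = ann$anchor, tss_bp = ann$tss_bp, tes_bp = ann$tes_bp,
                    gene_body_bp = ann$gene_body_bp, intergenic_bp = ann$intergenic_bp),
         "annotated_peaks.tsv",
         list(flank = flank, min_overlap = min_overlap,
              tss_window = config$tss_window, tes_window = config$tes_window))
    emit(as.data.frame(ann_dist), "category_distribution.tsv",
         list(flank = flank, min_overlap = min_overlap))
    genome_frac <- genome_category_fractions(partition)
    emit(data.frame(category = names(genome_frac), genome_fraction = as.numeric(genome_frac)),
         "genome_category_fractions.tsv", list())
    list(ann = ann, partition = partition, sizes = sizes, genes = genes, peaks = peaks)
  })
  .log(logcon, "annotate: %d peaks, %.1f%% TSS", length(annotated$ann),
       ann_dist$percentage[ann_dist$category == "TSS"])

  # --- stage 2: colocalize ----------------------------------------------
  coloc <- NULL
  if (!is.null(inputs[["partner_peaks"]])) {
    coloc <- stage("colocalize", {
      partner <- read_bed(inputs[["partner_peaks"]])
      ref_regions <- peak_region(as.character(seqnames(annotated$peaks)),
                                 peak_anchor(annotated$peaks), annotated$sizes, flank)
      qry_regions <- peak_region(as.character(seqnames(partner)),
                                 peak_anchor(partner), annotated$sizes, flank)
      vc <- venn_counts(ref_regions, qry_regions, min_overlap = min_overlap,
                        names = c("factor", "partner"))
      emit(data.frame(statistic = c(names(vc$counts), names(vc$fractions)),
                      value = c(as.numeric(vc$counts), as.numeric(vc$fractions))),
           "colocalization.tsv", list(min_overlap = min_overlap, flank = flank))
      vc
    })
    .log(logcon, "colocalize: %.1f%% of factor peaks on partner peaks",
         100 * coloc$fractions[["factor_in_partner"]])
  } else .log(logcon, "colocalize: no partner peak set given, stage skipped")

  # --- stage 3: metaprofile ---------------------------------------------
  bundles <- list()
  prof_seed <- config$seed + 10L
  for (tr in c("track_factor", "track_histone")) {
    if (is.null(inputs[[tr]])) { .log(logcon, "metaprofile: %s not given, skipped", tr); next }
    bundles[[tr]] <- stage("metaprofile", {
      track <- read_wig(inputs[[tr]], annotated$sizes)
      fs <- site_set(as.character(seqnames(annotated$peaks)),
                     peak_anchor(annotated$peaks), "factor_sites")
      bundle <- three_curve_bundle(track, fs, annotated$genes, annotated$sizes,
                                   seed = prof_seed, flank = profile_flank,
                                   bin_width = profile_bin)
      emit(as.data.frame(bundle), sprintf("metaprofile_%s.tsv", sub("track_", "", tr)),
           list(flank = profile_flank, bin = profile_bin, seed = prof_seed, track = tr))
      bundle
    })
  }

  # --- stage 4: qpcr ----------------------------------------------------
  panel <- NULL
  if (!is.null(inputs[["qpcr"]])) {
    panel <- stage("qpcr", {
      ct <- read_ct_table(inputs[["qpcr"]], config$reference_gene)
      pn <- expression_panel(ct, efficiency = config$efficiency, threshold = 0.20)
      emit(as.data.frame(pn), "expression_response.tsv",
           list(reference_gene = config$reference_gene,
                efficiency = config$efficiency, threshold = 0.20))
      pn
    })
    tab <- table(factor(panel$response, levels = c("down", "up", "unchanged")))
    .log(logcon, "qpcr: %d down / %d up / %d unchanged", tab["down"], tab["up"],
         tab["unchanged"])
  } else .log(logcon, "qpcr: no Ct table given, stage skipped")

  manifest <- structure(list(
    tool = "promoterscope", version = as.character(packageVersion("promoterscope")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(flank = flank, min_overlap = min_overlap,
                      tss_window = config$tss_window, tes_window = config$tes_window,
                      profile_flank = profile_flank, profile_bin = profile_bin,
                      efficiency = config$efficiency, threshold = 0.20),
    inputs = lapply(inputs, function(f) list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = unlist(outputs)), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log(logcon, "done: %d result tables", length(outputs))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("promoterscope run (v%s, seed %d) at %s\n", x$version, x$seed, x$timestamp))
  cat(sprintf("  %d input(s), %d output table(s):\n", length(x$inputs), length(x$outputs)))
  for (o in x$outputs) cat("   -", o, "\n")
  invisible(x)
}
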