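# promoterscope

Genome-wide characterization of transcription-factor binding sites from
ChIP-Seq peak calls, for regulatory-genomics analysts working with
peak-caller output, gene annotations and signal tracks (e.g. a Drosophila
zinc-finger factor assayed in S2 cells). The package answers four questions
about a peak set:

1. **Where do the peaks sit?** The genome is partitioned exhaustively into
   promoter (**TSS**), gene-end (**TES**), gene-body and intergenic regions
   from gene models; each peak's ±100 bp region is assigned the
   highest-priority category it overlaps by at least 10 bp
   (TSS > TES > gene body > intergenic), and the category distribution is
   compared against the genome-wide category representation.
2. **Do the peaks colocalize with another factor's peaks?** Two sites are
   colocalized when their genomic intervals share ≥ 10 bp; the package
   reports the (asymmetric) overlap fractions in both directions and
   Euler–Venn membership counts for two or three peak sets.
3. **What does the chromatin around the sites look like?** Averaged signal
   meta-profiles over ±5 kb around the sites, against two size-matched
   controls — randomly selected promoters and random genomic sites — with
   optional log2 enrichment-ratio tracks
   (`log2((treatment + p) / (control + p))`). A central dip in a histone H3
   profile marks a nucleosome-depleted, active regulatory element.
4. **Does knocking the factor down change its target genes?** RT-qPCR Ct
   tables are analyzed by ΔΔCt with reference-gene normalization
   (`fold change = E^(−ΔΔCt)`, default efficiency `E = 2`), and responses
   are classified at the inclusive ±20 % thresholds
   (down: FC ≤ 0.8, up: FC ≥ 1.2).

Every analysis is exercisable end to end on synthetic data with planted
ground truth: the generator builds multi-chromosome genomes with annotated
genes, plants peaks with an exact category composition (by default
promoter-heavy, 73.2 % TSS), partner peak sets with an exact colocalization
rate, signal tracks with Gaussian enrichment bumps or histone-depletion dips,
and qPCR tables with planted fold changes — so annotation, overlap,
profile and expression results can be checked against known truth.

## Worked example

```r
library(promoterscope)

cfg <- simulation_config(seed = 42, chrom_lengths = c(chr2L = 2.2e6, chrX = 1.8e6),
                         n_genes = 1100, n_peaks = 1000)
genome    <- generate_genome(cfg)
partition <- build_partition(genome$genes, genome$chrom_sizes)
sites     <- plant_peaks(partition, cfg$n_peaks, cfg$peak_fractions, seed = 43)
ann       <- annotate_peaks(as_peak_records(sites), partition, genome$chrom_sizes,
                            flank = 100, min_overlap = 10)
category_distribution(ann)
#> Peak category distribution (1000 peaks):
#>    category count percentage
#>         TSS   732      73.2%
#>         TES    50       5.0%
#>   GENE_BODY   150      15.0%
#>  INTERGENIC    68       6.8%
```

The planted composition (73.2 % of peaks in promoter regions) is recovered
exactly: each percentage is `100 * count / total` over the four categories.
Colocalization and the qPCR analysis close the loop the same way:

```r
partner <- plant_colocalized_sites(sites, genome$chrom_sizes, fraction = 0.6, seed = 44)
ra <- peak_region(sites$chrom, sites$pos, genome$chrom_sizes, 100)
rb <- peak_region(partner$chrom, partner$pos, genome$chrom_sizes, 100)
overlap_fraction(ra, rb)
#> [1] 0.6

ct <- generate_qpcr(cfg)
knockdown_efficiency(ct, "CG9890")
#> Knockdown of CG9890: 7.95-fold mRNA decrease (effective, bar = 5-fold)
table(expression_panel(ct)$response[expression_panel(ct)$gene != "CG9890"])
#>      down        up unchanged
#>         7         3        11
```

The 60 % planted colocalization rate returns exactly at zero jitter; the
RNAi target planted at an 8-fold mRNA depletion measures 7.95-fold with
Ct noise sd 0.05, clearing the conventional ≥ 5-fold bar for an effective
knockdown; and the 21-gene panel classifies 7 genes down / 3 up / 11
unchanged at the ±20 % thresholds.

`run_full_analysis(out_dir, cfg)` chains all four stages
(annotate → colocalize → metaprofile → qpcr) over files on disk
(BED peaks, GFF3 genes, chrom.sizes, WIG tracks, Ct TSV) and writes
parameter-stamped result tables plus a JSON run manifest. The same stages
are available from a shell:

```sh
inst/exec/promoterscope run-all --seed 1 --out-dir run1
inst/exec/promoterscope annotate --peaks peaks.bed --genes genes.gff3 --chrom-sizes chrom.sizes
```

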