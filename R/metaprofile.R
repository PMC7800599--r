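# Meta-profiles: averaged signal in position bins around a set of anchor
# sites (-flank .. +flank), with random-promoter and random-genome control
# curves, and log2 enrichment-ratio tracks.

#' Per-site binned signal around anchors
#'
#' For each site, lays out bins of `bin_width` bp centered at offsets
#' `-flank, -flank + bin_width, ..., +flank` relative to the anchor and takes
#' the mean of the track over each bin's genomic span. Bases falling outside
#' the chromosome or lacking track data are excluded from the bin mean; a bin
#' with no covered base at all is "no data" (`NA`). Sites on chromosomes
#' absent from the track yield all-`NA` rows with a warning.
#'
#' @param track A [signal_track()].
#' @param sites A [site_set()].
#' @param flank Half-window in bp (default 5000); must be a positive multiple
#'   of `bin_width`.
#' @param bin_width Bin size in bp (default 50).
#' @return A numeric matrix (sites x bins) of class `profile_matrix`;
#'   `attr(, "bin_centers")` gives the offsets of the bin centers.
#' @export
extract_profile_matrix <- function(track, sites, flank = 5000, bin_width = 50) {
  if (flank <= 0 || bin_width <= 0 || flank %% bin_width != 0)
    stopf("flank must be a positive multiple of bin_width")
  centers <- seq(-flank, flank, by = bin_width)
  nbins <- length(centers)
  half <- bin_width %/% 2
  # offsets (0-based, relative to anchor) covered by the bin layout
  offs <- seq(-flank - half, flank + (bin_width - half) - 1L)
  stopifnot(length(offs) == nbins * bin_width)

  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = nbins)
  missing_chrom <- setdiff(unique(sites$chrom), names(track$values))
  if (length(missing_chrom))
    warnf("site chromosome(s) absent from track, rows set to no-data: %s",
          paste(missing_chrom, collapse = ", "))
  for (ch in intersect(unique(sites$chrom), names(track$values))) {
    rows <- which(sites$chrom == ch)
    v <- as.numeric(track$values[[ch]])
    L <- length(v)
    for (grp in split(rows, ceiling(seq_along(rows) / 512))) {
      idx <- outer(sites$pos[grp], offs, "+")
      vals <- matrix(NA_real_, nrow(idx), ncol(idx))
      ok <- idx >= 1L & idx <= L
      vals[ok] <- v[idx[ok]]
      for (b in seq_len(nbins)) {
        colsel <- ((b - 1L) * bin_width + 1L):(b * bin_width)
        m <- rowMeans(vals[, colsel, drop = FALSE], na.rm = TRUE)
        m[is.nan(m)] <- NA_real_
        mat[grp, b] <- m
      }
    }
  }
  rownames(mat) <- sprintf("%s:%d", sites$chrom, sites$pos)
  structure(mat, class = c("profile_matrix", "matrix"),
            bin_centers = centers, flank = flank, bin_width = bin_width,
            set_name = attr(sites, "set_name"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix '%s': %d sites x %d bins (flank %d bp, bin %d bp)\n",
              attr(x, "set_name") %||% "?", nrow(x), ncol(x),
              attr(x, "flank"), attr(x, "bin_width")))
  invisible(x)
}

#' Average profile across sites
#'
#' Per-bin arithmetic mean over sites with data in that bin (available-data
#' mean; missing bins are excluded per site, not zero-filled), plus the
#' per-bin site count and standard error.
#'
#' @param matrix A `profile_matrix`.
#' @return An object of class `average_profile`: a data.frame with columns
#'   `bin_center`, `mean`, `n`, `se`.
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix) == 0) stopf("profile matrix has no sites")
  n <- colSums(!is.na(matrix))
  mu <- colMeans(matrix, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  structure(data.frame(bin_center = attr(matrix, "bin_centers"),
                       mean = as.numeric(mu), n = as.integer(n), se = as.numeric(se)),
            class = c("average_profile", "data.frame"),
            set_name = attr(matrix, "set_name"),
            flank = attr(matrix, "flank"), bin_width = attr(matrix, "bin_width"))
}

#' @export
plot.average_profile <- function(x, xlab = "Position relative to site (bp)",
                                 ylab = "Mean signal", type = "l", ...) {
  plot(x$bin_center, x$mean, type = type, xlab = xlab, ylab = ylab, ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' log2 enrichment ratio of two signal tracks
#'
#' Per-base `log2((treatment + pseudocount) / (control + pseudocount))`.
#' Positions lacking either input are "no data".
#'
#' @param treatment,control [signal_track()] objects on the same chromosomes.
#' @param pseudocount Positive stabilizer added to both tracks (default 1).
#' @return A `signal_track` of log2 ratios.
#' @export
log2_enrichment <- function(treatment, control, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stopf("pseudocount must be positive")
  if (!identical(names(treatment$sizes), names(control$sizes)) ||
      !all(treatment$sizes == control$sizes))
    stopf("treatment and control tracks must share chromosome sizes")
  vals <- lapply(names(treatment$sizes), function(ch) {
    log2((treatment$values[[ch]] + pseudocount) / (control$values[[ch]] + pseudocount))
  })
  names(vals) <- names(treatment$sizes)
  signal_track(vals, treatment$sizes)
}

#' Factor / random-promoter / random-site profile bundle
#'
#' Computes the averaged profile of a track around the factor's binding sites
#' together with two size-matched control curves: `n` randomly selected
#' promoters and `n` random genomic sites, with `n` the number of factor
#' sites. Controls are sampled deterministically from `seed` (promoters at
#' `seed`, random sites at `seed + 1`).
#'
#' @param track A [signal_track()].
#' @param factor_sites A [site_set()] of binding-site anchors.
#' @param genes `GRanges` of gene models (promoter source).
#' @param sizes Named chromosome lengths.
#' @param seed Integer seed for the control samplers.
#' @param flank,bin_width Profile geometry (defaults 5000 / 50 bp).
#' @param margin Margin for the random-site sampler (default 100 bp).
#' @return An object of class `profile_bundle`: list of three
#'   [average_profile()]s (`factor`, `promoters`, `random`) plus the three
#'   profile matrices and the parameters.
#' @export
three_curve_bundle <- function(track, factor_sites, genes, sizes, seed,
                               flank = 5000, bin_width = 50, margin = 100) {
  n <- nrow(factor_sites)
  prom <- sample_random_promoters(genes, n, seed)
  rand <- sample_random_sites(sizes, n, seed + 1L, margin = margin)
  mats <- list(factor = extract_profile_matrix(track, factor_sites, flank, bin_width),
               promoters = extract_profile_matrix(track, prom, flank, bin_width),
               random = extract_profile_matrix(track, rand, flank, bin_width))
  structure(list(profiles = lapply(mats, average_profile),
                 matrices = mats,
                 params = list(n = n, flank = flank, bin_width = bin_width,
                               seed = seed, margin = margin)),
            class = "profile_bundle")
}

#' @export
print.profile_bundle <- function(x, ...) {
  cat(sprintf("profile_bundle: %d sites per curve, flank %d bp, bin %d bp\n",
              x$params$n, x$params$flank, x$params$bin_width))
  for (nm in names(x$profiles)) {
    p <- x$profiles[[nm]]
    ctr <- p$mean[p$bin_center == 0]
    cat(sprintf("  %-10s central bin mean = %s\n", nm,
                ifelse(is.na(ctr), "no data", sprintf("%.4f", ctr))))
  }
  invisible(x)
}

#' Wide result table of a profile bundle
#'
#' @param x A `profile_bundle`.
#' @param ... Unused.
#' @return A data.frame with columns `bin_center`, `mean_factor`, `n_factor`,
#'   `mean_promoters`, `n_promoters`, `mean_random`, `n_random`.
#' @method as.data.frame profile_bundle
#' @export
as.data.frame.profile_bundle <- function(x, ...) {
  p <- x$profiles
  data.frame(bin_center = p$factor$bin_center,
             mean_factor = p$factor$mean, n_factor = p$factor$n,
             mean_promoters = p$promoters$mean, n_promoters = p$promoters$n,
             mean_random = p$random$mean, n_random = p$random$n)
}

#' @export
plot.profile_bundle <- function(x, main = "Averaged profile", ...) {
  df <- as.data.frame(x)
  rng <- range(c(df$mean_factor, df$mean_promoters, df$mean_random), na.rm = TRUE)
  plot(df$bin_center, df$mean_factor, type = "l", col = "blue", ylim = rng,
       xlab = "Position relative to site (bp)", ylab = "Mean signal", main = main, ...)
  lines(df$bin_center, df$mean_promoters, col = "red")
  lines(df$bin_center, df$mean_random, col = "darkgreen")
  legend("topright", legend = c("factor sites", "random promoters", "random sites"),
         col = c("blue", "red", "darkgreen"), lty = 1, bty = "n")
  abline(v = 0, lty = 3)
  invisible(x)
}
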