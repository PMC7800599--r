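# RNAi / qPCR expression response: delta-delta-Ct relative expression with
# reference-gene normalization, response classification at the +/-20%
# threshold, and knockdown-efficiency measurement.

CONDITIONS <- c("knockdown", "control")

#' Construct a validated qPCR Ct table
#'
#' @param df Data.frame with columns `condition` (`"knockdown"` or
#'   `"control"`), `replicate`, `gene`, `ct` (cycles, > 0).
#' @param reference_gene Gene used for within-condition normalization (e.g.
#'   `Ras`); must be measured in every (condition, replicate).
#' @return A data.frame of class `ct_table` with attribute `reference_gene`.
#' @export
ct_table <- function(df, reference_gene) {
  need <- c("condition", "replicate", "gene", "ct")
  if (!all(need %in% names(df)))
    stopf("ct table must have columns: %s", paste(need, collapse = ", "))
  df <- df[need]
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$gene <- as.character(df$gene)
  df$ct <- as.numeric(df$ct)
  if (!all(df$condition %in% CONDITIONS))
    stopf("condition must be one of: %s", paste(CONDITIONS, collapse = ", "))
  if (any(is.na(df$ct)) || any(df$ct <= 0)) stopf("Ct values must be positive")
  reps <- unique(df[c("condition", "replicate")])
  ref <- df[df$gene == reference_gene, c("condition", "replicate")]
  has_ref <- paste(reps$condition, reps$replicate) %in% paste(ref$condition, ref$replicate)
  if (!all(has_ref))
    stopf("reference gene '%s' missing from %s", reference_gene,
          paste(sprintf("(%s, replicate %s)", reps$condition[!has_ref],
                        reps$replicate[!has_ref]), collapse = ", "))
  structure(df, class = c("ct_table", "data.frame"), reference_gene = reference_gene)
}

#' Read a qPCR Ct table from TSV
#'
#' @param path TSV with columns condition, replicate, gene, ct.
#' @param reference_gene Reference gene id.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, reference_gene) {
  ct_table(read_result_tsv(path), reference_gene)
}

#' Write a qPCR Ct table as TSV
#'
#' @param ct A [ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  write_result_tsv(as.data.frame(ct), path,
                   params = list(reference_gene = attr(ct, "reference_gene")))
}

# Per-(condition, replicate) delta-Ct of `gene` vs the reference gene.
# Multiple wells of one gene in one replicate are averaged first.
.delta_ct <- function(ct, gene, condition) {
  ref <- attr(ct, "reference_gene")
  sub <- ct[ct$condition == condition & ct$gene %in% c(gene, ref), ]
  g <- tapply(sub$ct[sub$gene == gene], sub$replicate[sub$gene == gene], mean)
  r <- tapply(sub$ct[sub$gene == ref], sub$replicate[sub$gene == ref], mean)
  common <- names(g)
  stats::setNames(as.numeric(g[common]) - as.numeric(r[common]), common)
}

#' Relative expression of a gene after knockdown (delta-delta-Ct)
#'
#' Within each condition the gene's Ct is normalized to the reference gene
#' (`dCt = Ct_gene - Ct_reference` per replicate); `ddCt` is the difference
#' of condition means and the fold change is `efficiency^(-ddCt)`
#' (knockdown relative to control). The SEM is computed over per-replicate
#' fold-change estimates: replicates are paired by id when the two conditions
#' share the same replicate ids, otherwise each knockdown replicate is
#' compared against the control mean.
#'
#' @param ct A [ct_table()].
#' @param gene Target gene id (must not be the reference gene).
#' @param efficiency Amplification efficiency in fold per cycle (default 2,
#'   perfect doubling).
#' @return An object of class `expression_change` with elements `gene`,
#'   `fold_change`, `sem`, `n_knockdown`, `n_control`, `paired`,
#'   `efficiency`.
#' @export
relative_expression <- function(ct, gene, efficiency = 2) {
  ref <- attr(ct, "reference_gene")
  if (identical(gene, ref)) stopf("'%s' is the reference gene; pick a target gene", gene)
  if (efficiency <= 1) stopf("efficiency must exceed 1 fold per cycle")
  for (cond in CONDITIONS)
    if (!any(ct$gene == gene & ct$condition == cond))
      stopf("gene '%s' has no measurement in condition '%s'", gene, cond)
  d_kd <- .delta_ct(ct, gene, "knockdown")
  d_ct <- .delta_ct(ct, gene, "control")
  ddct <- mean(d_kd) - mean(d_ct)
  fc <- efficiency^(-ddct)
  paired <- length(d_kd) == length(d_ct) && setequal(names(d_kd), names(d_ct))
  ddct_i <- if (paired) d_kd - d_ct[names(d_kd)] else d_kd - mean(d_ct)
  fc_i <- efficiency^(-ddct_i)
  sem <- if (length(fc_i) > 1) stats::sd(fc_i) / sqrt(length(fc_i)) else NA_real_
  structure(list(gene = gene, fold_change = as.numeric(fc), sem = as.numeric(sem),
                 n_knockdown = length(d_kd), n_control = length(d_ct),
                 paired = paired, efficiency = efficiency),
            class = "expression_change")
}

#' @export
print.expression_change <- function(x, ...) {
  cat(sprintf("%s: fold change %.3f (knockdown/control), SEM %s, %d+%d replicates%s\n",
              x$gene, x$fold_change,
              ifelse(is.na(x$sem), "NA", sprintf("%.3f", x$sem)),
              x$n_knockdown, x$n_control, ifelse(x$paired, " (paired)", "")))
  invisible(x)
}

#' Classify an expression response at a fold-change threshold
#'
#' `down` means the mRNA decreased by at least the threshold fraction
#' (fold change `<= 1 - threshold`), `up` that it increased by at least that
#' fraction (`>= 1 + threshold`); both boundaries are inclusive ("at least
#' 20%"). Anything between is `unchanged`.
#'
#' @param change An `expression_change`, or a numeric vector of fold changes.
#' @param threshold Fraction in (0, 1); default 0.20.
#' @return Character vector of `"down"`, `"up"`, `"unchanged"`.
#' @export
classify_response <- function(change, threshold = 0.20) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  fc <- if (inherits(change, "expression_change")) change$fold_change else as.numeric(change)
  if (any(is.na(fc) | fc <= 0)) stopf("fold changes must be positive")
  ifelse(fc <= 1 - threshold, "down", ifelse(fc >= 1 + threshold, "up", "unchanged"))
}

#' Knockdown efficiency of the RNAi target
#'
#' The fold decrease of the target's own mRNA (reciprocal of its relative
#' expression), plus a validity flag for the conventional >= 5-fold bar an
#' effective knockdown should clear.
#'
#' @param ct A [ct_table()].
#' @param target Target gene id.
#' @param efficiency Amplification efficiency (default 2).
#' @param min_fold Fold-decrease bar for the `effective` flag (default 5).
#' @return An object of class `knockdown_efficiency` with elements
#'   `fold_decrease`, `effective` and the underlying `expression_change`.
#' @export
knockdown_efficiency <- function(ct, target, efficiency = 2, min_fold = 5) {
  change <- relative_expression(ct, target, efficiency)
  fd <- 1 / change$fold_change
  # inclusive boundary, robust to roundoff of efficiency^(-ddCt)
  effective <- fd >= min_fold * (1 - 1e-12)
  structure(list(target = target, fold_decrease = fd, effective = effective,
                 min_fold = min_fold, change = change),
            class = "knockdown_efficiency")
}

#' @export
print.knockdown_efficiency <- function(x, ...) {
  cat(sprintf("Knockdown of %s: %.2f-fold mRNA decrease (%s, bar = %.0f-fold)\n",
              x$target, x$fold_decrease,
              ifelse(x$effective, "effective", "NOT effective"), x$min_fold))
  invisible(x)
}

#' Expression-response panel for all assayed genes
#'
#' Runs [relative_expression()] and [classify_response()] for every gene in
#' the table except the reference gene.
#'
#' @param ct A [ct_table()].
#' @param efficiency Amplification efficiency (default 2).
#' @param threshold Classification threshold (default 0.20).
#' @return An object of class `expression_panel`: a data.frame with columns
#'   `gene`, `fold_change`, `sem`, `response`.
#' @export
expression_panel <- function(ct, efficiency = 2, threshold = 0.20) {
  genes <- setdiff(unique(ct$gene), attr(ct, "reference_gene"))
  rows <- lapply(genes, function(g) {
    ch <- relative_expression(ct, g, efficiency)
    data.frame(gene = g, fold_change = ch$fold_change, sem = ch$sem,
               response = classify_response(ch, threshold), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("expression_panel", "data.frame"),
            reference_gene = attr(ct, "reference_gene"),
            efficiency = efficiency, threshold = threshold)
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel (%d genes, reference %s, threshold +/-%.0f%%):\n",
              nrow(x), attr(x, "reference_gene"), 100 * attr(x, "threshold")))
  df <- as.data.frame(x)
  df$fold_change <- sprintf("%.3f", df$fold_change)
  df$sem <- ifelse(is.na(x$sem), "NA", sprintf("%.3f", x$sem))
  print(df, row.names = FALSE)
  tab <- table(factor(x$response, levels = c("down", "up", "unchanged")))
  cat(sprintf("down: %d, up: %d, unchanged: %d\n", tab["down"], tab["up"], tab["unchanged"]))
  invisible(x)
}

#' @export
plot.expression_panel <- function(x, main = "Expression change after knockdown", ...) {
  thr <- attr(x, "threshold")
  col <- c(down = "steelblue", up = "firebrick", unchanged = "grey70")[x$response]
  bp <- barplot(x$fold_change, names.arg = x$gene, las = 2, col = col,
                ylab = "mRNA fold change (knockdown / control)", main = main, ...)
  ok <- !is.na(x$sem)
  if (any(ok))
    arrows(bp[ok], x$fold_change[ok] - x$sem[ok], bp[ok], x$fold_change[ok] + x$sem[ok],
           angle = 90, code = 3, length = 0.03)
  abline(h = c(1 - thr, 1, 1 + thr), lty = c(2, 1, 2), col = "grey40")
  invisible(x)
}
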