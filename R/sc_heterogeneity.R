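# Single-cell qPCR analysis: Ct-to-expression conversion, outlier-cell
# removal, per-gene genotype distribution comparisons (KS / Wilcoxon) and
# heterogeneity summaries.

sc_gene_cols <- function(table) {
  setdiff(names(table), c("cell", "genotype", "plate"))
}

#' Convert a Ct table to log2 expression
#'
#' Expression is `max(0, lod_ct - Ct)`: a reaction at or past the
#' limit-of-detection Ct scores zero, as do failed reactions (the sentinel
#' `failed_ct`, 999 by default).
#'
#' @param ct_table data.frame with columns `cell`, `genotype`, optionally
#'   `plate`, and one Ct column per gene.
#' @param lod_ct limit-of-detection Ct.
#' @param failed_ct sentinel value marking failed reactions.
#' @return a `cell_table`: same shape with expression values; the LOD is
#'   recorded in the `lod_ct` attribute.
#' @export
ct_to_expression <- function(ct_table, lod_ct = 24, failed_ct = 999) {
  genes <- sc_gene_cols(ct_table)
  out <- ct_table
  for (g in genes) {
    ct <- ct_table[[g]]
    if (any(ct < 0, na.rm = TRUE)) stop("negative Ct in assay ", g)
    e <- pmax(0, lod_ct - ct)
    e[ct == failed_ct | is.na(ct)] <- 0
    out[[g]] <- e
  }
  attr(out, "lod_ct") <- lod_ct
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Remove outlier cells
#'
#' Two explicit rules replace the unpublished vendor heuristic: (1) cells
#' detecting fewer than `min_detected_frac` of assays are removed; (2) cells
#' whose median expression deviates from their genotype's median-of-medians
#' by more than `mad_k` robust deviations (MAD) are removed. Removals are
#' returned with reasons.
#'
#' @param table a `cell_table` of expression values.
#' @param min_detected_frac minimum fraction of assays with non-zero
#'   expression.
#' @param mad_k robust-deviation multiplier for the median rule.
#' @return list with `table` (filtered) and `removed` (data.frame cell /
#'   genotype / reason).
#' @export
filter_outlier_cells <- function(table, min_detected_frac = 0.3, mad_k = 3) {
  genes <- sc_gene_cols(table)
  if (any(table(table$genotype) < 4L))
    stop("need >= 4 cells per genotype")
  expr <- as.matrix(table[, genes, drop = FALSE])
  det_frac <- rowMeans(expr > 0)
  cell_med <- apply(expr, 1L, median)
  drop_detect <- det_frac < min_detected_frac
  drop_median <- logical(nrow(table))
  for (gt in unique(table$genotype)) {
    i <- which(table$genotype == gt & !drop_detect)
    if (length(i) < 2L) next
    ctr <- median(cell_med[i])
    s <- mad(cell_med[i])
    if (s > 0) drop_median[i] <- abs(cell_med[i] - ctr) > mad_k * s
  }
  drop <- drop_detect | drop_median
  removed <- data.frame(
    cell = table$cell[drop], genotype = table$genotype[drop],
    reason = ifelse(drop_detect[drop], "low_detection", "median_outlier"),
    stringsAsFactors = FALSE)
  kept <- table[!drop, , drop = FALSE]
  if (any(!unique(table$genotype) %in% kept$genotype))
    stop("outlier filtering removed every cell of a genotype")
  rownames(kept) <- NULL
  list(table = kept, removed = removed)
}

#' Per-gene distribution tests between two genotypes
#'
#' KS and Wilcoxon rank-sum tests on the per-cell expression values of one
#' gene. With fewer than `min_cells` cells in either genotype the result is
#' flagged missing rather than computed.
#'
#' @param table a (filtered) `cell_table`.
#' @param gene gene column name.
#' @param genotypeA,genotypeB genotype labels to compare.
#' @param min_cells minimum cells per genotype.
#' @return list with `ks` and `wilcoxon` `prime_test` results (or `NULL`s
#'   with `insufficient = TRUE`).
#' @export
genotype_distribution_tests <- function(table, gene, genotypeA, genotypeB,
                                        min_cells = 3L) {
  x <- table[[gene]][table$genotype == genotypeA]
  y <- table[[gene]][table$genotype == genotypeB]
  if (length(x) < min_cells || length(y) < min_cells)
    return(list(gene = gene, pair = c(genotypeA, genotypeB),
                ks = NULL, wilcoxon = NULL, insufficient = TRUE))
  list(gene = gene, pair = c(genotypeA, genotypeB),
       ks = ks_two_sample(x, y),
       wilcoxon = wilcoxon_ranksum(x, y),
       insufficient = FALSE)
}

#' Run the distribution tests for every gene and genotype pair
#'
#' @param table a (filtered) `cell_table`.
#' @param reference reference genotype (compared against every other).
#' @return data.frame: gene, pair, KS D and p, Wilcoxon U and p, BH q per
#'   test family.
#' @export
sc_test_table <- function(table, reference = "WT") {
  genes <- sc_gene_cols(table)
  others <- setdiff(unique(table$genotype), reference)
  rows <- list()
  for (gt in others) for (g in genes) {
    r <- genotype_distribution_tests(table, g, reference, gt)
    if (r$insufficient) next
    rows[[paste(gt, g)]] <- data.frame(
      gene = g, genotype = gt, ks_d = r$ks$statistic, ks_p = r$ks$p,
      w_u = r$wilcoxon$statistic, w_p = r$wilcoxon$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ks_q <- bh_adjust(out$ks_p)
  out$w_q <- bh_adjust(out$w_p)
  out
}

#' Per-gene, per-genotype heterogeneity summary
#'
#' Mean, median, IQR and the "off fraction" (fraction of cells at zero
#' expression, the lower mode of a bimodal gene).
#'
#' @param table a (filtered) `cell_table`.
#' @return data.frame with one row per gene x genotype.
#' @export
heterogeneity_summary <- function(table) {
  genes <- sc_gene_cols(table)
  rows <- list()
  for (gt in unique(table$genotype)) {
    sub <- table[table$genotype == gt, , drop = FALSE]
    for (g in genes) {
      v <- sub[[g]]
      rows[[paste(gt, g)]] <- data.frame(
        gene = g, genotype = gt, n_cells = length(v),
        mean = mean(v), median = median(v),
        iqr = unname(quantile(v, 0.75) - quantile(v, 0.25)),
        off_fraction = mean(v == 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom stats mad quantile
NULL
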