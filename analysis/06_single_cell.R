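#!/usr/bin/env Rscript
# Single-cell qPCR heterogeneity: Ct -> log2 expression at LOD Ct 24,
# outlier-cell removal, per-gene KS and Wilcoxon tests of each polycomb
# mutant genotype against wild type, and heterogeneity summaries.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
sim <- simulate_scqpcr_table(cfg)
cells <- ct_to_expression(sim$ct, lod_ct = cfg$lod_ct)
filt <- filter_outlier_cells(cells)
cat(sprintf("removed %d of %d cells (%s)\n", nrow(filt$removed), nrow(cells),
            paste(unique(filt$removed$reason), collapse = ", ")))

tests <- sc_test_table(filt$table)
tests$heterogeneous <- tests$gene %in% sim$truth$gene[sim$truth$heterogeneous]
write.table(tests, res_path("sc_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- heterogeneity_summary(filt$table)
write.table(summ, res_path("sc_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (gt in unique(tests$genotype)) {
  sub <- tests[tests$genotype == gt, ]
  cat(sprintf("%s vs WT: KS q<0.05 for %d/%d heterogeneous and %d/%d housekeeping genes\n",
              gt, sum(sub$ks_q < 0.05 & sub$heterogeneous),
              sum(sub$heterogeneous),
              sum(sub$ks_q < 0.05 & !sub$heterogeneous),
              sum(!sub$heterogeneous)))
}
wt <- summ[summ$genotype == "WT", ]
mt <- summ[summ$genotype == "mutantA", ]
het <- sim$truth$gene[sim$truth$heterogeneous]
cat(sprintf("median IQR at heterogeneous genes: WT %.2f vs mutantA %.2f\n",
            median(wt$iqr[wt$gene %in% het]),
            median(mt$iqr[mt$gene %in% het])))
cat(sprintf("median off-fraction: WT %.2f vs mutantA %.2f\n",
            median(wt$off_fraction[wt$gene %in% het]),
            median(mt$off_fraction[mt$gene %in% het])))
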