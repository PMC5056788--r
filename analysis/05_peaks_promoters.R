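#!/usr/bin/env Rscript
# Broad H3K27me3 domain calling (fixed-lambda Poisson, score cutoff 1000),
# merged across the two populations; TSS +-100 bp peak status per gene;
# peak and CGI enrichment of the detected priming lists.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
g <- simulate_genome(cfg)
chip <- simulate_chip_tracks(g$genes, g$truth, cfg, g$chrom_lengths,
                             which = c("epi_ip", "pren_ip"))
params <- caller_params(genome_size = sum(as.numeric(g$chrom_lengths)))
domains <- merge_domain_sets(call_domains(chip$epi_ip, params),
                             call_domains(chip$pren_ip, params))
write_domains_bed(domains, res_path("h3k27me3_domains.bed"))
flags <- score_tss_peak_status(domains, g$genes, halfwidth = 100L)
write.table(data.frame(gene_id = names(flags), tss_peak = flags),
            res_path("tss_peak_flags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sets <- list(epi_up = read_gene_set(res_path("epi_up.txt")),
             pren_up = read_gene_set(res_path("pren_up.txt")))
cat(sprintf("called %d merged H3K27me3 domains; %.1f%% of all TSSs flagged\n",
            nrow(domains), 100 * mean(flags)))
for (nm in names(sets)) {
  enr <- tss_peak_enrichment(flags, sets[[nm]], g$genes$gene_id)
  cat(sprintf("%-8s TSS peak: %.1f%% of set vs %.1f%% of universe, Fisher p %s\n",
              nm, enr$pct_set, enr$pct_universe, format.pval(enr$test$p)))
}

feats <- promoter_features(g$promoters, g$genes, g$cgis)
write.table(feats, res_path("promoter_features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cgi_fl <- setNames(feats$cgi_overlap, feats$gene_id)
for (nm in names(sets)) {
  enr <- cgi_enrichment(cgi_fl, sets[[nm]], g$genes$gene_id)
  cat(sprintf("%-8s CGI promoters: %.1f%% of set vs %.1f%% of universe, Fisher p %s\n",
              nm, enr$pct_set, enr$pct_universe, format.pval(enr$test$p)))
}
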