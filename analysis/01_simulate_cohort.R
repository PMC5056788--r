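#!/usr/bin/env Rscript
# Build the synthetic cohort: genome annotation, truth labels, promoter
# sequences, expression matrix and single-cell Ct table. Coverage tracks are
# regenerated on demand by the later drivers (they are pure functions of the
# config), so only the light tables are written here.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
cohort <- simulate_cohort(cfg, res_path("cohort"), write_tracks = FALSE)

cat(sprintf("cohort: %d genes on %d chromosomes (%.1f Mb)\n",
            nrow(cohort$genes), length(cohort$chrom_lengths),
            sum(as.numeric(cohort$chrom_lengths)) / 1e6))
print(table(cohort$truth$label))
cat(sprintf("TSS H3K27me3 domains planted: %d genes (%.1f%% of pren_up, %.1f%% of epi_up)\n",
            sum(cohort$truth$has_tss_domain),
            100 * mean(cohort$truth$has_tss_domain[cohort$truth$label == "pren_up"]),
            100 * mean(cohort$truth$has_tss_domain[cohort$truth$label == "epi_up"])))
cat("wrote", length(cohort$files), "files under", res_path("cohort"), "\n")
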