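# Shared settings for the analysis drivers. All scripts regenerate what they
# need from this one configuration: every generator in the package is a pure
# function of (config, seed), so coverage tracks never have to be written to
# disk to be shared between steps.

library(primelens)

analysis_seed <- 20160501L

analysis_config <- function() {
  sim_config(seed = analysis_seed,
             n_genes = 800L, n_chroms = 4L,
             n_epi_up = 112L, n_pren_up = 284L, # 210/533 scaled to 800 genes
             gene_len_median = 8000L, gene_spacing = 6000L)
}

results_dir <- file.path("results", "analysis")
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
res_path <- function(...) file.path(results_dir, ...)
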