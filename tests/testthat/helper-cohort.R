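# Shared fixtures, built in code. The small cohort keeps the planted effect
# structure of the defaults but scales the problem size down (fewer, shorter
# genes) so repeated stochastic checks stay fast.

small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes = 300L, n_chroms = 2L,
               n_epi_up = 40L, n_pren_up = 60L,
               gene_len_median = 5000L, gene_spacing = 4000L,
               sc_n_cells = 40L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# one lazily built small cohort shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- small_config(seed = 42L)
    gen <- simulate_genome(cfg)
    chip <- simulate_chip_tracks(gen$genes, gen$truth, cfg, gen$chrom_lengths)
    .fixture_env$cohort <- c(gen, list(config = cfg, chip = chip))
  }
  .fixture_env$cohort
}

# a tiny deterministic coverage track for toy-genome oracles
toy_track <- function(seed = 7L, chrom_lengths = c(chrA = 4000L, chrB = 2500L),
                      rate = 3) {
  set.seed(seed)
  depth <- lapply(chrom_lengths, function(n) as.numeric(rpois(n, rate)))
  coverage_track(depth, label = "toy")
}

random_gene_table <- function(n, chrom_lengths, min_len = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- sample(min_len:200L, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_lengths[[chrom[i]]] - len[i] - 1L, 1L), integer(1))
  gene_table(paste0("rg", seq_len(n)), paste0("RG", seq_len(n)),
             chrom, start, start + len,
             sample(c("+", "-"), n, replace = TRUE))
}
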