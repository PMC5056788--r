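test_that("all generators are pure functions of the configuration", {
  cfg <- small_config(seed = 7, n_genes = 60L, n_epi_up = 10L, n_pren_up = 15L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)

  ea <- simulate_expression_matrix(a$genes, a$truth, cfg)
  eb <- simulate_expression_matrix(b$genes, b$truth, cfg)
  expect_identical(ea, eb)

  ga <- simulate_groseq_tracks(a$genes, a$truth, cfg, a$chrom_lengths)
  gb <- simulate_groseq_tracks(b$genes, b$truth, cfg, b$chrom_lengths)
  expect_identical(ga, gb)

  sa <- simulate_scqpcr_table(cfg)
  sb <- simulate_scqpcr_table(cfg)
  expect_identical(sa, sb)

  # a track subset reproduces the corresponding tracks of a full run
  full <- simulate_chip_tracks(a$genes, a$truth, cfg, a$chrom_lengths)
  sub <- simulate_chip_tracks(a$genes, a$truth, cfg, a$chrom_lengths,
                              which = "pren_ip")
  expect_identical(sub$pren_ip, full$pren_ip)
})

test_that("the simulated genome respects counts, spacing and feasibility", {
  cfg <- small_config(seed = 8, n_genes = 100L, n_epi_up = 20L,
                      n_pren_up = 30L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 100L)
  expect_equal(sum(g$truth$label == "epi_up"), 20L)
  expect_equal(sum(g$truth$label == "pren_up"), 30L)
  for (ch in unique(g$genes$chrom)) {
    sub <- g$genes[g$genes$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] >=
                        cfg$gene_spacing))
  }
  expect_error(simulate_genome(small_config(n_genes = 100L,
                                            chrom_length = 10000L)),
               "chrom_length")
  expect_error(sim_config(n_genes = 100L, n_epi_up = 80L, n_pren_up = 80L),
               "exceed")
})

test_that("planted TSS-domain counts follow the configured fractions exactly", {
  cfg <- sim_config(seed = 2, n_genes = 1000L, n_chroms = 2L,
                    gene_len_median = 2000L, gene_spacing = 2000L)
  g <- simulate_genome(cfg)
  tab <- table(g$truth$label, g$truth$has_tss_domain)
  # round(frac * class size): the default study counts give 220 of 533
  expect_equal(tab["pren_up", "TRUE"], round(0.413 * 533))
  expect_equal(tab["epi_up", "TRUE"], round(0.195 * 210))
  expect_equal(tab["null", "TRUE"], round(0.10 * (1000 - 533 - 210)))
})

test_that("promoter composition separates CGI from non-CGI promoters", {
  cohort <- small_cohort()
  feats <- promoter_features(cohort$promoters, cohort$genes, cohort$cgis)
  oe <- feats$cpg_oe
  flag <- cohort$truth$cgi
  expect_true(all(oe[flag] > 0.6))
  expect_true(all(oe[!flag] < 0.4))
  expect_gt(median(feats$gc[flag]), median(feats$gc[!flag]))
})

test_that("realized gene-body log-ratio differential recovers the planted value", {
  # averaged over seeds, the epi-minus-pren body log2 difference of primed
  # genes is within +-0.05 of the planted +-0.3
  diffs_epi <- diffs_pren <- numeric(0)
  for (seed in 1:50) {
    cfg <- sim_config(seed = seed, n_genes = 40L, n_chroms = 1L,
                      n_epi_up = 10L, n_pren_up = 10L,
                      gene_len_median = 4000L, gene_len_sdlog = 0.2,
                      gene_spacing = 4000L)
    g <- simulate_genome(cfg)
    chip <- simulate_chip_tracks(g$genes, g$truth, cfg, g$chrom_lengths)
    r <- list(
      epi = window_log2_ratio(chip$epi_ip, chip$epi_input, width = 50),
      pren = window_log2_ratio(chip$pren_ip, chip$pren_input, width = 50))
    # measure over the exact planted differential region [TSS+501, TES]
    s <- lapply(r, stratified_gene_signal, genes = g$genes, body_end_pad = 0L)
    d <- s$epi$body - s$pren$body
    diffs_epi <- c(diffs_epi, d[g$truth$label == "epi_up"])
    diffs_pren <- c(diffs_pren, d[g$truth$label == "pren_up"])
  }
  expect_lt(abs(mean(diffs_epi) - (-0.3)), 0.05)
  expect_lt(abs(mean(diffs_pren) - 0.3), 0.05)
})

test_that("expression matrix plants the configured structure", {
  cfg <- small_config(seed = 9)
  g <- simulate_genome(cfg)
  ex <- simulate_expression_matrix(g$genes, g$truth, cfg)
  ep <- ex$sample_map$sample[ex$sample_map$population == "epi_primed"]
  pp <- ex$sample_map$sample[ex$sample_map$population == "pren_primed"]
  d <- rowMeans(ex$expr[, ep]) - rowMeans(ex$expr[, pp])

  # null genes: planted fold 1 -> expected log-ratio 0
  expect_lt(abs(mean(d[g$truth$label == "null"])), 0.05)
  # planted direction and magnitude
  epi <- g$truth$label == "epi_up"; pren <- g$truth$label == "pren_up"
  expect_equal(mean(d[epi] - g$truth$log2_fold[epi]), 0, tolerance = 0.1)
  expect_equal(mean(d[pren] + g$truth$log2_fold[pren]), 0, tolerance = 0.1)
})

test_that("nascent fold changes are compressed by the configured scale", {
  cfg <- small_config(seed = 10, n_genes = 80L, n_epi_up = 15L,
                      n_pren_up = 15L, gro_depth = 2)
  g <- simulate_genome(cfg)
  gro <- simulate_groseq_tracks(g$genes, g$truth, cfg, g$chrom_lengths)
  body <- lapply(gro, function(t)
    stratified_gene_signal(t, g$genes, body_start_offset = 1L,
                           body_end_pad = 0L)$body)
  lr <- log2(body$epi / body$pren)
  epi <- g$truth$label == "epi_up"; pren <- g$truth$label == "pren_up"
  # gro_fold_scale 0.5: nascent log2 fold is half the steady-state one
  expect_equal(mean(lr[epi] - 0.5 * g$truth$log2_fold[epi]), 0,
               tolerance = 0.1)
  expect_equal(mean(lr[pren] + 0.5 * g$truth$log2_fold[pren]), 0,
               tolerance = 0.1)
  # composite differential sign matches the truth label for >=95% of primed
  sign_ok <- c(lr[epi] > 0, lr[pren] < 0)
  expect_gte(mean(sign_ok), 0.95)
})

test_that("single-cell tables plant WT bimodality and mutant homogenisation", {
  cfg <- small_config(seed = 11)
  sim <- simulate_scqpcr_table(cfg)
  cells <- ct_to_expression(sim$ct, lod_ct = cfg$lod_ct)
  het <- sim$truth$gene[sim$truth$heterogeneous]
  hk <- sim$truth$gene[!sim$truth$heterogeneous]
  wt <- cells[cells$genotype == "WT", ]
  mt <- cells[cells$genotype == "mutantA", ]
  off_wt <- vapply(het, function(g) mean(wt[[g]] == 0), numeric(1))
  off_mt <- vapply(het, function(g) mean(mt[[g]] == 0), numeric(1))
  expect_gt(mean(off_wt), 0.3) # WT off component present
  expect_lt(mean(off_mt), 0.05) # lost in the mutant
  iqr <- function(tab, g) quantile(tab[[g]], 0.75) - quantile(tab[[g]], 0.25)
  expect_gt(median(vapply(het, function(g) iqr(wt, g), numeric(1))),
            median(vapply(het, function(g) iqr(mt, g), numeric(1))))
  # housekeeping genes unimodal and undisturbed
  expect_true(all(vapply(hk, function(g) mean(wt[[g]] == 0), numeric(1)) == 0))
})
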