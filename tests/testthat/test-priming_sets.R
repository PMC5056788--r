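make_expr <- function(n_genes, reps = 3, lfc = NULL, seed = 1, sd = 0.2,
                      pops = c("A", "B")) {
  set.seed(seed)
  base <- rnorm(n_genes, 8, 1)
  samples <- paste(rep(pops, each = reps), 1:reps, sep = "_")
  expr <- sapply(seq_along(samples), function(j) {
    popj <- (j - 1) %/% reps + 1
    eff <- if (popj == 1 && !is.null(lfc)) lfc else 0
    base + eff + rnorm(n_genes, 0, sd)
  })
  dimnames(expr) <- list(paste0("g", seq_len(n_genes)), samples)
  map <- data.frame(sample = samples,
                    population = rep(pops, each = reps),
                    replicate = rep(1:reps, length(pops)))
  list(expr = expr, map = map)
}

test_that("threshold DE calls require both fold and q, with strict bounds", {
  # identical groups: zero calls
  e <- make_expr(200, sd = 0.15, seed = 2)
  de <- threshold_de(e$expr, e$map, "A", "B")
  expect_true(all(de$direction == "ns"))
  expect_true(all(de$q >= de$p))
  # direction consistent with fold-change sign
  expect_true(all(de$fc[de$direction == "up_in_A"] > 1))

  # planted 50 genes at fold 3: >= 45 recovered, <= 2 false calls
  lfc <- c(rep(log2(3), 50), rep(0, 350))
  e2 <- make_expr(400, lfc = lfc, sd = 0.2, seed = 3)
  de2 <- threshold_de(e2$expr, e2$map, "A", "B")
  expect_gte(sum(de2$direction[1:50] == "up_in_A"), 45)
  expect_lte(sum(de2$direction[51:400] != "ns"), 2)

  # a gene exactly at fold 1.5 is not called (strict inequality)
  expr <- matrix(c(rep(log2(3), 3), rep(1, 3)), nrow = 1,
                 dimnames = list("g1", paste0(c("A_", "A_", "A_",
                                                "B_", "B_", "B_"), 1:3)))
  map <- data.frame(sample = colnames(expr),
                    population = rep(c("A", "B"), each = 3))
  deb <- threshold_de(expr, map, "A", "B")
  expect_equal(deb$fc, 1.5)
  expect_equal(deb$direction, "ns")

  expect_error(threshold_de(e$expr[, 1:3], e$map[1:3, ], "A", "B"),
               "replicates|missing")
})

test_that("tightening thresholds never grows a DE list", {
  e <- make_expr(300, lfc = runif(300, -1, 1), sd = 0.3, seed = 4)
  called <- function(fc_min, q_max) {
    de <- threshold_de(e$expr, e$map, "A", "B", fc_min = fc_min,
                       q_max = q_max)
    de$gene_id[de$direction != "ns"]
  }
  loose <- called(1.2, 0.2)
  tight_fc <- called(1.5, 0.2)
  tight_q <- called(1.2, 0.01)
  expect_true(all(tight_fc %in% loose))
  expect_true(all(tight_q %in% loose))
})

test_that("two-stage selection follows the sign-consistency rule", {
  # gene up in stage 1 but discordant in stage 2 is excluded
  set.seed(5)
  reps <- 3
  samples <- paste(rep(c("epi_primed", "pren_primed", "differentiated"),
                       each = reps), 1:reps, sep = "_")
  map <- data.frame(sample = samples,
                    population = rep(c("epi_primed", "pren_primed",
                                       "differentiated"), each = reps))
  noise <- function() rnorm(reps, 0, 0.05)
  expr <- rbind(
    g_ok = c(9 + noise(), 8 + noise(), 8 + noise()),   # up in epi, epi>pren
    g_bad = c(9 + noise(), 9.8 + noise(), 8 + noise()), # up in epi, epi<pren
    g_null = c(8 + noise(), 8 + noise(), 8 + noise()))
  colnames(expr) <- samples
  out <- two_stage_priming_lists(expr, map)
  expect_equal(out$epi_up$genes, "g_ok")
  expect_length(out$pren_up$genes, 0)

  # invariant to gene and sample column order
  perm_g <- c(3, 1, 2); perm_s <- sample(ncol(expr))
  out2 <- two_stage_priming_lists(expr[perm_g, perm_s],
                                  map[perm_s, ])
  expect_setequal(out2$epi_up$genes, out$epi_up$genes)

  expect_error(two_stage_priming_lists(expr, map, pren = "missing_pop"),
               "missing")
})

test_that("two-stage selection recovers planted labels on the synthetic cohort", {
  cfg <- small_config(seed = 12)
  g <- simulate_genome(cfg)
  ex <- simulate_expression_matrix(g$genes, g$truth, cfg)
  out <- two_stage_priming_lists(ex$expr, ex$sample_map)
  truth_epi <- g$truth$gene_id[g$truth$label == "epi_up"]
  truth_pren <- g$truth$gene_id[g$truth$label == "pren_up"]
  called <- c(out$epi_up$genes, out$pren_up$genes)
  sens <- (sum(out$epi_up$genes %in% truth_epi) +
           sum(out$pren_up$genes %in% truth_pren)) /
    (length(truth_epi) + length(truth_pren))
  fdr <- mean(!called %in% c(truth_epi, truth_pren))
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("null cohorts yield nearly empty two-stage lists", {
  sizes <- vapply(1:10, function(seed) {
    cfg <- small_config(seed = seed, n_genes = 200L, n_epi_up = 0L,
                        n_pren_up = 0L)
    g <- simulate_genome(cfg)
    ex <- simulate_expression_matrix(g$genes, g$truth, cfg)
    out <- two_stage_priming_lists(ex$expr, ex$sample_map)
    length(out$epi_up$genes) + length(out$pren_up$genes)
  }, numeric(1))
  expect_lte(mean(sizes), 0.05 * 200)
})

test_that("RPKM calls floor low-expressed genes and use the ratio rule", {
  rpkm <- data.frame(gene_id = c("a", "b", "c", "d"),
                     A = c(0.4, 10, 10, 3), B = c(0.3, 4, 6, 0.2))
  out <- rpkm_de(rpkm)
  expect_false("a" %in% out$gene_id) # both below floor
  expect_equal(out$direction[out$gene_id == "b"], "up_in_A") # ratio 2.5
  expect_equal(out$direction[out$gene_id == "c"], "ns")      # ratio 1.67
  expect_equal(out$direction[out$gene_id == "d"], "up_in_A")
  expect_error(rpkm_de(data.frame(gene_id = "x", A = -1, B = 2)), ">= 0")
})

test_that("nascent/steady consistency is sign-matched intersection", {
  steady <- data.frame(gene_id = paste0("g", 1:10),
                       direction = c("up_in_A", "up_in_A", "up_in_B", "ns",
                                     "up_in_A", "up_in_B", "ns", "up_in_B",
                                     "up_in_A", "ns"))
  nascent <- data.frame(gene_id = paste0("g", 1:10),
                        direction = c("up_in_A", "up_in_B", "up_in_B", "ns",
                                      "ns", "up_in_B", "up_in_A", "up_in_A",
                                      "up_in_A", "up_in_B"))
  out <- consistent_nascent_steady(steady, nascent)
  # brute-force oracle
  up_a <- intersect(steady$gene_id[steady$direction == "up_in_A"],
                    nascent$gene_id[nascent$direction == "up_in_A"])
  up_b <- intersect(steady$gene_id[steady$direction == "up_in_B"],
                    nascent$gene_id[nascent$direction == "up_in_B"])
  expect_setequal(out$up_in_A$genes, up_a)
  expect_setequal(out$up_in_B$genes, up_b)
  expect_error(consistent_nascent_steady(
    steady, data.frame(gene_id = "zz", direction = "ns")), "disjoint")
})

test_that("PRC2 target classification is the stated conjunction", {
  set.seed(6)
  for (i in 1:10) {
    ids <- paste0("g", 1:30)
    flags <- setNames(runif(30) < 0.4, ids)
    eed <- gene_set("eed_up", sample(ids, 12))
    out <- classify_prc2_targets(flags, eed)
    expect_setequal(out$genes, ids[flags & ids %in% eed$genes])
  }
})

test_that("gene-set overlap builds the right 2x2 table and Fisher p", {
  uni <- paste0("g", 1:1000)
  a <- gene_set("A", uni[1:10]); b <- gene_set("B", uni[11:20])
  r <- list_overlap_fisher(a, b, uni)
  expect_equal(r$overlap, 0)
  expect_equal(unname(r$table["notA", "notB"]), 980)

  r2 <- list_overlap_fisher(a, a, uni)
  expect_equal(r2$overlap, 10)
  expect_lt(r2$test$p, 1e-20)
  expect_equal(r2$test$p, fisher.test(r2$table)$p.value, tolerance = 1e-9)

  expect_error(list_overlap_fisher(gene_set("x", "not_here"), b, uni),
               "universe")
})

test_that("gene sets round-trip through their text format", {
  s <- gene_set("demo", c("g3", "g1", "g2"),
                provenance = list(fc_min = 1.5, q_max = 0.05))
  f <- tempfile(fileext = ".txt")
  write_gene_set(s, f)
  back <- read_gene_set(f)
  expect_equal(back$label, "demo")
  expect_equal(back$genes, s$genes)
})
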