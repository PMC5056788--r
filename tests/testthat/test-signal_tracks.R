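test_that("window log-ratios match a per-window recomputation from raw depth", {
  tr <- toy_track(seed = 1)
  # identical tracks: all ratios zero (scale factor 1)
  r0 <- window_log2_ratio(tr, tr, width = 50)
  expect_true(all(abs(unlist(r0$values)) < 1e-12))

  # 4x IP in one window with a large pseudocount-free depth
  ip <- coverage_track(list(c1 = rep(c(10, 40, 10), each = 50)), "ip")
  inp <- coverage_track(list(c1 = rep(10, 150)), "input")
  r1 <- window_log2_ratio(ip, inp, width = 50, pseudocount = 0.001,
                          normalize = FALSE)
  expect_equal(r1$values$c1[2], 2, tolerance = 1e-3)

  # brute-force oracle on random unequal tracks, including the partial
  # terminal window
  set.seed(3)
  ipr <- toy_track(seed = 4, chrom_lengths = c(cc = 1037L), rate = 5)
  inr <- toy_track(seed = 5, chrom_lengths = c(cc = 1037L), rate = 4)
  r <- window_log2_ratio(ipr, inr, width = 50, pseudocount = 1,
                         normalize = FALSE)
  for (w in seq_along(r$values$cc)) {
    a <- (w - 1) * 50 + 1
    b <- min(w * 50, 1037)
    expect_equal(r$values$cc[w],
                 log2((sum(ipr$depth$cc[a:b]) + 1) /
                      (sum(inr$depth$cc[a:b]) + 1)))
  }
  expect_length(r$values$cc, ceiling(1037 / 50))
})

test_that("median pair normalisation equalises non-zero window-sum medians", {
  tr <- toy_track(seed = 6)
  expect_equal(median_pair_normalize(tr, tr)$scale, 1)

  dbl <- tr
  dbl$depth <- lapply(tr$depth, `*`, 2)
  n <- median_pair_normalize(tr, dbl)
  expect_equal(n$scale, 0.5)

  ipr <- toy_track(seed = 7, rate = 6)
  n2 <- median_pair_normalize(ipr, tr, width = 50)
  med <- function(t) {
    w <- unlist(lapply(t$depth, window_sums, width = 50))
    median(w[w > 0])
  }
  expect_equal(med(n2$ip), med(n2$input), tolerance = 1e-9)

  zero <- coverage_track(list(chrA = numeric(4000), chrB = numeric(2500)), "z")
  expect_error(median_pair_normalize(zero, tr), "all-zero")
})

test_that("quantile normalisation equalises distributions, keeps ranks, is idempotent", {
  expect_equal(quantile_normalize(list(a = c(1, 2, 3), b = c(1, 2, 3))),
               list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(quantile_normalize(list(c(1, 2, 3), c(4, 5, 6))),
               list(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  set.seed(8)
  x <- matrix(rnorm(400), ncol = 4)
  q <- quantile_normalize(x)
  for (j in 2:4) expect_equal(sort(q[, j]), sort(q[, 1]))
  for (j in 1:4) expect_equal(rank(q[, j]), rank(x[, j]))
  expect_equal(quantile_normalize(q), q)

  if (requireNamespace("limma", quietly = TRUE)) {
    expect_equal(unname(q), unname(limma::normalizeQuantiles(x)),
                 tolerance = 1e-12)
  }
})

test_that("TSS matrix has the stated shape and strand orientation", {
  lens <- c(chrA = 20000L)
  genes <- gene_table(c("p", "m"), c("P", "M"), "chrA",
                      c(6000L, 12000L), c(9000L, 15000L), c("+", "-"))
  flat <- coverage_track(list(chrA = rep(2, 20000)), "flat")
  m0 <- tss_signal_matrix(flat, genes)
  expect_equal(ncol(m0), 50)
  expect_true(all(m0 == 2))

  # signal planted strictly downstream of each TSS lands in columns 26-50
  depth <- rep(0, 20000)
  depth[(genes$tss[1] + 1):(genes$tss[1] + 2500)] <- 1  # + strand: after TSS
  depth[(genes$tss[2] - 2499):(genes$tss[2] + 1)] <- 1  # - strand: before TSS
  tr <- coverage_track(list(chrA = depth), "planted")
  m <- tss_signal_matrix(tr, genes)
  for (i in 1:2) {
    expect_true(all(m[i, 26:50] > 0.9), info = rownames(m)[i])
    expect_true(all(m[i, 1:25] < 0.1), info = rownames(m)[i])
  }

  off <- gene_table("o", "O", "chrA", 20050L, 20100L, "+")
  expect_error(tss_signal_matrix(flat, rbind(genes, off)), "off chromosome")
  expect_error(tss_signal_matrix(flat, genes, flank = 2500, bin = 300),
               "divisible")
})

test_that("meta-gene bins cover flanks and body as planted", {
  lens <- c(chrA = 30000L)
  genes <- gene_table(c("p", "m"), c("P", "M"), "chrA",
                      c(8000L, 20000L), c(12000L, 24000L), c("+", "-"))
  flat <- coverage_track(list(chrA = rep(3, 30000)), "flat")
  mm0 <- metagene_matrix(flat, genes)
  expect_true(all(abs(mm0 - 3) < 1e-12))

  # enrichment on the body only -> elevated in bins 11-30 at defaults
  depth <- rep(0, 30000)
  for (i in 1:2) depth[(genes$start[i] + 1):genes$end[i]] <- 1
  tr <- coverage_track(list(chrA = depth), "body")
  mm <- metagene_matrix(tr, genes)
  for (i in 1:2) {
    expect_true(all(mm[i, 11:30] > 0.99))
    expect_true(all(mm[i, c(1:10, 31:40)] < 0.01))
  }

  # a 4 kb gene at defaults: each bin covers 200 bp
  g4 <- gene_table("g4", "G4", "chrA", 10000L, 14000L, "+")
  b <- primelens:::oriented_bins(10000, -2000, 4000 + 2000, "+", 40)
  expect_true(all(b[, 2] - b[, 1] == 200))

  # genes shorter than n_bins are flagged missing
  short <- gene_table("s", "S", "chrA", 100L, 130L, "+")
  ms <- metagene_matrix(flat, short)
  expect_true(all(is.na(ms)))
  expect_equal(attr(ms, "short_genes"), "s")
})

test_that("stratified signal equals per-base brute force in oriented coordinates", {
  lens <- c(chrA = 60000L)
  set.seed(9)
  tr <- toy_track(seed = 9, chrom_lengths = lens, rate = 4)
  v <- tr$depth$chrA
  const <- coverage_track(list(chrA = rep(7, 60000)), "const")

  genes <- random_gene_table(100, c(chrA = 50000L), min_len = 600L, seed = 10)
  genes$start <- genes$start + 5000L # keep strata on-chromosome
  genes$end <- genes$end + 5000L
  genes <- gene_table(genes$gene_id, genes$symbol, genes$chrom,
                      genes$start, genes$end, genes$strand)

  s_const <- stratified_gene_signal(const, genes)
  expect_true(all(abs(s_const$upstream - 7) < 1e-12))
  expect_true(all(abs(s_const$tss - 7) < 1e-12))
  expect_true(all(abs(s_const$body[s_const$body_defined] - 7) < 1e-12))

  s <- stratified_gene_signal(tr, genes)
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]; L <- genes$end[i] - genes$start[i]
    orient <- function(o1, o2) { # oriented half-open offsets -> 1-based bases
      if (genes$strand[i] == "+") (tss + o1 + 1):(tss + o2)
      else (tss - o2 + 2):(tss - o1 + 1)
    }
    expect_equal(s$tss[i], mean(v[orient(-500, 500)]))
    expect_equal(s$upstream[i], mean(v[orient(-2000, -500)]))
    if (L > 501) {
      expect_equal(s$body[i], mean(v[orient(501, L + 2000)]))
      # a 1,000 bp gene's body region spans 2,499 bases
      expect_equal(length(orient(501, L + 2000)), L + 1499)
    } else {
      expect_false(s$body_defined[i])
    }
  }
})

test_that("differential composite is the per-bin mean difference", {
  a <- matrix(rnorm(12), 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  attr(a, "anchor") <- list(type = "metagene", n_bins = 4)
  b <- a + 1
  attr(b, "anchor") <- attr(a, "anchor")
  expect_equal(differential_composite(a, a)$profile, rep(0, 4))
  expect_equal(differential_composite(b, a)$profile, rep(1, 4))
  expect_equal(differential_composite(a, b)$profile, rep(-1, 4))

  # hand computation on a 3-gene, 4-bin toy with a missing cell
  a2 <- matrix(c(1, 2, 3,
                 4, 5, 6,
                 7, 8, 9,
                 10, 11, 12), nrow = 3,
               dimnames = list(c("x", "y", "z"), NULL))
  b2 <- matrix(0, 3, 4, dimnames = dimnames(a2))
  a2[2, 1] <- NA
  attr(a2, "anchor") <- attr(b2, "anchor") <- list(type = "toy")
  d <- differential_composite(a2, b2)
  expect_equal(d$profile, c(mean(c(1, 3)), 5, 8, 11))
  expect_error(differential_composite(a2, b2[c(2, 1, 3), ]), "row")
})

test_that("genome strata are disjoint, exhaustive, and match per-base labels", {
  # no genes: everything intergenic
  tr <- toy_track(seed = 11, chrom_lengths = c(c1 = 5000L))
  empty_genes <- gene_table(character(0), character(0), character(0),
                            integer(0), integer(0), character(0))
  s0 <- genome_strata_fractions(tr, empty_genes, data.frame(
    chrom = character(0), start = integer(0), end = integer(0)))
  expect_equal(s0$fraction[s0$stratum == "intergenic"], 1)

  # 10 kb toy genome with one CGI gene and one non-CGI gene
  lens <- c(c1 = 10000L)
  genes <- gene_table(c("a", "b"), c("A", "B"), "c1", c(2000L, 7000L),
                      c(3000L, 8000L), c("+", "-"))
  cgis <- data.frame(chrom = "c1", start = 1900L, end = 2100L)
  tr2 <- toy_track(seed = 12, chrom_lengths = lens)
  s <- genome_strata_fractions(tr2, genes, cgis, tss_halfwidth = 500L)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s$bases), 10000)

  # brute-force per-base labelling
  lab <- rep("intergenic", 10000)
  for (i in 1:2) lab[(genes$start[i] + 1):genes$end[i]] <- "intragenic"
  for (i in 1:2) {
    w <- (genes$tss[i] - 500):(genes$tss[i] + 500) + 1
    in_cgi <- genes$tss[i] >= cgis$start & genes$tss[i] < cgis$end
    lab[w] <- if (in_cgi) "tss_cgi" else "tss_noncgi"
  }
  v <- tr2$depth$c1
  for (st in s$stratum) {
    expect_equal(s$bases[s$stratum == st], sum(lab == st), info = st)
    expect_equal(s$signal[s$stratum == st], sum(v[lab == st]), info = st)
  }
  expect_equal(s$depth_per_10M, s$signal * 1e7 / tr2$total_mapped)
})

test_that("gene-anchored matrices are strand-equivariant under genome mirroring", {
  lens <- c(m1 = 9000L)
  tr <- toy_track(seed = 13, chrom_lengths = lens, rate = 3)
  genes <- random_gene_table(30, c(m1 = 3000L), min_len = 100L, seed = 14)
  genes <- gene_table(genes$gene_id, genes$symbol, genes$chrom,
                      genes$start + 3000L, genes$end + 3000L, genes$strand)

  mirror_pos <- function(p) 9000L - 1L - p
  m_genes <- gene_table(genes$gene_id, genes$symbol, genes$chrom,
                        9000L - genes$end, 9000L - genes$start,
                        ifelse(genes$strand == "+", "-", "+"))
  m_tr <- coverage_track(list(m1 = rev(tr$depth$m1)), "mirror")
  expect_equal(m_genes$tss, mirror_pos(genes$tss))

  expect_equal(tss_signal_matrix(m_tr, m_genes, flank = 1000, bin = 100),
               tss_signal_matrix(tr, genes, flank = 1000, bin = 100))
  expect_equal(metagene_matrix(m_tr, m_genes, n_bins = 20),
               metagene_matrix(tr, genes, n_bins = 20))
  expect_equal(stratified_gene_signal(m_tr, m_genes),
               stratified_gene_signal(tr, genes))
})

test_that("window-track and per-base stratified summaries agree to window error", {
  cohort <- small_cohort()
  ratio <- window_log2_ratio(cohort$chip$epi_ip, cohort$chip$epi_input,
                             width = 50)
  genes <- cohort$genes[1:20, ]
  s_win <- stratified_gene_signal(ratio, genes)
  # brute force: expand window values to per-base and average directly
  pb <- primelens:::base_values(ratio)
  for (i in seq_len(nrow(genes))) {
    v <- pb[[genes$chrom[i]]]
    tss <- genes$tss[i]; L <- genes$end[i] - genes$start[i]
    idx <- if (genes$strand[i] == "+") (tss + 501 + 1):(tss + L + 2000)
           else (tss - (L + 2000) + 2):(tss - 501 + 1)
    expect_equal(s_win$body[i], mean(v[idx]), tolerance = 1e-12)
  }
})
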