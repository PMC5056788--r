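# Synthetic cohort generator: genome annotation, promoter sequences,
# ChIP/GRO coverage, expression matrices and single-cell tables with planted
# effects matching the statistical structure the analysis assumes, plus
# ground-truth labels for parameter-recovery tests.
#
# Two interconverting ESC populations are emulated: "epi" (epiblast-primed)
# and "pren" (primitive-endoderm-primed), plus a spontaneously
# differentiated population for the expression arm. The planted structure:
#  * a few hundred genes with small (>= 1.5-fold) reciprocal expression
#    differences between the primed populations;
#  * ChIP coverage with population-invariant TSS H3K27me3 domains planted at
#    a higher fraction of pren-priming genes, and gene-body log-ratio
#    differences anti-correlated with transcription;
#  * nascent (GRO) coverage with fold changes compressed relative to
#    steady-state RNA;
#  * single-cell tables where mutant genotypes lose the bimodality/spread of
#    heterogeneous genes.

#' Build a simulation configuration
#'
#' All planted effect sizes and fractions default to the study conditions the
#' cohort emulates: 210 epiblast-priming and 533 primitive-endoderm-priming
#' genes, steady-state folds of 1.5-3, nascent folds compressed by 0.5, TSS
#' H3K27me3 domain fractions 41.3% / 19.5% for the two priming sets, and a
#' gene-body log2 IP/Input difference of 0.3 anti-correlated with
#' transcription. Problem-size knobs (`n_genes`, `n_chroms`, gene lengths)
#' scale the cohort without touching the planted effects.
#'
#' @param seed integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param n_genes,n_chroms cohort size.
#' @param chrom_length bases per chromosome; `NULL` sizes chromosomes
#'   automatically to fit the genes with the required spacing.
#' @param n_epi_up,n_pren_up planted priming-set sizes.
#' @param expr_fold range of steady-state fold changes (linear scale).
#' @param gro_fold_scale multiplier < 1 compressing nascent fold changes.
#' @param tss_peak_frac_pren,tss_peak_frac_epi,tss_peak_frac_null fraction of
#'   each gene class carrying a planted (population-invariant) TSS H3K27me3
#'   domain.
#' @param body_delta planted gene-body log2(IP/Input) difference (log2
#'   units), anti-correlated with transcription.
#' @param depth_mean mean per-base background read depth.
#' @param body_base baseline gene-body IP enrichment multiplier.
#' @param tss_amp TSS-domain IP amplitude multiplier (identical in both
#'   populations by construction). The default puts a planted domain's
#'   per-window Poisson score far above the caller's score-1000 cutoff
#'   (window mean ~290 tags against a background of ~16) so that planted
#'   domains are unambiguous peaks, while unenriched windows score near 0.
#' @param tss_domain_halfwidth half-width of planted TSS domains in bases.
#' @param gene_len_median,gene_len_sdlog,gene_len_min log-normal gene-length
#'   distribution (median ~20 kb) and lower truncation.
#' @param gene_spacing minimum gap between genes in bases.
#' @param cgi_frac_null,cgi_frac_epi,cgi_frac_pren fraction of each class
#'   with a CpG island over the TSS.
#' @param cgi_halfwidth CGI half-width in bases.
#' @param promoter_flank promoter window half-width for emitted FASTA.
#' @param expr_baseline_mean,expr_baseline_sd,expr_rep_sd log2 expression
#'   baseline distribution and replicate noise (log2 units).
#' @param n_replicates replicates per population for the expression matrix.
#' @param gro_depth,gro_background per-base nascent coverage over gene bodies
#'   and elsewhere.
#' @param sc_n_cells,sc_het_genes,sc_hk_genes single-cell table sizes.
#' @param sc_off_prob,sc_on_mean,sc_on_sd wild-type two-component mixture for
#'   heterogeneous genes (off component at the detection floor; on-component
#'   mean gap in log2 units).
#' @param sc_mut_shift,sc_mut_sd mutant single-component shift and spread.
#' @param sc_hk_mean,sc_hk_sd housekeeping expression distribution.
#' @param lod_ct limit-of-detection Ct used when emitting single-cell Ct
#'   values.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_chroms = 4L,
                       chrom_length = NULL,
                       n_epi_up = 210L, n_pren_up = 533L,
                       expr_fold = c(1.5, 3),
                       gro_fold_scale = 0.5,
                       tss_peak_frac_pren = 0.413, tss_peak_frac_epi = 0.195,
                       tss_peak_frac_null = 0.10,
                       body_delta = 0.3,
                       depth_mean = 2, body_base = 1.5, tss_amp = 20,
                       tss_domain_halfwidth = 1000L,
                       gene_len_median = 20000L, gene_len_sdlog = 0.5,
                       gene_len_min = 1000L, gene_spacing = 10000L,
                       cgi_frac_null = 0.55, cgi_frac_epi = 0.75,
                       cgi_frac_pren = 0.85, cgi_halfwidth = 300L,
                       promoter_flank = 500L,
                       expr_baseline_mean = 8, expr_baseline_sd = 1.5,
                       expr_rep_sd = 0.25, n_replicates = 4L,
                       gro_depth = 0.5, gro_background = 0.05,
                       sc_n_cells = 60L, sc_het_genes = 20L, sc_hk_genes = 8L,
                       sc_off_prob = 0.45, sc_on_mean = 4, sc_on_sd = 1.2,
                       sc_mut_shift = 1, sc_mut_sd = 0.6,
                       sc_hk_mean = 10, sc_hk_sd = 0.5,
                       lod_ct = 24) {
  cfg <- as.list(environment())
  fracs <- c(tss_peak_frac_pren, tss_peak_frac_epi, tss_peak_frac_null,
             cgi_frac_null, cgi_frac_epi, cgi_frac_pren, sc_off_prob,
             gro_fold_scale)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_genes < 1L || n_chroms < 1L || n_epi_up < 0L || n_pren_up < 0L)
    stop("counts must be positive")
  if (n_epi_up + n_pren_up > n_genes)
    stop("n_epi_up + n_pren_up must not exceed n_genes")
  if (length(expr_fold) != 2L || any(expr_fold < 1))
    stop("expr_fold must be a range of folds >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate the cohort genome: genes, truth labels, CGIs, promoters
#'
#' Deterministic given the configuration seed. Gene lengths are log-normal
#' (median `gene_len_median`); genes are placed non-overlapping with at
#' least `gene_spacing` bases between them. Priming labels, TSS-domain
#' flags, planted fold changes and CGI flags are drawn here and recorded in
#' the truth table. Promoter sequences (TSS +- `promoter_flank`) have high
#' CpG observed/expected where a CGI is planted and CpG-depleted composition
#' otherwise.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene table), `truth` (per-gene truth table),
#'   `cgis` (interval data.frame), `promoters` (named character vector of
#'   sequences) and `chrom_lengths`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed + 11L)
  n <- config$n_genes
  len <- pmax(config$gene_len_min,
              round(rlnorm(n, log(config$gene_len_median),
                           config$gene_len_sdlog)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- rep(seq_len(config$n_chroms), length.out = n)[order(runif(n))]
  chroms <- paste0("chr", seq_len(config$n_chroms))
  start <- integer(n)
  chrom_lengths <- setNames(integer(config$n_chroms), chroms)
  sp <- config$gene_spacing
  for (ci in seq_len(config$n_chroms)) {
    idx <- which(chrom_of == ci)
    pos <- sp
    for (i in idx) {
      start[i] <- pos
      pos <- pos + len[i] + sp
    }
    need <- pos
    if (!is.null(config$chrom_length)) {
      if (need > config$chrom_length)
        stop("cannot place genes: increase chrom_length to at least ", need)
      chrom_lengths[ci] <- config$chrom_length
    } else {
      chrom_lengths[ci] <- need
    }
  }
  genes <- gene_table(sprintf("g%05d", seq_len(n)),
                      sprintf("G%05d", seq_len(n)),
                      chroms[chrom_of], start, start + len, strand)

  label <- rep("null", n)
  planted <- sample.int(n, config$n_epi_up + config$n_pren_up)
  label[planted[seq_len(config$n_epi_up)]] <- "epi_up"
  label[planted[config$n_epi_up + seq_len(config$n_pren_up)]] <- "pren_up"
  tss_frac <- c(epi_up = config$tss_peak_frac_epi,
                pren_up = config$tss_peak_frac_pren,
                null = config$tss_peak_frac_null)
  # exact planted counts per class: round(frac * class size), membership drawn
  has_tss <- logical(n)
  for (cls in names(tss_frac)) {
    idx <- which(label == cls)
    k <- round(tss_frac[[cls]] * length(idx))
    if (k > 0L) has_tss[idx[sample.int(length(idx), k)]] <- TRUE
  }
  # planted epi-minus-pren body log2 difference: H3K27me3 is lower in the
  # population where the gene is transcriptionally up
  body_diff <- ifelse(label == "epi_up", -config$body_delta,
                      ifelse(label == "pren_up", config$body_delta, 0))
  lf <- runif(n, log2(config$expr_fold[1]), log2(config$expr_fold[2]))
  log2_fold <- ifelse(label == "null", 0, lf)
  cgi_frac <- c(epi_up = config$cgi_frac_epi, pren_up = config$cgi_frac_pren,
                null = config$cgi_frac_null)
  cgi <- runif(n) < cgi_frac[label]
  truth <- data.frame(gene_id = genes$gene_id, label = label,
                      has_tss_domain = as.logical(has_tss),
                      body_diff = body_diff, log2_fold = log2_fold,
                      cgi = as.logical(cgi), stringsAsFactors = FALSE)
  cgis <- merge_intervals(data.frame(
    chrom = genes$chrom[cgi],
    start = pmax(genes$tss[cgi] - config$cgi_halfwidth, 0L),
    end = genes$tss[cgi] + config$cgi_halfwidth + 1L))
  promoters <- simulate_promoter_seqs(n, cgi, config)
  names(promoters) <- genes$gene_id
  list(genes = genes, truth = truth, cgis = cgis, promoters = promoters,
       chrom_lengths = chrom_lengths)
}

# First-order Markov sequence generator. CGI promoters: GC-rich with no CpG
# suppression (o/e ~ 1); non-CGI: AT-richer with CpG transitions suppressed.
simulate_promoter_seqs <- function(n, cgi, config) {
  width <- 2L * config$promoter_flank
  bases <- c("A", "C", "G", "T")
  gen <- function(count, gc, cpg_factor) {
    if (count == 0L) return(character(0))
    p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    pC <- p0; pC[3] <- pC[3] * cpg_factor; pC <- pC / sum(pC)
    cum0 <- cumsum(p0); cumC <- cumsum(pC)
    m <- matrix(0L, nrow = count, ncol = width)
    prev_is_c <- logical(count)
    for (j in seq_len(width)) {
      u <- runif(count)
      pick0 <- 1L + findInterval(u, cum0, rightmost.closed = TRUE)
      pickC <- 1L + findInterval(u, cumC, rightmost.closed = TRUE)
      pick <- ifelse(prev_is_c, pickC, pick0)
      pick <- pmin(pick, 4L)
      m[, j] <- pick
      prev_is_c <- pick == 2L
    }
    apply(m, 1L, function(row) paste(bases[row], collapse = ""))
  }
  out <- character(n)
  out[cgi] <- gen(sum(cgi), gc = 0.65, cpg_factor = 1)
  out[!cgi] <- gen(sum(!cgi), gc = 0.40, cpg_factor = 0.08)
  out
}

#' Simulate H3K27me3 ChIP coverage tracks
#'
#' Input tracks are Poisson background at `depth_mean` per base. IP tracks
#' add (i) TSS domains (TSS +- `tss_domain_halfwidth`, amplitude `tss_amp`)
#' identical in both populations for genes with a planted domain, and (ii)
#' gene-body enrichment whose planted between-population log2 difference
#' equals the truth table's `body_diff` (epi minus pren): negative for
#' epi-priming genes, positive for pren-priming genes, zero for null genes.
#' The differential is confined to the body beyond TSS+500 (strand-aware),
#' leaving the TSS-proximal signal invariant between populations.
#' Each track has its own seed offset, so any subset of tracks reproduces
#' the corresponding tracks of a full run.
#'
#' @param genes,truth,chrom_lengths from [simulate_genome()].
#' @param config a [sim_config()].
#' @param which which tracks to generate (subset of
#'   `c("epi_ip", "epi_input", "pren_ip", "pren_input")`).
#' @return named list of `coverage_track` objects.
#' @export
simulate_chip_tracks <- function(genes, truth, config, chrom_lengths,
                                 which = c("epi_ip", "epi_input",
                                           "pren_ip", "pren_input")) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  all_tracks <- c("epi_ip", "epi_input", "pren_ip", "pren_input")
  which <- match.arg(which, all_tracks, several.ok = TRUE)
  out <- list()
  for (tr in which) {
    set.seed(config$seed + 17L + match(tr, all_tracks))
    pop <- sub("_.*", "", tr)
    is_ip <- grepl("_ip$", tr)
    depth <- list()
    for (ch in names(chrom_lengths)) {
      len <- chrom_lengths[[ch]]
      if (!is_ip) {
        depth[[ch]] <- rpois(len, config$depth_mean) # integer storage
        next
      }
      rate <- rep(config$depth_mean, len)
      g <- which(genes$chrom == ch)
      pop_sign <- if (pop == "epi") 0.5 else -0.5
      for (i in g) {
        a <- genes$start[i] + 1L; b <- genes$end[i]
        rate[a:b] <- rate[a:b] * config$body_base
        # population differential confined to the body beyond TSS+500 so the
        # TSS-proximal signal stays invariant between populations
        L <- genes$end[i] - genes$start[i]
        if (L > 501L && truth$body_diff[i] != 0) {
          if (genes$strand[i] == "+") {
            da <- genes$start[i] + 501L + 1L; db <- genes$end[i]
          } else {
            da <- genes$start[i] + 1L; db <- genes$end[i] - 501L
          }
          rate[da:db] <- rate[da:db] * 2^(pop_sign * truth$body_diff[i])
        }
      }
      for (i in g[truth$has_tss_domain[g]]) {
        a <- max(genes$tss[i] - config$tss_domain_halfwidth, 0L) + 1L
        b <- min(genes$tss[i] + config$tss_domain_halfwidth + 1L, len)
        rate[a:b] <- rate[a:b] * config$tss_amp
      }
      depth[[ch]] <- rpois(len, rate) # integer storage
    }
    out[[tr]] <- coverage_track(depth, label = tr)
  }
  out
}

#' Simulate the steady-state expression matrix
#'
#' Log2 intensities with a per-gene log-normal baseline. Epiblast-priming
#' genes are elevated in the epiblast-primed population; PrEn-priming genes
#' in the PrEn-primed and fully differentiated populations; folds are the
#' truth table's planted `log2_fold`. Replicate noise is Gaussian with sd
#' `expr_rep_sd` log2 units.
#'
#' @param genes,truth from [simulate_genome()].
#' @param config a [sim_config()].
#' @param n_replicates replicates per population (config default if NULL).
#' @param populations three population labels, in the order epiblast-primed,
#'   PrEn-primed, differentiated.
#' @return list with `expr` (genes x samples log2 matrix) and `sample_map`
#'   (data.frame sample/population/replicate).
#' @export
simulate_expression_matrix <- function(genes, truth, config,
                                       n_replicates = NULL,
                                       populations = c("epi_primed",
                                                       "pren_primed",
                                                       "differentiated")) {
  if (length(populations) != 3L) stop("exactly three population labels")
  if (is.null(n_replicates)) n_replicates <- config$n_replicates
  set.seed(config$seed + 19L)
  n <- nrow(genes)
  base <- rnorm(n, config$expr_baseline_mean, config$expr_baseline_sd)
  eff <- matrix(0, nrow = n, ncol = 3L,
                dimnames = list(genes$gene_id, populations))
  epi <- truth$label == "epi_up"; pren <- truth$label == "pren_up"
  eff[epi, 1L] <- truth$log2_fold[epi]
  eff[pren, 2L] <- truth$log2_fold[pren]
  eff[pren, 3L] <- truth$log2_fold[pren]
  samples <- paste(rep(populations, each = n_replicates),
                   rep(seq_len(n_replicates), times = 3L), sep = "_r")
  expr <- matrix(NA_real_, nrow = n, ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    popj <- (j - 1L) %/% n_replicates + 1L
    expr[, j] <- base + eff[, popj] + rnorm(n, 0, config$expr_rep_sd)
  }
  sample_map <- data.frame(sample = samples,
                           population = rep(populations, each = n_replicates),
                           replicate = rep(seq_len(n_replicates), times = 3L),
                           stringsAsFactors = FALSE)
  list(expr = expr, sample_map = sample_map)
}

#' Simulate nascent-transcription (GRO) coverage tracks
#'
#' Per-gene transcription rate proportional to steady-state level with the
#' between-population fold change compressed by `gro_fold_scale`; uniform
#' coverage over the gene body plus Poisson noise and a low background.
#'
#' @inheritParams simulate_chip_tracks
#' @return named list of two `coverage_track` objects (`epi`, `pren`).
#' @export
simulate_groseq_tracks <- function(genes, truth, config, chrom_lengths) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  # epi-minus-pren nascent log2 difference per gene
  expr_diff <- ifelse(truth$label == "epi_up", truth$log2_fold,
                      ifelse(truth$label == "pren_up", -truth$log2_fold, 0))
  gro_diff <- config$gro_fold_scale * expr_diff
  out <- list()
  for (pop in c("epi", "pren")) {
    set.seed(config$seed + 23L + (pop == "pren"))
    sgn <- if (pop == "epi") 0.5 else -0.5
    depth <- list()
    for (ch in names(chrom_lengths)) {
      len <- chrom_lengths[[ch]]
      rate <- rep(config$gro_background, len)
      for (i in which(genes$chrom == ch)) {
        a <- genes$start[i] + 1L; b <- genes$end[i]
        rate[a:b] <- config$gro_depth * 2^(sgn * gro_diff[i])
      }
      depth[[ch]] <- rpois(len, rate) # integer storage
    }
    out[[pop]] <- coverage_track(depth, label = paste0("groseq_", pop))
  }
  out
}

#' Simulate a single-cell qPCR Ct table
#'
#' Three genotypes (`WT`, `mutantA`, `mutantB`). Heterogeneous genes in WT
#' are drawn from a two-component mixture (an off component at the detection
#' floor and an on component `sc_on_mean` log2 units above it); in the
#' mutants from a single component with a higher mean (`sc_mut_shift`) and
#' lower spread (`sc_mut_sd`). Housekeeping genes are unimodal in all
#' genotypes. Ct values are emitted LOD-censored: expression e maps to
#' `lod_ct - e`, and undetected reactions carry the failed sentinel 999.
#'
#' @param config a [sim_config()].
#' @return list with `ct` (data.frame: cell, genotype, plate, one column per
#'   gene) and `truth` (per-gene heterogeneity class).
#' @export
simulate_scqpcr_table <- function(config) {
  set.seed(config$seed + 29L)
  genotypes <- c("WT", "mutantA", "mutantB")
  nh <- config$sc_het_genes; nk <- config$sc_hk_genes
  genes <- c(sprintf("het%02d", seq_len(nh)), sprintf("hk%02d", seq_len(nk)))
  nc <- config$sc_n_cells
  rows <- list()
  for (gt in genotypes) {
    m <- matrix(NA_real_, nrow = nc, ncol = length(genes),
                dimnames = list(NULL, genes))
    for (j in seq_len(nh)) {
      if (gt == "WT") {
        off <- runif(nc) < config$sc_off_prob
        e <- pmax(0, rnorm(nc, config$sc_on_mean, config$sc_on_sd))
        e[off] <- 0
      } else {
        e <- pmax(0, rnorm(nc, config$sc_on_mean + config$sc_mut_shift,
                           config$sc_mut_sd))
      }
      m[, j] <- e
    }
    for (j in seq_len(nk))
      m[, nh + j] <- pmax(0, rnorm(nc, config$sc_hk_mean, config$sc_hk_sd))
    ct <- config$lod_ct - m
    ct[m == 0] <- 999
    rows[[gt]] <- data.frame(cell = paste0(gt, "_c", seq_len(nc)),
                             genotype = gt, plate = 1L, ct,
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  truth <- data.frame(gene = genes,
                      heterogeneous = rep(c(TRUE, FALSE), c(nh, nk)),
                      stringsAsFactors = FALSE)
  list(ct = do.call(rbind, c(rows, make.row.names = FALSE)), truth = truth)
}

#' Generate and write a full synthetic cohort
#'
#' Runs every generator and writes the standard file layout: `genes.tsv`,
#' `cgi.bed`, `promoters.fa`, `{pop}_{ip|input}.bedgraph`,
#' `groseq_{pop}.bedgraph`, `expression.tsv`, `sample_map.tsv`,
#' `scqpcr.tsv`, `truth.tsv` and a `config.json` echo (seed included).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param write_tracks also write the coverage bedGraphs (the slowest part;
#'   disable when only the in-memory objects are needed).
#' @return (invisibly) list of all generated objects plus `files`.
#' @export
simulate_cohort <- function(config, outdir, write_tracks = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  chip <- simulate_chip_tracks(gen$genes, gen$truth, config, gen$chrom_lengths)
  gro <- simulate_groseq_tracks(gen$genes, gen$truth, config, gen$chrom_lengths)
  ex <- simulate_expression_matrix(gen$genes, gen$truth, config)
  sc <- simulate_scqpcr_table(config)

  files <- list()
  p <- function(f) file.path(outdir, f)
  files$genes <- write_gene_table(gen$genes, p("genes.tsv"))
  files$cgi <- write_bed(gen$cgis, p("cgi.bed"))
  seqs <- Biostrings::DNAStringSet(gen$promoters)
  Biostrings::writeXStringSet(seqs, p("promoters.fa"))
  files$promoters <- p("promoters.fa")
  if (write_tracks) {
    for (tr in names(chip))
      files[[tr]] <- write_bedgraph(chip[[tr]], p(paste0(tr, ".bedgraph")))
    for (popn in names(gro))
      files[[paste0("groseq_", popn)]] <-
        write_bedgraph(gro[[popn]], p(paste0("groseq_", popn, ".bedgraph")))
  }
  expr_out <- data.frame(gene_id = rownames(ex$expr), ex$expr,
                         check.names = FALSE)
  data.table::fwrite(expr_out, p("expression.tsv"), sep = "\t")
  files$expression <- p("expression.tsv")
  data.table::fwrite(ex$sample_map, p("sample_map.tsv"), sep = "\t")
  files$sample_map <- p("sample_map.tsv")
  data.table::fwrite(sc$ct, p("scqpcr.tsv"), sep = "\t")
  files$scqpcr <- p("scqpcr.tsv")
  data.table::fwrite(gen$truth, p("truth.tsv"), sep = "\t")
  files$truth <- p("truth.tsv")
  jsonlite::write_json(unclass(config), p("config.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  files$config <- p("config.json")
  invisible(list(config = config, genes = gen$genes, truth = gen$truth,
                 cgis = gen$cgis, promoters = gen$promoters,
                 chrom_lengths = gen$chrom_lengths, chip = chip, gro = gro,
                 expr = ex$expr, sample_map = ex$sample_map, sc = sc,
                 files = files))
}
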