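# End-to-end orchestration of the synthetic-cohort analysis: simulate ->
# signal tracks -> priming lists -> gene-set statistics -> domains/peaks ->
# promoter CGIs -> single-cell heterogeneity -> report, with a
# machine-readable manifest.

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order, writes all intermediate tables
#' under `outdir`, and finishes with a report that asserts the three
#' headline qualitative results on the cohort: (i) the gene-body H3K27me3
#' differential anti-correlates with transcription for both priming sets,
#' (ii) the TSS-proximal differential is approximately zero, and (iii) the
#' TSS peak fraction is higher for PrEn-priming than epiblast-priming
#' genes. Idempotent given an identical configuration: rerunning reproduces
#' byte-identical stochastic outputs.
#'
#' @param config a [sim_config()] or path to a JSON file of its fields.
#' @param outdir output directory.
#' @param window_width,pseudocount IP/Input window log-ratio settings.
#' @param n_perm,perm_seed permutation-test settings.
#' @param fc_min,q_max two-stage selection thresholds.
#' @param peak_halfwidth TSS peak-status distance in bases.
#' @param gro_fc_min fold threshold for nascent-direction calls.
#' @param write_tracks write the coverage bedGraphs (the slowest output;
#'   disable for repeated in-memory runs).
#' @return (invisibly) the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         window_width = 50L, pseudocount = 1,
                         n_perm = 10000L, perm_seed = NULL,
                         fc_min = 1.5, q_max = 0.05,
                         peak_halfwidth = 100L, gro_fc_min = 1.5,
                         write_tracks = TRUE) {
  if (is.character(config)) {
    fields <- jsonlite::read_json(config, simplifyVector = TRUE)
    known <- names(formals(sim_config))
    bad <- setdiff(names(fields), known)
    if (length(bad))
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    config <- do.call(sim_config, fields)
  }
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (is.null(perm_seed)) perm_seed <- config$seed + 101L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  outputs <- list()
  note <- function(stage, ...) {
    stages <<- c(stages, stage)
    outputs[[stage]] <<- unlist(list(...), use.names = FALSE)
  }

  # -- simulate ------------------------------------------------------------
  sim_dir <- file.path(outdir, "cohort")
  cohort <- simulate_cohort(config, sim_dir, write_tracks = write_tracks)
  note("simulate", unlist(cohort$files, use.names = FALSE))

  # -- signal tracks -------------------------------------------------------
  ratio <- list(
    epi = window_log2_ratio(cohort$chip$epi_ip, cohort$chip$epi_input,
                            width = window_width, pseudocount = pseudocount),
    pren = window_log2_ratio(cohort$chip$pren_ip, cohort$chip$pren_input,
                             width = window_width, pseudocount = pseudocount))
  qn <- quantile_normalize(list(epi = unlist(ratio$epi$values),
                                pren = unlist(ratio$pren$values)))
  for (popn in names(ratio)) {
    lens <- vapply(ratio[[popn]]$values, length, integer(1))
    ratio[[popn]]$values <- split(qn[[popn]],
                                  rep(seq_along(lens), lens))
    names(ratio[[popn]]$values) <- names(lens)
  }
  strat <- list(
    epi = stratified_gene_signal(ratio$epi, cohort$genes),
    pren = stratified_gene_signal(ratio$pren, cohort$genes))
  strat_diff <- data.frame(
    gene_id = strat$epi$gene_id,
    upstream = strat$epi$upstream - strat$pren$upstream,
    tss = strat$epi$tss - strat$pren$tss,
    body = strat$epi$body - strat$pren$body,
    stringsAsFactors = FALSE)
  f_strat <- file.path(outdir, "stratified_diff.tsv")
  data.table::fwrite(strat_diff, f_strat, sep = "\t")
  meta <- list(epi = metagene_matrix(ratio$epi, cohort$genes),
               pren = metagene_matrix(ratio$pren, cohort$genes))
  comp <- differential_composite(meta$epi, meta$pren)
  f_comp <- file.path(outdir, "metagene_diff_profile.tsv")
  data.table::fwrite(data.frame(bin = seq_along(comp$profile),
                                mean_diff = comp$profile), f_comp, sep = "\t")
  note("tracks", f_strat, f_comp)

  # -- priming lists -------------------------------------------------------
  lists <- two_stage_priming_lists(cohort$expr, cohort$sample_map,
                                   fc_min = fc_min, q_max = q_max)
  f_epi <- file.path(outdir, "epi_up.txt")
  f_pren <- file.path(outdir, "pren_up.txt")
  write_gene_set(lists$epi_up, f_epi)
  write_gene_set(lists$pren_up, f_pren)
  note("lists", f_epi, f_pren)

  # -- nascent consistency -------------------------------------------------
  gro_body <- list(
    epi = stratified_gene_signal(cohort$gro$epi, cohort$genes),
    pren = stratified_gene_signal(cohort$gro$pren, cohort$genes))
  gro_ratio <- (gro_body$epi$body + 1e-3) / (gro_body$pren$body + 1e-3)
  nascent <- data.frame(
    gene_id = cohort$genes$gene_id,
    direction = ifelse(gro_ratio > gro_fc_min, "up_in_A",
                       ifelse(gro_ratio < 1 / gro_fc_min, "up_in_B", "ns")),
    stringsAsFactors = FALSE)
  consistent <- consistent_nascent_steady(lists$stage1, nascent)
  f_cons <- file.path(outdir, "consistent_sets.json")
  jsonlite::write_json(list(up_in_A = consistent$up_in_A$genes,
                            up_in_B = consistent$up_in_B$genes),
                       f_cons)
  note("nascent", f_cons)

  # -- gene-set statistics -------------------------------------------------
  set_test <- function(vals, set_genes, seed_off) {
    sel <- strat_diff$gene_id %in% set_genes
    permutation_oneway_test(vals[sel], vals[!sel], n_perm = n_perm,
                            seed = perm_seed + seed_off)
  }
  tests <- list(
    epi_body = set_test(strat_diff$body, lists$epi_up$genes, 1L),
    pren_body = set_test(strat_diff$body, lists$pren_up$genes, 2L),
    epi_tss = set_test(strat_diff$tss, lists$epi_up$genes, 3L),
    pren_tss = set_test(strat_diff$tss, lists$pren_up$genes, 4L))
  f_tests <- file.path(outdir, "geneset_tests.json")
  jsonlite::write_json(lapply(tests, function(t)
    list(statistic = t$statistic, p = t$p, n_perm = t$n_perm,
         seed = t$seed)), f_tests, auto_unbox = TRUE, digits = NA)
  note("stats", f_tests)

  # -- domains and TSS peaks ----------------------------------------------
  params <- caller_params(genome_size = sum(as.numeric(cohort$chrom_lengths)))
  domains <- merge_domain_sets(call_domains(cohort$chip$epi_ip, params),
                               call_domains(cohort$chip$pren_ip, params))
  flags <- score_tss_peak_status(domains, cohort$genes,
                                 halfwidth = peak_halfwidth)
  universe <- cohort$genes$gene_id
  enrich <- list(
    pren = tss_peak_enrichment(flags, lists$pren_up, universe),
    epi = tss_peak_enrichment(flags, lists$epi_up, universe))
  f_dom <- file.path(outdir, "h3k27me3_domains.bed")
  write_domains_bed(domains, f_dom)
  f_flags <- file.path(outdir, "tss_peak_flags.tsv")
  data.table::fwrite(data.frame(gene_id = names(flags), flag = flags),
                     f_flags, sep = "\t")
  note("peaks", f_dom, f_flags)

  # -- promoter CGIs -------------------------------------------------------
  feats <- promoter_features(cohort$promoters, cohort$genes, cohort$cgis)
  cgi_enr <- cgi_enrichment(setNames(feats$cgi_overlap, feats$gene_id),
                            lists$pren_up, universe)
  f_feats <- file.path(outdir, "promoter_features.tsv")
  data.table::fwrite(feats, f_feats, sep = "\t")
  note("cgi", f_feats)

  # -- single-cell ---------------------------------------------------------
  cells <- ct_to_expression(cohort$sc$ct, lod_ct = config$lod_ct)
  filt <- filter_outlier_cells(cells)
  sc_tests <- sc_test_table(filt$table)
  f_sc <- file.path(outdir, "sc_tests.tsv")
  data.table::fwrite(sc_tests, f_sc, sep = "\t")
  f_sum <- file.path(outdir, "sc_summary.tsv")
  data.table::fwrite(heterogeneity_summary(filt$table), f_sum, sep = "\t")
  note("single_cell", f_sc, f_sum)

  # -- report --------------------------------------------------------------
  body_mean <- function(set) mean(
    strat_diff$body[strat_diff$gene_id %in% set$genes], na.rm = TRUE)
  tss_mean <- function(set) mean(
    strat_diff$tss[strat_diff$gene_id %in% set$genes], na.rm = TRUE)
  report <- list(
    body_diff_epi_up = body_mean(lists$epi_up),
    body_diff_pren_up = body_mean(lists$pren_up),
    tss_diff_epi_up = tss_mean(lists$epi_up),
    tss_diff_pren_up = tss_mean(lists$pren_up),
    tss_peak_pct_pren = enrich$pren$pct_set,
    tss_peak_pct_epi = enrich$epi$pct_set,
    cgi_pct_pren = cgi_enr$pct_set,
    cgi_pct_universe = cgi_enr$pct_universe,
    n_epi_up = length(lists$epi_up$genes),
    n_pren_up = length(lists$pren_up$genes),
    headline = list(
      body_anticorrelated =
        body_mean(lists$epi_up) < 0 && body_mean(lists$pren_up) > 0,
      tss_invariant =
        abs(tss_mean(lists$epi_up)) < 0.1 &&
        abs(tss_mean(lists$pren_up)) < 0.1,
      pren_peak_fraction_higher =
        enrich$pren$pct_set > enrich$epi$pct_set))
  f_report <- file.path(outdir, "report.json")
  jsonlite::write_json(report, f_report, auto_unbox = TRUE, digits = NA)
  note("report", f_report)

  all_files <- unlist(outputs, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("primelens")),
    config = unclass(config),
    seeds = list(simulate = config$seed, permutation = perm_seed),
    stage_order = stages,
    outputs = outputs,
    checksums = as.list(tools::md5sum(all_files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
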