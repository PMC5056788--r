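# Gene-list construction: threshold differential expression, the two-stage
# priming-gene selection, RPKM-ratio calls, nascent/steady-state consistency
# filtering, PRC2-target classification and list-overlap tests.

#' Construct a labeled gene set
#' @param label non-empty set label.
#' @param genes character vector of gene ids (duplicates removed, order kept).
#' @param provenance named list recording thresholds/contrasts/seeds.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, genes, provenance = list()) {
  if (!nzchar(label)) stop("gene_set label must be non-empty")
  structure(list(label = label, genes = unique(as.character(genes)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$label, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' Length of a gene set
#' @param x a `gene_set`.
#' @export
length.gene_set <- function(x) length(x$genes)

# vectorised Welch (or pooled) two-sample t-test on rows of log2 matrices
row_t_test <- function(a, b, var_equal = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, var); v2 <- apply(b, 1L, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  p[se == 0 & m1 == m2] <- 1
  list(t = t, p = p)
}

#' Threshold differential expression between two groups
#'
#' Per-gene two-sample t-test (Welch by default) on log2 intensities with
#' Benjamini-Hochberg adjustment. A gene is called `up_in_A` iff its
#' linear-scale fold change `A/B` strictly exceeds `fc_min` and `q < q_max`;
#' `up_in_B` iff the fold change is strictly below `1/fc_min` with the same
#' q rule. Fold changes are ratios of linear-scale group means.
#'
#' @param expr genes x samples matrix of log2 intensities (rownames =
#'   gene ids).
#' @param sample_map data.frame with columns `sample` and `population`
#'   matching `colnames(expr)`.
#' @param groupA,groupB population labels to contrast (A first).
#' @param fc_min minimum fold change (linear scale, strict).
#' @param q_max BH q-value cutoff (strict).
#' @param var_equal use a pooled-variance t-test instead of Welch.
#' @return a `de_result` data.frame: per-gene means, `fc`, `log2_fc`, `p`,
#'   `q`, `direction` in `{up_in_A, up_in_B, ns}`.
#' @export
threshold_de <- function(expr, sample_map, groupA, groupB, fc_min = 1.5,
                         q_max = 0.05, var_equal = FALSE) {
  for (g in c(groupA, groupB))
    if (!g %in% sample_map$population) stop("population label missing: ", g)
  sa <- sample_map$sample[sample_map$population == groupA]
  sb <- sample_map$sample[sample_map$population == groupB]
  if (length(sa) < 2L || length(sb) < 2L)
    stop("each group needs >= 2 replicates")
  a <- expr[, sa, drop = FALSE]; b <- expr[, sb, drop = FALSE]
  tt <- row_t_test(a, b, var_equal = var_equal)
  mean_a <- rowMeans(2^a); mean_b <- rowMeans(2^b)
  fc <- mean_a / mean_b
  q <- bh_adjust(tt$p)
  direction <- ifelse(fc > fc_min & q < q_max, "up_in_A",
                      ifelse(fc < 1 / fc_min & q < q_max, "up_in_B", "ns"))
  res <- data.frame(gene_id = rownames(expr), mean_A = mean_a,
                    mean_B = mean_b, fc = fc, log2_fc = log2(fc),
                    p = tt$p, q = q, direction = direction,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- c(A = groupA, B = groupB)
  attr(res, "thresholds") <- c(fc_min = fc_min, q_max = q_max)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Two-stage priming gene-list selection
#'
#' Stage 1 contrasts the epiblast-primed population against the
#' differentiated population (threshold DE at `fc_min`/`q_max`). Stage 2
#' retains only genes whose epiblast-primed vs PrEn-primed expression ratio
#' agrees in sign with the stage-1 direction - on group means by default, or
#' in every replicate pair with `mode = "per_replicate"`. Outputs are
#' partitioned by direction: genes up in the epiblast-primed population and
#' genes up in the PrEn-primed/differentiated direction.
#'
#' @inheritParams threshold_de
#' @param epi,pren,diff population labels for the epiblast-primed,
#'   PrEn-primed and differentiated groups.
#' @param mode stage-2 consistency rule: sign agreement of the mean
#'   log-ratio, or of every replicate-wise log-ratio.
#' @return list with `epi_up` and `pren_up` gene sets and the stage-1
#'   `de_result`.
#' @export
two_stage_priming_lists <- function(expr, sample_map,
                                    epi = "epi_primed", pren = "pren_primed",
                                    diff = "differentiated",
                                    fc_min = 1.5, q_max = 0.05,
                                    mode = c("mean", "per_replicate"),
                                    var_equal = FALSE) {
  mode <- match.arg(mode)
  for (g in c(epi, pren, diff))
    if (!g %in% sample_map$population) stop("population label missing: ", g)
  stage1 <- threshold_de(expr, sample_map, epi, diff, fc_min = fc_min,
                         q_max = q_max, var_equal = var_equal)
  se <- sample_map$sample[sample_map$population == epi]
  sp <- sample_map$sample[sample_map$population == pren]
  if (mode == "mean") {
    ratio_sign <- sign(rowMeans(expr[, se, drop = FALSE]) -
                       rowMeans(expr[, sp, drop = FALSE]))
    agree_up <- ratio_sign > 0
    agree_dn <- ratio_sign < 0
  } else {
    k <- min(length(se), length(sp))
    d <- expr[, se[seq_len(k)], drop = FALSE] -
      expr[, sp[seq_len(k)], drop = FALSE]
    agree_up <- apply(d > 0, 1L, all)
    agree_dn <- apply(d < 0, 1L, all)
  }
  prov <- list(contrast_stage1 = c(epi, diff), contrast_stage2 = c(epi, pren),
               fc_min = fc_min, q_max = q_max, mode = mode)
  epi_up <- gene_set("epi_up",
                     stage1$gene_id[stage1$direction == "up_in_A" & agree_up],
                     provenance = prov)
  pren_up <- gene_set("pren_up",
                      stage1$gene_id[stage1$direction == "up_in_B" & agree_dn],
                      provenance = prov)
  list(epi_up = epi_up, pren_up = pren_up, stage1 = stage1)
}

#' RPKM-ratio differential calls
#'
#' Genes whose RPKM is below `floor` in both samples are removed; the rest
#' are called by the A/B ratio alone (no p value): `up_in_A` when the ratio
#' is at least `fc_min`, `up_in_B` when at most `1/fc_min`.
#'
#' @param rpkm data.frame with columns `gene_id`, `A`, `B` (RPKM values).
#' @param floor minimum RPKM for a gene to be retained.
#' @param fc_min minimum fold change (inclusive).
#' @return a data.frame with `ratio` and `direction`, floored genes removed.
#' @export
rpkm_de <- function(rpkm, floor = 0.5, fc_min = 2) {
  if (any(rpkm$A < 0 | rpkm$B < 0)) stop("RPKM values must be >= 0")
  keep <- !(rpkm$A < floor & rpkm$B < floor)
  out <- rpkm[keep, , drop = FALSE]
  ratio <- out$A / out$B
  out$ratio <- ratio
  out$direction <- ifelse(ratio >= fc_min, "up_in_A",
                          ifelse(ratio <= 1 / fc_min, "up_in_B", "ns"))
  rownames(out) <- NULL
  out
}

#' Genes with consistent nascent and steady-state differential calls
#'
#' Retains genes called in the same (non-ns) direction in both results;
#' direction-discordant or single-dataset calls are excluded.
#'
#' @param steady,nascent `de_result`-like data.frames sharing a gene
#'   universe (columns `gene_id`, `direction`).
#' @return list of two gene sets, `up_in_A` and `up_in_B`.
#' @export
consistent_nascent_steady <- function(steady, nascent) {
  if (!any(steady$gene_id %in% nascent$gene_id))
    stop("steady and nascent results have disjoint gene universes")
  m <- merge(steady[, c("gene_id", "direction")],
             nascent[, c("gene_id", "direction")],
             by = "gene_id", suffixes = c("_steady", "_nascent"))
  same <- m$direction_steady == m$direction_nascent & m$direction_steady != "ns"
  prov <- list(rule = "same non-ns direction in steady and nascent")
  list(up_in_A = gene_set("consistent_up_in_A",
                          m$gene_id[same & m$direction_steady == "up_in_A"],
                          prov),
       up_in_B = gene_set("consistent_up_in_B",
                          m$gene_id[same & m$direction_steady == "up_in_B"],
                          prov))
}

#' Classify PRC2 target genes
#'
#' A gene is a PRC2 target iff it carries an H3K27me3 peak at its TSS
#' (+- 100 bp flag from the domain caller) and is upregulated in
#' PRC2-deficient (EED-null) cells.
#'
#' @param tss_peak_flags named logical vector of per-gene TSS peak status.
#' @param eed_up `gene_set` of genes upregulated on EED loss.
#' @return a `gene_set` of PRC2 targets.
#' @export
classify_prc2_targets <- function(tss_peak_flags, eed_up) {
  ids <- names(tss_peak_flags)
  if (is.null(ids)) stop("tss_peak_flags must be named by gene id")
  hit <- ids[tss_peak_flags & ids %in% eed_up$genes]
  gene_set("prc2_targets", hit,
           provenance = list(rule = "TSS peak flag AND up in EED-null"))
}

#' Overlap of two gene sets with Fisher's exact test
#'
#' Builds the 2x2 table (in both / A only / B only / neither) over the given
#' universe and tests it two-sided.
#'
#' @param setA,setB `gene_set` objects, subsets of `universe`.
#' @param universe `gene_set` or character vector of the full gene universe.
#' @return list with `overlap` (count), `table` (2x2 matrix) and `test`
#'   (Fisher `prime_test`).
#' @export
list_overlap_fisher <- function(setA, setB, universe) {
  uni <- if (inherits(universe, "gene_set")) universe$genes else
    unique(as.character(universe))
  a <- setA$genes; b <- setB$genes
  out_a <- setdiff(a, uni); out_b <- setdiff(b, uni)
  if (length(out_a) || length(out_b))
    stop("set elements outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5L), collapse = ", "))
  both <- length(intersect(a, b))
  tab <- matrix(c(both, length(a) - both,
                  length(b) - both,
                  length(uni) - length(union(a, b))),
                nrow = 2L,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  list(overlap = both, table = tab, test = fisher_2x2(tab))
}

#' Write a gene set as a one-id-per-line text file
#'
#' Provenance is recorded in `#`-prefixed header comments.
#' @param x a `gene_set`.
#' @param path output path.
#' @export
write_gene_set <- function(x, path) {
  hdr <- c(paste0("# gene_set: ", x$label),
           vapply(names(x$provenance), function(k)
             paste0("# ", k, ": ",
                    paste(format(x$provenance[[k]]), collapse = " ")),
             character(1)))
  writeLines(c(hdr, x$genes), path)
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#' @param path input path.
#' @param label set label (defaults to the header's, else the filename).
#' @return a `gene_set`.
#' @export
read_gene_set <- function(path, label = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  if (is.null(label)) {
    lab_line <- grep("^# gene_set: ", lines, value = TRUE)
    label <- if (length(lab_line)) sub("^# gene_set: ", "", lab_line[1L]) else
      tools::file_path_sans_ext(basename(path))
  }
  gene_set(label, lines[!hdr & nzchar(lines)])
}

#' @importFrom stats pt var
NULL
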