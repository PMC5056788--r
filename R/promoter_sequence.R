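# Promoter sequence characterisation: CpG observed/expected ratio, G+C
# fraction, CGI overlap flags and CGI-promoter enrichment.

norm_seq <- function(seq) {
  s <- toupper(as.character(seq))
  if (!nzchar(s)) stop("empty sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence must be over {A,C,G,T,N}")
  s
}

#' CpG observed/expected ratio of a sequence
#'
#' The Gardiner-Garden-Frommer form: `o/e = n_CG * L / (n_C * n_G)` with L
#' the sequence length. N bases are excluded from all counts and from L;
#' the ratio is defined as 0 when either the C or the G count is zero.
#' Case-insensitive.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`, length >= 2.
#' @return dimensionless ratio >= 0.
#' @export
cpg_observed_expected <- function(seq) {
  s <- norm_seq(seq)
  if (nchar(s) < 2L) stop("sequence must have length >= 2")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  keep <- chars != "N"
  nC <- sum(chars == "C"); nG <- sum(chars == "G")
  L <- sum(keep)
  if (nC == 0L || nG == 0L) return(0)
  ncg <- sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
  ncg * L / (nC * nG)
}

#' G+C fraction of a sequence
#'
#' `(C + G) / (non-N length)`; N bases are excluded symmetrically.
#' @inheritParams cpg_observed_expected
#' @return fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  s <- norm_seq(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- sum(chars != "N")
  if (L == 0L) stop("all-N sequence")
  (sum(chars == "C") + sum(chars == "G")) / L
}

#' Per-gene CGI overlap flags
#'
#' TRUE iff the TSS point lies within a CGI interval. A window-overlap mode
#' (any CGI overlapping TSS +- `window`) is available for sensitivity
#' analyses.
#'
#' @param genes gene table.
#' @param cgis sorted, merged CGI interval data.frame.
#' @param mode `"point"` (default) or `"window"`.
#' @param window half-width for window mode.
#' @return named logical vector over `genes$gene_id`.
#' @export
cgi_overlap_flags <- function(genes, cgis, mode = c("point", "window"),
                              window = 500L) {
  mode <- match.arg(mode)
  if (mode == "point") {
    flags <- points_in_intervals(genes$chrom, genes$tss, cgis)
  } else {
    widened <- if (nrow(cgis)) merge_intervals(data.frame(
      chrom = cgis$chrom, start = pmax(cgis$start - window, 0L),
      end = cgis$end + window)) else cgis
    flags <- points_in_intervals(genes$chrom, genes$tss, widened)
  }
  setNames(flags, genes$gene_id)
}

#' CGI enrichment of a gene set
#'
#' Percentage of CGI-positive promoters in the set and universe with a
#' two-sided Fisher test (set vs remaining genes).
#' @inheritParams tss_peak_enrichment
#' @return list with `pct_set`, `pct_universe`, `table`, `test`.
#' @export
cgi_enrichment <- function(flags, set, universe) {
  tss_peak_enrichment(flags, set, universe)
}

#' Promoter features for every gene
#'
#' CpG o/e, G+C fraction and CGI overlap flag per promoter window.
#'
#' @param promoters named character vector (or `Biostrings::DNAStringSet`)
#'   of promoter sequences keyed by gene id.
#' @param genes gene table (for CGI flags; optional when `cgis` is NULL).
#' @param cgis CGI interval data.frame or NULL to skip flags.
#' @return data.frame: `gene_id`, `cpg_oe`, `gc`, `cgi_overlap`.
#' @export
promoter_features <- function(promoters, genes = NULL, cgis = NULL) {
  seqs <- setNames(as.character(promoters), names(promoters))
  ids <- names(seqs)
  if (is.null(ids)) stop("promoter sequences must be named by gene id")
  feats <- data.frame(
    gene_id = ids,
    cpg_oe = vapply(seqs, cpg_observed_expected, numeric(1), USE.NAMES = FALSE),
    gc = vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (!is.null(cgis) && !is.null(genes)) {
    flags <- cgi_overlap_flags(genes, cgis)
    feats$cgi_overlap <- unname(flags[feats$gene_id])
  }
  feats
}
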