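# Simplified fixed-lambda Poisson broad-domain caller for H3K27me3, plus
# peak-set merging, TSS peak-status scoring and gene-set peak enrichment.
# This is deliberately not a MACS reimplementation: there is no local
# lambda (the analysis it supports fixes the background lambda) and no
# model-based read shifting (the input is coverage, not tags). Window
# tag-equivalent counts are depth sums divided by the tag size.

#' Parameters for the broad-domain caller
#'
#' @param genome_size effective genome size in bases (2.7e9 for real
#'   mammalian data; the synthetic genome size otherwise; `NULL` uses the
#'   track's total length).
#' @param tag_size read length used to convert depth sums into
#'   tag-equivalent counts.
#' @param bandwidth scoring window width in bases (step is half this).
#' @param score_cutoff minimum window score (-10*log10 Poisson p) for a call.
#' @param lambda fixed background tag rate per window; derived from
#'   `total_tags * bandwidth / genome_size` when `NULL`.
#' @param score_cap display cap for reported scores (comparisons are done in
#'   log space before capping).
#' @return a `caller_params` list.
#' @export
caller_params <- function(genome_size = NULL, tag_size = 42L,
                          bandwidth = 300L, score_cutoff = 1000,
                          lambda = NULL, score_cap = 10000) {
  if (tag_size <= 0 || bandwidth <= 0 || score_cutoff <= 0)
    stop("caller parameters must be positive")
  structure(list(genome_size = genome_size, tag_size = tag_size,
                 bandwidth = as.integer(bandwidth),
                 score_cutoff = score_cutoff, lambda = lambda,
                 score_cap = score_cap),
            class = "caller_params")
}

#' Call broad enrichment domains against a fixed background lambda
#'
#' Sliding windows of width `bandwidth` (step `bandwidth/2`) are scored by
#' the Poisson upper-tail probability of their tag-equivalent count against
#' the genome-wide expected count per window. Windows at or above the score
#' cutoff are merged into domains when separated by less than one bandwidth;
#' a domain's score is its best window's (capped for display at
#' `score_cap`).
#'
#' @param ip a `coverage_track` (ChIP sample; no input track is used - the
#'   background is the fixed lambda).
#' @param params a [caller_params()].
#' @return data.frame of domains: `chrom`, `start`, `end`, `score`,
#'   `max_count`, `fold` (max count over lambda), sorted, non-overlapping.
#' @export
call_domains <- function(ip, params = caller_params()) {
  total_depth <- sum(vapply(ip$depth, sum, numeric(1)))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      max_count = numeric(), fold = numeric())
  if (total_depth == 0) return(empty)
  gsize <- params$genome_size
  if (is.null(gsize)) gsize <- sum(as.numeric(ip$chrom_lengths))
  total_tags <- total_depth / params$tag_size
  lambda <- params$lambda
  if (is.null(lambda)) lambda <- total_tags * params$bandwidth / gsize
  bw <- params$bandwidth
  step <- max(1L, bw %/% 2L)
  out <- list()
  for (ch in names(ip$depth)) {
    v <- ip$depth[[ch]]
    n <- length(v)
    if (n == 0L) next
    cs <- c(0, cumsum(v))
    starts <- seq.int(0L, max(n - 1L, 0L), by = step)
    ends <- pmin(starts + bw, n)
    counts <- (cs[ends + 1L] - cs[starts + 1L]) / params$tag_size
    # -10*log10 P(X >= count); count 0 scores 0 by convention
    logp <- ppois(pmax(ceiling(counts) - 1, 0), lambda,
                  lower.tail = FALSE, log.p = TRUE)
    logp[counts <= 0] <- 0
    score <- -10 * logp / log(10)
    hit <- which(score >= params$score_cutoff)
    if (!length(hit)) next
    # merge hit windows gapped by < bandwidth
    ws <- starts[hit]; we <- ends[hit]; sc <- score[hit]; cn <- counts[hit]
    brk <- c(TRUE, ws[-1L] - we[-length(we)] >= bw)
    grp <- cumsum(brk)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = as.integer(tapply(ws, grp, min)),
      end = as.integer(tapply(we, grp, max)),
      score = pmin(as.numeric(tapply(sc, grp, max)), params$score_cap),
      max_count = as.numeric(tapply(cn, grp, max)),
      fold = as.numeric(tapply(cn, grp, max)) / lambda,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge two domain sets into one interval set
#'
#' Union with overlapping or book-ended intervals coalesced.
#' @param setA,setB sorted domain data.frames (`chrom`, `start`, `end`).
#' @return merged sorted interval data.frame.
#' @export
merge_domain_sets <- function(setA, setB) {
  cols <- c("chrom", "start", "end")
  merge_intervals(rbind(setA[, cols, drop = FALSE],
                        setB[, cols, drop = FALSE]))
}

#' Score per-gene TSS peak status
#'
#' A gene is flagged iff some domain lies within `halfwidth` bases of its
#' TSS under the edge-based distance (zero inside a domain, else the gap to
#' the nearest covered base).
#'
#' @param domains interval data.frame (`chrom`, `start`, `end`).
#' @param genes gene table.
#' @param halfwidth maximum distance in bases (inclusive).
#' @return named logical vector over `genes$gene_id`.
#' @export
score_tss_peak_status <- function(domains, genes, halfwidth = 100L) {
  if (halfwidth < 0L) stop("halfwidth must be >= 0")
  # distance <= halfwidth iff the TSS lies in the domain widened by
  # halfwidth on each side (edge-based metric)
  widened <- if (nrow(domains)) merge_intervals(data.frame(
    chrom = domains$chrom,
    start = pmax(domains$start - halfwidth, 0L),
    end = domains$end + halfwidth)) else domains
  flags <- points_in_intervals(genes$chrom, genes$tss, widened)
  setNames(flags, genes$gene_id)
}

#' TSS-peak enrichment of a gene set
#'
#' Percentage of flag-positive genes in the set and in the whole universe,
#' with a two-sided Fisher test of the set against the remaining genes.
#'
#' @param flags named logical vector of per-gene TSS peak status.
#' @param set a `gene_set` (subset of the universe).
#' @param universe `gene_set` or character vector of all genes.
#' @return list with `pct_set`, `pct_universe`, `table`, `test`.
#' @export
tss_peak_enrichment <- function(flags, set, universe) {
  uni <- if (inherits(universe, "gene_set")) universe$genes else
    unique(as.character(universe))
  if (length(set$genes) == 0L) stop("empty gene set")
  if (!all(set$genes %in% uni)) stop("set is not a subset of the universe")
  if (!all(uni %in% names(flags))) stop("flags missing for some genes")
  in_set <- uni %in% set$genes
  f <- flags[uni]
  tab <- matrix(c(sum(f & in_set), sum(!f & in_set),
                  sum(f & !in_set), sum(!f & !in_set)),
                nrow = 2L,
                dimnames = list(c("flag", "noflag"), c("set", "rest")))
  list(pct_set = 100 * mean(f[in_set]),
       pct_universe = 100 * mean(f),
       table = tab,
       test = fisher_2x2(tab))
}

#' Write domain calls as BED6 with the score column
#' @param domains caller output.
#' @param path output path.
#' @export
write_domains_bed <- function(domains, path) {
  if (nrow(domains) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- if ("score" %in% names(domains)) round(domains$score, 1) else
    rep(0, nrow(domains)) # merged sets carry no per-domain score
  out <- data.frame(chrom = domains$chrom, start = domains$start,
                    end = domains$end,
                    name = sprintf("domain_%d", seq_len(nrow(domains))),
                    score = score, strand = ".")
  write_bed(out, path)
}

#' @importFrom stats ppois
NULL
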