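# Windowed IP/Input log-ratio tracks, TSS-anchored and normalized-length
# meta-gene matrices, stratified per-gene signal, differential composites,
# and genome-stratum fractions.

#' Sums of abutting windows over a per-base vector
#'
#' The final partial window at the chromosome end is retained at its true
#' width.
#' @param v per-base numeric vector.
#' @param width window width in bases (>= 1).
#' @return numeric vector of window sums.
#' @export
window_sums <- function(v, width) {
  if (width < 1L) stop("width must be >= 1")
  n <- length(v)
  if (n == 0L) return(numeric(0))
  cs <- c(0, cumsum(v))
  starts <- seq.int(0L, n - 1L, by = width)
  ends <- pmin(starts + width, n)
  cs[ends + 1L] - cs[starts + 1L]
}

#' Median-normalise an IP/Input coverage pair
#'
#' Scales the input track so that the median of its non-zero window sums
#' matches the IP's. The scale factor is reported in the result.
#'
#' @param ip,input `coverage_track` objects over the same chromosomes.
#' @param width window width used for the medians (the analysis window).
#' @return list with elements `ip`, `input` (scaled) and `scale`.
#' @export
median_pair_normalize <- function(ip, input, width = 50L) {
  check_same_chroms(ip, input)
  med <- function(track) {
    w <- unlist(lapply(track$depth, window_sums, width = width), use.names = FALSE)
    w <- w[w > 0]
    if (!length(w)) stop("all-zero coverage track: ", track$label)
    median(w)
  }
  scale <- med(ip) / med(input)
  input$depth <- lapply(input$depth, `*`, scale)
  input$total_mapped <- input$total_mapped * scale
  list(ip = ip, input = input, scale = scale)
}

#' Windowed log2(IP/Input) ratio track
#'
#' Signal ratios for all abutting windows across the genome:
#' `log2((sum_IP(w) + pseudocount) / (sum_Input(w) + pseudocount))` after
#' per-pair median normalisation of the input. The pseudocount (1 read per
#' window by default) keeps every value finite.
#'
#' @param ip,input `coverage_track` objects over the same chromosomes.
#' @param width window width in bases (50 by default).
#' @param pseudocount depth added to both window sums.
#' @param normalize apply [median_pair_normalize()] first.
#' @return object of class `window_ratio_track`: per-chromosome window value
#'   vectors plus `width` and true `chrom_lengths`.
#' @export
window_log2_ratio <- function(ip, input, width = 50L, pseudocount = 1,
                              normalize = TRUE) {
  check_same_chroms(ip, input)
  scale <- 1
  if (normalize) {
    norm <- median_pair_normalize(ip, input, width = width)
    ip <- norm$ip; input <- norm$input; scale <- norm$scale
  }
  values <- lapply(names(ip$depth), function(ch) {
    wi <- window_sums(ip$depth[[ch]], width)
    wn <- window_sums(input$depth[[ch]], width)
    log2((wi + pseudocount) / (wn + pseudocount))
  })
  names(values) <- names(ip$depth)
  structure(list(values = values, width = as.integer(width),
                 chrom_lengths = ip$chrom_lengths,
                 pseudocount = pseudocount, input_scale = scale,
                 label = paste0(ip$label, "/", input$label)),
            class = "window_ratio_track")
}

#' @export
print.window_ratio_track <- function(x, ...) {
  cat("<window_ratio_track>", x$label, "-", x$width, "bp windows,",
      length(x$values), "chromosome(s)\n")
  invisible(x)
}

check_same_chroms <- function(a, b) {
  na <- names(if (inherits(a, "coverage_track")) a$depth else a$values)
  nb <- names(if (inherits(b, "coverage_track")) b$depth else b$values)
  if (!setequal(na, nb))
    stop("tracks cover different chromosome sets")
  invisible(TRUE)
}

# Per-base value vectors for either track flavour. Window values are
# expanded as a step function truncated at the true chromosome length.
base_values <- function(track) {
  if (inherits(track, "coverage_track")) return(track$depth)
  if (inherits(track, "window_ratio_track")) {
    out <- lapply(names(track$values), function(ch) {
      v <- rep(track$values[[ch]], each = track$width)
      v[seq_len(track$chrom_lengths[[ch]])]
    })
    names(out) <- names(track$values)
    return(out)
  }
  stop("expected a coverage_track or window_ratio_track")
}

#' Quantile normalisation across samples
#'
#' After normalisation the sorted values of every sample are identical (the
#' per-rank mean of the inputs); tied values receive the mean of their
#' spanned ranks. Applying the transform twice equals applying it once.
#'
#' @param x numeric matrix (samples in columns) or list of equal-length
#'   numeric vectors.
#' @return object of the same shape as the input.
#' @export
quantile_normalize <- function(x) {
  was_list <- is.list(x)
  if (was_list) {
    lens <- vapply(x, length, integer(1))
    if (length(unique(lens)) != 1L) stop("vectors must have equal length")
    x <- do.call(cbind, x)
  }
  n <- nrow(x)
  sorted <- apply(x, 2L, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = n)
  target <- rowMeans(sorted)
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (target[lo] + target[hi]) / 2
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = n)
  dimnames(out) <- dimnames(x)
  if (was_list) {
    res <- lapply(seq_len(ncol(out)), function(j) out[, j])
    names(res) <- colnames(out)
    return(res)
  }
  out
}

# Oriented, equal bins over the half-open oriented offset range [o1, o2)
# around an anchor point: oriented offset o maps to genomic `anchor + o` on
# the plus strand and `anchor - o` on the minus strand. Bin j covers oriented
# offsets [o1 + ceil(j*span/n), o1 + ceil((j+1)*span/n)); defining bins in
# oriented coordinates makes binning exactly strand-equivariant even when
# span is not divisible by n.
oriented_bins <- function(anchor, o1, o2, strand, n_bins) {
  span <- o2 - o1
  b <- o1 + ceiling((0:n_bins) * span / n_bins)
  lo <- b[-length(b)]; hi <- b[-1L]
  if (strand == "+") {
    cbind(start = anchor + lo, end = anchor + hi)
  } else {
    cbind(start = anchor - hi + 1L, end = anchor - lo + 1L)
  }
}

# Mean of per-base values over [a, b) clipped to [0, len); NA when nothing
# remains (or when partial = FALSE and the bin is truncated).
clipped_mean <- function(cs, len, a, b, partial = TRUE) {
  a2 <- max(a, 0L); b2 <- min(b, len)
  if (b2 <= a2) return(NA_real_)
  if (!partial && (a < 0L || b > len)) return(NA_real_)
  (cs[b2 + 1L] - cs[a2 + 1L]) / (b2 - a2)
}

# Per-chromosome cumulative sums, shared by the matrix builders.
chrom_cumsums <- function(vals) lapply(vals, function(v) c(0, cumsum(v)))

#' TSS-anchored signal matrix
#'
#' Genes x bins matrix of mean signal over `flank` bases either side of the
#' TSS at `bin` resolution (+-2.5 kb at 100 bp by default, 50 columns).
#' Rows are oriented so column 1 is most upstream for both strands; bins
#' truncated at a chromosome edge are flagged missing (NA).
#'
#' @param track `coverage_track` or `window_ratio_track`.
#' @param genes gene table.
#' @param flank flank width in bases (divisible by `bin`).
#' @param bin bin width in bases.
#' @return a numeric matrix with attribute `anchor`.
#' @export
tss_signal_matrix <- function(track, genes, flank = 2500L, bin = 100L) {
  if (flank %% bin != 0L) stop("flank must be divisible by bin")
  vals <- base_values(track)
  cs <- chrom_cumsums(vals)
  lens <- vapply(vals, length, numeric(1))
  n_bins <- as.integer(2L * flank / bin)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    if (!ch %in% names(vals)) stop("chromosome missing from track: ", ch)
    tss <- genes$tss[i]
    if (tss < 0 || tss >= lens[[ch]])
      stop("gene TSS off chromosome: ", genes$gene_id[i])
    bins <- oriented_bins(tss, -flank, flank, genes$strand[i], n_bins)
    mat[i, ] <- vapply(seq_len(n_bins), function(j)
      clipped_mean(cs[[ch]], lens[[ch]], bins[j, 1L], bins[j, 2L],
                   partial = FALSE), numeric(1))
  }
  structure(mat, anchor = list(type = "tss", flank = flank, bin = bin))
}

#' Normalized-length meta-gene signal matrix
#'
#' Each gene's region spans TSS - `flank_fraction`*L to TES +
#' `flank_fraction`*L (L = gene length), split into `n_bins` equal
#' strand-oriented bins (40 bins, 10 upstream / 20 body / 10 downstream at
#' defaults). Bin means are per-base means that ignore bases beyond the
#' chromosome edge; genes shorter than `n_bins` bases give an all-NA row,
#' listed in the `short_genes` attribute.
#'
#' @inheritParams tss_signal_matrix
#' @param n_bins number of bins (divisible by 4 so the flanks land on whole
#'   bins at the default flank fraction).
#' @param flank_fraction flank length as a fraction of gene length.
#' @return a numeric matrix with attributes `anchor` and `short_genes`.
#' @export
metagene_matrix <- function(track, genes, n_bins = 40L, flank_fraction = 0.5) {
  if (n_bins %% 4L != 0L) stop("n_bins must be divisible by 4")
  vals <- base_values(track)
  cs <- chrom_cumsums(vals)
  lens <- vapply(vals, length, numeric(1))
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, NULL))
  short <- character(0)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    if (!ch %in% names(vals)) stop("chromosome missing from track: ", ch)
    L <- genes$end[i] - genes$start[i]
    if (L < n_bins) { short <- c(short, genes$gene_id[i]); next }
    f <- round(flank_fraction * L)
    bins <- oriented_bins(genes$tss[i], -f, L + f, genes$strand[i], n_bins)
    mat[i, ] <- vapply(seq_len(n_bins), function(j)
      clipped_mean(cs[[ch]], lens[[ch]], bins[j, 1L], bins[j, 2L]),
      numeric(1))
  }
  structure(mat, anchor = list(type = "metagene", n_bins = n_bins,
                               flank_fraction = flank_fraction),
            short_genes = short)
}

#' Stratified per-gene signal: upstream, TSS, gene body
#'
#' Mean signal in three strand-oriented strata per gene: TSS +-
#' `tss_halfwidth`; gene body from TSS + `body_start_offset` through TES +
#' `body_end_pad` (inclusive); and an upstream window of `upstream_span`
#' bases abutting the TSS window. The body is flagged undefined (NA) for
#' genes shorter than `body_start_offset` bases.
#'
#' @inheritParams tss_signal_matrix
#' @param tss_halfwidth half-width of the TSS window in bases.
#' @param body_start_offset first oriented base of the body stratum
#'   (TSS + 501 by default).
#' @param body_end_pad bases past the TES included in the body stratum.
#' @param upstream_span width of the upstream stratum.
#' @return data.frame with columns `gene_id`, `upstream`, `tss`, `body`,
#'   `body_defined`.
#' @export
stratified_gene_signal <- function(track, genes, tss_halfwidth = 500L,
                                   body_start_offset = 501L,
                                   body_end_pad = 2000L,
                                   upstream_span = 1500L) {
  vals <- base_values(track)
  cs <- chrom_cumsums(vals)
  lens <- vapply(vals, length, numeric(1))
  n <- nrow(genes)
  up <- tssv <- body <- rep(NA_real_, n)
  defined <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ch <- genes$chrom[i]
    if (!ch %in% names(vals)) stop("chromosome missing from track: ", ch)
    L <- genes$end[i] - genes$start[i]
    # oriented half-open offsets relative to the TSS
    o_mean <- function(o1, o2) {
      if (genes$strand[i] == "+") {
        clipped_mean(cs[[ch]], lens[[ch]], genes$tss[i] + o1, genes$tss[i] + o2)
      } else {
        clipped_mean(cs[[ch]], lens[[ch]],
                     genes$tss[i] - o2 + 1L, genes$tss[i] - o1 + 1L)
      }
    }
    tssv[i] <- o_mean(-tss_halfwidth, tss_halfwidth)
    up[i] <- o_mean(-(tss_halfwidth + upstream_span), -tss_halfwidth)
    if (L > body_start_offset) {
      body[i] <- o_mean(body_start_offset, L + body_end_pad)
    } else {
      defined[i] <- FALSE
    }
  }
  data.frame(gene_id = genes$gene_id, upstream = up, tss = tssv, body = body,
             body_defined = defined, stringsAsFactors = FALSE)
}

#' Differential composite between two signal matrices
#'
#' Per-bin mean over genes of `A - B`, with per-gene differences returned as
#' well. Bins missing in either matrix are excluded pairwise.
#'
#' @param matA,matB signal matrices with identical anchors and row sets.
#' @return list with `profile` (per-bin mean difference) and `per_gene`
#'   (genes x bins difference matrix).
#' @export
differential_composite <- function(matA, matB) {
  if (!identical(dim(matA), dim(matB)) ||
      !identical(rownames(matA), rownames(matB)))
    stop("matrices must share dimensions and row (gene) sets")
  if (!identical(attr(matA, "anchor"), attr(matB, "anchor")))
    stop("matrices must share anchor metadata")
  d <- matA - matB
  list(profile = colMeans(d, na.rm = TRUE), per_gene = d)
}

#' Row order for ranked signal heatmaps
#'
#' Descending order of per-gene mean signal in a reference matrix, the
#' ranking used for TSS heatmaps.
#' @param mat a signal matrix.
#' @return integer permutation of the rows.
#' @export
heatmap_row_order <- function(mat) {
  order(rowMeans(mat, na.rm = TRUE), decreasing = TRUE)
}

# TRUE for each point lying inside any interval of a sorted, merged set.
points_in_intervals <- function(chrom, pos, intervals) {
  flag <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(sub) == 0L) next
    idx <- findInterval(pos[sel], sub$start)
    flag[sel] <- idx > 0L & pos[sel] < sub$end[pmax(idx, 1L)]
  }
  flag
}

#' Genome stratification and per-stratum signal fractions
#'
#' Partitions the genome into four disjoint, exhaustive strata - CGI TSS
#' (+- `tss_halfwidth`), non-CGI TSS (+- `tss_halfwidth`), intragenic (gene
#' bodies minus TSS windows) and intergenic (the remainder) - and reports
#' each stratum's fraction of total track signal plus its depth scaled to
#' 10 million mapped reads. TSS windows are classified CGI/non-CGI by
#' whether the TSS point lies in a CGI interval; where windows of the two
#' classes overlap, CGI takes precedence.
#'
#' @param track a `coverage_track`.
#' @param genes gene table.
#' @param cgis sorted, merged CGI interval data.frame.
#' @param tss_halfwidth TSS window half-width (5 kb by default).
#' @return data.frame with one row per stratum: `bases`, `signal`,
#'   `fraction`, `depth_per_10M`.
#' @export
genome_strata_fractions <- function(track, genes, cgis, tss_halfwidth = 5000L) {
  strata <- c("intergenic", "intragenic", "tss_noncgi", "tss_cgi")
  sig <- bases <- setNames(numeric(4L), strata)
  cgi_flag <- points_in_intervals(genes$chrom, genes$tss, cgis)
  for (ch in names(track$depth)) {
    v <- track$depth[[ch]]
    len <- length(v)
    lab <- integer(len) # 0 intergenic
    g <- genes[genes$chrom == ch, , drop = FALSE]
    gf <- cgi_flag[genes$chrom == ch]
    if (nrow(g)) {
      for (i in seq_len(nrow(g))) {
        a <- max(g$start[i], 0L) + 1L; b <- min(g$end[i], len)
        if (b >= a) lab[a:b] <- 1L
      }
      for (cls in c(FALSE, TRUE)) { # non-CGI first so CGI wins overlaps
        for (i in which(gf == cls)) {
          a <- max(g$tss[i] - tss_halfwidth, 0L) + 1L
          b <- min(g$tss[i] + tss_halfwidth + 1L, len)
          if (b >= a) lab[a:b] <- if (cls) 3L else 2L
        }
      }
    }
    for (s in 0:3) {
      m <- lab == s
      bases[s + 1L] <- bases[s + 1L] + sum(m)
      sig[s + 1L] <- sig[s + 1L] + sum(v[m])
    }
  }
  total <- sum(sig)
  frac <- if (total > 0) sig / total else rep(NA_real_, 4L)
  scale <- if (track$total_mapped > 0) 1e7 / track$total_mapped else NA_real_
  data.frame(stratum = strata, bases = as.numeric(bases), signal = sig,
             fraction = frac, depth_per_10M = sig * scale,
             row.names = NULL, stringsAsFactors = FALSE)
}
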