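#' @importFrom data.table fread fwrite data.table
#' @importFrom stats median rnorm rpois rlnorm runif rbinom setNames
NULL

# All coordinates are 0-based half-open internally, matching BED/bedGraph.
# Any 1-based display is formatting only.

#' Construct a gene table with strand-aware TSS/TES
#'
#' A gene table is a plain `data.frame` with columns `gene_id`, `symbol`,
#' `chrom`, `start`, `end`, `strand`, `tss`, `tes`. Coordinates are 0-based
#' half-open. The TSS is `start` on the plus strand and `end - 1` (the last
#' covered base) on the minus strand; the TES is the opposite terminus.
#'
#' @param gene_id,symbol character vectors of identifiers and display names.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"` for every gene.
#' @return a `data.frame` with computed `tss` and `tes` columns.
#' @export
gene_table <- function(gene_id, symbol, chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  if (length(end) != n || length(gene_id) != n)
    stop("gene_id, start and end must have equal length")
  symbol <- rep_len(as.character(symbol), n)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) || any(start >= end))
    stop("gene intervals must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-', got: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicated gene_id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  plus <- strand == "+"
  data.frame(
    gene_id = as.character(gene_id), symbol = as.character(symbol),
    chrom = as.character(chrom), start = start, end = end,
    strand = as.character(strand),
    tss = ifelse(plus, start, end - 1L),
    tes = ifelse(plus, end - 1L, start),
    stringsAsFactors = FALSE
  )
}

#' Read a gene annotation file (6-column TSV or BED12)
#'
#' The TSV form has a header row with columns
#' `gene_id, symbol, chrom, start, end, strand`; the BED12 form is headerless
#' and uses the BED `name` field as both id and symbol. Strand-aware TSS/TES
#' are computed on load and duplicate gene ids are rejected.
#'
#' @param path file path.
#' @return a gene table (see [gene_table()]).
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty gene annotation file: ", path)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (nfield >= 12L) {
    dt <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
    gene_table(dt[[4L]], dt[[4L]], dt[[1L]], dt[[2L]], dt[[3L]], dt[[6L]])
  } else {
    dt <- fread(path, header = TRUE, sep = "\t", data.table = FALSE)
    need <- c("gene_id", "symbol", "chrom", "start", "end", "strand")
    if (!all(need %in% names(dt)))
      stop("gene TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(is.na(dt$start) | is.na(dt$end))
    if (length(bad))
      stop("malformed gene record at line ", bad[1L] + 1L, " of ", path)
    gene_table(dt$gene_id, dt$symbol, dt$chrom, dt$start, dt$end, dt$strand)
  }
}

#' Write a gene table as TSV
#' @param genes a gene table.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes[order(genes$chrom, genes$start),
               c("gene_id", "symbol", "chrom", "start", "end", "strand")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Construct a coverage track
#'
#' Per-chromosome base-resolution read depth (hits per base) plus the total
#' mapped-read count the track represents.
#'
#' @param depth named list of non-negative numeric vectors, one per chromosome.
#' @param label sample name (population, IP/Input, antibody).
#' @param read_length nominal read length used to convert summed per-base
#'   depth into a mapped-read count when `total_mapped` is not given.
#' @param total_mapped mapped-read count; computed from the depth sum if `NULL`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(depth, label = "", read_length = 42L,
                           total_mapped = NULL) {
  if (length(depth) &&
      (is.null(names(depth)) || any(!nzchar(names(depth)))))
    stop("depth list must be named by chromosome")
  for (v in depth) if (any(v < 0)) stop("coverage depths must be >= 0")
  tot <- sum(vapply(depth, sum, numeric(1)))
  if (is.null(total_mapped)) total_mapped <- round(tot / read_length)
  structure(
    list(depth = depth, label = label, read_length = read_length,
         total_mapped = total_mapped,
         chrom_lengths = vapply(depth, length, integer(1))),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", x$label, "\n",
      length(x$depth), "chromosome(s),",
      sum(as.numeric(x$chrom_lengths)), "bases,",
      x$total_mapped, "mapped reads\n")
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Four-column, 0-based half-open bedGraph. Gaps are filled with zero depth.
#' Unsorted input is tolerated (sorted on load, with a message); overlapping
#' records are an error because overlapping depth is ambiguous.
#'
#' @param path bedGraph path.
#' @param chrom_lengths optional named integer vector; when given, vectors are
#'   padded with zeros to these lengths (otherwise to the last covered base).
#' @param label,read_length passed to [coverage_track()].
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL, label = basename(path),
                          read_length = 42L) {
  if (file.size(path) == 0L) {
    depth <- list()
    if (!is.null(chrom_lengths))
      depth <- lapply(chrom_lengths, numeric)
    return(coverage_track(depth, label = label, read_length = read_length))
  }
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"),
              colClasses = list(character = 1), data.table = TRUE)
  if (any(dt$value < 0)) stop("negative depth value in ", path)
  if (any(dt$start < 0 | dt$start >= dt$end)) stop("invalid interval in ", path)
  o <- order(dt$chrom, dt$start)
  if (!identical(o, seq_len(nrow(dt)))) {
    message("read_bedgraph: input not sorted; sorting ", basename(path))
    dt <- dt[o, ]
  }
  chroms <- unique(dt$chrom)
  depth <- vector("list", length(chroms)); names(depth) <- chroms
  for (ch in chroms) {
    sub <- dt[dt$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping bedGraph records on ", ch, " in ", path)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(sub$end)
    v <- numeric(len)
    for (i in seq_len(nrow(sub)))
      if (sub$value[i] != 0)
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    depth[[ch]] <- v
  }
  if (!is.null(chrom_lengths))
    for (ch in setdiff(names(chrom_lengths), chroms))
      depth[[ch]] <- numeric(chrom_lengths[[ch]])
  coverage_track(depth, label = label, read_length = read_length)
}

#' Write a coverage track as bedGraph
#'
#' Equal-value runs are merged; zero-depth runs are omitted. Output is sorted
#' by (chrom, start).
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- list()
  for (ch in sort(names(track$depth))) {
    v <- track$depth[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    rows[[ch]] <- data.table(chrom = ch, start = starts[keep],
                             end = ends[keep], value = r$values[keep])
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table(chrom = character(), start = integer(),
               end = integer(), value = numeric())
  fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a BED file of CpG-island intervals
#'
#' Intervals are sorted and merged (overlapping or book-ended runs coalesced)
#' so the invariants of an unstranded interval set hold.
#'
#' @param path BED3+ path.
#' @return data.frame with columns `chrom`, `start`, `end`, sorted and
#'   non-overlapping.
#' @export
read_cgi_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  cgi <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]))
  merge_intervals(cgi)
}

#' Write intervals as BED3
#' @param intervals data.frame with `chrom`, `start`, `end` (and optionally
#'   `name`/`score` columns, written when present).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(iv))
  fwrite(iv[, cols, drop = FALSE], path, sep = "\t", col.names = FALSE,
         scipen = 50)
  invisible(path)
}

#' Sort and merge an interval set
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param gap merge intervals separated by less than `gap` bases
#'   (0 merges only overlapping/book-ended intervals).
#' @return sorted, non-overlapping data.frame.
#' @export
merge_intervals <- function(intervals, gap = 0L) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  out <- list()
  k <- 0L
  cur_chrom <- ""; cur_start <- 0L; cur_end <- -1L
  for (i in seq_len(nrow(iv))) {
    if (iv$chrom[i] != cur_chrom || iv$start[i] > cur_end + gap) {
      if (cur_end >= 0L) {
        k <- k + 1L
        out[[k]] <- list(chrom = cur_chrom, start = cur_start, end = cur_end)
      }
      cur_chrom <- iv$chrom[i]; cur_start <- iv$start[i]; cur_end <- iv$end[i]
    } else {
      cur_end <- max(cur_end, iv$end[i])
    }
  }
  k <- k + 1L
  out[[k]] <- list(chrom = cur_chrom, start = cur_start, end = cur_end)
  res <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  rownames(res) <- NULL
  res
}

#' Distance from a point to a genomic interval
#'
#' Zero when the point lies inside the half-open interval, otherwise the gap
#' to the nearest covered base: `min(|p - start|, |p - (end - 1)|)`. Points on
#' a different chromosome are at `Inf`.
#'
#' @param chrom,start,end the interval (0-based half-open).
#' @param point_chrom,point the query point.
#' @return numeric distance in bases (vectorised over the interval arguments).
#' @export
interval_distance <- function(chrom, start, end, point_chrom, point) {
  d <- ifelse(point >= start & point < end, 0,
              pmin(abs(point - start), abs(point - (end - 1))))
  ifelse(chrom == point_chrom, d, Inf)
}
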