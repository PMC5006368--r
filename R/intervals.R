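#' @name genomic-intervals
#' @title Genomic interval conventions
#'
#' @description
#' All interval tables in this package use 0-based half-open coordinates
#' (the BED convention): `start` is the first base of the feature, `end`
#' is one past the last. `strand` is one of `"+"`, `"-"` or `"*"`
#' (unstranded). Single-base positions (summits, motif centers, 5' ends,
#' probe midpoints) are 0-based.
NULL

# Validate an interval data frame. Returns it invisibly.
validate_intervals <- function(x, stranded = FALSE, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
    stop(what, ": chrom must be non-empty")
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$end <= x$start)) stop(what, ": end must be > start")
  if (!is.null(x$strand)) {
    ok <- x$strand %in% c("+", "-", "*")
    if (any(!ok)) stop(what, ": strand must be one of +, -, *")
    if (stranded && any(x$strand == "*"))
      stop(what, ": strand must be + or - (unstranded not allowed)")
  } else if (stranded) {
    stop(what, ": stranded table requires a strand column")
  }
  invisible(x)
}

# Bridge to GRanges (1-based closed) for interval algebra.
as_granges <- function(x, ignore_strand = TRUE) {
  strand <- if (!ignore_strand && !is.null(x$strand)) x$strand
            else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Merge intervals overlapping by at least one base pair
#'
#' Two intervals belong to the same merged region iff they are connected by
#' a chain of pairwise overlaps of >= 1 bp. Book-ended (abutting) intervals
#' are deliberately *not* merged: a region ending at `x` and a region
#' starting at `x` share no base. This differs from `bedtools merge`'s
#' default (distance 0 merges abutting intervals).
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param labels optional character vector, one label per interval (e.g.
#'   the ChIP factor a peak belongs to).
#' @return list with `regions`: merged, sorted, disjoint intervals with a
#'   `region_id` column and a `labels` column (comma-collapsed sorted
#'   unique source labels, if labels were given); and `members`: a data
#'   frame mapping each input row (`interval_index`) to its `region_id`.
#' @export
merge_overlapping <- function(intervals, labels = NULL) {
  validate_intervals(intervals)
  if (!is.null(labels)) stopifnot(length(labels) == nrow(intervals))
  if (nrow(intervals) == 0) {
    return(list(
      regions = data.frame(region_id = integer(), chrom = character(),
                           start = integer(), end = integer(),
                           labels = character()),
      members = data.frame(interval_index = integer(), region_id = integer())
    ))
  }
  gr <- as_granges(intervals)
  # min.gapwidth = 0 keeps abutting intervals apart (>= 1 bp rule)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L,
                                      ignore.strand = TRUE)
  region_of <- integer(length(gr))
  region_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  regions <- data.frame(
    region_id = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    lab_by_region <- split(labels, region_of)
    regions$labels <- ""
    regions$labels[as.integer(names(lab_by_region))] <-
      vapply(lab_by_region,
             function(l) paste(sort(unique(l)), collapse = ","), "")
  }
  list(regions = regions,
       members = data.frame(interval_index = seq_along(gr),
                            region_id = region_of))
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count number of reads in the region (vectorised).
#' @param region_length region length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return numeric RPKM values.
#' @export
rpkm <- function(read_count, region_length, library_size) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  read_count / (region_length / 1000) / (library_size / 1e6)
}

#' Drop reads or intervals overlapping an exclusion list
#'
#' Pre-filter used before genome-wide signal comparisons: anything with
#' >= 1 bp overlap with an excluded region (e.g. an ENCODE-blacklist-style
#' BED) is removed.
#'
#' @param x interval data frame.
#' @param blacklist interval data frame of regions to exclude.
#' @return `x` without rows overlapping the blacklist.
#' @export
filter_blacklist <- function(x, blacklist) {
  validate_intervals(x)
  validate_intervals(blacklist, what = "blacklist")
  if (nrow(x) == 0 || nrow(blacklist) == 0) return(x)
  n <- GenomicRanges::countOverlaps(as_granges(x), as_granges(blacklist),
                                    minoverlap = 1L, ignore.strand = TRUE)
  x[n == 0, , drop = FALSE]
}

#' Count reads in fixed-width genome bins
#'
#' Each read is assigned to the bin containing its midpoint (rounded
#' down). Bins cover only the declared chromosomes.
#'
#' @param reads stranded or unstranded interval data frame.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 10 kb).
#' @return data frame `chrom`, `bin` (0-based index), `count`, with one
#'   row per bin of every declared chromosome; attribute `bin_size`.
#' @export
bin_reads <- function(reads, genome, bin_size = 10000L) {
  stopifnot(bin_size > 0, length(genome) > 0, !is.null(names(genome)))
  validate_intervals(reads, what = "read")
  grid <- do.call(rbind, lapply(names(genome), function(ch) {
    nb <- ceiling(genome[[ch]] / bin_size)
    data.frame(chrom = ch, bin = seq_len(nb) - 1L)
  }))
  keep <- reads$chrom %in% names(genome)
  reads <- reads[keep, , drop = FALSE]
  mid <- floor((reads$start + reads$end) / 2)
  key <- paste(reads$chrom, mid %/% bin_size)
  tab <- table(key)
  grid$count <- as.integer(tab[paste(grid$chrom, grid$bin)])
  grid$count[is.na(grid$count)] <- 0L
  attr(grid, "bin_size") <- bin_size
  grid
}

#' Rank correlation of two binned genome tracks
#'
#' @param a,b outputs of [bin_reads()] on the same bin grid.
#' @param method correlation method, default Spearman.
#' @return the correlation coefficient.
#' @export
binned_track_correlation <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- merge(a, b, by = c("chrom", "bin"))
  if (nrow(m) < 3) stop("fewer than 3 shared bins")
  stats::cor(m$count.x, m$count.y, method = method)
}
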