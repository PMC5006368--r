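# Readers and writers for BED-family text formats. All readers tolerate
# `track ...`, `browser ...` and `#` comment lines and report the 1-based
# file line number of any malformed row.

read_format_lines <- function(path) {
  lines <- readLines(path)
  keep <- !(grepl("^(track|browser)\\b", lines) | grepl("^#", lines) |
              !nzchar(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

check_ncol <- function(fields, lineno, expected, format) {
  n <- lengths(fields)
  bad <- which(!(n %in% expected))
  if (length(bad) > 0)
    stop(sprintf("malformed %s row at line %d: expected %s fields, found %d",
                 format, lineno[bad[1]], paste(expected, collapse = " or "),
                 n[bad[1]]))
}

num_field <- function(fields, i, lineno, format) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    stop(sprintf("malformed %s row at line %d: field %d is not numeric",
                 format, lineno[bad[1]], i))
  v
}

#' Read genomic intervals, peaks or reads from BED-family files
#'
#' Supported formats: `"bed"` (BED3--BED6), `"narrowPeak"` (ENCODE
#' 10-column; column 10 is the summit offset from `start`, with `-1`
#' mapped to the interval midpoint rounded down), and `"tagAlign"`
#' (6-column aligned tags with mandatory `+`/`-` strand). Coordinates are
#' returned 0-based half-open as in the files themselves.
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"tagAlign"`.
#' @param factor optional factor label attached to every row (for peak
#'   files of a single ChIP target).
#' @return data frame of intervals; narrowPeak adds `summit` (absolute
#'   0-based bp) and `signal`; tagAlign rows are stranded reads.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "tagAlign"),
                           factor = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  fl <- read_format_lines(path)
  fields <- split_fields(fl$lines)
  lineno <- fl$lineno
  if (length(fields) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character())
    if (format == "narrowPeak") { out$signal <- numeric(); out$summit <- integer() }
    return(out)
  }
  expected <- switch(format, bed = 3:6, narrowPeak = 10L, tagAlign = 6L)
  check_ncol(fields, lineno, expected, format)
  n <- lengths(fields)
  get <- function(i, default = NA_character_) {
    vapply(seq_along(fields), function(k)
      if (n[k] >= i) fields[[k]][[i]] else default, "")
  }
  out <- data.frame(
    chrom = get(1),
    start = as.integer(num_field(fields, 2, lineno, format)),
    end = as.integer(num_field(fields, 3, lineno, format)),
    name = get(4),
    score = suppressWarnings(as.numeric(get(5))),
    strand = get(6),
    stringsAsFactors = FALSE
  )
  out$strand[is.na(out$strand) | out$strand == "."] <- "*"
  bad <- which(out$end <= out$start | out$start < 0)
  if (length(bad) > 0)
    stop(sprintf("malformed %s row at line %d: empty or negative interval",
                 format, lineno[bad[1]]))
  if (format == "tagAlign") {
    bad <- which(!(out$strand %in% c("+", "-")))
    if (length(bad) > 0)
      stop(sprintf("malformed tagAlign row at line %d: strand must be + or -",
                   lineno[bad[1]]))
  }
  if (format == "narrowPeak") {
    out$signal <- num_field(fields, 7, lineno, format)
    offset <- as.integer(num_field(fields, 10, lineno, format))
    summit <- ifelse(offset == -1L,
                     out$start + (out$end - out$start) %/% 2L,
                     out$start + offset)
    bad <- which(summit < out$start | summit >= out$end)
    if (length(bad) > 0)
      stop(sprintf("narrowPeak row at line %d: summit outside interval",
                   lineno[bad[1]]))
    out$summit <- as.integer(summit)
  }
  if (!is.null(factor)) out$factor <- factor
  validate_intervals(out, stranded = (format == "tagAlign"), what = format)
  out
}

#' Write intervals as BED6
#'
#' @param x interval data frame (`chrom`, `start`, `end`; optional `name`,
#'   `score`, `strand`).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  df <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if (!is.null(x$name)) ifelse(is.na(x$name), ".", x$name) else ".",
    score = if (!is.null(x$score)) ifelse(is.na(x$score), 0, x$score) else 0,
    strand = if (!is.null(x$strand)) ifelse(x$strand == "*", ".", x$strand) else "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write stranded reads as tagAlign
#' @param reads stranded interval data frame.
#' @param path output path.
#' @export
write_tagalign <- function(reads, path) {
  validate_intervals(reads, stranded = TRUE, what = "read")
  df <- data.frame(reads$chrom, reads$start, reads$end, "N", 1000,
                   reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks peak data frame with `summit` (absolute bp) and `signal`.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks)
  stopifnot(!is.null(peaks$summit))
  stopifnot(all(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  sig <- if (!is.null(peaks$signal)) peaks$signal else 0
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, ".", 0, ".",
                   sig, -1, -1, peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bp track as bedGraph
#'
#' Consecutive equal values are collapsed into maximal runs.
#'
#' @param track named list of per-bp numeric vectors, one per chromosome
#'   (position i of the vector is genomic bp i-1).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(is.list(track), !is.null(names(track)))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- rle(track[[ch]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, start[keep], end[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}
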