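# Position weight matrix scanning with explicit background models, exact
# tail p-values by dynamic programming, per-region best hits with
# orientation assignment, and column permutation for background matrices.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif count matrix
#'
#' @param counts 4 x w numeric matrix of non-negative per-column base
#'   counts, rows in A, C, G, T order (rownames are set if absent).
#' @param pseudocount added to every cell before normalisation (default 1).
#' @return object of class `motif_matrix` with elements `counts`,
#'   `pseudocount`, `probs` (column-normalised) and `width`.
#' @export
motif_matrix <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            pseudocount >= 0)
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  adj <- counts + pseudocount
  tot <- colSums(adj)
  if (any(tot <= 0)) stop("every column must have positive total after pseudocount")
  probs <- sweep(adj, 2, tot, "/")
  structure(list(counts = counts, pseudocount = pseudocount,
                 probs = probs, width = ncol(counts)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: width %d, pseudocount %g, IC %.2f bits\n",
              x$width, x$pseudocount, information_content(x)))
  invisible(x)
}

#' Total information content of a motif matrix (bits)
#' @param matrix a [motif_matrix()].
#' @return total IC in bits, summed over columns against a uniform background.
#' @export
information_content <- function(matrix) {
  p <- matrix$probs
  sum(2 + colSums(ifelse(p > 0, p * log2(p), 0)))
}

#' Permute the columns of a motif matrix
#'
#' Columns are reordered by a uniform random permutation; per-column base
#' composition and hence total information content are preserved. Used to
#' build sequence-composition-matched background motifs.
#'
#' @param matrix a [motif_matrix()].
#' @param seed integer seed (the permutation is reproducible; the caller's
#'   RNG state is untouched).
#' @return a new `motif_matrix`.
#' @export
permute_matrix <- function(matrix, seed = NULL) {
  perm <- with_seed(seed, sample(matrix$width))
  motif_matrix(matrix$counts[, perm, drop = FALSE],
               pseudocount = matrix$pseudocount)
}

#' Read a TRANSFAC-style count matrix
#'
#' Accepts the usual TRANSFAC layout: an optional `ID`/`NA` header, a
#' `P0  A  C  G  T` column-header line, numbered rows of four counts, and
#' a terminating `//`. Only the first matrix in the file is read.
#'
#' @param path file path.
#' @param pseudocount passed to [motif_matrix()].
#' @return a `motif_matrix`.
#' @export
read_transfac <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  p0 <- grep("^P0\\b", lines)
  if (length(p0) == 0) stop("no P0 header line found in ", path)
  hdr <- strsplit(trimws(lines[p0[1]]), "\\s+")[[1]][-1]
  ord <- match(DNA_BASES, toupper(hdr))
  if (any(is.na(ord[1:4]))) stop("P0 header must name A, C, G, T")
  rows <- list()
  for (i in seq(p0[1] + 1, length(lines))) {
    ln <- trimws(lines[i])
    if (grepl("^(//|XX)", ln) || !grepl("^[0-9]", ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    rows[[length(rows) + 1]] <- as.numeric(f[2:5])[ord]
  }
  if (length(rows) == 0) stop("no count rows found in ", path)
  motif_matrix(t(do.call(rbind, rows)), pseudocount = pseudocount)
}

#' Write a motif matrix in TRANSFAC format
#' @param matrix a `motif_matrix`.
#' @param path output path.
#' @param id identifier written on the ID line.
#' @export
write_transfac <- function(matrix, path, id = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ID %s", id), "P0\tA\tC\tG\tT"), con)
  for (j in seq_len(matrix$width))
    writeLines(sprintf("%02d\t%s", j,
                       paste(format(matrix$counts[, j]), collapse = "\t")), con)
  writeLines("//", con)
  invisible(path)
}

encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  code
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Estimate a Markov background model from sequences
#'
#' Base (order 0) or transition (order 1) frequencies are counted on the
#' supplied sequences and their reverse complements, so the model is
#' strand-symmetric. `N` bases are ignored.
#'
#' @param sequences character vector (or `DNAStringSet`) of sequences.
#' @param order 0 or 1.
#' @return list with `order`, `freq` (marginal base frequencies) and, for
#'   order 1, `trans` (4 x 4 row-stochastic transition matrix).
#' @export
estimate_background <- function(sequences, order = 1) {
  stopifnot(order %in% c(0, 1))
  sequences <- unname(as.character(sequences))
  both <- c(sequences, vapply(sequences, revcomp, "", USE.NAMES = FALSE))
  codes <- lapply(both, encode_dna)
  all_codes <- unlist(codes, use.names = FALSE)
  freq <- tabulate(all_codes, 4) + 1  # add-one smoothing
  freq <- freq / sum(freq)
  names(freq) <- DNA_BASES
  bg <- list(order = order, freq = freq)
  if (order == 1) {
    cnt <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (code in codes) {
      if (length(code) < 2) next
      a <- code[-length(code)]; b <- code[-1]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        t4 <- tabulate((a[ok] - 1) * 4 + b[ok], 16)
        cnt <- cnt + matrix(t4, 4, 4, byrow = TRUE)
      }
    }
    bg$trans <- sweep(cnt, 1, rowSums(cnt), "/")
  }
  bg
}

#' Uniform background model
#' @param order Markov order (0 or 1).
#' @return a background model with equal base frequencies (and uniform
#'   transitions for order 1).
#' @export
uniform_background <- function(order = 0) {
  bg <- list(order = order, freq = stats::setNames(rep(0.25, 4), DNA_BASES))
  if (order == 1) bg$trans <- matrix(0.25, 4, 4,
                                     dimnames = list(DNA_BASES, DNA_BASES))
  bg
}

# log2 background probability of every window of width w (NA where the
# window contains an unknown base).
window_log2_bg <- function(code, w, background) {
  L <- length(code)
  npos <- L - w + 1
  if (npos < 1) return(numeric(0))
  lf <- log2(background$freq)
  out <- numeric(npos)
  nas <- logical(npos)
  if (background$order == 0) {
    for (j in seq_len(w)) {
      b <- code[j:(j + npos - 1)]
      nas <- nas | is.na(b)
      out <- out + lf[ifelse(is.na(b), 1L, b)]
    }
  } else {
    lt <- log2(background$trans)
    b1 <- code[seq_len(npos)]
    nas <- is.na(b1)
    out <- lf[ifelse(nas, 1L, b1)]
    for (j in seq(2, length.out = w - 1)) {
      prev <- code[(j - 1):(j + npos - 2)]
      cur <- code[j:(j + npos - 1)]
      bad <- is.na(prev) | is.na(cur)
      nas <- nas | bad
      out <- out + lt[cbind(ifelse(bad, 1L, prev), ifelse(bad, 1L, cur))]
    }
  }
  out[nas] <- NA_real_
  out
}

# log2 matrix probability of every window.
window_log2_mat <- function(code, matrix) {
  w <- matrix$width
  L <- length(code)
  npos <- L - w + 1
  if (npos < 1) return(numeric(0))
  lp <- log2(matrix$probs)
  out <- numeric(npos)
  nas <- logical(npos)
  for (j in seq_len(w)) {
    b <- code[j:(j + npos - 1)]
    nas <- nas | is.na(b)
    out <- out + lp[cbind(ifelse(is.na(b), 1L, b), j)]
  }
  out[nas] <- NA_real_
  out
}

#' Exact score distribution of a motif matrix under an order-0 background
#'
#' Column-wise dynamic programming over the achievable log-odds scores.
#' Scores are aggregated on a 1e-9 lattice, so the result is exact for any
#' matrix whose distinct column scores differ by more than that; if the
#' support grows beyond `max_support` points the lattice is coarsened.
#'
#' @param matrix a `motif_matrix`.
#' @param background an order-0 background (only `freq` is used).
#' @param max_support support-size cap before lattice coarsening.
#' @return list with sorted `scores` and `tail` where `tail[i]` =
#'   P(score >= scores\[i\]).
#' @export
pwm_score_distribution <- function(matrix, background,
                                   max_support = 2e5) {
  freq <- background$freq
  lodds <- log2(matrix$probs) - log2(freq)
  scores <- 0
  probs <- 1
  digits <- Inf  # aggregate exact doubles; coarsen only past the cap
  for (j in seq_len(matrix$width)) {
    s <- as.vector(outer(scores, lodds[, j], "+"))
    p <- as.vector(outer(probs, freq, "*"))
    agg <- rowsum(p, group = if (is.finite(digits)) round(s, digits) else s)
    scores <- as.numeric(rownames(agg))
    probs <- as.vector(agg)
    while (length(scores) > max_support) {
      digits <- if (is.finite(digits)) digits - 2 else 9
      agg <- rowsum(probs, group = round(scores, digits))
      scores <- as.numeric(rownames(agg))
      probs <- as.vector(agg)
      if (digits <= 3) break
    }
  }
  ord <- order(scores)
  scores <- scores[ord]
  probs <- probs[ord]
  list(scores = scores, tail = rev(cumsum(rev(probs))))
}

#' Tail p-value of a motif score
#'
#' P(score(window) >= `score`) for a random window under the order-0
#' background (the marginal of an order-1 model is used when an order-1
#' model is supplied).
#'
#' @param matrix a `motif_matrix`.
#' @param background background model from [estimate_background()] or
#'   [uniform_background()].
#' @param score numeric vector of scores (bits).
#' @param dist optional precomputed [pwm_score_distribution()].
#' @return numeric vector of p-values in (0, 1].
#' @export
pwm_pvalue <- function(matrix, background, score, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(matrix, background)
  vapply(score, function(q) {
    if (is.na(q)) return(NA_real_)
    j <- sum(dist$scores < q - 1e-9) + 1
    if (j > length(dist$scores)) 0 else dist$tail[j]
  }, 0)
}

scan_one_strand <- function(code, matrix, background, chrom, L, strand,
                            score_cut) {
  w <- matrix$width
  s <- window_log2_mat(code, matrix) - window_log2_bg(code, w, background)
  keep <- which(!is.na(s) & s >= score_cut)
  if (length(keep) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric()))
  if (strand == "+") {
    start0 <- keep - 1L
  } else {
    # position i on the reverse complement maps back to forward coordinates
    start0 <- L - (keep - 1L) - w
  }
  data.frame(chrom = chrom, start = as.integer(start0),
             end = as.integer(start0 + w), strand = strand, score = s[keep])
}

#' Scan sequences for motif hits
#'
#' Windows are scored as `sum_j log2(p_matrix(base_j | col j) /
#' p_background(base_j | context))`; minus-strand hits are scored on the
#' reverse complement. Windows containing `N` are skipped. Only hits with
#' tail p-value <= `pvalue_threshold` are returned.
#'
#' @param sequences named character vector or `DNAStringSet`; names are
#'   used as chromosome names.
#' @param matrix a `motif_matrix`.
#' @param background background model; by default an order-1 model
#'   estimated from the scanned sequences themselves.
#' @param pvalue_threshold upper p-value threshold (default 1e-4).
#' @param both_strands scan both strands (default TRUE).
#' @return data frame of hits: `chrom`, `start`, `end` (0-based half-open,
#'   forward-strand coordinates), `strand`, `score` (bits), `pvalue`.
#' @export
scan_motif <- function(sequences, matrix, background = NULL,
                       pvalue_threshold = 1e-4, both_strands = TRUE) {
  if (!is.character(sequences)) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (is.null(background)) background <- estimate_background(sequences, 1)
  dist <- pwm_score_distribution(matrix, background)
  ok <- dist$tail <= pvalue_threshold
  score_cut <- if (any(ok)) min(dist$scores[ok]) else Inf
  out <- list()
  for (ch in names(sequences)) {
    seq <- sequences[[ch]]
    L <- nchar(seq)
    if (L < matrix$width) next
    out[[length(out) + 1]] <- scan_one_strand(
      encode_dna(seq), matrix, background, ch, L, "+", score_cut)
    if (both_strands)
      out[[length(out) + 1]] <- scan_one_strand(
        encode_dna(revcomp(seq)), matrix, background, ch, L, "-", score_cut)
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), score = numeric())
  if (nrow(hits) > 0) {
    hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
    hits$pvalue <- pwm_pvalue(matrix, background, hits$score, dist = dist)
  } else hits$pvalue <- numeric(0)
  hits
}

# Motif center convention: the base immediately 3' of the midpoint in
# motif orientation. For odd widths this is the middle base on either
# strand; for even widths the two strands mirror each other.
motif_center <- function(start, width, strand) {
  ifelse(strand == "+",
         start + width %/% 2L,
         start + (width + 1L) %/% 2L - 1L)
}

#' Best motif hit per region, as an oriented site
#'
#' For each region the overlapping hit with maximum score is kept (ties:
#' leftmost genomic start, then `+` before `-`). The site center follows
#' the mirror-symmetric convention of `motif_center`. Regions without a
#' hit are omitted.
#'
#' @param regions interval data frame (a `region_id` column is used if
#'   present, else row order).
#' @param hits hit data frame from [scan_motif()].
#' @param width motif width (needed for the center; defaults to the hit
#'   interval length).
#' @return oriented-site data frame: `site_id`, `chrom`, `center`
#'   (absolute 0-based bp), `orientation`, `score`.
#' @export
best_hit_per_region <- function(regions, hits, width = NULL) {
  validate_intervals(regions, what = "region")
  ids <- if (!is.null(regions$region_id)) regions$region_id else seq_len(nrow(regions))
  empty <- data.frame(site_id = integer(), chrom = character(),
                      center = integer(), orientation = character(),
                      score = numeric())
  if (nrow(hits) == 0 || nrow(regions) == 0) return(empty)
  ov <- GenomicRanges::findOverlaps(as_granges(hits), as_granges(regions),
                                    type = "within", ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  h <- hits[S4Vectors::queryHits(ov), , drop = FALSE]
  h$site_id <- ids[S4Vectors::subjectHits(ov)]
  h <- h[order(h$site_id, -h$score, h$start, h$strand), , drop = FALSE]
  h <- h[!duplicated(h$site_id), , drop = FALSE]
  w <- if (is.null(width)) h$end - h$start else width
  data.frame(site_id = h$site_id, chrom = h$chrom,
             center = motif_center(h$start, w, h$strand),
             orientation = h$strand, score = h$score)
}
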