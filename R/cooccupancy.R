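# Combinatorial occupancy classification (triple/double/singleton sites)
# and the category-level comparisons built on it.

# All 2^k - 1 non-empty class labels for a factor set, as sorted
# "+"-joined strings.
occupancy_classes <- function(factors) {
  factors <- sort(factors)
  k <- length(factors)
  sets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(factors, m, FUN = paste, collapse = "+",
                 simplify = FALSE)), use.names = FALSE)
  sets
}

#' Classify merged regions by co-occupying factors
#'
#' Pools the peaks of all factors, merges regions overlapping by >= 1 bp
#' ([merge_overlapping()]), and labels every merged region with the set of
#' factors contributing at least one overlapping peak. Regions occupied by
#' all declared factors are the "triple sites" when three factors are
#' supplied.
#'
#' @param peaks_by_factor named list of peak data frames (one per factor).
#' @return list with `sites` (merged regions with `region_id`, coordinates
#'   and `class`, the sorted `+`-joined member factors), `members` (per
#'   input peak: `factor`, `peak_index` within its factor's table, and
#'   `region_id`), and `table` (named count of regions in each of the
#'   2^k - 1 occupancy classes).
#' @export
classify_occupancy <- function(peaks_by_factor) {
  stopifnot(is.list(peaks_by_factor), length(peaks_by_factor) >= 2,
            !is.null(names(peaks_by_factor)))
  factors <- names(peaks_by_factor)
  for (f in factors) {
    validate_intervals(peaks_by_factor[[f]], what = paste0(f, " peaks"))
    if (nrow(peaks_by_factor[[f]]) == 0)
      warning("factor ", f, " has no peaks; retained in the class table")
  }
  pooled <- do.call(rbind, lapply(factors, function(f) {
    p <- peaks_by_factor[[f]]
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               factor = rep_len(f, nrow(p)),
               peak_index = seq_len(nrow(p)))
  }))
  mg <- merge_overlapping(pooled, labels = pooled$factor)
  sites <- mg$regions
  names(sites)[names(sites) == "labels"] <- "class"
  sites$class <- gsub(",", "+", sites$class, fixed = TRUE)
  members <- data.frame(factor = pooled$factor,
                        peak_index = pooled$peak_index,
                        region_id = mg$members$region_id)
  classes <- occupancy_classes(factors)
  tab <- table(factor(sites$class, levels = classes))
  list(sites = sites, members = members,
       table = stats::setNames(as.integer(tab), classes))
}

#' Per-class peak intensity distributions and pairwise tests
#'
#' Computes RPKM for every original peak of `factor` (reads with >= 1 bp
#' overlap), groups peaks by the occupancy class of their merged region,
#' and compares each class pair with a one-sided Wilcoxon rank-sum test in
#' the direction of the larger median; p-values are Benjamini-Hochberg
#' adjusted within the family of pairwise tests.
#'
#' @param occupancy result of [classify_occupancy()].
#' @param factor which factor's peaks to score.
#' @param peaks that factor's original peak data frame.
#' @param reads stranded or unstranded read data frame for that factor.
#' @param library_size total mapped reads.
#' @return list with `values` (per-peak `class`, `rpkm`) and `tests`
#'   (`class_a`, `class_b`, `median_a`, `median_b`, `fold_change` =
#'   median_a / median_b with a as the larger-median class, `p`,
#'   `p_adj`, `skipped` for classes with < 2 peaks).
#' @export
intensity_by_category <- function(occupancy, factor, peaks, reads,
                                  library_size) {
  validate_intervals(peaks, what = "peak")
  m <- occupancy$members[occupancy$members$factor == factor, , drop = FALSE]
  cls <- occupancy$sites$class[match(m$region_id, occupancy$sites$region_id)]
  cnt <- GenomicRanges::countOverlaps(as_granges(peaks), as_granges(reads),
                                      minoverlap = 1L, ignore.strand = TRUE)
  vals <- data.frame(
    class = cls[match(seq_len(nrow(peaks)), m$peak_index)],
    rpkm = rpkm(cnt, peaks$end - peaks$start, library_size)
  )
  groups <- split(vals$rpkm, vals$class)
  cl <- names(groups)
  tests <- NULL
  if (length(cl) >= 2) {
    pairs <- utils::combn(cl, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
      skipped <- length(x) < 2 || length(y) < 2
      ma <- stats::median(x); mb <- stats::median(y)
      if (ma < mb) { pr <- rev(pr); tmp <- x; x <- y; y <- tmp
                     tmp <- ma; ma <- mb; mb <- tmp }
      p <- if (skipped) NA_real_ else
        suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "greater")$p.value)
      data.frame(class_a = pr[1], class_b = pr[2], median_a = ma,
                 median_b = mb, fold_change = ma / mb, p = p,
                 skipped = skipped)
    }))
    tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  }
  list(values = vals, tests = tests)
}

#' Randomisation test for overlap enrichment between two peak sets
#'
#' The observed statistic is the fraction of query peaks overlapping at
#' least one reference peak by >= 1 bp. The null is built by uniformly
#' re-placing the query intervals (lengths preserved) within the supplied
#' workspace `n_sim` times; the empirical p-value is
#' `(1 + #(null >= observed)) / (n_sim + 1)`. This is a deliberately plain
#' placement null: no mappability or isochore stratification is applied.
#'
#' @param query,reference peak data frames.
#' @param workspace interval data frame of allowed placement regions.
#' @param n_sim number of randomisations (default 1000).
#' @param seed integer seed for reproducible placement.
#' @return list: `observed` overlap fraction, `null_mean`, `null` vector,
#'   `p` empirical p-value.
#' @export
overlap_enrichment_test <- function(query, reference, workspace,
                                    n_sim = 1000, seed = NULL) {
  validate_intervals(query, what = "query")
  validate_intervals(reference, what = "reference")
  validate_intervals(workspace, what = "workspace")
  ws_len <- workspace$end - workspace$start
  q_len <- query$end - query$start
  if (sum(ws_len) < sum(q_len))
    stop("workspace smaller than total query length")
  ref_gr <- as_granges(reference)
  obs_frac <- function(q_df) {
    if (nrow(reference) == 0) return(0)
    mean(GenomicRanges::countOverlaps(as_granges(q_df), ref_gr,
                                      minoverlap = 1L,
                                      ignore.strand = TRUE) > 0)
  }
  observed <- obs_frac(query)
  null <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      # place each query length uniformly among fitting workspace intervals
      starts <- vapply(q_len, function(l) {
        room <- ws_len - l
        ok <- which(room >= 0)
        if (length(ok) == 0)
          stop("a query interval is longer than every workspace interval")
        w <- ok[sample.int(length(ok), 1, prob = room[ok] + 1)]
        workspace$start[w] + sample.int(room[w] + 1, 1) - 1L
      }, 0)
      obs_frac(data.frame(chrom = workspace$chrom[1], start = starts,
                          end = starts + q_len))
    }, 0)
  })
  if (nrow(reference) == 0)
    return(list(observed = 0, null_mean = 0, null = null, p = 1))
  list(observed = observed, null_mean = mean(null), null = null,
       p = (1 + sum(null >= observed)) / (n_sim + 1))
}

#' Tissue-sharing counts and constitutive classification of peaks
#'
#' A peak's sharing count is the number of tissue peak sets it overlaps by
#' >= 1 bp; it is "constitutive" iff shared in strictly more than
#' `threshold` tissues.
#'
#' @param peaks peak data frame.
#' @param tissue_peak_sets named list of interval data frames, one per
#'   tissue.
#' @param threshold constitutive iff sharing count > threshold (default 7).
#' @return data frame with `sharing_count` and logical `constitutive`, one
#'   row per peak.
#' @export
constitutive_classification <- function(peaks, tissue_peak_sets,
                                        threshold = 7) {
  validate_intervals(peaks, what = "peak")
  stopifnot(is.list(tissue_peak_sets), length(tissue_peak_sets) >= 1)
  gr <- as_granges(peaks)
  cnt <- Reduce(`+`, lapply(tissue_peak_sets, function(ts)
    as.integer(GenomicRanges::countOverlaps(gr, as_granges(ts),
                                            minoverlap = 1L,
                                            ignore.strand = TRUE) > 0)))
  data.frame(sharing_count = as.integer(cnt),
             constitutive = cnt > threshold)
}

#' Fisher's exact test comparing a binary property between two groups
#'
#' Convenience wrapper building the 2x2 table (property yes/no x group)
#' used for constitutive-fraction and conservation-category comparisons.
#'
#' @param flag_a,flag_b logical vectors for groups a and b.
#' @param alternative passed to [stats::fisher.test()].
#' @return the `htest` object.
#' @export
fraction_fisher_test <- function(flag_a, flag_b,
                                 alternative = "two.sided") {
  tab <- matrix(c(sum(flag_a), sum(!flag_a), sum(flag_b), sum(!flag_b)),
                nrow = 2)
  stats::fisher.test(tab, alternative = alternative)
}

#' Phylogenetic conservation categories from orthology flags
#'
#' Each peak carries logical flags for whether a shared orthologous site
#' was found in rat, human and dog. Categories: "Beyond rodents" iff
#' shared in at least one non-rodent species; else "Rodents only" iff
#' shared in rat; else "Mouse only".
#'
#' @param flags data frame with logical columns `rat`, `human`, `dog`.
#' @param class optional occupancy class per peak; when supplied, per-class
#'   counts and pairwise Fisher tests on the Beyond-rodents fraction are
#'   returned.
#' @return list with `category` (per peak), `counts` (per class if given)
#'   and `tests` (pairwise Fisher p-values on the Beyond-rodents fraction).
#' @export
phylo_category_counts <- function(flags, class = NULL) {
  stopifnot(all(c("rat", "human", "dog") %in% names(flags)))
  category <- ifelse(flags$human | flags$dog, "Beyond rodents",
                     ifelse(flags$rat, "Rodents only", "Mouse only"))
  category <- factor(category,
                     levels = c("Mouse only", "Rodents only", "Beyond rodents"))
  out <- list(category = category)
  if (!is.null(class)) {
    out$counts <- table(class = class, category = category)
    cl <- unique(class)
    if (length(cl) >= 2) {
      pairs <- utils::combn(cl, 2, simplify = FALSE)
      out$tests <- do.call(rbind, lapply(pairs, function(pr) {
        a <- category[class == pr[1]] == "Beyond rodents"
        b <- category[class == pr[2]] == "Beyond rodents"
        data.frame(class_a = pr[1], class_b = pr[2],
                   frac_a = mean(a), frac_b = mean(b),
                   p = fraction_fisher_test(a, b)$p.value)
      }))
    }
  }
  out
}

#' Keep peaks whose summit falls inside a repeat element
#'
#' @param peaks peak data frame with `summit` (absolute 0-based bp).
#' @param repeats interval data frame of repeat annotations.
#' @return the subset of `peaks` with summit inside some repeat interval.
#' @export
summit_repeat_filter <- function(peaks, repeats) {
  validate_intervals(peaks, what = "peak")
  validate_intervals(repeats, what = "repeat")
  stopifnot(!is.null(peaks$summit))
  if (nrow(peaks) == 0 || nrow(repeats) == 0)
    return(peaks[integer(), , drop = FALSE])
  s <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                  end = peaks$summit + 1L)
  hit <- GenomicRanges::countOverlaps(as_granges(s), as_granges(repeats),
                                      ignore.strand = TRUE) > 0
  peaks[hit, , drop = FALSE]
}
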