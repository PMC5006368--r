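# Allele-specific binding analysis: allele frequencies, exact binomial
# bias classification, cross-factor correlation at co-bound sites, and
# group-shift tests. Counts come from an F1 cross; "ref" is the reference
# parental genome (C57BL/6J), "alt" the alternate (A/J).

BIAS_CLASSES <- c("C57 > A/J", "A/J > C57", "C57 ~ A/J")

#' Reference-allele frequency
#'
#' @param ref_count,alt_count non-negative allelic read counts
#'   (vectorised).
#' @return `ref / (ref + alt)`; sites with zero total get `NA` with a
#'   message (they carry no allelic information).
#' @export
allele_frequency <- function(ref_count, alt_count) {
  stopifnot(all(ref_count >= 0), all(alt_count >= 0))
  tot <- ref_count + alt_count
  if (any(tot == 0))
    message(sum(tot == 0), " site(s) with zero allelic reads set to NA")
  ifelse(tot == 0, NA_real_, ref_count / tot)
}

# Exact two-sided binomial p-values against p0 = 0.5, memoised over the
# unique (count, total) pairs (binom.test uses the minimum-likelihood
# two-sided convention).
binomial_bias_p <- function(ref_count, alt_count) {
  tot <- ref_count + alt_count
  key <- paste(ref_count, tot)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    if (tot[i] == 0) return(NA_real_)
    stats::binom.test(ref_count[i], tot[i], p = 0.5)$p.value
  }, 0)
  pu[match(key, key[uk])]
}

#' Classify allelic bias at each site
#'
#' Exact two-sided binomial test of the allelic read counts against an
#' unbiased 0.5; sites with p below `alpha` are classified toward their
#' majority allele, the rest as unbiased.
#'
#' @param ref_count,alt_count allelic read counts (vectorised).
#' @param alpha significance level (default 0.05).
#' @return data frame with `p` and `class` (one of `"C57 > A/J"`,
#'   `"A/J > C57"`, `"C57 ~ A/J"`).
#' @export
classify_bias <- function(ref_count, alt_count, alpha = 0.05) {
  stopifnot(all(ref_count + alt_count >= 1))
  p <- binomial_bias_p(ref_count, alt_count)
  class <- ifelse(p < alpha,
                  ifelse(ref_count > alt_count, "C57 > A/J", "A/J > C57"),
                  "C57 ~ A/J")
  data.frame(p = p, class = factor(class, levels = BIAS_CLASSES))
}

#' Allele-frequency correlation of two factors at co-bound sites
#'
#' @param a,b data frames with `site_id`, `ref_count`, `alt_count` for the
#'   two factors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_total minimum informative coverage (ref + alt) per site and
#'   factor (default 5).
#' @return list: `r`, `p`, `n` shared sites used.
#' @export
cobinding_correlation <- function(a, b, method = c("pearson", "spearman"),
                                  min_total = 5) {
  method <- match.arg(method)
  a <- a[a$ref_count + a$alt_count >= min_total, , drop = FALSE]
  b <- b[b$ref_count + b$alt_count >= min_total, , drop = FALSE]
  m <- merge(a, b, by = "site_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop("fewer than 3 shared informative sites")
  fa <- allele_frequency(m$ref_count_a, m$alt_count_a)
  fb <- allele_frequency(m$ref_count_b, m$alt_count_b)
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0)
    stop("constant allele-frequency vector")
  ct <- suppressWarnings(stats::cor.test(fa, fb, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Shift of a target factor's allele frequencies within anchor bias classes
#'
#' For sites whose anchor factor (e.g. CTCF) is classified
#' `"C57 > A/J"`, tests whether the target factor's allele frequencies are
#' greater than in the unbiased class (one-sided Wilcoxon rank-sum);
#' for `"A/J > C57"` the test is one-sided less.
#'
#' @param target_freq numeric vector of the target factor's allele
#'   frequencies, one per site.
#' @param anchor_class the anchor factor's bias class per site (from
#'   [classify_bias()]).
#' @return data frame with one row per biased class: `class`, `n`,
#'   `n_neutral`, `alternative`, `p` (`NA` and `skipped = TRUE` when a
#'   group has fewer than 2 sites).
#' @export
group_shift_test <- function(target_freq, anchor_class) {
  stopifnot(length(target_freq) == length(anchor_class))
  neutral <- target_freq[anchor_class == "C57 ~ A/J"]
  do.call(rbind, lapply(c("C57 > A/J", "A/J > C57"), function(cl) {
    x <- target_freq[anchor_class == cl]
    alt <- if (cl == "C57 > A/J") "greater" else "less"
    skipped <- length(x) < 2 || length(neutral) < 2
    p <- if (skipped) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, neutral,
                                          alternative = alt)$p.value)
    data.frame(class = cl, n = length(x), n_neutral = length(neutral),
               alternative = alt, p = p, skipped = skipped)
  }))
}
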