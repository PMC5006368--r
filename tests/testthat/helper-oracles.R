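# Fixture builders and independent brute-force oracles used across tests.

iv <- function(start, end, chrom = "chr1", strand = NULL) {
  df <- data.frame(chrom = rep_len(chrom, length(start)),
                   start = start, end = end)
  if (!is.null(strand)) df$strand <- rep_len(strand, length(start))
  df
}

rand_interval_set <- function(n, span = 10000, max_len = 300,
                              chroms = c("chr1", "chr2")) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len)
}

# O(n^2) union-find partition of intervals by chained >= 1 bp overlap;
# independent of the package's GRanges-based implementation.
merge_partition_oracle <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1) {
    # vectorised all-pairs overlap test (brute force, no sweep/merge logic)
    same_chrom <- outer(df$chrom, df$chrom, "==")
    ov <- outer(df$start, df$end, "<") & outer(df$end, df$start, ">")
    pairs <- which(same_chrom & ov & upper.tri(ov), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  split(seq_len(n), roots)
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(groups) {
  groups <- unname(lapply(groups, sort))
  groups[order(vapply(groups, `[[`, 0L, 1))]
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric point-mass
# summation (all tables with probability <= the observed one).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact one-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed).
wilcox_p_oracle <- function(x, y, alternative = "greater") {
  all_v <- c(x, y)
  n <- length(all_v); k <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(k)])
  combs <- utils::combn(n, k)
  sums <- colSums(matrix(rank(all_v)[combs], nrow = k))
  if (alternative == "greater") mean(sums >= obs) else mean(sums <= obs)
}

toy_config <- function(seed = 42, n_sites = 60, ...) {
  sim_config(seed = seed, n_sites = n_sites, ...)
}
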