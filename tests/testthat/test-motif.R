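# PWM scanning, exact tail p-values, best hits, matrix permutation.

point_mass_ac <- function() {
  # columns: all-A then all-C, no pseudocount so probabilities are 0/1
  motif_matrix(matrix(c(1, 0, 0, 0,
                        0, 1, 0, 0), 4, 2), pseudocount = 0)
}

random_matrix <- function(w) {
  motif_matrix(matrix(sample(0:9, 4 * w, replace = TRUE), 4, w))
}

test_that("point-mass dinucleotide matrix scores 4 bits on its consensus", {
  hits <- scan_motif(c(s = "AC"), point_mass_ac(),
                     background = uniform_background(),
                     pvalue_threshold = 1)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(max(fwd$score), 4)  # 2 * log2(1/0.25)
  expect_equal(fwd$pvalue[which.max(fwd$score)], 1 / 16)
})

test_that("reverse-complement consensus is found on the minus strand", {
  hits <- scan_motif(c(s = "GT"), point_mass_ac(),
                     background = uniform_background(),
                     pvalue_threshold = 1)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$strand, "-")
  expect_equal(best$score, 4)
})

test_that("scanning a sequence and its reverse complement is symmetric", {
  set.seed(4100)
  m <- random_matrix(6)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  bg <- uniform_background()
  h1 <- scan_motif(c(x = seq), m, bg, pvalue_threshold = 0.05)
  h2 <- scan_motif(c(x = rc), m, bg, pvalue_threshold = 0.05)
  # map h2 back: start' = L - end, strands swapped
  L <- 400
  h2m <- data.frame(start = L - h2$end,
                    strand = ifelse(h2$strand == "+", "-", "+"),
                    score = h2$score)
  o1 <- h1[order(h1$start, h1$strand), c("start", "strand", "score")]
  o2 <- h2m[order(h2m$start, h2m$strand), ]
  expect_equal(o1$start, o2$start)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score, tolerance = 1e-12)
})

test_that("windows containing N are skipped", {
  hits <- scan_motif(c(s = "ACNAC"), point_mass_ac(),
                     background = uniform_background(), pvalue_threshold = 1)
  expect_true(all(hits$start %in% c(0, 3)))
})

test_that("DP tail probabilities equal exhaustive enumeration (w <= 8)", {
  set.seed(4101)
  for (w in c(1, 2, 3, 5, 8)) {
    m <- random_matrix(w)
    freq <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    bg <- list(order = 0, freq = freq)
    # enumerate all 4^w windows
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    lodds <- log2(m$probs) - log2(freq)
    sc <- rowSums(matrix(lodds[cbind(as.vector(grid),
                                     rep(seq_len(w), each = nrow(grid)))],
                         nrow(grid), w))
    pr <- apply(matrix(freq[as.vector(grid)], nrow(grid), w), 1, prod)
    dist <- pwm_score_distribution(m, bg)
    qs <- c(sort(unique(sc)), max(sc) + 1, min(sc) - 1,
            sort(unique(sc)) + 1e-3)
    want <- vapply(qs, function(q) sum(pr[sc >= q - 1e-9]), 0)
    got <- pwm_pvalue(m, bg, qs, dist = dist)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("p-value is monotone non-increasing in score and hits bounds", {
  set.seed(4102)
  m <- random_matrix(5)
  bg <- uniform_background()
  d <- pwm_score_distribution(m, bg)
  qs <- seq(min(d$scores) - 1, max(d$scores) + 1, length.out = 60)
  ps <- pwm_pvalue(m, bg, qs, dist = d)
  expect_true(all(diff(ps) <= 1e-12))
  expect_equal(ps[1], 1)
  expect_equal(ps[length(ps)], 0)
})

test_that("expected hit count on random sequence matches theory", {
  # point-mass width-4 matrix: expected hits ~ 2 (L - w + 1) 4^-w
  set.seed(4103)
  cons <- c(1, 3, 3, 2)
  counts <- matrix(0, 4, 4); counts[cbind(cons, 1:4)] <- 1
  m <- motif_matrix(counts, pseudocount = 0)
  L <- 2000; reps <- 60
  nhit <- vapply(seq_len(reps), function(i) {
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    nrow(scan_motif(c(x = seq), m, uniform_background(),
                    pvalue_threshold = 1 / 256 + 1e-12))
  }, 0)
  expected <- 2 * (L - 4 + 1) * 4^-4
  se <- sd(nhit) / sqrt(reps)
  expect_lt(abs(mean(nhit) - expected), 3 * se + 1e-9)
})

test_that("best hit per region follows score then deterministic tie-break", {
  hits <- data.frame(chrom = "c", start = c(10, 40, 60, 70),
                     end = c(16, 46, 66, 76),
                     strand = c("+", "-", "-", "+"),
                     score = c(8.1, 12.3, 7, 7), pvalue = 1e-5)
  region <- data.frame(region_id = 1L, chrom = "c", start = 0L, end = 100L)
  best <- best_hit_per_region(region, hits, width = 6)
  expect_equal(best$score, 12.3)
  expect_equal(best$orientation, "-")

  tied <- hits[3:4, ]; tied$score <- 7
  b2 <- best_hit_per_region(region, tied, width = 6)
  expect_equal(b2$center, triplesites:::motif_center(60, 6, "-"))  # leftmost wins
  expect_equal(best_hit_per_region(region, hits[0, ], width = 6),
               best[0, ], ignore_attr = TRUE)
})

test_that("motif center convention is mirror-symmetric", {
  # odd width: same base both strands; even width: 3' of midpoint
  expect_equal(triplesites:::motif_center(100, 15, "+"), 107)
  expect_equal(triplesites:::motif_center(100, 15, "-"), 107)
  expect_equal(triplesites:::motif_center(100, 14, "+"), 107)
  expect_equal(triplesites:::motif_center(100, 14, "-"), 106)
})

test_that("permute_matrix preserves columns, IC, and is seed-stable", {
  set.seed(4104)
  m <- random_matrix(6)
  p1 <- permute_matrix(m, seed = 99)
  p2 <- permute_matrix(m, seed = 99)
  expect_identical(p1$counts, p2$counts)
  expect_equal(information_content(p1), information_content(m))
  cols <- function(x) sort(apply(x$counts, 2, paste, collapse = ","))
  expect_equal(cols(p1), cols(m))
  w1 <- motif_matrix(matrix(c(3, 1, 1, 1), 4, 1))
  expect_equal(permute_matrix(w1, seed = 1)$counts, w1$counts)
})

test_that("order-1 background estimation is strand-symmetric", {
  bg <- estimate_background("AAAAAAAACC", order = 1)
  expect_equal(bg$freq[["A"]], bg$freq[["T"]])
  expect_equal(bg$freq[["C"]], bg$freq[["G"]])
  expect_equal(rowSums(bg$trans), rep(1, 4), ignore_attr = TRUE)
})
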