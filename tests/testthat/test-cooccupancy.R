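# Occupancy classification and category-level comparisons.

test_that("toy occupancy classification matches hand-worked classes", {
  pk <- list(TOP2B = iv(100, 200), CTCF = iv(150, 250), RAD21 = iv(240, 300))
  occ <- classify_occupancy(pk)
  expect_equal(nrow(occ$sites), 1)
  expect_equal(occ$sites$class, "CTCF+RAD21+TOP2B")

  pk2 <- list(TOP2B = iv(100, 200), CTCF = iv(500, 600))
  occ2 <- classify_occupancy(pk2)
  expect_equal(sort(occ2$sites$class), c("CTCF", "TOP2B"))
  expect_equal(sum(occ2$table), 2)
})

test_that("class table is invariant under factor input order", {
  set.seed(4200)
  pk <- list(A = rand_interval_set(40), B = rand_interval_set(40),
             C = rand_interval_set(40))
  t1 <- classify_occupancy(pk)$table
  t2 <- classify_occupancy(pk[c(3, 1, 2)])$table
  expect_equal(t1[sort(names(t1))], t2[sort(names(t2))])
})

test_that("empty factor warns but is retained in the class table", {
  pk <- list(A = iv(0, 10), B = iv(integer(), integer()))
  expect_warning(occ <- classify_occupancy(pk), "no peaks")
  expect_equal(occ$table[["A"]], 1L)
  expect_equal(occ$table[["B"]], 0L)
})

test_that("planted class proportions are recovered from merged regions", {
  cfg <- sim_config(seed = 31, n_sites = 2000)
  gm <- simulate_genome_and_motifs(cfg)
  pk <- simulate_peaks(cfg, gm$motifs)
  occ <- classify_occupancy(pk$peaks_by_factor)
  expect_equal(sum(occ$table), cfg$n_sites)  # no cross-site merging
  planted <- table(pk$truth$class)
  for (cl in names(planted))
    expect_equal(occ$table[[cl]], as.integer(planted[[cl]]))
})

test_that("intensity grouping: identical classes give p ~ 1, fold 1", {
  pk <- list(A = iv(seq(0, 1900, 100), seq(0, 1900, 100) + 50),
             B = iv(seq(5000, 6900, 100), seq(5000, 6900, 100) + 50))
  occ <- classify_occupancy(pk)
  # one read per peak of each factor -> identical RPKM multisets
  reads <- iv(c(seq(0, 1900, 100), seq(5000, 6900, 100)),
              c(seq(0, 1900, 100), seq(5000, 6900, 100)) + 10,
              strand = "+")
  pooled <- rbind(pk$A, pk$B)
  res <- intensity_by_category(occ, "A", pk$A, reads, 1e6)
  expect_equal(nrow(res$values), 20)
  expect_true(all(res$values$class == "A"))

  # two-class comparison via a shifted read depth
  pkc <- list(A = pooled)
  # classify against factor B to get two classes
  occ2 <- classify_occupancy(list(A = pooled, B = pk$B))
  res2 <- intensity_by_category(occ2, "A", pooled, reads, 1e6)
  expect_setequal(unique(res2$values$class), c("A", "A+B"))
  t2 <- res2$tests
  expect_equal(t2$fold_change, 1)
  expect_gt(t2$p, 0.9)
})

test_that("planted 2-fold intensity shift is detected one-sidedly", {
  set.seed(4201)
  n <- 500
  a_start <- seq(0, by = 1000, length.out = n)
  b_start <- seq(n * 1000 + 5000, by = 1000, length.out = n)
  pkA <- iv(c(a_start, b_start), c(a_start, b_start) + 200)
  pkB <- iv(b_start, b_start + 200)  # co-binding marks the high class
  occ <- classify_occupancy(list(A = pkA, B = pkB))
  depth_a <- rpois(n, 10); depth_b <- rpois(n, 20)
  mk_reads <- function(starts, depth) iv(rep(starts + 50, depth),
                                         rep(starts + 50, depth) + 36)
  reads <- rbind(mk_reads(a_start, depth_a), mk_reads(b_start, depth_b))
  res <- intensity_by_category(occ, "A", pkA, reads, 1e6)
  t <- res$tests
  expect_equal(t$class_a, "A+B")
  expect_lt(abs(t$fold_change - 2), 0.2)
  expect_lt(t$p_adj, 0.01)
})

test_that("one-sided rank-sum wiring matches the exact enumeration oracle", {
  expect_equal(wilcox.test(c(4, 5, 6), c(1, 2, 3),
                           alternative = "greater")$p.value,
               wilcox_p_oracle(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(wilcox_p_oracle(c(4, 5, 6), c(1, 2, 3)), 0.05)
})

test_that("overlap enrichment: self-overlap and empty reference bounds", {
  q <- iv(c(100, 500, 900), c(150, 560, 980))
  ws <- iv(0, 5000)
  r1 <- overlap_enrichment_test(q, q, ws, n_sim = 99, seed = 5)
  expect_equal(r1$observed, 1)
  expect_equal(r1$p, 1 / 100)
  r2 <- overlap_enrichment_test(q, q[0, ], ws, n_sim = 19, seed = 5)
  expect_equal(r2$observed, 0)
  expect_equal(r2$p, 1)
  expect_error(overlap_enrichment_test(q, q, iv(0, 100), n_sim = 9),
               "workspace smaller")
})

test_that("overlap enrichment null is calibrated under independence", {
  set.seed(4202)
  ws <- iv(0, 100000)
  ref_start <- seq(0, 99000, by = 1000)
  ref <- iv(ref_start, ref_start + 100)  # covers 10% of workspace
  q_start <- sample.int(99000, 50)
  q <- iv(q_start, q_start + 10)
  r <- overlap_enrichment_test(q, ref, ws, n_sim = 400, seed = 11)
  # a ~10 bp query hits ~ (100 + 10) / 1000 of the workspace
  expect_lt(abs(r$null_mean - 0.11), 0.02)
  ps <- vapply(1:40, function(i) {
    qs <- sample.int(99000, 30)
    overlap_enrichment_test(iv(qs, qs + 10), ref, ws, n_sim = 60,
                            seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("constitutive classification uses a strict > threshold rule", {
  peak <- iv(1000, 1200)
  tissues <- lapply(1:14, function(i)
    if (i <= 8) iv(1100, 1300) else iv(50000, 50100))
  cc8 <- constitutive_classification(peak, tissues)
  expect_equal(cc8$sharing_count, 8)
  expect_true(cc8$constitutive)
  cc7 <- constitutive_classification(peak, tissues[c(1:7, 9:14)])
  expect_equal(cc7$sharing_count, 7)
  expect_false(cc7$constitutive)
})

test_that("Fisher tests agree with the hypergeometric sum oracle", {
  expect_equal(fraction_fisher_test(rep(c(TRUE, FALSE), c(30, 70)),
                                    rep(c(TRUE, FALSE), c(10, 90)))$p.value,
               fisher_p_oracle(30, 70, 10, 90), tolerance = 1e-12)
  set.seed(4203)
  for (i in 1:20) {
    n <- sample(4:50, 4, replace = TRUE)
    expect_equal(fisher.test(matrix(n, 2))$p.value,
                 fisher_p_oracle(n[1], n[3], n[2], n[4]),
                 tolerance = 1e-9)
  }
})

test_that("phylogenetic categories follow the rodent/non-rodent rules", {
  flags <- data.frame(rat = c(TRUE, FALSE, FALSE, TRUE),
                      human = c(FALSE, TRUE, FALSE, TRUE),
                      dog = c(FALSE, FALSE, FALSE, FALSE))
  got <- phylo_category_counts(flags)$category
  expect_equal(as.character(got),
               c("Rodents only", "Beyond rodents", "Mouse only",
                 "Beyond rodents"))
})

test_that("planted conservation fractions give a strong Fisher signal", {
  set.seed(4204)
  n <- 1000
  cls <- rep(c("triple", "double"), each = n)
  beyond <- c(runif(n) < 0.45, runif(n) < 0.21)
  flags <- data.frame(rat = FALSE, human = beyond, dog = FALSE)
  res <- phylo_category_counts(flags, class = cls)
  expect_lt(res$tests$p, 1e-6)
})

test_that("summit repeat filter agrees with a per-peak linear scan", {
  pk <- iv(c(100, 100), c(200, 200))
  pk$summit <- c(150, 99)
  reps <- iv(100, 200)
  expect_equal(summit_repeat_filter(pk, reps)$summit, 150)

  set.seed(4205)
  pk2 <- rand_interval_set(100)
  pk2$summit <- pk2$start + (pk2$end - pk2$start) %/% 2L
  reps2 <- rand_interval_set(30)
  got <- summit_repeat_filter(pk2, reps2)
  want <- vapply(seq_len(nrow(pk2)), function(i)
    any(reps2$chrom == pk2$chrom[i] & reps2$start <= pk2$summit[i] &
          pk2$summit[i] < reps2$end), TRUE)
  expect_equal(got, pk2[want, ], ignore_attr = TRUE)
})
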