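# Metaprofiles, expression grouping, coverage, bTMP normalisation and
# the supercoiling pipeline.

test_that("summit profile places planted nucleosomes at their offset", {
  summits <- iv(seq(10000, 100000, 10000) - 100,
                seq(10000, 100000, 10000) + 100)
  summits$summit <- seq(10000, 100000, 10000)
  tss <- data.frame(chrom = "chr1", pos = 500000, strand = "+")  # all distal
  nuc <- data.frame(chrom = "chr1", pos = summits$summit + 200)
  prof <- summit_profile(nuc, summits, tss, flank = 1500)
  expect_equal(unique(prof$class), "distal")
  expect_equal(prof$value[prof$offset == 200], 1)
  expect_equal(sum(prof$value), 1)
})

test_that("proximal windows flip with the nearest TSS strand", {
  summits <- iv(9900, 10100); summits$summit <- 10000
  tss <- data.frame(chrom = "chr1", pos = 10300, strand = "-")
  feat <- data.frame(chrom = "chr1", pos = 10000 + 120)
  prof <- summit_profile(feat, summits, tss, flank = 500)
  expect_equal(unique(prof$class), "proximal")
  expect_equal(prof$value[prof$offset == -120], 1)
})

test_that("planted periodic nucleosomes give autocorrelation at the period", {
  set.seed(4500)
  n <- 1000; period <- 185
  centers <- seq(5000, by = 5000, length.out = n)
  summits <- iv(centers - 100, centers + 100); summits$summit <- centers
  tss <- data.frame(chrom = "chr1", pos = 1e9, strand = "+")
  offsets <- as.vector(outer(seq(-7, 7) * period,
                             round(rnorm(3 * n, 0, 18)), "+"))
  nuc <- data.frame(chrom = "chr1",
                    pos = rep(centers, length.out = length(offsets)) + offsets)
  prof <- summit_profile(nuc, summits, tss, flank = 1500)
  v <- prof$value - mean(prof$value)
  ac <- vapply(150:220, function(l)
    sum(v[1:(length(v) - l)] * v[(l + 1):length(v)]), 0)
  best_lag <- (150:220)[which.max(ac)]
  expect_lte(abs(best_lag - period), 5)
})

test_that("expression groups follow strict mean +/- sd cuts", {
  g <- expression_groups(c(0, 5, 5, 5, 10))
  expect_equal(as.character(g), c("low", "medium", "medium", "medium", "high"))
  expect_warning(g2 <- expression_groups(c(3, 3, 3)), "zero variance")
  expect_true(all(g2 == "medium"))
  v <- c(0, 5, 5, 5, 10)
  exact <- mean(v) + sd(v)
  g3 <- expression_groups(c(v, exact))
  expect_equal(as.character(g3[6]), "medium")  # boundary is not high
})

test_that("subtracted coverage extends reads and normalises to RPM", {
  genome <- c(c = 1000)
  chip <- iv(100, 136, "c", "+")
  tr <- subtracted_coverage(chip, NULL, genome, extension = 150,
                            chip_library_size = 1e6)
  expect_equal(tr$c[101], 1)    # bp 100 (1-based index 101)
  expect_equal(tr$c[250], 1)    # bp 249, last of [100, 250)
  expect_equal(tr$c[251], 0)
  expect_equal(sum(tr$c), 150)
  same <- subtracted_coverage(chip, chip, genome, extension = 150,
                              chip_library_size = 5, input_library_size = 5)
  expect_true(all(same$c == 0))
})

test_that("coverage matches a brute-force per-bp pileup oracle", {
  set.seed(4501)
  genome <- c(z = 2000)
  n <- 100
  p5 <- sample.int(1800, n) + 50
  strand <- sample(c("+", "-"), n, TRUE)
  reads <- data.frame(chrom = "z",
                      start = ifelse(strand == "+", p5, p5 - 35),
                      end = ifelse(strand == "+", p5 + 36, p5 + 1),
                      strand = strand)
  tr <- subtracted_coverage(reads, NULL, genome, extension = 150,
                            chip_library_size = 1e6)
  oracle <- numeric(2000)
  for (i in seq_len(n)) {
    s <- if (strand[i] == "+") p5[i] else p5[i] - 149
    e <- s + 149
    s <- max(s, 0); e <- min(e, 1999)
    oracle[(s:e) + 1] <- oracle[(s:e) + 1] + 1
  }
  expect_equal(tr$z, oracle, ignore_attr = TRUE)
})

test_that("oriented track profile is flat on constant tracks and flips spikes", {
  sites <- data.frame(site_id = 1:2, chrom = "c", center = c(1000, 3000),
                      orientation = c("+", "-"))
  grid <- data.frame(chrom = "c", pos = 0:4000, score = 2.5)
  prof <- oriented_track_profile(grid, sites, flank = 50)
  expect_true(all(prof$value == 2.5))

  spike <- grid
  spike$score[spike$pos %in% c(1000 - 20, 3000 + 20)] <- 9  # 20 bp 5' of each
  prof2 <- oriented_track_profile(spike, sites, flank = 50)
  expect_equal(prof2$value[prof2$offset == -20], 9)
  expect_true(all(prof2$value[prof2$offset != -20] == 2.5))
})

test_that("missing positions are excluded from per-offset means", {
  set.seed(4502)
  sites <- data.frame(site_id = 1:5, chrom = "c",
                      center = seq(1000, 5000, 1000),
                      orientation = sample(c("+", "-"), 5, TRUE))
  track <- data.frame(chrom = "c", pos = sort(sample(0:6000, 3000)),
                      score = rnorm(3000))
  prof <- oriented_track_profile(track, sites, flank = 30)
  # naive loop oracle
  for (k in c(1, 31, 61)) {
    off <- prof$offset[k]
    vals <- c()
    for (i in 1:5) {
      p <- sites$center[i] + if (sites$orientation[i] == "+") off else -off
      v <- track$score[track$pos == p]
      if (length(v) == 1) vals <- c(vals, v)
    }
    if (length(vals) > 0) expect_equal(prof$value[k], mean(vals))
    else expect_true(is.na(prof$value[k]))
    expect_equal(prof$n[k], length(vals))
  }
})

test_that("bTMP normalisation is a scale-invariant double log-ratio", {
  r <- normalize_btmp(4, 1, 2)
  expect_equal(r$value, 1)
  expect_equal(normalize_btmp(8, 3, 8)$value, 0)
  expect_equal(normalize_btmp(8, 2, 4)$value, normalize_btmp(16, 4, 8)$value)
  dropped <- normalize_btmp(c(4, -1), c(1, 1), c(2, 2))
  expect_equal(dropped$n_dropped, 1)
  lit <- normalize_btmp(4, 1, 3, literal_difference = TRUE)
  expect_equal(lit$value, 2 - 1)
})

test_that("rolling mean length formula and values", {
  expect_equal(rolling_mean(c(1, 2, 3, 4), 3, 1), c(2, 3))
  expect_equal(rolling_mean(1:10, 4, 3), c(mean(1:4), mean(4:7), mean(7:10)))
  expect_equal(rolling_mean(1:3, 5, 1), numeric(0))
  set.seed(4503)
  for (i in 1:25) {
    n <- sample(1:60, 1); w <- sample(1:15, 1); s <- sample(1:6, 1)
    out <- rolling_mean(rnorm(n), w, s)
    expect_equal(length(out), if (n < w) 0 else floor((n - w) / s) + 1)
  }
  expect_equal(rolling_mean(rep(7, 12), 4, 2), rep(7, 5))
})

test_that("binned medians land probes in the documented bins", {
  bm <- triplesites:::binned_median_profile(
    dist = c(5, 50, 120), value = c(1, 3, 7), bin = 100, max_dist = 200)
  expect_equal(bm$median[bm$center == 50], 2)
  expect_equal(bm$median[bm$center == 150], 7)
  expect_true(is.na(bm$median[bm$center == -150]))
})

test_that("planted supercoiling dip is recovered and centred", {
  cfg <- sim_config(seed = 71, n_sites = 400, site_spacing = 10000,
                    supercoil_model = list(dip_depth = -0.5, dip_sd = 300,
                                           probe_spacing = 400,
                                           noise_sd = 0.3))
  gm <- simulate_genome_and_motifs(cfg)
  sites <- motifs_as_sites(gm$motifs)
  pd <- simulate_probes_and_domains(cfg, sites)
  sp <- supercoiling_profile(pd$probes, sites, seed = 710, max_dist = 5000)
  expect_lt(sp$ks_p, 0.01)
  expect_equal(sp$empirical_p, 1 / 11)  # strongest rank among 10 randoms
  expect_lte(abs(sp$profile$position[which.min(sp$profile$value)]), 200)
  # background stays flat where the observed profile dips
  bg_at_min <- sp$background$value[which.min(sp$profile$value)]
  expect_gt(bg_at_min, min(sp$profile$value) + 0.2)
})

test_that("supercoiling profiles are reproducible under a fixed seed", {
  cfg <- sim_config(seed = 72, n_sites = 100, site_spacing = 4000)
  gm <- simulate_genome_and_motifs(cfg)
  sites <- motifs_as_sites(gm$motifs)
  pd <- simulate_probes_and_domains(cfg, sites)
  s1 <- supercoiling_profile(pd$probes, sites, seed = 720, max_dist = 2000)
  s2 <- supercoiling_profile(pd$probes, sites, seed = 720, max_dist = 2000)
  expect_identical(s1$profile, s2$profile)
  expect_identical(s1$random, s2$random)
})
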