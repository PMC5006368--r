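# Seeded synthetic-data generator. Every simulated input carries planted
# ground truth (motif instances, occupancy classes, summit offsets,
# footprint boundaries, allelic biases, supercoiling dip, domain-border
# flags) so each downstream analysis can be asserted against truth
# without external data. All stages are fully deterministic given the
# config seed and leave the caller's RNG untouched.

default_ctcf_like_matrix <- function() {
  consensus <- c("C", "C", "A", "C", "T", "A", "G", "G", "G", "G",
                 "G", "C", "G", "C")
  counts <- matrix(1, 4, length(consensus), dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(consensus, DNA_BASES), seq_along(consensus))] <- 100
  motif_matrix(counts)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' define the package's reference simulation: a fifty/forty-nine/one
#' percent split of triple, CTCF+RAD21 and CTCF+TOP2B sites; oriented
#' summit offsets of -15 bp (TOP2B), 0 (CTCF) and +12 bp (RAD21) with
#' 5 bp spread; exonuclease footprints at +13..+26 (forward strand) and
#' -27..-13 (reverse strand) with 50 reads per site and 20 % noise;
#' allele-frequency correlation 0.4 at coverage 20; a 0.5-unit
#' supercoiling dip of 300 bp spread; and 60 % of sites placed within
#' 10 % of a domain border.
#'
#' Motif strands are assigned in antithetic pairs (site 2i-1 on `+`,
#' site 2i on `-`, sharing the same oriented summit offsets), so strand
#' balance is exact and the pre-orientation offset distribution is
#' symmetric by construction.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_sites number of planted motif sites.
#' @param site_spacing centre-to-centre site spacing in bp (the genome is
#'   sized to fit; sites are jittered within +/- spacing/6).
#' @param motif a [motif_matrix()] (default: a sharp 14-bp CTCF-like
#'   matrix).
#' @param occupancy_proportions named probabilities over occupancy
#'   classes (`+`-joined sorted factor names); must sum to 1.
#' @param offset_model named list: per factor `c(mean, sd)` of the
#'   oriented summit offset in bp.
#' @param peak_width `c(min, max)` of uniform peak widths.
#' @param signal_meanlog lognormal meanlog of peak signal,
#'   `c(triple, other)`.
#' @param signal_sdlog lognormal sdlog of peak signal.
#' @param exo_model list: `forward`/`reverse` inclusive oriented-offset
#'   footprint intervals, `reads_per_site`, `noise_rate` (fraction of
#'   reads placed uniformly on the genome), `read_length`.
#' @param allelic_model list: `n_sites`, `coverage`, `correlation`
#'   (target allele-frequency correlation between the two factors),
#'   `bias_sd` (sd of the per-site logit bias).
#' @param supercoil_model list: `dip_depth`, `dip_sd` (Gaussian dip in
#'   probe units and bp), `probe_spacing`, `noise_sd`.
#' @param domain_model list: `n_domains`, `border_fraction` (fraction of
#'   sites re-placed near a border), `border_margin` (border zone as a
#'   fraction of domain size, default 0.1).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_sites = 2000,
                       site_spacing = 3000,
                       motif = default_ctcf_like_matrix(),
                       occupancy_proportions = c(
                         "CTCF+RAD21+TOP2B" = 0.50,
                         "CTCF+RAD21" = 0.49,
                         "CTCF+TOP2B" = 0.01),
                       offset_model = list(TOP2B = c(mean = -15, sd = 5),
                                           CTCF = c(mean = 0, sd = 5),
                                           RAD21 = c(mean = 12, sd = 5)),
                       peak_width = c(200, 400),
                       signal_meanlog = c(triple = 3, other = 2.5),
                       signal_sdlog = 0.4,
                       exo_model = list(forward = c(13, 26),
                                        reverse = c(-27, -13),
                                        reads_per_site = 50,
                                        noise_rate = 0.2,
                                        read_length = 36),
                       allelic_model = list(n_sites = 5000, coverage = 20,
                                            correlation = 0.4, bias_sd = 1),
                       supercoil_model = list(dip_depth = -0.5,
                                              dip_sd = 300,
                                              probe_spacing = 500,
                                              noise_sd = 0.3),
                       domain_model = list(n_domains = 40,
                                           border_fraction = 0.6,
                                           border_margin = 0.1)) {
  stopifnot(abs(sum(occupancy_proportions) - 1) < 1e-9,
            all(vapply(offset_model, function(m) m[["sd"]] > 0, TRUE)),
            n_sites >= 0, site_spacing >= 10 * motif$width)
  genome <- c(sim1 = as.integer(max(n_sites, 1) * site_spacing + site_spacing))
  structure(list(seed = seed, n_sites = n_sites,
                 site_spacing = site_spacing, genome = genome,
                 motif = motif,
                 occupancy_proportions = occupancy_proportions,
                 offset_model = offset_model, peak_width = peak_width,
                 signal_meanlog = signal_meanlog,
                 signal_sdlog = signal_sdlog, exo_model = exo_model,
                 allelic_model = allelic_model,
                 supercoil_model = supercoil_model,
                 domain_model = domain_model),
            class = "sim_config")
}

#' Simulate a genome with planted stranded motif instances
#'
#' The background sequence is i.i.d. uniform over A/C/G/T; motif
#' instances (sampled column-wise from the matrix) are embedded at
#' jittered grid positions, on `+`/`-` strands in alternating antithetic
#' pairs. No two instances overlap by construction of the grid.
#'
#' @param config a [sim_config()].
#' @return list: `sequences` (named character vector), `motifs` (truth
#'   data frame `site_id`, `chrom`, `start`, `end`, `strand`, `center`).
#' @export
simulate_genome_and_motifs <- function(config) {
  w <- config$motif$width
  probs <- config$motif$probs
  with_seed(child_seed(config$seed, 1), {
    ch <- names(config$genome)[1]
    L <- config$genome[[1]]
    seq_codes <- sample.int(4, L, replace = TRUE)
    n <- config$n_sites
    if (n == 0)
      return(list(sequences = stats::setNames(
        paste(DNA_BASES[seq_codes], collapse = ""), ch),
        motifs = data.frame(site_id = integer(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), center = integer())))
    sp <- config$site_spacing
    jitter <- round(stats::runif(n, -sp / 6, sp / 6))
    centers <- as.integer((seq_len(n) - 1) * sp + sp %/% 2 + jitter)
    strand <- ifelse(seq_len(n) %% 2 == 1, "+", "-")
    start <- ifelse(strand == "+", centers - w %/% 2,
                    centers - (w + 1) %/% 2 + 1)
    if (any(diff(start) < w) || start[1] < 0 || start[n] + w > L)
      stop("planted instances overlap; increase site_spacing")
    for (i in seq_len(n)) {
      inst <- vapply(seq_len(w), function(j)
        sample.int(4, 1, prob = probs[, j]), 0L)
      if (strand[i] == "-") inst <- rev(5L - inst)  # reverse complement
      seq_codes[(start[i] + 1):(start[i] + w)] <- inst
    }
    sequences <- stats::setNames(
      paste(DNA_BASES[seq_codes], collapse = ""), ch)
    motifs <- data.frame(site_id = seq_len(n), chrom = ch,
                         start = as.integer(start),
                         end = as.integer(start + w), strand = strand,
                         center = centers)
    list(sequences = sequences, motifs = motifs)
  })
}

#' Convert truth motif instances to oriented sites
#' @param motifs truth data frame from [simulate_genome_and_motifs()].
#' @return oriented-site data frame (`site_id`, `chrom`, `center`,
#'   `orientation`).
#' @export
motifs_as_sites <- function(motifs) {
  data.frame(site_id = motifs$site_id, chrom = motifs$chrom,
             center = motifs$center, orientation = motifs$strand)
}

#' Simulate factor peak sets with planted occupancy classes and offsets
#'
#' Each site draws an occupancy class; each member factor receives a peak
#' whose summit sits at the motif center plus an orientation-corrected
#' Normal offset. Oriented offsets are shared within each antithetic
#' strand pair, so the un-oriented offset distribution is exactly
#' symmetric. Peak widths are uniform, signals lognormal with a higher
#' mean for the all-factor class.
#'
#' @param config a [sim_config()].
#' @param motifs truth motifs from [simulate_genome_and_motifs()].
#' @return list: `peaks_by_factor` (named list of peak data frames),
#'   `truth` (per site: `site_id`, `class`, and oriented offset columns
#'   `offset_<factor>`).
#' @export
simulate_peaks <- function(config, motifs) {
  props <- config$occupancy_proportions
  factors <- sort(unique(unlist(strsplit(names(props), "+", fixed = TRUE))))
  om <- config$offset_model
  stopifnot(all(factors %in% names(om)))
  n <- nrow(motifs)
  full_class <- paste(factors, collapse = "+")
  with_seed(child_seed(config$seed, 2), {
    cls <- sample(names(props), n, replace = TRUE, prob = props)
    npair <- ceiling(n / 2)
    offsets <- matrix(unlist(lapply(factors, function(f) {
      per_pair <- round(stats::rnorm(npair, om[[f]][["mean"]],
                                     om[[f]][["sd"]]))
      rep(per_pair, each = 2)[seq_len(n)]
    })), ncol = length(factors), dimnames = list(NULL, factors))
    truth <- data.frame(site_id = motifs$site_id, class = cls)
    for (f in factors) truth[[paste0("offset_", f)]] <- offsets[, f]
    peaks_by_factor <- stats::setNames(lapply(factors, function(f) {
      member <- vapply(strsplit(cls, "+", fixed = TRUE),
                       function(s) f %in% s, TRUE)
      idx <- which(member)
      o <- offsets[idx, f]
      summit <- motifs$center[idx] +
        ifelse(motifs$strand[idx] == "+", o, -o)
      wdt <- round(stats::runif(length(idx), config$peak_width[1],
                                config$peak_width[2]))
      frac <- stats::runif(length(idx), 0.25, 0.75)
      start <- pmax(summit - round(frac * wdt), 0)
      ml <- ifelse(cls[idx] == full_class,
                   config$signal_meanlog[["triple"]],
                   config$signal_meanlog[["other"]])
      data.frame(chrom = motifs$chrom[idx], start = as.integer(start),
                 end = as.integer(start + wdt), strand = "*",
                 summit = as.integer(summit),
                 signal = stats::rlnorm(length(idx), ml,
                                        config$signal_sdlog),
                 factor = f, site_id = motifs$site_id[idx])
    }), factors)
    list(peaks_by_factor = peaks_by_factor, truth = truth)
  })
}

#' Simulate strand-specific exonuclease-stop reads with planted footprints
#'
#' Per site, `reads_per_site * (1 - noise_rate)` footprint reads place
#' their 5' ends uniformly on the planted motif-oriented footprint
#' intervals (half on the motif-forward strand in the forward interval,
#' half on the motif-reverse strand in the reverse interval), and the
#' remaining reads are uniform genome-wide noise on random strands.
#'
#' @param config a [sim_config()].
#' @param sites oriented-site data frame (typically
#'   `motifs_as_sites(motifs)` truth, or scanned sites).
#' @return list: `reads` (stranded read data frame), `truth` (the planted
#'   footprint intervals).
#' @export
simulate_exo_reads <- function(config, sites) {
  em <- config$exo_model
  len <- em$read_length
  L <- config$genome[[1]]
  ch <- names(config$genome)[1]
  n <- nrow(sites)
  with_seed(child_seed(config$seed, 3), {
    n_noise <- round(em$reads_per_site * em$noise_rate)
    n_fp <- em$reads_per_site - n_noise
    per_site <- function(i) {
      fwd <- stats::rbinom(1, n_fp, 0.5)
      o <- c(sample(em$forward[1]:em$forward[2], fwd, replace = TRUE),
             sample(em$reverse[1]:em$reverse[2], n_fp - fwd,
                    replace = TRUE))
      motif_fwd <- rep(c(TRUE, FALSE), c(fwd, n_fp - fwd))
      plus_site <- sites$orientation[i] == "+"
      gstrand <- ifelse(motif_fwd == plus_site, "+", "-")
      p5 <- sites$center[i] + if (plus_site) o else -o
      data.frame(p5 = p5, strand = gstrand)
    }
    fp <- do.call(rbind, lapply(seq_len(n), per_site))
    noise <- data.frame(
      p5 = sample.int(L - len, n_noise * n, replace = TRUE) + len %/% 2,
      strand = sample(c("+", "-"), n_noise * n, replace = TRUE))
    all <- rbind(fp, noise)
    start <- ifelse(all$strand == "+", all$p5, all$p5 - len + 1L)
    reads <- data.frame(chrom = ch, start = as.integer(pmax(start, 0)),
                        end = as.integer(pmax(start, 0) + len),
                        strand = all$strand)
    list(reads = reads,
         truth = list(forward = em$forward, reverse = em$reverse,
                      noise_rate = em$noise_rate))
  })
}

# Monotone map from the latent logit-scale correlation to the induced
# allele-frequency correlation, inverted by bisection on a fixed internal
# Monte-Carlo stream (independent of the data-generating seed).
calibrate_latent_correlation <- function(target, coverage, bias_sd,
                                         n = 40000) {
  if (target <= 0) return(0)
  induced <- function(rho) with_seed(900001, {
    z <- stats::rnorm(n)
    lg1 <- bias_sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n))
    lg2 <- bias_sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n))
    f1 <- stats::rbinom(n, coverage, stats::plogis(lg1)) / coverage
    f2 <- stats::rbinom(n, coverage, stats::plogis(lg2)) / coverage
    stats::cor(f1, f2)
  })
  if (induced(0.999) < target)
    stop("target correlation unattainable at this coverage/bias_sd")
  lo <- 0; hi <- 0.999
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (induced(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate allelic count tables for two co-bound factors
#'
#' Each site draws a shared latent logit bias plus independent per-factor
#' noise; allele counts are Binomial(coverage, logistic(logit)). The
#' latent sharing is calibrated by bisection so the induced
#' allele-frequency correlation matches `allelic_model$correlation`.
#'
#' @param config a [sim_config()].
#' @param factors two factor names (default CTCF and TOP2B).
#' @param n_sites number of sites (default `allelic_model$n_sites`).
#' @return list: `counts` (long data frame `site_id`, `factor`,
#'   `ref_count`, `alt_count`), `truth` (per site latent logits and true
#'   frequencies).
#' @export
simulate_allelic_counts <- function(config, factors = c("CTCF", "TOP2B"),
                                    n_sites = config$allelic_model$n_sites) {
  am <- config$allelic_model
  stopifnot(length(factors) == 2)
  rho <- calibrate_latent_correlation(am$correlation, am$coverage,
                                      am$bias_sd)
  with_seed(child_seed(config$seed, 4), {
    z <- stats::rnorm(n_sites)
    lg <- sapply(factors, function(f)
      am$bias_sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n_sites)))
    pi <- stats::plogis(lg)
    counts <- do.call(rbind, lapply(factors, function(f) {
      ref <- stats::rbinom(n_sites, am$coverage, pi[, f])
      data.frame(site_id = seq_len(n_sites), factor = f, ref_count = ref,
                 alt_count = am$coverage - ref)
    }))
    truth <- data.frame(site_id = seq_len(n_sites), z = z)
    for (f in factors) truth[[paste0("pi_", f)]] <- pi[, f]
    list(counts = counts, truth = truth, latent_correlation = rho)
  })
}

#' Simulate supercoiling probes and topological domains
#'
#' Probes sit on a jittered regular grid; their values are Gaussian noise
#' plus a planted Gaussian dip centred on the nearest site. Domains tile
#' the genome with jittered sizes; a configured fraction of sites is
#' re-placed within `border_margin` of a random domain edge (truth
#' flagged), the rest keep their original positions.
#'
#' @param config a [sim_config()].
#' @param sites oriented-site data frame (motif truth).
#' @return list: `probes` (`chrom`, `position`, `value`), `domains`
#'   (`chrom`, `start`, `end`), `domain_sites` (sites with a logical
#'   `border` truth column), `truth` (dip parameters).
#' @export
simulate_probes_and_domains <- function(config, sites) {
  sm <- config$supercoil_model
  dm <- config$domain_model
  ch <- names(config$genome)[1]
  L <- config$genome[[1]]
  with_seed(child_seed(config$seed, 5), {
    grid <- seq(sm$probe_spacing %/% 2, L - 1, by = sm$probe_spacing)
    pos <- grid + round(stats::runif(length(grid), -sm$probe_spacing / 5,
                                     sm$probe_spacing / 5))
    pos <- pmin(pmax(pos, 0), L - 1)
    d <- nearest_oriented_distance(rep(ch, length(pos)), pos, sites)
    dip <- ifelse(is.na(d), 0,
                  sm$dip_depth * exp(-d^2 / (2 * sm$dip_sd^2)))
    probes <- data.frame(chrom = ch, position = as.integer(pos),
                         value = dip + stats::rnorm(length(pos), 0,
                                                    sm$noise_sd))
    base_size <- L / dm$n_domains
    sizes <- stats::runif(dm$n_domains, 0.8, 1.2) * base_size
    bounds <- round(c(0, cumsum(sizes)) / sum(sizes) * L)
    domains <- data.frame(chrom = ch, start = as.integer(bounds[-length(bounds)]),
                          end = as.integer(bounds[-1]))
    ds <- sites
    nb <- round(nrow(ds) * dm$border_fraction)
    sel <- sample.int(nrow(ds), nb)
    di <- sample.int(nrow(domains), nb, replace = TRUE)
    size <- domains$end[di] - domains$start[di]
    zone <- pmax(round(dm$border_margin * size), 1)
    at_start <- stats::runif(nb) < 0.5
    offs <- floor(stats::runif(nb) * zone)
    ds$center[sel] <- ifelse(at_start, domains$start[di] + offs,
                             domains$end[di] - 1 - offs)
    ds$border <- FALSE
    ds$border[sel] <- TRUE
    list(probes = probes, domains = domains, domain_sites = ds,
         truth = list(dip_depth = sm$dip_depth, dip_sd = sm$dip_sd))
  })
}

#' Write a full simulated dataset to standard-format files
#'
#' Emits the genome FASTA, truth motif BED6, per-factor narrowPeak files,
#' exo tagAlign, allelic count TSV, probe TSV, domain BED3, and truth
#' tables, all derived deterministically from the config seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulate_genome_and_motifs(config)
  pk <- simulate_peaks(config, gm$motifs)
  sites <- motifs_as_sites(gm$motifs)
  exo <- simulate_exo_reads(config, sites)
  al <- simulate_allelic_counts(config)
  pd <- simulate_probes_and_domains(config, sites)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gm$sequences),
                              file.path(outdir, "genome.fa"))
  write_bed(data.frame(chrom = gm$motifs$chrom, start = gm$motifs$start,
                       end = gm$motifs$end, name = gm$motifs$site_id,
                       score = 0, strand = gm$motifs$strand),
            file.path(outdir, "motifs.bed"))
  for (f in names(pk$peaks_by_factor))
    write_narrowpeak(pk$peaks_by_factor[[f]],
                     file.path(outdir, paste0(f, ".narrowPeak")))
  write_tagalign(exo$reads, file.path(outdir, "exo.tagAlign"))
  tsv <- function(x, name) utils::write.table(
    x, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(al$counts, "allelic_counts.tsv")
  tsv(pd$probes, "probes.tsv")
  write_bed(pd$domains, file.path(outdir, "domains.bed"))
  tsv(pk$truth, "truth_sites.tsv")
  invisible(list(genome = gm, peaks = pk, exo = exo, allelic = al,
                 probes_domains = pd))
}
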