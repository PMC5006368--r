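# triplesites

Analyses of the combinatorial occupancy and base-pair-scale spatial
organisation of architectural proteins — CTCF, the cohesin subunit RAD21,
and topoisomerase II beta (TOP2B) — around the oriented CTCF motif, with a
seeded synthetic-data generator that plants ground truth for every stage.

## The scientific problem

CTCF binds an asymmetric DNA motif, and cohesin and TOP2B co-occupy many
CTCF sites with a fixed spatial order along the motif axis. Characterising
that order from ChIP-seq and ChIP-exo data requires a chain of analyses,
each individually simple but easy to get subtly wrong (strand conventions,
orientation mirroring, off-by-one coordinates):

* **Occupancy classification.** Peaks of *k* factors are pooled and merged
  wherever they overlap by ≥ 1 bp; each merged region is labelled with the
  set of contributing factors, giving 2^k − 1 occupancy classes ("triple
  sites" are regions bound by all three factors).
* **Motif-oriented geometry.** For every site, the CTCF core motif is
  located (PWM scan with a Markov background and exact tail p-values
  p = P(score ≥ s)), oriented to its G-rich direction, and each factor's
  summit is expressed as a signed offset *d* = ±(summit − center), negative
  5′ of the motif. Medians, orderings (e.g. TOP2B–CTCF–RAD21), and the
  enrichment of the canonical order before vs after orientation (Fisher's
  exact test) follow.
* **ChIP-exo footprints.** λ-exonuclease stops mark protein boundaries at
  the 5′ ends of reads. Per-strand 5′-end pileups over −50..+50 bp around
  oriented motifs (for a − oriented motif, offsets are mirrored *and*
  strand labels swapped) are compared to a background from column-permuted
  motif matrices, and protection footprints are called where the observed
  profile exceeds background mean + *k*·sd over ≥ 3 consecutive bp.
* **Allele-specific binding.** From F1-cross allelic read counts, sites
  are classified by an exact two-sided binomial test against 0.5; the
  allele-frequency correlation between co-bound factors and one-sided
  rank-sum shifts between bias classes quantify co-directional binding.
* **Supercoiling and domains.** Psoralen (bTMP) probe intensities are
  profiled by oriented distance to the nearest site (100-bp bin medians,
  rolling mean), against random-feature backgrounds with both the
  classical two-sample Kolmogorov–Smirnov p and a calibrated permutation
  p; site positions within topological domains are reduced to a relative
  coordinate in [0, 1] (0 and 1 = borders).

The package is written for genomicists who want these statistics as
tested, composable functions rather than one-off scripts, and for method
evaluation: the `simulate_*` family generates every input format the
pipeline consumes with planted truth (motif instances, class proportions,
summit offsets, footprint boundaries, allelic biases, supercoiling dips,
domain-border placement), so each stage's recovery can be asserted
exactly.

All coordinates are 0-based half-open (BED convention).

## Worked example

```r
library(triplesites)
cfg <- sim_config(seed = 1, n_sites = 500)   # reference study conditions
gm  <- simulate_genome_and_motifs(cfg)
pk  <- simulate_peaks(cfg, gm$motifs)

classify_occupancy(pk$peaks_by_factor)$table
#>             CTCF            RAD21            TOP2B       CTCF+RAD21
#>                0                0                0              265
#>       CTCF+TOP2B      RAD21+TOP2B CTCF+RAD21+TOP2B
#>                7                0              228
```

228/500 regions are triple sites and 265 CTCF+RAD21 doubles — the planted
50/49/1 % class split. Summit offsets around the oriented motif:

```r
sites <- motifs_as_sites(gm$motifs)
off <- site_offsets(sites, pk$peaks_by_factor)
distance_summaries(off$offsets)
#>   factor       mode median q25    q75   n
#> 1   CTCF   oriented    0.0  -4   2.25 228
#> 2   CTCF unoriented    0.0  -3   3.00 228
#> 3  RAD21   oriented   11.0   8  16.00 228
#> 4  RAD21 unoriented    4.0 -11  12.00 228
#> 5  TOP2B   oriented  -14.5 -18 -12.00 228
#> 6  TOP2B unoriented   -7.5 -15  14.00 228
```

TOP2B sits ~15 bp 5′ and RAD21 ~12 bp 3′ of the motif center once motifs
are oriented; without orientation the offsets mix both signs. The ordering
statistic makes this explicit:

```r
oe <- order_enrichment(classify_order(off$offsets, oriented = FALSE),
                       classify_order(off$offsets))
#> canonical TOP2B-CTCF-RAD21 order: 92.5% (vs 50.0% unoriented), Fisher p = 3.83e-25
```

ChIP-exo 5′-end profiling calls the planted protection footprints at
base-pair accuracy:

```r
exo  <- simulate_exo_reads(cfg, sites)
prof <- exo_profile(exo$reads, sites)
regions <- data.frame(region_id = gm$motifs$site_id, chrom = gm$motifs$chrom,
                      start = pmax(gm$motifs$start - 500, 0),
                      end = gm$motifs$end + 500)
bg <- permuted_background(exo$reads, regions, cfg$motif, gm$sequences,
                          n_perm = 10, seed = 2)
call_footprints(prof, bg)
#>    strand start_offset end_offset max_signal
#> 1 forward           13         26      1.534
#> 2 reverse          -27        -13      1.406
```

The forward-strand footprint at +13..+26 (cohesin side) and the
reverse-strand footprint at −27..−13 (TOP2B side) are exactly the planted
boundaries.

Real data enters through `read_intervals()` (BED3/6, ENCODE narrowPeak
with summit offsets, tagAlign), `read_transfac()` (count matrices; a small
synthetic example ships in `inst/extdata/`), and plain TSV tables for
allelic counts and probe intensities.

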