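---
title: "Methods: motif-oriented architecture of CTCF/cohesin/TOP2B sites"
author: "triplesites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-oriented architecture of CTCF/cohesin/TOP2B sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplesites)
```

# Scope and model

This package quantifies how architectural proteins arrange themselves
around the asymmetric CTCF binding motif. Its object model is small:
peaks (intervals with a summit and signal), stranded reads, oriented
sites (a motif center plus a G-rich orientation that defines a signed
local axis), allelic count pairs, probe intensities, and domains. All
genomic coordinates are 0-based half-open; single-base positions
(summits, motif centers, 5′ ends) are 0-based. Interval algebra is
delegated to GenomicRanges internally and converted at the boundary.

Five analyses are built on these objects, plus a generator that plants
ground truth for all of them.

# Occupancy classification

Peaks of all declared factors are pooled and merged wherever they overlap
by **at least one base pair**; a merged region's class is the set of
factors contributing ≥ 1 overlapping peak. Book-ended intervals
(`[a,b) [b,c)`) share no base and are deliberately *not* merged — this
differs from the bedtools-merge default of distance 0 and is the stricter
reading of "≥ 1 bp overlap". The class table counts merged regions; peak
intensity comparisons (`intensity_by_category()`) score the *original*
peaks, grouped by their region's class, with one-sided Wilcoxon rank-sum
tests in the direction of the larger median and Benjamini–Hochberg
adjustment within the family of pairwise tests. Both region-level and
peak-level counts are reported because the two denominators answer
different questions (how many loci vs how many peaks).

`overlap_enrichment_test()` implements a deliberately plain randomisation
null: query intervals are uniformly re-placed (lengths preserved) within
a user-supplied workspace and the empirical p is
`(1 + #{null ≥ observed}) / (n_sim + 1)`. No mappability or isochore
stratification is attempted; if those structures matter for a dataset
the workspace should encode them.

# Motif scanning and orientation

Windows are scored as
$\sum_j \log_2\left(p_\mathrm{matrix}(b_j \mid j)\, /\, p_\mathrm{bg}(b_j \mid \mathrm{context})\right)$
(bits), with minus-strand windows scored on the reverse complement.
The background is, by default, an order-1 Markov model estimated
strand-symmetrically from the scanned sequences themselves; a pseudocount
of 1 is added to every matrix cell before normalisation. Windows
containing `N` are skipped.

Tail p-values `P(score ≥ s)` come from a column-wise dynamic programme
over the achievable score sums. Partial sums are aggregated on exact
doubles, so for widths where the support fits in memory the result equals
exhaustive enumeration to floating-point accuracy (the test suite checks
all widths ≤ 8 against full enumeration at 1e-9); only when the support
exceeds a cap (2·10^5 points) is the score lattice coarsened. P-values
under an order-1 background are approximated by the model's order-0
marginal — the score is computed order-1, its p-value order-0. This
approximation is documented rather than hidden because exact order-1
tail probabilities would require a lag-aware DP that the analyses here
do not need: scanning thresholds sit in a regime (1e-4) where the
ranking of hits, not the absolute tail mass, drives the results.

Per region, only the highest-scoring hit is kept (ties: leftmost start,
then `+` strand). The motif **center** is the base immediately 3′ of the
midpoint in motif orientation — mirror-symmetric for even widths, the
middle base for odd widths — and every offset statistic uses it
consistently. Column-order permutation (`permute_matrix()`) preserves
per-column composition and total information content; it is the
conservative reading of matrix permutation for background construction
(within-column shuffling would also change column entropies).

# Oriented distances, ordering, domains

The signed offset of a summit from an oriented site is
`summit − center` for `+` orientation and `center − summit` for `−`;
negative means 5′ of the G-rich motif. Sites enter the ordering analysis
only if every factor's nearest summit lies within ±100 bp of the motif
center; excluded sites are counted. The CTCF position used in orderings
is its own *summit* offset (not 0 by construction); anchoring CTCF at
its motif center instead is possible by passing a pseudo-factor, but the
summit is the default because all three factors are then measured by the
same estimator. Exact offset ties are broken alphabetically and flagged.
The canonical order along the G-rich axis is TOP2B–CTCF–RAD21; its
enrichment after orientation is tested by Fisher's exact test on the
2×2 table canonical/other × before/after.

A site's relative position inside its topological domain is
`(anchor − domain_center + size/2) / size` — 0 at the 5′ border, 1 at the
3′ border. The anchor is the motif center when available, else the peak
summit. Border enrichment is summarised as the density ratio of
positions in `[0, 0.1] ∪ [0.9, 1]` over `[0.45, 0.55]`.

# ChIP-exo 5′-end profiles

A read's 5′ end is `start` (`+` strand) or `end − 1` (`−` strand). For a
profile, 5′ ends within ±50 bp of each retained site are binned by
oriented offset; for `−` oriented sites offsets are mirrored **and**
strand labels swapped, so "forward" always means the top strand of the
motif's own axis and a statement like "reverse-strand protection at
−27..−13" is independent of which genomic strand the motif occupies.
Sites with fewer than 10 in-window 5′ ends are discarded before
averaging (the filter counts 5′ ends inside the window, not reads
overlapping it), and averages divide summed counts by the number of
retained regions — deep regions therefore weigh more, which is the
written convention of this analysis; per-region normalisation is a
caller-side transformation of the same counts.

The background envelope re-runs scan → orient → profile for each of 10
column-permuted matrices. Its depth filter defaults to 1 rather than 10:
permuted motifs land away from genuine binding sites, where depth is at
background level, and filtering there would discard most permuted
regions and keep only accidental read clusters, biasing the envelope
upward. Footprints are maximal runs of ≥ 3 consecutive offsets where the
observed profile exceeds background mean + 3·sd (per strand); both the
multiplier and the run length are package choices — the classical
presentation of these profiles is visual — and both are exposed as
arguments.

# Allele-specific binding

Allele frequency is `ref / (ref + alt)` with the C57BL/6J parent as
reference. Bias classification uses the exact two-sided binomial test
against 0.5 (minimum-likelihood two-sided convention, as in
`binom.test`), at α = 0.05; the test's discreteness at coverage ~20
makes it conservative, so the realised type-I rate sits near 4 %, not
5 %. Sites need ≥ 5 informative reads (configurable) to enter
correlations, a floor the source analyses leave unstated. The
co-binding correlation is Pearson on the two allele-frequency vectors
(Spearman available); group shifts are one-sided Wilcoxon rank-sum
tests of the target factor's frequencies in each biased anchor class
against the unbiased class, sided toward the anchor's bias.

# Supercoiling profiles

Each probe is assigned to its nearest oriented feature (ties toward the
5′ feature; probes farther than 50 kb excluded, configurable); signed
oriented distances are binned at 100 bp, per-bin medians taken, and a
rolling mean (window 10 bins, step 2) applied. Empty bins stay `NA` and
are not interpolated. The bTMP normalisation is
`log2(cell/input) − log2(genomic/input)`; the literal-difference variant
`log2(genomic − input)` that sometimes appears in print is dimensionally
inconsistent but available behind `literal_difference = TRUE`, asserting
neither reading as authoritative.

The background runs the same pipeline on `n_random` uniformly drawn
feature sets of equal size. Two p-values are reported. `ks_p` is the
classical two-sample Kolmogorov–Smirnov p of observed vs pooled random
smoothed values — reported for comparability, but *not* calibrated: the
observed and random profiles regroup the same probes, and overlapping
rolling windows autocorrelate neighbouring values, so under a no-signal
null its distribution is far from uniform (we measured this directly in
simulation, in both directions depending on smoothing). `empirical_p`
is the calibrated alternative: the observed profile and the random
profiles are exchangeable under the null, so ranking the observed
profile's KS distance-to-pool among every member's leave-one-out
distance gives a p uniform on `{1/(R+1), …, 1}`. Detection claims in the
tests use both; calibration claims use `empirical_p`. Increase
`n_random` (e.g. 199) when p-value resolution below 0.1 is needed.

# The synthetic-data generator

The generator's defaults are the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| occupancy proportions | 50 % triple, 49 % CTCF+RAD21, 1 % CTCF+TOP2B | the reported genome-wide split of ~20k/~20k/~400 sites |
| oriented summit offsets | TOP2B N(−15, 5), CTCF N(0, 5), RAD21 N(+12, 5) bp | reported median geometry; 5 bp spread is a realistic summit-calling error |
| footprint intervals | forward +13..+26, reverse −27..−13 | reported exonuclease protection boundaries |
| exo reads | 50/site, 20 % uniform genome-wide noise, 36 bp | typical exo depth; noise models unbound background |
| allelic model | coverage 20, logit bias sd 1, target frequency correlation 0.4 | reported co-binding correlation |
| supercoiling dip | depth −0.5, σ = 300 bp, probe noise sd 0.3 | a dip clearly resolvable at array-like probe densities |
| domains | 40 per genome, 60 % of sites within 10 % of a border | border-enriched placement with a non-degenerate interior |

Design choices worth knowing:

* **Antithetic strand pairs.** Sites are planted in pairs sharing the
  same oriented offsets, one on each motif strand. Strand balance is
  therefore exact and the pre-orientation offset distribution is
  symmetric *by construction*, so the un-oriented medians are identically
  zero rather than estimates with a sampling spread — the cleanest
  possible negative control for the orientation machinery. Occupancy
  classes are still drawn independently per site.
* **Grid placement.** Sites sit on a jittered grid with spacing
  `site_spacing` (default 3 kb), which precludes overlapping planted
  instances and cross-site peak merging by construction (violations are
  an error, not silently retried).
* **Exo noise is genome-wide.** Noise reads are uniform over the genome,
  not over site windows, so the permuted-motif background sees the same
  read density as off-footprint offsets in the observed profile.
* **Allelic calibration.** The shared-logit weight is found by bisection
  on an internal fixed-seed Monte-Carlo map from latent correlation to
  induced frequency correlation at the configured coverage, so the
  *realised* correlation matches the target (binomial sampling noise
  attenuates any naive latent correlation).
* **Determinism.** Every stage derives its own stream from the config
  seed and restores the caller's RNG; identical configs give
  byte-identical output files.

What the generator does **not** emulate: mappability and blacklist
structure, PCR duplicates and fragment-length distributions,
sequence-composition biases of real genomes (background is i.i.d.
uniform), SNP density driving allelic informativeness, peak-caller
artefacts, or correlated placement of domains and binding sites beyond
the configured border fraction. Passing recovery tests therefore
demonstrates the correctness of the statistics and conventions, not
robustness to those real-data pathologies.

# Problem sizes and tolerances used in the tests

The recovery suite runs at the reference conditions: 10,000 sites for
class-proportion recovery (asserted within 3 binomial standard errors),
2,000 triple sites for the geometry (medians within ±1 bp; canonical
order enrichment Fisher p < 1e-6), 500 sites × 50 reads for footprint
calling (boundaries within ±1 bp), exhaustive enumeration up to width 8
for PWM p-values (1e-9), 5,000 sites at coverage 20 for allelic
calibration (null bias-call rate in [0.02, 0.07], correlation ±0.05, 500
null replicates for rank-sum uniformity), ~19,000 probes over 2,000
features for the supercoiling dip (minimum within ±200 bp, p < 0.01;
200 null replicates for calibration), and 600 sites for border
enrichment (edge/center density ratio ≥ 3). `scripts/acceptance.R`
recomputes all of these from scratch for any seed.

# Known limitations

* Order-1 tail p-values are approximated by the order-0 marginal (above).
* The placement null for overlap enrichment ignores mappability.
* `ks_p` for supercoiling profiles is knowingly uncalibrated; use
  `empirical_p` for inference.
* The exact binomial bias test is conservative at low coverage; power at
  coverage 20 is limited to frequencies beyond roughly 0.25/0.75.
* Footprint calling assumes the background envelope's sd is a fair
  noise scale; with very few permutations (< 5) the envelope is noisy
  and the default `k = 3` can over- or under-call.
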