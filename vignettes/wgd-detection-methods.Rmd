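---
title: "Detecting and dating paleopolyploidy from gene order and Ks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating paleopolyploidy from gene order and Ks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

# Overview

`wgdtrace` reconstructs the polyploid history of a plant genome from three
kinds of evidence that survive tens of millions of years after the event
itself:

1. **Collinearity.** A whole-genome duplication (WGD) leaves every
   chromosome with a duplicated partner; even after massive gene loss, the
   surviving duplicates preserve long stretches of shared gene order
   (collinear or synteny blocks).
2. **Synonymous divergence.** All gene pairs created by the same WGD start
   diverging at the same instant, so the distribution of synonymous
   distance (Ks) between collinear gene pairs carries one peak per event.
3. **Karyotype structure.** Chromosome fusions and translocations leave
   diagnostic junction patterns whose copy number relative to a WGD dates
   the rearrangement itself.

The package implements each step as a function over plain tables (tibbles),
plus a genome-evolution simulator that generates inputs with full ground
truth so every step can be validated against known answers.

# Collinear block detection

Homologous gene pairs (from BLAST-style hit tables, E-value at most 1e-5)
are placed in the plane of gene *order indices* — the rank of each gene
along its chromosome — rather than base-pair positions. Rank space makes
the `max_gap` parameter directly interpretable as "number of skipped
genes", which is the natural unit when fractionation has deleted genes
between surviving anchors.

Within each chromosome pair, `detect_blocks()` finds maximal chains of
pairs that are strictly increasing on both axes (orientation +1) or
increasing on the query and decreasing on the subject axis (−1), with at
most `max_gap` skipped genes between consecutive anchors on either axis.
Chains are scored by their number of anchor pairs, with no gap penalty:
this minimal scoring keeps an exhaustive-search oracle exact, and the test
suite verifies that the dynamic-programming chain equals the brute-force
optimum on small instances. Chains are extracted greedily by descending
score, each anchor belonging to at most one block; chains shorter than
`min_pairs` are discarded. Ties between equal-score chains resolve to the
chain starting at the smallest query index, making output deterministic
and independent of hit-file row order.

Defaults `min_pairs = 5` and `max_gap = 25` are declared choices in the
range conventional for collinearity scanners of this family; published
scanners vary in their settings, so the values here are stated rather
than inherited.

# NG86 Ka/Ks estimation

`ng86()` implements the Nei–Gojobori counting method with Jukes–Cantor
correction under the universal genetic code:

* Each codon position contributes a synonymous-site fraction equal to the
  number of its one-step changes that preserve the amino acid, divided
  by 3; changes into stop codons count as nonsynonymous. Sites are averaged
  over the two sequences, so S + N = 3 × (compared codons) exactly.
* Codons differing at 2–3 positions average their synonymous and
  nonsynonymous difference counts over all minimal substitution paths with
  equal weights. Any path step passing through a stop codon is excluded
  from the average; if every path is blocked, the codon is skipped and
  removed from the site totals. This stop handling follows standard NG86
  practice and is stated explicitly because classic descriptions of the
  method leave it implicit.
* Proportions are corrected by d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is
  saturation and the distance is reported missing with status `saturated`.
  Codons containing gaps or ambiguity characters are skipped pairwise.
  Degenerate inputs (length mismatch, internal stops) yield a flagged row,
  never an exception, so batch runs continue.

The suite checks the difference counts against an independent
path-enumeration oracle on **every** sense-codon pair, and checks that the
estimator recovers the simulator's planted synonymous distance in
expectation.

Ks values above 5 are treated as saturation-adjacent and excluded from
peak fitting; beyond that point the Jukes–Cantor correction amplifies
noise faster than signal and a Gaussian mixture would chase artefacts.

# Ks peaks, rate correction, and dating

Mixture fitting operates on **block-median** Ks, not raw pair Ks: medians
within a block suppress pair-level noise and gene-specific rate variation,
and sharpen event peaks. `fit_ks_peaks()` fits a k-component Gaussian
mixture by expectation–maximization with kmeans initialization from the
caller's seed, taking the best of 10 restarts by likelihood. EM over
explicit Gaussian components was preferred to least-squares fitting of a
smoothed density because it is deterministic given the seed, yields
component weights directly, and the same "sum of Gaussian functions" model
is what it fits. A standard-deviation floor of 1e-4 prevents component
collapse onto repeated values. The component count k is user-specified
(three peaks — two WGDs plus the core-eudicot hexaploidy — is the
expected within-genome structure for a twice-duplicated eudicot); a BIC scan can be run by
fitting several k and comparing `glance()$bic`, but is deliberately not
automatic.

Lineages evolve at different rates, so the same event can sit at different
Ks in different genomes. `correct_ks()` aligns the peak generated by a
shared event onto a reference value by multiplying every component mean
and standard deviation by `reference_mu / shared_event_mu` — proportional
peak alignment. Component mean *ratios* are invariant under this
correction, which is what makes proportional dating consistent.
Proportional peak alignment is the declared form of rate correction used
throughout this package.

`date_event()` converts a Ks peak to absolute time linearly against a
calibrated event: t = (ks_event / ks_calib) · t_calib, applied to both
calibration bounds. With the core-eudicot hexaploidy at Ks 1.90 calibrated
to 115–130 Mya, the within-genome peaks at 0.30 and 0.66 date to about
18–21 and 40–45 Mya. (Published estimates computed from rate-corrected
peaks can be slightly narrower for the older event than raw proportional
arithmetic gives; the pipeline reproduces the computation itself, and the
younger-event range directly.)

`assign_blocks_to_events()` labels each block with the component that
maximizes the posterior responsibility of its median Ks, leaving blocks
below responsibility 0.6 unassigned. The threshold avoids coin-flip labels
where neighbouring peaks overlap: a block exactly between two equal
components has responsibility 0.5 and stays unassigned.

# Orthologous ratios

The modal number of matched chromosomal regions in genome B per region of
genome A reflects their relative ploidy: an unduplicated outgroup sees 4
matched regions in a twice-duplicated genome (1:4), two WGDs against one
see 4:2. `orthologous_ratio()` slides windows of `window_genes` genes
(default 100) with 50% overlap along each genome, collects the block
footprints on the other genome that overlap each window, merges footprints
on the same chromosome separated by at most `2 × window_genes` ranks into
one region (fragmented blocks must not inflate the count), and takes the
modal region count over windows with at least one block. Ties in the mode
resolve to the smaller count, biasing against overcounting. The
genome-wide ratio is reported as the raw modal counts of the two
directions (e.g. 4:2), following the field's presentation, and is never
reduced. Window size and merge distance are declared defaults; published
ratio figures rarely state how best-matched regions were counted.

# Fractionation: the geometric run-length model

After a WGD, duplicated genes are deleted in runs of consecutive genes.
`retention_profile()` marks each reference gene retained in a query
subgenome iff it anchors a block pair assigned to that subgenome; genes
outside every block footprint are excluded from denominators, since
nothing can be said about them. `loss_runs()` enumerates maximal runs of
consecutive non-retained genes bounded on both sides by retained genes
(edge runs are unobserved in full and are not counted); runs longer than
`segmental_cutoff` (default 30) are counted separately as segmental
losses: whole-segment deletions are a different mechanism from
gene-by-gene fractionation and would otherwise dominate the tail, and a
run-length cutoff is the declared rule for separating them.

`fit_geometric()` fits N_k = N₁·p^(k−1) two ways: least-squares regression
of ln N_k on (k−1) over lengths with N_k ≥ 5 (log of small counts is
unstable), and the closed-form maximum-likelihood estimate
p̂ = Σ(kᵢ−1)/Σkᵢ, which uses every run and no binning. Both are reported
so either convention can be compared. Goodness of fit is an
extra-parameter F test of the pure geometric decay against the
k^b-modulated alternative N_k = N₁·p^(k−1)·k^b (null b = 0): a **high**
P-value means the one-parameter geometric law is adequate. This
construction was chosen deliberately: in the fractionation literature a
high P-value (e.g. 0.9) is read as evidence of good geometric fit, which
an overall regression-significance F test would invert. When both models fit
perfectly (noiseless geometric counts) the test is degenerate and the
P-value is reported as 1.

# Karyotype event calculus

A karyotype is an ordered list of chromosomes, each an ordered list of
oriented segments labelled by ancestral chromosome, with spans as
fractions of the ancestral unit interval. Six events rewrite it:

| event | effect | count |
|-------|--------|-------|
| EEJ   | end-to-end joining (telomeric fusion) | −1 |
| NCF   | nested chromosome fusion (donor inserted at host breakpoint, default 0.5 as a centromere proxy) | −1 |
| XO    | crossover = reciprocal translocation of arms at one breakpoint per chromosome | 0 |
| IV    | segmental inversion | 0 |
| WGD   | duplication, copy suffixes a/b | ×2 |
| WGT   | triplication, suffixes a/b/c | ×3 |

Every EEJ/NCF records one satellite from the joined telomeres; satellites
never re-enter the karyotype and are excluded from all counts, consistent
with their eventual loss. XO is strictly a two-chromosome reciprocal
translocation. After every event, consecutive segments that are contiguous
pieces of the same ancestral chromosome in the same orientation are merged,
so a reverted inversion leaves no trace and the representation is
canonical. Conservation invariants (count algebra, span-multiset
invariance under rearrangements, satellite ledger) are asserted on
randomized event scripts in the test suite.

`infer_fusion_timing()` applies the copy-number rule for dating fusions
relative to a WGD: a junction of two distinct ancestral chromosomes formed
*before* the WGD is inherited by both copies and appears in two (or more)
chromosomes; a junction formed *after* appears in exactly one. Junctions
are canonicalized reversal-invariantly (a fusion read from either telomere
is the same junction). A junction seen once whose two flanking ancestors
both also occur in other heterologous junctions is flagged
`possibly_disrupted`: this is the signature left when a later crossover
breaks one copy of a pre-WGD junction, and the copy-count rule is then
inapplicable rather than decisive. On engine-generated histories without
post-fusion breakage the classification is exact.

# The simulator: what it emulates, and what it does not

`simulate_genomes()` evolves lineages from a shared ancestral gene order.
The simulation clock is Ks itself: WGD/WGT events carry Ks-age stamps that
become the true synonymous distance between the copies they create, and
dating tests translate to absolute time only through a declared
calibration — the same way real WGDs are dated relative to the
hexaploidy.

* **Fractionation.** After each polyploidy event, every retained duplicate
  independently initiates a loss run on its homoeolog with probability
  `loss_initiation_rate`; the run continues gene-by-gene with probability
  `loss_extension_p`. A run extends over the next *deletable* gene:
  already-absent genes and genes whose deletion would remove the last
  surviving copy are skipped rather than terminating the run, so realized
  run lengths remain geometric except for rare chromosome-end truncation
  — the distribution the downstream fit assumes. Unconditional retention
  of one copy means fractionation is loss of duplicates only. The default
  extension parameter 0.28 matches values estimated for heavily
  fractionated eudicot genomes; initiation rates are not reported in that
  literature and 0.2 is the declared default.
  The directional, sequential application of loss (copy a onto b, then b
  onto a) produces mild subgenome bias, which real fractionated genomes
  also show.
* **Observed Ks.** In table mode, observed pair Ks = true event Ks +
  Gaussian noise (sd `ks_noise_sd`, default 0.05, truncated at 0),
  mirroring the dispersion that fitted Ks peaks show in practice. In sequence mode, codon
  sequences accrue Poisson-distributed synonymous substitutions placed
  uniformly over synonymous one-step changes (and nonsynonymous ones at a
  fixed Ka/Ks scalar), so NG86 recovers the true Ks in expectation; stop
  codons are excluded from the alphabet at generation time.
* **Hits.** Bitscores decay as s₀·exp(−Ks), so the closest surviving
  relative is always the best hit; exact ties are impossible except at
  identical true Ks, where the lexicographic subject tie-break applies.
* **Not modelled:** indels, codon-usage bias, rate variation across genes
  or lineages (beyond what `correct_ks()` is tested against), tandem-array
  birth processes beyond a fixed count of tandem duplicates, and gene
  birth. Passing tests therefore validate the *inference machinery* under
  the generative assumptions the analysis itself makes; they do not
  certify behaviour on real genomes with segmental duplications,
  translocated singletons, or assembly artefacts.

# Numerical choices and problem sizes

Determinism: every stochastic entry point takes a seed; identical seed and
configuration give byte-identical outputs. EM restarts derive their seeds
from the caller's seed. kmeans initialization uses a single start per
restart so the restart loop explores genuinely different initializations.

The validation suite uses desk-scale problems chosen so each check has
clear statistical headroom: mixture recovery at 1500 block medians
(500 per component), geometric-parameter recovery at ≥5000 loss runs,
orthologous-ratio simulations at 3–5 chromosomes × 200–500 genes, NG86
oracle equivalence over all 3721 sense-codon pairs, and chain-oracle
equivalence at ≤60 pairs per chromosome pair where exhaustive search is
exact. Genome-scale runs (tens of thousands of collinear pairs) require real
assemblies and are out of scope here; the package reproduces the
*arithmetic* of the event calculus and dating exactly, and the
*structural* predictions (orthologous ratios, peak recovery, geometric
loss) on synthetic genomes with known truth.

# Known limitations

* The block chainer scores by anchor count only; no E-value-based block
  significance model is provided.
* Orthologous-ratio counting depends on declared window defaults; genomes
  with very uneven gene density along chromosomes may need a different
  `window_genes`.
* `infer_fusion_timing()` flags, but cannot resolve, junctions broken
  after the WGD; resolving them needs outgroup karyotypes.
* Proportional dating inherits every bias of its calibration interval and
  assumes rate constancy between the calibrated and dated events after
  peak alignment.
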