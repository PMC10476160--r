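# wgdtrace

Detecting, dating, and dissecting ancient whole-genome duplications (WGDs)
from gene order and coding sequence.

Many plant genomes are layered paleopolyploids: one or more rounds of
whole-genome duplication, followed by massive loss of the duplicated genes
("fractionation") and chromosome rearrangement, shaped the genome long
before any extant species diverged. `wgdtrace` is an R toolkit for the
comparative-genomics side of this problem — the analyses a genome paper
runs after assembly and annotation are done:

* **Collinear (synteny) block detection** — dynamic-programming chaining of
  homologous gene pairs in gene-order space, with an exhaustive-search
  oracle it provably matches at small scale.
* **NG86 Ka/Ks** — Nei–Gojobori counting with Jukes–Cantor correction
  (d = −¾·ln(1 − 4p/3)), multi-hit codons averaged over all minimal
  substitution paths, stop-blocked paths excluded.
* **Ks-peak dating** — Gaussian-mixture (EM) fitting of block-median Ks
  distributions; proportional rate correction by aligning a shared event's
  peak; linear dating t = (Ks_event / Ks_calib) · t_calib against the
  core-eudicot hexaploidy (ECH, ~115–130 Mya).
* **Orthologous ratios** — the modal number of matched chromosomal regions
  per window of the other genome (1:4 for an unduplicated outgroup vs a
  2-WGD genome; 4:2 for two WGDs vs one).
* **Fractionation** — gene-retention profiles against a reference genome
  and the geometric run-length model of consecutive gene loss
  N_k = N₁·p^(k−1), with both a log-linear regression and the closed-form
  MLE p̂ = Σ(kᵢ−1)/Σkᵢ, plus an extra-parameter F test of geometric
  adequacy.
* **Karyotype event calculus** — a telomere-centric engine for end-to-end
  joining (EEJ), nested chromosome fusion (NCF), crossover/reciprocal
  translocation (XO), inversion (IV), WGD and WGT over segment-labelled
  chromosomes, with satellite bookkeeping and copy-number–based inference
  of whether a fusion predates or postdates a WGD.
* **A genome-evolution simulator** with full ground truth (true pair Ks,
  event log, loss runs, ancestral identity) for validating all of the
  above; the simulation clock is Ks itself.

Everything takes and returns tibbles, pipes cleanly, and has
`tidy()`/`glance()`/`autoplot()` methods for the fitted objects. A thin
subcommand CLI (`exec/wgdtrace`, or `cli_main()` from R) covers the whole
pipeline for shell use.

## Worked example

Simulate one lineage that went through three polyploidy events at Ks 1.90,
0.66 and 0.30 (the oldest standing in for a hexaploidy-like divergence
layer), with geometric fractionation; then recover the events from the
simulated homology data alone:

```r
library(wgdtrace)

cfg <- sim_config(
  n_chromosomes = 2, genes_per_chromosome = 150,
  lineages = list(P = list(sim_event("WGD", 1.90), sim_event("WGD", 0.66),
                           sim_event("WGD", 0.30))),
  divergence_ks = 2, loss_extension_p = 0.28, loss_initiation_rate = 0.25,
  ks_noise_sd = 0.08, seed = 11)
sim <- simulate_genomes(cfg)
sim
#> <wgd_sim> 1 lineage(s): P (877 genes, 16 chromosomes)

blocks <- detect_blocks(sim$hits$P_vs_P, sim$tables$P) |>
  block_median_ks(setNames(sim$truth$true_pair_ks$ks_obs,
                           sim$truth$true_pair_ks$pair_id))
fit <- fit_ks_peaks(blocks$median_ks, k = 3, seed = 5)
tidy(fit)
#> # A tibble: 3 × 4
#>   component    mu   sigma weight
#>       <int> <dbl>   <dbl>  <dbl>
#> 1         1 0.289 0.00915  0.143
#> 2         2 0.659 0.0229   0.286
#> 3         3 1.90  0.0275   0.571
```

The three fitted peak means land on the planted event ages. Dating the two
younger events against the oldest peak with the ECH calibration:

```r
date_event(tidy(fit)$mu[1:2], ks_calib = tidy(fit)$mu[3],
           t_calib = c(115, 130), event = c("alpha", "beta"))
#> # A tibble: 2 × 7
#>   event ks_event ks_calib t_calib_low t_calib_high t_low t_high
#>   <chr>    <dbl>    <dbl>       <dbl>        <dbl> <dbl>  <dbl>
#> 1 alpha    0.289     1.90         115          130  17.5   19.8
#> 2 beta     0.659     1.90         115          130  39.9   45.1
```

so the younger WGD dates to ~18–20 Mya and the older to ~40–45 Mya under
this calibration. The fractionation module recovers the planted extension
parameter from the simulator's loss runs:

```r
runs <- simulate_genomes(sim_config(
  n_chromosomes = 5, genes_per_chromosome = 1000,
  lineages = list(B = list(sim_event("WGD", 0.5), sim_event("WGD", 0.25))),
  divergence_ks = 1, loss_extension_p = 0.28, loss_initiation_rate = 0.2,
  seed = 9))$truth$loss_runs$run_length
fit_geometric(dplyr::count(tibble::tibble(k = runs), k, name = "n_k"))
#> <geom_loss_fit> extension parameter p_hat = 0.308 (MLE 0.283); lack-of-fit F P-value = 0.14
#>   4309 runs; 0 segmental losses excluded
```

`autoplot(fit)` and `autoplot()` on the geometric fit draw the mixture
over the Ks histogram and the run-length decay; `plot_dotplot()` renders
ranked-hit dot plots in order-index space.

## Karyotype trajectories

```r
k <- karyotype(paste0("E", 1:7))        # 7 pre-hexaploidy chromosomes
n_chromosomes(apply_event(k, karyo_event("WGT")))
#> [1] 21
```

Event scripts are plain text (`EEJ chr1 chr2`, `NCF host=c2 donor=c5
pos=0.5`, `XO c1@0.4 c6@0.7`, `IV c4@0.2-0.6`, `WGD`, `WGT`);
`run_script()` applies them and logs the chromosome count per step, and
`infer_fusion_timing()` classifies each inter-ancestor junction of a
post-WGD karyotype as pre- or post-WGD from its copy number.

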