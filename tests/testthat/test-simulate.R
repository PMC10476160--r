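test_that("configs violating invariants are rejected before generation", {
  expect_error(sim_config(loss_extension_p = 1),
               class = "wgdtrace_validation_error")
  expect_error(sim_config(divergence_ks = -0.1),
               class = "wgdtrace_validation_error")
  expect_error(sim_config(lineages = list(list())),
               class = "wgdtrace_validation_error")
  # age stamps must be non-increasing toward the present
  expect_error(sim_config(lineages = list(
    A = list(sim_event("WGD", 0.3), sim_event("WGD", 0.66)))),
    class = "wgdtrace_validation_error")
  # polyploidy cannot predate speciation
  expect_error(sim_config(lineages = list(A = list(), B = list(sim_event("WGD", 2))),
                          divergence_ks = 1),
               class = "wgdtrace_validation_error")
})

test_that("zero events and zero divergence reproduce the ancestor", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 30,
                    lineages = list(A = list(), B = list()),
                    divergence_ks = 0, ks_noise_sd = 0, seed = 1)
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(sim$tables$A), 60)
  expect_equal(nrow(sim$tables$B), 60)
  strip <- function(tb) sub(":.*$", "", tb$gene_id)
  expect_equal(sort(strip(sim$tables$A)), sort(strip(sim$tables$B)))
  expect_true(all(sim$truth$true_pair_ks$ks_true == 0))
})

test_that("copy number is conserved under loss-free polyploidy", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 25,
                    lineages = list(
                      B = list(sim_event("WGD", 0.6), sim_event("WGD", 0.3))),
                    divergence_ks = 1, loss_initiation_rate = 0, seed = 2)
  sim <- simulate_genomes(cfg)
  copies <- table(sub(":.*$", "", sim$tables$B$gene_id))
  expect_true(all(copies == 4))

  cfg3 <- sim_config(n_chromosomes = 2, genes_per_chromosome = 25,
                     lineages = list(
                       B = list(sim_event("WGT", 0.6), sim_event("WGD", 0.3))),
                     divergence_ks = 1, loss_initiation_rate = 0, seed = 2)
  sim3 <- simulate_genomes(cfg3)
  expect_true(all(table(sub(":.*$", "", sim3$tables$B$gene_id)) == 6))
})

test_that("rearrangements never create or destroy genes", {
  cfg <- sim_config(n_chromosomes = 4, genes_per_chromosome = 40,
                    lineages = list(A = list(
                      sim_event("EEJ"), sim_event("NCF"), sim_event("XO"),
                      sim_event("IV"), sim_event("XO"))),
                    divergence_ks = 0.5, seed = 8)
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(sim$tables$A), 160)
  expect_equal(length(unique(sim$tables$A$chrom)), 2)  # 4 - EEJ - NCF
  expect_equal(sort(sub(":.*$", "", sim$tables$A$gene_id)),
               sort(sprintf("c%02dg%04d", rep(1:4, each = 40), rep(1:40, 4))))
})

test_that("true pair Ks reflects the event ages", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 40,
                    lineages = list(
                      A = list(),
                      B = list(sim_event("WGD", 0.66), sim_event("WGD", 0.30))),
                    divergence_ks = 1, loss_initiation_rate = 0,
                    ks_noise_sd = 0, seed = 5)
  sim <- simulate_genomes(cfg)
  tp <- sim$truth$true_pair_ks
  cross <- tp |> dplyr::filter(lineage_a != lineage_b)
  expect_true(all(cross$ks_true == 1))
  intra <- tp |> dplyr::filter(lineage_a == "B", lineage_b == "B")
  expect_setequal(unique(intra$ks_true), c(0.3, 0.66))
  # each ancestral gene: 4 copies -> 2 pairs at 0.30 (within first-WGD sides)
  # and 4 pairs at 0.66 (across them)
  per_gene <- intra |>
    dplyr::mutate(anc = sub(":.*$", "", gene_a)) |>
    dplyr::count(anc, ks_true)
  expect_true(all(per_gene$n[per_gene$ks_true == 0.3] == 2))
  expect_true(all(per_gene$n[per_gene$ks_true == 0.66] == 4))
})

test_that("best hits point to the closest surviving relative", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 50,
                    lineages = list(
                      B = list(sim_event("WGD", 0.66), sim_event("WGD", 0.30))),
                    divergence_ks = 1, loss_initiation_rate = 0, seed = 6)
  sim <- simulate_genomes(cfg)
  ranked <- rank_hits(sim$hits$B_vs_B)
  best <- ranked |> dplyr::filter(rank == "best")
  truth <- sim$truth$true_pair_ks
  min_ks <- setNames(rep(Inf, nrow(sim$tables$B)), sim$tables$B$gene_id)
  for (i in seq_len(nrow(truth))) {
    min_ks[truth$gene_a[i]] <- min(min_ks[truth$gene_a[i]], truth$ks_true[i])
    min_ks[truth$gene_b[i]] <- min(min_ks[truth$gene_b[i]], truth$ks_true[i])
  }
  got_ks <- purrr::map2_dbl(best$query_id, best$subject_id, function(q, s) {
    pid <- paste(sort(c(q, s)), collapse = "__")
    truth$ks_true[truth$pair_id == pid]
  })
  expect_equal(got_ks, unname(min_ks[best$query_id]))
})

test_that("loss runs recover the planted extension parameter", {
  cfg <- sim_config(n_chromosomes = 5, genes_per_chromosome = 1000,
                    lineages = list(B = list(sim_event("WGD", 0.5),
                                             sim_event("WGD", 0.25))),
                    divergence_ks = 1, loss_extension_p = 0.28,
                    loss_initiation_rate = 0.2, seed = 9)
  sim <- simulate_genomes(cfg)
  runs <- sim$truth$loss_runs$run_length
  expect_gte(length(runs), 3000)
  expect_lt(abs(oracle_geom_mle(runs) - 0.28), 0.03)
  # the module's own fit agrees with the closed-form oracle
  fit <- fit_geometric(dplyr::count(tibble::tibble(k = runs), k, name = "n_k"))
  expect_lt(abs(fit$p_mle - oracle_geom_mle(runs)), 1e-12)
  expect_lt(abs(fit$p_hat - 0.28), 0.05)
})

test_that("loss never removes the last surviving copy", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 100,
                    lineages = list(B = list(sim_event("WGD", 0.5),
                                             sim_event("WGD", 0.25))),
                    divergence_ks = 1, loss_extension_p = 0.5,
                    loss_initiation_rate = 0.9, seed = 10)
  sim <- simulate_genomes(cfg)
  copies <- table(sub(":.*$", "", sim$tables$B$gene_id))
  expect_equal(length(copies), 200)
  expect_true(all(copies >= 1))
})

test_that("identical seeds give identical output", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 60,
                    lineages = list(A = list(sim_event("WGD", 0.4),
                                             sim_event("XO")),
                                    B = list()),
                    divergence_ks = 0.8, seed = 123)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_equal(s1$tables, s2$tables)
  expect_equal(s1$hits, s2$hits)
  expect_equal(s1$truth, s2$truth)
  s3 <- simulate_genomes(cfg, seed = 124)
  expect_false(identical(s1$truth$true_pair_ks, s3$truth$true_pair_ks))
})

test_that("truth tables round-trip through TSV", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 30,
                    lineages = list(B = list(sim_event("WGD", 0.4))),
                    divergence_ks = 1, seed = 30)
  sim <- simulate_genomes(cfg)
  outdir <- tempfile()
  emit_truth_tables(sim$truth, outdir)
  expect_equal(nrow(wgdtrace:::read_tsv_hashed(file.path(outdir, "events.tsv"))),
               nrow(sim$truth$events))
  tp <- wgdtrace:::read_tsv_hashed(file.path(outdir, "true_pair_ks.tsv"))
  expect_equal(tp$pair_id, sim$truth$true_pair_ks$pair_id)
  expect_equal(tp$ks_true, sim$truth$true_pair_ks$ks_true, tolerance = 1e-12)
})

test_that("tandem duplicates land adjacent and carry the tandem age", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 50,
                    lineages = list(A = list()), divergence_ks = 0.5,
                    tandem_n = 5, tandem_ks = 0.05, ks_noise_sd = 0, seed = 15)
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(sim$tables$A), 55)
  tand <- grep("\\.t$", sim$tables$A$gene_id, value = TRUE)
  expect_length(tand, 5)
  for (g in tand) {
    parent <- sub("\\.t$", "", g)
    rows <- sim$tables$A |> dplyr::filter(gene_id %in% c(g, parent))
    expect_equal(diff(sort(rows$order_index)), 1L)
    pid <- paste(sort(c(g, parent)), collapse = "__")
    expect_equal(
      sim$truth$true_pair_ks$ks_true[sim$truth$true_pair_ks$pair_id == pid],
      0.05)
  }
})
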