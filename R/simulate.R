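#' Synthetic genome-evolution simulator
#'
#' Generates gene orders, homology hits, optional coding sequences and full
#' ground truth (events, true pair Ks, loss runs, ancestral identity) for
#' lineages descending from a shared ancestral gene order. Each lineage
#' applies an ordered event script: whole-genome duplications/triplications
#' (with a Ks-age stamp that becomes the true divergence of the copies),
#' chromosome rearrangements (end-to-end joining, nested fusion,
#' reciprocal-translocation crossover, inversion), and geometric segment-wise
#' gene loss after each polyploidy event. The simulation clock is Ks itself:
#' event ages are synonymous-distance stamps, translated to absolute time
#' only through a declared calibration downstream.
#'
#' @name simdata
NULL

#' Describe one simulated lineage event
#'
#' @param kind `"WGD"`, `"WGT"`, `"EEJ"`, `"NCF"`, `"XO"` or `"IV"`.
#' @param ks_age Ks-age stamp of the event (only meaningful for WGD/WGT,
#'   where it becomes the true Ks separating the copies; rearrangements may
#'   carry 0). Stamps must be non-increasing along a lineage script.
#' @param ... Optional operands (`chrom_a`, `chrom_b`, `host`, `donor`,
#'   `pos`, `chrom`, `from`, `to`); omitted operands are drawn from the
#'   seeded random stream.
#' @return A `sim_event` list.
#' @export
sim_event <- function(kind, ks_age = 0, ...) {
  kind <- toupper(kind)
  stopifnot(kind %in% c("WGD", "WGT", "EEJ", "NCF", "XO", "IV"))
  structure(c(list(kind = kind, ks_age = ks_age), list(...)),
            class = "sim_event")
}

#' Build a simulation configuration
#'
#' @param n_chromosomes,genes_per_chromosome Ancestral genome dimensions.
#' @param lineages Named list of lineage scripts; each script is a list of
#'   [sim_event()]s (possibly empty), ordered oldest first with
#'   non-increasing `ks_age`.
#' @param divergence_ks True synonymous distance between any two genes of
#'   different lineages (the speciation age on the Ks clock). Polyploidy
#'   events must not be older than this.
#' @param loss_extension_p Continuation probability of a fractionation loss
#'   run (the geometric extension parameter), in `[0, 1)`.
#' @param loss_initiation_rate Probability that a retained duplicate
#'   initiates a loss run on its homoeolog.
#' @param ks_noise_sd Standard deviation of the Gaussian noise added to the
#'   true Ks of each pair in table mode (truncated at 0).
#' @param sequence_mode `"table"` (observed Ks = true + noise) or
#'   `"sequence"` (codon sequences accrue Poisson synonymous substitutions
#'   so NG86 recovers the true Ks in expectation).
#' @param codons_per_gene Gene length in codons (sequence mode).
#' @param ka_ks Fixed nonsynonymous/synonymous rate ratio used in sequence
#'   mode.
#' @param tandem_n Number of tandem duplicates appended after all events
#'   (for duplicate-classification testing), each at Ks age `tandem_ks`.
#' @param tandem_ks Ks age stamp of tandem duplications.
#' @param seed Integer seed; identical seed and config give identical output.
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5, genes_per_chromosome = 200,
                       lineages = list(A = list(), B = list()),
                       divergence_ks = 1, loss_extension_p = 0.28,
                       loss_initiation_rate = 0.2, ks_noise_sd = 0.05,
                       sequence_mode = c("table", "sequence"),
                       codons_per_gene = 150, ka_ks = 0.3,
                       tandem_n = 0, tandem_ks = 0.05, seed = 1) {
  sequence_mode <- match.arg(sequence_mode)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              lineages = lineages, divergence_ks = divergence_ks,
              loss_extension_p = loss_extension_p,
              loss_initiation_rate = loss_initiation_rate,
              ks_noise_sd = ks_noise_sd, sequence_mode = sequence_mode,
              codons_per_gene = as.integer(codons_per_gene), ka_ks = ka_ks,
              tandem_n = as.integer(tandem_n), tandem_ks = tandem_ks,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1 || cfg$genes_per_chromosome < 1) {
    abort("genome dimensions must be positive", class = "wgdtrace_validation_error")
  }
  if (!(cfg$loss_extension_p >= 0 && cfg$loss_extension_p < 1)) {
    abort("loss_extension_p must lie in [0, 1)", class = "wgdtrace_validation_error")
  }
  if (cfg$loss_initiation_rate < 0 || cfg$loss_initiation_rate > 1) {
    abort("loss_initiation_rate must lie in [0, 1]", class = "wgdtrace_validation_error")
  }
  if (cfg$divergence_ks < 0) {
    abort("divergence_ks must be non-negative", class = "wgdtrace_validation_error")
  }
  if (is.null(names(cfg$lineages)) || any(!nzchar(names(cfg$lineages)))) {
    abort("lineages must be a named list", class = "wgdtrace_validation_error")
  }
  for (nm in names(cfg$lineages)) {
    ages <- vapply(cfg$lineages[[nm]], function(e) e$ks_age, double(1))
    if (length(ages) > 1 && any(diff(ages) > 1e-12)) {
      abort(paste0("lineage ", nm,
                   ": event ks_age stamps must be non-increasing toward the present"),
            class = "wgdtrace_validation_error")
    }
    kinds <- vapply(cfg$lineages[[nm]], function(e) e$kind, character(1))
    if (length(cfg$lineages) > 1 &&
        any(ages[kinds %in% c("WGD", "WGT")] > cfg$divergence_ks + 1e-12)) {
      abort(paste0("lineage ", nm,
                   ": polyploidy events cannot predate lineage divergence"),
            class = "wgdtrace_validation_error")
    }
  }
  invisible(cfg)
}

# ---- simulation core -------------------------------------------------------

# a lineage genome is a list of chromosomes; each chromosome is a tibble
# (anc_gene, anc_chrom, path, strand) ordered along the chromosome

ancestral_genome <- function(cfg, lineage) {
  chroms <- list()
  for (c_i in seq_len(cfg$n_chromosomes)) {
    nm <- sprintf("chr%02d", c_i)
    chroms[[paste0(lineage, "_", nm)]] <- tibble(
      anc_gene = sprintf("c%02dg%04d", c_i, seq_len(cfg$genes_per_chromosome)),
      anc_chrom = nm,
      path = lineage,
      strand = sample(c(1L, -1L), cfg$genes_per_chromosome, replace = TRUE))
  }
  chroms
}

pick_chroms <- function(genome, n) {
  nm <- names(genome)
  if (length(nm) < n) {
    abort("not enough chromosomes for rearrangement event",
          class = "wgdtrace_validation_error")
  }
  sample(nm, n)
}

sim_apply_rearrangement <- function(genome, ev) {
  kind <- ev$kind
  if (kind == "EEJ") {
    ops <- c(ev$chrom_a, ev$chrom_b)
    if (length(ops) < 2) ops <- pick_chroms(genome, 2)
    genome[[ops[1]]] <- bind_rows(genome[[ops[1]]], genome[[ops[2]]])
    genome[[ops[2]]] <- NULL
  } else if (kind == "NCF") {
    ops <- c(ev$host, ev$donor)
    if (length(ops) < 2) ops <- pick_chroms(genome, 2)
    host <- genome[[ops[1]]]
    cut <- max(1L, min(nrow(host) - 1L, as.integer(round(nrow(host) *
      (if (is.null(ev$pos)) 0.5 else ev$pos)))))
    genome[[ops[1]]] <- bind_rows(
      host[seq_len(cut), ], genome[[ops[2]]],
      host[seq(cut + 1L, length.out = nrow(host) - cut), ])
    genome[[ops[2]]] <- NULL
  } else if (kind == "XO") {
    ops <- c(ev$chrom_a, ev$chrom_b)
    if (length(ops) < 2) ops <- pick_chroms(genome, 2)
    a <- genome[[ops[1]]]
    b <- genome[[ops[2]]]
    cut_a <- if (is.null(ev$pos_a)) sample(nrow(a) - 1L, 1) else
      max(1L, min(nrow(a) - 1L, as.integer(round(ev$pos_a * nrow(a)))))
    cut_b <- if (is.null(ev$pos_b)) sample(nrow(b) - 1L, 1) else
      max(1L, min(nrow(b) - 1L, as.integer(round(ev$pos_b * nrow(b)))))
    genome[[ops[1]]] <- bind_rows(a[seq_len(cut_a), ],
                                  b[seq(cut_b + 1L, nrow(b)), ])
    genome[[ops[2]]] <- bind_rows(b[seq_len(cut_b), ],
                                  a[seq(cut_a + 1L, nrow(a)), ])
  } else if (kind == "IV") {
    op <- ev$chrom
    if (is.null(op)) op <- pick_chroms(genome, 1)
    segs <- genome[[op]]
    n <- nrow(segs)
    if (n >= 2) {
      ends <- sort(sample(n, 2))
      span <- seq(ends[1], ends[2])
      inverted <- segs[rev(span), ] |> mutate(strand = -.data$strand)
      genome[[op]][span, ] <- inverted
    }
  }
  genome
}

# geometric fractionation between one ordered pair of homoeologous copies;
# returns list(keep_tgt, runs) -- run lengths actually deleted
fractionate_direction <- function(keep_src, keep_tgt, tgt_genes, counts,
                                  init_rate, ext_p) {
  runs <- integer(0)
  n <- length(keep_tgt)
  for (i in seq_len(n)) {
    if (!keep_src[i]) next
    if (runif(1) >= init_rate) next
    j <- i
    deleted <- 0L
    repeat {
      # next deletable target at or after j (skip absent / last-copy genes)
      while (j <= n && (!keep_tgt[j] || counts[[tgt_genes[j]]] < 2L)) {
        j <- j + 1L
      }
      if (j > n) break
      keep_tgt[j] <- FALSE
      counts[[tgt_genes[j]]] <- counts[[tgt_genes[j]]] - 1L
      deleted <- deleted + 1L
      j <- j + 1L
      if (runif(1) >= ext_p) break
    }
    if (deleted > 0L) runs <- c(runs, deleted)
  }
  list(keep_tgt = keep_tgt, counts = counts, runs = runs)
}

sim_apply_polyploidy <- function(genome, ploidy, cfg, counts) {
  suffixes <- letters[seq_len(ploidy)]
  new_genome <- list()
  copy_sets <- list()
  for (nm in names(genome)) {
    copies <- character(ploidy)
    for (s_i in seq_along(suffixes)) {
      cp <- genome[[nm]] |>
        mutate(path = paste0(.data$path, ".", suffixes[s_i]))
      nm2 <- paste0(nm, suffixes[s_i])
      new_genome[[nm2]] <- cp
      copies[s_i] <- nm2
    }
    copy_sets[[nm]] <- copies
  }
  # update copy counts: every gene multiplied by ploidy
  for (nm in names(genome)) {
    for (g in genome[[nm]]$anc_gene) {
      counts[[g]] <- counts[[g]] + (ploidy - 1L) * 1L
    }
  }
  # geometric loss between every ordered pair of copies
  all_runs <- integer(0)
  if (cfg$loss_initiation_rate > 0) {
    for (nm in names(copy_sets)) {
      copies <- copy_sets[[nm]]
      keep <- lapply(copies, function(cp) rep(TRUE, nrow(new_genome[[cp]])))
      names(keep) <- copies
      genes <- new_genome[[copies[1]]]$anc_gene
      for (src in copies) {
        for (tgt in setdiff(copies, src)) {
          res <- fractionate_direction(keep[[src]], keep[[tgt]], genes,
                                       counts, cfg$loss_initiation_rate,
                                       cfg$loss_extension_p)
          keep[[tgt]] <- res$keep_tgt
          counts <- res$counts
          all_runs <- c(all_runs, res$runs)
        }
      }
      for (cp in copies) {
        new_genome[[cp]] <- new_genome[[cp]][keep[[cp]], , drop = FALSE]
      }
    }
  }
  list(genome = new_genome, counts = counts, runs = all_runs)
}

#' Run the genome-evolution simulation
#'
#' @param cfg A [sim_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return A `wgd_sim` object: list with `tables` (one gene table per
#'   lineage), `hits` (named list of hit tibbles, `"A_vs_B"` with queries
#'   from the first-named lineage, plus `"A_vs_A"`-style intra-genome
#'   tables), `cds` (named character vector, sequence mode only), `truth`
#'   (list: `events`, `true_pair_ks`, `loss_runs`, `ancestral_identity`)
#'   and `config`.
#' @export
simulate_genomes <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))
  lineage_names <- names(cfg$lineages)
  genomes <- list()
  dup_ages <- list()     # ks ages of WGD/WGT events per lineage, in order
  loss_runs <- list()
  events_log <- list()
  for (ln in lineage_names) {
    genome <- ancestral_genome(cfg, ln)
    counts <- new.env(parent = emptyenv())
    for (nm in names(genome)) {
      for (g in genome[[nm]]$anc_gene) counts[[g]] <- 1L
    }
    ages <- double(0)
    for (step in seq_along(cfg$lineages[[ln]])) {
      ev <- cfg$lineages[[ln]][[step]]
      if (ev$kind %in% c("WGD", "WGT")) {
        ploidy <- if (ev$kind == "WGD") 2L else 3L
        res <- sim_apply_polyploidy(genome, ploidy, cfg, counts)
        genome <- res$genome
        counts <- res$counts
        ages <- c(ages, ev$ks_age)
        if (length(res$runs) > 0) {
          loss_runs[[length(loss_runs) + 1L]] <- tibble(
            lineage = ln, event_index = length(ages), run_length = res$runs)
        }
      } else {
        genome <- sim_apply_rearrangement(genome, ev)
      }
      events_log[[length(events_log) + 1L]] <- tibble(
        lineage = ln, step = step, kind = ev$kind, ks_age = ev$ks_age,
        n_chromosomes = length(genome))
    }
    # optional tandem duplicates (appended after all events)
    if (cfg$tandem_n > 0) {
      genome <- add_tandem_duplicates(genome, cfg$tandem_n)
    }
    genomes[[ln]] <- genome
    dup_ages[[ln]] <- ages
  }
  tables <- purrr::imap(genomes, genome_to_table)
  truth_pairs <- build_true_pairs(genomes, tables, dup_ages, cfg)
  hits <- build_hits(truth_pairs, lineage_names)
  cds <- NULL
  if (cfg$sequence_mode == "sequence") {
    cds <- build_cds(genomes, dup_ages, cfg)
  }
  anc_identity <- purrr::imap(tables, function(tb, ln) {
    ids <- strsplit(tb$gene_id, ":", fixed = TRUE)
    tibble(gene_id = tb$gene_id, lineage = ln,
           anc_gene = vapply(ids, `[`, character(1), 1),
           anc_chrom = substr(vapply(ids, `[`, character(1), 1), 1, 3))
  }) |> bind_rows()
  truth <- list(
    events = bind_rows(events_log),
    true_pair_ks = truth_pairs,
    loss_runs = if (length(loss_runs)) bind_rows(loss_runs) else
      tibble(lineage = character(), event_index = integer(),
             run_length = integer()),
    ancestral_identity = anc_identity)
  structure(list(tables = tables, hits = hits, cds = cds, truth = truth,
                 config = cfg),
            class = "wgd_sim")
}

#' @export
print.wgd_sim <- function(x, ...) {
  cat("<wgd_sim>", length(x$tables), "lineage(s):",
      paste(sprintf("%s (%d genes, %d chromosomes)", names(x$tables),
                    vapply(x$tables, nrow, integer(1)),
                    vapply(x$tables, \(t) length(unique(t$chrom)), integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

add_tandem_duplicates <- function(genome, n_tandem) {
  all_pos <- purrr::imap(genome, function(ch, nm) {
    tibble(chrom = nm, row = seq_len(nrow(ch)))
  }) |> bind_rows()
  picks <- all_pos[sample(nrow(all_pos), min(n_tandem, nrow(all_pos))), ]
  # insert from the bottom so row indices stay valid
  picks <- picks |> arrange(.data$chrom, desc(.data$row))
  for (i in seq_len(nrow(picks))) {
    ch <- picks$chrom[i]
    r <- picks$row[i]
    seg <- genome[[ch]]
    dup <- seg[r, ] |> mutate(path = paste0(.data$path, ".t"))
    genome[[ch]] <- bind_rows(seg[seq_len(r), ], dup,
                              seg[seq(r + 1L, length.out = nrow(seg) - r), ])
  }
  genome
}

genome_to_table <- function(genome, lineage) {
  purrr::imap(genome, function(ch, nm) {
    n <- nrow(ch)
    tibble(gene_id = paste0(ch$anc_gene, ":", ch$path),
           chrom = nm,
           start = (seq_len(n) - 1L) * 2000L,
           end = (seq_len(n) - 1L) * 2000L + 1500L,
           strand = ch$strand)
  }) |> bind_rows() |> build_gene_table()
}

# true Ks between two copies of the same ancestral gene: the age stamp of
# the event at which their copy paths first diverge
path_divergence_ks <- function(path_a, path_b, ages, tandem_ks, divergence_ks) {
  pa <- strsplit(path_a, ".", fixed = TRUE)[[1]]
  pb <- strsplit(path_b, ".", fixed = TRUE)[[1]]
  if (pa[1] != pb[1]) return(divergence_ks)
  m <- min(length(pa), length(pb))
  for (i in seq_len(m)[-1]) {
    if (pa[i] != pb[i]) {
      return(if (pa[i] == "t" || pb[i] == "t") tandem_ks else ages[i - 1L])
    }
  }
  tandem_ks  # identical prefix: one is a tandem copy of the other
}

build_true_pairs <- function(genomes, tables, dup_ages, cfg) {
  per_lineage <- purrr::imap(tables, function(tb, ln) {
    ids <- strsplit(tb$gene_id, ":", fixed = TRUE)
    tibble(gene_id = tb$gene_id, lineage = ln,
           anc_gene = vapply(ids, `[`, character(1), 1),
           path = vapply(ids, `[`, character(1), 2))
  })
  all_genes <- bind_rows(per_lineage)
  pairs <- all_genes |>
    inner_join(all_genes, by = "anc_gene", suffix = c("_a", "_b"),
               relationship = "many-to-many") |>
    filter(.data$gene_id_a < .data$gene_id_b)
  if (nrow(pairs) == 0) {
    return(tibble(pair_id = character(), gene_a = character(),
                  gene_b = character(), lineage_a = character(),
                  lineage_b = character(), ks_true = double(),
                  ks_obs = double()))
  }
  ks_true <- purrr::pmap_dbl(
    list(pairs$path_a, pairs$path_b, pairs$lineage_a, pairs$lineage_b),
    function(pa, pb, la, lb) {
      if (la != lb) return(cfg$divergence_ks)
      path_divergence_ks(pa, pb, dup_ages[[la]], cfg$tandem_ks,
                         cfg$divergence_ks)
    })
  ks_obs <- pmax(0, ks_true + rnorm(length(ks_true), 0, cfg$ks_noise_sd))
  tibble(pair_id = paste(pairs$gene_id_a, pairs$gene_id_b, sep = "__"),
         gene_a = pairs$gene_id_a, gene_b = pairs$gene_id_b,
         lineage_a = pairs$lineage_a, lineage_b = pairs$lineage_b,
         ks_true = ks_true, ks_obs = ks_obs)
}

# bitscore decreases monotonically with true Ks so the closest relative is
# always the best hit; ties (identical Ks) fall to the lexicographic
# subject-id tie-break downstream
sim_hit_rows <- function(query, subject, ks_true) {
  bitscore <- 500 * exp(-ks_true)
  tibble(query_id = query, subject_id = subject,
         identity_pct = round(100 * exp(-0.15 * ks_true), 2),
         align_len = 300L,
         evalue = pmax(10^(-bitscore / 5), 1e-180),
         bitscore = round(bitscore, 1))
}

build_hits <- function(truth_pairs, lineage_names) {
  hits <- list()
  for (i in seq_along(lineage_names)) {
    for (j in seq(i, length(lineage_names))) {
      la <- lineage_names[i]
      lb <- lineage_names[j]
      sub <- truth_pairs |>
        filter((.data$lineage_a == la & .data$lineage_b == lb) |
                 (.data$lineage_a == lb & .data$lineage_b == la))
      if (nrow(sub) == 0) next
      nm <- paste0(la, "_vs_", lb)
      if (la == lb) {
        hits[[nm]] <- bind_rows(
          sim_hit_rows(sub$gene_a, sub$gene_b, sub$ks_true),
          sim_hit_rows(sub$gene_b, sub$gene_a, sub$ks_true))
      } else {
        a_first <- sub$lineage_a == la
        q <- ifelse(a_first, sub$gene_a, sub$gene_b)
        s <- ifelse(a_first, sub$gene_b, sub$gene_a)
        hits[[nm]] <- sim_hit_rows(q, s, sub$ks_true)
      }
    }
  }
  hits
}

#' Write ground-truth tables for a simulation
#'
#' Emits `true_pair_ks.tsv`, `events.tsv`, `loss_runs.tsv` and
#' `ancestral_identity.tsv` under `outdir`.
#'
#' @param truth The `truth` element of a [simulate_genomes()] result.
#' @param outdir Output directory (created if absent).
#' @return The output paths, invisibly.
#' @export
emit_truth_tables <- function(truth, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    file.path(outdir, "true_pair_ks.tsv"),
    file.path(outdir, "events.tsv"),
    file.path(outdir, "loss_runs.tsv"),
    file.path(outdir, "ancestral_identity.tsv"))
  write_tsv_hashed(truth$true_pair_ks, paths[1])
  write_tsv_hashed(truth$events, paths[2])
  write_tsv_hashed(truth$loss_runs, paths[3])
  write_tsv_hashed(truth$ancestral_identity, paths[4])
  invisible(paths)
}

# ---- sequence mode ---------------------------------------------------------

.syn_change_cache <- new.env(parent = emptyenv())

syn_change_tables <- function() {
  if (!is.null(.syn_change_cache$tables)) return(.syn_change_cache$tables)
  codons <- names(.GENCODE)[.GENCODE != "*"]
  syn <- list()
  nonsyn <- list()
  for (cd in codons) {
    aa <- .GENCODE[[cd]]
    s_pos <- integer(0); s_tgt <- character(0)
    n_pos <- integer(0); n_tgt <- character(0)
    for (pos in 1:3) {
      for (nb in codon_neighbours(cd, pos)) {
        if (.GENCODE[[nb]] == "*") next  # stops excluded from the alphabet
        if (.GENCODE[[nb]] == aa) {
          s_pos <- c(s_pos, pos); s_tgt <- c(s_tgt, nb)
        } else {
          n_pos <- c(n_pos, pos); n_tgt <- c(n_tgt, nb)
        }
      }
    }
    syn[[cd]] <- s_tgt
    nonsyn[[cd]] <- n_tgt
  }
  .syn_change_cache$tables <- list(syn = syn, nonsyn = nonsyn)
  .syn_change_cache$tables
}

random_cds <- function(n_codons) {
  codons <- names(.GENCODE)[.GENCODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# evolve a codon vector over branch length d (Ks units): synonymous events
# Poisson(d * S) placed uniformly over synonymous one-step changes,
# nonsynonymous events Poisson(d * ka_ks * N) likewise
evolve_codons <- function(cod, d, ka_ks) {
  if (d <= 0) return(cod)
  tabs <- syn_change_tables()
  syn_sites <- ng_syn_sites()
  S <- sum(syn_sites[cod])
  N <- 3 * length(cod) - S
  n_syn <- rpois(1, d * S)
  n_non <- rpois(1, d * ka_ks * N)
  for (k in seq_len(n_syn)) {
    weights <- lengths(tabs$syn[cod])
    i <- sample.int(length(cod), 1, prob = weights)
    opts <- tabs$syn[[cod[i]]]
    cod[i] <- opts[sample.int(length(opts), 1)]
  }
  for (k in seq_len(n_non)) {
    weights <- lengths(tabs$nonsyn[cod])
    i <- sample.int(length(cod), 1, prob = weights)
    opts <- tabs$nonsyn[[cod[i]]]
    cod[i] <- opts[sample.int(length(opts), 1)]
  }
  cod
}

split_codons <- function(seq) {
  starts <- seq(1, nchar(seq), by = 3)
  substring(seq, starts, starts + 2)
}

build_cds <- function(genomes, dup_ages, cfg) {
  lineage_names <- names(genomes)
  root_depth <- cfg$divergence_ks / 2
  anc_genes <- unique(unlist(lapply(genomes, function(g) {
    unlist(lapply(g, function(ch) ch$anc_gene))
  })))
  out <- character(0)
  survivors <- lapply(genomes, function(g) {
    bind_rows(g)[, c("anc_gene", "path")]
  })
  for (ag in sort(anc_genes)) {
    anc_cod <- split_codons(random_cds(cfg$codons_per_gene))
    for (ln in lineage_names) {
      leaves <- evolve_gene_tree_multi(anc_cod, ln, dup_ages[[ln]],
                                       root_depth, cfg)
      keep <- survivors[[ln]] |> filter(.data$anc_gene == ag)
      for (r in seq_len(nrow(keep))) {
        nm <- paste0(ag, ":", keep$path[r])
        if (!is.null(leaves[[keep$path[r]]])) {
          out[nm] <- leaves[[keep$path[r]]]
        }
      }
    }
  }
  out
}

# general n-ary version keyed by the stored copy paths (handles WGT and the
# no-duplication case); tandem copies reuse the parent sequence evolved an
# extra tandem_ks
evolve_gene_tree_multi <- function(anc_cod, lineage, ages, root_depth, cfg) {
  depths <- ages / 2
  ka_ks <- cfg$ka_ks
  kinds <- vapply(cfg$lineages[[lineage]], function(e) e$kind, character(1))
  ploidies <- ifelse(kinds[kinds %in% c("WGD", "WGT")] == "WGD", 2L, 3L)
  recurse <- function(cod, depth, level, path) {
    if (level > length(depths)) {
      leaf <- evolve_codons(cod, depth, ka_ks)
      return(setNames(list(paste(leaf, collapse = "")), path))
    }
    cod2 <- evolve_codons(cod, depth - depths[level], ka_ks)
    out <- list()
    for (s in letters[seq_len(ploidies[level])]) {
      out <- c(out, recurse(cod2, depths[level], level + 1L,
                            if (nzchar(path)) paste0(path, ".", s) else s))
    }
    out
  }
  base <- recurse(anc_cod, root_depth, 1L, "")
  names(base) <- ifelse(nzchar(names(base)),
                        paste0(lineage, ".", names(base)), lineage)
  # tandem copies: evolve an extra branch from the parent leaf
  td <- cfg$tandem_ks
  extra <- list()
  for (nm in names(base)) {
    extra[[paste0(nm, ".t")]] <- paste(
      evolve_codons(split_codons(base[[nm]]), td, ka_ks), collapse = "")
  }
  c(base, extra)
}
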