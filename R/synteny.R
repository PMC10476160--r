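#' Collinear block detection by dynamic-programming chaining
#'
#' Homologous gene pairs are plotted in (query order_index, subject
#' order_index) space per chromosome pair, and maximal chains of pairs that
#' are strictly monotone on both axes (ascending for orientation +1,
#' descending subject for -1) with at most `max_gap` skipped genes between
#' consecutive anchors are extracted greedily by descending pair count.
#' Chain score is the number of pairs (no gap penalty); ties between
#' equal-score chains are broken by the smallest starting query index. Each
#' pair may belong to at most one block.
#'
#' @name synteny-blocks
NULL

empty_blocks <- function() {
  tibble(block_id = character(), chrom_a = character(), chrom_b = character(),
         orientation = integer(), n_pairs = integer(),
         pairs = list(), median_ks = double())
}

#' Detect collinear blocks between two gene tables
#'
#' @param hits Hit tibble (from [read_hits()] or [rank_hits()]) with
#'   `query_id` referring to genes of `table_a` and `subject_id` to genes of
#'   `table_b`.
#' @param table_a,table_b Gene tables (see [read_gene_table()]). Pass
#'   `table_b = NULL` for an intra-genome comparison: self-pairs are dropped
#'   and each unordered gene pair is used once.
#' @param min_pairs Minimum anchors per reported block (default 5).
#' @param max_gap Maximum number of skipped genes between consecutive
#'   anchors on either axis (default 25, order-index units).
#' @return Tibble with one row per block: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_pairs`, `median_ks` (`NA` until
#'   [block_median_ks()]), and list-column `pairs` (tibbles with `gene_a`,
#'   `gene_b`, `idx_a`, `idx_b`, `pair_id`, ordered along the chain).
#' @export
detect_blocks <- function(hits, table_a, table_b = NULL, min_pairs = 5,
                          max_gap = 25) {
  intra <- is.null(table_b)
  if (intra) table_b <- table_a
  if (nrow(hits) == 0) return(empty_blocks())
  missing_ids <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                         c(table_a$gene_id, table_b$gene_id))
  if (!intra) {
    missing_ids <- unique(c(setdiff(hits$query_id, table_a$gene_id),
                            setdiff(hits$subject_id, table_b$gene_id)))
  }
  if (length(missing_ids) > 0) {
    abort(paste0("hit gene ids absent from gene tables: ",
                 paste(head(missing_ids, 10), collapse = ", "),
                 if (length(missing_ids) > 10) " ..."),
          class = "wgdtrace_validation_error")
  }
  a_idx <- table_a |> select(query_id = "gene_id", chrom_a = "chrom",
                             idx_a = "order_index")
  b_idx <- table_b |> select(subject_id = "gene_id", chrom_b = "chrom",
                             idx_b = "order_index")
  pairs <- hits |>
    distinct(.data$query_id, .data$subject_id) |>
    inner_join(a_idx, by = "query_id") |>
    inner_join(b_idx, by = "subject_id") |>
    mutate(pair_id = paste(.data$query_id, .data$subject_id, sep = "__"))
  if (intra) {
    pairs <- pairs |>
      filter(.data$query_id != .data$subject_id) |>
      filter(.data$chrom_a < .data$chrom_b |
               (.data$chrom_a == .data$chrom_b & .data$idx_a < .data$idx_b)) |>
      mutate(pair_id = ifelse(.data$query_id < .data$subject_id,
                              paste(.data$query_id, .data$subject_id, sep = "__"),
                              paste(.data$subject_id, .data$query_id, sep = "__"))) |>
      distinct(.data$pair_id, .keep_all = TRUE)
  }
  if (nrow(pairs) == 0) return(empty_blocks())
  groups <- pairs |>
    arrange(.data$chrom_a, .data$chrom_b, .data$idx_a, .data$idx_b) |>
    (\(d) split(d, paste(d$chrom_a, d$chrom_b, sep = "\r")))()
  blocks <- purrr::map(groups, chain_group, min_pairs = min_pairs,
                       max_gap = max_gap) |>
    purrr::discard(is.null) |>
    bind_rows()
  if (nrow(blocks) == 0) return(empty_blocks())
  blocks |>
    arrange(desc(.data$n_pairs), .data$chrom_a, .data$chrom_b,
            purrr::map_int(.data$pairs, \(p) p$idx_a[1])) |>
    mutate(block_id = sprintf("blk%04d", row_number()), median_ks = NA_real_) |>
    select("block_id", "chrom_a", "chrom_b", "orientation", "n_pairs",
           "median_ks", "pairs")
}

# greedy chain extraction for one chromosome pair
chain_group <- function(g, min_pairs, max_gap) {
  out <- list()
  repeat {
    if (nrow(g) < min_pairs) break
    cand <- list(best_chain(g, +1L, max_gap), best_chain(g, -1L, max_gap))
    lens <- vapply(cand, function(x) if (is.null(x)) 0L else length(x), integer(1))
    if (max(lens) < min_pairs) break
    pick <- if (lens[1] >= lens[2]) 1L else 2L
    chain_rows <- g[cand[[pick]], , drop = FALSE]
    out[[length(out) + 1L]] <- tibble(
      chrom_a = chain_rows$chrom_a[1], chrom_b = chain_rows$chrom_b[1],
      orientation = if (pick == 1L) 1L else -1L,
      n_pairs = nrow(chain_rows),
      pairs = list(chain_rows |>
                     select(gene_a = "query_id", gene_b = "subject_id",
                            "idx_a", "idx_b", "pair_id")))
    g <- g[-cand[[pick]], , drop = FALSE]
  }
  if (length(out) == 0) NULL else bind_rows(out)
}

# longest monotone chain with gap constraint; returns row indices into g
# (ordered along the chain) or NULL
best_chain <- function(g, dir, max_gap) {
  n <- nrow(g)
  if (n == 0) return(NULL)
  # sort so that any valid predecessor comes earlier
  ord <- order(g$idx_a, if (dir == 1L) g$idx_b else -g$idx_b)
  ia <- g$idx_a[ord]
  ib <- g$idx_b[ord]
  dp <- rep(1L, n)
  parent <- rep(NA_integer_, n)
  step <- max_gap + 1L
  for (j in seq_len(n)) {
    if (dir == 1L) {
      ok <- ia < ia[j] & ia >= ia[j] - step & ib < ib[j] & ib >= ib[j] - step
    } else {
      ok <- ia < ia[j] & ia >= ia[j] - step & ib > ib[j] & ib <= ib[j] + step
    }
    ok <- which(ok[seq_len(j - 1L)])
    if (length(ok) > 0) {
      best <- max(dp[ok])
      cands <- ok[dp[ok] == best]
      parent[j] <- cands[1]  # smallest idx_a among equal-score predecessors
      dp[j] <- best + 1L
    }
  }
  ends <- which(dp == max(dp))
  # tie-break: chain whose starting anchor has the smallest query index
  starts <- vapply(ends, function(e) {
    while (!is.na(parent[e])) e <- parent[e]
    ia[e]
  }, double(1))
  end <- ends[which.min(starts)]
  chain <- integer(0)
  while (!is.na(end)) {
    chain <- c(end, chain)
    end <- parent[end]
  }
  ord[chain]
}

#' Attach the median pair Ks to each block
#'
#' A block's median Ks is the median over its anchors' Ks values; anchors
#' without a Ks value are ignored. Blocks where fewer than half of the
#' anchors have a Ks value keep `median_ks = NA` and are flagged.
#'
#' @param blocks Block tibble from [detect_blocks()].
#' @param ks_table Mapping `pair_id` to Ks: either a tibble with columns
#'   `pair_id` and `Ks` (for example from [pairwise_ks_table()]) or a named
#'   numeric vector.
#' @return `blocks` with `median_ks`, `ks_n` (anchors with Ks) and logical
#'   `ks_flagged` filled in.
#' @export
block_median_ks <- function(blocks, ks_table) {
  ks <- if (is_tibble(ks_table) || is.data.frame(ks_table)) {
    setNames(ks_table$Ks, ks_table$pair_id)
  } else {
    ks_table
  }
  stats <- purrr::map(blocks$pairs, function(p) {
    vals <- unname(ks[p$pair_id])
    vals <- vals[!is.na(vals)]
    tibble(ks_n = length(vals),
           med = if (length(vals) > 0) median(vals) else NA_real_)
  }) |> bind_rows()
  blocks |>
    mutate(ks_n = stats$ks_n,
           ks_flagged = stats$ks_n < .data$n_pairs / 2,
           median_ks = ifelse(.data$ks_flagged, NA_real_, stats$med))
}

#' Classify duplicate genes by mechanism
#'
#' Priority classification of every gene of a genome from its intra-genome
#' homology structure: a gene anchored in any intra-genome collinear block is
#' `wgd`; otherwise a hit to a gene on the same chromosome within
#' `tandem_max_gap` order indices makes it `tandem`; within 20 indices,
#' `proximal`; any remaining hit, `dispersed`; no hits, `singleton`.
#'
#' @param blocks Intra-genome block tibble from [detect_blocks()].
#' @param hits Intra-genome hit tibble.
#' @param table The genome's gene table.
#' @param tandem_max_gap Maximum order-index distance for tandem calls
#'   (default 5).
#' @return Tibble `gene_id`, `dup_type`.
#' @export
classify_duplicates <- function(blocks, hits, table, tandem_max_gap = 5) {
  proximal_gap <- 20L
  wgd_genes <- unique(unlist(purrr::map(blocks$pairs,
                                        \(p) c(p$gene_a, p$gene_b))))
  idx <- table |> select("gene_id", "chrom", "order_index")
  h <- hits |>
    filter(.data$query_id != .data$subject_id) |>
    distinct(.data$query_id, .data$subject_id)
  h <- bind_rows(h, h |> rename(query_id = "subject_id",
                                subject_id = "query_id")) |>
    distinct()
  h <- h |>
    inner_join(idx, by = c(query_id = "gene_id")) |>
    inner_join(idx, by = c(subject_id = "gene_id"),
               suffix = c("_q", "_s")) |>
    mutate(same_chrom = .data$chrom_q == .data$chrom_s,
           gap = abs(.data$order_index_q - .data$order_index_s))
  per_gene <- h |>
    group_by(gene_id = .data$query_id) |>
    summarise(tandem = any(.data$same_chrom & .data$gap <= tandem_max_gap),
              proximal = any(.data$same_chrom & .data$gap <= proximal_gap),
              .groups = "drop")
  table |>
    select("gene_id") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(
      has_hit = !is.na(.data$tandem),
      dup_type = dplyr::case_when(
        .data$gene_id %in% wgd_genes ~ "wgd",
        .data$has_hit & .data$tandem ~ "tandem",
        .data$has_hit & .data$proximal ~ "proximal",
        .data$has_hit ~ "dispersed",
        TRUE ~ "singleton")) |>
    select("gene_id", "dup_type")
}
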