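#' Hit ranking and orthologous-ratio estimation
#'
#' Dot plots of homologous genes are drawn in order-index space with hits
#' coloured by rank (best / second-best / other per query, as in published
#' WGD dot plots). The orthologous ratio between two genomes — the modal
#' number of matched chromosomal regions in one genome per region of the
#' other — reflects their relative polyploidy level (1:4 for an unduplicated
#' outgroup against a twice-duplicated genome, and so on).
#'
#' @name dotplot-ratio
NULL

#' Rank hits per query gene
#'
#' For every query, hits are sorted by descending bitscore (ties broken by
#' ascending E-value, then lexicographic subject id); the first is `best`,
#' the next `second`, the rest `other`.
#'
#' @param hits Hit tibble from [read_hits()].
#' @return The hits with a `rank` column, sorted per query. The result is a
#'   function of the hit multiset only (row order of the input is
#'   irrelevant).
#' @export
rank_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(hits |> mutate(rank = character()))
  }
  hits |>
    arrange(.data$query_id, desc(.data$bitscore), .data$evalue,
            .data$subject_id) |>
    group_by(.data$query_id) |>
    mutate(rank = dplyr::case_when(
      row_number() == 1L ~ "best",
      row_number() == 2L ~ "second",
      TRUE ~ "other")) |>
    ungroup()
}

#' Dot-plot coordinates in order-index space
#'
#' @param hits Ranked hit tibble from [rank_hits()] (a plain hit tibble is
#'   accepted; `rank` is then omitted).
#' @param table_a,table_b Gene tables for the query and subject genomes.
#' @return Tibble `query_id`, `subject_id`, `chrom_a`, `idx_a`, `chrom_b`,
#'   `idx_b` (+ `rank` if present), one row per hit.
#' @export
dotplot_coords <- function(hits, table_a, table_b) {
  a_idx <- table_a |> select(query_id = "gene_id", chrom_a = "chrom",
                             idx_a = "order_index")
  b_idx <- table_b |> select(subject_id = "gene_id", chrom_b = "chrom",
                             idx_b = "order_index")
  keep <- intersect(c("query_id", "subject_id", "rank"), names(hits))
  hits |>
    select(dplyr::all_of(keep)) |>
    inner_join(a_idx, by = "query_id") |>
    inner_join(b_idx, by = "subject_id")
}

#' Orthologous ratio between two genomes from their collinear blocks
#'
#' Windows of `window_genes` genes (50% overlap) slide along each genome;
#' for every window the block footprints on the other genome are clustered
#' into chromosomal regions (footprints on the same chromosome separated by
#' at most `2 * window_genes` order indices merge into one region) and
#' counted. The modal count over windows with at least one overlapping
#' block, per chromosome and genome-wide, gives the ratio. Following the
#' field's convention the genome-wide ratio is reported as the raw modal
#' counts (for example 4:2), never reduced.
#'
#' @param blocks Block tibble from [detect_blocks()] run with `table_a` as
#'   query and `table_b` as subject.
#' @param table_a,table_b The two gene tables.
#' @param window_genes Window width in genes (default 100).
#' @return An object of class `ortho_ratio`: list with `ratio` (named
#'   integer vector `c(a = ..., b = ...)`: modal regions of A per B window
#'   and of B per A window), `per_chrom` (modal count per reference
#'   chromosome and direction) and `window_counts` (per-window region
#'   counts). Errors if `blocks` is empty (ratio undefined).
#' @export
orthologous_ratio <- function(blocks, table_a, table_b, window_genes = 100) {
  if (nrow(blocks) == 0) {
    abort("no collinear blocks: orthologous ratio undefined",
          class = "wgdtrace_empty_blocks_error")
  }
  fp <- block_footprints(blocks)
  cnt_b_per_a <- window_region_counts(fp, table_a, window_genes, side = "a")
  cnt_a_per_b <- window_region_counts(fp, table_b, window_genes, side = "b")
  per_chrom <- bind_rows(
    cnt_b_per_a |> group_by(.data$chrom) |>
      summarise(modal_regions = modal_count(.data$n_regions), .groups = "drop") |>
      mutate(direction = "regions_of_b_per_a_window"),
    cnt_a_per_b |> group_by(.data$chrom) |>
      summarise(modal_regions = modal_count(.data$n_regions), .groups = "drop") |>
      mutate(direction = "regions_of_a_per_b_window"))
  ratio <- c(a = modal_count(cnt_a_per_b$n_regions),
             b = modal_count(cnt_b_per_a$n_regions))
  structure(list(ratio = ratio, per_chrom = per_chrom,
                 window_counts = bind_rows(
                   cnt_b_per_a |> mutate(direction = "regions_of_b_per_a_window"),
                   cnt_a_per_b |> mutate(direction = "regions_of_a_per_b_window")),
                 window_genes = window_genes),
            class = "ortho_ratio")
}

#' @export
print.ortho_ratio <- function(x, ...) {
  cat("<orthologous ratio> ", x$ratio[["a"]], ":", x$ratio[["b"]],
      " (window = ", x$window_genes, " genes)\n", sep = "")
  invisible(x)
}

# one footprint row per block: ref/other chromosome + order-index ranges
block_footprints <- function(blocks) {
  purrr::map2(blocks$pairs, seq_len(nrow(blocks)), function(p, i) {
    tibble(chrom_a = blocks$chrom_a[i], lo_a = min(p$idx_a), hi_a = max(p$idx_a),
           chrom_b = blocks$chrom_b[i], lo_b = min(p$idx_b), hi_b = max(p$idx_b))
  }) |> bind_rows()
}

# per-window counts of merged regions on the other genome; side = which
# footprint end is the reference
window_region_counts <- function(fp, ref_table, window_genes, side) {
  if (side == "b") {
    fp <- fp |> rename(chrom_a = "chrom_b", lo_a = "lo_b", hi_a = "hi_b",
                       chrom_b = "chrom_a", lo_b = "lo_a", hi_b = "hi_a")
  }
  merge_gap <- 2 * window_genes
  step <- max(1L, as.integer(window_genes / 2))
  chrom_sizes <- ref_table |> count(.data$chrom, name = "n_genes")
  out <- list()
  for (ci in seq_len(nrow(chrom_sizes))) {
    chrom <- chrom_sizes$chrom[ci]
    n <- chrom_sizes$n_genes[ci]
    f <- fp |> filter(.data$chrom_a == chrom)
    if (nrow(f) == 0) next
    starts <- seq(0L, max(0L, n - 1L), by = step)
    for (w0 in starts) {
      w1 <- min(w0 + window_genes, n) - 1L
      hitting <- f |> filter(.data$lo_a <= w1, .data$hi_a >= w0)
      if (nrow(hitting) == 0) next
      nr <- hitting |>
        group_by(.data$chrom_b) |>
        summarise(k = count_merged_intervals(.data$lo_b, .data$hi_b, merge_gap),
                  .groups = "drop") |>
        pull(.data$k) |> sum()
      out[[length(out) + 1L]] <- tibble(chrom = chrom, window_start = w0,
                                        n_regions = nr)
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), window_start = integer(),
                  n_regions = integer()))
  }
  bind_rows(out)
}

count_merged_intervals <- function(lo, hi, merge_gap) {
  o <- order(lo)
  lo <- lo[o]
  hi <- hi[o]
  k <- 1L
  cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] - cur_hi > merge_gap) {
      k <- k + 1L
      cur_hi <- hi[i]
    } else {
      cur_hi <- max(cur_hi, hi[i])
    }
  }
  k
}

# modal value; ties broken toward the smaller count
modal_count <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
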