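#' Gene retention profiles and the geometric model of consecutive gene loss
#'
#' After a polyploidy event, duplicated genes are lost ("fractionation") in
#' runs of consecutive deletions. Against a reference genome, each
#' reference gene is either retained or lost in each query subgenome; the
#' lengths of maximal runs of consecutive losses follow, under a
#' segment-wise deletion model, a geometric law
#' `N_k = N_1 * p^(k-1)` whose continuation probability `p` is the
#' extension parameter.
#'
#' @name fractionation
NULL

#' Per-gene retention of a reference genome in query subgenomes
#'
#' A reference gene is retained in a subgenome iff it anchors a collinear
#' block pair assigned to that subgenome. Reference genes outside every
#' block footprint are excluded from the denominators.
#'
#' @param ref_table Gene table of the reference genome (the blocks' A side).
#' @param blocks Reference-vs-query block tibble from [detect_blocks()].
#' @param subgenome_assignment Tibble mapping `block_id` to `subgenome`
#'   (from [assign_blocks_to_events()] labels or simulator truth).
#' @return A `retention_profile` object: `presence` (long tibble `gene_id`,
#'   `chrom`, `order_index`, `subgenome`, `retained`, footprint genes only)
#'   and `rates` (per chromosome and `"genome"`-wide retention and loss
#'   rate per subgenome).
#' @export
retention_profile <- function(ref_table, blocks, subgenome_assignment) {
  if (nrow(blocks) == 0) {
    abort("no blocks: retention profile undefined (empty footprint)",
          class = "wgdtrace_empty_blocks_error")
  }
  stopifnot(all(c("block_id", "subgenome") %in% names(subgenome_assignment)))
  blk <- blocks |>
    inner_join(subgenome_assignment, by = "block_id")
  if (nrow(blk) == 0) {
    abort("subgenome assignment matches no block", class = "wgdtrace_validation_error")
  }
  fp <- purrr::map2(blk$pairs, seq_len(nrow(blk)), function(p, i) {
    tibble(chrom = blk$chrom_a[i], lo = min(p$idx_a), hi = max(p$idx_a),
           subgenome = blk$subgenome[i])
  }) |> bind_rows()
  anchored <- purrr::map2(blk$pairs, blk$subgenome, function(p, sg) {
    tibble(gene_a = p$gene_a, subgenome = sg)
  }) |> bind_rows() |> distinct()
  subgenomes <- sort(unique(blk$subgenome))
  in_footprint <- function(chrom, idx) {
    f <- fp[fp$chrom == chrom, ]
    purrr::map_lgl(idx, \(i) any(f$lo <= i & f$hi >= i))
  }
  presence <- ref_table |>
    select("gene_id", "chrom", "order_index") |>
    group_by(.data$chrom) |>
    filter(in_footprint(.data$chrom[1], .data$order_index)) |>
    ungroup() |>
    tidyr::crossing(subgenome = subgenomes) |>
    left_join(anchored |> mutate(retained = TRUE),
              by = c(gene_id = "gene_a", "subgenome")) |>
    mutate(retained = !is.na(.data$retained))
  rates <- bind_rows(
    presence |>
      group_by(.data$subgenome, .data$chrom) |>
      summarise(n_genes = n(), retention_rate = mean(.data$retained),
                .groups = "drop"),
    presence |>
      group_by(.data$subgenome) |>
      summarise(n_genes = n(), retention_rate = mean(.data$retained),
                .groups = "drop") |>
      mutate(chrom = "genome")) |>
    mutate(loss_rate = 1 - .data$retention_rate) |>
    select("subgenome", "chrom", "n_genes", "retention_rate", "loss_rate")
  structure(list(presence = presence, rates = rates),
            class = "retention_profile")
}

#' @export
print.retention_profile <- function(x, ...) {
  overall <- x$rates |> filter(.data$chrom == "genome")
  cat("<retention_profile>", length(unique(x$presence$subgenome)),
      "subgenome(s);", nrow(x$presence) / max(1, length(unique(x$presence$subgenome))),
      "footprint genes\n")
  print(overall)
  invisible(x)
}

#' Run lengths of consecutive gene loss
#'
#' Maximal runs of consecutive non-retained reference genes, bounded on
#' both sides by retained genes of the same chromosome/subgenome footprint
#' sequence (runs touching a footprint edge are not counted, since their
#' full length is unobserved). Runs longer than `segmental_cutoff` are
#' treated as segmental losses: counted in `excluded_runs` and omitted
#' from the run-length table.
#'
#' @param profile A `retention_profile`.
#' @param segmental_cutoff Maximum run length kept (default 30).
#' @return List with `run_counts` (tibble `k`, `n_k`), `runs` (per-run
#'   records), and `excluded_runs` (count of segmental losses).
#' @export
loss_runs <- function(profile, segmental_cutoff = 30) {
  stopifnot(inherits(profile, "retention_profile"))
  runs <- profile$presence |>
    arrange(.data$subgenome, .data$chrom, .data$order_index) |>
    group_by(.data$subgenome, .data$chrom) |>
    summarise(run = list(interior_zero_runs(.data$retained)), .groups = "drop") |>
    tidyr::unnest("run")
  if (nrow(runs) == 0 || all(is.na(runs$run))) {
    return(list(run_counts = tibble(k = integer(), n_k = integer()),
                runs = runs[0, ], excluded_runs = 0L))
  }
  runs <- runs |> filter(!is.na(.data$run))
  excluded <- sum(runs$run > segmental_cutoff)
  kept <- runs |> filter(.data$run <= segmental_cutoff)
  run_counts <- kept |> count(k = .data$run, name = "n_k")
  list(run_counts = run_counts, runs = kept, excluded_runs = excluded)
}

# lengths of 0-runs strictly between 1s
interior_zero_runs <- function(retained) {
  r <- rle(as.integer(retained))
  if (length(r$lengths) < 3) return(NA_integer_)
  zero_pos <- which(r$values == 0L)
  zero_pos <- zero_pos[zero_pos > 1 & zero_pos < length(r$values)]
  if (length(zero_pos) == 0) return(NA_integer_)
  r$lengths[zero_pos]
}

#' Fit the geometric run-length model of gene loss
#'
#' Fits `N_k = N_1 * p^(k-1)` two ways: `p_hat` from least-squares
#' regression of `log N_k` on `k - 1` over lengths with `N_k >= 5` (small
#' counts are excluded to avoid log instability), and the closed-form
#' maximum-likelihood estimate `p_mle = sum(k_i - 1) / sum(k_i)` over all
#' runs. Goodness of fit is an extra-parameter F test against the
#' `k^b`-modulated alternative `N_k = N_1 * p^(k-1) * k^b` (null `b = 0`):
#' a large P-value means the pure geometric decay is adequate.
#'
#' @param run_counts Tibble `k`, `n_k` (from [loss_runs()]) or a named
#'   numeric vector (names = run lengths).
#' @param excluded_runs Count of segmental losses excluded upstream
#'   (carried into the result).
#' @param min_count Minimum `N_k` entering the regression (default 5).
#' @return A `geom_loss_fit` object with `p_hat`, `p_mle`, `f_stat`,
#'   `p_value`, `run_counts`, `n_runs`, `excluded_runs`.
#' @export
fit_geometric <- function(run_counts, excluded_runs = 0L, min_count = 5) {
  if (!is.data.frame(run_counts)) {
    run_counts <- tibble(k = as.integer(names(run_counts)),
                         n_k = as.numeric(run_counts))
  }
  stopifnot(all(c("k", "n_k") %in% names(run_counts)))
  rc <- run_counts |> filter(.data$n_k > 0) |> arrange(.data$k)
  if (nrow(rc) < 3) {
    abort("need at least 3 distinct run lengths with nonzero counts",
          class = "wgdtrace_validation_error")
  }
  p_mle <- sum(rc$n_k * (rc$k - 1)) / sum(rc$n_k * rc$k)
  reg <- rc |> filter(.data$n_k >= min_count)
  if (nrow(reg) < 3) {
    warn("fewer than 3 run lengths reach min_count; regressing on all lengths")
    reg <- rc
  }
  m0 <- lm(log(n_k) ~ I(k - 1), data = reg)
  p_hat <- unname(exp(coef(m0)[2]))
  f_stat <- NA_real_
  p_value <- NA_real_
  if (nrow(reg) >= 4) {
    m1 <- lm(log(n_k) ~ I(k - 1) + log(k), data = reg)
    rss0 <- sum(residuals(m0)^2)
    rss1 <- sum(residuals(m1)^2)
    if (rss0 < 1e-10) {
      # both models (near-)perfect: pure geometric already explains the data
      f_stat <- 0
      p_value <- 1
    } else {
      df2 <- nrow(reg) - 3
      f_stat <- (rss0 - rss1) / (rss1 / df2)
      p_value <- pf(f_stat, 1, df2, lower.tail = FALSE)
    }
  } else {
    warn("too few run lengths for the lack-of-fit F test")
  }
  structure(list(run_counts = rc, p_hat = p_hat, p_mle = p_mle,
                 f_stat = f_stat, p_value = p_value,
                 n_runs = sum(rc$n_k), excluded_runs = excluded_runs,
                 regression = m0, min_count = min_count),
            class = "geom_loss_fit")
}

#' @export
print.geom_loss_fit <- function(x, ...) {
  cat("<geom_loss_fit> extension parameter p_hat =", signif(x$p_hat, 3),
      "(MLE", paste0(signif(x$p_mle, 3), ");"),
      "lack-of-fit F P-value =", signif(x$p_value, 3), "\n")
  cat(" ", x$n_runs, "runs;", x$excluded_runs, "segmental losses excluded\n")
  invisible(x)
}
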