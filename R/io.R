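#' Read and write the package's tab-separated formats
#'
#' All on-disk tables are plain TSV with a single `#`-prefixed header line
#' naming the columns; no binary formats are used anywhere.
#'
#' @name wgdtrace-io
NULL

# ---- low-level TSV helpers -------------------------------------------------

write_tsv_hashed <- function(x, path) {
  header <- paste0("#", paste(names(x), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, format_tsv_col), list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.numeric(v) && !is.integer(v)) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1))
    return(out)
  }
  as.character(v)
}

read_tsv_hashed <- function(path, required = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "wgdtrace_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    abort(paste0("empty file with no header: ", path), class = "wgdtrace_parse_error")
  }
  if (!startsWith(first, "#")) {
    abort(paste0("expected '#'-prefixed header line in ", path),
          class = "wgdtrace_parse_error")
  }
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  x <- readr::read_tsv(path, skip = 1L, col_names = cols,
                       col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE, show_col_types = FALSE,
                       na = c("NA", ""))
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing) > 0) {
      abort(paste0("missing columns in ", path, ": ",
                   paste(missing, collapse = ", ")),
            class = "wgdtrace_parse_error")
    }
  }
  as_tibble(x)
}

# ---- gene tables -----------------------------------------------------------

#' Read a gene-position table
#'
#' Reads a BED-like tab-separated table of gene coordinates (0-based,
#' half-open) and assigns each gene a rank along its chromosome
#' (`order_index`, starting at 0). `order_index` is the coordinate axis for
#' all downstream analysis; base-pair positions are carried for I/O only.
#'
#' @param path Path to a TSV with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`. A `#`-prefixed header naming the columns is accepted (and is
#'   what [write_gene_table()] emits); a headerless file is read positionally.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (+1/-1 integer) and `order_index`, sorted by chromosome and
#'   start position.
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- c("chrom", "start", "end", "strand", "gene_id")
  if (length(first) > 0 && startsWith(first, "#")) {
    x <- read_tsv_hashed(path, required = cols)
  } else {
    x <- readr::read_tsv(path, col_names = cols,
                         col_types = "ciicc", progress = FALSE,
                         show_col_types = FALSE, na = c("NA", ""))
  }
  x <- as_tibble(x)[, cols]
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$start >= x$end)
  if (length(bad) > 0) {
    abort(paste0("gene table ", path, ": start >= end (or non-numeric) at line ",
                 bad[1] + 1L, " (gene ", x$gene_id[bad[1]], ")"),
          class = "wgdtrace_parse_error")
  }
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("gene table ", path, ": duplicate gene_id: ",
                 paste(unique(dup), collapse = ", ")),
          class = "wgdtrace_validation_error")
  }
  x$strand <- parse_strand(x$strand)
  build_gene_table(x)
}

parse_strand <- function(s) {
  s <- as.character(s)
  out <- dplyr::case_when(
    s %in% c("+", "+1", "1") ~ 1L,
    s %in% c("-", "-1") ~ -1L,
    TRUE ~ NA_integer_
  )
  if (anyNA(out)) {
    warn(paste0(sum(is.na(out)), " gene(s) with missing strand; defaulting to +1"))
    out[is.na(out)] <- 1L
  }
  out
}

# assign order_index by start position within each chromosome
build_gene_table <- function(x) {
  x |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(order_index = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "chrom", "start", "end", "strand", "order_index")
}

#' Write a gene-position table
#'
#' @param x A gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id") %in% names(x)))
  out <- x |> arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "strand", "gene_id")
  write_tsv_hashed(out, path)
}

# ---- homology hits ---------------------------------------------------------

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Reads the 12-column BLAST tabular dialect, drops hits above the E-value
#' threshold and drops self-hits (query equal to subject).
#'
#' @param path Path to the hit table (no header, 12 tab-separated columns:
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#'   send, evalue, bitscore).
#' @param max_evalue Maximum E-value retained (default `1e-5`).
#' @return A tibble with columns `query_id`, `subject_id`, `identity_pct`,
#'   `align_len`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path, max_evalue = 1e-5) {
  blast_cols <- c("query_id", "subject_id", "identity_pct", "align_len",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  identity_pct = double(), align_len = integer(),
                  evalue = double(), bitscore = double()))
  }
  skip <- if (startsWith(first, "#")) 1L else 0L
  x <- readr::read_tsv(path, col_names = blast_cols, skip = skip,
                       col_types = readr::cols(
                         query_id = "c", subject_id = "c",
                         .default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  for (col in c("identity_pct", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad) > 0) {
      abort(paste0("hit table ", path, ": non-numeric ", col, " at line ",
                   bad[1] + skip), class = "wgdtrace_parse_error")
    }
    x[[col]] <- v
  }
  x$align_len <- suppressWarnings(as.integer(x$align_len))
  x |>
    filter(.data$evalue <= max_evalue, .data$query_id != .data$subject_id) |>
    select("query_id", "subject_id", "identity_pct", "align_len",
           "evalue", "bitscore")
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' Columns not carried by the tibble (alignment coordinates) are written as
#' zeros; the result round-trips through [read_hits()].
#'
#' @param x Tibble with columns `query_id`, `subject_id`, `identity_pct`,
#'   `evalue`, `bitscore` (and optionally `align_len`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(x, path) {
  n <- nrow(x)
  al <- if ("align_len" %in% names(x)) x$align_len else rep(0L, n)
  out <- tibble(
    query_id = x$query_id, subject_id = x$subject_id,
    identity_pct = x$identity_pct, align_len = al,
    mismatch = rep(0L, n), gapopen = rep(0L, n),
    qstart = rep(1L, n), qend = al, sstart = rep(1L, n), send = al,
    evalue = x$evalue, bitscore = x$bitscore)
  body <- do.call(paste, c(lapply(out, format_tsv_col), list(sep = "\t")))
  writeLines(body, path)
  invisible(path)
}

# ---- collinear blocks ------------------------------------------------------

#' Write detected collinear blocks to a pair of TSV files
#'
#' Emits `<prefix>.blocks.tsv` (one row per block) and `<prefix>.pairs.tsv`
#' (one row per anchored gene pair, ordered along the block).
#'
#' @param blocks Nested block tibble from [detect_blocks()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_blocks <- function(blocks, prefix) {
  block_path <- paste0(prefix, ".blocks.tsv")
  pair_path <- paste0(prefix, ".pairs.tsv")
  flat <- blocks |> select(-"pairs")
  if (!"median_ks" %in% names(flat)) flat$median_ks <- NA_real_
  write_tsv_hashed(flat, block_path)
  pairs <- blocks |>
    select("block_id", "pairs") |>
    tidyr::unnest("pairs")
  write_tsv_hashed(pairs, pair_path)
  invisible(c(block_path, pair_path))
}

#' Read collinear blocks written by [write_blocks()]
#'
#' @param prefix Path prefix used when writing.
#' @return Nested block tibble (list-column `pairs`).
#' @export
read_blocks <- function(prefix) {
  flat <- read_tsv_hashed(paste0(prefix, ".blocks.tsv"),
                          required = c("block_id", "chrom_a", "chrom_b",
                                       "orientation", "n_pairs"))
  pairs <- read_tsv_hashed(paste0(prefix, ".pairs.tsv"), required = "block_id")
  nested <- pairs |> tidyr::nest(pairs = -"block_id")
  out <- flat |> left_join(nested, by = "block_id")
  empty <- tibble(gene_a = character(), gene_b = character(),
                  idx_a = integer(), idx_b = integer(), pair_id = character())
  out$pairs <- lapply(out$pairs, function(p) if (is.null(p)) empty else p)
  out
}

# ---- config ----------------------------------------------------------------

#' Read a `key = value` configuration file
#'
#' Lines starting with `#` and blank lines are ignored; values that parse as
#' numbers are returned numeric, `true`/`false` as logical, everything else
#' as character.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) {
      abort(paste0("malformed config line (expected key = value): ", ln),
            class = "wgdtrace_parse_error")
    }
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!nzchar(key)) {
      abort(paste0("malformed config line (expected key = value): ", ln),
            class = "wgdtrace_parse_error")
    }
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}

# ---- FASTA -----------------------------------------------------------------

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_cds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write coding sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
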