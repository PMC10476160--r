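#' Nei-Gojobori (NG86) Ka/Ks estimation
#'
#' Counting-method estimation of synonymous (Ks) and nonsynonymous (Ka)
#' substitution rates between two aligned coding sequences under the
#' universal genetic code, with Jukes-Cantor correction for multiple hits.
#'
#' Site counting: for each codon, the synonymous site fraction at each of
#' the three positions is the number of one-step changes that preserve the
#' amino acid (changes to stop codons count as nonsynonymous), divided by 3;
#' sites are averaged over the two sequences. Codons differing at several
#' positions average their synonymous/nonsynonymous difference counts over
#' all minimal substitution paths with equal weight; any path step passing
#' through a stop codon is excluded from the average, and a codon pair whose
#' paths are all blocked is skipped entirely (also removed from the site
#' totals, preserving S + N = 3 x compared codons).
#'
#' @name ng86-method
NULL

# universal genetic code, internal copy ('*' = stop)
.GENCODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.ng_cache <- new.env(parent = emptyenv())

codon_translate <- function(codon) unname(.GENCODE[codon])

is_stop_codon <- function(codon) !is.na(.GENCODE[codon]) & .GENCODE[codon] == "*"

# one-step neighbours of a codon at a given position
codon_neighbours <- function(codon, pos) {
  nts <- c("A", "C", "G", "T")
  cur <- substr(codon, pos, pos)
  vapply(setdiff(nts, cur), function(nt) {
    paste0(substr(codon, 1, pos - 1), nt, substr(codon, pos + 1, 3))
  }, character(1))
}

# fractional synonymous sites per codon (changes to stops = nonsynonymous)
ng_syn_sites <- function() {
  if (!is.null(.ng_cache$syn_sites)) return(.ng_cache$syn_sites)
  codons <- names(.GENCODE)[.GENCODE != "*"]
  s <- vapply(codons, function(cd) {
    aa <- .GENCODE[[cd]]
    syn <- 0L
    for (pos in 1:3) {
      nb <- codon_neighbours(cd, pos)
      syn <- syn + sum(.GENCODE[nb] == aa, na.rm = TRUE)
    }
    syn / 3
  }, double(1))
  .ng_cache$syn_sites <- s
  s
}

# average (sd, nd) over all stop-free minimal substitution paths between two
# codons; NULL if every path is blocked
ng_path_counts <- function(ca, cb) {
  diffs <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(diffs)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- switch(d,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  tot_sd <- 0
  tot_nd <- 0
  n_valid <- 0L
  chb <- strsplit(cb, "")[[1]]
  for (perm in perms) {
    cur <- ca
    sd <- 0L
    nd <- 0L
    ok <- TRUE
    for (step in perm) {
      pos <- diffs[step]
      nxt <- paste0(substr(cur, 1, pos - 1), chb[pos], substr(cur, pos + 1, 3))
      if (is_stop_codon(nxt) && !identical(nxt, cb)) { ok <- FALSE; break }
      if (is_stop_codon(nxt)) { ok <- FALSE; break }  # endpoints checked upstream
      if (codon_translate(cur) == codon_translate(nxt)) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) {
      tot_sd <- tot_sd + sd
      tot_nd <- tot_nd + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(NULL)
  c(sd = tot_sd / n_valid, nd = tot_nd / n_valid)
}

ng_result_row <- function(pair_id, status, reason = NA_character_,
                          S = NA_real_, N = NA_real_, Sd = NA_real_,
                          Nd = NA_real_, ps = NA_real_, pn = NA_real_,
                          Ks = NA_real_, Ka = NA_real_, n_codons = NA_integer_) {
  tibble(pair_id = pair_id, S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
         Ks = Ks, Ka = Ka, n_codons = n_codons, status = status,
         reason = reason)
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks for one aligned coding-sequence pair
#'
#' @param cds_a,cds_b Aligned coding sequences (equal length, multiple of 3,
#'   gap columns removed upstream; codons containing gap `-` or ambiguity
#'   characters are skipped pairwise). A stop codon at the final position is
#'   trimmed; an internal stop makes the pair degenerate.
#' @param pair_id Identifier carried into the result row.
#' @return One-row tibble: fractional site counts `S`, `N`, difference
#'   counts `Sd`, `Nd`, proportions `ps`, `pn`, Jukes-Cantor distances `Ks`,
#'   `Ka`, `n_codons` compared, `status` (`ok`, `saturated`, `degenerate`)
#'   and `reason`. At saturation (p >= 3/4) the affected distance is `NA`.
#' @export
ng86 <- function(cds_a, cds_b, pair_id = NA_character_) {
  a <- toupper(gsub("U", "T", cds_a, fixed = TRUE))
  b <- toupper(gsub("U", "T", cds_b, fixed = TRUE))
  if (nchar(a) != nchar(b)) {
    return(ng_result_row(pair_id, "degenerate", "length mismatch"))
  }
  if (nchar(a) %% 3 != 0) {
    return(ng_result_row(pair_id, "degenerate", "length not a multiple of 3"))
  }
  nc <- nchar(a) / 3
  starts <- seq(1, by = 3, length.out = nc)
  cod_a <- substring(a, starts, starts + 2)
  cod_b <- substring(b, starts, starts + 2)
  # trim a terminal stop in either sequence
  if (nc > 0 && (is_stop_codon(cod_a[nc]) || is_stop_codon(cod_b[nc]))) {
    cod_a <- cod_a[-nc]
    cod_b <- cod_b[-nc]
    nc <- nc - 1L
  }
  clean <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[clean]
  cod_b <- cod_b[clean]
  if (any(is_stop_codon(cod_a)) || any(is_stop_codon(cod_b))) {
    return(ng_result_row(pair_id, "degenerate", "internal stop codon"))
  }
  if (length(cod_a) == 0) {
    return(ng_result_row(pair_id, "degenerate", "no comparable codons"))
  }
  syn <- ng_syn_sites()
  S_tot <- 0
  Sd <- 0
  Nd <- 0
  used <- 0L
  for (i in seq_along(cod_a)) {
    counts <- ng_path_counts(cod_a[i], cod_b[i])
    if (is.null(counts)) next  # all paths blocked by stops: skip codon
    S_tot <- S_tot + (syn[[cod_a[i]]] + syn[[cod_b[i]]]) / 2
    Sd <- Sd + counts[["sd"]]
    Nd <- Nd + counts[["nd"]]
    used <- used + 1L
  }
  if (used == 0L) {
    return(ng_result_row(pair_id, "degenerate", "no comparable codons"))
  }
  S <- S_tot
  N <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  status <- if (ps >= 0.75 || pn >= 0.75) "saturated" else "ok"
  ng_result_row(pair_id, status, NA_character_, S, N, Sd, Nd, ps, pn,
                Ks, Ka, used)
}

#' Batch NG86 over a table of sequence pairs
#'
#' @param pairs Tibble with columns `pair_id`, `id_a`, `id_b`.
#' @param cds Named character vector (or list) of coding sequences indexed
#'   by the ids in `pairs`; pairs with a missing sequence are recorded as
#'   degenerate and the run continues.
#' @return Tibble of [ng86()] rows, one per pair, in input order.
#' @export
pairwise_ks_table <- function(pairs, cds) {
  stopifnot(all(c("pair_id", "id_a", "id_b") %in% names(pairs)))
  purrr::pmap(pairs[c("pair_id", "id_a", "id_b")],
              function(pair_id, id_a, id_b) {
    sa <- if (id_a %in% names(cds)) cds[[id_a]] else NULL
    sb <- if (id_b %in% names(cds)) cds[[id_b]] else NULL
    if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb)) {
      return(ng_result_row(pair_id, "degenerate", "missing sequence"))
    }
    ng86(sa, sb, pair_id = pair_id)
  }) |> bind_rows()
}
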