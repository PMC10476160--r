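# Independent oracles used across the suite.

# --- NG86 oracle: exhaustive substitution-path enumeration using the
# Biostrings genetic code (independent of the package's internal tables).
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  nts <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      nb <- paste0(substr(codon, 1, pos - 1), nt, substr(codon, pos + 1, 3))
      if (oracle_translate(nb) == aa) syn <- syn + 1
    }
  }
  syn / 3
}

# average (sd, nd) over stop-free orderings of the differing positions
oracle_path_counts <- function(ca, cb) {
  av <- strsplit(ca, "")[[1]]
  bv <- strsplit(cb, "")[[1]]
  diffs <- which(av != bv)
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(diffs)
  acc <- c(sd = 0, nd = 0)
  nvalid <- 0
  for (perm in perms) {
    cur <- av
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (pos in perm) {
      nxt <- cur
      nxt[pos] <- bv[pos]
      if (oracle_translate(paste(nxt, collapse = "")) == "*") { ok <- FALSE; break }
      if (oracle_translate(paste(cur, collapse = "")) ==
            oracle_translate(paste(nxt, collapse = ""))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      acc <- acc + c(sd = sd, nd = nd)
      nvalid <- nvalid + 1
    }
  }
  if (nvalid == 0) return(NULL)
  acc / nvalid
}

all_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

# --- brute-force longest monotone chain (exhaustive depth-first search,
# no dynamic programming); returns the maximum chain length
oracle_longest_chain <- function(idx_a, idx_b, dir, max_gap) {
  n <- length(idx_a)
  step <- max_gap + 1
  succ_ok <- function(i, j) {
    da <- idx_a[j] - idx_a[i]
    db <- (idx_b[j] - idx_b[i]) * dir
    da > 0 && da <= step && db > 0 && db <= step
  }
  best <- 0
  extend <- function(i, len) {
    best <<- max(best, len)
    for (j in seq_len(n)) {
      if (succ_ok(i, j)) extend(j, len + 1)
    }
  }
  for (i in seq_len(n)) extend(i, 1)
  best
}

# closed-form geometric MLE on raw run lengths
oracle_geom_mle <- function(runs) sum(runs - 1) / sum(runs)

# small helpers for fixture files
write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

blast6_line <- function(q, s, evalue, bitscore, ident = 90) {
  paste(q, s, ident, 300, 10, 0, 1, 300, 1, 300,
        format(evalue, scientific = TRUE), bitscore, sep = "\t")
}
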