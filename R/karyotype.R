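#' Telomere-centric karyotype event engine
#'
#' A karyotype is an ordered set of chromosomes, each an ordered list of
#' oriented segments labelled by the ancestral chromosome they descend from
#' (spans are fractional intervals of the ancestral chromosome, half-open in
#' `[0, 1)`). Six event kinds rewrite the karyotype:
#'
#' * `EEJ` — end-to-end joining (telomeric fusion) of two chromosomes;
#'   chromosome count decreases by one and the two joined telomeres are
#'   recorded as a satellite.
#' * `NCF` — nested chromosome fusion: the donor chromosome is inserted into
#'   the host at a breakpoint (centromere proxy); count decreases by one and
#'   the donor's telomeres form a satellite.
#' * `XO` — crossover / reciprocal translocation of chromosome arms at one
#'   breakpoint on each chromosome; count unchanged.
#' * `IV` — segmental inversion of an interval within one chromosome.
#' * `WGD` / `WGT` — whole-genome duplication / triplication; every
#'   chromosome is copied with suffixes `a`/`b` (`/c`).
#'
#' Satellites are recorded but never re-enter the karyotype and are excluded
#' from all chromosome counts.
#'
#' @name karyotype-engine
NULL

#' Construct a karyotype
#'
#' @param labels Character vector of ancestral chromosome labels (for example
#'   `paste0("E", 1:7)`); one single-segment chromosome per label, spanning
#'   the full ancestral unit interval with orientation +1. Chromosome names
#'   default to the labels.
#' @param generation_tag Free-text tag describing the generation (for
#'   example `"post-ECH"`).
#' @return A `karyotype` object.
#' @export
karyotype <- function(labels, generation_tag = "") {
  stopifnot(is.character(labels), length(labels) > 0, !anyDuplicated(labels))
  chroms <- lapply(labels, function(l) {
    tibble(ancestral_chrom = l, span_lo = 0, span_hi = 1, orientation = 1L)
  })
  names(chroms) <- labels
  structure(
    list(chromosomes = chroms,
         satellites = tibble(label = character(), telomere_a = character(),
                             telomere_b = character()),
         n_wgd = 0L,
         generation_tag = generation_tag),
    class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype>", length(x$chromosomes), "chromosomes,",
      nrow(x$satellites), "satellites recorded")
  if (nzchar(x$generation_tag)) cat(" [", x$generation_tag, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of chromosomes in a karyotype (satellites excluded)
#'
#' @param k A `karyotype`.
#' @return Integer count.
#' @export
n_chromosomes <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  length(k$chromosomes)
}

#' @export
as_tibble.karyotype <- function(x, ...) {
  purrr::imap(x$chromosomes, function(segs, nm) {
    segs |> mutate(chrom = nm, seg_index = row_number() - 1L)
  }) |>
    bind_rows() |>
    select("chrom", "seg_index", "ancestral_chrom", "span_lo", "span_hi",
           "orientation")
}

#' Write / read a karyotype as TSV
#'
#' The main file holds one row per segment (`chrom`, `seg_index`,
#' `ancestral_chrom`, `span_lo`, `span_hi`, `orientation`); a companion
#' `<path>.satellites.tsv` holds the satellite ledger.
#'
#' @param k A `karyotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(k, path) {
  write_tsv_hashed(as_tibble(k), path)
  write_tsv_hashed(k$satellites, paste0(path, ".satellites.tsv"))
  invisible(path)
}

#' @rdname write_karyotype
#' @return For `read_karyotype`, the reconstructed `karyotype` (with an
#'   empty satellite ledger if the companion file is absent).
#' @export
read_karyotype <- function(path) {
  x <- read_tsv_hashed(path, required = c("chrom", "seg_index",
                                          "ancestral_chrom", "span_lo",
                                          "span_hi", "orientation"))
  chroms <- x |>
    arrange(match(.data$chrom, unique(x$chrom)), .data$seg_index) |>
    (\(d) split(d, factor(d$chrom, levels = unique(d$chrom))))() |>
    lapply(function(d) {
      d |> select("ancestral_chrom", "span_lo", "span_hi", "orientation") |>
        mutate(orientation = as.integer(.data$orientation))
    })
  sat_path <- paste0(path, ".satellites.tsv")
  sats <- if (file.exists(sat_path)) {
    read_tsv_hashed(sat_path)
  } else {
    tibble(label = character(), telomere_a = character(),
           telomere_b = character())
  }
  structure(list(chromosomes = chroms, satellites = sats, n_wgd = 0L,
                 generation_tag = ""), class = "karyotype")
}

#' Construct a karyotype event
#'
#' @param kind One of `"EEJ"`, `"NCF"`, `"XO"`, `"IV"`, `"WGD"`, `"WGT"`.
#' @param ... Operands by kind: EEJ takes `chrom_a`, `chrom_b` and optional
#'   `end_a`/`end_b` (`"start"`/`"end"`; defaults join the end of the first
#'   to the start of the second); NCF takes `host`, `donor` and optional
#'   `pos` (fractional breakpoint along the host, default 0.5); XO takes
#'   `chrom_a`, `pos_a`, `chrom_b`, `pos_b`; IV takes `chrom`, `from`, `to`;
#'   WGD/WGT take no operands.
#' @return A `karyo_event` object.
#' @export
karyo_event <- function(kind, ...) {
  kind <- toupper(kind)
  if (!kind %in% c("EEJ", "NCF", "XO", "IV", "WGD", "WGT")) {
    abort(paste0("unknown event kind: ", kind), class = "wgdtrace_validation_error")
  }
  args <- list(...)
  defaults <- switch(kind,
    EEJ = list(chrom_a = NULL, chrom_b = NULL, end_a = "end", end_b = "start"),
    NCF = list(host = NULL, donor = NULL, pos = 0.5),
    XO  = list(chrom_a = NULL, pos_a = NULL, chrom_b = NULL, pos_b = NULL),
    IV  = list(chrom = NULL, from = NULL, to = NULL),
    list())
  ev <- modifyList(defaults, args)
  ev$kind <- kind
  structure(ev, class = "karyo_event")
}

seg_len <- function(segs) sum(segs$span_hi - segs$span_lo)

flip_chrom <- function(segs) {
  segs[rev(seq_len(nrow(segs))), , drop = FALSE] |>
    mutate(orientation = -.data$orientation)
}

telomere_desc <- function(segs, which_end) {
  seg <- if (which_end == "start") segs[1, ] else segs[nrow(segs), ]
  side <- if (which_end == "start") {
    if (seg$orientation == 1L) "lo" else "hi"
  } else {
    if (seg$orientation == 1L) "hi" else "lo"
  }
  paste0(seg$ancestral_chrom, ":", side)
}

# split an ordered segment list at fractional position `frac` of its total
# length, returning list(left, right)
split_chrom_at <- function(segs, frac) {
  total <- seg_len(segs)
  if (!(frac > 0 && frac < 1)) {
    abort("breakpoint must lie strictly inside (0, 1)",
          class = "wgdtrace_validation_error")
  }
  cut <- frac * total
  lens <- segs$span_hi - segs$span_lo
  cum <- cumsum(lens)
  i <- which(cum >= cut - 1e-12)[1]
  before <- if (i > 1) cum[i - 1] else 0
  within <- cut - before
  left <- segs[seq_len(i - 1), , drop = FALSE]
  right <- segs[seq(i + 1, length.out = nrow(segs) - i), , drop = FALSE]
  seg <- segs[i, ]
  if (within <= 1e-12) {
    right <- bind_rows(seg, right)
  } else if (within >= lens[i] - 1e-12) {
    left <- bind_rows(left, seg)
  } else {
    if (seg$orientation == 1L) {
      l <- seg |> mutate(span_hi = .data$span_lo + within)
      r <- seg |> mutate(span_lo = .data$span_lo + within)
    } else {
      l <- seg |> mutate(span_lo = .data$span_hi - within)
      r <- seg |> mutate(span_hi = .data$span_hi - within)
    }
    left <- bind_rows(left, l)
    right <- bind_rows(r, right)
  }
  list(left = left, right = right)
}

# merge consecutive segments that are contiguous pieces of the same
# ancestral chromosome in the same orientation (breakpoints that have been
# healed, e.g. by reverting an inversion, leave no trace)
merge_segments <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  keep <- rep(TRUE, nrow(segs))
  i <- 1L
  for (j in 2:nrow(segs)) {
    same <- segs$ancestral_chrom[j] == segs$ancestral_chrom[i] &&
      segs$orientation[j] == segs$orientation[i]
    contiguous <- if (segs$orientation[i] == 1L) {
      abs(segs$span_lo[j] - segs$span_hi[i]) < 1e-12
    } else {
      abs(segs$span_hi[j] - segs$span_lo[i]) < 1e-12
    }
    if (same && contiguous) {
      if (segs$orientation[i] == 1L) {
        segs$span_hi[i] <- segs$span_hi[j]
      } else {
        segs$span_lo[i] <- segs$span_lo[j]
      }
      keep[j] <- FALSE
    } else {
      i <- j
    }
  }
  segs[keep, , drop = FALSE]
}

get_chrom <- function(k, nm) {
  if (is.null(nm) || !nm %in% names(k$chromosomes)) {
    abort(paste0("no such chromosome: ", if (is.null(nm)) "<missing>" else nm,
                 " (have: ", paste(names(k$chromosomes), collapse = ", "), ")"),
          class = "wgdtrace_validation_error")
  }
  k$chromosomes[[nm]]
}

add_satellite <- function(k, tel_a, tel_b) {
  lab <- paste0("S", nrow(k$satellites) + 1L)
  k$satellites <- bind_rows(
    k$satellites, tibble(label = lab, telomere_a = tel_a, telomere_b = tel_b))
  k
}

#' Apply a single event to a karyotype
#'
#' @param k A `karyotype`.
#' @param e A `karyo_event` (or a DSL string accepted by
#'   [parse_event_script()], for example `"EEJ chr1 chr2"`).
#' @return The rewritten `karyotype`.
#' @export
apply_event <- function(k, e) {
  stopifnot(inherits(k, "karyotype"))
  if (is.character(e)) e <- parse_event_line(e)
  stopifnot(inherits(e, "karyo_event"))
  out <- switch(e$kind,
    EEJ = apply_eej(k, e),
    NCF = apply_ncf(k, e),
    XO  = apply_xo(k, e),
    IV  = apply_iv(k, e),
    WGD = apply_wgx(k, 2L),
    WGT = apply_wgx(k, 3L))
  out$chromosomes <- lapply(out$chromosomes, merge_segments)
  out
}

apply_eej <- function(k, e) {
  if (identical(e$chrom_a, e$chrom_b)) {
    abort("EEJ requires two distinct chromosomes", class = "wgdtrace_validation_error")
  }
  a <- get_chrom(k, e$chrom_a)
  b <- get_chrom(k, e$chrom_b)
  # orient so that a's joining end is its end and b's is its start
  if (identical(e$end_a, "start")) a <- flip_chrom(a)
  if (identical(e$end_b, "end")) b <- flip_chrom(b)
  tel_a <- telomere_desc(a, "end")
  tel_b <- telomere_desc(b, "start")
  fused <- bind_rows(a, b)
  k$chromosomes[[e$chrom_a]] <- fused
  k$chromosomes[[e$chrom_b]] <- NULL
  add_satellite(k, tel_a, tel_b)
}

apply_ncf <- function(k, e) {
  if (identical(e$host, e$donor)) {
    abort("NCF requires distinct host and donor", class = "wgdtrace_validation_error")
  }
  host <- get_chrom(k, e$host)
  donor <- get_chrom(k, e$donor)
  halves <- split_chrom_at(host, e$pos)
  tel_a <- telomere_desc(donor, "start")
  tel_b <- telomere_desc(donor, "end")
  k$chromosomes[[e$host]] <- bind_rows(halves$left, donor, halves$right)
  k$chromosomes[[e$donor]] <- NULL
  add_satellite(k, tel_a, tel_b)
}

apply_xo <- function(k, e) {
  if (identical(e$chrom_a, e$chrom_b)) {
    abort("XO requires two distinct chromosomes", class = "wgdtrace_validation_error")
  }
  a <- split_chrom_at(get_chrom(k, e$chrom_a), e$pos_a)
  b <- split_chrom_at(get_chrom(k, e$chrom_b), e$pos_b)
  k$chromosomes[[e$chrom_a]] <- bind_rows(a$left, b$right)
  k$chromosomes[[e$chrom_b]] <- bind_rows(b$left, a$right)
  k
}

apply_iv <- function(k, e) {
  if (!(e$from < e$to)) {
    abort("IV interval must satisfy from < to", class = "wgdtrace_validation_error")
  }
  segs <- get_chrom(k, e$chrom)
  outer <- split_chrom_at(segs, e$to)
  inner <- split_chrom_at(outer$left, e$from / e$to)
  k$chromosomes[[e$chrom]] <- bind_rows(inner$left, flip_chrom(inner$right),
                                        outer$right)
  k
}

apply_wgx <- function(k, ploidy) {
  suffixes <- letters[seq_len(ploidy)]
  new <- list()
  for (nm in names(k$chromosomes)) {
    for (s in suffixes) {
      new[[paste0(nm, s)]] <- k$chromosomes[[nm]]
    }
  }
  k$chromosomes <- new
  if (ploidy >= 2L) k$n_wgd <- k$n_wgd + 1L
  k
}

# ---- event script DSL ------------------------------------------------------

parse_event_line <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kind <- toupper(toks[1])
  rest <- toks[-1]
  if (kind %in% c("WGD", "WGT")) return(karyo_event(kind))
  if (kind == "EEJ") {
    if (length(rest) != 2) abort(paste0("EEJ needs 2 operands: ", line),
                                 class = "wgdtrace_parse_error")
    pa <- strsplit(rest[1], ":", fixed = TRUE)[[1]]
    pb <- strsplit(rest[2], ":", fixed = TRUE)[[1]]
    return(karyo_event("EEJ", chrom_a = pa[1], chrom_b = pb[1],
                       end_a = if (length(pa) > 1) pa[2] else "end",
                       end_b = if (length(pb) > 1) pb[2] else "start"))
  }
  if (kind == "NCF") {
    kv <- setNames(sub("^[^=]*=", "", rest), sub("=.*$", "", rest))
    return(karyo_event("NCF", host = unname(kv["host"]),
                       donor = unname(kv["donor"]),
                       pos = if ("pos" %in% names(kv)) as.numeric(kv["pos"]) else 0.5))
  }
  if (kind == "XO") {
    if (length(rest) != 2) abort(paste0("XO needs 2 operands: ", line),
                                 class = "wgdtrace_parse_error")
    pa <- strsplit(rest[1], "@", fixed = TRUE)[[1]]
    pb <- strsplit(rest[2], "@", fixed = TRUE)[[1]]
    return(karyo_event("XO", chrom_a = pa[1], pos_a = as.numeric(pa[2]),
                       chrom_b = pb[1], pos_b = as.numeric(pb[2])))
  }
  if (kind == "IV") {
    pa <- strsplit(rest[1], "@", fixed = TRUE)[[1]]
    iv <- as.numeric(strsplit(pa[2], "-", fixed = TRUE)[[1]])
    return(karyo_event("IV", chrom = pa[1], from = iv[1], to = iv[2]))
  }
  abort(paste0("unparseable event line: ", line), class = "wgdtrace_parse_error")
}

#' Parse an event script
#'
#' One event per line: `EEJ chr3 chr7`, `NCF host=chr2 donor=chr5 pos=0.5`,
#' `XO chr1@0.4 chr6@0.7`, `IV chr4@0.2-0.6`, `WGD`, `WGT`. Blank lines and
#' `#` comments are ignored.
#'
#' @param lines Character vector of script lines, or a single path to a
#'   script file.
#' @return List of `karyo_event` objects.
#' @export
parse_event_script <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_event_line)
}

#' Apply an ordered event script to a karyotype
#'
#' @param k A `karyotype`.
#' @param events List of `karyo_event`s (from [karyo_event()] or
#'   [parse_event_script()]), or a character vector of DSL lines.
#' @return A list with `karyotype` (final state) and `log`, a tibble with one
#'   row per step (`step`, `kind`, `n_chromosomes` after the step).
#' @export
run_script <- function(k, events) {
  if (is.character(events)) events <- parse_event_script(events)
  log <- vector("list", length(events))
  for (i in seq_along(events)) {
    k <- tryCatch(apply_event(k, events[[i]]), error = function(cnd) {
      abort(paste0("event script failed at step ", i, " (",
                   events[[i]]$kind, "): ", conditionMessage(cnd)),
            class = "wgdtrace_script_error")
    })
    log[[i]] <- tibble(step = i, kind = events[[i]]$kind,
                       n_chromosomes = n_chromosomes(k))
  }
  list(karyotype = k, log = bind_rows(log))
}

# ---- dot-plot projection ---------------------------------------------------

#' Predicted dot-plot tracts between two labelled karyotypes
#'
#' Every pair of segments sharing an ancestral chromosome with overlapping
#' spans yields one homologous tract — the block structure a dot plot of the
#' two genomes would show.
#'
#' @param k1,k2 `karyotype` objects labelled against the same ancestral set.
#' @return Tibble with one row per tract: `chrom1`, `lo1`, `hi1`, `chrom2`,
#'   `lo2`, `hi2`, `ancestral_chrom`, `orientation` (product of the two
#'   segment orientations).
#' @export
expected_dotplot <- function(k1, k2) {
  t1 <- as_tibble(k1)
  t2 <- as_tibble(k2)
  shared <- intersect(unique(t1$ancestral_chrom), unique(t2$ancestral_chrom))
  if (length(shared) == 0) {
    warn("karyotypes share no ancestral chromosome labels")
    return(tibble(chrom1 = character(), lo1 = double(), hi1 = double(),
                  chrom2 = character(), lo2 = double(), hi2 = double(),
                  ancestral_chrom = character(), orientation = integer()))
  }
  inner_join(t1, t2, by = "ancestral_chrom", suffix = c("1", "2"),
             relationship = "many-to-many") |>
    filter(pmin(.data$span_hi1, .data$span_hi2) -
             pmax(.data$span_lo1, .data$span_lo2) > 1e-12) |>
    mutate(lo = pmax(.data$span_lo1, .data$span_lo2),
           hi = pmin(.data$span_hi1, .data$span_hi2),
           orientation = as.integer(.data$orientation1 * .data$orientation2)) |>
    transmute(chrom1 = .data$chrom1, lo1 = .data$lo, hi1 = .data$hi,
              chrom2 = .data$chrom2, lo2 = .data$lo, hi2 = .data$hi,
              ancestral_chrom = .data$ancestral_chrom,
              orientation = .data$orientation)
}

# ---- fusion timing ----------------------------------------------------------

# collapse consecutive same-ancestor segments, then list junctions between
# distinct ancestral chromosomes
chrom_adjacencies <- function(segs, chrom_name) {
  anc <- segs$ancestral_chrom
  anc <- anc[c(TRUE, anc[-1] != anc[-length(anc)])]
  if (length(anc) < 2) return(NULL)
  tibble(chrom = chrom_name, left = anc[-length(anc)], right = anc[-1]) |>
    filter(.data$left != .data$right)
}

#' Infer whether chromosome fusions predate or postdate a WGD
#'
#' A junction between two distinct ancestral chromosomes that was formed
#' before a WGD is inherited by every duplicated copy, so it appears in two
#' (or more) chromosomes of the post-WGD karyotype; a junction formed after
#' the WGD appears in exactly one. Junctions seen once whose two flanking
#' ancestral chromosomes both also occur in other heterologous junctions are
#' flagged `possibly_disrupted`: this is the signature left when a later
#' crossover breaks one copy of a pre-WGD junction, and the copy-count rule
#' cannot then distinguish the two histories.
#'
#' @param post_wgd `karyotype` derived from `ancestor` through at least one
#'   WGD/WGT plus fusions.
#' @param ancestor The pre-event `karyotype` (used to validate the label set).
#' @return Tibble with one row per distinct junction: `anc_a`, `anc_b`
#'   (canonical order), `n_copies` (chromosomes carrying it), `timing`
#'   (`"pre_wgd"` or `"post_wgd"`), `possibly_disrupted`.
#' @export
infer_fusion_timing <- function(post_wgd, ancestor) {
  stopifnot(inherits(post_wgd, "karyotype"), inherits(ancestor, "karyotype"))
  if (post_wgd$n_wgd < 1L) {
    abort("fusion-timing rule needs at least one WGD in the karyotype history",
          class = "wgdtrace_validation_error")
  }
  anc_labels <- unique(as_tibble(ancestor)$ancestral_chrom)
  post_labels <- unique(as_tibble(post_wgd)$ancestral_chrom)
  if (!all(post_labels %in% anc_labels)) {
    abort("post-WGD karyotype carries ancestral labels absent from the ancestor",
          class = "wgdtrace_validation_error")
  }
  adj <- purrr::imap(post_wgd$chromosomes, chrom_adjacencies) |> bind_rows()
  if (nrow(adj) == 0) {
    return(tibble(anc_a = character(), anc_b = character(),
                  n_copies = integer(), timing = character(),
                  possibly_disrupted = logical()))
  }
  # canonical reversal-invariant junction key
  adj <- adj |>
    mutate(anc_a = pmin(.data$left, .data$right),
           anc_b = pmax(.data$left, .data$right))
  counts <- adj |>
    distinct(.data$chrom, .data$anc_a, .data$anc_b) |>
    count(.data$anc_a, .data$anc_b, name = "n_copies")
  junction_partners <- counts |>
    tidyr::pivot_longer(c("anc_a", "anc_b"), values_to = "anc") |>
    count(.data$anc, name = "n_junctions")
  counts |>
    mutate(timing = ifelse(.data$n_copies >= 2L, "pre_wgd", "post_wgd"),
           possibly_disrupted = .data$n_copies == 1L &
             .data$anc_a %in% junction_partners$anc[junction_partners$n_junctions > 1] &
             .data$anc_b %in% junction_partners$anc[junction_partners$n_junctions > 1]) |>
    arrange(.data$anc_a, .data$anc_b)
}
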