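span_multiset <- function(k) {
  as_tibble(k) |>
    dplyr::select(ancestral_chrom, span_lo, span_hi) |>
    dplyr::arrange(ancestral_chrom, span_lo, span_hi)
}

# merge abutting spans per ancestral chromosome and total their length
span_coverage <- function(k) {
  as_tibble(k) |>
    dplyr::group_by(ancestral_chrom) |>
    dplyr::summarise(total = sum(span_hi - span_lo), .groups = "drop")
}

test_that("EEJ concatenates, decrements the count, and records a satellite", {
  k <- karyotype(c("A", "B", "C"))
  k2 <- apply_event(k, karyo_event("EEJ", chrom_a = "A", chrom_b = "B"))
  expect_equal(n_chromosomes(k2), 2)
  expect_equal(nrow(k2$chromosomes[["A"]]), 2)
  expect_equal(k2$chromosomes[["A"]]$ancestral_chrom, c("A", "B"))
  expect_equal(nrow(k2$satellites), 1)
  expect_error(apply_event(k, karyo_event("EEJ", chrom_a = "A", chrom_b = "A")),
               class = "wgdtrace_validation_error")
})

test_that("EEJ honours chosen ends by flipping the joined chromosomes", {
  k <- karyotype(c("A", "B"))
  k2 <- apply_event(k, karyo_event("EEJ", chrom_a = "A", chrom_b = "B",
                                   end_a = "start", end_b = "end"))
  segs <- k2$chromosomes[["A"]]
  expect_equal(segs$ancestral_chrom, c("A", "B"))
  expect_equal(segs$orientation, c(-1L, -1L))
})

test_that("WGD duplicates every span exactly twice", {
  k <- karyotype(paste0("c", 1:10))
  k2 <- apply_event(k, karyo_event("WGD"))
  expect_equal(n_chromosomes(k2), 20)
  cov <- span_coverage(k2)
  expect_true(all(cov$total == 2))
  expect_equal(k2$n_wgd, 1L)
})

test_that("XO conserves chromosome count and segment content", {
  k <- karyotype(c("A", "B"))
  k2 <- apply_event(k, karyo_event("XO", chrom_a = "A", pos_a = 0.4,
                                   chrom_b = "B", pos_b = 0.7))
  expect_equal(n_chromosomes(k2), 2)
  expect_equal(span_multiset(k2),
               tibble::tibble(ancestral_chrom = c("A", "A", "B", "B"),
                              span_lo = c(0, 0.4, 0, 0.7),
                              span_hi = c(0.4, 1, 0.7, 1)))
  expect_equal(k2$chromosomes[["A"]]$ancestral_chrom, c("A", "B"))
  expect_error(apply_event(k, karyo_event("XO", chrom_a = "A", pos_a = 0,
                                          chrom_b = "B", pos_b = 0.5)),
               class = "wgdtrace_validation_error")
})

test_that("NCF nests the donor inside the host", {
  k <- karyotype(c("H", "D", "X"))
  k2 <- apply_event(k, karyo_event("NCF", host = "H", donor = "D", pos = 0.5))
  expect_equal(n_chromosomes(k2), 2)
  expect_equal(k2$chromosomes[["H"]]$ancestral_chrom, c("H", "D", "H"))
  expect_equal(nrow(k2$satellites), 1)
})

test_that("inversion applied twice on the same interval is the identity", {
  k <- karyotype(c("A", "B"))
  k <- apply_event(k, karyo_event("XO", chrom_a = "A", pos_a = 0.5,
                                  chrom_b = "B", pos_b = 0.5))
  iv <- karyo_event("IV", chrom = "A", from = 0.2, to = 0.8)
  k1 <- apply_event(k, iv)
  k2 <- apply_event(k1, iv)
  expect_equal(span_multiset(k2), span_multiset(k))
  expect_equal(as_tibble(k2)$orientation, as_tibble(k)$orientation)
  expect_false(identical(as_tibble(k1), as_tibble(k)))
})

test_that("chromosome-count algebra holds on random event scripts", {
  set.seed(101)
  for (rep in 1:5) {
    k <- karyotype(paste0("c", 1:8))
    n_fusions <- 0L
    for (step in 1:12) {
      nms <- names(k$chromosomes)
      kind <- sample(c("EEJ", "NCF", "XO", "IV"), 1)
      if (length(nms) < 2) kind <- "IV"
      before <- n_chromosomes(k)
      ev <- switch(kind,
        EEJ = { ops <- sample(nms, 2)
                karyo_event("EEJ", chrom_a = ops[1], chrom_b = ops[2]) },
        NCF = { ops <- sample(nms, 2)
                karyo_event("NCF", host = ops[1], donor = ops[2],
                            pos = runif(1, 0.2, 0.8)) },
        XO  = { ops <- sample(nms, 2)
                karyo_event("XO", chrom_a = ops[1], pos_a = runif(1, 0.1, 0.9),
                            chrom_b = ops[2], pos_b = runif(1, 0.1, 0.9)) },
        IV  = karyo_event("IV", chrom = sample(nms, 1), from = 0.2, to = 0.7))
      k <- apply_event(k, ev)
      delta <- n_chromosomes(k) - before
      if (ev$kind %in% c("EEJ", "NCF")) {
        expect_equal(delta, -1L)
        n_fusions <- n_fusions + 1L
      } else {
        expect_equal(delta, 0L)
      }
      # content conservation: every ancestral unit interval covered once
      cov <- span_coverage(k)
      expect_equal(cov$total, rep(1, 8), tolerance = 1e-9)
    }
    expect_equal(nrow(k$satellites), n_fusions)
    k2 <- apply_event(k, karyo_event("WGD"))
    expect_equal(n_chromosomes(k2), 2 * n_chromosomes(k))
    k3 <- apply_event(k, karyo_event("WGT"))
    expect_equal(n_chromosomes(k3), 3 * n_chromosomes(k))
  }
})

test_that("event scripts reproduce the published trajectory arithmetic", {
  # 21 post-hexaploidy chromosomes: 9 EEJ + 2 NCF + 6 XO -> 10
  k21 <- karyotype(c(paste0("A", 1:7), paste0("B", 1:7), paste0("C", 1:7)))
  script1 <- c(
    "EEJ A1 A2", "EEJ A3 A4", "EEJ A5 A6", "EEJ A7 B1", "EEJ B2 B3",
    "EEJ B4 B5", "EEJ B6 B7", "EEJ C1 C2", "EEJ C3 C4",
    "NCF host=C5 donor=C6", "NCF host=C7 donor=A1",
    "XO A3@0.5 A5@0.5", "XO A7@0.3 B2@0.6", "XO B4@0.4 B6@0.4",
    "XO C1@0.5 C3@0.5", "XO C5@0.5 C7@0.2", "XO A3@0.2 B2@0.8")
  res1 <- run_script(k21, script1)
  expect_equal(n_chromosomes(res1$karyotype), 10)
  expect_equal(nrow(res1$karyotype$satellites), 11)

  # 20 post-WGD chromosomes: 10 EEJ + 11 XO -> 10
  k10 <- karyotype(paste0("b", 1:10))
  k20 <- apply_event(k10, karyo_event("WGD"))
  expect_equal(n_chromosomes(k20), 20)
  nms <- names(k20$chromosomes)
  script2 <- c(sprintf("EEJ %s %s", nms[seq(1, 20, 2)], nms[seq(2, 20, 2)]),
               sprintf("XO %s@0.4 %s@0.6", nms[seq(1, 20, 2)][1:11 %% 10 + 1],
                       nms[seq(1, 20, 2)][(3:13) %% 10 + 1]))
  expect_length(script2, 21)
  res2 <- run_script(k20, script2)
  expect_equal(n_chromosomes(res2$karyotype), 10)

  # 20 post-WGD chromosomes: 2 XO + 1 EEJ -> 19
  k20b <- apply_event(karyotype(paste0("a", 1:10)), karyo_event("WGD"))
  nmsb <- names(k20b$chromosomes)
  script3 <- c(sprintf("XO %s@0.5 %s@0.5", nmsb[1], nmsb[3]),
               sprintf("XO %s@0.4 %s@0.6", nmsb[5], nmsb[7]),
               sprintf("EEJ %s %s", nmsb[9], nmsb[11]))
  res3 <- run_script(k20b, script3)
  expect_equal(n_chromosomes(res3$karyotype), 19)

  # triplication of the 7 pre-hexaploidy chromosomes -> 21
  k7 <- karyotype(paste0("E", 1:7))
  expect_equal(n_chromosomes(apply_event(k7, karyo_event("WGT"))), 21)
})

test_that("a failing script step aborts with its index", {
  k <- karyotype(c("A", "B"))
  expect_error(run_script(k, c("EEJ A B", "EEJ A nope")),
               "step 2", class = "wgdtrace_script_error")
})

test_that("expected_dotplot projects homologous tracts", {
  k <- karyotype(c("A", "B", "C"))
  self <- expected_dotplot(k, k)
  expect_equal(nrow(self), 3)
  expect_true(all(self$lo1 == 0 & self$hi1 == 1))

  k2 <- apply_event(k, karyo_event("WGD"))
  dp <- expected_dotplot(k, k2)
  expect_equal(nrow(dp), 6)
  expect_equal(unname(table(dp$chrom1)), rep(2L, 3), ignore_attr = TRUE)

  # EEJ of two duplicated copies: the junction shows as two tracts meeting
  # on one fused chromosome
  k3 <- apply_event(k2, karyo_event("EEJ", chrom_a = "Aa", chrom_b = "Ba"))
  dp3 <- expected_dotplot(k, k3)
  fused <- dp3 |> dplyr::filter(chrom2 == "Aa")
  expect_equal(sort(fused$ancestral_chrom), c("A", "B"))

  expect_warning(out <- expected_dotplot(k, karyotype(c("Z1", "Z2"))),
                 "no ancestral")
  expect_equal(nrow(out), 0)
})

test_that("fusion timing is classified by junction copy number", {
  anc <- karyotype(c("A", "B", "C", "D"))
  pre <- apply_event(anc, "EEJ A B")
  both <- apply_event(pre, "WGD")
  post <- apply_event(both, "EEJ Ca Da")
  timing <- infer_fusion_timing(post, anc)
  expect_equal(timing$timing[timing$anc_a == "A"], "pre_wgd")
  expect_equal(timing$n_copies[timing$anc_a == "A"], 2L)
  expect_equal(timing$timing[timing$anc_a == "C"], "post_wgd")
  expect_false(any(timing$possibly_disrupted))

  # breaking one copy of the pre-WGD junction leaves a flagged single-copy
  # junction instead of a silent misclassification
  broken <- apply_event(post, karyo_event("XO", chrom_a = "Ab", pos_a = 0.5,
                                          chrom_b = "Cb", pos_b = 0.5))
  t2 <- infer_fusion_timing(broken, anc)
  ab <- t2 |> dplyr::filter(anc_a == "A", anc_b == "B")
  expect_equal(ab$n_copies, 1L)
  expect_true(ab$possibly_disrupted)

  expect_error(infer_fusion_timing(pre, anc),
               class = "wgdtrace_validation_error")
})

test_that("random engine-generated fusion histories classify perfectly", {
  set.seed(202)
  for (rep in 1:5) {
    labels <- paste0("c", 1:8)
    anc <- karyotype(labels)
    k <- anc
    pre_pairs <- list(c("c1", "c2"), c("c3", "c4"))
    for (p in pre_pairs) {
      k <- apply_event(k, karyo_event("EEJ", chrom_a = p[1], chrom_b = p[2]))
    }
    k <- apply_event(k, karyo_event("WGD"))
    post_pairs <- list(c("c5a", "c6a"), c("c7b", "c8b"))
    for (p in post_pairs) {
      k <- apply_event(k, karyo_event("EEJ", chrom_a = p[1], chrom_b = p[2]))
    }
    timing <- infer_fusion_timing(k, anc)
    expect_equal(nrow(timing), 4)
    got_pre <- timing |> dplyr::filter(timing == "pre_wgd")
    expect_setequal(paste(got_pre$anc_a, got_pre$anc_b),
                    c("c1 c2", "c3 c4"))
    got_post <- timing |> dplyr::filter(timing == "post_wgd")
    expect_setequal(paste(got_post$anc_a, got_post$anc_b),
                    c("c5 c6", "c7 c8"))
  }
})

test_that("the event DSL parses and rejects malformed lines", {
  evs <- parse_event_script(c("# header", "", "EEJ chr3 chr7",
                              "NCF host=chr2 donor=chr5 pos=0.5",
                              "XO chr1@0.4 chr6@0.7", "IV chr4@0.2-0.6",
                              "WGD", "WGT"))
  expect_length(evs, 6)
  expect_equal(vapply(evs, function(e) e$kind, character(1)),
               c("EEJ", "NCF", "XO", "IV", "WGD", "WGT"))
  expect_equal(evs[[3]]$pos_a, 0.4)
  expect_equal(evs[[4]]$from, 0.2)
  expect_error(parse_event_script("FUSE a b"), class = "wgdtrace_parse_error")
  expect_error(parse_event_script("EEJ onlyone"), class = "wgdtrace_parse_error")
})
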