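utr_model <- function(utr) {
  cds <- paste0("ATG", strrep("GCA", 18), "TAA")
  transcript_models("t1", "g1", nchar(utr) + nchar(cds),
                    nchar(utr), nchar(utr) + nchar(cds),
                    paste0(utr, cds))
}

test_that("constructed start-stop and elongating uORFs are found", {
  # AUG immediately followed by a stop: a 1-aa (start-stop) uORF
  m <- utr_model("AAATGTAAGG")
  u <- find_candidate_uorfs(m)
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 2L)
  expect_equal(u$n_sense_codons, 1L)
  expect_equal(u$stop_end - u$start, 6L)

  # no in-frame stop before the CDS -> no uORF from that start
  m2 <- utr_model("CCATGGCCCCC")
  expect_equal(nrow(find_candidate_uorfs(m2)), 0L)

  # UTR too short to host any uORF
  m3 <- utr_model("AAA")
  expect_equal(nrow(find_candidate_uorfs(m3)), 0L)
})

test_that("scanner equals the exhaustive brute-force oracle on random UTRs", {
  set.seed(14)
  for (r in 1:60) {
    utr_len <- sample(6:300, 1)
    m <- random_tx_with_utr(utr_len)
    got <- find_candidate_uorfs(m)
    want <- oracle_uorf_scan(m$sequence, m$cds_start)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$stop_end, want$stop_end)
      expect_equal(got$start_codon, want$start_codon)
      expect_equal(got$n_sense_codons, as.integer(want$n_sense_codons))
      # structural invariants
      expect_true(all(got$stop_end <= m$cds_start))
      expect_equal(got$stop_end - got$start, 3L * (got$n_sense_codons + 1L))
      stops <- substr(rep(m$sequence, nrow(got)), got$stop_end - 2,
                      got$stop_end)
      expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("coverage is breadth, density is count per nt, and 33% calls translation", {
  m <- utr_model("AAATGTAAGG")
  u <- find_candidate_uorfs(m)
  # 2 of 6 positions covered (one position twice): breadth 1/3 -> translated
  a <- make_asites("t1", c(2L, 2L, 5L))
  s <- score_and_call(u, a)
  expect_equal(s$coverage, 2 / 6)
  expect_equal(s$density, 3 / 6)
  expect_true(s$translated)
  # no A-sites: coverage 0, not translated
  s0 <- score_and_call(u, make_asites("t1", integer(0)))
  expect_equal(s0$coverage, 0)
  expect_false(s0$translated)
  # all positions covered
  s1 <- score_and_call(u, make_asites("t1", 2:7))
  expect_equal(s1$coverage, 1)
  # density rule option
  sd <- score_and_call(u, a, rule = "density")
  expect_true(sd$translated)
})

test_that("overlap resolution keeps the densest candidate greedily", {
  u <- data.frame(
    transcript_id = "t", start = c(0L, 4L), stop_end = c(9L, 13L),
    start_codon = c("AUG", "CUG"), n_sense_codons = c(2L, 2L),
    density = c(0.8, 0.3), stringsAsFactors = FALSE
  )
  kept <- resolve_overlaps(u)
  expect_equal(kept$start, 0L)

  # disjoint candidates all survive
  u2 <- u; u2$start <- c(0L, 20L); u2$stop_end <- c(9L, 29L)
  expect_equal(nrow(resolve_overlaps(u2)), 2L)

  # chain A-B, B-C overlapping, A-C disjoint, densities 5/9/1: B wins alone
  u3 <- data.frame(
    transcript_id = "t", start = c(0L, 6L, 15L),
    stop_end = c(9L, 18L, 24L),
    start_codon = "AUG", n_sense_codons = 2L,
    density = c(5, 9, 1), stringsAsFactors = FALSE
  )
  kept3 <- resolve_overlaps(u3)
  expect_equal(kept3$start, 6L)

  # tie broken by 5'-most start then start-codon strength
  u4 <- data.frame(
    transcript_id = "t", start = c(3L, 0L), stop_end = c(12L, 9L),
    start_codon = c("AUG", "AUG"), n_sense_codons = 2L,
    density = c(1, 1), stringsAsFactors = FALSE
  )
  expect_equal(resolve_overlaps(u4)$start, 0L)
  # output never contains overlapping pairs
  set.seed(8)
  for (r in 1:20) {
    n <- 12
    st <- sample(0:60, n, replace = TRUE)
    u5 <- data.frame(transcript_id = "t", start = st,
                     stop_end = st + 3L * sample(2:5, n, replace = TRUE),
                     start_codon = sample(c("AUG", "CUG"), n, TRUE),
                     n_sense_codons = 1L,
                     density = runif(n), stringsAsFactors = FALSE)
    k <- resolve_overlaps(u5)
    if (nrow(k) > 1) {
      for (i in seq_len(nrow(k) - 1))
        expect_true(all(k$start[(i + 1):nrow(k)] >= k$stop_end[i] |
                          k$stop_end[(i + 1):nrow(k)] <= k$start[i]))
    }
  }
})

test_that("penultimate codon and Kozak +4 annotation match the uORF structure", {
  # elongating uORF ending ...GUG UAG (hand-built sequence)
  utr <- paste0("CC", "ATG", "GCA", "GTG", "TAG", "AAAA")
  m <- utr_model(utr)
  u <- find_candidate_uorfs(m)
  u <- u[u$start == 2L, , drop = FALSE]
  ann <- annotate_context(u, m)
  expect_equal(ann$penultimate_codon, "GUG")
  expect_equal(ann$kozak_plus4, "G")

  # start-stop uORF: no penultimate codon, +4 is the stop's U
  m2 <- utr_model("AAATGTGAGG")
  u2 <- find_candidate_uorfs(m2)
  ann2 <- annotate_context(u2[u2$start == 2L, , drop = FALSE], m2)
  expect_true(is.na(ann2$penultimate_codon))
  expect_equal(ann2$kozak_plus4, "U")

  # AUG GCG UAA -> penultimate GCG
  m3 <- utr_model(paste0("T", "ATG", "GCG", "TAA", "CCCC"))
  u3 <- find_candidate_uorfs(m3)
  ann3 <- annotate_context(u3[u3$start == 1L, , drop = FALSE], m3)
  expect_equal(ann3$penultimate_codon, "GCG")
})

test_that("transcript classification distinguishes translated/candidate/no uORF", {
  models <- transcript_models(c("a", "b", "c"), "g", 100, 30, 90)
  uorfs <- data.frame(
    transcript_id = c("a", "a", "b"), start = c(0L, 10L, 5L),
    stop_end = c(6L, 16L, 11L), start_codon = "AUG",
    n_sense_codons = 1L, translated = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  cls <- classify_transcripts(models, uorfs)
  expect_equal(unname(cls[c("a", "b", "c")]),
               c("translated_uORF", "untranslated_uORF_only", "no_uORF"))
})

test_that("enrichment test agrees with Fisher's exact test", {
  # translated-vs-rest collapse on the published count layout
  r <- uorf_enrichment_test(c(5, 2, 1), c(20, 20, 20))
  f <- fisher.test(rbind(c(5, 3), c(15, 37)))
  expect_equal(r$p_value, f$p.value, tolerance = 1e-12)
  # full 2 x 3 homogeneity, exact, against fisher.test
  r3 <- uorf_enrichment_test(c(5, 2, 1), c(20, 20, 20), collapse = "none")
  f3 <- fisher.test(rbind(c(5, 2, 1), c(15, 18, 19)))
  expect_equal(r3$p_value, f3$p.value, tolerance = 1e-12)
  # homogeneous table -> p ~ 1
  rh <- uorf_enrichment_test(c(10, 10, 10), c(100, 100, 100),
                             collapse = "none")
  expect_gt(rh$p_value, 0.95)
  expect_error(uorf_enrichment_test(c(-1, 0, 0), c(5, 5, 5)), "negative")
  expect_error(uorf_enrichment_test(c(6, 0, 0), c(5, 5, 5)), "exceed")
})

test_that("Monte Carlo enrichment p matches exact enumeration within MC error", {
  sub <- c(8, 3, 2); bg <- c(40, 45, 50)
  ex <- uorf_enrichment_test(sub, bg, method = "exact", collapse = "none")
  mc <- uorf_enrichment_test(sub, bg, method = "montecarlo", n_mc = 2e4,
                             seed = 7, collapse = "none")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 2e4)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 1e-4)
})

test_that("5'UTR length comparison reports medians and detects shifts", {
  set.seed(2)
  bg <- rlnorm(200, log(150), 0.5)
  r0 <- utr_length_comparison(bg, bg)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$median_subset, median(bg))
  shifted <- rlnorm(200, log(150), 0.5) + 100
  r1 <- utr_length_comparison(shifted, bg)
  expect_lt(r1$p_value, 0.01)
  expect_gt(r1$median_subset, r1$median_background)
  expect_error(utr_length_comparison(1:3, bg), "at least 5")
})

test_that("mean translated uORFs per UTR averages over qualifying transcripts", {
  models <- transcript_models(c("a", "b", "c", "d"), "g", 100, 30, 90)
  uorfs <- data.frame(
    transcript_id = c("a", "b", "b", "c", "c", "c"),
    start = 0L, stop_end = 6L, start_codon = "AUG", n_sense_codons = 1L,
    translated = TRUE, stringsAsFactors = FALSE
  )
  expect_equal(uorfs_per_utr(models, uorfs), 2)
  one <- uorfs[rep(1, 4), ]; one$transcript_id <- "a"
  expect_equal(uorfs_per_utr(models, one), 4)
  none <- uorfs; none$translated <- FALSE
  expect_warning(v <- uorfs_per_utr(models, none), "no transcript")
  expect_true(is.nan(v))
})
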