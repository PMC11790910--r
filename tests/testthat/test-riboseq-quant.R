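test_that("size filter keeps 26-35 nt footprints and 21-60 nt RNA reads, inclusive", {
  reads <- data.frame(
    transcript_id = "t", five_prime_pos = 0L,
    read_length = c(25, 26, 35, 36, 20, 21, 60, 61),
    assay = rep(c("RPF", "RNA"), each = 4),
    sample_id = "s", stringsAsFactors = FALSE
  )
  kept <- size_filter(reads)
  expect_equal(kept$read_length, c(26, 35, 21, 60))
  expect_identical(size_filter(reads[0, ]), reads[0, ])
})

test_that("A-site offset is +16 up to 31 nt and +17 above", {
  reads <- data.frame(transcript_id = "t",
                      five_prime_pos = c(100L, 100L, 0L),
                      read_length = c(31L, 32L, 26L),
                      assay = "RPF", sample_id = "s",
                      stringsAsFactors = FALSE)
  a <- assign_asite(reads)
  expect_equal(a$position, c(116L, 117L, 16L))
  # positions past the transcript end are dropped and counted
  m <- transcript_models("t", "g", 117, 0, 117, complete = FALSE)
  a2 <- assign_asite(reads, m)
  expect_equal(nrow(a2), 2L)
  expect_equal(attr(a2, "n_dropped"), 1L)
})

test_that("region counting respects the CDS boundaries", {
  m <- transcript_models("t", "g", 200, 20, 170)
  a <- make_asites("t", c(19L, 20L, 169L, 170L, 199L))
  rc <- count_regions(a, m)
  expect_equal(unname(rc$counts[1, grepl("UTR5", colnames(rc$counts))]), 1L)
  expect_equal(unname(rc$counts[1, grepl("CDS", colnames(rc$counts))]), 2L)
})

test_that("random A-sites classify exactly as per-position brute force", {
  set.seed(5)
  m <- transcript_models("t", "g", 300, 45, 255)
  pos <- sample(0:299, 1000, replace = TRUE)
  rc <- count_regions(make_asites("t", pos), m)
  expect_equal(sum(rc$counts), sum(pos < 255))
  expect_equal(unname(rc$counts[1, grepl("UTR5", colnames(rc$counts))]),
               sum(pos < 45))
  # every A-site lands in exactly one of UTR5 / CDS / uncounted 3'UTR
  expect_equal(sum(rc$counts) + sum(pos >= 255), length(pos))
})

test_that("low-count filter removes transcripts under the total threshold", {
  m <- transcript_models(c("a", "b", "c"), "g", 100, 20, 80)
  counts <- matrix(c(4L, 5L, 5L, 5L, 6L, 5L), nrow = 3,
                   dimnames = list(c("a", "b", "c"), NULL))
  rc <- structure(list(
    counts = counts,
    cols = data.frame(sample_id = c("s1", "s1"), assay = "RPF",
                      region = c("UTR5", "CDS"))), class = "region_counts")
  colnames(rc$counts) <- paste(rc$cols$sample_id, rc$cols$assay,
                               rc$cols$region, sep = ".")
  kept <- filter_low_counts(rc, 10L)
  expect_setequal(rownames(kept$counts), c("b", "c"))  # totals 9,10,11
  expect_equal(nrow(filter_low_counts(rc, 0L)$counts), 3L)
  rc$counts[] <- 0L
  expect_equal(nrow(filter_low_counts(rc, 10L)$counts), 0L)
})

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(1)
  x <- matrix(rnbinom(200, mu = 100, size = 5), ncol = 2)
  same <- cbind(x[, 1], x[, 1])
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  scaled <- cbind(x[, 1], 2L * x[, 1])
  expect_equal(unname(tmm_factors(scaled)), c(1, 1))
  expect_error(tmm_factors(cbind(x[, 1], 0L * x[, 1])), "zero")
})

test_that("TMM matches the direct definition on perturbed instances", {
  set.seed(42)
  for (r in 1:10) {
    x <- matrix(rnbinom(20 * 3, mu = 200, size = 10), ncol = 3)
    infl <- sample(20, 2)
    x[infl, 2] <- x[infl, 2] * 10L
    expect_equal(unname(tmm_factors(x)), unname(oracle_tmm(x)),
                 tolerance = 1e-12)
  }
})

test_that("TPM columns conserve 1e6 and scale with length", {
  m <- transcript_models(c("a", "b"), "g", c(120, 240), c(30, 60),
                         c(120, 240))
  counts <- matrix(c(0L, 0L, 50L, 50L, 0L, 0L, 80L, 80L), nrow = 2,
                   byrow = FALSE)
  cols <- expand.grid(region = c("UTR5", "CDS"), sample_id = c("s1", "s2"),
                      stringsAsFactors = FALSE)
  cols$assay <- "RNA"
  cols <- cols[, c("sample_id", "assay", "region")]
  rownames(counts) <- c("a", "b")
  colnames(counts) <- paste(cols$sample_id, cols$assay, cols$region, sep = ".")
  rc <- structure(list(counts = counts, cols = cols), class = "region_counts")
  ne <- tpm_transform(rc, m, factors = c(s1.RNA = 1, s2.RNA = 1))
  key <- paste(ne$cols$sample_id, ne$cols$assay, sep = ".")
  for (k in unique(key))
    expect_equal(sum(ne$tpm[, key == k]), 1e6)
  # equal counts on CDS regions of length 90 and 180 -> TPM ratio 2:1
  cds_cols <- which(ne$cols$region == "CDS" & ne$cols$sample_id == "s1")
  expect_equal(ne$tpm["a", cds_cols] / ne$tpm["b", cds_cols], 2)
})

test_that("random TPM instances conserve the per-sample total", {
  set.seed(9)
  cfg <- sim_config(n_genes = 50, seed = 9)
  sim <- simulate_transcriptome(cfg, sequences = FALSE)
  out <- simulate_counts(cfg, sim$models, sim$truth, reads = FALSE)
  rc <- filter_low_counts(out$counts, 10L)
  ne <- tpm_transform(rc, sim$models)
  key <- paste(ne$cols$sample_id, ne$cols$assay, sep = ".")
  sums <- vapply(unique(key), function(k) sum(ne$tpm[, key == k]),
                 numeric(1))
  expect_true(all(abs(sums - 1e6) < 1))
})

make_norm <- function(tpm, cols) {
  structure(list(tpm = tpm, cols = cols, factors = NULL),
            class = "norm_expr")
}

test_that("translation efficiency is the replicate-mean log2 RPF/RNA ratio", {
  cols <- data.frame(
    sample_id = c("c_RPF_1", "c_RNA_1", "c_RPF_2", "c_RNA_2"),
    assay = c("RPF", "RNA", "RPF", "RNA"),
    region = "CDS", condition = "control", replicate = c(1, 1, 2, 2),
    stringsAsFactors = FALSE
  )
  tpm <- matrix(c(100, 50, 400, 100), nrow = 1,
                dimnames = list("t", NULL))
  te <- compute_te(make_norm(tpm, cols))
  expect_equal(te$te_log2, mean(c(log2(100 / 50), log2(400 / 100))))
  # zero in one replicate excludes the transcript and reports it
  tpm2 <- rbind(tpm, c(0, 50, 10, 10))
  rownames(tpm2) <- c("t", "z")
  te2 <- compute_te(make_norm(tpm2, cols))
  expect_equal(te2$transcript_id, "t")
  expect_equal(attr(te2, "excluded")$control, "z")
})

test_that("TE is invariant to a common factor on RPF and RNA counts", {
  cols <- data.frame(
    sample_id = c("a", "b"), assay = c("RPF", "RNA"), region = "CDS",
    condition = "c", replicate = 1, stringsAsFactors = FALSE
  )
  tpm <- matrix(c(80, 40), nrow = 1, dimnames = list("t", NULL))
  te1 <- compute_te(make_norm(tpm, cols))$te_log2
  te2 <- compute_te(make_norm(tpm * 7, cols))$te_log2
  expect_equal(te1, te2)
})

test_that("UTR/CDS shift is zero for identical conditions and antisymmetric", {
  set.seed(3)
  n <- 30
  u <- runif(n, 1, 10); cc <- runif(n, 10, 100)
  u2 <- u * 2^runif(n, -1, 1)
  cols <- expand.grid(region = c("UTR5", "CDS"),
                      condition = c("control", "kd"),
                      stringsAsFactors = FALSE)
  cols$sample_id <- paste0(cols$condition, "_RPF_1")
  cols$assay <- "RPF"; cols$replicate <- 1
  tpm <- cbind(u, cc, u2, cc)
  rownames(tpm) <- paste0("t", seq_len(n))
  ne <- make_norm(tpm, cols)
  same <- make_norm(cbind(u, cc, u, cc), cols)
  s0 <- utr_cds_shift(same, "kd", "control")
  expect_equal(s0$median, 0)
  expect_true(all(s0$delta == 0))
  s1 <- utr_cds_shift(ne, "kd", "control")
  s1r <- utr_cds_shift(ne, "control", "kd")
  expect_equal(s1$delta, -s1r$delta)
  expect_equal(s1$median, -s1r$median)
})

test_that("shift p-value is undefined below 5 transcripts", {
  cols <- expand.grid(region = c("UTR5", "CDS"),
                      condition = c("control", "kd"),
                      stringsAsFactors = FALSE)
  cols$sample_id <- paste0(cols$condition, "_RPF_1")
  cols$assay <- "RPF"; cols$replicate <- 1
  tpm <- matrix(c(1, 2, 3, 4), nrow = 1, dimnames = list("t", NULL))
  s <- utr_cds_shift(make_norm(tpm, cols), "kd", "control")
  expect_true(is.na(s$p_value))
  expect_equal(s$n, 1L)
})

test_that("region counts round-trip through the long TSV schema", {
  cfg <- sim_config(n_genes = 12, seed = 21)
  sim <- simulate_transcriptome(cfg, sequences = FALSE)
  out <- simulate_counts(cfg, sim$models, sim$truth, reads = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_region_counts(out$counts, path)
  back <- read_region_counts(path)
  expect_equal(back$counts[rownames(out$counts$counts),
                           colnames(out$counts$counts)],
               out$counts$counts)
})
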