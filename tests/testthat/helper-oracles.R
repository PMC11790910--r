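# Independent oracles, written directly from the definitions and kept
# separate from the package implementations they check.

# Exhaustive uORF scan: for every position in the 5'UTR, in every frame,
# check for a near-cognate start and walk codon by codon to the first
# stop, requiring it to end within the UTR.
oracle_uorf_scan <- function(seq, cds_start) {
  seq <- toupper(chartr("uU", "tT", seq))
  starts <- c("ATG", "CTG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  p <- 0
  while (p + 3 <= cds_start) {
    codon <- substr(seq, p + 1, p + 3)
    if (codon %in% starts) {
      q <- p + 3
      while (q + 3 <= cds_start) {
        cod2 <- substr(seq, q + 1, q + 3)
        if (cod2 %in% stops) {
          hits[[length(hits) + 1]] <- data.frame(
            start = p, stop_end = q + 3,
            start_codon = chartr("T", "U", codon),
            n_sense_codons = (q - p) / 3)
          break
        }
        q <- q + 3
      }
    }
    p <- p + 1
  }
  if (!length(hits))
    return(data.frame(start = integer(0), stop_end = integer(0),
                      start_codon = character(0),
                      n_sense_codons = numeric(0)))
  do.call(rbind, hits)
}

# Direct TMM implementation from the definition: reference sample by
# upper quartile closest to the mean upper quartile; per sample the
# factor is 2^(weighted trimmed mean of M = log2((x/N)/(r/Nr)) with
# weights 1/asymptotic variance, trimming 30% of M tails and 5% of
# A tails); factors rescaled to geometric mean 1.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# brute-force per-base genomic -> transcript projection for a set of
# exons (1-based genomic, strand-aware)
oracle_project <- function(exon_starts, exon_ends, strand, g) {
  bases <- unlist(lapply(seq_along(exon_starts), function(k)
    seq(exon_starts[k], exon_ends[k])))
  bases <- if (strand == "-") sort(bases, decreasing = TRUE) else sort(bases)
  match(g, bases) - 1L
}

random_tx_with_utr <- function(utr_len, cds_codons = 20) {
  utr <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
               collapse = "")
  cds <- paste0("ATG", paste(sample(c("A", "C", "G", "T"),
                                    3 * (cds_codons - 2), replace = TRUE),
                             collapse = ""), "TAA")
  transcript_models(
    transcript_id = "tx1", gene_id = "g1",
    length_nt = nchar(utr) + nchar(cds),
    cds_start = nchar(utr), cds_end = nchar(utr) + nchar(cds),
    sequence = paste0(utr, cds)
  )
}

make_asites <- function(transcript_id, positions, sample_id = "s1",
                        assay = "RPF") {
  n <- length(positions)
  data.frame(transcript_id = rep_len(transcript_id, n),
             position = positions,
             source_length = rep_len(30L, n), assay = rep_len(assay, n),
             sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
}
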