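#' Size-filter footprint and RNA reads
#'
#' Keeps ribosome-protected fragments (RPF) of 26-35 nt and RNA reads of
#' 21-60 nt, both bounds inclusive; input order is preserved.
#'
#' @param reads read record `data.frame` with columns `transcript_id`,
#'   `five_prime_pos`, `read_length`, `assay`, `sample_id`.
#' @param rpf_range,rna_range inclusive length bounds per assay.
#' @return the filtered `data.frame`.
#' @export
size_filter <- function(reads, rpf_range = c(26L, 35L),
                        rna_range = c(21L, 60L)) {
  validate_reads(reads)
  if (!nrow(reads)) return(reads)
  len <- reads$read_length
  keep <- ifelse(reads$assay == "RPF",
                 len >= rpf_range[1] & len <= rpf_range[2],
                 len >= rna_range[1] & len <= rna_range[2])
  reads[keep, , drop = FALSE]
}

#' Assign A-site positions to footprint reads
#'
#' The decoding (A-site) position of an RPF is its 5' end plus a
#' length-dependent offset: +16 for reads of at most 31 nt, +17 for longer
#' reads. RNA reads keep their 5' position (offset 0) so that the same
#' record structure can be counted on regions.
#'
#' Reads whose assigned position falls at or beyond the transcript end are
#' dropped; the number dropped is returned as attribute `n_dropped`.
#'
#' @param reads size-filtered read records.
#' @param models transcript model `data.frame` (used to drop positions past
#'   the transcript end); `NULL` skips that check.
#' @param offset_short,offset_long offsets for reads `<= break_length` nt
#'   and longer reads.
#' @param break_length read length at and below which `offset_short`
#'   applies (default 31).
#' @return `data.frame` with columns `transcript_id`, `position`,
#'   `source_length`, `assay`, `sample_id`.
#' @export
assign_asite <- function(reads, models = NULL, offset_short = 16L,
                         offset_long = 17L, break_length = 31L) {
  validate_reads(reads)
  offset <- ifelse(reads$assay == "RPF",
                   ifelse(reads$read_length <= break_length,
                          offset_short, offset_long),
                   0L)
  out <- data.frame(
    transcript_id = reads$transcript_id,
    position = reads$five_prime_pos + as.integer(offset),
    source_length = reads$read_length,
    assay = reads$assay,
    sample_id = reads$sample_id,
    stringsAsFactors = FALSE
  )
  n_dropped <- 0L
  if (!is.null(models) && nrow(out)) {
    tx_len <- setNames(models$length_nt, models$transcript_id)
    keep <- out$position < tx_len[out$transcript_id]
    keep[is.na(keep)] <- TRUE  # unknown transcripts handled downstream
    n_dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Count A-sites on 5'UTR and CDS regions
#'
#' An A-site at position `p` counts to the 5'UTR when `p < cds_start`, to
#' the CDS when `cds_start <= p < cds_end`; positions in the 3'UTR
#' (`p >= cds_end`) are not counted in either region.
#'
#' @param asites A-site records (see [assign_asite()]).
#' @param models transcript model `data.frame`.
#' @param samples optional sample sheet `data.frame` with columns
#'   `sample_id`, `assay` and any metadata (`condition`, `replicate`);
#'   defaults to the sample/assay combinations present in `asites`.
#' @return a `region_counts` object: list with `counts` (integer matrix,
#'   transcripts x columns), and `cols` (`data.frame` with `sample_id`,
#'   `assay`, `region` plus any metadata). Attribute `n_unknown` counts
#'   A-sites on transcripts absent from `models`.
#' @export
count_regions <- function(asites, models, samples = NULL) {
  validate_models(models, complete = FALSE)
  known <- asites$transcript_id %in% models$transcript_id
  n_unknown <- sum(!known)
  if (n_unknown)
    warning(n_unknown, " A-site(s) on unknown transcripts dropped")
  a <- asites[known, , drop = FALSE]

  if (is.null(samples)) {
    samples <- unique(data.frame(sample_id = a$sample_id, assay = a$assay,
                                 stringsAsFactors = FALSE))
    samples <- samples[order(samples$sample_id, samples$assay), ,
                       drop = FALSE]
  }
  if (nrow(samples)) {
    cols <- do.call(rbind, lapply(c("UTR5", "CDS"), function(r) {
      cbind(samples, region = r, stringsAsFactors = FALSE)
    }))
    cols <- cols[order(cols$sample_id, cols$assay, cols$region), ,
                 drop = FALSE]
    rownames(cols) <- NULL
  } else {
    cols <- cbind(samples, region = character(0))
  }

  counts <- matrix(0L, nrow = nrow(models), ncol = nrow(cols),
                   dimnames = list(models$transcript_id,
                                   paste(cols$sample_id, cols$assay,
                                         cols$region, sep = ".")))
  if (nrow(a)) {
    idx <- match(a$transcript_id, models$transcript_id)
    cs <- models$cds_start[idx]
    ce <- models$cds_end[idx]
    region <- ifelse(a$position < cs, "UTR5",
                     ifelse(a$position < ce, "CDS", NA_character_))
    in_region <- !is.na(region)
    key <- paste(a$sample_id, a$assay, region, sep = ".")[in_region]
    col <- match(key, colnames(counts))
    if (anyNA(col))
      stop("A-sites from sample/assay combinations absent from 'samples'")
    tab <- table(factor(a$transcript_id[in_region],
                        levels = models$transcript_id),
                 factor(col, levels = seq_len(ncol(counts))))
    counts <- counts + matrix(as.integer(tab), nrow = nrow(models),
                              dimnames = dimnames(counts))
  }
  structure(list(counts = counts, cols = cols),
            class = "region_counts", n_unknown = n_unknown)
}

#' @export
print.region_counts <- function(x, ...) {
  cat("region_counts: ", nrow(x$counts), " transcripts x ",
      ncol(x$counts), " columns (",
      length(unique(x$cols$sample_id)), " samples)\n", sep = "")
  invisible(x)
}

#' Remove transcripts with few counts overall
#'
#' A transcript is kept iff its counts summed over all samples, assays and
#' regions reach `min_total` (default 10, i.e. transcripts with less than
#' 10 counts in total are filtered out).
#'
#' @param rc `region_counts` object.
#' @param min_total minimum summed count.
#' @return filtered `region_counts`.
#' @export
filter_low_counts <- function(rc, min_total = 10L) {
  stopifnot(inherits(rc, "region_counts"))
  keep <- rowSums(rc$counts) >= min_total
  rc$counts <- rc$counts[keep, , drop = FALSE]
  rc
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors between samples: the per-sample factor
#' is 2 to the weighted trimmed mean of gene-wise log2 ratios against a
#' reference sample (the one whose upper-quartile count is closest to the
#' mean upper quartile), with the M-value and A-value tails trimmed at 0.3
#' and 0.05 and inverse asymptotic-variance weights; factors are rescaled
#' to geometric mean 1. Computed via `edgeR::calcNormFactors`.
#'
#' @param counts numeric matrix, genes x samples (by convention the CDS
#'   counts of one assay).
#' @param log_ratio_trim,abs_expr_trim trim fractions for the M and A tails.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, log_ratio_trim = 0.3, abs_expr_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with zero total count")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = log_ratio_trim,
                              sumTrim = abs_expr_trim)
  setNames(as.numeric(f), colnames(counts))
}

#' @keywords internal
region_lengths <- function(models) {
  rbind(UTR5 = setNames(models$cds_start, models$transcript_id),
        CDS = setNames(models$cds_end - models$cds_start,
                       models$transcript_id))
}

#' TMM-scaled TPM transformation
#'
#' Converts region counts to transcripts-per-million within each
#' sample x assay: `rate = count / (effective_library_factor x
#' region_length)`, scaled so rates sum to 1e6 over all counted regions of
#' the sample. TMM factors are computed per assay on CDS counts by
#' default and applied to both regions of a sample.
#'
#' @param rc `region_counts` object.
#' @param models transcript model `data.frame` covering the transcripts in
#'   `rc` (for region lengths).
#' @param factors optional named per-(sample, assay) TMM factors, names
#'   `"<sample_id>.<assay>"`; computed with [tmm_factors()] when `NULL`.
#' @return a `norm_expr` object: list with `tpm` matrix (same shape as
#'   `rc$counts`), `cols` metadata and `factors`.
#' @export
tpm_transform <- function(rc, models, factors = NULL) {
  stopifnot(inherits(rc, "region_counts"))
  idx <- match(rownames(rc$counts), models$transcript_id)
  if (anyNA(idx)) stop("models do not cover all counted transcripts")
  rl <- region_lengths(models[idx, , drop = FALSE])

  key <- paste(rc$cols$sample_id, rc$cols$assay, sep = ".")
  if (is.null(factors)) {
    factors <- setNames(rep(1, length(unique(key))), unique(key))
    for (as_ in unique(rc$cols$assay)) {
      jj <- which(rc$cols$assay == as_ & rc$cols$region == "CDS")
      if (length(jj) >= 2L) {
        cds <- rc$counts[, jj, drop = FALSE]
        colnames(cds) <- paste(rc$cols$sample_id[jj], as_, sep = ".")
        factors[colnames(cds)] <- tmm_factors(cds)
      }
    }
  }
  tpm <- matrix(0, nrow = nrow(rc$counts), ncol = ncol(rc$counts),
                dimnames = dimnames(rc$counts))
  for (k in unique(key)) {
    jj <- which(key == k)
    lib <- sum(rc$counts[, jj])
    eff <- lib * factors[[k]]
    rate <- sapply(jj, function(j) {
      r <- rc$counts[, j] / (eff * rl[rc$cols$region[j], ])
      r[rc$counts[, j] == 0] <- 0  # zero-length regions carry no counts
      r
    })
    tot <- sum(rate)
    if (tot > 0) tpm[, jj] <- 1e6 * rate / tot
  }
  structure(list(tpm = tpm, cols = rc$cols, factors = factors),
            class = "norm_expr")
}

#' @keywords internal
rep_mean_matrix <- function(ne, assay, region, condition = NULL) {
  jj <- which(ne$cols$assay == assay & ne$cols$region == region &
                (if (is.null(condition)) TRUE
                 else ne$cols$condition == condition))
  if (!length(jj)) stop("no columns for ", assay, "/", region,
                        if (!is.null(condition)) paste0("/", condition))
  ne$tpm[, jj, drop = FALSE]
}

#' Translation efficiency per transcript and condition
#'
#' TE is the log2 ratio of normalized CDS footprint signal to normalized
#' CDS RNA signal, computed per replicate (RPF and RNA samples matched by
#' condition and replicate) and averaged over replicates. Transcripts with
#' a zero in either term of any replicate are excluded and reported.
#'
#' @param ne `norm_expr` object whose `cols` carry `condition` and
#'   `replicate`.
#' @return `data.frame` with `transcript_id`, `condition`, `te_log2`;
#'   excluded transcript ids per condition in attribute `excluded`.
#' @export
compute_te <- function(ne) {
  stopifnot(inherits(ne, "norm_expr"))
  if (!all(c("condition", "replicate") %in% names(ne$cols)))
    stop("compute_te needs 'condition' and 'replicate' sample metadata")
  out <- list(); excl <- list()
  for (cond in unique(ne$cols$condition)) {
    jr <- which(ne$cols$assay == "RPF" & ne$cols$region == "CDS" &
                  ne$cols$condition == cond)
    jn <- which(ne$cols$assay == "RNA" & ne$cols$region == "CDS" &
                  ne$cols$condition == cond)
    if (!length(jr) || !length(jn))
      stop("condition ", cond, " lacks matched RPF/RNA samples")
    reps <- intersect(ne$cols$replicate[jr], ne$cols$replicate[jn])
    if (!length(reps))
      stop("condition ", cond, " has no matched replicate pairs")
    te_rep <- sapply(reps, function(r) {
      rpf <- ne$tpm[, jr[match(r, ne$cols$replicate[jr])]]
      rna <- ne$tpm[, jn[match(r, ne$cols$replicate[jn])]]
      log2(rpf / rna)
    })
    te_rep <- matrix(te_rep, ncol = length(reps))
    ok <- apply(is.finite(te_rep), 1L, all)
    excl[[cond]] <- rownames(ne$tpm)[!ok]
    out[[cond]] <- data.frame(
      transcript_id = rownames(ne$tpm)[ok],
      condition = cond,
      te_log2 = rowMeans(te_rep[ok, , drop = FALSE]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "excluded") <- excl
  res
}

#' Ribosome redistribution between 5'UTR and CDS
#'
#' For each transcript with nonzero 5'UTR and CDS footprint signal in both
#' conditions, computes the change in the log2 ratio of 5'UTR to CDS
#' footprint occupancy, `log2((UTR5/CDS)_treated) - log2((UTR5/CDS)_control)`,
#' using replicate-mean normalized footprint values, and tests the
#' per-transcript changes against a zero median with a one-sample Wilcoxon
#' signed-rank test. A positive median indicates ribosomes redistributing
#' from the CDS to the 5'UTR, as expected when re-initiation is blocked.
#'
#' @param ne `norm_expr` object with `condition` metadata.
#' @param treated,control condition labels.
#' @return list with `delta` (named vector), `median`, `p_value` (`NA`
#'   when fewer than 5 transcripts qualify) and `n`.
#' @export
utr_cds_shift <- function(ne, treated, control) {
  stopifnot(inherits(ne, "norm_expr"))
  u_t <- rowMeans(rep_mean_matrix(ne, "RPF", "UTR5", treated))
  c_t <- rowMeans(rep_mean_matrix(ne, "RPF", "CDS", treated))
  u_c <- rowMeans(rep_mean_matrix(ne, "RPF", "UTR5", control))
  c_c <- rowMeans(rep_mean_matrix(ne, "RPF", "CDS", control))
  ok <- u_t > 0 & c_t > 0 & u_c > 0 & c_c > 0
  delta <- log2(u_t[ok] / c_t[ok]) - log2(u_c[ok] / c_c[ok])
  p <- if (length(delta) >= 5L) {
    suppressWarnings(wilcox.test(delta, mu = 0)$p.value)
  } else {
    NA_real_
  }
  list(delta = delta, median = if (length(delta)) median(delta) else NA_real_,
       p_value = p, n = length(delta))
}

#' Write/read region count tables
#'
#' Long TSV schema: `transcript_id`, `sample_id`, `assay`, `region`,
#' `count`, plus any sample metadata columns. Round-trips a
#' `region_counts` object.
#'
#' @param rc `region_counts` object.
#' @param path file path.
#' @export
write_region_counts <- function(rc, path) {
  stopifnot(inherits(rc, "region_counts"))
  long <- do.call(rbind, lapply(seq_len(ncol(rc$counts)), function(j) {
    cbind(data.frame(transcript_id = rownames(rc$counts),
                     stringsAsFactors = FALSE),
          rc$cols[rep(j, nrow(rc$counts)), , drop = FALSE],
          count = rc$counts[, j], row.names = NULL)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_counts
#' @export
read_region_counts <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  meta_cols <- setdiff(names(long), c("transcript_id", "count"))
  cols <- unique(long[, meta_cols, drop = FALSE])
  cols <- cols[order(cols$sample_id, cols$assay, cols$region), , drop = FALSE]
  rownames(cols) <- NULL
  tx <- unique(long$transcript_id)
  counts <- matrix(0L, nrow = length(tx), ncol = nrow(cols),
                   dimnames = list(tx, paste(cols$sample_id, cols$assay,
                                             cols$region, sep = ".")))
  key <- paste(long$sample_id, long$assay, long$region, sep = ".")
  counts[cbind(match(long$transcript_id, tx), match(key, colnames(counts)))] <-
    as.integer(long$count)
  structure(list(counts = counts, cols = cols), class = "region_counts")
}
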