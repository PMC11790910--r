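#' Run the profiling analysis workflow
#'
#' Ties the quantification and annotation stages together: size filter,
#' A-site assignment, region counting, low-count filter, TMM/TPM
#' normalization, translation efficiency, uORF calling with enrichment
#' statistics, the differential-TE interaction test and the 5'UTR/CDS
#' redistribution statistic. Every stage's table is written to
#' `output_dir` as TSV (uORFs additionally as BED) and a JSON summary
#' collects the headline numbers. Deterministic given inputs and the
#' configured seed.
#'
#' @param models transcript model `data.frame` (with sequences for uORF
#'   calling; transcripts without sequence are classified from candidates
#'   found on those that have one).
#' @param reads read record `data.frame` (or path to a read TSV).
#' @param samples sample sheet `data.frame` (`sample_id`, `condition`,
#'   `assay`, `replicate`); defaults to what is present in `reads`.
#' @param output_dir directory for result files (created if needed).
#' @param condition_treated,condition_control condition labels for the
#'   differential contrasts; default to the two conditions present
#'   (alphabetically: control first, other treated).
#' @param coverage_threshold,min_total,fdr_threshold analysis thresholds
#'   (defaults 0.33, 10 and 0.1).
#' @param seed seed for the enrichment Monte Carlo.
#' @return invisibly, a list with all stage results and the summary.
#' @export
run_profiling_pipeline <- function(models, reads, samples = NULL,
                                   output_dir = ".",
                                   condition_treated = NULL,
                                   condition_control = NULL,
                                   coverage_threshold = 0.33,
                                   min_total = 10L,
                                   fdr_threshold = 0.1,
                                   seed = 42) {
  if (is.character(reads)) reads <- read_reads(reads)
  validate_models(models, complete = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  filtered <- size_filter(reads)
  asites <- assign_asite(filtered, models)
  if (is.null(samples) && nrow(asites)) {
    samples <- unique(data.frame(sample_id = asites$sample_id,
                                 assay = asites$assay,
                                 stringsAsFactors = FALSE))
    parts <- strsplit(samples$sample_id, "_")
    samples$condition <- vapply(parts, `[`, "", 1L)
    samples$replicate <- vapply(parts, function(p) p[length(p)], "")
  }
  rc <- count_regions(asites, models, samples = samples)
  rc <- filter_low_counts(rc, min_total = min_total)
  write_region_counts(rc, file.path(output_dir, "region_counts.tsv"))

  has_data <- nrow(rc$counts) > 0 && ncol(rc$counts) > 0
  ne <- NULL
  te <- data.frame(transcript_id = character(0), condition = character(0),
                   te_log2 = numeric(0))
  if (has_data) {
    ne <- tpm_transform(rc, models)
    conds <- unique(rc$cols$condition)
    if (is.null(condition_control)) condition_control <- sort(conds)[1]
    if (is.null(condition_treated))
      condition_treated <- setdiff(sort(conds), condition_control)[1]
    te <- compute_te(ne)
  }
  write.table(te, file.path(output_dir, "te.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # uORF calling on transcripts with sequence
  with_seq <- models[!is.na(models$sequence), , drop = FALSE]
  cand <- do.call(rbind, c(lapply(seq_len(nrow(with_seq)), function(i)
    find_candidate_uorfs(with_seq[i, , drop = FALSE])),
    list(make.row.names = FALSE)))
  if (is.null(cand))
    cand <- data.frame(transcript_id = character(0), start = integer(0),
                       stop_end = integer(0), start_codon = character(0),
                       n_sense_codons = integer(0))
  called <- score_and_call(cand, asites,
                           coverage_threshold = coverage_threshold)
  called <- resolve_overlaps(called)
  called <- annotate_context(called, with_seq)
  write.table(called, file.path(output_dir, "uorfs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_uorf_bed(called, file.path(output_dir, "uorfs.bed"))
  classes <- classify_transcripts(with_seq, called)
  write.table(data.frame(transcript_id = names(classes), class = classes),
              file.path(output_dir, "transcript_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # differential TE + enrichment of the TE-down set
  dte_cl <- data.frame(transcript_id = character(0), class = character(0))
  if (has_data && !is.na(condition_treated))
    dte_cl <- adjust_and_classify(
      fit_te_interaction(rc, condition_ref = condition_control),
      fdr_threshold = fdr_threshold)
  write.table(dte_cl, file.path(output_dir, "diff_te.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  down_ids <- dte_cl$transcript_id[dte_cl$class == "te_down"]
  cls_levels <- c("translated_uORF", "untranslated_uORF_only", "no_uORF")
  bg_counts <- as.integer(table(factor(classes, levels = cls_levels)))
  sub_counts <- as.integer(table(factor(classes[intersect(down_ids,
                                                          names(classes))],
                                        levels = cls_levels)))
  enrich <- if (sum(sub_counts) > 0)
    uorf_enrichment_test(sub_counts, bg_counts, seed = seed)
  else
    list(p_value = NA_real_, method = "none")

  shift <- if (has_data && !is.na(condition_treated)) {
    utr_cds_shift(ne, condition_treated, condition_control)
  } else {
    list(delta = numeric(0), median = NA_real_, p_value = NA_real_, n = 0L)
  }

  summary <- list(
    n_transcripts_counted = nrow(rc$counts),
    n_reads_in = nrow(reads), n_reads_size_kept = nrow(filtered),
    class_counts = as.list(setNames(bg_counts, cls_levels)),
    n_te_down = length(down_ids),
    te_down_class_counts = as.list(setNames(sub_counts, cls_levels)),
    enrichment_p = enrich$p_value,
    enrichment_method = enrich$method,
    shift_median = shift$median, shift_p = shift$p_value,
    shift_n = shift$n,
    thresholds = list(coverage = coverage_threshold,
                      min_total = min_total, fdr = fdr_threshold),
    seed = seed
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(counts = rc, norm = ne, te = te, uorfs = called,
                 classes = classes, diff_te = dte_cl, enrichment = enrich,
                 shift = shift, summary = summary))
}

#' Run the reporter flux workflow
#'
#' Normalizes a reporter table, fits the flux decomposition per genotype
#' with bootstrap CIs, and (for two or more genotypes) runs per-construct
#' t-tests between the first two. Writes a flux TSV and JSON report.
#'
#' @param measurements reporter `data.frame` or path to a TSV with
#'   columns `construct`, `genotype`, `replicate`, `firefly`, `renilla`.
#' @param output_dir directory for result files.
#' @param n_boot,conf,seed bootstrap settings (see [reporter_flux()]).
#' @return invisibly, the `reporter_flux` fit plus the comparison.
#' @export
run_flux_pipeline <- function(measurements, output_dir = ".",
                              n_boot = 2000L, conf = 0.95, seed = 42) {
  if (is.character(measurements))
    measurements <- read.delim(measurements, stringsAsFactors = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- reporter_flux(measurements, n_boot = n_boot, conf = conf,
                       seed = seed)
  tab <- as.data.frame(coef(fit))
  tab <- cbind(genotype = rownames(tab), tab, row.names = NULL)
  write.table(tab, file.path(output_dir, "flux.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  genos <- names(fit$fits)
  comparison <- NULL
  if (length(genos) >= 2L)
    comparison <- compare_fluxes(measurements, genos[1], genos[2])
  report <- list(
    flux = lapply(fit$fits, function(f)
      list(leaky_pct = f$leaky_pct, reinit_pct = f$reinit_pct,
           inhibition_pct = f$inhibition_pct,
           uorf_engaged_pct = f$uorf_engaged_pct,
           conditional_reinit = f$conditional_reinit,
           flags = f$flags, n_replicates = as.list(f$n_replicates))),
    comparison = if (!is.null(comparison)) list(
      genotypes = genos[1:2],
      tests = comparison$tests,
      interaction_p = comparison$interaction_p) else NULL,
    seed = seed
  )
  jsonlite::write_json(report, file.path(output_dir, "flux_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, comparison = comparison, report = report))
}
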