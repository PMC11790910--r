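#' Build a table of transcript models
#'
#' A transcript model describes one transcript in transcript space:
#' its length, its CDS as a 0-based half-open interval `[cds_start,
#' cds_end)`, and optionally its sequence. The 5'UTR is `[0, cds_start)`,
#' so `cds_start` equals the 5'UTR length.
#'
#' @param transcript_id,gene_id character vectors.
#' @param length_nt integer transcript lengths (nt).
#' @param cds_start,cds_end 0-based half-open CDS bounds in transcript
#'   coordinates.
#' @param sequence optional nucleotide sequences (`A/C/G/T` or `U`;
#'   normalised to `T` internally), or `NA`.
#' @param complete logical; when `TRUE` (default) the CDS length must be a
#'   multiple of 3.
#' @return a `data.frame` with one row per transcript and columns
#'   `transcript_id`, `gene_id`, `length_nt`, `cds_start`, `cds_end`,
#'   `sequence`.
#' @export
transcript_models <- function(transcript_id, gene_id, length_nt,
                              cds_start, cds_end, sequence = NA_character_,
                              complete = TRUE) {
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    length_nt = as.integer(length_nt),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    sequence = normalize_seq(sequence),
    stringsAsFactors = FALSE
  )
  validate_models(df, complete = complete)
  df
}

#' @keywords internal
normalize_seq <- function(x) {
  x <- as.character(x)
  toupper(chartr("uU", "tT", x))
}

#' @keywords internal
validate_models <- function(models, complete = TRUE) {
  stopifnot(is.data.frame(models))
  need <- c("transcript_id", "gene_id", "length_nt", "cds_start", "cds_end")
  miss <- setdiff(need, names(models))
  if (length(miss))
    stop("transcript model table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(models$transcript_id))
    stop("duplicated transcript_id in model table")
  bad <- !(models$cds_start >= 0 & models$cds_start < models$cds_end &
             models$cds_end <= models$length_nt)
  if (any(bad))
    stop("invalid CDS bounds for: ",
         paste(models$transcript_id[bad], collapse = ", "))
  if (complete) {
    nb <- (models$cds_end - models$cds_start) %% 3L != 0L
    if (any(nb))
      stop("CDS length not a multiple of 3 for: ",
           paste(models$transcript_id[nb], collapse = ", "))
  }
  has_seq <- !is.na(models$sequence)
  if (any(has_seq)) {
    lm <- nchar(models$sequence[has_seq]) != models$length_nt[has_seq]
    if (any(lm))
      stop("sequence length does not match length_nt for: ",
           paste(models$transcript_id[has_seq][lm], collapse = ", "))
  }
  invisible(models)
}

#' Load transcript models from genome-space annotation
#'
#' Projects genomic `exon`/`CDS` features of a GTF/GFF annotation into
#' transcript space: exons are concatenated 5'-to-3' (strand resolved, so
#' position 0 is the transcript 5' end) and the CDS interval is expressed
#' in those coordinates. Transcripts without CDS features, or whose CDS
#' does not project onto a contiguous block of the exon chain, are skipped
#' with a warning.
#'
#' @param annotation path to a GTF/GFF file, or a `GRanges` as returned by
#'   `rtracklayer::import()` with metadata columns `type`, `transcript_id`
#'   and (optionally) `gene_id`.
#' @param sequences optional path to a transcript-space FASTA file or a
#'   named character vector of sequences; names must match transcript ids
#'   and lengths must agree with the projected models (error otherwise).
#' @return transcript model `data.frame` (see [transcript_models()]).
#' @export
load_transcript_models <- function(annotation, sequences = NULL) {
  gr <- if (is.character(annotation)) rtracklayer::import(annotation) else annotation
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id") %in% names(md)))
    stop("annotation must carry 'type' and 'transcript_id' attributes")
  keep <- as.character(md$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tid
  type <- as.character(md$type)
  st <- GenomicRanges::start(gr)   # 1-based genomic
  en <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))

  out <- list()
  for (t in unique(tid)) {
    i <- which(tid == t)
    iex <- i[type[i] == "exon"]
    icd <- i[type[i] == "CDS"]
    if (!length(iex) || !length(icd)) {
      warning("skipping transcript without exon or CDS features: ", t)
      next
    }
    minus <- strand[iex[1]] == "-"
    ord <- if (minus) order(st[iex], decreasing = TRUE) else order(st[iex])
    iex <- iex[ord]
    widths <- en[iex] - st[iex] + 1L
    offs <- cumsum(c(0L, widths[-length(widths)]))
    tx_len <- sum(widths)

    # project each genomic CDS base onto the exon chain
    proj <- function(g) {
      for (k in seq_along(iex)) {
        e <- iex[k]
        if (g >= st[e] && g <= en[e]) {
          within <- if (minus) en[e] - g else g - st[e]
          return(offs[k] + within)
        }
      }
      NA_integer_
    }
    cds_pos <- unlist(lapply(icd, function(j) {
      vapply(seq.int(st[j], en[j]), proj, integer(1))
    }))
    if (anyNA(cds_pos)) {
      warning("skipping transcript with CDS outside its exons: ", t)
      next
    }
    cs <- min(cds_pos)
    ce <- max(cds_pos) + 1L
    if (ce - cs != length(cds_pos)) {
      warning("skipping transcript with non-contiguous projected CDS: ", t)
      next
    }
    out[[t]] <- data.frame(
      transcript_id = t, gene_id = gid[iex[1]],
      length_nt = tx_len, cds_start = cs, cds_end = ce,
      sequence = NA_character_, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop("no usable transcripts in annotation")
  models <- do.call(rbind, c(out, list(make.row.names = FALSE)))

  if (!is.null(sequences)) {
    seqs <- if (is.character(sequences) && length(sequences) == 1L &&
                  file.exists(sequences)) {
      s <- Biostrings::readDNAStringSet(sequences)
      setNames(as.character(s), sub("\\s.*$", "", names(s)))
    } else {
      sequences
    }
    seqs <- setNames(normalize_seq(seqs), names(seqs))
    hit <- match(models$transcript_id, names(seqs))
    got <- !is.na(hit)
    if (any(nchar(seqs[hit[got]]) != models$length_nt[got]))
      stop("FASTA sequence length disagrees with projected transcript length")
    models$sequence[got] <- seqs[hit[got]]
  }
  validate_models(models, complete = (ncol(models) > 0))
  models
}

#' Select the transcript used for uORF annotation of a gene
#'
#' Genes with a single expressed isoform contribute that isoform. Genes
#' with several expressed isoforms are used only when all of them share
#' the same CDS start (identical CDS 5' ends in genomic terms), in which
#' case the isoform with the longest 5'UTR is selected; otherwise the gene
#' is excluded (`NULL`).
#'
#' @param isoforms transcript model `data.frame` for one gene. When a
#'   `cds_genomic_start` column is present it identifies the genomic CDS
#'   5' end used to decide whether isoforms share a CDS start; otherwise
#'   a transcript-space proxy is used (identical distance from CDS start
#'   to the transcript 3' end, which holds when isoforms differ only in
#'   their 5'UTR).
#' @param expression named numeric abundances (FPKM-like), one per isoform.
#' @param expressed_threshold abundance above which an isoform counts as
#'   expressed (default 0, i.e. any positive abundance).
#' @return a single-row model `data.frame`, or `NULL` when the gene is
#'   excluded.
#' @export
select_uorf_transcript <- function(isoforms, expression,
                                   expressed_threshold = 0) {
  stopifnot(is.data.frame(isoforms), nrow(isoforms) >= 1L)
  if (length(unique(isoforms$gene_id)) != 1L)
    stop("isoforms must all belong to one gene")
  expr <- expression[isoforms$transcript_id]
  if (anyNA(expr))
    stop("expression value missing for some isoform(s)")
  keep <- which(expr > expressed_threshold)
  if (!length(keep)) return(NULL)
  expressed <- isoforms[keep, , drop = FALSE]
  if (nrow(expressed) == 1L) return(expressed)
  anchor <- if ("cds_genomic_start" %in% names(expressed)) {
    expressed$cds_genomic_start
  } else {
    # transcript-space fallback: a shared CDS 5' end means the sequence
    # downstream of cds_start is the same, so isoforms differ only in
    # 5'UTR length; detectable as identical distance from CDS start to
    # transcript 3' end
    expressed$length_nt - expressed$cds_start
  }
  if (length(unique(anchor)) != 1L) return(NULL)
  expressed[which.max(expressed$cds_start), , drop = FALSE]
}

#' Read/write the package's transcript model TSV
#'
#' Columns: `transcript_id`, `gene_id`, `length_nt`, `cds_start`,
#' `cds_end`, `sequence` (empty when absent). Round-trips exactly.
#'
#' @param models transcript model `data.frame`.
#' @param path file path.
#' @return `read_models` returns the model `data.frame`.
#' @export
write_models <- function(models, path) {
  validate_models(models, complete = FALSE)
  out <- models[, c("transcript_id", "gene_id", "length_nt",
                    "cds_start", "cds_end", "sequence")]
  out$sequence[is.na(out$sequence)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sequence = "character"))
  df$sequence[!nzchar(df$sequence)] <- NA_character_
  df$sequence <- normalize_seq(df$sequence)
  validate_models(df, complete = FALSE)
  df
}

#' Read/write footprint read records
#'
#' TSV schema: `transcript_id`, `five_prime_pos` (0-based), `read_length`,
#' `assay` (`RPF`/`RNA`), `sample_id`.
#'
#' @param reads read record `data.frame`.
#' @param path file path.
#' @export
write_reads <- function(reads, path) {
  validate_reads(reads)
  write.table(reads[, c("transcript_id", "five_prime_pos", "read_length",
                        "assay", "sample_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_reads(df)
  df
}

#' @keywords internal
validate_reads <- function(reads) {
  need <- c("transcript_id", "five_prime_pos", "read_length", "assay",
            "sample_id")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("read table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(reads)) {
    stopifnot(all(reads$five_prime_pos >= 0), all(reads$read_length >= 1))
    bad <- !reads$assay %in% c("RPF", "RNA")
    if (any(bad)) stop("assay must be 'RPF' or 'RNA'")
  }
  invisible(reads)
}

#' Write uORF annotations as BED6+ in transcript space
#'
#' `thickStart`/`thickEnd` mark the sense-codon region (start codon up to,
#' excluding, the stop codon). Score is the breadth coverage in [0, 1000].
#'
#' @param uorfs uORF annotation `data.frame` (see [find_candidate_uorfs()]).
#' @param path file path.
#' @export
write_uorf_bed <- function(uorfs, path) {
  if (!nrow(uorfs)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cov <- if ("coverage" %in% names(uorfs)) uorfs$coverage else 0
  bed <- data.frame(
    chrom = uorfs$transcript_id,
    chromStart = uorfs$start,
    chromEnd = uorfs$stop_end,
    name = paste0(uorfs$start_codon, "_uORF"),
    score = as.integer(round(1000 * ifelse(is.na(cov), 0, cov))),
    strand = "+",
    thickStart = uorfs$start,
    thickEnd = uorfs$stop_end - 3L
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
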