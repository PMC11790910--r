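START_CODONS <- c("ATG", "CTG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @keywords internal
rna_codon <- function(x) chartr("T", "U", x)

#' Find candidate uORFs on a transcript
#'
#' Scans the 5'UTR `[0, cds_start)` of one transcript for upstream ORFs
#' satisfying: (i) the start codon is AUG, CUG, GUG or UUG; (ii) the first
#' in-frame stop codon lies entirely within the 5'UTR. Every qualifying
#' start yields one candidate ending at its first stop; overlapping
#' candidates are all returned (see [resolve_overlaps()]).
#'
#' `n_sense_codons` counts the start codon, so a start codon immediately
#' followed by a stop (a "start-stop" or 1-aa uORF) has `n_sense_codons =
#' 1` and a 6-nt extent.
#'
#' @param model single-row transcript model with `sequence`.
#' @return `data.frame` with columns `transcript_id`, `start`, `stop_end`
#'   (0-based half-open, stop codon included), `start_codon` (RNA
#'   alphabet), `n_sense_codons`; zero rows when no candidate exists.
#' @export
find_candidate_uorfs <- function(model) {
  stopifnot(is.data.frame(model), nrow(model) == 1L)
  if (is.na(model$sequence)) stop("model lacks a sequence")
  seq <- normalize_seq(model$sequence)
  cs <- model$cds_start
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      stop_end = integer(0), start_codon = character(0),
                      n_sense_codons = integer(0), stringsAsFactors = FALSE)
  if (cs < 6L) return(empty)
  out <- list()
  for (p in 0:(cs - 3L)) {
    cod <- substr(seq, p + 1L, p + 3L)
    if (!cod %in% START_CODONS) next
    q <- p + 3L
    found <- FALSE
    while (q + 3L <= cs) {
      stopc <- substr(seq, q + 1L, q + 3L)
      if (stopc %in% STOP_CODONS) { found <- TRUE; break }
      q <- q + 3L
    }
    if (!found) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = model$transcript_id,
      start = p, stop_end = q + 3L,
      start_codon = rna_codon(cod),
      n_sense_codons = (q - p) %/% 3L,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Score uORF candidates and call translated status
#'
#' Computes, from RPF A-sites, the breadth coverage of each uORF (fraction
#' of nucleotide positions in `[start, stop_end)` overlapped by at least
#' one A-site; the stop codon is part of the interval because terminating
#' ribosomes dwell there) and the read density (A-site count divided by
#' interval length). A uORF is called translated when its coverage
#' statistic reaches `coverage_threshold` (default 0.33, i.e. at least
#' 33%).
#'
#' @param uorfs candidate table from [find_candidate_uorfs()] (possibly
#'   several transcripts row-bound).
#' @param asites A-site records; only `assay == "RPF"` rows are used.
#' @param coverage_threshold minimum coverage for a translated call.
#' @param rule which statistic the threshold applies to: breadth coverage
#'   (default) or read density.
#' @return `uorfs` with columns `coverage`, `density`, `translated` added.
#' @export
score_and_call <- function(uorfs, asites, coverage_threshold = 0.33,
                           rule = c("breadth", "density")) {
  rule <- match.arg(rule)
  if (!nrow(uorfs)) {
    uorfs$coverage <- numeric(0); uorfs$density <- numeric(0)
    uorfs$translated <- logical(0)
    return(uorfs)
  }
  a <- asites[asites$assay == "RPF", , drop = FALSE]
  cov <- den <- numeric(nrow(uorfs))
  for (i in seq_len(nrow(uorfs))) {
    pos <- a$position[a$transcript_id == uorfs$transcript_id[i]]
    hit <- pos[pos >= uorfs$start[i] & pos < uorfs$stop_end[i]]
    len <- uorfs$stop_end[i] - uorfs$start[i]
    cov[i] <- length(unique(hit)) / len
    den[i] <- length(hit) / len
  }
  uorfs$coverage <- cov
  uorfs$density <- den
  uorfs$translated <- (if (rule == "breadth") cov else den) >=
    coverage_threshold
  uorfs
}

#' Resolve overlapping uORF candidates
#'
#' Among mutually overlapping candidates (sharing at least one nucleotide
#' on the same transcript) the one with the highest read density (A-site
#' count / uORF length) is kept; candidates overlapping a kept uORF are
#' removed, and the selection repeats. Ties are broken by the 5'-most
#' start, then by start-codon strength AUG > CUG > GUG > UUG.
#'
#' @param uorfs scored candidate table (needs `density`).
#' @return non-overlapping subset of `uorfs`.
#' @export
resolve_overlaps <- function(uorfs) {
  if (!nrow(uorfs)) return(uorfs)
  if (is.null(uorfs$density)) stop("density not computed; run score_and_call")
  rank_codon <- match(uorfs$start_codon, c("AUG", "CUG", "GUG", "UUG"))
  out <- list()
  for (t in unique(uorfs$transcript_id)) {
    u <- uorfs[uorfs$transcript_id == t, , drop = FALSE]
    rk <- rank_codon[uorfs$transcript_id == t]
    ord <- order(-u$density, u$start, rk)
    u <- u[ord, , drop = FALSE]
    keep <- logical(nrow(u))
    blocked <- logical(nrow(u))
    for (i in seq_len(nrow(u))) {
      if (blocked[i]) next
      keep[i] <- TRUE
      ov <- u$start < u$stop_end[i] & u$stop_end > u$start[i]
      blocked <- blocked | ov
    }
    out[[t]] <- u[keep, , drop = FALSE]
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$transcript_id, res$start), , drop = FALSE]
}

#' Annotate penultimate codon and Kozak +4 context
#'
#' The penultimate codon is the last sense codon before the stop, defined
#' only for uORFs with at least two sense codons (a start-stop uORF has
#' none). The Kozak +4 nucleotide is the base immediately 3' of the start
#' codon; for a start-stop uORF it is the first base of the stop codon and
#' hence always U.
#'
#' @param uorfs uORF table.
#' @param models transcript model `data.frame` with sequences.
#' @return `uorfs` with `penultimate_codon` and `kozak_plus4` (RNA
#'   alphabet) added; `NA` when the context is not defined.
#' @export
annotate_context <- function(uorfs, models) {
  uorfs$penultimate_codon <- NA_character_
  uorfs$kozak_plus4 <- NA_character_
  if (!nrow(uorfs)) return(uorfs)
  seqs <- setNames(normalize_seq(models$sequence), models$transcript_id)
  lens <- setNames(models$length_nt, models$transcript_id)
  for (i in seq_len(nrow(uorfs))) {
    s <- seqs[[uorfs$transcript_id[i]]]
    if (is.null(s) || is.na(s)) next
    if (uorfs$n_sense_codons[i] >= 2L) {
      pe <- uorfs$stop_end[i] - 6L
      uorfs$penultimate_codon[i] <- rna_codon(substr(s, pe + 1L, pe + 3L))
    }
    k4 <- uorfs$start[i] + 3L
    if (k4 < lens[[uorfs$transcript_id[i]]])
      uorfs$kozak_plus4[i] <- rna_codon(substr(s, k4 + 1L, k4 + 1L))
  }
  uorfs
}

#' Classify transcripts by uORF content
#'
#' @param models transcript model `data.frame`.
#' @param uorfs called uORF table with `translated` (candidates for the
#'   same transcripts, before or after overlap resolution).
#' @return named character vector over `models$transcript_id` with values
#'   `translated_uORF` (at least one translated uORF),
#'   `untranslated_uORF_only` (candidates but none translated) or
#'   `no_uORF`.
#' @export
classify_transcripts <- function(models, uorfs) {
  cls <- setNames(rep("no_uORF", nrow(models)), models$transcript_id)
  if (nrow(uorfs)) {
    has_cand <- unique(uorfs$transcript_id)
    cls[intersect(has_cand, names(cls))] <- "untranslated_uORF_only"
    has_tr <- unique(uorfs$transcript_id[uorfs$translated])
    cls[intersect(has_tr, names(cls))] <- "translated_uORF"
  }
  cls
}

#' @keywords internal
log_prob_2xC <- function(row1, colsums, n1, N) {
  # conditional probability of a 2 x C table given margins
  sum(lchoose(colsums, row1)) - lchoose(N, n1)
}

#' Fisher-type test for translated-uORF enrichment in a transcript subset
#'
#' Tests whether the uORF-class composition of a transcript subset
#' (translated uORF / untranslated uORF only / no uORF) differs from the
#' remaining transcripts. The table has row 1 = subset counts and row 2 =
#' background minus subset. By default the question is the one the
#' enrichment figures ask — is the *proportion of transcripts with at
#' least one translated uORF* different? — so the first class is tested
#' against the pooled others (2 x 2 Fisher exact). With `collapse =
#' "none"` the full 2 x C class-composition homogeneity is tested
#' instead.
#'
#' The two-sided p-value sums all tables (given the margins) whose
#' conditional probability does not exceed that of the observed table; it
#' is computed by exact enumeration when the table has two columns or a
#' total of at most `exact_limit`, otherwise by Monte Carlo over the
#' conditional-margins null with `p = (1 + #extreme) / (1 + n_mc)`.
#'
#' @param subset_counts integer vector of class counts in the subset
#'   (translated-uORF class first).
#' @param background_counts class totals over all transcripts (the subset
#'   included); must be elementwise at least `subset_counts`.
#' @param method `"auto"` (exact when feasible), `"exact"` or
#'   `"montecarlo"`.
#' @param n_mc number of Monte Carlo tables.
#' @param seed RNG seed for the Monte Carlo branch.
#' @param exact_limit table total above which `"auto"` switches to Monte
#'   Carlo for tables with 3 or more columns.
#' @param collapse `"translated_vs_rest"` (default) pools all classes but
#'   the first; `"none"` keeps the full class table.
#' @return list with `p_value`, `method`, `table`.
#' @export
uorf_enrichment_test <- function(subset_counts, background_counts,
                                 method = c("auto", "exact", "montecarlo"),
                                 n_mc = 1e5, seed = 42,
                                 exact_limit = 500L,
                                 collapse = c("translated_vs_rest", "none")) {
  method <- match.arg(method)
  collapse <- match.arg(collapse)
  s <- as.integer(subset_counts)
  b <- as.integer(background_counts)
  if (length(s) != length(b)) stop("count vectors differ in length")
  if (any(s < 0) || any(b < 0)) stop("negative counts")
  if (any(s > b)) stop("subset counts exceed background totals")
  if (collapse == "translated_vs_rest" && length(s) > 2L) {
    s <- c(s[1L], sum(s[-1L]))
    b <- c(b[1L], sum(b[-1L]))
  }
  tab <- rbind(subset = s, rest = b - s)
  N <- sum(tab)
  if (method == "auto")
    method <- if (length(s) == 2L || N <= exact_limit) "exact" else
      "montecarlo"

  n1 <- sum(s)
  colsums <- colSums(tab)
  lp_obs <- log_prob_2xC(s, colsums, n1, N)
  tol <- 1e-7

  if (method == "exact") {
    # enumerate all row-1 vectors compatible with the margins
    grids <- lapply(seq_len(length(s) - 1L), function(j) 0:min(colsums[j], n1))
    combos <- expand.grid(grids)
    last <- n1 - rowSums(combos)
    ok <- last >= 0 & last <= colsums[length(s)]
    combos <- cbind(combos[ok, , drop = FALSE], last[ok])
    lp <- apply(as.matrix(combos), 1L, log_prob_2xC,
                colsums = colsums, n1 = n1, N = N)
    p <- sum(exp(lp[lp <= lp_obs + tol]))
    p <- min(1, p)
  } else {
    set.seed(seed)
    extreme <- 0L
    done <- 0
    chunk <- 1e5
    while (done < n_mc) {
      m <- min(chunk, n_mc - done)
      tabs <- r2dtable(m, c(n1, N - n1), colsums)
      lp <- vapply(tabs, function(tt) log_prob_2xC(tt[1L, ], colsums, n1, N),
                   numeric(1))
      extreme <- extreme + sum(lp <= lp_obs + tol)
      done <- done + m
    }
    p <- (1 + extreme) / (1 + n_mc)
  }
  list(p_value = p, method = method, table = tab)
}

#' Compare 5'UTR length distributions
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test with the group medians,
#' as used to ask whether regulated transcripts have longer 5'UTRs than
#' the expressed background.
#'
#' @param lengths_subset,lengths_background numeric vectors (at least 5
#'   values each).
#' @return list with `median_subset`, `median_background`, `statistic`,
#'   `p_value`.
#' @export
utr_length_comparison <- function(lengths_subset, lengths_background) {
  if (length(lengths_subset) < 5L || length(lengths_background) < 5L)
    stop("need at least 5 values per group")
  kt <- suppressWarnings(ks.test(lengths_subset, lengths_background))
  list(median_subset = median(lengths_subset),
       median_background = median(lengths_background),
       statistic = unname(kt$statistic),
       p_value = kt$p.value)
}

#' Mean number of translated uORFs per uORF-bearing 5'UTR
#'
#' @param models transcript model `data.frame`.
#' @param uorfs called uORF table with `translated`.
#' @return arithmetic mean of translated-uORF counts over transcripts with
#'   at least one; `NaN` with a warning when no transcript qualifies.
#' @export
uorfs_per_utr <- function(models, uorfs) {
  tr <- uorfs[uorfs$translated, , drop = FALSE]
  if (!nrow(tr)) {
    warning("no transcript with a translated uORF")
    return(NaN)
  }
  counts <- table(tr$transcript_id)
  mean(as.numeric(counts))
}
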