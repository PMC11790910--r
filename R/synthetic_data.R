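#' Simulation configuration
#'
#' Defaults describe a desk-scale transcriptome whose summary statistics
#' mirror a cultured-cell ribosome-profiling experiment: lognormal 5'UTR
#' lengths with median ~150 nt, ~73% of transcripts carrying at least one
#' uORF with on average ~2.3 uORFs per uORF-bearing UTR and a point mass
#' of start-stop (1-aa) uORFs, negative-binomial counts with triplicate
#' libraries per condition and assay, and a knockdown condition in which
#' target transcripts lose translation efficiency (default -1 log2) while
#' uORF footprint occupancy persists.
#'
#' @param n_genes number of genes (one selected transcript each).
#' @param utr_meanlog,utr_sdlog lognormal parameters of 5'UTR length (nt).
#' @param cds_meanlog,cds_sdlog lognormal parameters of CDS length (nt;
#'   rounded to a codon multiple, minimum 9).
#' @param utr3_len fixed 3'UTR length (nt).
#' @param uorf_rate fraction of transcripts carrying at least one uORF.
#' @param uorf_mean mean number of uORFs per uORF-bearing UTR
#'   (zero-truncated Poisson).
#' @param start_stop_frac probability a planted uORF is a start-stop (one
#'   sense codon); otherwise sense-codon count is 1 + geometric.
#' @param uorf_len_geom_p geometric parameter for extra sense codons.
#' @param start_codon_probs named probabilities over AUG/CUG/GUG/UUG.
#' @param te_effect_log2 planted log2 TE change of targets in the
#'   knockdown condition.
#' @param target_frac fraction of uORF-bearing transcripts that respond
#'   to the knockdown (default 0.065, the share of translated-uORF
#'   transcripts with significantly reduced TE in the profiling study
#'   this emulates: 223 of ~3430).
#' @param dispersion negative-binomial dispersion of counts.
#' @param lib_size_rna,lib_size_rpf expected reads per library.
#' @param n_reps replicates per condition x assay.
#' @param conditions condition labels (control first).
#' @param uorf_density_boost footprint density on uORF nt relative to CDS
#'   nt in the control condition.
#' @param utr_bg_density background footprint density on non-uORF 5'UTR nt
#'   relative to CDS nt.
#' @param rpf_len_probs footprint length distribution over 26..35 nt.
#' @param reporter_cv lognormal coefficient of variation of reporter
#'   readouts.
#' @param reporter_reps replicates per reporter construct.
#' @param seed RNG seed (mandatory; every generator call is reproducible
#'   given the seed).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 400L,
                       utr_meanlog = log(150), utr_sdlog = 0.6,
                       cds_meanlog = log(900), cds_sdlog = 0.5,
                       utr3_len = 100L,
                       uorf_rate = 0.73,
                       uorf_mean = 2.28,
                       start_stop_frac = 0.3,
                       uorf_len_geom_p = 1 / 9,
                       start_codon_probs = c(AUG = 0.4, CUG = 0.25,
                                             GUG = 0.2, UUG = 0.15),
                       te_effect_log2 = -1,
                       target_frac = 0.065,
                       dispersion = 0.05,
                       lib_size_rna = 1e5, lib_size_rpf = 5e4,
                       n_reps = 3L,
                       conditions = c("control", "kd"),
                       uorf_density_boost = 1.5,
                       utr_bg_density = 0.02,
                       rpf_len_probs = c(`26` = 0.03, `27` = 0.05,
                                         `28` = 0.12, `29` = 0.22,
                                         `30` = 0.22, `31` = 0.16,
                                         `32` = 0.10, `33` = 0.06,
                                         `34` = 0.03, `35` = 0.01),
                       reporter_cv = 0.1, reporter_reps = 8L,
                       seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(cfg$uorf_rate >= 0, cfg$uorf_rate <= 1,
            cfg$start_stop_frac >= 0, cfg$start_stop_frac <= 1,
            cfg$target_frac >= 0, cfg$target_frac <= 1,
            !is.null(cfg$seed))
  cfg$start_codon_probs <- cfg$start_codon_probs / sum(cfg$start_codon_probs)
  cfg$rpf_len_probs <- cfg$rpf_len_probs / sum(cfg$rpf_len_probs)
  class(cfg) <- "sim_config"
  cfg
}

# background sampler: uniform A/C/G/T with every TG dinucleotide removed,
# so near-cognate start codons (NUG) cannot arise outside planted ones
#' @keywords internal
sample_background <- function(n) {
  if (n <= 0L) return(character(0))
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n >= 2L) {
    tg <- which(s[-n] == "T" & s[-1L] == "G")
    if (length(tg)) s[tg + 1L] <- sample(c("A", "C"), length(tg),
                                         replace = TRUE)
  }
  s
}

# sense codons free of TG (also across junctions: none starts with G),
# excluding stops
SAFE_SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  ok <- !grepl("TG", all3) & !grepl("^G", all3) &
    !all3 %in% c("TAA", "TAG", "TGA")
  all3[ok]
})

#' @keywords internal
build_uorf_seq <- function(start_codon, n_sense) {
  sense <- if (n_sense >= 2L) {
    sample(SAFE_SENSE_CODONS, n_sense - 1L, replace = TRUE)
  } else {
    character(0)
  }
  stopc <- sample(c("TAA", "TAG"), 1L)
  paste0(start_codon, paste(sense, collapse = ""), stopc)
}

#' Simulate a transcriptome with planted uORFs
#'
#' Generates one transcript model per gene with a known 5'UTR/CDS
#' structure and a truth table of planted uORFs. Sequences are built so
#' that the planted uORFs are the only candidate uORFs: backgrounds and
#' planted sense codons avoid the TG dinucleotide outside planted start
#' codons, so no unplanted near-cognate start with an in-frame stop can
#' occur (a deliberate deviation from natural sequence statistics that
#' keeps the truth table exhaustive). uORFs are placed at least 17 nt from
#' the cap so footprint 5' ends stay on the transcript.
#'
#' @param config `sim_config` list.
#' @param sequences generate nucleotide sequences (`TRUE`, default) or
#'   geometry and truth only (faster for count-level studies).
#' @return list with `models` (transcript model `data.frame`) and `truth`
#'   (`data.frame`: `transcript_id`, `start`, `stop_end`, `start_codon`,
#'   `n_sense_codons`, `penultimate_codon`, `kozak_plus4`).
#' @export
simulate_transcriptome <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  utr_len <- pmax(20L, as.integer(round(rlnorm(n, config$utr_meanlog,
                                               config$utr_sdlog))))
  cds_len <- pmax(9L, as.integer(round(rlnorm(n, config$cds_meanlog,
                                              config$cds_sdlog) / 3)) * 3L)
  has_uorf <- runif(n) < config$uorf_rate

  models <- list(); truth <- list()
  for (i in seq_len(n)) {
    tid <- sprintf("tx%04d", i)
    gid <- sprintf("gene%04d", i)
    ul <- utr_len[i]

    placed <- data.frame(start = integer(0), len = integer(0),
                         start_codon = character(0),
                         n_sense = integer(0), stringsAsFactors = FALSE)
    if (has_uorf[i]) {
      # zero-truncated Poisson count of uORFs
      lam <- ztpois_lambda(config$uorf_mean)
      k <- rpois(1L, lam); while (k == 0L) k <- rpois(1L, lam)
      for (attempt in seq_len(30L)) {
        n_sense <- ifelse(runif(k) < config$start_stop_frac, 1L,
                          2L + rgeom_int(k, config$uorf_len_geom_p))
        lens <- 3L * (n_sense + 1L)
        slack <- ul - 17L - sum(lens)
        if (slack >= 0L) break
        if (attempt %% 5L == 0L && k > 1L) k <- k - 1L
      }
      if (slack >= 0L) {
        # nondecreasing gap offsets in [0, slack] keep the last uORF
        # inside the 5'UTR
        offs <- sort(sample.int(slack + 1L, k, replace = TRUE)) - 1L
        starts <- 17L + offs + cumsum(c(0L, lens[-k]))
        codons <- sample(names(config$start_codon_probs), k, replace = TRUE,
                         prob = config$start_codon_probs)
        placed <- data.frame(start = starts, len = lens,
                             start_codon = chartr("U", "T", codons),
                             n_sense = n_sense, stringsAsFactors = FALSE)
      }
    }

    seq_str <- NA_character_
    uorf_seqs <- character(nrow(placed))
    if (sequences) {
      if (nrow(placed)) {
        uorf_seqs <- vapply(seq_len(nrow(placed)), function(j)
          build_uorf_seq(placed$start_codon[j], placed$n_sense[j]),
          character(1))
      }
      parts <- character(0); at <- 0L
      if (nrow(placed)) {
        for (j in seq_len(nrow(placed))) {
          bg <- sample_background(placed$start[j] - at)
          # a planted start beginning with G must not follow a T
          if (length(bg) && substr(placed$start_codon[j], 1, 1) == "G" &&
                bg[length(bg)] == "T")
            bg[length(bg)] <- "A"
          parts <- c(parts, bg, uorf_seqs[j])
          at <- placed$start[j] + placed$len[j]
        }
      }
      parts <- c(parts, sample_background(ul - at))
      # CDS and 3'UTR content is unconstrained: a start codon there cannot
      # begin a uORF (uORF starts lie strictly within the 5'UTR)
      cds_body <- c("A", "T", "G",
                    sample(c("A", "C", "G", "T"), cds_len[i] - 6L,
                           replace = TRUE), "T", "A", "A")
      utr3 <- sample(c("A", "C", "G", "T"), config$utr3_len, replace = TRUE)
      seq_str <- paste(c(parts, cds_body, utr3), collapse = "")
    }

    len_nt <- ul + cds_len[i] + config$utr3_len
    models[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, length_nt = len_nt,
      cds_start = ul, cds_end = ul + cds_len[i],
      sequence = seq_str, stringsAsFactors = FALSE
    )
    if (nrow(placed)) {
      pen <- vapply(seq_len(nrow(placed)), function(j) {
        if (placed$n_sense[j] < 2L) return(NA_character_)
        s <- uorf_seqs[j]
        if (!nzchar(s) || is.na(s)) return(NA_character_)
        rna_codon(substr(s, nchar(s) - 5L, nchar(s) - 3L))
      }, character(1))
      k4 <- vapply(seq_len(nrow(placed)), function(j) {
        s <- uorf_seqs[j]
        if (!nzchar(s) || is.na(s)) return(NA_character_)
        rna_codon(substr(s, 4L, 4L))
      }, character(1))
      truth[[i]] <- data.frame(
        transcript_id = tid,
        start = placed$start,
        stop_end = placed$start + placed$len,
        start_codon = rna_codon(placed$start_codon),
        n_sense_codons = placed$n_sense,
        penultimate_codon = pen,
        kozak_plus4 = k4,
        stringsAsFactors = FALSE
      )
    }
  }
  models <- do.call(rbind, c(models, list(make.row.names = FALSE)))
  truth <- if (length(truth))
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else
    data.frame(transcript_id = character(0), start = integer(0),
               stop_end = integer(0), start_codon = character(0),
               n_sense_codons = integer(0),
               penultimate_codon = character(0),
               kozak_plus4 = character(0), stringsAsFactors = FALSE)
  validate_models(models, complete = TRUE)
  list(models = models, truth = truth)
}

#' @keywords internal
ztpois_lambda <- function(target_mean) {
  # solve mean of zero-truncated Poisson = target
  f <- function(l) l / (1 - exp(-l)) - target_mean
  stats::uniroot(f, c(1e-6, 50))$root
}

#' @keywords internal
rgeom_int <- function(n, p) as.integer(rgeom_safe(n, p))

#' @keywords internal
rgeom_safe <- function(n, p) stats::rgeom(n, p)

#' Simulate region counts and footprint reads
#'
#' RNA counts are negative-binomial with mean proportional to transcript
#' abundance times region length. Footprint (RPF) CDS counts scale with
#' abundance, CDS length and per-transcript translation efficiency, which
#' is reduced by the planted effect for target transcripts in the
#' knockdown condition; footprint 5'UTR signal sits on planted uORFs
#' (density `uorf_density_boost` relative to the CDS) and persists in the
#' knockdown, emulating ribosomes retained on uORFs when re-initiation is
#' lost. Read-level records place A-sites uniformly within their region
#' (90% of 5'UTR footprints on uORF nucleotides) and derive 5' positions
#' by inverting the fixed A-site offsets, with footprint lengths drawn
#' from `rpf_len_probs`.
#'
#' @param config `sim_config`.
#' @param models,truth output of [simulate_transcriptome()].
#' @param reads also generate read-level records (slower); the returned
#'   region counts are exactly the counts of the generated reads.
#' @return list with `counts` (`region_counts`), `samples` sample sheet,
#'   `reads` (`data.frame` or `NULL`), `targets` (`data.frame`:
#'   `transcript_id`, `is_target`, `te_effect_log2`).
#' @export
simulate_counts <- function(config, models, truth, reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(models)
  tx <- models$transcript_id
  utr_len <- models$cds_start
  cds_len <- models$cds_end - models$cds_start

  uorf_nt <- setNames(rep(0L, n), tx)
  if (nrow(truth)) {
    agg <- tapply(truth$stop_end - truth$start, truth$transcript_id, sum)
    uorf_nt[names(agg)] <- as.integer(agg)
  }
  has_uorf <- uorf_nt > 0L

  abundance <- rlnorm(n, meanlog = 0, sdlog = 1)
  te <- rlnorm(n, meanlog = 0, sdlog = 0.3)
  is_target <- has_uorf & runif(n) < config$target_frac
  te_eff <- ifelse(is_target, config$te_effect_log2, 0)

  samples <- expand.grid(replicate = seq_len(config$n_reps),
                         assay = c("RNA", "RPF"),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$condition, samples$assay,
                             paste0("rep", samples$replicate), sep = "_")
  samples <- samples[, c("sample_id", "condition", "assay", "replicate")]

  cols <- do.call(rbind, lapply(c("UTR5", "CDS"), function(r)
    cbind(samples, region = r, stringsAsFactors = FALSE)))
  cols <- cols[order(cols$sample_id, cols$assay, cols$region), , drop = FALSE]
  rownames(cols) <- NULL
  counts <- matrix(0L, nrow = n, ncol = nrow(cols),
                   dimnames = list(tx, paste(cols$sample_id, cols$assay,
                                             cols$region, sep = ".")))

  read_list <- if (reads) vector("list", nrow(cols)) else NULL
  rpf_lens <- as.integer(names(config$rpf_len_probs))

  for (j in seq_len(nrow(cols))) {
    as_ <- cols$assay[j]; reg <- cols$region[j]; cond <- cols$condition[j]
    kd <- cond != config$conditions[1]
    if (as_ == "RNA") {
      w <- abundance * (if (reg == "UTR5") utr_len else cds_len)
      mu <- config$lib_size_rna * w / sum(abundance * (utr_len + cds_len))
    } else {
      w_cds <- abundance * cds_len * te * (if (kd) 2^te_eff else rep(1, n))
      w_utr <- abundance * te *
        (uorf_nt * config$uorf_density_boost +
           (utr_len - uorf_nt) * config$utr_bg_density)
      w <- if (reg == "UTR5") w_utr else w_cds
      # library share of each region reflects the sample's own totals
      mu <- config$lib_size_rpf * w / sum(w_cds + w_utr)
    }
    y <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
    counts[, j] <- y

    if (reads) {
      tot_reads <- sum(y)
      if (tot_reads == 0L) { read_list[[j]] <- NULL; next }
      tx_rep <- rep.int(tx, y)
      pos <- integer(tot_reads)
      idx <- rep.int(seq_len(n), y)
      if (reg == "CDS") {
        pos <- models$cds_start[idx] +
          floor(runif(tot_reads) * cds_len[idx])
      } else {
        # 5'UTR: for RPF put 90% of A-sites on uORF nt when present
        pos <- 17L + floor(runif(tot_reads) * pmax(1L, utr_len[idx] - 17L))
        if (as_ == "RPF" && nrow(truth)) {
          on_uorf <- has_uorf[idx] & runif(tot_reads) < 0.9
          if (any(on_uorf)) {
            pick <- which(on_uorf)
            spl <- split(pick, tx_rep[pick])
            for (t in names(spl)) {
              iv <- truth[truth$transcript_id == t, , drop = FALSE]
              ivlen <- iv$stop_end - iv$start
              kk <- spl[[t]]
              row <- sample.int(nrow(iv), length(kk), replace = TRUE,
                                prob = ivlen)
              pos[kk] <- iv$start[row] +
                floor(runif(length(kk)) * ivlen[row])
            }
          }
        }
      }
      if (as_ == "RPF") {
        len <- sample(rpf_lens, tot_reads, replace = TRUE,
                      prob = config$rpf_len_probs)
        five <- pos - ifelse(len <= 31L, 16L, 17L)
      } else {
        len <- sample(21:60, tot_reads, replace = TRUE)
        five <- pos
      }
      read_list[[j]] <- data.frame(
        transcript_id = tx_rep, five_prime_pos = as.integer(five),
        read_length = as.integer(len), assay = as_,
        sample_id = cols$sample_id[j], stringsAsFactors = FALSE
      )
    }
  }

  rc <- structure(list(counts = counts, cols = cols),
                  class = "region_counts")
  list(
    counts = rc,
    samples = samples,
    reads = if (reads)
      do.call(rbind, c(read_list[!vapply(read_list, is.null, logical(1))],
                       list(make.row.names = FALSE)))
    else NULL,
    targets = data.frame(transcript_id = tx, is_target = is_target,
                         te_effect_log2 = te_eff, stringsAsFactors = FALSE)
  )
}

#' Simulate three-reporter dual-luciferase readouts
#'
#' Forward model of the reporter assay: with leaky-scanning probability
#' `true_leaky` and conditional re-initiation probability
#' `true_conditional_reinit`, the noiseless expectations are `no_uorf =
#' 100`, `overlapping = 100 * leaky` and `wt = 100 * (leaky + (1 - leaky)
#' * reinit)`. Multiplicative lognormal noise with coefficient of
#' variation `cv` is applied to the firefly readout; Renilla is an
#' independent lognormal, exercising the ratio normalization.
#'
#' @param true_leaky,true_conditional_reinit probabilities in \[0, 1\].
#' @param n_reps replicates per construct.
#' @param cv lognormal CV of the readouts (0 gives noiseless signals).
#' @param genotype genotype label for the generated rows.
#' @param firefly_scale,renilla_scale mean raw luminescence of the
#'   no-uORF firefly signal and of Renilla.
#' @param seed RNG seed.
#' @return reporter measurement `data.frame` (see
#'   [normalize_reporters()]).
#' @export
simulate_reporters <- function(true_leaky, true_conditional_reinit,
                               n_reps = 8L, cv = 0.1, genotype = "WT",
                               firefly_scale = 1e5, renilla_scale = 2e5,
                               seed = 42) {
  stopifnot(true_leaky >= 0, true_leaky <= 1,
            true_conditional_reinit >= 0, true_conditional_reinit <= 1)
  set.seed(seed)
  expect <- c(
    no_uorf = 100,
    wt_uorf = 100 * (true_leaky + (1 - true_leaky) * true_conditional_reinit),
    overlapping_uorf = 100 * true_leaky
  )
  sdlog <- sqrt(log(1 + cv^2))
  out <- do.call(rbind, lapply(names(expect), function(cc) {
    noise_f <- if (cv > 0) rlnorm(n_reps, -sdlog^2 / 2, sdlog) else rep(1, n_reps)
    noise_r <- if (cv > 0) rlnorm(n_reps, -sdlog^2 / 2, sdlog) else rep(1, n_reps)
    data.frame(
      construct = cc, genotype = genotype, replicate = seq_len(n_reps),
      firefly = firefly_scale * (expect[[cc]] / 100 + 1e-12) * noise_f,
      renilla = renilla_scale * noise_r,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
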