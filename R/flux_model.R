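#' Normalize dual-luciferase reporter measurements
#'
#' Per replicate, the reporter signal is the firefly/Renilla ratio
#' (Renilla is the internal transfection/translation control). Within each
#' genotype (lysate), the mean ratio of the `no_uorf` construct is set to
#' 100% and every construct's replicate ratios are expressed on that
#' scale.
#'
#' @param measurements `data.frame` with columns `construct` (one of
#'   `no_uorf`, `wt_uorf`, `overlapping_uorf`), `genotype`, `replicate`,
#'   `firefly`, `renilla` (both positive).
#' @return the input with `ratio` and `norm_pct` columns added.
#' @export
normalize_reporters <- function(measurements) {
  need <- c("construct", "genotype", "replicate", "firefly", "renilla")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("reporter table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(measurements$firefly <= 0) || any(measurements$renilla <= 0))
    stop("firefly and renilla readouts must be positive")
  out <- measurements
  out$ratio <- out$firefly / out$renilla
  out$norm_pct <- NA_real_
  for (g in unique(out$genotype)) {
    i <- out$genotype == g
    base <- out$ratio[i & out$construct == "no_uorf"]
    if (!length(base))
      stop("genotype ", g, " lacks a no_uorf construct")
    out$norm_pct[i] <- out$ratio[i] * (100 / mean(base))
  }
  out
}

#' Decompose three-reporter signal into ribosome fluxes
#'
#' With the no-uORF reporter at 100%, the overlapping-uORF reporter
#' (readable only through leaky scanning) gives the leaky-scanning
#' percentage directly, the WT-uORF minus overlapping-uORF signal is the
#' re-initiation-mediated percentage, and 100 minus the WT-uORF signal is
#' the uORF inhibition. The uORF-engaged fraction is 100 minus leaky
#' scanning, and the conditional re-initiation probability is
#' re-initiation divided by uORF engagement: the chance that a ribosome
#' which terminated on the uORF re-initiates on the CDS.
#'
#' The three percentages sum to 100 exactly by construction. Negative
#' re-initiation (measurement noise) and signals above 100 are preserved
#' and flagged rather than clamped, so replicate averages stay unbiased.
#'
#' @param no_uorf,wt,overlapping normalized percent signals; `no_uorf`
#'   must be 100 (the scale anchor).
#' @return object of class `flux_estimate`: list with `leaky_pct`,
#'   `reinit_pct`, `inhibition_pct`, `uorf_engaged_pct`,
#'   `conditional_reinit` and `flags`.
#' @export
decompose_flux <- function(no_uorf = 100, wt, overlapping) {
  if (abs(no_uorf - 100) > 1e-9)
    stop("signals must be normalized so that no_uorf = 100")
  wt <- unname(wt); overlapping <- unname(overlapping)
  leaky <- overlapping
  reinit <- wt - overlapping
  inhibition <- 100 - wt
  engaged <- 100 - overlapping
  flags <- character(0)
  if (reinit < 0) flags <- c(flags, "negative_reinit")
  if (wt > 100) flags <- c(flags, "wt_above_100")
  if (overlapping > 100) flags <- c(flags, "overlapping_above_100")
  structure(list(
    leaky_pct = leaky,
    reinit_pct = reinit,
    inhibition_pct = inhibition,
    uorf_engaged_pct = engaged,
    conditional_reinit = if (engaged > 0) reinit / engaged else NA_real_,
    flags = flags
  ), class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, digits = 3, ...) {
  cat("Ribosome flux decomposition (% of no-uORF signal)\n")
  cat("  leaky scanning: ", signif(x$leaky_pct, digits),
      "\n  re-initiation:  ", signif(x$reinit_pct, digits),
      "\n  uORF inhibition:", signif(x$inhibition_pct, digits),
      "\n  uORF engaged:   ", signif(x$uorf_engaged_pct, digits),
      "  (conditional re-initiation ",
      signif(x$conditional_reinit, digits), ")\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @keywords internal
construct_means <- function(norm, genotype) {
  d <- norm[norm$genotype == genotype, , drop = FALSE]
  vapply(c("no_uorf", "wt_uorf", "overlapping_uorf"), function(cc) {
    v <- d$norm_pct[d$construct == cc]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
}

#' Fit the reporter flux model to dual-luciferase data
#'
#' The model-fitting entry point for the three-reporter assay: normalizes
#' replicate readouts within each genotype, decomposes construct means
#' into leaky scanning, re-initiation and uORF inhibition, and attaches
#' nonparametric bootstrap percentile confidence intervals (replicates
#' resampled within each construct, the whole normalize-and-decompose
#' computation repeated per resample).
#'
#' With few replicates, raw percentile intervals are systematically
#' narrow (coverage error of order 1/n). The default therefore uses
#' expanded percentile levels: the nominal tail probability is widened by
#' the usual t-versus-normal small-sample factor,
#' `alpha'/2 = Phi(-sqrt(n/(n-1)) * t_(1-alpha/2, n-1))`, with `n` the
#' smallest replicate count across constructs (Hesterberg's expanded
#' percentile interval). `expand = FALSE` gives the plain percentile
#' interval.
#'
#' @param measurements reporter `data.frame` (see [normalize_reporters()]).
#' @param n_boot bootstrap resamples (0 skips CIs); CIs are also skipped,
#'   with a message, for genotypes where any construct has fewer than 3
#'   replicates.
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap (reproducible for a fixed seed).
#' @param expand use expanded percentile levels (default) or the plain
#'   percentile interval.
#' @return object of class `reporter_flux`: list of per-genotype
#'   estimates (`flux_estimate` plus `ci` matrix and `n_replicates`),
#'   with the normalized data attached.
#' @export
reporter_flux <- function(measurements, n_boot = 2000L, conf = 0.95,
                          seed = 42, expand = TRUE) {
  norm <- normalize_reporters(measurements)
  genos <- unique(norm$genotype)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(genos, function(g) {
    m <- construct_means(norm, g)
    if (anyNA(m))
      stop("genotype ", g, " lacks construct(s): ",
           paste(names(m)[is.na(m)], collapse = ", "))
    est <- decompose_flux(100, wt = m["wt_uorf"] * 100 / m["no_uorf"],
                          overlapping = m["overlapping_uorf"] * 100 / m["no_uorf"])
    d <- norm[norm$genotype == g, , drop = FALSE]
    nrep <- vapply(c("no_uorf", "wt_uorf", "overlapping_uorf"),
                   function(cc) sum(d$construct == cc), integer(1))
    est$n_replicates <- nrep
    est$ci <- NULL
    if (n_boot > 0L && all(nrep >= 3L)) {
      ratios <- lapply(c("no_uorf", "wt_uorf", "overlapping_uorf"),
                       function(cc) d$ratio[d$construct == cc])
      alpha2 <- (1 - conf) / 2
      if (expand) {
        nmin <- min(nrep)
        alpha2 <- pnorm(-sqrt(nmin / (nmin - 1)) *
                          stats::qt(1 - alpha2, df = nmin - 1))
      }
      qs <- c(alpha2, 1 - alpha2)
      boot <- vapply(seq_len(n_boot), function(b) {
        mb <- vapply(ratios, function(v)
          mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
        wt_b <- 100 * mb[2] / mb[1]
        ov_b <- 100 * mb[3] / mb[1]
        c(leaky_pct = ov_b, reinit_pct = wt_b - ov_b,
          inhibition_pct = 100 - wt_b, uorf_engaged_pct = 100 - ov_b,
          conditional_reinit = if (ov_b < 100) (wt_b - ov_b) / (100 - ov_b)
          else NA_real_)
      }, numeric(5))
      est$ci <- t(apply(boot, 1L, quantile, probs = qs, na.rm = TRUE))
    } else if (n_boot > 0L) {
      message("genotype ", g,
              ": fewer than 3 replicates in some construct; CIs skipped")
    }
    est
  })
  names(fits) <- genos
  structure(list(fits = fits, data = norm, conf = conf, n_boot = n_boot),
            class = "reporter_flux")
}

#' @export
print.reporter_flux <- function(x, ...) {
  for (g in names(x$fits)) {
    cat("== genotype:", g, "==\n")
    print(x$fits[[g]])
    if (!is.null(x$fits[[g]]$ci)) {
      cat("  ", 100 * x$conf, "% bootstrap CIs:\n", sep = "")
      print(round(x$fits[[g]]$ci, 2))
    }
  }
  invisible(x)
}

#' @method coef reporter_flux
#' @export
coef.reporter_flux <- function(object, ...) {
  t(vapply(object$fits, function(f) {
    c(leaky_pct = f$leaky_pct, reinit_pct = f$reinit_pct,
      inhibition_pct = f$inhibition_pct,
      uorf_engaged_pct = f$uorf_engaged_pct,
      conditional_reinit = f$conditional_reinit)
  }, numeric(5)))
}

#' @method confint reporter_flux
#' @export
confint.reporter_flux <- function(object, parm, level, ...) {
  lapply(object$fits, function(f) f$ci)
}

#' @method summary reporter_flux
#' @export
summary.reporter_flux <- function(object, ...) {
  print(object)
  invisible(coef(object))
}

#' Bootstrap uncertainty for a single-genotype flux decomposition
#'
#' Convenience wrapper around [reporter_flux()] for measurements of one
#' genotype.
#'
#' @inheritParams reporter_flux
#' @return a `flux_estimate` with `ci` matrix attached (or `NULL` CI when
#'   fewer than 3 replicates per construct).
#' @export
flux_uncertainty <- function(measurements, n_boot = 2000L, conf = 0.95,
                             seed = 42, expand = TRUE) {
  g <- unique(measurements$genotype)
  if (length(g) != 1L) stop("flux_uncertainty expects a single genotype")
  reporter_flux(measurements, n_boot = n_boot, conf = conf,
                seed = seed, expand = expand)$fits[[1L]]
}

#' Compare reporter fluxes between genotypes
#'
#' Per construct, a two-tailed unpaired t-test (pooled variance by
#' default, Welch optionally) on the normalized replicate signals between
#' two genotypes. When `interaction_constructs` names two constructs, a
#' two-way fixed-effects ANOVA interaction p-value (genotype x construct)
#' is also returned, asking whether the genotype effect differs between
#' the reporter variants.
#'
#' @param measurements reporter `data.frame`.
#' @param genotype_a,genotype_b genotype labels.
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @param interaction_constructs optional length-2 character vector of
#'   constructs for the 2 x 2 interaction ANOVA.
#' @return list with `tests` (`data.frame`: construct, t, df, p_value,
#'   mean_a, mean_b) and `interaction_p` (`NA` when not requested).
#' @export
compare_fluxes <- function(measurements, genotype_a, genotype_b,
                           var_equal = TRUE, interaction_constructs = NULL) {
  norm <- normalize_reporters(measurements)
  constructs <- intersect(unique(norm$construct[norm$genotype == genotype_a]),
                          unique(norm$construct[norm$genotype == genotype_b]))
  tests <- do.call(rbind, lapply(constructs, function(cc) {
    va <- norm$norm_pct[norm$genotype == genotype_a & norm$construct == cc]
    vb <- norm$norm_pct[norm$genotype == genotype_b & norm$construct == cc]
    if (length(va) < 2L || length(vb) < 2L)
      return(data.frame(construct = cc, t = NA_real_, df = NA_real_,
                        p_value = NA_real_, mean_a = mean(va),
                        mean_b = mean(vb)))
    tt <- tryCatch(t.test(va, vb, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # zero-variance groups: equal means carry no evidence, unequal
      # constant means are infinitely separated
      equal <- isTRUE(all.equal(mean(va), mean(vb)))
      tt <- list(statistic = if (equal) 0 else Inf * sign(mean(va) - mean(vb)),
                 parameter = length(va) + length(vb) - 2,
                 p.value = if (equal) 1 else 0)
    }
    data.frame(construct = cc, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = unname(tt$p.value),
               mean_a = mean(va), mean_b = mean(vb),
               stringsAsFactors = FALSE)
  }))
  interaction_p <- NA_real_
  if (!is.null(interaction_constructs)) {
    stopifnot(length(interaction_constructs) == 2L)
    d <- norm[norm$genotype %in% c(genotype_a, genotype_b) &
                norm$construct %in% interaction_constructs, , drop = FALSE]
    d$genotype <- factor(d$genotype)
    d$construct <- factor(d$construct)
    av <- stats::anova(aov(norm_pct ~ genotype * construct, data = d))
    interaction_p <- av["genotype:construct", "Pr(>F)"]
  }
  list(tests = tests, interaction_p = interaction_p)
}
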