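#' Negative-binomial interaction model for differential translation
#' efficiency
#'
#' For each transcript, fits a log-linear negative-binomial model to the
#' CDS counts of both assays and conditions,
#' `count ~ condition + assay + condition:assay + offset(log(effective
#' library size))`, where the effective library size is the column total
#' times its TMM factor. The `condition:assay` interaction is the change
#' in translation efficiency between conditions (a transcript whose RPF
#' and RNA counts move together has interaction 0); the condition main
#' effect on the reference assay (RNA) is the RNA-abundance change.
#'
#' Estimation is iteratively reweighted least squares (`stats::glm` with a
#' fixed-dispersion NB family), alternated with a per-transcript
#' method-of-moments dispersion estimate that matches the Pearson
#' statistic to its residual degrees of freedom; the dispersion is floored
#' at 1e-8. P-values are two-sided Wald tests on the asymptotic normal of
#' each coefficient. Transcripts whose fit fails to converge are flagged
#' and given p = 1.
#'
#' This is a deliberately simplified interaction test in the deltaTE
#' spirit: per-transcript dispersions are not shrunk across transcripts
#' and fold changes are unmoderated.
#'
#' @param rc `region_counts` object; only `region == "CDS"` columns are
#'   used. `cols` must carry `condition` and `assay`.
#' @param condition_ref,assay_ref reference levels (defaults: first
#'   condition alphabetically, and `"RNA"`).
#' @param size_factors optional named effective-library-size vector per
#'   column key `"<sample_id>.<assay>"`; computed from TMM x library size
#'   when `NULL`.
#' @param max_iter maximum dispersion/IRLS alternations.
#' @return object of class `dte_fit`: `data.frame` with `transcript_id`,
#'   `log2fc_rna`, `log2fc_te`, `se_te`, `p_rna`, `p_te`, `dispersion`,
#'   `converged`.
#' @export
fit_te_interaction <- function(rc, condition_ref = NULL, assay_ref = "RNA",
                               size_factors = NULL, max_iter = 5L) {
  stopifnot(inherits(rc, "region_counts"))
  jj <- which(rc$cols$region == "CDS")
  counts <- rc$counts[, jj, drop = FALSE]
  cols <- rc$cols[jj, , drop = FALSE]
  if (!all(c("condition", "assay") %in% names(cols)))
    stop("sample metadata must carry 'condition' and 'assay'")
  conds <- sort(unique(cols$condition))
  if (length(conds) != 2L || length(unique(cols$assay)) != 2L)
    stop("a 2 condition x 2 assay design is required")
  if (is.null(condition_ref)) condition_ref <- conds[1]
  cond <- factor(cols$condition,
                 levels = c(condition_ref, setdiff(conds, condition_ref)))
  assay <- factor(cols$assay,
                  levels = c(assay_ref, setdiff(unique(cols$assay), assay_ref)))
  if (min(table(cond, assay)) < 2L)
    stop("need at least 2 replicates per condition x assay cell")

  if (is.null(size_factors)) {
    sf <- numeric(ncol(counts))
    for (as_ in levels(assay)) {
      k <- which(assay == as_)
      f <- tmm_factors(counts[, k, drop = FALSE])
      sf[k] <- colSums(counts[, k, drop = FALSE]) * f
    }
  } else {
    sf <- size_factors[paste(cols$sample_id, cols$assay, sep = ".")]
    if (anyNA(sf)) stop("size_factors do not cover all columns")
  }
  off <- log(sf)
  X <- stats::model.matrix(~ cond * assay)
  df_res <- ncol(counts) - ncol(X)
  i_te <- grep(":", colnames(X))
  i_rna <- grep("^cond", setdiff(colnames(X), colnames(X)[i_te]), value = TRUE)

  fit_one <- function(y) {
    if (all(y == 0))
      return(c(NA, NA, NA, 1, 1, NA, 0))
    phi <- 1e-8
    fit <- NULL
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      fam <- if (phi <= 1e-8) poisson(link = "log") else
        MASS::negative.binomial(theta = 1 / phi, link = "log")
      fit <- tryCatch(
        suppressWarnings(glm(y ~ cond * assay, family = fam, offset = off)),
        error = function(e) NULL)
      if (is.null(fit)) break
      mu <- fit$fitted.values
      # moment update from the quadratic variance var = mu + phi * mu^2
      num <- sum((y - mu)^2) - sum(mu)
      den <- sum(mu^2)
      phi_new <- max(1e-8, num / den)
      ok <- fit$converged
      if (abs(log(phi_new + 1e-8) - log(phi + 1e-8)) < 1e-3) {
        phi <- phi_new
        break
      }
      phi <- phi_new
    }
    if (is.null(fit) || !ok)
      return(c(NA, NA, NA, 1, 1, phi, 0))
    sm <- suppressWarnings(summary(fit)$coefficients)
    b <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    z_te <- b[i_te] / se[i_te]
    z_rna <- b[i_rna] / se[i_rna]
    c(b[i_rna] / log(2), b[i_te] / log(2), se[i_te] / log(2),
      2 * pnorm(-abs(z_rna)), 2 * pnorm(-abs(z_te)), phi, 1)
  }

  res <- t(apply(counts, 1L, fit_one))
  out <- data.frame(
    transcript_id = rownames(counts),
    log2fc_rna = res[, 1], log2fc_te = res[, 2], se_te = res[, 3],
    p_rna = res[, 4], p_te = res[, 5],
    dispersion = res[, 6], converged = res[, 7] == 1,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("dte_fit", "data.frame"),
            condition_ref = condition_ref,
            condition_alt = setdiff(conds, condition_ref),
            df_res = df_res)
}

#' @export
print.dte_fit <- function(x, ...) {
  cat("Differential translation efficiency fit: ", nrow(x),
      " transcripts, ", attr(x, "condition_alt"), " vs ",
      attr(x, "condition_ref"), "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more)\n", sep = "")
  invisible(x)
}

#' @method summary dte_fit
#' @export
summary.dte_fit <- function(object, fdr_threshold = 0.1, ...) {
  cl <- adjust_and_classify(object, fdr_threshold)
  tab <- table(cl$class)
  cat("FDR <", fdr_threshold, ":",
      sum(cl$class == "te_down"), "TE down,",
      sum(cl$class == "te_up"), "TE up,",
      sum(cl$class == "rna_only"), "RNA only\n")
  invisible(tab)
}

#' Adjust p-values and classify transcripts
#'
#' Benjamini-Hochberg adjustment within each contrast (TE interaction and
#' RNA main effect separately), then classification at the FDR threshold:
#' `te_down`/`te_up` when the TE interaction is significant (by sign),
#' `rna_only` when only the RNA effect is, else `unchanged`.
#'
#' @param fit `dte_fit` object (or `data.frame` with `p_te`, `p_rna`,
#'   `log2fc_te`).
#' @param fdr_threshold significance threshold on the adjusted values
#'   (default 0.1).
#' @return `data.frame` with `fdr_te`, `fdr_rna` and `class` added.
#' @export
adjust_and_classify <- function(fit, fdr_threshold = 0.1) {
  out <- as.data.frame(fit)
  out$fdr_te <- p.adjust(out$p_te, method = "BH")
  out$fdr_rna <- p.adjust(out$p_rna, method = "BH")
  cls <- rep("unchanged", nrow(out))
  sig_te <- !is.na(out$fdr_te) & out$fdr_te < fdr_threshold
  cls[sig_te & out$log2fc_te < 0] <- "te_down"
  cls[sig_te & out$log2fc_te >= 0] <- "te_up"
  sig_rna <- !is.na(out$fdr_rna) & out$fdr_rna < fdr_threshold
  cls[!sig_te & sig_rna] <- "rna_only"
  out$class <- cls
  out
}
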