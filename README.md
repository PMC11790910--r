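# uorfflux

Upstream open reading frames (uORFs) intercept ribosomes scanning the 5'UTR
and are generally inhibitory to translation of the main coding sequence
(CDS). Two routes keep CDS translation going: **leaky scanning** (the
preinitiation complex ignores the uORF start codon) and **re-initiation**
(after terminating on the uORF, the 40S subunit resumes scanning and
initiates again downstream, a step that depends on non-canonical factors
such as MCTS1-DENR). `uorfflux` is an R toolkit for quantifying these
processes from the two data types such studies produce:

* **Ribosome profiling + RNA-seq** — transcript-space footprint records are
  size-filtered (RPF 26–35 nt, RNA 21–60 nt), assigned A-site positions
  (5' end +16 for reads ≤31 nt, +17 otherwise), counted on 5'UTR vs CDS,
  TMM/TPM-normalized, and summarized as translation efficiency
  TE = log2(CDS footprint / CDS RNA). Translated uORFs are annotated from
  footprint coverage (near-cognate starts AUG/CUG/GUG/UUG, in-frame stop
  within the 5'UTR, ≥33% coverage, overlaps resolved by read density), with
  Fisher-type enrichment tests, Kolmogorov–Smirnov 5'UTR-length
  comparisons, a simplified negative-binomial interaction test for
  differential TE (condition × assay, Wald, BH FDR), and a Wilcoxon
  signed-rank statistic for ribosome redistribution from CDS to 5'UTR.

* **Three-reporter dual-luciferase assays** — a no-uORF reporter (anchored
  at 100%), a WT-uORF reporter, and an overlapping-uORF reporter readable
  only through leaky scanning. With normalized signals the decomposition is

  ```
  leaky      = overlapping
  reinit     = wt − overlapping
  inhibition = 100 − wt          (the three sum to 100 exactly)
  engaged    = 100 − leaky
  conditional re-initiation = reinit / engaged
  ```

  `reporter_flux()` fits this to replicate firefly/Renilla readouts and
  attaches bootstrap confidence intervals (expanded percentile).

A synthetic-data module generates every input with known ground truth
(planted uORFs, planted TE effects, known leaky/re-initiation rates), so
the whole pipeline is testable without any sequencing download.

## Worked example

Simulate reporter assays for a wild-type lysate (2% leaky scanning,
conditional re-initiation 0.19/0.98) and a re-initiation-factor knockout
(re-initiation lost), then fit the flux model:

```r
library(uorfflux)
d <- rbind(
  simulate_reporters(0.02, 0.19/0.98, n_reps = 6, cv = 0.1, genotype = "WT",      seed = 7),
  simulate_reporters(0.02, 0.01,      n_reps = 6, cv = 0.1, genotype = "Denr_KO", seed = 8))
fit <- reporter_flux(d, n_boot = 2000, seed = 42)
fit
#> == genotype: WT ==
#> Ribosome flux decomposition (% of no-uORF signal)
#>   leaky scanning: 2.37
#>   re-initiation:  22.1
#>   uORF inhibition:75.6
#>   uORF engaged:   97.6  (conditional re-initiation 0.226)
#> ...
#> == genotype: Denr_KO ==
#>   leaky scanning: 1.78
#>   re-initiation:  0.813
#>   uORF inhibition:97.4
#>   uORF engaged:   98.2  (conditional re-initiation 0.00827)
```

Almost all ribosomes engage the uORF in both lysates (leaky scanning ~2%),
but the ~22% of terminating ribosomes that re-initiate on the CDS in WT
drop to ~1% in the knockout — the WT-uORF reporter signal collapses onto
the leaky-scanning floor. The per-construct comparison makes that formal:

```r
compare_fluxes(d, "WT", "Denr_KO")$tests
#>          construct      t df   p_value mean_a mean_b
#> 1          no_uorf   0.00 10   1.00000 100.00 100.00
#> 2          wt_uorf  14.08 10   6.4e-08  24.44   2.60
#> 3 overlapping_uorf   3.35 10   0.00731   2.37   1.78
```

The profiling side runs the same way from read records:

```r
cfg <- sim_config(n_genes = 300, seed = 1)
sim <- simulate_transcriptome(cfg)
counts <- simulate_counts(cfg, sim$models, sim$truth)
res <- run_profiling_pipeline(sim$models, counts$reads,
                              samples = counts$samples, output_dir = "out",
                              condition_treated = "kd",
                              condition_control = "control")
res$summary$class_counts    # 186 translated-uORF / 36 candidate-only / 78 none
res$summary$shift_median    # 5'UTR-vs-CDS footprint redistribution
```

All stage outputs (region counts, TE table, uORF BED/TSV, differential-TE
table, JSON summary) are written to `output_dir`.

## Vignette

`vignettes/uorf-flux-methods.Rmd` documents the models, parameter
defaults, normalization choices, the synthetic-data generator and its
limitations, and the numerical design decisions.
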