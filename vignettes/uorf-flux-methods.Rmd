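---
title: "Methods: quantifying uORF-dependent translation and re-initiation fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying uORF-dependent translation and re-initiation fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfflux)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design decisions taken where the
methodology was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate convention

All positions are 0-based, half-open, in transcript space, with position
0 at the transcript 5' end. A transcript model stores its CDS as
`[cds_start, cds_end)`; the 5'UTR is `[0, cds_start)` so the 5'UTR length
equals `cds_start`, and `cds_end - cds_start` is a multiple of 3 for
complete models. Genome-space GTF/GFF input is projected into this space
by concatenating exons 5'-to-3' with the strand resolved
(`load_transcript_models()`); the projection is validated in the tests
against a brute-force per-base mapping. `U` and `T` are interchangeable on
input and normalized internally to `T`; codons are reported in the RNA
alphabet.

## Footprint quantification

**Size filter.** Ribosome-protected fragments are kept at 26–35 nt and
RNA reads at 21–60 nt, both bounds inclusive. These windows reflect the
monosome footprint size range plus the library's RNA fragmentation range.

**A-site assignment.** The decoding position of a footprint is estimated
from its 5' end with a fixed, length-dependent offset: +16 nt for reads of
at most 31 nt and +17 nt for longer reads. Offsets are deliberately fixed
rather than learned from periodicity — the package targets region-level
(5'UTR vs CDS) and uORF-interval counting, where a one-codon refinement is
immaterial. Reads whose A-site would fall past the transcript end are
dropped and counted.

**Region counting.** An A-site at `p` counts to the 5'UTR iff
`p < cds_start` and to the CDS iff `cds_start <= p < cds_end`; 3'UTR
positions are left uncounted, so every A-site lands in exactly one of
three disjoint bins and totals are conserved. Transcripts with fewer than
10 counts summed over all samples, assays and regions are removed
(`filter_low_counts()`, threshold configurable).

**Normalization.** Between-sample factors are trimmed-mean-of-M-values
(TMM) with the canonical parameters — reference sample by upper quartile
closest to the mean upper quartile, 30%/5% trimming of the M and A tails,
inverse asymptotic-variance weights, factors rescaled to geometric mean 1
— computed per assay on CDS counts (the region-level choice is
configurable; CDS counts dominate library composition and are the
quantity entering TE). The implementation delegates to
`edgeR::calcNormFactors`; the test suite holds it to an independently
coded implementation of the definition at 1e-10. Counts are then
expressed as transcripts per million with region-length normalization:
`rate = count / (effective library size x region length)`, rescaled so
each sample x assay sums to 1e6. Note that a per-sample compositional
unit like TPM absorbs any global scale factor, so the TMM factors matter
exactly where normalization matters: through the effective library sizes
used as offsets in the count-level interaction model below.

**Translation efficiency.** Per replicate (RPF and RNA libraries matched
by condition and replicate), `te = log2(CDS_RPF / CDS_RNA)` on normalized
values; per condition the arithmetic mean of the log2 values over
replicates. Zeros are not imputed: transcripts with a zero term in any
replicate are excluded and reported, which avoids pseudocount bias at the
cost of dropping the weakest signals.

**5'UTR/CDS redistribution.** For transcripts with nonzero 5'UTR and CDS
footprint signal in both conditions, the statistic is
`log2((UTR5/CDS)_treated) - log2((UTR5/CDS)_control)` on replicate-mean
normalized values, tested against a zero median with a one-sample
Wilcoxon signed-rank test (undefined below 5 transcripts). When a
re-initiation factor is lost, ribosomes are still delivered to uORFs but
fail to reach the CDS, so the distribution shifts positive.

## uORF annotation

For genes with several expressed isoforms, footprints in the 5'UTR are
only unambiguous when all expressed isoforms share the CDS start; in that
case the isoform with the longest 5'UTR is used, otherwise the gene is
excluded (`select_uorf_transcript()`). "Expressed" means abundance
strictly above a configurable threshold whose default is 0 — any positive
abundance counts, since no published FPKM cutoff exists for this step.

Candidate uORFs satisfy: (i) start codon AUG, CUG, GUG or UUG — the
near-cognate set that initiating ribosomes use in 5'UTRs; (ii) first
in-frame stop codon entirely within the 5'UTR. Every qualifying start
yields one candidate; a start codon immediately followed by a stop is a
"start-stop" (1-aa) uORF with `n_sense_codons = 1`. The scanner is held
equal, in tests, to an exhaustive brute-force scan over all positions and
frames.

**Translated calls.** Coverage is *breadth*: the fraction of uORF
positions (stop codon included, since terminating ribosomes dwell there)
overlapped by at least one A-site; a uORF is translated when breadth
reaches 0.33. The per-nt read *density* (count/length) is stored
alongside and is what resolves overlapping candidates: among mutually
overlapping candidates the highest-density one is kept greedily, ties
broken by 5'-most start then start-codon strength (AUG > CUG > GUG >
UUG; the tie-break order is this package's choice). Both statistics are
kept because the field's usage is ambiguous between them; the threshold
rule is configurable (`rule = "breadth"` or `"density"`).

**Context annotation.** The penultimate codon (last sense codon before
the stop — the codon whose tRNA occupies the P-site at termination, and a
known modulator of re-initiation-factor dependence) is defined only for
uORFs with at least 2 sense codons. The Kozak +4 base is the nucleotide
after the start codon; for start-stop uORFs it is necessarily the U of
the stop codon, a structurally suboptimal context.

**Enrichment statistics.** Transcripts are classified as
`translated_uORF` / `untranslated_uORF_only` / `no_uORF`. The enrichment
question the figures ask is binary — does a transcript subset carry *at
least one translated uORF* more often than the background? — so
`uorf_enrichment_test()` defaults to collapsing the table to translated
vs rest and computing a 2x2 Fisher-type exact p-value (sum of
conditional table probabilities not exceeding the observed one). The full
2xC composition test is available (`collapse = "none"`): exact
enumeration up to a total of 500, otherwise conditional-margins Monte
Carlo (`r2dtable`) with `p = (1 + #extreme)/(1 + n_mc)`. 5'UTR-length
comparisons use the two-sample Kolmogorov–Smirnov test with group
medians reported; with integer lengths the p-value is the asymptotic
(tie-tolerant) one.

## Differential translation efficiency

The interaction test separates RNA-level from TE-level regulation with a
per-transcript negative-binomial log-linear model on CDS counts:

`log mu = offset + b0 + b_cond + b_assay + b_cond:assay`

with offsets `log(library size x TMM factor)` per sample. The
`condition:assay` coefficient is the log TE change (`/log 2` for log2
units); the condition effect on the RNA reference assay is the RNA
change. Fitting alternates IRLS (`stats::glm` with a fixed-dispersion NB
family) with a method-of-moments dispersion update from the quadratic
variance `var = mu + phi mu^2`, floored at 1e-8; two-sided Wald p-values
come from the asymptotic normal. Benjamini–Hochberg adjustment is applied
within each contrast and transcripts classified at FDR < 0.1
(`te_down`/`te_up`/`rna_only`/`unchanged`).

This is deliberately a simplified stand-in for the DESeq2-based
interaction frameworks: dispersions are per-transcript moments without
empirical-Bayes shrinkage and fold changes are unmoderated. Consequences,
measured by the test suite on simulated data: the Wald test is mildly
anticonservative at triplicate sample sizes (type-I error ~0.066 at
nominal 0.05 on a 2000-transcript null), and hit lists from real depth
data would not numerically match a shrinkage-based pipeline. Transcript
identities and counts from the original deposited data are therefore out
of scope; the properties that are checked instead are calibration,
planted-effect recovery, and invariances (label-swap antisymmetry, offset
absorption of depth factors).

## Reporter flux model

Each construct's replicate signal is firefly/Renilla; within a genotype
the mean no-uORF ratio is anchored at 100% (per genotype separately, so
lysates of different overall activity remain comparable). With the
overlapping-uORF reporter readable only through leaky scanning,

* leaky scanning = overlapping signal,
* re-initiation = WT signal − overlapping signal,
* uORF inhibition = 100 − WT signal,

summing to 100 exactly; uORF engagement is 100 − leaky, and conditional
re-initiation = reinit/engaged is the probability that a uORF-terminating
ribosome re-initiates on the CDS. The model assumes a binary
post-termination fate (recycle or re-initiate) and no interference
between uORF ribosomes; because terminating ribosomes that fail to
re-initiate may also have translated the uORF more than once, the
decomposed re-initiation percentages are lower bounds — a documented
limitation, not modeled. Negative re-initiation estimates (noise when WT
< overlapping) are flagged, never clamped, so replicate averaging stays
unbiased.

**Uncertainty.** `reporter_flux()` bootstraps replicates within each
construct and pushes every resample through the full
normalize-and-decompose computation. Plain percentile intervals are
systematically narrow at small replicate counts (coverage error of order
1/n, which at single-digit replicate numbers is enough to pull a nominal
95% interval visibly below target), so the default interval is the
expanded percentile: tail levels widened by the t-versus-normal factor,
`alpha'/2 = Phi(-sqrt(n/(n-1)) t_{1-alpha/2, n-1})` with `n` the smallest
replicate count. The acceptance suite verifies ~95% (+/-3) coverage under
the generator's reporter conditions. Bootstraps are seeded and
bit-reproducible.

**Comparisons.** Per-construct two-tailed unpaired t-tests between
genotypes (pooled variance by default, matching standard practice for
these assays; Welch via `var_equal = FALSE`); zero-variance groups yield
t = 0, p = 1 when means agree. For designs crossing genotype with a
reporter variant, a 2x2 fixed-effects ANOVA interaction p-value asks
whether the genotype effect differs between variants.

## Synthetic data

The generator emulates the statistical structure of a cultured-cell
profiling experiment at desk scale. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| 5'UTR length | lognormal, median 150 nt, sdlog 0.6 | expressed-transcript median ~153 nt |
| CDS length | lognormal, median 900 nt, codon-rounded | typical mammalian CDS, desk scale |
| uORF-bearing fraction | 0.73 | ~6800 of 9266 expressed transcripts carry uORF sequence |
| uORFs per bearing UTR | zero-truncated Poisson, mean 2.28 | reported mean among uORF-containing UTRs |
| start-stop point mass | 0.3 | start-stop uORFs are the largest single length class |
| start codons | AUG .4, CUG .25, GUG .2, UUG .15 | AUG-skewed near-cognate mix |
| planted TE effect | −1 log2 on targets | two-fold loss, the scale probed by recovery checks |
| responding fraction | 0.065 of uORF-bearing | 223 TE-down among ~3430 translated-uORF transcripts |
| NB dispersion | 0.05 | cell-line biological replicates |
| replicates | 3 per condition x assay | triplicate design |
| libraries | 1e5 RNA / 5e4 RPF reads over 400 genes | desk-scale depth with real-data per-gene coverage |
| footprint lengths | 26–35 nt, mode 29–30 | monosome footprint distribution |
| reporter noise | lognormal, CV 0.1, 8 replicates | typical luciferase replicate scatter |

Counts are negative binomial; RPF 5'UTR signal sits on planted uORFs
(density 1.5x CDS) and persists in the knockdown while target CDS signal
drops — the footprint pattern expected when re-initiation is blocked.
Read-level records place A-sites uniformly within regions (90% of 5'UTR
footprints on uORF nucleotides) and invert the fixed offsets for 5'
positions; regenerated counts from those reads reproduce the matrix
exactly.

**Sequence model and its limits.** So that the planted-uORF truth table
is *exhaustive* — every candidate the caller can find is planted — 5'UTR
backgrounds and planted sense codons avoid the TG dinucleotide outside
planted start codons (every near-cognate start is `NUG`, so no TG means
no start). uORFs are placed at least 17 nt from the cap so footprint 5'
ends stay on the transcript. This deliberately deviates from natural
sequence statistics: real UTRs contain nested and out-of-frame
near-cognate starts, non-uniform codon usage, and penultimate codons
containing TG (e.g. GTG), which the generator cannot plant (tests use
hand-built sequences for those cases). Passing tests on this generator
therefore demonstrate correctness of the counting, calling and inference
machinery under known truth — not robustness to the full ambiguity of
real 5'UTR annotation.

Known residual of the normalization design: when a *large* fraction of
transcripts carries a strong one-sided effect and the per-gene M-value
noise at realistic dispersion overlaps the effect size, trimmed-mean
normalization cannot fully separate the changed set from the unchanged
majority and part of the composition shift leaks into fold changes. The
emulated study's regime is sparse (~5% of transcripts affected), where
this is negligible; dense-effect designs would need spike-in or
control-gene anchoring.

## Problem sizes used by the checks

The test and acceptance runs use: 1000 random UTRs (≤300 nt) for the
scanner-vs-oracle equivalence; 50 random instances for the TMM oracle
comparison; a 2000-transcript null and a 2000-transcript planted-effect
simulation for calibration and recovery of the interaction test; a
400-gene simulation for the redistribution statistic; 500 simulated
reporter experiments x 999 bootstrap resamples for CI coverage; and 1e6
Monte Carlo tables for the large-table enrichment test. These sizes give
Monte-Carlo error comfortably inside every asserted tolerance.

## Open choices resolved here

* Enrichment construction: the printed p-values correspond to the binary
  translated-uORF proportion test, not a three-class homogeneity test;
  the package defaults to the binary reading and keeps the 2xC machinery
  as an option (see `uorf_enrichment_test()`).
* TE normalization route: TPM-then-ratio; since TPM is compositional the
  alternative (TMM-scaled counts directly) differs per transcript only by
  a sample-level constant, and the count-level model uses TMM offsets
  directly.
* Wilcoxon pairing for the redistribution statistic: one-sample
  signed-rank on the per-transcript paired differences.
* Fisher background row: the subset is excluded from the complement row
  (comparing a subset against the superset containing it double-counts).
* Which footprints define "translated": all RPF samples passed to
  `score_and_call()`; the caller is agnostic, and restricting to control
  samples is a one-line filter on the A-site table.
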