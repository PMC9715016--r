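---
title: "Methods: transcriptome-based quality assessment of blastocyst biopsies"
author: "blastomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based quality assessment of blastocyst biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastomics)
```

## Scope and data model

`blastomics` implements an analysis pipeline for low-input RNA-seq of human
blastocyst biopsies, in which 5–40 cells are taken from the inner cell mass
(ICM) and the trophectoderm (TE) of each embryo and sequenced as SMART-Seq
libraries. The pipeline starts from a gene-by-sample count matrix; read-level
processing (trimming, alignment, quantification) is out of scope. Four
analysis stages sit on top of three small data contracts — a gene annotation
(chromosome, length, pseudoautosomal and Y-marker flags), sample metadata
(blastocyst, compartment, grouping covariates), and a unit-tagged expression
matrix (`counts` or `TPM`):

1. **Clinical classification** of transfer cases by blastocyst growth
   kinetics, with chi-square contingency analysis of pregnancy rates.
2. **Expression QC**: expressed-gene filtering, reference-set transcriptome
   coverage, PCA.
3. **Digital karyotyping**: sex calls from Y-marker expression and X-dosage
   Z-scores; autosomal gain/loss calls from per-chromosome expression
   Z-scores.
4. **Differential expression**: a negative-binomial Wald test between
   prognosis groups, a Z-score reliability filter, and intersection of DEG
   sets across alternative groupings.

Because the motivating study deposited no raw data, a seeded synthetic-data
generator reproduces the study's design (13 blastocysts × ICM/TE) with
planted ground truth, and every stage is validated against that truth.

## Clinical classification

A transfer case is classified from two growth parameters: the time to reach
the blastocyst stage (hours post-insemination) and the blastocyst diameter
(µm). Group 1 (high expectation of pregnancy) requires under 130 h to exceed
170 µm; Group 2 (low expectation) requires over 140 h while remaining under
180 µm; everything else is Group 3. All four inequalities are strict, so
boundary values fall to Group 3 — the most literal reading of the rules; the
thresholds are configurable in `pipeline_config()`. Gardner scores of BB or
better on both letter grades define the "good" morphology group; maternal age
under 35 years defines the "young" group (35 itself is "elder").

The group-by-outcome table is tested with Pearson's chi-square without
continuity correction (the correction is available behind `correct = TRUE`;
the source clinical software's default is ambiguous), plus all three pairwise
2×2 chi-squares with a Bonferroni factor of 3. Both the overall and the
minimum pairwise adjusted p are reported, since a printed "p < 0.001" could
refer to either. Significance is assessed at α = 0.001.

The published per-case records are not available; the cohort table is
reconstructed from the printed group sizes (676, 158, 1056; total 1890) and
pregnancy rates (59.0 %, 16.5 %, 34.2 %) by rounding, and `simulate_cohort()`
can generate per-case data with those parameters for end-to-end exercises of
the classify → tabulate → test path.

## Expression QC

A gene is *expressed* in a sample when TPM > 1 (strict); the expressed set
requires this in ≥ 1 sample, and the *reference set* used for coverage in
≥ 6 samples. Coverage is the fraction of reference genes a sample expresses
above 1 TPM — a library-complexity check that poor-prognosis biopsies are not
simply degraded libraries. TPM uses the standard single-length formula
(count/length rates scaled to 10⁶ per sample); effective-length corrections
are out of scope. PCA runs on log2(TPM + 1) with genes centered and not
scaled (the transform is not stated in the source analysis; this is the
common choice and is configurable), and component signs are fixed by making
the largest-magnitude loading positive so results are deterministic.

## Digital karyotyping

Sex is called per blastocyst. The Y chromosome is present when the summed
TPM of the three Y-linked markers DDX3Y, RPS4Y1, EIF1AY strictly exceeds
250; an embryo is XY when both compartments agree, and `discordant` when
they disagree. X dosage uses a Z-score: counts over expressed X genes
(pseudoautosomal genes excluded, as they sit on both sex chromosomes) are
summed per sample, scaled to reads-per-million of the sample's expressed-gene
total, and standardized across samples *within each compartment* (the
operative convention; a pooled mode exists). Clearly positive X Z-scores with
no Y indicate XX. When both compartments' X Z-scores fall below 0.5 with no
Y, the blastocyst is flagged `potential_XO`; the 0.5 bound is this package's
choice (`xo_flag_z_upper`), since the original analysis only speculated XO
from an intermediate X dosage, and the flag is advisory rather than a
monosomy call.

Autosomes use the same normalized signal and per-compartment Z-scores, with
gains at z > 2 and losses at z < −2 (strict; z = 2 exactly is euploid). Two
unit conventions are deliberately mixed, following the source procedure:
chromosome signals come from **counts**, Y detection from **TPM**. Signals
are normalized by total expressed-gene depth (not autosome-only depth — the
alternative reading; with 24 chromosomes the difference is small), and the
karyotyping gene panel is the ≥ 1-sample expressed set with scope `"all"` so
both compartments share one panel (both are configurable). The Z-score
denominator is the sample SD (n−1); with n samples the largest attainable
|z| is (n−1)/√n, so a warning is emitted when the compartment is too small
(n ≤ 5 at the default cutoff) for any call to be possible. Note that with 13
samples per compartment the z > 2 tail implies an irreducible false-call
rate of roughly 2–5 % of sample × chromosome combinations; the per-blastocyst
report therefore flags whether ICM and TE agree on each event.

## Differential expression

The two-group test is a documented, simplified implementation of the
standard negative-binomial RNA-seq test:

* **Normalization** — median-of-ratios size factors (geometric-mean
  reference over genes positive in all samples; a positive-subset fallback
  covers sparse matrices), rescaled to geometric mean 1.
* **Dispersion** — per-gene Cox–Reid adjusted profile maximum likelihood on
  a log-α grid with quadratic refinement, then shrunk toward a log-linear
  mean–dispersion trend, weighting the gene-wise estimate by the ratio of
  the trend's excess scatter to the sampling variance of a log-dispersion
  estimate (≈ 2/(n−2)).
* **Testing** — group means fitted by Newton iteration with size-factor
  offsets; the Wald statistic for the group log2 fold change uses the
  expected Fisher information and is referred to a **Student-t with
  n₁ + n₂ − 2 degrees of freedom**. With nine samples the plug-in dispersion
  leaves the statistic over-dispersed (its null SD is ≈ 1.17), and the normal
  reference is visibly anticonservative; the t reference restores raw-p
  uniformity (Kolmogorov–Smirnov statistic ≈ 0.02 against ≈ 0.06 for the
  normal in null simulations at 2000 genes). No fold-change shrinkage is
  applied.
* **Multiplicity** — Benjamini–Hochberg q-values over tested genes (the
  expressed set; all-zero genes are excluded), DEGs at q < 0.01.

The reference (baseline) group is always the lower-prognosis one — low
expectation, poor Gardner grade, elder age — so positive log2 fold changes
mean higher expression in the better-prognosis group.

The **reliability filter** addresses embryo-to-embryo variability: per DEG,
log2(TPM+1) is standardized to Z-scores across the compartment's samples,
and the DEG is *reliable* when the within-group SD of those Z-scores is
strictly below 0.5 in both groups. The filter sentence it implements is
ambiguous between this reading and a between-group-mean gap; the within-group
reading matches the stated motivation ("variability between individual
blastocysts in each group") and is the default, with the gap reading behind
`method = "between_gap"`. Z-scores use log2(TPM+1) for variance
stabilization; raw-TPM mode is available.

**Power at this design size is intrinsically limited.** With 5 vs 4 samples
and dispersion α = 0.1 the standard error of a log fold change cannot fall
below √(α(1/n₁ + 1/n₂)) ≈ 0.21 natural-log units however deep the libraries,
so a 4-fold change tops out near |z| ≈ 6.5 and an 8-fold change near 10.
Under the t reference such genes reach p ≈ 10⁻³–10⁻⁵, which
Benjamini–Hochberg at q < 0.01 over ~10⁴ genes converts into moderate
recall: 2-fold planted changes are rarely recovered at q < 0.01, 8-fold
changes in roughly a third of cases (with essentially no false
discoveries). Published DEG counts at this design size
obtained with normal-reference Wald tests should be read with that in mind.

## Synthetic-data generator

`sim_design()`/`simulate_counts()` emulate the 13-blastocyst study: groups
H (5), M (4), L (4), two libraries per blastocyst. Counts are negative
binomial with variance μ + αμ², α = 0.1 by default (typical low-input bulk).
Per-gene baseline means are log-normal, 2^N(6, 2), giving ≈ 1.6 million
counts over the default 9600 genes per unit library — the depth scale of a
sequenced SMART-Seq biopsy library; library sizes are log-uniform on
0.5×–2× so depth normalization matters. Dosage factors: gained chromosomes
1.5×, lost 0.5×, the single X of XY embryos 0.5×, the XO X at 0.7× —
between XX and XY, a modeling choice that reproduces the intermediate
X-expression observation motivating the XO flag, not a measured value.
Pseudoautosomal X genes stay at full dose except in XO (0.5×). Y genes have
mean zero outside XY embryos, and the three Y markers sit well above the
average gene so XY marker TPM clears the 250 rule at any marker length. The
default sex mix is the study's: 6 XY, 6 XX, and L1 XO. Planted DE applies
2^±lfc to H samples and 2^±lfc/2 to M samples relative to the L baseline, so
intermediate-prognosis embryos show intermediate expression. Ploidy events
may hit one compartment (mosaicism) or both (default both). All randomness
derives from a single seed; two runs with the same design are bit-identical.

What the generator does **not** model: amplification dropout beyond NB
noise, batch effects, 3'-coverage bias, mosaicism fractions below a whole
compartment, or any real biological co-expression structure. Passing tests
therefore demonstrate that the *procedures* behave as specified under their
own statistical assumptions, not that those assumptions hold for real
biopsies.

## Numerical choices and degenerate inputs

* Strict inequalities throughout (TPM > 1, > 250 TPM, |z| > 2, q < 0.01,
  SD < 0.5, age < 35), matching the stated rules; ties fall to the
  conservative side.
* Zero-variance chromosome signals give z = 0 with a flag; degenerate
  contingency margins give p = 1 with a warning; all-zero genes and samples
  are hard errors or exclusions as documented per function.
* Dispersion estimates are clamped to [10⁻⁴, ~6] on the grid; group-mean
  Newton steps are damped to ±3 on the log scale with a 10⁻¹⁰ floor so
  groups with all-zero counts yield huge standard errors rather than
  divergence.
* TPM columns are validated to sum to 10⁶ within a relative 10⁻⁶.

## Problem sizes used in the test suite

The packaged checks run the generator at the study's geometry (13
blastocysts × 2 compartments, 400 genes per chromosome) for karyotype
recovery over 200 seeds, and at 2016 genes, 5 vs 4 samples for null
calibration of the DE test over 100 seeds; brute-force loop oracles for the
chi-square statistic, BH procedure, chromosome signals and Z-scores run on
small random instances. These sizes were chosen so the full suite documents
each property at meaningful replication while remaining quick to run.

## Known limitations

* The pipeline starts at the count matrix; quantifier-specific effects
  (multi-mapping, effective length) are invisible to it.
* Karyotype calls are whole-chromosome only; segmental events and mosaicism
  fractions are out of scope, and RNA-dosage calls are not a substitute for
  DNA-based PGT-A.
* The DE implementation is deliberately simpler than DESeq2 (no Cook's
  outlier handling, no fold-change shrinkage, single-factor designs only);
  it is validated against DESeq2 as an independent cross-check on shared
  data, not intended to replicate its numerics.
* The reliability filter's published definition is ambiguous; both readings
  are implemented and the default is documented above.
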