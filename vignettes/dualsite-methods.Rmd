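---
title: "Methods: dual-target variant prioritization and its statistical evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-target variant prioritization and its statistical evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsite)
```

## Scope and model

`dualsite` prioritizes genetic variants that sit inside FOXA binding
elements within regions co-bound by FOXA1/2 and ERα near gene promoters,
and evaluates such variants in a case-control association framework and in
genotype-stratified qPCR expression data. The package's working assumption
is the pioneer-factor model: FOXA1/2 binding opens chromatin and enables
ERα recruitment, so a variant disrupting a FOXA element in a jointly bound
promoter region is a plausible modifier of estrogen-dependent regulation
and hence of sex-differential disease risk.

All genomic coordinates are 0-based half-open (`[start, end)`, the BED
convention); 1-based inputs are converted at parse time. Interval
arithmetic is delegated to IRanges/GenomicRanges behind the package's
function surface, with conversion at the call boundary.

## The prioritization chain and its parameters

**Replicate handling.** Replicated ChIP-seq experiments from the same cell
line are combined by selecting overlapping peak locations. "Overlapping"
means sharing at least one base; the retained span is the *intersection*
of the pair, the conservative reading (a `keep = "union"` option retains
the merged pair span instead, and more than two replicates fold left
pairwise). Independent experiments from different cell lines are pooled by
union; overlapping *and bookended* intervals merge into maximal spans,
since two abutting intervals describe one contiguous bound region. FOXA1
and FOXA2 peaks are pooled the same way into a single FOXA set, reflecting
their largely redundant binding in liver.

**Dual-target regions** (`max_distance`, bp, default 250, strict `<`). A
FOXA peak and an ERα peak on the same chromosome whose edge-to-edge gap is
strictly below the threshold define a dual-target region, reported as the
merged span of the pair. Distance is edge-to-edge (0 for overlapping
peaks) because peak summits are unavailable in BED3 inputs; a `summit`
mode measures between interval midpoints instead. Each qualifying pair is
reported separately by default — the same FOXA peak paired with two ERα
peaks yields two regions — because downstream element scanning and variant
attribution are per-pair; `merge = TRUE` collapses overlapping regions
when a non-redundant region count is wanted.

**Promoters** (`upstream`, bp, default 5000). The promoter is the window
strictly upstream of the TSS: `[tss - upstream, tss)` for `+` genes,
`[tss + 1, tss + 1 + upstream)` for `-` genes, clipped at position 0. A
dual region is kept if it overlaps a promoter by at least one base (full
or partial overlap), so elements "near or within" a promoter are retained
without including the gene body in the window itself.

**Element scanning** (`core_cutoff` 0.75, `matrix_cutoff` 0.85, both in
[0, 1]). Binding elements are fine-mapped with the Match scoring scheme:
the information vector `I(i) = Σ_b f(i,b) ln(4 f(i,b))` (the `0·ln 0` term
defined as 0) weights each matrix position, and a window scores
`MSS = (Current − Min)/(Max − Min)` where `Current = Σ_i I(i) f(i, b_i)`
and `Max`/`Min` use the per-position extreme frequencies. The core score
applies the same ratio to the 5 consecutive positions with the highest
summed information (leftmost window on ties; the whole matrix when
`L ≤ 5`). Both strands are scanned; reverse-strand windows are scored on
the reverse complement and reported in forward coordinates. The default
cut-offs are the common Match convention for a balanced
false-positive/false-negative trade-off and are configurable per run;
since cut-off profiles vary between analyses, exact element counts on
real data are not a package claim.

**Variant filter** (`maf_threshold`, default 0.05, strict `>`). A variant
is a candidate if its position lies inside an element's half-open span;
one row is emitted per (variant, element) pair so the element context is
preserved, and consumers deduplicate by rsid. "Common" means known MAF
strictly above the threshold; unknown-MAF candidates are dropped from the
common set with a logged count rather than guessed.

## Numerical choices

* Natural logarithms in `I(i)`: any fixed base cancels in the MSS ratio,
  so the choice only pins test reproducibility.
* A degenerate matrix position table with `Max = Min` scores 0, and
  windows containing non-ACGT letters are skipped, not scored.
* PWM parsing adds a configurable pseudocount (default 0) per cell before
  row normalization; rows must sum to 1 within 1e-9.
* Regions shorter than the matrix yield an empty hit set, not an error.
* 2×2 tables with a zero cell receive the Haldane-Anscombe 0.5 correction
  and are flagged.
* The scan accumulates position weights in vectorized order, so a
  consensus window may score `1 − O(1e-16)` rather than exactly 1;
  equality comparisons on scores should allow a ~1e-12 band.

## Association statistics

Crude odds ratios use the cross-product ratio with the Woolf CI
`exp(ln OR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`; for a single binary
predictor this is identical to the logistic-regression ML estimate and
Wald CI, which the test suite verifies to 6 decimals. Genetic models
recode the genotype triple as: genotype (het and hom-alt each vs hom-ref),
dominant (carrier vs non-carrier), recessive (hom-alt vs rest), and
additive (allele dosage 0/1/2, fitted as a dosage logistic on grouped
data). Adjusted ORs come from multivariable logistic regression
(`stats::glm`, binomial IRLS) with age, smoking, drinking and — in the
overall stratum only — sex; smoking/drinking "unknown" is kept as a third
indicator level by default to preserve n (`unknown = "exclude"` drops
those subjects), and missing genotypes are dropped listwise per analysis.
The per-model omnibus P reported alongside the genotype model is the crude
3×2 genotype-distribution χ²; per-contrast p-values are Wald.

Hardy-Weinberg equilibrium is tested by the 1-df χ² goodness of fit
against `(N p², 2 N p q, N q²)` with the allele frequency estimated from
the counts, conventionally in controls; monomorphic markers return
`p = 1` with a warning. Demographics use the Welch t by default (the
pooled-variance t is available; with ~1000/2000 subjects the two differ
only in the third decimal of p) and the uncorrected Pearson χ² with the
"unknown" category excluded from the test. Power uses the two-sided
normal-approximation Wald form
`Φ(|ln OR|/SE − z₁₋α/₂) + Φ(−|ln OR|/SE − z₁₋α/₂)` with the SE from
expected cell counts at the control exposure frequency; the test suite
checks it against a vectorized Monte-Carlo simulation of 50,000 studies.

## Expression analysis

Relative expression is `2^−ΔCt` with
`ΔCt = mean Ct(target) − mean Ct(reference)` over technical replicates.
The duplicate coefficient of variation is computed per gene on the Ct
scale (SD/mean, in %; an option uses linearized `2^−Ct` values) and
samples above 5% are flagged `high_cv`, mirroring the bench convention of
re-assaying such samples. Group comparisons are rank-based: tie-corrected
Kruskal-Wallis across genotypes and two-sided Mann-Whitney per genotype
pair (and male vs female when sex is recorded), exact by enumeration when
the combined sample is ≤ 20 without ties, otherwise the normal
approximation with tie and continuity correction. All-tied data return
`p = 1` with a degeneracy warning; groups under 2 samples are skipped from
pairwise tests with a warning.

## What the generators emulate — and what they do not

`make_regulatory_fixture()` lays out one synthetic chromosome in 10-kb
gene slots (`+`-strand gene body at slot offsets 7000–9000, promoter at
2000–7000) and assigns each feature class its own slots: planted
dual-target sites (a consensus FOXA motif embedded in overlapping
replicate FOXA peaks, an ERα peak at a gap drawn in 0–249 bp, all inside
the promoter), lone-FOXA and lone-ERα decoys, dual-pair decoys placed
upstream of the promoter window, and decoy SNPs placed in gene bodies.
This layout makes the key acceptance properties hold *by construction for
every seed*: planted sites always survive to scanning, decoy peaks can
never pair within 250 bp, and decoy SNPs can never fall inside a scanned
region. Planted variants sit inside the embedded motifs with MAF drawn
from (0.1, 0.5) for the common subset and (0.005, 0.049) for the rare one.
The fixture does not emulate: realistic peak-width or signal
distributions, minus-strand genes (exercised by unit tests instead),
overlapping genes, chance motif matches in real promoters, or linkage
between SNPs.

`simulate_cohort()` draws control genotypes in Hardy-Weinberg proportions
at the risk-allele frequency and tilts case genotype probabilities by the
genetic-model odds multipliers of the subject's sex stratum — the
standard retrospective-sampling construction under which the logistic fit
recovers the planted ORs. Defaults are fixed to the reference cohort design: 1,081 cases / 2,008 controls, ~80% male, control risk-allele
frequency 0.4807, a female-only effect (het/hom odds 1.5/2.0, male 1/1),
age N(54.96, 11.37²) in cases vs N(55.56, 10.28²) in controls, smoking
59.9% vs 48.9% ever, drinking 52.9% vs 44.7%, small "unknown" fractions,
and 0.6% missing genotypes. Covariates are drawn conditional on status but
independent of genotype, so adjusted and crude ORs coincide in
expectation; confounding structures are not simulated.

`simulate_ct_table()` gives each sample a latent reference Ct
(N(20, 0.5²)) and a latent ΔCt equal to a baseline of 5 cycles plus its
genotype shift plus biological noise (SD 1 cycle), then adds technical
noise (SD 0.15 cycles) to each of 2 duplicates per gene. Group sizes
default to 22/38/12 (CC/CG/GG) matching a 72-tissue liver study design. The
genotype shifts default to (0, −0.5, −1.3) cycles — a ~2.5-fold GG
expression increase — chosen once as a strong-but-plausible regulatory
effect large enough that the rank tests at these small group sizes detect
it in the clear majority of simulated data sets; raw expression values from real
cohorts of this design are typically unpublished, so an exact empirical
effect size is not a reproducible target.

Consequently, passing tests demonstrate algorithmic correctness
(oracle-verified interval, scoring and containment logic; exact
closed-form/ML equivalences), statistical calibration (type-I error near
the nominal 5%) and parameter recovery on data whose generating process is
known — not concordance with any external data release.

## Problem sizes used by the test suite

Simulation-based checks use: 10,000 replicates for type-I-error
calibration of the Wald, HWE, Kruskal-Wallis and Mann-Whitney tests;
50,000 vectorized studies for the power cross-check; 20,000 subjects for
stratified parameter recovery; 400 simulated 72-sample qPCR sets for
shift-detection; 200–300 replicates for null-centering and HWE-rate
properties of the generators; and exhaustive enumeration (all 256 windows
of a 4-position matrix, all C(6,3) rank orderings) for the scoring and
exact-test oracles.

## Known limitations

* Interval logic assumes a shared assembly and chromosome naming across
  inputs; no liftover.
* No LD expansion, imputation, population-stratification correction or
  exact logistic regression; single-variant analyses only.
* PWM scanning is mononucleotide; no dinucleotide or higher-order models,
  and no matrix training from ChIP-seq.
* The CV QC rule flags but does not re-measure; flagged samples stay in
  the table for the caller to handle.
* Stage counts on real ENCODE/dbSNP inputs depend on the exact peak
  files, matrices and cut-off profiles used, which are rarely fully
  identified in such analyses; the package therefore validates the pipeline
  on planted synthetic truth instead of reproducing those counts.
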