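---
title: "ritox: models, assumptions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ritox: models, assumptions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritox)
```

## The problem

Anthracycline chemotherapy damages the heart, and susceptibility varies
widely between individuals. A recombinant inbred (RI) panel bred from two
founders — such as the BXD family from C57BL/6J ("B") and DBA/2J ("D")
mice — turns that variability into a mappable genetic signal: every
strain is a fixed homozygous mosaic of the two founder genomes, so a
toxic challenge can be phenotyped across genetically identical replicates
and strain means mapped to quantitative trait loci (QTL). `ritox`
implements that workflow end to end: per-animal records to strain traits,
genome scans with permutation thresholds, 2-LOD support intervals,
weighted multi-criteria candidate scoring, two-sample Mendelian
randomization (MR) against human outcome GWAS, and hypergeometric
over-representation analysis.

## Trait derivation

- **Survival.** Median survival is the Kaplan–Meier product-limit median
  of the day of death, with animals alive at the end of the 10-day
  window censored there. Animals euthanized at the 20% body-weight-loss
  endpoint count as deaths, matching the mortality framing of the
  experiment the package models. When the survival curve never reaches
  0.5 the median is undefined; `median_survival()` returns `Inf`, which
  reports as "≥10". Daily survival rates are simple survivor fractions
  and are non-increasing in day by construction.
- **Body weight.** Loss at day *d* is baseline (day −1) minus current
  weight per animal, averaged over the animals still measurable that day
  (survivor bias accepted: dead animals have no weight). Percent loss is
  relative to each animal's own baseline and therefore unit-free. A gain
  appears as a negative loss; the sign convention is documented rather
  than clipped.
- **Echocardiography.** `echo_delta()` pairs baseline and day-5 values
  by animal and reports both strain means with a paired two-sided
  t-test. Degenerate inputs are flagged, not fudged: fewer than two
  pairs gives no p-value; identical nonzero differences (zero variance)
  return a `zero_variance` flag; all-zero differences return p = 1.
- **Expression.** The `2Z + 8` normalization is the affine map to mean 8
  and sample SD 2 used for array expression to avoid negative values. It
  is idempotent on its image and affine-invariant; constant input is an
  error rather than a silent division by zero.
- Strain traits for mapping are unweighted means over animals, sexes
  pooled by default (a per-sex filter exists), following the
  group-average convention of RI-panel analyses.

## QTL mapping

At a fully informative RI marker, Haley–Knott interval-mapping
regression at the marker reduces to ordinary least squares of the strain
mean on the genotype code (0 / 0.5 / 1; heterozygous calls appear only
in input data, never in simulation). The scan statistic is

$$\mathrm{LRS} = n \ln(\mathrm{RSS}_0 / \mathrm{RSS}_1), \qquad
  \mathrm{LOD} = \mathrm{LRS} / (2\ln 10),$$

so the 2-LOD interval rule is a fixed 9.21-LRS drop. Scans are computed
at genotyped markers only — no pseudomarkers — a deliberate
simplification appropriate for dense RI maps. Missing genotypes are
dropped marker-wise; monomorphic markers score LRS 0 with a flag; a
perfect fit reports `Inf` with a flag rather than a fabricated large
number.

**Permutation thresholds** shuffle the trait across strains, keep the
genome-wide maximum LRS per permutation, and take the empirical
`1 − α` quantile (R's default type-7 quantile; `alpha = 1` degenerates
to the minimum of the maxima). The default 1,000 permutations keeps test
runtimes reasonable; the published analyses this models used 10,000 to
1,000,000, and the quantile estimate simply sharpens with `n_perm`.
Thresholds are bit-reproducible for a fixed seed.

**Mixed-model scan.** `lmm_scan()` is an EMMA-style analogue of the
GEMMA scans used alongside Haley–Knott in this literature: kinship is
the centered-genotype cross-product over all markers (no
leave-one-chromosome-out by default; pass your own kinship to change
that), normalized to unit mean diagonal so the REML heritability
`h² = 1/(1 + δ)` is interpretable — the normalization is absorbed into
δ and leaves per-marker tests unchanged. Variance components are
estimated once under the null on the eigen-rotated model and reused for
every marker's GLS Wald t-test (the EMMAX speed/accuracy trade-off,
documented rather than hidden). With identity kinship the scan equals
ordinary regression exactly, which the tests assert to 1e−8.

**Support intervals** walk outward from the chromosome peak to the
outermost *contiguous* markers within the LOD drop; endpoints are marker
positions in Mb, a peak at the chromosome edge is flagged one-sided, and
ties at the peak take the first (leftmost) maximum.

## Candidate scoring

Eight criteria with weights (1, 1, 1, 1, 1, 1, 2, 2) and a 10-point
maximum: founder coding variant (nonsynonymous, frameshift, stop-gain —
splice-site variants count too), heart-failure GWAS, cardiovascular
GWAS, cis-regulation (gene midpoint within ±5 Mb of the eQTL peak on
the same chromosome), differential expression in cardiomyopathy
(adjusted p < 0.05 and |fold change| > 1.5, log2 inputs converted),
heart expression strictly above 2 TPM, functional relevance in the
heart, and MR significance. The "minimum score of 30%" selection rule is
interpreted as ≥ 3 of 10, consistent with every published row scoring
at least 3; both the threshold fraction and the TPM cutoff are
configurable. Expression exactly at 2 TPM scores 0 (strict inequality —
the published sub-threshold rows at 1.26 and 1.40 TPM pin the rule
down only up to the boundary, so the boundary choice is documented).
Ranking ties beyond the score are broken by heart TPM descending, then
symbol — an invented, recorded convention; the source tables are silent.
Evidence flags are *inputs* (database lookups are out of scope); missing
flags are treated as absent evidence.

## Mendelian randomization

Two-sample MR with eQTL exposures and outcome-GWAS summary statistics.
Harmonization matches by variant id, flips the outcome beta when the
alleles are swapped, and drops palindromic (A/T, C/G) variants — the
conservative policy when allele frequencies are unavailable — plus any
irreconcilable or unshared variants, all logged. Estimators:

- Wald ratio (single instrument): `θ̂ = β_out/β_exp`,
  `se = se_out/|β_exp|` (first-order delta method, no
  exposure-uncertainty term), two-sided normal p.
- Fixed-effects IVW (≥2 instruments): precision-weighted mean of the
  per-instrument ratios with `wᵢ = (β_exp,i/se_out,i)²`, algebraically
  the zero-intercept weighted regression of outcome on exposure betas.
  One instrument reduces exactly to the Wald ratio; instruments with
  zero exposure effect are dropped with a warning.

No LD pruning is performed (instruments arrive pre-selected) and no
multiple-testing correction is applied across the gene × outcome grid by
default — significance is raw p < 0.05, the convention of the screening
analysis this reproduces; a BH option exists.

## Enrichment

Upper-tail hypergeometric test per category with the minimum-overlap
filter (default 5) applied *before* BH correction, so excluded
categories do not inflate the denominator — matching WebGestalt-style
tools. The background defaults to whatever universe the caller supplies;
no built-in genome background is shipped.

## The synthetic world

The generator emulates the stated experimental design, not a tuning
surface; its defaults are fixed once:

- **Genotypes.** Two founders, 0/1 codes, chromosomes independent.
  Adjacent-marker recombination uses Haldane's map function for the
  single-meiosis fraction `r` and the sib-mating RI map expansion
  `R = 4r/(1+6r)` — the faithful default for a sib-mated panel like the
  BXD (a pass-through `R = r` option exists). Default map: 5
  chromosomes × 21 markers at 5 cM (≈2 Mb/cM), a coarse but realistic
  density for an RI scan.
- **Phenotypes.** 60 strains (the modeled study used 58 plus founders)
  with 8 animals per strain (the study states ≥4 per sex; replicate
  counts are configurable). Strain-level noise is normal and scaled so
  the planted additive QTL explains `h2` of strain-mean variance
  (default 0.5, a mid-range single-QTL effect); within-strain replicate
  noise is normal with configurable SD.
- **MR statistics.** True exposure effects drawn away from zero
  (|β| ∈ [0.3, 0.8]), measurement SEs 0.05 on both sides — typical of
  well-powered eQTL/GWAS extractions — outcome betas from the planted
  slope θ (default 0.5), and 30% of instruments stored allele-swapped
  so harmonization is always exercised; alleles are drawn
  non-palindromic so no instruments are silently lost.

What a green test does establish: the estimators are exact against
independent oracles (closed forms, per-marker `lm()`, enumeration,
hand-computed product-limit and paired-t values), the permutation
threshold is calibrated, planted QTL are detected and localized at the
stated power, and MR recovers the planted slope with calibrated type-I
error. What it does not: real linkage-disequilibrium structure beyond
the RI map, sex chromosomes, epistasis, selection effects in real eQTL
extraction, or the undeposited genomic positions of the original animal
data — reproducing those positions is explicitly out of scope.

## Numerical and design choices

- Empirical quantiles use R's default (type 7); permutation maxima are
  reproducible bit-exactly given a seed.
- Undefined KM medians return `Inf` (rendered "≥10") rather than NA, so
  arithmetic comparisons against death days stay valid.
- `LRS = ∞` (perfect fit) and monomorphic markers are flagged, never
  interpolated.
- The pipeline config is accepted as an R list or JSON file (JSON
  chosen over YAML to avoid an extra dependency); all outputs are plain
  TSV/JSON and a rerun with the same config is byte-identical, which
  the test suite checks by checksum.
- Scoring weights, TPM threshold, selection fraction, LOD drop, MR
  alpha and the BH option are all exposed parameters with the defaults
  given above.

## Limitations

The mixed-model scan estimates variance components once under the null
(EMMAX approximation); with very strong single-QTL effects the
per-marker p-values are slightly conservative compared to per-marker
REML. IVW here is fixed-effects with no heterogeneity, pleiotropy or
weak-instrument diagnostics (MR-Egger and weighted-median estimators
are deliberately out of scope). The enrichment module is property-tested
only: the modeled study prints no enrichment table to reproduce.
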