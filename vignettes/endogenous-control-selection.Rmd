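---
title: "Endogenous control selection for circulating miRNA Ct data: methods and design"
author: "EndoCt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous control selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EndoCt)
```

## Scope and data model

EndoCt analyzes cycle-threshold (Ct) matrices from qPCR-based miRNA
profiling of plasma. All computation assumes amplification efficiency
exactly 2, so a Ct difference is a log2 expression ratio; no efficiency
correction is applied. The central container, `CtExperiment`, follows the
Bioconductor convention (miRNAs as rows, samples as columns) and keeps
three pieces of information separate at all times: the Ct values, the
`detected` mask recording which reactions crossed threshold, and — after
imputation — an `imputed` mask. A non-detect is a censored observation,
not a zero; keeping the mask rather than a sentinel value makes imputation
an explicit, reversible step, and lets downstream code (restricted-set
normalization, missingness filters) always see the original detection
structure.

Sample and miRNA identifiers are kept in canonical (locale-independent
lexicographic) order, so the result of a run never depends on the order in
which rows were read.

## Quality control

Two named presets encode two profiling designs; they differ in exactly two
rules and are deliberately not mixable field by field without noticing:

| rule | `discovery` (array) | `validation` (single-tube, triplicate) |
|---|---|---|
| amplification score | reading `< 1.1` → non-detect | same |
| Cq confidence | reading `< 0.7` → non-detect | filter off |
| miRNA missingness | dropped at `>= 50%` | dropped at `> 50%` |

Both boundary readings (score exactly 1.1, confidence exactly 0.7) are
retained: the filters are strict inequalities. The laxer validation rules
reflect that a triplicate design already provides internal confirmation of
each measurement. The inclusive-versus-exclusive missingness threshold is
kept as two distinct behaviors rather than harmonized: a miRNA missing in
exactly half the samples is dropped in discovery mode but kept in
validation mode.

The remaining QC rules, in the fixed order applied by `runQC()`:

1. **Replicate aggregation**: the Ct of a sample × miRNA is the arithmetic
   mean of its *detected* replicate Cts. Partially detected triplicates
   keep the mean of the detected readings; discarding the whole triplicate
   would throw away data that a sufficiently-expressed miRNA clearly
   provides. A fully non-detect set stays a non-detect.
2. **Low-detection samples**: samples whose detected-miRNA count falls
   below a configurable minimum are excluded. The default is 25% of the
   *analyzable* panel — the miRNAs that would pass the missingness filter —
   not of the full assay panel, most of which is never detected in plasma;
   a threshold keyed to the full panel would reject every plasma sample.
   The criterion is configurable because no universal count exists.
3. **miRNA missingness filter** as in the table above.
4. **Imputation**: every surviving non-detect becomes Ct 40, the panel's
   maximal cycle number, i.e. "at or below the detection limit". Imputing
   before filtering is not possible through `runQC()`; an imputed 40 is a
   statement about a censored value and must not influence which rows and
   columns survive.

Every operation returns a `QCReport` recording removals and thresholds, so
the surviving matrix reconciles cell-by-cell against the input.

## The five normalization strategies

For sample $i$ with Ct values $ct_{ij}$:

1. **Global mean** (after imputation): $ct_{ij} - \overline{ct_{i\cdot}}$.
   Every sample's mean ΔCt is zero afterwards; per-sample technical
   offsets cancel exactly.
2. **Unimputed mean-centering**: the same, with the reference mean taken
   over detected miRNAs only; non-detects stay missing. This can look
   deceptively good in an SD benchmark: samples with many censored
   low-expression miRNAs compute their reference from a biased,
   better-expressed subset.
3. **MCR** (mean-centering restricted): the reference is the mean over the
   restricted set — miRNAs detected in *every* sample, determined from the
   pre-imputation mask and recorded in the output's parameters.
4. **Quantile**: each sample's values are replaced by the across-sample
   mean order statistics at their ranks. Ties within a sample receive the
   mean of the reference values their ranks span. The tie rule matters
   here: imputed non-detects form large blocks of tied 40s, and this rule
   maps each block to one deterministic value. Two consequences are worth
   stating precisely: on tie-free data every sample ends with exactly the
   same multiset of values and the operation is idempotent; with ties the
   averaged tie values differ between samples with different block sizes,
   so the multiset identity holds only up to those tie groups. Quantile
   normalization is applied after imputation — its behavior on ragged
   (unimputed) rows is undefined.
5. **Endogenous control**: classic ΔCt, $ct_{ij} - c_i$ with $c_i$ the
   control's Ct. For a multi-miRNA control set, $c_i$ is the arithmetic
   mean of the control Cts — the geometric mean in linear abundance space,
   the qPCR convention for multi-gene normalization factors.

The benchmark (`compareNormalizations()`) summarizes the per-miRNA SD
across samples — sample SD with the $n-1$ denominator everywhere, and
quartiles by the linear-interpolation convention (type 7) so that box
summaries are bit-reproducible — on both the full analyzable panel and the
restricted panel.

## Stability algorithms

All four run on raw post-QC Ct values, not normalized values (configurable
by passing any matrix): the pairwise and model-based methods are invariant
to the per-sample offsets that normalization would remove, while BestKeeper
is deliberately expression-level sensitive and would be meaningless on
mean-centered data.

- **geNorm**: $V_{jl} = \mathrm{SD}_i(ct_{ij} - ct_{il})$,
  $M_j = \mathrm{mean}_{l \ne j} V_{jl}$; the largest-$M$ candidate is
  removed and $M$ recomputed until two remain. The final pair cannot be
  separated (their mutual $V$ is all that is left) and shares rank 1, the
  next-removed candidate takes rank 2, and so on. The reported $M$ for the
  final pair is the value each held in the last three-candidate round, the
  last round in which the statistic is informative. A tie in $M$ at
  removal is broken by dropping the id that sorts last — an arbitrary but
  documented and deterministic choice.
- **Comparative ΔCt**: the first-pass $M_j$ without iterative exclusion,
  ranked ascending. Its identity with first-pass geNorm is definitional
  and is asserted against an independent brute-force recomputation in the
  tests.
- **BestKeeper**: candidates ranked ascending by the sample SD of their
  raw Ct. The BestKeeper index (per-sample geometric mean of candidate
  Cts) and each candidate's Pearson correlation with it are reported
  descriptively, but the ranking key is the SD: it reproduces the
  characteristic behavior where a low-variance, weakly-expressed candidate
  tops BestKeeper while the offset-invariant methods disagree.
- **NormFinder** (single group): after double-centering removes gene means
  and sample offsets, the per-gene residual variance
  $s_j^2 = \sum_i z_{ij}^2/(n-1)$ is contaminated by every other gene
  through the per-sample means; the bias-corrected estimate is
  $\hat\sigma_j^2 = \max\!\big(0,\ \tfrac{k}{k-2}\big(s_j^2 -
  \bar S/(k-1)\big)\big)$ with $\bar S$ the mean of the $s_j^2$, and the
  stability value is $\hat\sigma_j$. The correction requires $k \ge 3$
  candidates. The truncation at zero keeps stabilities well-defined when
  $s_j^2 < \bar S/(k-1)$; its side effect is a small upward bias of
  $\hat\sigma_j$ for genes whose true noise is near zero, since sampling
  noise in $\hat\sigma^2_j$ is rectified — an estimator property, not an
  implementation artifact. The multi-group inter-group term is out of
  scope: the cohorts analyzed here are single-group.
- **Comprehensive ranking**: per-method dense ranks (ties share the
  smaller rank), combined as the geometric mean
  $G_j = (r_1 r_2 r_3 r_4)^{1/4}$; the final ordering is ascending in
  $G$, ties broken by mean rank, then id. "Weights" are taken to be plain
  ranks, the standard reading.

Candidates with any remaining non-detect are excluded from stability
analysis with a warning — a candidate that is not consistently detected
cannot be assessed, let alone used, as a reference.

Two selection criteria complement the ranking: `selectByGlobalMeanSD()`
orders miRNAs by SD after global-mean normalization (expression closest to
the per-sample mean, the practical gold standard), optionally truncated
strictly below 2 ΔCt for presentation; and `evaluateCombination()` appends
the combined pseudo-control (per-sample mean Ct of the set) as a virtual
candidate and reports whether it outranks each member — averaging two
references with independent noise shrinks the reference variance by half,
so a genuine combination should win.

## Covariate sensitivity

`sensitivityReport()` repeats both selection criteria with age and sex
regressed out (per-miRNA OLS on intercept + age + sex indicator) and
reports top-set equality and a Spearman rank correlation, descriptively —
no significance test is attached. Two arms mirror the two criteria: the SD
criterion is recomputed on residualized *global-mean-normalized* levels;
the stability ranking on residualized *raw* Ct. For the stability arm the
residuals keep their per-miRNA mean (`keep_level = TRUE`): mean-zero
residuals would break BestKeeper's geometric-mean index, while per-miRNA
constants provably change none of the four ranking keys except BestKeeper's
descriptive correlation. A degenerate covariate (single-sex cohort) is
dropped with a warning rather than failing.

## The synthetic data generator

`simulateCtData()` draws
$Ct_{ijr} = \mu_j + t_i + \gamma_j\,\mathrm{age}^c_i + \delta_j\,\mathrm{sex}_i
+ \varepsilon_{ij} + \eta_{ijr}$, with $t \sim N(0,\tau)$ per-sample
technical offsets, $\varepsilon \sim N(0,\sigma_j)$ per-miRNA noise, and
$\eta \sim N(0, \text{replicate\_sd})$ replicate noise; age effects apply
to centered age so $\mu_j$ keeps its interpretation. A reading is censored
to a non-detect with probability
$\mathrm{logit}^{-1}((Ct-\mathrm{lod})/\text{slope})$ — a hard threshold at
the detection limit when the slope is zero — so missingness increases as
abundance decreases (missing-not-at-random), the defining feature of
dilute-plasma qPCR data. Replicate-level records also synthesize
amplification-score and Cq-confidence fields with a configurable fraction
below the QC thresholds. Every realized parameter is returned as ground
truth; a seed fixes the dataset bit-for-bit.

This additive Gaussian model is the minimal structure under which the
normalization arms are distinguishable: offsets that mean-subtraction
removes exactly, gene-specific noise that stability methods should
recover, and censoring that separates the imputed and unimputed variants.
It does **not** emulate correlated miRNA modules, heavy-tailed or
batch-structured noise, platform/probe efficiency differences, or any
true biological signal between groups — so passing tests demonstrate
algorithmic correctness under the assumed model, not performance on any
particular clinical dataset.

`discoveryPreset()` calibrates the generator to the shape of a genome-wide
plasma array study: 754 assayed miRNAs, 30 samples, a 10% well-expressed
component (mean Ct 22–32) against a near/below-LOD background (33–46),
noise SDs 0.5–2 cycles, offsets $\tau = 2$, LOD 33 with a 0.5-cycle
logistic edge. This yields a few hundred miRNAs detected somewhere, on the
order of $10^2$ analyzable miRNAs, and roughly a hundred detected per
sample. The planted maximally-stable candidate ($\sigma = 0.1$) is placed
at mean Ct 25, the well-expressed end of the panel, because consistent
detection across samples is part of the definition of a usable endogenous
control — a "stable" miRNA that drops out near the LOD is not a control.

## Problem sizes and numerical tolerances

Exact algebraic identities (centering, offset cancellation, oracle
equivalence) are asserted at 1e-10 to 1e-12. The simulation studies in the
test suite use sizes chosen to make the assertions sharp while keeping the
suite fast to iterate: 100 random instances for oracle equivalence
(5 candidates × 8 samples), 500 replicates at n = 200 for NormFinder
recovery, 200 replicates for planted-control recovery (15 candidates,
30 samples) and for the combination-control property, and 100 replicates
for the normalization-ordering benchmark (150 miRNAs × 30 samples).

## Known limitations

- NormFinder is single-group only; group-difference stability terms are a
  possible extension.
- No exogenous spike-in normalization: spike-ins address extraction/RT
  efficiency only and are a different design.
- Imputation is the fixed-value Ct 40 rule; model-based non-detect
  imputation is out of scope.
- The internal variants of public reference-gene web tools are not
  published in detail; the four algorithms here follow their original
  publications, and comprehensive rankings may differ from such tools in
  tie handling.
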