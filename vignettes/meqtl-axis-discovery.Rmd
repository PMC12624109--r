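---
title: "Discovering and stress-testing SNP–methylation–expression–risk axes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and stress-testing SNP-methylation-expression-risk axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqaxis)
```

## The problem

Many disease-associated SNPs fall in non-coding DNA, where their mechanism
is invisible to expression analysis alone. Methylation quantitative trait
loci (meQTLs) — SNPs whose genotype shifts the methylation level of a nearby
CpG — offer a mechanistic bridge: allele → CpG methylation → promoter
activity → gene expression → disease risk. `meqaxis` implements an
integrated pipeline that assembles and stress-tests such axes in a
case-control cancer-susceptibility setting:

1. **Consensus differential methylation** (`testDifferentialMethylation()`,
   `consensusSites()`): per-CpG tumor-vs-normal tests in two independent
   datasets, Benjamini–Hochberg FDR within each, and the intersection of
   concordant calls.
2. **Candidate funnel** (`runFunnel()`): intersect consensus CpGs with
   tissue and blood meQTL summary records, then filter by tumor
   methylation–expression correlation, tumor-vs-normal expression fold
   change, reference minor allele frequency, and greedy LD pruning.
3. **Case-control association** (`fitAdditiveLogistic()`,
   `associateCandidates()`): additive-model logistic regression of case
   status on variant-allele dosage, optionally age-adjusted, with Wald
   confidence intervals.
4. **Biological plausibility** (`classifyAxis()`, `classifyTable()`): a
   two-rule sign-consistency classifier under the negative-regulation model.
5. **Joint co-methylation burden** (`coMethylationSet()`,
   `burdenPerSample()`, `burdenExpressionTest()`): an allele-dosage-style
   analysis of how many co-hypermethylated CpGs a subject carries and how
   that burden tracks target-gene expression.

A synthetic cohort generator (`simulateCohort()`) reproduces the
statistical structure every stage assumes, so the full pipeline is testable
without restricted individual-level genotype data.

## Methylation scales

CpG methylation is carried as beta values (the methylated fraction, in
(0, 1)) at the interfaces, but every statistical operation happens on the
M-value scale, `m = log2(beta / (1 - beta))`, which is unbounded and
approximately variance-stabilized near the boundaries. The two scales are
linked by the strictly monotone logistic map (`mToBeta()`, `betaToM()`), so
direction calls (Hyper/Hypo, High/Low) agree between scales. Simulated
effects are specified on the M scale and transported to betas through the
map — this keeps generated betas strictly inside (0, 1) by construction,
with no clipping; configurations whose expected M-values would drive betas
to within floating-point distance of the boundary are rejected at
validation time.

## The differential methylation stand-in

Production methylation-array pipelines reach consensus calls through large
preprocessing stacks. Here the per-CpG test is deliberately minimal and
fully specified: Welch's two-sample t on M-values, BH adjustment across all
tested CpGs **within each dataset**, and then the cross-dataset intersection
requiring FDR < 0.05 in both datasets with the same direction. Zero-variance
CpGs are flagged with p = 1 rather than erroring. This is a transparent
methodological stand-in, not an emulation of any specific array pipeline;
probe-level normalization, probe filtering and cell-type deconvolution are
out of scope.

## Funnel conventions

* **meQTL intersection.** Records carry only summary statistics (sign, p,
  source). FDR is computed within source; a pair must pass in *both* the
  tissue and blood source. Sign agreement between sources is enforced by
  default — all seven axes of the bundled reference table satisfy it — but
  can be disabled (`funnelThresholds(require_sign_agreement = FALSE)`) since
  one can read the published screen as merely observing, not requiring,
  agreement.
* **Correlation filter.** Pearson r between CpG M-values and
  log2(expression + 1), on tumor samples only by default (the reference
  table's r column describes tumor coupling); configurable to all samples.
* **Expression filter.** Fold change is a ratio of linear-scale group means;
  the test is Welch's t on log2(expression + 1); BH across tested genes.
* **LD pruning.** r² is the squared Pearson correlation of genotype dosages
  (composite LD) — deterministic and phasing-free. After the MAF gate,
  pruning is greedy in order of tissue meQTL p (ties broken by SNP ID), so
  each correlated cluster keeps its most significant representative. The
  retention rule is a convention; the published screen specifies only the
  r² < 0.80 criterion.
* All thresholds are strict inequalities exactly as conventionally printed:
  |r| > 0.3, FC > 2 or FC < 0.5, MAF > 0.05, r² < 0.80.

## The association model

Case status is regressed on variant-allele dosage (0/1/2; the second allele
of the "X>Y" annotation string is always the counted allele) with optional
covariates such as standardized age. Odds ratios use symmetric Wald
intervals, matching conventional GWAS logistic output. No multiple-testing
correction is applied at this stage — candidates reaching association
testing are a small pre-filtered set, and the nominal P < 0.05 rule is
retained; the BH-FDR over the tested set is reported alongside for
transparency but never filters. Perfect separation is detected and returned
as a flagged result with infinite confidence limits.

Reproducing the published rs939408 association from its genotype counts:

```{r rs939408}
axes <- loadReferenceAxes()
row <- axes[axes$snp_id == "rs939408", ]
d <- expandCounts(unlist(row[, c("cases_n0", "cases_n1", "cases_n2")]),
                  unlist(row[, c("controls_n0", "controls_n1", "controls_n2")]))
fitAdditiveLogistic(d$dosage, d$status, snp_id = "rs939408")[,
  c("maf_cases", "maf_controls", "or_value", "ci_low", "ci_high", "p_value")]
```

The unadjusted point estimate differs slightly from the published 0.89
because the published value is age-adjusted; it falls inside the published
interval (0.82–0.98).

## The plausibility classifier

Under the classical negative-regulation model — promoter hypermethylation
silences the gene — a coherent axis must satisfy two rules:

* **Rule 1 (negative regulation):** the tumor methylation–expression
  correlation is negative *and* the tumor-vs-normal methylation and
  expression calls point in opposite directions.
* **Rule 2 (risk concordance):** if the variant allele pushes methylation
  *toward* the tumor-like level (sign "+" with tumor-High methylation, or
  "−" with tumor-Low), the axis predicts risk (OR > 1); pushing *away*
  predicts protection (OR < 1). The observed OR must fall on the predicted
  side.

Three design choices matter. The classifier is restricted to the
negative-regulation model: a positively correlated axis fails Rule 1 rather
than being evaluated under a mirrored positive model. The "tumor-like"
direction is defined by the methylation call, not expression, because the
causal chain reasons from the allele to methylation first. And OR
significance is assumed pre-filtered upstream; the classifier uses only the
OR side, with OR = 1 flagged indeterminate. On the bundled seven-axis
reference table this yields exactly two passes:

```{r classify}
v <- classifyTable(axes)
data.frame(axis = v$axis_id, overall = v$overall)
attr(v, "counts")
```

## The synthetic cohort generator

The generator's defaults encode the study-like conditions the pipeline
assumes; they are conventions chosen once, not tuning knobs.

* **Genotypes** are Hardy–Weinberg dosages built from two independent
  haplotype panels. Within an LD block every SNP shares one MAF (drawn
  uniformly from `maf_range`), and a haplotype's allele at SNP *j* copies
  SNP *j − 1* with probability `ld_rho`, else is drawn fresh. This
  first-order copier preserves marginal MAF (hence HWE) exactly and gives
  adjacent-SNP allele correlation `ld_rho`, i.e. dosage r² = `ld_rho²` —
  the simplest mechanism with directly tunable pairwise LD.
  `simulateHaplotypes()` exposes the pre-collapse haplotype table for
  cross-checks.
* **Planted axes** carry four independently signed effects (per-allele
  M-shift, tumor M-shift, expression slope per M-unit, per-allele log OR),
  so both plausibility-passing and plausibility-failing patterns can be
  planted.
* **Tissue panel vs association cohort.** Tumor/normal methylation samples
  form a panel separate from the case-control cohort, mirroring the usual
  split between a tissue discovery population and a GWAS population.
* **Phenotype.** Age is uniform on [40, 75] (no published distribution
  exists for the source cohorts; a uniform middle-aged span is a neutral
  convention) and standardized before entering the risk model with a mild
  default log OR of 0.1 per SD. The logistic intercept is solved
  numerically so the expected case fraction matches the configured
  case/control split.
* **Expression** is `baseline_expr + slope * M + noise`, floored at zero.
  The baseline (default 8, noise SD 1) keeps typical values well away from
  the floor; demonstrations of methylation-silenced genes use a lower
  baseline (2–6) with slopes of −1 to −3 so that a +2 tumor M-shift moves
  the fold change decisively below 0.5.

What the generator does **not** emulate: realistic genome-wide LD maps,
probe artefacts, batch effects, cell-type composition, count-based
expression noise, or population stratification. Passing tests therefore
demonstrate the pipeline's statistical correctness under its stated model,
not robustness to the full messiness of array data.

## Problem sizes and test design

The test-suite simulations use a 500-tumor/50-normal tissue panel over
~2000 background CpGs with three planted axes for funnel-recovery checks;
20-seed batches for null-control and calibration properties; and the full
published cohort size (3453 cases / 3710 controls at MAF 0.158) for
odds-ratio recovery, averaged over 50 seeds. These sizes give every planted
effect essentially full power per stage while keeping each property check
in the seconds-to-tens-of-seconds range. Independent brute-force oracles
(step-up BH from its definition, r² from raw sums, exact Mann–Whitney by
enumeration of the permutation distribution, an exhaustive 32-pattern rule
table for the classifier) back every algorithmic component.

## Numerical and degenerate-input choices

Logistic fits run IRLS to a deviance tolerance of 1e−12; separation is
flagged, never silently reported. Matrix TSVs are written with 17
significant digits so write/read cycles are bit-exact and equal seeds give
byte-identical cohort directories. Zero-variance CpGs, constant expression
vectors, missing panel SNPs, empty consensus sets and empty burden bins are
all defined, warned/reported outcomes rather than errors. Annotation
positions are 1-based fully closed; BED-like input is converted explicitly.
One bundled CpG (cg09596674) has two discordant published positions; both
are retained and flagged rather than resolved.

## Joint burden conventions

No standard definition exists for "carrying" a hypermethylated site; the
package uses beta > normal-reference mean + k·SD with k = 1 by default,
prominently configurable. Default burden bins follow the conventional
0 / 1–3 / 4–6 / 7 grouping for a seven-CpG set; arbitrary partitions are
accepted. Group contrasts use two-sided Mann–Whitney U tests against the
zero-burden bin and the trend measure is the Spearman correlation of burden
against expression. Burden scoring defaults to tumor samples with the
normal panel used only for thresholds.

## Known limitations

The funnel's published end-to-end counts (tens of thousands of consensus
CpGs down to 93 meQTLs) depend on restricted individual-level datasets and
are not reproducible here; the package instead validates the funnel by
planted-recovery, null-control and monotonicity properties on synthetic
cohorts. The differential methylation and expression tests are two-group
Welch tests without covariates or empirical-Bayes moderation. The
association stage does not model population stratification or imputation
uncertainty. The plausibility classifier is qualitative — a sign-consistency
screen, not a mediation analysis or causal effect estimate.
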