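---
title: "Methods: condition-aware eQTL inference with stimqtl"
author: "stimqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-aware eQTL inference with stimqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimqtl)
```

# Scope

`stimqtl` implements the inference stack for expression quantitative trait
locus (eQTL) studies with a *paired-condition* design: the same individuals
contribute samples under a resting and a stimulated condition for one or
more cell types (the motivating setting is resting/LPS-stimulated myeloid
cells and resting/PHA-stimulated CD4+ T cells from cord blood, with
per-condition sample sizes near 116/125/126/127 and ~95 complete cases).
The stack comprises per-condition cis-eQTL mapping with hierarchical
multiple-testing correction, conditional dissection of independent cis
signals, response-eQTL (reQTL) detection by genotype-by-condition
interaction with a permutation null, cross-chromosome trans-eQTL scans,
mediation analysis of trans effects through cis genes, Bayesian
colocalisation with GWAS loci, two-sample Mendelian randomisation (MR), and
pi1 replication-rate estimation.  A synthetic-data generator with planted
ground truth makes every stage testable end to end.

# The synthetic-data generator

## What it emulates

`simConfig()` defaults encode the study conditions: 135 genotyped
individuals; four conditions with retention fractions 116/135, 125/135,
126/135, 127/135 (post-QC attrition) and a complete-case core of 95/135;
SNPs with alternative-allele frequency drawn uniformly from [0.10, 0.50]
(the analysis MAF floor); LD blocks of 10 SNPs with target adjacent-dosage
correlation 0.8; and 14 covariates (sex, three genotype-PC proxies, ten
latent factors with small loadings on every gene).  Planted effects are cis
eQTLs (effect s.d. 0.6 expression units per allele), reQTLs including sign
flips, cis-mediated trans trios, GWAS loci that share or do not share a
causal SNP with an eQTL, and genes with causal liability effects.

Where the emulated study design leaves a value open we fixed one realistic choice once:
gene-level condition main effects and individual random intercepts have
s.d. 0.5, residual noise s.d. 1, trans mediation paths have |b| in
[0.6, 1.0] with direct effects ~ N(0, 0.15), GWAS locus effects have
magnitude 0.08–0.15 liability units per allele, and the default GWAS cohort
is 20,000.

## LD model

Genotypes come from a Gaussian copula per block: two latent AR(1) haplotype
vectors per individual are thresholded at the Hardy–Weinberg quantile of the
block allele frequency and summed.  Thresholding attenuates correlation, so
the latent AR parameter is calibrated numerically (one-dimensional
quadrature for the bivariate normal orthant probability plus root finding)
so that the *dosage* correlation of adjacent SNPs matches the target.  The
allele frequency is constant within a block — adjacent SNPs with very
different frequencies cannot reach high dosage correlation, and real LD
blocks have similar frequencies.  Blocks whose realised sample MAF drops
below 0.08 (or that come out monomorphic) are redrawn.  Block parameters
are free simulation knobs, not estimates of any real LD map.

## What it does not emulate

Probe-level microarray intensities, background correction, population
structure beyond the PC proxies, and sex chromosomes are out of scope.
Passing tests therefore show correctness of the statistical machinery under
a well-specified generative model, not robustness to microarray artefacts
or confounding structure absent from the generator.

# Preprocessing

The expression pipeline order is fixed: genotype QC (missing call rate
> 1%, MAF < 1%, HWE p < 1e-6 on a 1-d.f. chi-square without continuity
correction) -> analysis MAF filter (>= 10%, inclusive) -> detectability
filter (detection p <= 0.01 in >= 2.5% of any one condition's samples or >=
5% of all samples) -> one probe per gene (highest mean intensity, exact
ties to the lexicographically smaller probe id) -> quantile normalisation
within condition (via `limma::normalizeQuantiles`) and log2 -> rank-based
inverse normal transform (INT) per gene within condition for eQTL use.

Two deliberate substitutions: background correction is a pass-through with
a positivity check (the negative-control model is microarray-specific and
the generator emits post-correction intensities), and the latent technical
factors normally estimated with PEER are replaced by the top 10 expression
principal components per condition after INT (`addExpressionFactors()`) —
the same role, deterministic, and dependency-free.  The INT offset is
Blom's 3/8, the common default.  Note that
the per-condition + overall detectability rule is formally redundant in its
overall branch (an overall fraction is a weighted mean of per-condition
fractions), but both branches are implemented as stated.

# Cis-eQTL mapping and the hierarchical correction

Each gene is regressed on every SNP within 1 Mb of its TSS (1-based
positions, inclusive on both sides) with the 14 covariates; p-values use
the t distribution with n - k - 1 d.f.  Dosages enter as-is, without
rounding.  Multiple testing is corrected hierarchically: locally, each
gene's minimum p is multiplied by its effective independent SNP count
m_eff — eigendecomposition of the dosage correlation matrix in consecutive
chunks of <= 200 SNPs, counting eigenvalues needed to reach 99% of total
variance (both config-exposed); globally, Benjamini–Hochberg across genes
at FDR 5%.  The largest locally adjusted p passing the global step (p*)
yields per-gene nominal thresholds p*/m_eff, which define the significant
eSNP sets (the top SNP is always a member).  Top-SNP ties break by smallest
p, then largest |beta|, then smallest position.

Conditional analysis proceeds forward (re-scan conditioning on all selected
SNPs while any p beats the nominal threshold; at most 10 iterations by
default — multi-signal genes are rare) and backward (each signal re-tested
in a leave-one-out model; retained if the strongest association in that
model still beats the threshold), so the backward set is a subset of the
forward set.  Cross-condition conditioning adjusts condition B's scan for
condition A's top eSNP; because a non-significant conditional scan cannot
distinguish a genuinely shared signal from lack of power, the label is
documented as "shared (or underpowered)".  Both conditioning directions are
computed by the pipeline since neither is canonical.

# Response eQTLs

For each cell type, eGene top eSNPs are selected per condition; a gene
significant in both conditions contributes both top eSNPs when their
r^2 < 0.8 and only the more significant one otherwise.  The interaction
model is a linear mixed model: expression on dosage, condition,
dosage-by-condition, the 14 covariates and all covariate-by-condition
interactions, with a random intercept per individual.  The package fits it
by profiled REML: with a single random intercept the covariance has a
closed-form block whitening, leaving a one-dimensional optimisation over
the variance ratio; estimates agree with `lme4::lmer` (checked in the test
suite, which uses lme4 as the independent oracle).

The null distribution of the interaction Wald |t| comes from permutations
that swap (or not) each individual's full condition pair independently —
equivalent to shuffling condition within individual, and preserving
covariates and the random-effect structure exactly.  Two numerical
decisions: the comparison statistic is |t| of the interaction term (the
source procedure says only "more significant"), and the variance ratio is
held at its observed-data REML estimate during permutation refits (the
grouping, and hence the whitening, is unchanged by the permutation; only
the fixed effects are refit by GLS).  The empirical p-value is
(s + 1)/(n + 1), bounded below by 1/(n + 1); BH across all tests in a cell
type at 5% defines response eGenes.  Optional early stopping (once s is
large enough that significance is out of reach) is off by default and does
not change calls when enabled.

# Trans eQTLs and mediation

Trans tests pair every gene with every SNP on a different chromosome, with
the cis model and covariates.  To bound memory only rows with p < 1e-5 plus
each gene's minimum-p row are retained — sufficient for all three
correction schemes: (1) BH over all pair p-values (the default reported
scheme, the least conservative); (2) per-gene min p times the effective
genome-wide test count 0.05/5e-8 = 1e6, capped at 1, BH across genes;
(3) per-gene Bonferroni at 5e-8/n_genes.  The schemes are nested, scheme 3
being the most conservative.

Trans-eSNPs that are also significant cis-eSNPs of a local gene define
mediation trios (exposure SNP, cis mediator, trans outcome); combinations
without that cis link are reported as not tested.  Paths come from two OLS
fits sharing the same covariates — a (mediator on exposure), and b, c'
(outcome on mediator and exposure) — so total = a*b + c' holds as an
algebraic identity.  Inference on the indirect effect a*b uses a
nonparametric bootstrap (10,000 resamples by default) that resamples
*individuals*, respecting the paired design (the resampling unit is a
modelling choice); the p-value is the percentile-interval sign crossing
(percentile rather than BCa, config-exposed), floored at 1/n_boot, with BH
across trios.  The proportion mediated a*b/(a*b + c') is reported raw and
clipped to [-1, 2] because the ratio is unstable when the total effect is
near zero.

# Colocalisation

Loci are selected where a significant cis-eSNP has GWAS p <= 1e-6; the SNP
set is the intersection of both summary sets within +/- 200 kb of the top
eSNP (inclusive), and loci with fewer than 25 shared SNPs are skipped.
Per-SNP evidence is the Wakefield log approximate Bayes factor
0.5*log(1 - r) + z^2 r/2 with r = W/(W + se^2); prior effect variances
default to 0.15^2 (quantitative) and 0.2^2 (log-odds), the standard
defaults for Wakefield-ABF colocalisation.  Single-causal-variant configurations are enumerated for
the five hypotheses with priors p1 = p2 = 1e-4 and p12 = 1e-6 (the
conservative choice); all sums use log-sum-exp because ABFs overflow
doubles at large z.  Decisions: underpowered if PP3 + PP4 < 0.8, else
colocalised if PP4/PP3 >= 5, else distinct.  A sensitivity table over p12
in 1e-9..1e-5 (log-spaced) reports whether the decision is robust; PP4 is
monotone non-decreasing in p12, and a single-SNP locus has PP3 = 0
identically.  GWAS alleles are harmonised to the panel orientation first,
dropping strand-ambiguous SNPs.

# Mendelian randomisation

Instruments are cis-eSNPs present in the GWAS: harmonisation aligns effect
alleles (flipping the outcome beta on swaps), removes palindromic A/T and
C/G SNPs and irreconcilable allele pairs, and is idempotent.  Greedy LD
pruning by ascending exposure p-value enforces pairwise r^2 < 0.1; genes
with fewer than three instruments are skipped.  Estimators: IVW (weighted
through-origin regression, algebraically the precision-weighted mean of
ratio estimates, with multiplicative random-effects SE floored at 1);
weighted median (interpolated, SE from 1000 seeded parametric bootstrap
draws); weighted mode (weighted normal-kernel density of ratios,
modified-Silverman bandwidth with factor 1); and Egger regression with
intercept after orienting exposure betas positive.  First-order ratio SEs
se_out/|beta_exp| supply the median/mode weights.  The verdict is
excluded_pleiotropy when the Egger intercept p <= 0.05, causal_suggestive
when at least three of four methods reach p <= 0.05, else not_significant;
no multiple-testing correction is applied across genes/diseases; the
consensus rule itself is the guard against single-method artefacts.  When a gene is testable in several conditions the
reporting rule keeps the condition with the most instruments
(config-overridable).  The weighted-mode estimator is conservative by
construction (sub-nominal type-I error under valid instruments); the test
suite asserts the nominal band only for IVW and the weighted median and an
upper bound for all four.

# Replication rate

pi1 = 1 - pi0 on the replication p-values of one dataset's significant
pairs, with pi0 from the Storey smoother: pi0(lambda) = #{p > lambda}/(n(1
- lambda)) on the grid 0.05..0.95, a 3-d.f. cubic smoothing spline
evaluated at the largest lambda, clipped to [0, 1] (the smoother rather
than the bootstrap variant: deterministic, and the usual default).
Output metadata repeats the caveat that this sharing measure ignores
direction and magnitude of effects.

# Orchestration and reproducibility

`runPipeline()` executes simulate -> INT -> cis -> signals -> reqtl ->
trans -> mediate -> coloc -> mr -> pi1 with any stage skippable; stages
needing skipped outputs refuse to run.  Every stage derives its own RNG
stream from the master seed, so each stage's outputs are pure functions of
(inputs, config, seed) and the run manifest's hashes reproduce exactly.
Genomic positions are 1-based inclusive internally; BED-like outputs are
converted to 0-based half-open at the boundary.  There is no shell
executable: the exported functions, this vignette and the repository's
acceptance script are the interface.

# Problem sizes used in validation

The packaged validation suites are sized for a single CPU: global-null
calibrations use 500 genes x ~50-SNP cis windows (40 seeds in the test
suite for the cis and trans FDR checks; the acceptance script reports a
10-seed estimate) and 200 genes x 100 permutations over 10 seeds for the
reQTL check; recovery suites use 20 seeds (cis effect sizes at n = 120,
interaction power at n = 120 with 200 permutations) or 50 seeds (mediation
proportion at n = 126, MR coverage with 8 instruments).  Two properties of
the realised-FDR estimate deserve note.  First, under a global null each
dataset's false-discovery proportion is exactly 0 or 1 (BH rejects at most
a gene or two when it rejects at all), so the mean-FDP estimate has
granularity 1/(number of seeds): with 10 seeds it cannot distinguish a
calibrated procedure from a mildly liberal one, which is why the test
suite uses 40.  Second, the permutation count in the reQTL null
calibration is deliberately modest: lowering it only *raises* the
attainable minimum p-value and makes false reQTL calls harder, so the
realised-FDR bound is insensitive to it.

# Known limitations

Single-causal-variant colocalisation only (no SuSiE-style multi-causal
extension); no exposure-mediator interaction or unmeasured-confounding
sensitivity analysis in mediation; no MR outlier removal (MR-PRESSO),
multivariable MR or Steiger filtering; trans analysis restricted to
different chromosomes (no same-chromosome distal associations); and the
permutation and bootstrap nulls inherit the generator's assumption of
Gaussian, homoscedastic noise.
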