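---
title: "Methods: GMDR interaction search, risk-allele PRS and stratified G×E"
author: "gmdrprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GMDR interaction search, risk-allele PRS and stratified G×E}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdrprs)
```

This vignette documents the statistical model behind each pipeline stage,
the tunable parameters and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where the conventions of the field leave room.

## 1. The pipeline in one paragraph

Candidate SNPs (additive minor-allele dosage, 0/1/2) pass per-SNP QC, a
covariate-adjusted logistic association scan with a hard p-value gate, and
LD pruning. Generalized multifactor dimensionality reduction (GMDR) then
searches k-SNP combinations for multilocus interaction structure; the best
model's SNPs define an unweighted risk-allele-count polygenic risk score
(PRS), whose Low/Medium/High categories are related to the outcome by
adjusted odds ratios and tested for multiplicative interaction with
dichotomized environment variables.

## 2. Quality control

* **Allele frequency** is `sum(dosage) / (2 n_called)`, folded to the
  minor allele (≤ 0.5) with a flip flag.
* **Hardy–Weinberg equilibrium** uses the 1-df Pearson chi-square of the
  genotype counts against (p², 2pq, q²) at the estimated allele frequency;
  SNPs are kept when p > 0.05. The chi-square (rather than an exact test)
  mirrors the GWAS-era QC convention this pipeline reproduces; an exact
  conditional mid-p test is available via `hwe_test(g, exact = TRUE)` and
  is preferable below MAF ≈ 0.05, where the chi-square approximation
  thins out.
* **Call rate** threshold is 0.96 per SNP and per sample, i.e. under 4%
  missingness. **Heterozygosity** is flagged above 0.30 per sample; the
  bound's direction is configurable (`het_upper = FALSE` flags deficits
  instead) because published QC descriptions are often ambiguous about
  which tail the bound addresses — excess heterozygosity signals sample
  contamination, deficits signal inbreeding or genotyping failure.
* **LD r²** is the squared Pearson correlation of dosages over
  pairwise-complete subjects (the composite, genotype-scale r²), not the
  EM-haplotype r² of phase-aware tools such as Haploview. The composite
  form needs no phase, is deterministic, and is flip-invariant
  (d → 2 − d leaves r² unchanged); for the pruning decision at a 0.4 gate
  the two definitions rarely disagree, but the divergence is real and
  documented here.
* **Pruning rule**: within each chromosome, while any kept pair has
  r² ≥ 0.4, the pair with the largest r² is resolved by dropping the SNP
  with the larger association p-value (the scan precedes pruning in this
  design), with lexicographic snp_id as the tie-break. SNPs of unknown
  chromosome are conservatively pruned against each other as one group.

## 3. Association scan and adjusted odds ratios

Each SNP is fit by maximum likelihood (IRLS) in
`outcome ~ intercept + dosage + covariates`, complete-case per SNP.
Reported are the per-allele odds ratio `exp(beta)`, the Wald 95% interval
`exp(beta ± 1.96 SE)` and the two-sided Wald p — the standard output of a
GWAS-era logistic scan; no likelihood-ratio or score variant is used for
the scan itself. Monomorphic SNPs yield a flagged record with OR 1 and
p 1. Coefficients above 15 in absolute value raise a separation warning
and clear the convergence flag. Selection keeps SNPs with p strictly
below the gate (default 10⁻⁴), ordered by p. `adjusted_or()` is the same
engine for categorical exposures (one multivariate fit, treatment coding
against a reference level); no multiplicity adjustment is applied beyond
the hard gate, matching the source design.

## 4. GMDR

**Score residuals.** A null logistic model of the outcome on covariates
only (always including an intercept) yields s_i = y_i − p̂_i. The
residuals sum to zero; cases have s > 0, controls s < 0, so the sign of s
generalizes case/control status. With no covariates, cases score 1 − π
and controls −π at sample prevalence π.

**Cell labeling.** Training subjects are partitioned into the 3^k cells
of a k-SNP genotype tuple (subjects missing any of the k genotypes are
excluded). A cell is high-risk when its score sum exceeds the threshold
T = 0; ties, negative sums and empty cells are low. Ties-to-low is the
conservative choice (toward the null); an epsilon of 1e-9 × Σ|s| keeps
exact ties from flipping high through floating-point noise. In the
no-covariate case the rule is exactly classic MDR's "cell case/control
ratio above the cohort ratio".

**Balanced accuracy on the score scale.** Sensitivity is the share of
positive score mass in high-labeled cells, specificity the share of
negative score mass in low-labeled cells, BA their mean. Genotype tuples
unseen in training count as low. This reduces to classic MDR's
count-based BA for two-valued scores — the anchor the test-suite verifies
against a brute-force MDR oracle on all instances up to 3 SNPs and 30
subjects. Published GMDR descriptions do not spell out a formula; the
score-mass form is the natural generalization with that exact reduction.

**Cross-validation.** Folds (default 10, the convention for cohorts above
1,000 subjects) are stratified by the sign of s and fixed by a seed. Per
fold, cells are labeled on the training 9/10; TRBA is the training BA and
TEBA the held-out BA.

**Model search.** For each order k, every candidate set (exhaustive up to
a budget of 200,000 model × fold evaluations; a seeded greedy forward
search beyond it, since an exhaustive C(43, 5) search at cohort scale is
not desk-scale) is evaluated on the shared folds. Each fold picks the
model with the highest *training* BA — selecting on training keeps the
held-out accuracy honest. CVC is the number of folds picking the modal
model; reported TRBA/TEBA are that model's fold means (whether published
TRBA/TEBA are fold means or whole-sample statistics is typically
unstated; fold means are implemented). Across orders, models are ranked
by: significant sign test first, then higher TEBA, then smaller k (a
smaller model at comparable accuracy is preferred), then lexicographic
SNP set.

**Sign test.** The per-fold TEBAs are tested against 0.5 by a two-sided
Wilcoxon signed-rank test — exact by full enumeration of sign assignments
(midranks for ties, zeros dropped) up to 20 non-zero folds, normal
approximation with tie correction beyond. Ten folds all above 0.5 give
the minimal two-sided p of 2/1024 ≈ 0.00195. Some of the literature uses
a plain sign test in this role; `method = "sign"` provides it. Per-fold
differences are rounded at the 12th decimal before ranking so that
floating-point noise cannot break exact ties.

## 5. PRS construction

Risk alleles are fixed by the scan: beta > 0 keeps the minor-allele
dosage, beta < 0 reflects it (d → 2 − d, an involution), beta = 0 is an
error (no defined risk direction). The PRS is the unweighted integer sum
of risk-allele counts, in [0, 2k] for k model SNPs — unweighted by
design; a beta-weighted score is deliberately not the default and is left
out of the surface. Subjects missing any model genotype are excluded by
default (`missing_policy = "impute"` substitutes the rounded mean
risk-dosage instead, recording the count of imputed SNPs).

Categories: tertile mode uses type-1 (attained-value) quantiles at 1/3
and 2/3 with ties falling low, so the category map is a deterministic
function of the score. Fixed mode implements the 0–3 / 4–5 / ≥6
convention via `fixed_cutoffs = c(3, 5)`; a published variant of this
rule prints "0–3, 4–5, >6", leaving score 6 unassigned — since the three
groups must be exhaustive, 6 belongs to the top category here. Fixed
cutoffs presuppose a score distribution like the one they were derived
on; with other orientation profiles they can leave categories empty,
which is why the pipeline default is tertile.

## 6. Stratified G×E

Environments are dichotomized with "below the cutoff = low = reference";
the boundary value itself goes high (a glucose of exactly 126 mg/dL is
not "< 126"). Median and percentile cutoffs (e.g. the 67th percentile for
dietary-pattern scores) are computed on non-missing values; composite
rules (blood pressure from SBP and DBP jointly) use a predicate function.
Degenerate splits are errors.

Per-stratum PRS-category ORs come from separate per-stratum logistic
fits — not from one interaction model — so non-monotone stratum patterns
can show through; zero-event cells are flagged and their OR omitted. The
interaction test compares, by a 1-df likelihood ratio, the model with a
product of ordinal PRS (0/1/2) and the binary environment against the
same model without the product. The ordinal 1-df coding matches reporting
one interaction p per environment; a 2-df categorical product test is
available (`ordinal = FALSE`). Without covariates the categorical
interaction model is saturated in (PRS, environment), so its low-stratum
coefficients equal the per-stratum fits exactly — a property the tests
assert to 1e-6.

## 7. The synthetic cohort generator

The generator is the package's substitute for access-restricted cohort
data, and its defaults are the study conditions it emulates: the bundled
ten-SNP candidate panel with published MAFs (0.041–0.300) and per-allele
ORs (0.63–1.78); covariates age 53.7 ± 5.5 y, male fraction 0.339, BMI
23.9 ± 2.8; environments carbohydrate 71.7 ± 20.8 energy% and glucose
95.0 ± 20.2 mg/dL; an outcome prevalence near 0.78% (377 cases among
48,197) via `calibrate_intercept()`; genotype missingness ≤ 4% MCAR.

* **Genotypes** are drawn at exact HWE marginals by thresholding a
  standard Gaussian at the (q², q² + 2pq) quantiles. **LD blocks** share a
  common latent factor whose loading is calibrated by 1-d numerical
  integration so the realized dosage r² matches the target; thresholding
  preserves each SNP's HWE marginal exactly, which is why this mechanism
  was chosen over resampling haplotypes. Realized r² is within ±0.1 of
  target at n = 10,000 (tested), exact at target 1.
* **Outcome**: Bernoulli with logit = intercept + Σ beta·dosage +
  covariate terms + an epistasis cell offset + a G×E term. Epistasis is an
  explicit penetrance-table delta — extra log-odds attached to chosen
  multilocus cells — precisely the structure GMDR is designed to detect.
  The G×E term is `beta × risk-allele count × 1(env ≥ cutoff)` with risk
  orientation taken from the sign of the generative per-SNP beta, so the
  planted interaction acts on the same scale as the PRS that is supposed
  to pick it up. Missing dosages enter the linear predictor at their HWE
  expectation 2q.
* **Not emulated**: population structure and admixture, family
  relatedness, imputation dosages, X-chromosome dosage rules,
  genotype-dependent (non-MCAR) missingness, and outcome misclassification
  — the self-reported diagnosis behind the motivating cohort is treated as
  error-free because no ascertainment model is stated for it. Environments
  are independent of genotype unless a G×E term is set (the simplest
  null). Passing tests therefore demonstrate correctness of the machinery
  under these idealized conditions, not robustness to stratification or
  differential misclassification.

## 8. Problem sizes and calibration choices in the tests

Test and acceptance simulations are sized for a laptop-class single core:
null-calibration suites use 200–1,000 replicates at n = 300–600;
parameter-recovery suites use 50 replicates at n = 2,000–5,000; the
demonstration cohort in the acceptance script is full-scale (48,197).
Recovery suites run at enriched case fractions (10–40%) rather than the
0.78% of the emulated cohort: with under 400 cases, single-run
interaction statistics are dominated by noise, so detection properties
are asserted as rates over seeded replicates, and a rare-outcome cohort
of that size would make per-replicate recovery tests both slow and
uninformative. The planted-effect magnitudes (per-allele OR 1.7, cell
delta +1.2 at MAF 0.3, G×E beta 0.3 per risk allele) sit at the scale of
the published panel's ORs.

## 9. Known limitations

* The Wald scan p-value is anti-conservative in small strata and under
  separation; flagged records should not be over-read.
* Composite dosage r² underestimates haplotype r² when allele frequencies
  differ strongly; a pair just under the 0.4 gate by one definition can
  be just over by the other.
* The greedy search is not guaranteed to find the exhaustive optimum;
  it is seeded and reproducible but path-dependent.
* CVC is reported against the number of folds actually run; with a single
  candidate model it is trivially maximal.
* Fixed PRS cutoffs are only meaningful for score distributions
  resembling the one they were derived on (see §5).
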