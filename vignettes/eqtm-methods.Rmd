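---
title: "Methods: methylation-expression association, colocalization and causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-expression association, colocalization and causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtmr)
```

This vignette documents the statistical models implemented in `eqtmr`,
the assumptions behind them, the defaults and why they were chosen, and
the design decisions taken where more than one reasonable convention
exists. It also describes what the synthetic cohort generator does and
does not emulate, and therefore what passing tests do and do not
demonstrate about real data.

## The two-stage residualization model

Molecular matrices are cleaned per feature by ordinary least squares
against `[intercept | covariates]` — age, sex, six leukocyte proportions,
and technical batch as a categorical fixed effect — followed by a second
projection onto `k` surrogate variables estimated from the covariate
residuals. Although cleanup protocols of this kind are sometimes phrased
as mixed models, no random-effects grouping structure is involved when
all listed covariates are fixed individual-level quantities, so the
projection is implemented as fixed-effects OLS: it is exactly testable
against the closed-form hat-matrix projector, and idempotent.

Surrogate variables are the top `k` left singular vectors of the
feature-centered residual matrix. Full iterative surrogate variable
analysis re-weights features against a working model; the truncated-SVD
form used here is deterministic, orthonormal by construction, and
recovers dense latent structure (such as hidden batch) essentially as
well when confounding is broad. The sign of each SV is fixed by making
its largest-magnitude loading positive, so results are reproducible
across BLAS implementations. `k` defaults to 25, the count commonly used
for whole-blood arrays; for small synthetic cohorts it is capped at
`n/10` (with a message), because estimating many singular vectors from
few samples makes the second projection ill-conditioned.

Two caveats follow from the SVD formulation and are worth knowing when
interpreting simulations. First, with *few features*, a single feature
carrying a very strong genetic effect can dominate a singular vector, and
the second projection will then absorb real signal; with realistic
feature counts (hundreds to thousands) surrogate variables are dominated
by structure shared across features. Second, surrogate variables are
re-estimated per matrix and per cohort, mirroring the practice of letting
each cohort specify its own technical covariates.

## The per-pair association model

For a CpG-transcript pair the model is simple linear regression of the
expression residual on the methylation residual (methylation is the
predictor: the quantity of interest is the proportion of expression
variance explained by the CpG). Estimates are computed in closed form
(vectorized over pairs; pairwise-complete observations when values are
missing, with per-pair `n` recorded), and p-values use the t distribution
with n − 2 df. Exact fits return `r_squared = 1` with the p-value clamped
at the smallest positive double rather than 0.

Pair classification: *cis* means same chromosome and CpG position inside
the closed interval `[tss − w, tes + w]` with `w = 500000` bp; everything
else, including all cross-chromosome pairs, is *trans*. Closure of the
boundary is a convention fixed here and asserted in tests (a CpG at
exactly `tss − w` is cis). Distance is 0 inside the gene body, otherwise
the distance to the nearer of TSS/TES, after collapsing strand so
`tss ≤ tes`. Significance thresholds are applied inclusively
(`p ≤ 1e−8` cis, `p ≤ 1e−12` trans) to the raw p-values: the thresholds
themselves are the published multiplicity-corrected cutoffs, so no
Bonferroni divisor is recomputed.

## Conditional analysis

Per transcript, the most associated CpG (lowest p; ties broken by larger
|t|, then smaller genomic position, then lexicographic id — p-values are
clamped at 1e−300 first so underflow cannot create spurious ties) is
added to the model, and each remaining significant CpG is re-tested
conditionally. The default `single_round` mode performs exactly one such
round, because the procedure is described as adding *the* top CpG; a
`stepwise` mode (add the best survivor and repeat until none pass) is
provided because collapsing to fully non-redundant sets is the plural
reading, and the mode is recorded in the output. A tested CpG whose
correlation with a conditioning CpG exceeds 0.999 in magnitude is
declared redundant with a collinearity flag instead of producing an
unstable fit.

## Censored-effect meta-analysis

When some cohorts stored results only at p below a storage threshold,
complete-case inverse-variance pooling conditions on significance and is
biased away from zero. The estimator here maximizes the proper censored
likelihood: reported studies contribute `N(beta_i; theta, se_i^2 + tau^2)`
densities and each censored study contributes
`P(|beta/se_i| < z_crit(censor_p))` under the same distribution. The
reference approach in the field imputes unstored effects by multiple
imputation under the same likelihood; direct maximization was chosen
because it is deterministic and oracle-testable, and reduces exactly to
fixed-effect IVW when nothing is censored. Censored studies must carry a
standard-error proxy (typically `sd/sqrt(n)` from the study's reported
results), since the likelihood needs their sampling scale. The random
model optimizes over `(theta, log tau^2)` from a deterministic grid of
restarts, with the `tau = 0` boundary handled by comparison against the
fixed-model fit; `se(theta)` comes from the observed information
(numerical second derivative). Non-convergence is flagged, never silent.

## Colocalization

Per-SNP evidence uses the Wakefield asymptotic Bayes factor with a normal
effect prior of standard deviation `W = 0.15` per trait — the documented
default for quantitative traits, configurable per trait. Assuming at most
one causal variant per trait per region, the five-hypothesis posterior is
assembled from log-sum-exp accumulations of the per-SNP log ABFs; the H3
mass `exp(L1 + L2) − exp(L12)` is computed via `log1p(-exp(d))` with
`d = L12 − L1 − L2`, clamped (and flagged) in the rare numerical case
`d ≥ 0`. A single-SNP region has no two-distinct-variant support, so PP3
is exactly 0 with a flag. Priors default to `p1 = p2 = 1e−4`,
`p12 = 1e−5`; a pair is called colocalized at `PP4 > 0.8`. Region
intersection uses a closed ±1 Mb window, harmonizes effect alleles
(swaps and strand flips resolved; palindromic SNPs resolved by allele
frequency when it is informative — more than 0.08 from 0.5 in both
tables — otherwise dropped with a count). The screen that decides which
pairs are colocalizable applies Benjamini-Hochberg FDR < 0.05 within each
QTL store separately and requires at least one passing SNP shared by the
pair; the posterior is then computed over *all* shared SNPs.

## Mendelian randomization

Instruments are cis-QTL SNPs pruned greedily by LD: keep the smallest-p
SNP, drop everything with `r² ≥ 0.001` against it, repeat. With one
instrument the causal estimate is the Wald ratio `b_out/b_exp` with the
first-order delta-method standard error `|se_out/b_exp|` (the
second-order term involving `se_exp` is intentionally omitted: it matches
the standard toolkit default and keeps the closed-form identity with the
weighted-least-squares oracle exact). With several instruments the
fixed-effect IVW estimate pools per-instrument ratios by inverse
first-order variance — algebraically identical to zero-intercept WLS of
outcome betas on exposure betas with weights `1/se_out²`. Cochran's Q is
reported as a diagnostic, not absorbed. P-values are two-sided normal,
appropriate to the summary-statistic regime. Bidirectional analyses
require each instrument set to have been selected on its own exposure
(`p_exposure ≤ iv_p_max`, default 1e−3); violating that — e.g. using a
SNP chosen for its outcome association — is a validation error. The
binary-outcome scale of summary statistics is passed through as metadata;
estimates for binary outcomes are on the log-odds scale of the input
GWAS.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions for every downstream test. It emulates:

- LD-blocked genotypes: two latent-Gaussian haplotypes per sample with
  block-equicorrelation `ld_rho` thresholded at the allele-frequency
  quantile (Hardy-Weinberg dosages 0-2, controllable within-block r²,
  zero between blocks); per-SNP MAF uniform on `maf_range`.
- Methylation on the logit (latent) scale — baseline + mQTL dosage
  effects + smoking pack-year effects + covariate/batch effects +
  Gaussian noise — squashed through the logistic so beta values stay in
  (0, 1). Downstream analysis consumes raw beta values. Per-CpG
  baselines belong to the architecture (not the cohort), so several
  cohorts drawn from one architecture share loci; baselines default to
  Uniform(−2, 2), giving mean methylation levels spread over ~(0.12,
  0.88).
- Expression as intercept + eQTM effects of CpG beta values + eQTL
  dosage effects + covariate effects + noise; eQTM signs are explicit,
  with the demo architecture making two thirds negative, matching the
  predominance of inverse methylation-expression associations in blood.
- Pack-years from a never/former/current mixture (45/35/20%) with
  gamma-distributed exposure among ever-smokers; a binary outcome from a
  logistic model whose intercept is solved numerically to hit a target
  prevalence.
- Cohort-level GWAS-style summary statistics (vectorized OLS for
  quantitative traits, per-SNP logistic fits for binary ones;
  monomorphic SNPs flagged, not dropped), providing the two-sample MR
  and colocalization inputs.
- Replication cohorts: a second seed with an optional platform effect
  (per-transcript `exp(N(0, 0.2))` rescaling plus independent noise,
  sd 0.5) emulating a different expression array.

Magnitudes not fixed by the emulated study design are generator
parameters chosen once as field-realistic: mQTL effects 0.8
logit-units/allele and eQTL effects 0.6 expression-units/allele (strong
cis QTLs), eQTM effects 2-8 expression units per unit beta value,
smoking −0.02 logit-units per pack-year, disease effect 0.03 log-odds
per pack-year.

What it does **not** emulate — and hence what passing tests cannot show:
bimodal beta-value distributions and probe-chemistry artefacts of real
450K arrays, family relatedness, realistic recombination maps or
long-range LD, cell-type-specific effects, and array detection-level
missingness. Calibration and recovery results here validate the
estimators under the generative model, not the biology of any particular
cohort.

## Numerical choices and problem sizes

All closed-form estimators are checked against independent
normal-equations, enumeration or quadrature oracles at 1e−10 relative
tolerance. Stochastic guarantees use fixed seeds with Monte-Carlo bands
of three standard errors. The test and reproduction scripts use problem
sizes chosen to make those bands informative while keeping a full run on
one CPU in the low minutes: n = 500-2000 samples, 10,000 null pairs for
calibration, 60-100 replicates for colocalization scenario recovery,
150-200 replicates per causal-effect level (400-1000 at the null) for
MR coverage and type-I error, and 300-500 replicates for the
censored-meta bias comparison.

## Known limitations

- The censored-likelihood meta-analysis reduces, not eliminates, the
  selective-storage bias at small study counts (its absolute bias is
  verified to be below the complete-case bias, not zero).
- Colocalization assumes at most one causal variant per trait per
  region; multi-causal fine-mapping is out of scope.
- No MR sensitivity estimators (Egger, weighted median) are provided;
  the design mirrors a Wald/IVW-only analysis.
- The conditional analysis conditions within transcripts only; no
  cross-transcript or joint model selection is attempted.
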