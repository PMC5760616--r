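---
title: "Multivariate rare-variant region testing: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate rare-variant region testing: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murat)
```

## The problem

Bone mineral density (BMD) measured at the femoral neck (FN) and lumbar
spine (LS) are strongly correlated continuous traits (correlation around
0.68 after log transformation in large combined cohorts), and both are
partly driven by the same genes. Rare variants (MAF < 5%) are tested
region by region rather than one at a time because individually they carry
too little information. This package implements the two tests such a study
runs side by side:

* **SKAT**, the univariate variance-component score test of a set of
  variants against one trait; and
* **MURAT**, its multivariate extension, which tests all traits jointly
  while allowing each variant's effects on the different traits to be
  correlated (pleiotropy).

## The model

For subject $i$ with traits $Y_i \in \mathbb{R}^K$, covariates $X_i$, and
dosages $G_i \in [0,2]^v$ for the $v$ variants of a region, the stacked
mixed model is

$$Y_i = \alpha_0 + (1_K \otimes X_i^\top)\alpha + (1_K \otimes G_i^\top)\beta + \varepsilon_i,$$

with $\varepsilon_i \sim N(0, \Sigma)$ for an arbitrary positive-definite
$K \times K$ residual covariance, and random variant effects

$$\beta \sim N(0,\; \tau^2\, R_\rho \otimes W), \qquad
R_\rho = (1-\rho) I_K + \rho\, 1_K 1_K^\top .$$

$W = \mathrm{diag}(w_1,\dots,w_v)$ carries per-variant weights, and $\rho$
is a single correlation shared by every variant's effects across traits
("pleiotropy correlation"). The null hypothesis is $\tau^2 = 0$, i.e.
$\beta = 0$.

The score statistic at a fixed $\rho$ is a quadratic form in the stacked
null residuals. Writing $E$ for the $N \times K$ residual matrix of the
per-trait least-squares fits, $\hat\Sigma = E^\top E/(N - m - 1)$, and
$B = G W^{1/2}$, the $v \times K$ score matrix is
$S = B^\top E \hat\Sigma^{-1}$ and

$$Q(\rho) = \mathrm{vec}(S)^\top (R_\rho \otimes I_v)\, \mathrm{vec}(S)
          = (1-\rho)\,\mathrm{tr}(C) + \rho\, 1^\top C 1,
  \qquad C = S^\top S .$$

Under the null, $Q(\rho)$ is a weighted mixture of 1-df chi-squares whose
weights are the eigenvalues of
$(R_\rho^{1/2} \hat\Sigma^{-1} R_\rho^{1/2}) \otimes M$ with
$M = W^{1/2} G^\top P G W^{1/2}$ and $P$ the covariate projection — a
Kronecker product of a $K \times K$ and a $v \times v$ spectrum, which is
what makes the factorized implementation cheap. The package verifies this
factorization against a dense construction of the full $NK$-dimensional
stacked model in its test suite.

At $K = 1$ the statistic reduces exactly to SKAT (every $R_\rho$ is the
scalar 1), and at $\rho = 0$ it reduces to the independent-effects
multivariate test that models only the trait correlation, not effect
correlation. Both reductions are enforced to ten significant digits in the
tests.

## The omnibus over $\rho$

$\rho$ is unknown, so the test is run on a grid (default $0, 0.1, \dots,
1$) and the smallest p-value is taken, with a correction for that
minimization: the omnibus p-value is
$P\{\min_\rho p(Q(\rho)) \le p_{\min}\}$ under the joint null law. All
$Q(\rho)$ are quadratic forms in the *same* Gaussian score vector, so the
joint law is known exactly and is evaluated by Monte Carlo over that
shared vector (default $10^4$ draws, seedable); per draw, every $Q(\rho)$
is closed-form because $Q$ is linear in $\rho$ given $C$. The estimate is
clipped to the envelope $[p_{\min},\, n_{\mathrm{grid}} \cdot p_{\min}]$,
which the true quantity must satisfy (selection only increases the
p-value; Bonferroni bounds it above). An analytic one-dimensional
integration is a known alternative for this correction; the Monte-Carlo
evaluation of the exact joint law was chosen because it is transparent,
testable, and exact up to a quantifiable Monte-Carlo error, and the
`method` slot leaves room for an analytic routine. Ties in the minimizing
$\rho$ resolve to the smallest $\rho$, for determinism.

The reported `optimal_rho` is the grid minimizer of the per-$\rho$
p-value. With a single-point grid, or $K = 1$, there is no selection and
the omnibus p equals the per-point p exactly. When $p_{\min}$ falls far
below the Monte-Carlo resolution ($p_{\min} < 1/(20\, n_{\mathrm{grid}}\,
n_{\mathrm{draws}})$), the exceedance count is zero with overwhelming
probability and the clipped estimate is the Bonferroni envelope
deterministically, so the envelope is returned directly — the same number,
without the per-$\rho$ quantile inversions.

## Mixture-of-chi-squares tails

P-values of all these statistics are tails of $\sum_l \lambda_l \chi^2_1$.
The package computes them by Imhof/Gil–Pelaez characteristic-function
inversion evaluated with an equal-step midpoint rule: the step is set so
the rule's periodization error is a tail probability beyond a Chernoff
point below the accuracy target, and the integral is truncated where an
oscillation-aware envelope bound falls below the same target (default
$10^{-9}$, in absolute terms). The computation is normalized by the
leading eigenvalue, so exactly proportional inputs give bit-identical
p-values — that is what makes the $K=1$ and $\rho=0$ reductions exact in
practice. If the inversion fails or leaves $(0,1]$, the moment-matched
noncentral chi-square approximation of Liu, Tang and Zhang is used and the
result is labelled `liu` in its `method` attribute. Eigenvalues below
$10^{-10}$ of the largest are treated as numerical zeros. Inside the
omnibus, per-$\rho$ quantile inversions use a $10^{-7}$ target — far below
the $10^4$-draw Monte-Carlo resolution they feed.

## Variant weights

Three schemes, selected per scan: `identical` ($w_j = 1$),
`beta:1,25` ($\sqrt{w_j}$ the Beta(1,25) density at MAF$_j$, the usual
rare-variant up-weighting), and `beta:0.5,0.5`, implemented through its
unnormalized equivalent $\sqrt{w_j} = 1/\sqrt{\mathrm{MAF}_j
(1-\mathrm{MAF}_j)}$ — dropping the $1/\pi$ density constant rescales $W$
by a constant, and score-test p-values are invariant to positive rescaling
of $W$ (a property the tests assert). Weights use the sample MAF unless an
external per-variant MAF is supplied; monomorphic variants must be dropped
before applying a scheme that diverges at MAF 0.

## Regions

Three granularities, as a genome scan uses them:

* **Gene pieces** — each gene interval is flanked by 5 kb on both ends;
  flanked intervals over 150 kb are partitioned into
  $\lceil L/100\,\mathrm{kb} \rceil$ contiguous pieces of near-equal
  length, which lands every piece in [50 kb, 100 kb]. Equal splitting is
  one admissible reading of the stated constraints (a greedy 100-kb cut
  also satisfies them); it was chosen because it is deterministic and
  leaves no short orphan piece. Flanks are applied before the 150-kb size
  check.
* **Windows** — a region's ordered variants are chunked into
  $\lceil v/30 \rceil$ windows whose sizes differ by at most one,
  avoiding a trailing near-empty window while respecting the at-most-30
  constraint.
* **Single variants** — one region per variant carried by at least 4
  individuals (dosage > 0.5 counts as carrying, consistent with best-guess
  genotypes).

The rare-variant filter (`filter_rare`, MAF strictly below 0.05) accepts
an external MAF source because reference-panel frequencies are often more
stable than sample frequencies for rare alleles.

## Significance thresholds

`bonferroni_threshold(0.05, 3, 2, 24333)` reproduces the genome-scan
arithmetic $3.42\times10^{-7}$ for 3 weights × 2 separately tested traits
× 24,333 regions. The permutation route shuffles the genotype rows —
not the phenotypes — so phenotype-derived and genotype-derived covariates
each stay internally consistent; either shuffle breaks the
genotype-phenotype link, but this one preserves the phenotype-covariate
model, and the null regression is fitted once and reused. The minimum p
per permutation is modelled as Beta$(1, M_{\mathrm{eff}})$ with
$M_{\mathrm{eff}}$ estimated by maximum likelihood
($\hat M = -n / \sum \log(1-p_{\min})$), and the genome-wide threshold is
$1-(1-\alpha)^{1/\hat M}$. This Beta model is exact for independent
uniform tests and is used here as a documented surrogate for more
elaborate extrapolation schemes; the estimator is a pluggable slot. When
the extrapolated threshold comes out *below* the Bonferroni threshold for
the same scope — impossible for a correct effective-count argument, since
correlation can only reduce the effective number of tests — the function
warns and reports the Bonferroni value alongside so callers can prefer it.

## The simulator

`sim_config()` / `simulate_dataset()` generate the study conditions the
tests are run under: haplotypes from a first-order Markov chain with a
chosen MAF spectrum (default uniform on 0.005–0.05, a rare-variant
spectrum) and adjacent-site correlation `ld`; genotypes as haplotype sums;
covariate analogs (age centered near 72 ± 5, its square, sex, weight) with
fixed coefficients, matching an elderly osteoporosis-cohort profile; and
traits from the mixed model above with residual correlation 0.68 — the
value observed for log-FN/log-LS in combined cohort data. Effects $\beta$
are redrawn per replicate from $N(0, \tau^2 R_{\rho_{\mathrm{sim}}}
\otimes W_{\mathrm{sim}})$ (the model's own random-effects view, which
makes power well defined); $W_{\mathrm{sim}}$ defaults to identity and is
deliberately decoupled from the analysis weights so weight
misspecification can be studied.

What the simulator does *not* emulate: linkage structure beyond
first-order (no recombination hotspots or haplotype blocks), population
stratification and cohort heterogeneity, genotype imputation error, and
non-Gaussian trait tails. Calibration and power results on these synthetic
data therefore demonstrate correctness of the statistics under their own
model, not robustness to those real-data features.

## Study sizes used in the checks

The packaged checks run at sizes chosen to estimate each quantity with
useful precision: calibration uses N = 500, v = 20, K = 2 and 2,000 null
replicates (the binomial 99% band at $\alpha = 0.05$ is then
[0.037, 0.063]); the power comparison uses 200 replicates with five causal
variants shared between traits, $\rho_{\mathrm{sim}} = 0.7$ and
$\tau = 0.3$ — about 2–3% of trait variance explained by the region, a
strong-locus regime picked so power sits away from both 0 and 1;
threshold extrapolation uses 500 permutations over 40 single-variant
regions. The inversion oracle is checked against $10^6$-draw Monte-Carlo
tails.

## When does the joint test actually win?

A point worth understanding before interpreting power comparisons against
the adjusted (minimum) univariate p-value. For effects shared across
traits, the multivariate score concentrates along the sum direction, whose
noncentrality gain over a single-trait test is $2/(1+r)$ for residual
correlation $r$ — about 19% at $r = 0.68$. The gain is therefore
*largest when the effect correlation differs from the residual
correlation* (most dramatically for opposite-sign effects on positively
correlated traits, where the contrast direction has variance $1-r$), and
smallest when the two nearly coincide. Meanwhile the comparator
$\min(p_{FN}, p_{LS})$ carries no multiplicity correction, so at a nominal
$\alpha$ its effective size is up to $2\alpha$ (about $1.6\alpha$ at
$r = 0.68$). In the package's own simulations with effect correlation 0.7
against residual correlation 0.68 — a nearly matched pair — these two
forces offset and the empirical powers of the omnibus and the adjusted
univariate test are within a few percentage points of each other across a
range of effect sizes and causal densities; certifying the ordering at
that configuration would need thousands of replicates, not hundreds. With
genuinely identical shared effects ($\rho = 1$ in the generator) the
per-$\rho$ statistic at $\rho = 1$ shows the full theoretical gain
(median p about half the single-trait SKAT median in the packaged
experiments). Scans of real data can show larger multivariate gains than
the matched-correlation simulation suggests precisely because real
effect patterns need not align with the residual correlation.

## Degenerate inputs and numerical conventions

All-zero genotype columns are dropped with a warning; a region left with
no polymorphic variants reports p = 1 and a reason rather than an error,
so scans keep their region × weight row count. A null fit with
(numerically) zero residual variance is refused. Coordinates are 1-based
inclusive everywhere; BED input is converted at the boundary. Missing
dosages are mean-imputed to 2·MAF (keeping N constant, as score tests
usually do — how the motivating study handled missing dosages is not
stated, so this is this package's choice); missing phenotype/covariate
rows are dropped complete-case. Dosages are folded so MAF ≤ 0.5, with
re-orientations recorded. `Sigma_hat` is plugged in as known when forming
the null law, the standard practice for $N \gg K$; no small-sample moment
correction is applied.

## Known limitations

Binary traits, kinship/relatedness adjustment, and effect-correlation
structures richer than exchangeable are out of scope. The analytic
integration variant of the omnibus is not implemented (the Monte-Carlo
joint law is the default and only method). Genome-scale extrapolation
from a chromosome-restricted permutation scope is left to the caller: the
permutation machinery exposes its scope, and the extrapolation applies to
whatever scope was scanned.
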