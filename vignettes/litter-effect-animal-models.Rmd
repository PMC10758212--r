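---
title: "Pedigree BLUP and REML with common-litter effects: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree BLUP and REML with common-litter effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedblup)
```

## The problem

Pig breeding programs evaluate candidates with pedigree-based linear mixed
models ("animal models"). For traits recorded early in life — birth weight,
days to 115 kg, feed conversion, body measurements — piglets reared in the
same litter share a non-genetic environment (the dam's uterine and nursing
environment, the pen). If that shared environment is ignored, its
covariance is absorbed by the additive-genetic term, because full sibs are
also the most genetically similar animals in the data: heritability is then
overestimated and breeding values are distorted.

`pedblup` implements the two competing models,

* **model 1** (plain animal model): `y = Xb + Z_a a + e`,
* **model 2** (common-environment model): `y = Xb + Z_a a + Z_c c + e`,

with `a ~ N(0, A sigma_a2)`, `c ~ N(0, I sigma_c2)`, `e ~ N(0, I sigma_e2)`,
where `A` is the numerator relationship matrix over the full pedigree and
`c` holds one effect per litter (a litter code = dam id + birth period).
Derived parameters follow the standard definitions: phenotypic variance
`sigma_p2` is the sum of the model's components; heritability
`h2 = sigma_a2 / sigma_p2`; the litter-effect ratio
`c2 = sigma_c2 / sigma_p2`; for two traits the genetic correlation is
`r_g = sigma_a12 / sqrt(sigma_a1^2 sigma_a2^2)` and the phenotypic
correlation divides the summed component covariances by the phenotypic
SDs. Models are compared on the same records by `AIC = 2k - 2 logL`.

One published convention deserves a note: the litter ratio is sometimes
displayed with the litter variance left out of its own denominator
(`sigma_c2 / (sigma_a2 + sigma_e2)`). Every published litter-ratio value we
reproduce is consistent with the *total-variance* denominator, so
`litter_ratio()` reports that as `c2` and the variant as `c2_alt`.

## Pedigree machinery

* Pedigrees are validated (unique ids, no self-parents, no cycles) and
  topologically sorted with a stable Kahn pass; undeclared parents are
  auto-registered as founders with a warning, since real pedigree extracts
  routinely truncate ancestors.
* Inbreeding coefficients use the Meuwissen–Luo recursive algorithm
  (compiled; exact, `O(n * ancestors)`), so `diag(A) = 1 + F` holds by
  construction and is tested against the tabular `A` on random pedigrees.
* `A` itself is only materialized densely for small oracles. Model fitting
  uses the sparse `A^-1` assembled directly by Henderson's rules with the
  inbreeding-corrected Mendelian-sampling ratios `d_i`; the same pass
  yields `log|A| = sum(log d_i)`, needed by the likelihood at no extra
  cost. Unknown parents are treated as unrelated, non-inbred base animals
  (no genetic groups — none are identifiable from a single-herd pedigree).

## REML through the sparse mixed-model equations

The restricted log-likelihood is evaluated exactly through Henderson's
mixed-model equations in variance-ratio form: one sparse Cholesky
factorization per evaluation gives `log|C|`, the solutions, and `y'Py`;
`log|A|` comes from the pedigree pass above. The reported value includes
the `-(n-p)/2 log(2*pi)` constant, so single-trait and bivariate fits are
on the same scale (the constant cancels in every AIC comparison).

For single-trait models the residual variance is profiled out analytically
and the likelihood is maximized over the log variance ratios
(`log(sigma_a2/sigma_e2)`, `log(sigma_c2/sigma_e2)`) with a quasi-Newton
optimizer (`nlminb`, relative tolerance `1e-10`, cap 200 iterations). The
log parameterization keeps variances positive, with an effective floor of
`1e-8` on each ratio; boundary fits (`sigma_a2` at the floor) are returned
as such, never masked. We chose direct likelihood maximization over
classical AI-REML/EM iteration because exact EM updates and AI score
vectors require traces of selected blocks of the inverse coefficient
matrix — a selected sparse inversion that would have to be hand-built —
while the profiled likelihood needs only the factorization itself and is
deterministic given the data. The **average-information matrix is still
computed at convergence** (each AI entry needs only MME solves against the
converged factorization), and standard errors of variance components are
taken from its inverse; SEs of `h2`, `c2` and `r_g` follow by the delta
method with analytic gradients.

Bivariate fits estimate full 2x2 genetic, litter and residual covariance
matrices (9 parameters; 6 without litters). Each matrix is parameterized
by its log-Cholesky factor, which keeps every iterate positive definite —
the "project back to the PSD cone" fallback can never trigger, though the
correlation accessors still clamp to [-1, 1] with a warning if a boundary
fit lands marginally outside. Records missing one trait contribute only
their measured trait; the residual covariance enters only for animals
measured on both (per-record 2x2 residual blocks). Starting values come
from the two single-trait fits plus the OLS-residual correlation of
doubly-measured records applied to all three matrices. Because the
coefficient matrix's sparsity pattern is constant across iterations, the
assembly is precomputed as a linear combination of fixed sparse templates
and the symbolic Cholesky analysis is reused; a likelihood evaluation is
then a numeric refactorization only. `nlminb`'s PORT code occasionally
reports "false convergence" when the warm start is already at the optimum;
the fitter restarts once and otherwise accepts the point only if a
coordinate-wise probe finds no improvement beyond round-off.

Model comparison refuses to compare fits whose data fingerprints (trait,
record count, response checksum, id hash) differ, since AIC across
different data is meaningless. `k` counts variance parameters only (2/3
single-trait, 6/9 bivariate): the fixed effects are identical between the
models being compared, so they cancel in AIC differences.

## Phenotype screening

The outlier rule removes values more than 3 sample SDs from the trait mean
in a **single pass** per trait (mean and SD computed once, not iterated),
blanking only the offending trait value — the record stays available for
its other traits, which have different record counts anyway. Fixed effects
(farm, year-season, sex, parity) are screened per trait by Type-II F tests
from a joint OLS fit; Type II is invariant to factor order for
main-effects models, which is what the screen fits. The screen is
advisory: all factors are kept unless the caller opts in to dropping
non-significant ones. Aliased factors are reported untestable rather than
silently dropped. Reference levels are the lexicographically first level
of each factor, which makes reports deterministic across runs.

## The herd simulator

`simulate_herd()` generates data under exactly the model the fitter
assumes, so parameter-recovery tests are well-posed. Discrete,
non-overlapping generations: each mated dam receives a random sire and a
Poisson-sized litter (mean 10, the pen size of the emulated herd; minimum
1). Founder breeding values are drawn at `sigma_a2` (correlated across
traits through the genetic correlation matrix); descendants get the parent
average plus a Mendelian deviate with variance
`sigma_a2 (1 - (F_s + F_d)/2)/2`, keeping simulated covariances exactly
consistent with `A`, which the oracle tests require. One litter effect per
litter; founders count as singleton litters. Fixed effects mirror a real
herd's confounding structure without modeling it: farms assigned per
litter (6 levels), year-season per litter within generation (4 seasons per
generation-year), sex Bernoulli(1/2), parity cycling over 1..11 per dam.
Level effects are drawn once per herd with SDs of 0.2-0.3 phenotypic SDs.
Trait architectures default to the published litter-model components of
the six Duroc traits; the published FCR litter variance (0.079) is
inconsistent with its own published total (0.0429) and is reconciled to
0.0079. Truncation selection, when enabled, retains the top/bottom
fraction of each cohort (by phenotype or true breeding value) as the
parent pool of the next generation.

What the simulator does **not** emulate: overlapping generations and
culling policies, cross-fostering (litter codes are taken at face value,
as the fitted model also assumes), maternal genetic effects,
genotype-by-environment interaction, and non-random mate allocation.
Passing recovery tests therefore show the estimator is correct *under the
model's own assumptions*, not that the model is adequate for any real
herd.

## Study sizes and numerical choices

The replicated studies run at sizes chosen to keep the full suite fast
while leaving Monte-Carlo error well inside the tolerances being asserted
(binding Monte-Carlo SEs are quoted with each study):

* single-trait recovery and AIC selection: 20 replicate herds of ~5,000
  animals in ~500 litters (4 generations x 125 dams x Poisson-10 litters),
  AGE architecture (true h2 0.298, c2 0.196); per-replicate SD of `h2` is
  about 0.04, so the mean over 20 replicates carries an SE near 0.01
  against a 0.03 tolerance;
* the no-litter-variance scenario for AIC penalty behavior uses 3
  generations x 80 dams (~2,500 animals): boundary behavior does not
  depend on herd size;
* bivariate recovery: 20 replicates per scenario of ~3,000 animals, both
  traits with the AGE architecture so `r_g` is estimated with useful
  precision; the per-replicate SD of `r_g` measured in calibration runs is
  about 0.11-0.13, so 20 replicates put the SE of the mean near 0.03
  against a 0.07 tolerance;
* selection trends: 6 generations of 20 dams with litter size 10, i.e. a
  demographically stable herd under 20% truncation (each generation
  regenerates its parent pool), 10 replicates plus a no-selection control;
  the control's flatness is judged against its own Monte-Carlo SE.

Convergence is declared at a relative likelihood change below `1e-10`;
variance floors sit at `1e-8` of the residual variance; correlations are
clamped to [-1, 1] only with a warning. Degenerate inputs fail loudly:
zero variances in the MME, litter models with fewer than two litters,
bivariate fits with no doubly-measured animal, non-PSD correlation inputs
to the simulator (no silent repair).

## Limitations

Estimates at variance boundaries have asymmetric sampling distributions
the AI-based SEs do not capture; the bivariate fitter handles two traits
only (the published evaluation is pairwise too); litter ratios from herds
with pervasive cross-fostering will mix maternal and pen effects in ways
neither model 2 nor the simulator represents; and AIC comparisons are only
ever made within identical record sets — the package refuses otherwise.
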