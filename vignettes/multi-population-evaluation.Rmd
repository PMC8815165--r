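---
title: "Exact solving strategies for multi-population genomic evaluation"
author: "mpblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact solving strategies for multi-population genomic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpblup)
```

## The model

Genomic prediction across several populations (purebred lines and their
crosses, or the same breed in different environments) is naturally a
multiple-trait problem: the effect of a SNP is allowed to differ between
populations, but the effects are correlated. `mpblup` implements the
linear mixed model, for population $i \in \{1, \dots, P\}$,

$$
\mathbf{y}_i = \mathbf{X}_i \boldsymbol\beta_i + \mathbf{Z}_i \mathbf{a}_i
  + \mathbf{W}_i \mathbf{d}_i + \mathbf{e}_i,
$$

where $\mathbf{y}_i$ are the $n_i$ phenotypes, $\boldsymbol\beta_i$ the
population-specific fixed effects (a mean and a genomic-inbreeding
covariate by default), $\mathbf{a}_i$ and $\mathbf{d}_i$ the additive and
dominance effects of the $m$ shared SNPs, and
$\mathbf{e}_i \sim N(0, \sigma^2_{e_i}\mathbf{I})$. The codings are
$\mathbf{Z}_i = \text{dosage} - 1 \in \{-1, 0, 1\}$ and
$\mathbf{W}_i = \mathbf{1}[\text{dosage} = 1]$, the heterozygote
indicator. Dominance effects have zero prior mean because inbreeding
depression is absorbed by the inbreeding covariate.

Across populations the effects of one SNP are correlated:
$\mathrm{Var}(\mathbf{a}_1', \dots, \mathbf{a}_P')' =
\mathbf{G}_{0a} \otimes \mathbf{I}_m$ and analogously
$\mathbf{G}_{0d} \otimes \mathbf{I}_m$, where $\mathbf{G}_{0a}$ and
$\mathbf{G}_{0d}$ are $P \times P$ covariance matrices of per-SNP
effects. The phenotypic covariance is then

$$
\mathbf{V} = \mathbf{G}_A + \mathbf{G}_D + \mathbf{R}, \qquad
\mathbf{G}_A^{(ij)} = \mathbf{Z}_i \sigma_{a_{ij}} \mathbf{Z}_j', \quad
\mathbf{G}_D^{(ij)} = \mathbf{W}_i \sigma_{d_{ij}} \mathbf{W}_j',
$$

with $\mathbf{R}$ the diagonal of residual variances. Variance components
are treated as known throughout (their estimation, e.g. by REML, is out
of scope).

## The four strategies and why they are equivalent

All four are *exact* (inversion-based) solvers of the same model, so they
must agree to numerical precision; the package tests and the acceptance
script verify this agreement to a relative $10^{-6}$ (observed
discrepancies are around $10^{-11}$). They differ only in which matrix is
assembled and factorized:

| strategy | unknowns factorized | random equations | marker effects |
|---|---|---|---|
| SNP-BLUP (`solveSnpBlup`) | marker effects | $2Pm$ | direct |
| standard MT-GBLUP (`solveGblupStandard`) | $P$ trait copies per individual | $2Pn$ | not produced |
| compact GBLUP (`solveGblupCompact`) | own-population genetic values | $2n$ | by backsolving |
| GLS + SI (`solveGlsSi`) | the $n \times n$ matrix $\mathbf{V}$ | $n$ | by backsolving |

**SNP-BLUP** assembles Henderson's mixed-model equations in the marker
effects. The left-hand side mixes dense blocks
($\mathbf{Z}_i'\mathbf{Z}_i \sigma_{e_i}^{-2} + \mathbf{I} g^{ii}_{0a}$),
sparse blocks ($\mathbf{I} g^{ij}_{0a}$), and zero blocks — a structure
that defeats general sparse solvers, so the system is stored dense. The
equation count $2Pm$ is independent of $n$: three populations at a 50K
panel already give 300{,}000 random equations.

**Standard multiple-trait GBLUP** treats each population as a trait with
missing records and carries $P$ additive and $P$ dominance values for
*every* individual. A single arbitrarily scaled cross-product matrix
$\mathbf{G}^*_A = \{\mathbf{Z}_i\mathbf{Z}_j'\}$ per effect is inverted
and combined with $\mathbf{G}_{0a}^{-1}$ through a Kronecker product.
Most of the $2Pn$ unknowns are never used (each individual has one record
in one population), which is exactly the redundancy the other two
individual-level strategies remove. $\mathbf{G}^*$ is deliberately left
unscaled — covariances between individuals arise only after
multiplication by the SNP-effect variances, so its entries are not
"relationships".

**Compact GBLUP** keeps only each individual's own-population additive
and dominance genetic values ($2n$ unknowns) and uses
$\mathbf{G}_A^{-1}$, $\mathbf{G}_D^{-1}$ directly. Marker effects are
recovered afterwards by the selection-index identity
$\hat{\mathbf{a}} = \mathbf{C}_{au} \mathbf{G}_A^{-1}\hat{\mathbf{u}}_a$
(`backsolveMarkers`), which is exact only when the prior actually used in
the equations is the true covariance, i.e. unblended — a blended
backsolve is refused rather than silently approximated.

**GLS + selection index** is the most compact path: build $\mathbf{V}$
once (a plain sum of matrices), factorize it once, estimate
$\hat{\boldsymbol\beta} = (\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})^{-1}
\mathbf{X}'\mathbf{V}^{-1}\mathbf{y}$, and backsolve every marker effect
from the shared adjusted data
$\mathbf{y}^c = \mathbf{V}^{-1}(\mathbf{y} - \mathbf{X}\hat{\boldsymbol\beta})$:
per population $\mathbf{v}_i = \mathbf{Z}_i'\mathbf{y}^c_i$, then
$\hat{\mathbf{a}}_k = \sum_j \sigma_{a_{kj}} \mathbf{v}_j$ — the
covariance matrix $\mathbf{C}_a$ is never materialized. Because every
residual variance is positive, $\mathbf{V}$ is invertible by
construction; this is the robustness advantage the `singular-clones`
fixture demonstrates (clones make $\mathbf{G}_A$ exactly singular, so
compact GBLUP needs blending while GLS + SI does not).

A matrix-free variant (`solveMatrixFree`) replaces the factorization of
$\mathbf{V}$ with conjugate-gradient solves of
$\mathbf{V}\boldsymbol\Theta = \mathbf{y}$ and
$\mathbf{V}\mathbf{M} = \mathbf{X}$, applying $\mathbf{V}$ as an operator
(three products per population block); then
$(\mathbf{X}'\mathbf{M})\hat{\boldsymbol\beta} = \mathbf{X}'\boldsymbol\Theta$
and $\mathbf{y}^c = \boldsymbol\Theta - \mathbf{M}\hat{\boldsymbol\beta}$.

## Prediction-error variances and reliabilities

From SNP-BLUP, the PEV of each marker-effect estimate is the
corresponding diagonal of the inverse left-hand side. From GLS + SI the
same quantities come from the projection

$$
\mathrm{PEV}(t) = \mathrm{Var}(t) - \mathbf{C}_t' \mathbf{P} \mathbf{C}_t,
\qquad
\mathbf{P} = \mathbf{V}^{-1} - \mathbf{V}^{-1}\mathbf{X}
 (\mathbf{X}'\mathbf{V}^{-1}\mathbf{X})^{-1}\mathbf{X}'\mathbf{V}^{-1},
$$

which accounts for fixed-effect estimation. The projection form is not
written out in the classical selection-index references, so the package
pins it by a cross-method contract: on the `tiny-2pop` fixture the two
routes agree to $10^{-6}$ relative (observed: $10^{-15}$). Reliability is
$1 - \mathrm{PEV}/\mathrm{priorVar}$, clipped to $[0, 1]$; an
uninformative SNP (zero additive coding everywhere, under a diagonal
$\mathbf{G}_{0a}$) keeps its prior variance and has reliability 0.

## The simulator

`simConfig()` + `simulateDataset()` generate data with exactly the
covariance structure the solvers assume — no more, no less:

* **Allele frequencies.** A base frequency per SNP from Beta(2, 2);
  population frequencies follow the Balding–Nichols model
  Beta$(p(1-F_{st})/F_{st},\ (1-p)(1-F_{st})/F_{st})$, making $F_{st}$ a
  single interpretable divergence knob. Default $F_{st} = 0.15$, a
  moderate between-breed divergence. SNPs monomorphic in every
  population are redrawn (bounded retries) so all $m$ SNPs carry signal
  somewhere.
* **Genotypes.** Binomial(2, $p_{\text{pop}}$) dosages; a crossbred
  population instead draws one Bernoulli gamete at each parental
  population's frequency — enough to exercise the cross-population
  covariance machinery without a mating/pedigree module.
* **Effects.** Per SNP, $P$-vectors drawn from MVN(0, $\mathbf{G}_{0a}$)
  and MVN(0, $\mathbf{G}_{0d}$). Defaults: additive per-SNP variance
  $2/m$ with cross-population correlation 0.8 (strongly but not
  perfectly correlated effects), dominance variance $0.8/m$ with
  correlation 0.5, residual variance 1. At the default $m$ this yields a
  realized additive variance near 0.8 and broad-sense heritability
  around 0.5 — an ordinary polygenic trait.
* **Fixed effects.** Mean 10, inbreeding-depression slope $-2$ trait
  units per unit homozygosity. The inbreeding covariate is observed
  homozygosity $F_q = 1 - \text{het}_q/m$: simple, bounded in $[0, 1]$,
  and sufficient to absorb directional dominance.
* **Reproducibility.** One master seed spawns fixed per-stage streams
  (frequencies, genotypes, additive effects, dominance effects, noise),
  so enlarging $m$ does not reshuffle the phenotype noise.

What the simulator does *not* emulate: linkage disequilibrium, explicit
pedigrees, selection, non-normal effect distributions, or
genotype-by-environment structure beyond the population index. Passing
tests therefore demonstrate algebraic and statistical correctness of the
solvers under the model's own assumptions, not robustness to model
violations in real data.

### Fixtures and problem sizes

The test fixtures are chosen to be the smallest instances that exhibit
each regime: `tiny-2pop` ($P=2$, $n = 16$, $m = 12$) for brute-force
oracle comparisons; `equiv-3pop` ($P=3$, $n = 180$, $m = 400$, so
$m > n$ and all individual-level covariances are full rank) for the
four-way equivalence; `crossbred-3pop` for the crossbred path; and
`singular-clones` (a duplicated genotype row) for the rank-deficiency
contrast. The calibration experiment uses 20 replicates of $P=3$,
$n = 900$, $m = 300$, large enough that the regression of true on
estimated genetic value concentrates near 1 while each replicate solves
in well under a second.

## Numerical choices

* **Dense Cholesky everywhere.** All systems are positive definite when
  the priors are and $\mathbf{X}$ has full rank; the mixed
  dense/sparse/zero block structure makes sparse solvers unattractive.
* **Rank checks.** Cholesky success alone is an unreliable singularity
  test — an exactly singular matrix can pass by rounding. Covariance
  matrices destined for inversion are therefore also screened by their
  smallest eigenvalue against $10^{-10} \times$ mean diagonal, and the
  error says which matrix failed and suggests blending.
* **Blending** adds $\varepsilon \cdot \bar{s} \cdot \mathbf{I}$ with
  $\bar{s}$ the mean diagonal, so $\varepsilon$ is dimensionless across
  problems; the smallest eigenvalue of the result is at least
  $\varepsilon \bar{s}$ for PSD input.
* **Equivalence tolerance** is relative $10^{-6}$ on the scale
  $\max(|x|, 1)$, accommodating conditioning differences between
  formulations whose systems differ in size by factors of $Pm/n$.
* **Conjugate gradients** use a relative-residual tolerance (default
  $10^{-10}$) and an iteration cap of $10n$, failing loudly with the
  achieved residual rather than returning an unconverged answer.
* **Centering** of $\mathbf{Z}$/$\mathbf{W}$ is available but off by
  default: it is a per-population column shift, which the solutions are
  provably invariant to when per-population intercepts are fitted (a
  tested property), but it makes the $n \times n$ covariance matrices
  rank deficient whenever $n \ge m$. Missing genotypes are rejected, not
  imputed: the exact integer codings are load-bearing for the MME
  structure.
* **Equation ordering** is fixed and documented
  ($[\boldsymbol\beta; \mathbf{a}_1..\mathbf{a}_P;
  \mathbf{d}_1..\mathbf{d}_P]$ for SNP-BLUP; trait-major for standard
  GBLUP) so that inverse diagonals map to effects unambiguously and the
  displayed block patterns can be tested element by element.

## Design choices that were genuinely open

* The standard-GBLUP display pattern is extended to the dominance and
  additive-by-dominance blocks by symmetry; the cross blocks are
  $\mathbf{I}\sigma_{e_i}^{-2}$ on matched records.
* Fixed-effect rows of the SNP-BLUP system use the standard Henderson
  couplings, block-diagonal across populations; all fixed effects are
  population-specific.
* Marker backsolving is offered from the compact formulation only; from
  the standard formulation it is unsupported (the compact route is
  exact and cheaper), and from blended systems it is refused.
* The equivalence checker compares in solution space
  ($\hat{\boldsymbol\beta}$, $\hat{\mathbf{a}}$, $\hat{\mathbf{d}}$,
  $\hat{\mathbf{u}}$), not matrix space, because the formulations differ
  in layout by design; it refuses to compare solutions whose dataset
  fingerprints differ.

## Limitations

Variance components are inputs, never estimated. No pedigree or
single-step extensions, no epistasis, no iteration-on-data solvers for
very large $n$ beyond the matrix-free GLS variant, no
allele-frequency-based scaling of the cross-product matrices. Indirect
prediction of new genotypes (`indirectPredict`) weights gene content by
a *single* population's marker-effect estimates; combining populations is
left to the user.
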