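---
title: "Single-step genomic evaluation of carcass traits: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation of carcass traits: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stepblup` implements a multi-trait single-step genomic evaluation for beef
carcass traits — carcass weight (CW, kg), eye muscle area (EMA, cm²),
backfat thickness (BF, mm) and marbling score (MS, score units) — together
with the machinery needed to validate such an evaluation end to end:
pedigree relationship algebra with inbreeding and unknown-parent (phantom)
groups, the marker-effect (ssSNPBLUP) and breeding-value (ssGBLUP)
parameterizations of the single-step model, conventional pedigree BLUP,
forward validation by the linear-regression (LR) method, standardized
SNP-effect scans, genetic trends, and a gene-dropping simulator of a
selected breeding population. This vignette explains the models, the
choices that were genuinely open, and what the simulation-based tests do
and do not establish.

## The observation model

Carcass traits are measured once, at slaughter, on cows and steers; the four
traits are recorded together (all-or-none). For an animal with a record the
multi-trait model is

$$
\mathbf{y} = \mathbf{X}_f\,\mathbf{f} + \mathbf{X}_b\,\mathbf{b} +
\mathbf{u} + \mathbf{e},
$$

with classification fixed effects of herd-year and year-season of slaughter
and sex (cow vs. steer), a linear regression on age at slaughter, additive
genetic values $\mathbf{u}$, and residuals $\mathbf{e}$ with a 4×4
covariance `R0`. Breeding values carry the prior
$\mathbf{u} \sim N(0, \mathbf{A} \otimes \mathbf{G_0})$ with `A` the
pedigree numerator relationship matrix and `G0` the 4×4 additive genetic
covariance. Variance components are inputs, not estimated here.

Two identifiability conventions matter and are deliberate:

* the first classification effect (herd-year) keeps all its levels and
  thereby carries the intercept; later class effects drop their first
  level. Because herd-year and year-season jointly span the slaughter-year
  means, the remaining aliased columns are detected by pivoted QR and
  constrained to zero (logged). Estimable functions — in particular every
  contrast of breeding values — are unaffected.
* the age covariate is centered on its mean, with one slope per trait.

## The single-step models

If an animal is genotyped, its breeding value decomposes as
$\mathbf{u}_g = \mathbf{Z}\mathbf{g} + \mathbf{a}$: a sum of SNP marker
effects (through the centered genotype matrix `Z`) and a residual polygenic
(RPG) effect capturing the fraction $k$ of additive variance the markers do
not track. Per trait,

$$
\sigma^2_{SNP} = (1 - k)\,\sigma^2_u \Big/ \sum_{j=1}^m 2p_j(1 - p_j),
$$

with $p_j$ the allele frequency of marker $j$; the default $k = 0.2$
assigns 80% of the genetic variance to the markers. Allele frequencies are
the observed frequencies among genotyped animals (clamped away from 0 and 1
by half an allele count), missing calls are mean-imputed as $2p_j$ — a
deliberately simple stand-in for haplotype imputation, adequate for the
estimation machinery though not for marker-level genotype accuracy.

Two algebraically equivalent parameterizations are implemented.

**Marker-effect form (ssSNPBLUP).** Unknowns are fixed effects, breeding
values of all animals, and the marker effects. The prior precision adds, on
the genotyped block, $(1/k - 1)\,\mathbf{A}_{22}^{-1}$ to the pedigree
precision, couples breeding values and markers through
$-\mathbf{A}_{22}^{-1}\mathbf{Z}/k$, and gives markers
$\mathbf{Z}'\mathbf{A}_{22}^{-1}\mathbf{Z}/k$ plus the
$\sigma^2_{SNP}$ identity. At $k = 1$ the markers carry nothing and the
system collapses to conventional BLUP exactly; $k = 0$ leaves the RPG
precision undefined and is rejected.

**Breeding-value form (ssGBLUP).** The same model expressed through
$\mathbf{H}^{-1} = \mathbf{A}^{-1} + \begin{bmatrix} 0 & 0 \\ 0 &
\mathbf{G}_w^{-1} - \mathbf{A}_{22}^{-1}\end{bmatrix}$ with
$\mathbf{G} = \mathbf{Z}\mathbf{Z}'/D$, $D = \sum_j 2p_j(1-p_j)$ and the
polygenic blend $\mathbf{G}_w = (1-k)\mathbf{G} + k\mathbf{A}_{22}$.
Marker effects are recovered exactly by the linear backsolve
$\hat{\mathbf{g}} = \frac{1-k}{D}\,\mathbf{Z}'\mathbf{G}_w^{-1}
\hat{\mathbf{u}}_g$ (per trait); this is an identity between equivalent
models, not an approximation, and the test suite verifies agreement of the
two forms to solver precision (GEBV correlation > 0.9999, differences
< 1e-6 genetic SD). At this package's scale the breeding-value form is much
cheaper (its dense block is genotyped × genotyped rather than
markers × markers), so the study driver uses it by default and the
marker-effect system is available as `model_kind = "ssnpblup"`.

## Pedigree algebra

`ped_a_inverse()` builds the sparse inverse of `A` directly from
Henderson's rules with inbreeding: each animal contributes
$b_i = 1/(0.5 - 0.25(F_s + F_d))$ with both parents known, falling back to
$1/(0.75 - 0.25 F)$ and $1$ with one or no known parent. Inbreeding comes
from a Meuwissen–Luo style ancestor trace (`ped_inbreeding()`), checked in
the tests against a dense tabular-method oracle. `ped_a22()` uses the
tabular method on the ancestor-restricted sub-pedigree; the Colleau
indirect method would replace it at population scale but is unnecessary
here.

**Phantom parent groups.** Missing parents are assigned to unknown-parent
groups by selection path and birth-year bin; the group count is whatever
the configuration yields (a national evaluation may use 33; the simulated
study uses four). Groups enter `A`⁻¹ by the Westell/Quaas rules, which is
exactly the Quaas–Pollak transformed precision — the package verifies this
identity in its tests. Two consequences shaped the implementation:

* the grouped matrix is singular by construction, and group contrasts that
  the data cannot separate would drift freely. Group diagonals therefore
  receive a ridge of `group_ridge = 0.01` times the mean animal diagonal,
  i.e. the group pseudo-effects are treated as vague random effects (prior
  variance ≈ 100 genetic variances). Unidentifiable contrasts are pinned
  at zero; estimable group means are essentially unshrunk. A much smaller
  ridge leaves the solutions free to wander thousands of genetic units
  along near-null directions, visibly corrupting downstream statistics.
* in the grouped parameterization the animal solutions are group-inclusive
  totals $\mathbf{u}^* = \mathbf{u} + \mathbf{Q}\boldsymbol{\gamma}$.
  Every genotyped-block correction of the single-step models applies to
  the deviations $\mathbf{u}$, so with groups those corrections are
  carried by $\mathbf{S} - \mathbf{S}_{grp}\mathbf{Q}_{22}'$, which
  places the matching terms on the group equations; the marker backsolve
  and the RPG decomposition likewise use
  $\hat{\mathbf{u}}^*_g - \mathbf{Q}_{22}\hat{\boldsymbol{\gamma}}$.
  Omitting this (a common pitfall with unknown-parent groups in single-step
  models) produces exactly the kind of distorted validation statistics the
  test suite guards against.

Inbreeding in the `A`⁻¹ coefficients is on by default and toggleable
(`use_inbreeding = FALSE`) since evaluations differ on this point.

## Solvers

Equations are ordered level-major: the four trait equations of one effect
level are adjacent, so the prior is a Kronecker product with the 4×4 trait
covariance inverses and the natural preconditioner is the block-diagonal of
4×4 trait blocks. `solve_direct()` (sparse Cholesky, LU fallback) is the
default up to 20,000 equations and the oracle for `solve_pcg()`, a
preconditioned conjugate-gradient solver with convergence declared at a
relative residual below `tol` (default 1e-10). Iteration counts depend on
the preconditioner and the criterion and are not comparable across
implementations.

## Post-processing and forward validation

All four evaluations of a study (single-step and conventional, each with
the full and the truncated data) are rebased to a common base cohort — by
default the animals born in the reference year (cutoff − 1) that have
carcass records — and divided by the genetic standard deviation of each
trait, so results are comparable across traits and runs. Rebasing is
affine: ranks and pairwise differences are invariant to the base choice.

Forward validation removes all records of animals born after the cutoff
year (genotypes and pedigree are never truncated). Validation animals are
genotyped cows or steers with a record in the full data, born after the
cutoff; bulls are excluded (too few genotyped bulls to validate on). The
LR test regresses the full evaluation's predictions on the truncated ones
over the cohort: intercept `b0` (genetic-SD units) measures bias, slope
`b1` inflation (`b1` < 1) or deflation, and `r2` is the squared Pearson
correlation (raw, not adjusted). The regression direction (full on
truncated) is fixed; part of the LR literature uses the reverse, so the
direction is stated here once and used everywhere.

SNP scans divide each trait's marker effects by the per-trait
$\sigma_{SNP}$ (the diagonal of the marker covariance), giving
Manhattan-style standardized effects comparable across traits. No P values
or significance thresholds are attached to the scan — approximating
standard errors of single-step marker effects is an open research problem —
so peaks are descriptive.

## The simulated study

Because the motivating data (millions of Korean beef records) are
proprietary, the package ships a generator whose default study
(`sim_carcass_study()`) emulates the population structure the evaluation
assumes, at desk scale:

* ~2,000 animals: 260 founders (born 2013) plus four cohorts of 435;
  about 500 genotyped, skewed to recent cohorts
  (2%/5%/12%/35%/60% per cohort);
* 1,000 SNP on 29 chromosomes; founder frequencies Uniform(0.05, 0.95);
  Mendelian transmission with one crossover per chromosome per meiosis
  (enough linkage for single-step prediction; no genetic-map realism);
* true marker effects drawn multivariate normal and then linearly
  recalibrated so the founder genic covariance is exactly $(1-k)G_0$;
  three markers on chromosomes 4, 6 and 14 are planted with effects
  inflated 15-fold on carcass weight before recalibration, so the three
  regions jointly carry roughly a third of the CW marker variance —
  "major gene" scale;
* residual polygenic effects simulated down the pedigree for all animals
  with covariance $kG_0$ and inbreeding-corrected Mendelian sampling
  variance, so both model classes are correctly specified generatively;
* heritabilities 0.28–0.48 across the four traits, moderate positive
  genetic correlations except small negative BF–EMA and BF–MS, phenotypic
  scales typical of the breed (e.g. CW variance 900 kg²); these are
  plausible defaults, not estimates from any dataset;
* one slaughter record per cow and steer at birth-year + 2, with
  herd-year (15 herds) and year-season effects, a sex effect and an age
  regression; bulls get no record;
* sire selection by truncation on an equal-weight EBV index from a
  conventional BLUP of the records available at selection time (top 20
  males). Selecting on an index of *true* breeding values is also
  available (`selection = "tbv"`) but is deliberately not the default:
  information outside the evaluation data lets the fixed year effects
  absorb the genetic trend and deflates validation slopes — a
  mis-specification, not a property of the evaluation;
* truncation cutoff at the penultimate cohort (2016) and the 2015-born
  recorded animals as common base — the forward-validation design of a
  routine evaluation simulated "four years ago".

What passing tests on this generator establish: the algebra (pedigree
inverse, equivalence of the two single-step forms, solver agreement,
decomposition of GEBV into marker and polygenic parts) is exact; the LR
machinery is exact on identities and approximately unbiased
(`b1` ≈ 1) at study conditions; the single-step model predicts withheld
cohorts better than pedigree BLUP; planted major regions surface at the
top of the CW scan. What they do not establish: behaviour under real LD
structure, three-chip genotyping with haplotype imputation, pedigree
errors, heterogeneous variances, or population sizes in the millions — the
generator makes no attempt to emulate those.

At this scale statistical power differs from a national evaluation in one
visible way: with ~500 genotyped animals the largest one or two planted CW
regions dominate the scan reliably, but the third competes with the upper
tail of the polygenic background, so the strict "all top-3 scan hits inside
planted regions" property holds only in a minority of replicates. The test
suite states the property at full strictness and the accompanying analysis
treats its failure rate as a power statement, not as a defect of the scan.

## Numerical choices

* Convergence: relative residual < 1e-10 (PCG); direct solves verify their
  residual. Tests comparing PCG to the direct solution run PCG at 1e-12.
* Degenerate inputs rejected with errors: pedigree cycles, animals used as
  both sire and dam, all-missing markers, non-positive-definite covariance
  inputs, monomorphic-only panels (D = 0), empty base cohorts or
  validation cohorts, fewer than 3 validation animals.
* Monomorphic markers are kept with clamped frequencies rather than
  dropped, so marker panels keep their dimension across runs.
* Problem sizes in the tests (up to ~2,000 animals, 1,000 markers,
  ten study replicates) were chosen so the whole suite runs on a single
  CPU in minutes while leaving the estimation problems non-trivial.

## Known limitations

Mean-dosage imputation ignores linkage; `A22` inversion and the dense
`Gw` limit the genotyped set to a few thousand animals (the large-scale
strategies in the literature — iteration on data, Colleau products,
avoiding explicit `A22`⁻¹ — are documented but not implemented);
variance components are taken as known; no selection-index or P-value
machinery is provided.
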