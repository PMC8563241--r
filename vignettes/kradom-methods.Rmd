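---
title: "Additive and dominance genetic analysis of a two-line chicken cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive and dominance genetic analysis of a two-line chicken cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kradom)
```

## The study system and the model

kradom implements the quantitative-genetic analysis chain used for crossbred
slow-growing chickens such as the Korat chicken (KR), the F1 of a Leung Hang
Khao sire line (LK) and a Suranaree University of Technology dam line (SUT).
Body weight is recorded every two weeks from hatch to ten weeks; because the
cross combines two divergent purebred lines, both additive genetic variance
and dominance variance contribute to the trait, and midparent heterosis is of
direct economic interest.

The core model is the additive-plus-dominance animal model

$$ y = X\beta + Za + Wd + \varepsilon, \qquad
   \mathrm{var}\begin{pmatrix} a \\ d \\ \varepsilon \end{pmatrix} =
   \begin{pmatrix} A\sigma^2_a & & \\ & D\sigma^2_d & \\ & & I\sigma^2_\varepsilon \end{pmatrix}, $$

where $\beta$ holds the fixed effects (hatch date and sex, optionally line
when purebred records are analysed together with crossbreds), $a$ is the
vector of additive (breeding) values with the numerator relationship matrix
$A$, and $d$ the vector of dominance deviations with the dominance
relationship matrix $D$. Each age is fitted as an independent univariate
model; genetic correlations between ages are out of scope.

Derived parameters are $\sigma^2_p = \sigma^2_a + \sigma^2_d +
\sigma^2_\varepsilon$, the narrow-sense heritability $h^2 =
\sigma^2_a/\sigma^2_p$, and the dominance ratio $\sigma^2_d/\sigma^2_p$.
Rounding to two decimals happens only in the report layer
(`format_genetic_parameters()`), never inside the estimators.

## Relationship matrices

`additive_relationship_matrix()` uses the tabular (recursive) method on a
topologically ordered pedigree: $a_{ii} = 1 + \tfrac12 a_{s_i d_i}$ and
$a_{ij} = \tfrac12 (a_{j s_i} + a_{j d_i})$ for earlier $j$, with
unknown-parent terms contributing zero. Founders are taken as unrelated and
non-inbred (the standard base-population assumption). The diagonal is
therefore $1 + F_i$ with $F_i$ the inbreeding coefficient.

`dominance_relationship_matrix()` uses the classical non-inbred formula
$d_{ij} = \tfrac14 (a_{s_i s_j} a_{d_i d_j} + a_{s_i d_j} a_{d_i s_j})$ with
the diagonal fixed at 1 and zero off-diagonals for animals with an unknown
parent. Inbreeding is deliberately ignored in $D$ — the inbred dominance
covariance has no agreed single-matrix treatment, and the non-inbred
convention matches standard animal-breeding software. Consequence worth
knowing: in pedigrees with inbreeding the closed-form $D$ is *not* the
probability of double identity-by-descent; the gene-dropping oracle below
agrees with $D$ only when mates are unrelated (as they are in an F1 cross
design, where this analysis lives).

`gene_drop_relationships()` is an independent Monte-Carlo oracle: every
founder contributes two distinct alleles, offspring sample one allele per
parent, and realized additive and double-IBD relationships are tallied over
replicates with entrywise standard errors. It shares no code with the
tabular recursions and is used throughout the tests. Note that a 3-SE band
is exceeded by ~0.27% of stochastic entries purely by Monte-Carlo chance, so
the tests check the exceedance *rate* and an absolute cap rather than
demanding every entry inside the band.

## REML estimation

`reml_estimate()` works on the marginal covariance of the records,
$V = \sigma^2_a Z A Z' + \sigma^2_d W D W' + \sigma^2_\varepsilon I$ (an
$n \times n$ matrix, $n$ = records), a convenient size because each animal
has one record per age. The iteration is:

* EM-REML updates, expressed through the REML projection matrix $P$:
  $\theta_i \leftarrow \theta_i + (\theta_i^2/q_i)\,(y'P G_i P y -
  \mathrm{tr}(P G_i))$. These are guaranteed not to decrease the restricted
  log-likelihood.
* An average-information (AI) acceleration step once past the first two
  iterations, accepted only if the evaluated log-likelihood does not
  decrease; otherwise the step is halved (up to 8 times) and finally the EM
  update is used. The recorded log-likelihood trace is therefore monotone by
  construction; if numerical precision is exhausted (a theoretical ascent
  step evaluates as a decrease), the fit stops at the current estimates.
* Active-set boundary handling: when the AI step drives a component through
  its bound, the candidate with that component *at* the bound (zero for the
  genetic components, a small positive floor of $10^{-8}\,\mathrm{var}(y)$
  for the residual, which keeps $V$ invertible) is evaluated first. A
  genetic component that stays pinned for three consecutive iterations is
  fixed at exactly 0 and its block leaves the working model — this is what
  produces exact-zero dominance estimates at early ages rather than
  epsilon-sized ones.
* Convergence requires relative component change below `tol` (default 1e-8)
  *and* log-likelihood change below 1e-6; hitting `max_iter` returns
  `converged = FALSE` with a warning, never silently.

Standard errors come from the inverse AI matrix at convergence; the SE of
$h^2$ uses the delta method. Note that an estimate *at* a boundary makes the
usual asymptotics approximate; the tests treat the SEs as calibrated only
for interior components (their empirical coverage at n = 1,500 is ~93–97%).

A statistical caveat the test suite respects: when the true variance is at
the boundary (e.g. pure i.i.d. noise), the REML estimate is positive with
probability about one half by sampling noise — the exact-zero contract can
only be asserted on data whose likelihood decisively favors the boundary
(the tests construct negative within-family resemblance for this).

`solve_mme()` then solves Henderson's mixed-model equations with the
variance ratios $k_a = \sigma^2_\varepsilon/\sigma^2_a$,
$k_d = \sigma^2_\varepsilon/\sigma^2_d$ added to the $A^{-1}$ and $D^{-1}$
blocks, via dense factorizations with an escalating diagonal jitter
($10^{-10}$ of the mean diagonal, growing tenfold, at most 8 rungs). A
variance fixed at zero drops its block and returns exact-zero BLUPs. Dense
linear algebra is a deliberate desk-scale choice: pedigrees up to a few
thousand animals fit comfortably; Henderson/Quaas sparse inverse rules are a
documented non-goal.

## Heterosis

`least_square_means()` fits a within-line fixed-effects model and averages
the cell predictions with equal weight over all *observed* fixed-factor
combinations (the classical LSMEANS convention; whether the original
analysis pooled or averaged sexes is not stated, so the unweighted-marginal
convention is the documented choice here). Unestimable cells are dropped
with a warning; a single record returns its value with a missing SE.
`heterosis_percent()` is $100\,(\mathrm{LSM}_{KR} - \mathrm{MP})/\mathrm{MP}$
with $\mathrm{MP} = (\mathrm{LSM}_{LK} + \mathrm{LSM}_{SUT})/2$; any missing
LSM propagates to a missing heterosis, mirroring ages at which parental
lines were not weighed.

One subtlety: in a cross design the sire line is all-male and the dam line
all-female, so a within-line model cannot adjust for sex and each parental
LSM absorbs its line's sex effect. The two effects cancel in the midparent
mean when sex effects are coded symmetrically — which is why the simulator
codes them sum-to-zero. With asymmetric real-world sex effects the midparent
(and hence H%) carries that asymmetry; this is a property of the
study design, not of the software.

## Genotype association

`genotype_effect()` fits `value ~ genotype + sex` and tests genotype with a
type-II F-test (identical to type III here because no interaction is
fitted). Genotype least-square means average over observed sex levels;
pairwise comparisons use the Tukey–Kramer studentized-range procedure with
the unequal-$n$ adjustment (group sizes in genotype tables are unbalanced),
rendered as a compact letter display by the insert-and-absorb sweep over
groups sorted by decreasing mean, so the top group carries "a" as in the
published tables. With two balanced groups the procedure reduces exactly to
the pooled t-test ($q = t\sqrt2$). No multiple-testing correction is applied
across ages or traits, matching the original analysis; $\alpha$ defaults to
0.05 and is overridable. `pearson_correlation()` wraps the standard
product-moment test on complete pairs.

## The synthetic-data generator

`simulate_dataset()` emulates the two-line cross: LK sires and SUT dams
(founders), round-robin mating of dams to sires, KR offspring with 50:50
sexes and round-robin hatch codes; deeper pedigrees breed each line within
itself for the earlier generations. Marker genotypes start from per-line
genotype-group weights patterned on the real mating design (GH locus with
alleles A1/A3; IGF-I locus with alleles A/C) and are transmitted by
Mendelian sampling, so homozygote-by-opposite-homozygote matings yield
all-heterozygous offspring by construction. Genetic effects are drawn
directly from the $A$- and $D$-structured multivariate normals (Cholesky
with jitter): that is exactly the covariance structure the analysis model
assumes, which makes parameter recovery a clean test. A multi-locus
genotypic generator is a documented extension point, not implemented.
Markers have zero phenotypic effect by default (null calibration); optional
per-locus `add`/`dom` effects create association-table-like signal.

Defaults are study-shaped: 142 sires, 259 dams; week-6 variance components
(14250, 3315, 713 g²); baseline 572 g with line offsets (+28, −28, +143 g)
giving a 25% true midparent heterosis and a ~715 g crossbred mean; sex
effects ±30 g and three hatch codes at −15/0/+15 g (plausible magnitudes for
a 6-week slow-growing bird; the source analysis reports none). Everything is
reproducible bit-for-bit from one integer seed.

What the generator does **not** emulate: longitudinal correlation across
ages (each age is one independent cross-section), maternal genetic or
permanent-environment effects (excluded from the analysis model as well),
selection or assortative mating within lines, genotype-by-fixed-effect
confounding, and the internal composite history of the dam line. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to these real-data features.

## Problem sizes used by the tests

* Variance-component recovery: 20 replicates of 60 sires × 180 dams ×
  7 offspring with the parents phenotyped (exactly 1,500 records) and line
  as a fixed effect. Phenotyping only the crossbreds separates
  $\sigma^2_d$ from $\sigma^2_\varepsilon$ poorly (their contrast then rests
  on full-sib versus half-sib covariances alone); parental records anchor
  $\sigma^2_a$ through parent–offspring covariance and roughly halve the
  dominance SE. True components (100, 40, 60) g².
* Heterosis recovery: ~5,200 records with all variance residual
  (CV ≈ 16%). Genetic variance is irrelevant to the heterosis estimator's
  expectation, and independent records make the delta-method Monte-Carlo SE
  exact rather than family-correlated.
* Grid-search oracle: a 20-animal pedigree (4 sires × 4 dams × 3 offspring,
  so full-sib families exist — with single-offspring matings $D = I$ over
  the crossbreds and $\sigma^2_d$ would be confounded with
  $\sigma^2_\varepsilon$) against a brute-force lattice of the
  error-contrast restricted likelihood.
* Gene-dropping: 100,000 replicates per pedigree on 25 random non-inbred
  pedigrees of 23–83 animals.

## Known limitations

Univariate-by-age only; no maternal effects; no epistasis; dominance under
inbreeding approximated by the non-inbred convention; dense algebra only
(practical to roughly 5,000 animals); SEs of individual BLUPs not reported.
The published record counts for the underlying study are mutually
inconsistent (the per-line totals exceed the stated overall count), so the
simulator makes no attempt to match them — its defaults reproduce the
design's *shape*, not its exact bookkeeping. The source also prints a
heritability range in the text (0.53–1.00) that disagrees with its own
parameter table (0.32–1.00); the packaged worked-example table follows the
printed per-age components.
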