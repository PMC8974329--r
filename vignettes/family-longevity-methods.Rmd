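---
title: "Models and design choices in famlong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in famlong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famlong)
```

famlong implements the methodological core of family studies of
exceptional longevity: scoring families for familial clustering of
survival, estimating individual longitudinal change with a
random-coefficient (growth-curve) model rather than naive two-visit
differences, estimating kinship-based heritability of cross-sectional
and slope phenotypes, and demonstrating by gene-dropping simulation how
clusters of rare lineage-specific variants create linkage peaks that
single-variant association misses. Because the cohorts this methodology
serves are restricted-access, the package ships a seeded synthetic-data
generator so that every stage can be exercised and validated end to end.

## Family longevity scoring

A sibship's survival exceptionality sums, over siblings, the negative
log tail probability of each sibling's survival status under a sex- and
birth-cohort-appropriate life table: $-\log S(T)$ for a sibling dead at
age $T$, and $E[-\log S(T) \mid T > t] = -\log S(t) + 1$ for a sibling
alive at age $t$. The closed form for living siblings follows from the
probability-integral transform: when $T$ has survival function $S$,
$-\log S(T)$ is unit exponential, so the conditional excess beyond
$-\log S(t)$ has mean exactly 1. A quadrature oracle in the test suite
verifies the identity numerically. Because each sibling's expected
contribution is 1, subtracting the sibship size centers the component at
zero for any sibship size -- zero means survival exactly as expected
from the tables, and the centering is confirmed by Monte-Carlo
simulation with lifespans drawn from the scoring table (including
right-censoring of the living: censoring preserves the per-sib unit
expectation exactly). A bonus per living sibling (default coefficient
0.5, configurable -- the magnitude used in the original scoring
literature is not restated here) favours families available for
prospective follow-up. Eligibility combines a score threshold
(default 7, inclusive) with a structural rule: a proband, at least one
living proband-generation sibling, and at least one offspring.

Life tables are tabulated on integer ages per sex/cohort stratum.
Survival between grid ages interpolates linearly in $\log S$
(piecewise-constant hazard, the standard actuarial convention; exact
for exponential segments). Beyond the last grid age a Gompertz tail is
fitted through the last two grid points of the cumulative hazard, with
a constant-hazard fallback when the tabulated hazard is not
accelerating; evaluations are clamped to $(10^{-12}, 1]$.
`survival_quantile()` inverts the same interpolated curve, so
inverse-transform lifespans are distributed exactly according to the
evaluated table.

## Pedigrees and kinship

Pedigrees follow the PED convention (missing parent "0", sex 1/2).
Individuals with exactly one known parent are rejected rather than
silently completed -- silent pedigree alteration hides data errors --
with `add_dummy_parents = TRUE` available for explicit auto-completion.
Kinship uses the standard recursion (parents before children;
$\phi_{ij} = \tfrac12[\phi_{pj} + \phi_{qj}]$,
$\phi_{ii} = \tfrac12[1 + \phi_{pq}]$), computed per family with
cross-family kinship zero, families being independent sampling units.
The independent oracle is `kinship_mc()`: vectorized gene dropping that
estimates $\phi$ as the Monte-Carlo probability that two randomly drawn
alleles are identical by descent. The agreement test compares every
within-family pair at its own Monte-Carlo standard error; with on the
order of 1500 simultaneous pair comparisons the maximum standardized
deviation concentrates around 3.5 even when everything is correct, so
the suite requires at least 99% of pairs within 3 SE and every pair
within 4.5 SE.

## Individual change: growth curves versus two-visit differences

The naive change estimate $\Delta = (P_2 - P_1)/\text{years}$ (years =
days between visits / 365.25) accumulates the measurement error of both
visits: its error variance is the sum of the two visit error variances.
The random-coefficient model
$$y_{ij} = (\beta_0 + u_{i0}) + (\beta_1 + u_{i1})\,t_{ij} + e_{ij},
\qquad (u_{i0}, u_{i1}) \sim N(0, G),\quad e_{ij} \sim N(0,\sigma^2_e)$$
models the per-visit error explicitly and returns empirical-Bayes
(BLUP) person slopes that trade bias for a large reduction in error
variance. Fitting is REML via lme4 (profiled deviance with a Cholesky
parameterization of the relative covariance, which keeps G positive
semidefinite); persons with a single visit stay in the fit and receive
shrunken estimates.

**Time axis.** The package measures time as age centered at a reference
age (default 75), not as years since the person's own first visit, and
the synthetic cohort generates person trajectories as lines in age. The
reason is identifiability, and it is the most consequential design
choice in the package. With two visits per person and a common
per-person origin, every person contributes the same two-point layout
($t = 0$ and $t \approx 9$), and the decomposition of the visit-1
variance into intercept variance versus measurement error rests on
extrapolating the covariance-versus-gap line nine years back to zero
gap; simulation (and an independent direct REML implementation used as
a cross-check) shows median relative errors of 40--80% on the variance
components at $n = 600$, with the residual variance frequently driven
to zero -- which silently turns the BLUP slopes back into the naive
difference estimates. On the age axis, participants measured at widely
different ages (two generations spanning roughly ages 30--105) separate
the components locally, and the same simulations recover all four
components with median relative errors of 2--11% at $n = 1500$. The
slopes themselves are unchanged in meaning: a slope per year of age is
a slope per year of follow-up.

Degenerate inputs: exactly collinear per-person measurements (the
zero-measurement-error limit, detectable when persons have three or
more visits) are fit directly -- per-person least-squares lines,
$\sigma^2_e = 0$, G the empirical coefficient covariance -- because the
mixed-model deviance is unbounded there; and a layout in which every
person shares an identical two-visit design is rejected as
unidentifiable rather than fitted.

## Covariate adjustment and exclusions

Visit values are adjusted for sex, same-visit age, age squared, and
field site by linear projection; slope phenotypes for sex, baseline
age, baseline age squared, and field site. Blood-pressure values are
shifted (+15 systolic, +10 diastolic) under antihypertensive
medication; glycemic traits are blanked for diabetics (fasting glucose
at or above 126 mg/dL, HbA1c at or above 6.5, reported diagnosis, or
diabetes medication -- boundaries inclusive), glucose additionally when
non-fasting; lipid traits are blanked under lipid-lowering medication
or non-fasting. Heritability is then estimated on the adjusted
residuals (a two-stage workflow, which keeps the variance-component
kernel two-parameter).

## Kinship heritability

`polygenic_reml()` maximizes the REML likelihood of
$y \sim N(\mu 1, 2\Phi\sigma^2_g + I\sigma^2_e)$ with the grand mean
and total variance profiled out, leaving a one-dimensional search over
$h^2 \in [0, 1]$ evaluated through the per-family eigendecomposition of
$2\Phi$ (each likelihood evaluation is a weighted sum; eigenvalues are
floored at $10^{-10}$). A coarse 51-point scan brackets a golden-section
refinement to tolerance $10^{-8}$, and a 101-point brute-force profile
(`reml_profile()`) serves as the grid oracle in the tests. Boundary
estimates are reported as exactly 0 or 1; the test against
$\sigma^2_g = 0$ uses the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$
boundary mixture, whose type-I error the suite checks by simulation.
No household/common-environment component is modelled (spouses act as
genetically unrelated in-family controls), and mortality/ascertainment
selection is deliberately ignored -- both standing assumptions of the
workflow this package mirrors, and documented limitations. The
heritability table restricts all four estimates (visit 1, visit 2,
growth-curve slope, naive slope) to participants with both visits, for
comparability.

## Rare lineage-specific variants: linkage versus association

`gene_drop()` transmits uniquely labelled founder alleles down the
pedigree, giving simulation-true locus IBD (no marker-based IBD
inference -- exact and orthogonal to the claim being demonstrated).
Per-family linkage evidence comes from the variance-component model
$y \sim N(\mu 1, \Pi\sigma^2_q + 2\Phi\sigma^2_g + I\sigma^2_e)$.
Two aggregation routes are provided. `family_vc_lod()` maximizes the
model family by family; its lods are nonnegative by nesting, sit
exactly at zero when $\sigma^2_q$ hits the boundary, and suit
single-family questions. `vc_linkage()` fits one set of variance
components jointly across families and reports each family's log10
likelihood-ratio contribution at the joint estimates -- the form in
which per-pedigree LOD scores are conventionally reported. Joint
contributions can be negative for unlinked families, and under the null
the joint $\hat\sigma^2_q$ sits on the zero boundary about half the
time, collapsing every contribution to exactly zero; this is the route
the demonstration pipeline aggregates, because a heterogeneity LOD
built from per-family-maximized (hence nonnegative) lods grows linearly
with family count under the null and cannot stay calibrated.
The admixture HLOD maximizes
$\sum_i \log_{10}[\alpha\,10^{L_i} + (1-\alpha)]$ over the linked
proportion $\alpha$ on a 0.001 grid (smallest $\alpha$ on ties); the
default reports the exact grid maximum, deterministic and reproducible
against a brute-force scan, with optional local refinement whose gain
is below $10^{-5}$. Families with lod above 0.2 are flagged as the
driving families.

The demonstration scenario (`raredrop_config()`) uses 50 linked and 30
null families, each a sibship of three with spouses and one offspring
per sibling (nine phenotyped members), one private causal variant per
linked family introduced through a heterozygous founder parent, a
carrier shift of 3 residual standard deviations, and a polygenic
background ($\sigma^2_g = 0.5$, $\sigma^2_e = 1$). The geometry is
chosen so each variant is carried by only a handful of phenotyped
descendants: per-variant pooled allele frequencies stay near 0.2%
(below 0.5%), which caps every single-variant score statistic below
genome-wide significance ($5\times10^{-8}$, the conventional
comparator threshold, configurable), while fifty families each
contributing modest positive lods push the HLOD far above 3. The
scenario parameters were fixed once from this design arithmetic, which
is why the dissociation is a majority-of-seeds event rather than a
certainty: the association side sits deliberately close to the
threshold.

## The synthetic cohort

`sim_config()` defaults encode the study conditions the package
emulates: two-generation families built around a long-lived proband
sibship with spouses and offspring (enrolled family size calibrated to
mean 9.1, range [3, 79]; truncated negative-binomial sibship sizes,
Poisson offspring counts); proband-generation first-visit ages
$N(90.2, 6.6^2)$ and offspring ages $N(61.2, 8.4^2)$; Gompertz
lifespans per sex ($a = 1.1\times10^{-4}$ male, $6\times10^{-5}$
female, $b = 0.085$ -- median lifespans in the mid-70s/around 80);
second visits 8--10 years after the first. The default trait is scaled
like systolic blood pressure: between-person SD 10 at the reference
age, slope SD 0.2 per year, intercept-slope correlation 0.5,
measurement-error SD about 3.9 ($\sigma^2_e = 15$). Two features of
that choice matter for the headline experiment: the error variance
exceeds four times the slope-induced signal variance over the visit
window ($0.04 \times 9^2 = 3.24$), which is what drives naive slope
heritability toward zero; and the intercept-slope correlation lets the
BLUP slope borrow strength from the precisely measured level, which is
how the growth-curve slope retains most of the generating heritability.
Genetic structure: person intercept and slope deviations split into a
genetic part with within-family covariance $2\Phi$ times the heritable
fraction (default $h^2 = 0.4$ for both) and an independent
environmental part, drawn per family through a symmetric square root of
the kinship block; spouses are founders. Nuisance sex, site, and
baseline-age effects are added to the level and removed downstream by
residualization. Sibship-parent founders are included in pedigrees (so
sibling kinship is represented) but marked not enrolled.

Per-family random substreams are derived deterministically from the
single config seed, so output is byte-identical across runs and
independent of family iteration order. What the generator does not
emulate: trait-specific means/variances of any real cohort table,
mortality-driven attrition between visits (visit-2 dropout exists only
as an optional missing-at-random flag), assortative mating, shared
household environment, and ascertainment on the score. Passing tests
therefore validate the estimators under the stated model, not the
selection effects of a real cohort.

## Problem sizes and numerical conventions

The validation suite uses 10,000 simulated sibships for score
calibration; five random pedigrees with 200,000 gene drops each for the
kinship oracle; 20 replicates of ~150-family (~1,500-person) cohorts
for heritability recovery (generating $h^2 = 0.40$, tolerance
$\pm 0.05$ on the mean) and for the attenuation experiment; 100 random
lod vectors against the 1001-point HLOD grid; and 11 demonstration plus
20 null linkage scenarios. Convergence and tolerance conventions:
REML heritability search tolerance $10^{-8}$; variance-component
linkage fits use L-BFGS-B with multiple starts from the null solution
(guaranteeing nonnegative per-family lods by nesting), with a
$10^{-8}$ floor treated as the zero boundary; lme4 convergence
messages are captured into the fit object rather than printed.

## Known limitations

Slope heritability from the growth-curve route inherits level
information when intercepts and slopes correlate; with truly
uncorrelated intercepts and slopes and heavy error, part of the
advantage over naive slopes disappears. The two-stage
residualize-then-fit workflow ignores uncertainty in the adjustment
stage. The linkage demonstration uses simulation-true IBD; with
marker-inferred IBD the dissociation would be attenuated. X-linked
kinship, genotype-based (realized) kinship, bivariate genetic
correlations, and informative dropout are out of scope.
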