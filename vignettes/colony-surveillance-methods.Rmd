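---
title: "Colony surveillance methods: segregation, mortality, growth, and composition geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony surveillance methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bkcolony)
```

bkcolony analyzes surveillance records of a heterozygote-by-heterozygote
BK-channel (*Kcnma1*) knockout mouse breeding colony. Because pups of a
het x het cross segregate 1:2:1 (WT : het : KO) and sexes are equally
likely, every pup falls into one of six "gender categories" (mWT, fWT, mhet,
fhet, mKO, fKO) with Mendelian fractions 1/8, 1/8, 1/4, 1/4, 1/8, 1/8.
Departures from those fractions — at birth, at genotyping, and at weaning —
carry the biological signal: prenatal and perinatal disadvantage of pups
lacking the channel, modulated by an environmental stressor (adjacent
building construction). This vignette explains the models implemented, the
parameters that matter, the synthetic-colony generator used for testing, and
the numerical choices made where the design was genuinely open.

## Segregation testing and the Mendelian2 cohort estimator

The standard test compares observed category counts with expectations
`total x fraction_c` via the chi-square statistic, decomposed per category as
`(obs_c - exp_c)^2 / exp_c`. Degrees of freedom are `categories - 1` (5 for
six categories, 2 for three, 1 for a sex ratio). Individual categories whose
component exceeds 3.84 — the P = 0.05 point at one degree of freedom — are
flagged as major contributors to a falsified null. Expected counts are never
rounded in computation; display rounding is applied only in reports. Two
consequences worth knowing:

* a published table total of this kind can be the sum of *display-rounded*
  components (18.27 for the weaned-pup table, where the unrounded total is
  18.2756); `chi_square_fit()` keeps full precision and the report layer
  rounds;
* for the weaned-pup table the p-value at df = 5 is about 0.003, not the
  "< 0.0001" sometimes quoted for that statistic; the package always computes
  p at `categories - 1` degrees of freedom and leaves reconciling historical
  footnotes to the reader.

The standard model is biased whenever pups vanish before categorization: the
categorized count stands in for the whole cohort. The **Mendelian2**
estimator assumes instead that a subset of categories (default mWT and mhet)
was neither advantaged nor disadvantaged, seeds an alternative cohort size at
`n_ref / sum(reference fractions)` — 8/3 of the mWT + mhet count — and
refines it by minimizing the sum of the reference categories' chi-square
components over *integer* totals (pups are discrete). Ties break toward the
smaller total; the search window defaults to half to twice the seed and is
configurable, since the estimator's objective is strictly convex in the
continuous relaxation and the optimum always lies near the seed. The
refinement recovers losses occurring by *non-Mendelian* mechanisms only;
losses that hit every category in Mendelian proportion are invisible to it,
a limitation inherited from the design.

```{r mendelian2}
weaned <- c(mWT = 102L, fWT = 88L, mhet = 168L, fhet = 145L,
            mKO = 59L, fKO = 62L)
mendelian2_estimate(weaned)
```

Per-litter **deviation ratios** `obs_c / (L x fraction_c)` give a
litter-resolved view: 1.0 is the Mendelian expectation. Ratios are treated as
independent litter-level observations (mean, SEM, and a two-tailed one-sample
t test against 1.0), matching the mean-and-SEM presentation style of the
field. Subgroup screens (e.g. litters with more than four males) use a plain
Bonferroni criterion within each subgroup; Holm stepdown adjustment is
available via `holm_adjust()` for families where stepdown is preferred.

## Mortality timecourse

Death days are postnatal days with birth at P0. A boundary at P9 demarcates
the early death peak (P1, mostly newborns) from a late cluster near P13-P15.
Deaths with no recorded day are assigned to the early period — in colony
practice these are scavenged newborns, and all undated deaths in the source
records occurred early. Missing pups count as deaths on the day first noted
missing and are therefore censored observations of the true death day; the
package keeps them in mortality analyses and excludes them from category
tallies when ungenotyped, logging the exclusion count. "Survived day 3"
means alive at the end of P3. The chronological smoother is a *centered*
five-litter running average with shrunken edge windows; trailing averages are
obtainable by shifting, and the source figures cannot disambiguate the
convention at desk scale, so the choice is documented rather than inferred.

## Growth gains, pauses, and ASH densities

Weekly fractional gain is `(w[t+1] - w[t]) / w[t]` over consecutive observed
weeks only (no interpolation; a missing week breaks the pair). A **growth
pause** is a week with gain strictly below 2% of the beginning weight —
losses are pauses, and the strictness matters only on the exact boundary,
which is tested explicitly. First-pause distributions report, per category,
the week of each mouse's earliest pause and the cumulative proportion paused
by a cutoff week (default 9).

Littermate comparisons control for litter effects: the delta series pairs
mice of two categories within each litter, using all cross pairs when a
litter holds several eligible mice (pair counts in the source tables indicate
pairs, not litter means); litter-level averaging first is available as an
option. The SEM uses the pair count. SEMs of independent group means combine
in quadrature (`sem_combine()`).

Weight distributions use the **average shifted histogram**: the average of
`m` ordinary histograms of bin width `h` whose origins shift by `h/m`, which
collapses to a triangular-weighted count smooth on the fine grid. `m`
defaults to 8; `h` is chosen per comparison set and *shared by all
categories in one comparison* so their resolutions match (the analysis
drivers use the Freedman-Diaconis rule on the pooled sample). The estimator
is exactly equivalent to brute-force shifted-histogram averaging — the test
suite asserts bin-exact agreement — integrates to 1 on its grid, and is
translation-invariant up to grid alignment.

## Composition geometry

QMR components (lean, fat, total water, free water, grams) are normalized to
total body mass; specific water is total minus free water, and the hydration
ratio `(total water - free water) / lean` is ~0.85 in adult mice. Per-mouse
values are means of that mouse's weekly measurements before any category
statistics.

With axes x = lean, y = specific water, z = fat (all proportions), adult
composition points cluster near an oblique plane through the origin. The
package parametrizes that plane by two origin-preserving rotations: by phi
about the fat axis (mixing lean and water into x'), then by psi about the
resulting x' axis. The eight transform coefficients are products of the
angle sines/cosines (`plane_coefficients()`), the out-of-plane coordinate is
`y' = zeta*water - eta*lean - theta*fat`, and `fit_plane_rotation()`
minimizes `sum(y'^2)`. Because `(eta, zeta, theta)` is a unit vector, the
minimizer is the smallest principal direction of the origin second-moment
matrix (un-centered; the plane must pass through the origin), converted to
angles under the sign convention zeta > 0, phi in [0, 90), psi in (-90, 90).
This closed form is exact and fast; an exhaustive 0.01-degree grid search is
retained in the package purely as an independent test oracle. The fit is
invariant to point relabeling and to uniform scaling of the cloud, and such
a 3D fit is not unique in general — the two-rotation, origin-preserving
parametrization is the constraint that pins it down, and degenerate
(collinear) clouds are rejected. The forward/inverse transform round-trips
in-plane points to 1e-12.

```{r plane}
round(plane_coefficients(39, 21.5), 3)
```

## The synthetic colony: what it emulates, and what it does not

Every analysis stage runs end to end on generated data; the generator's
defaults are fixed at the colony's printed summary statistics and are not
tuning knobs:

* 110 litters, 73 during construction and 37 quiescent; litter sizes from a
  rounded truncated normal, 8.5 +/- 2.0, minimum 1 (honoring the printed
  mean +/- SD and the 2-14 range; a Poisson draw would be overdispersed
  relative to the records);
* independent 50:50 sex and 1:2:1 genotype per conceptus; an optional
  `ko_prenatal_deletion` probability removes KO conceptuses before birth —
  the non-Mendelian loss channel that the Mendelian2 estimator is designed
  to see through, used by the recovery studies;
* a two-peak *daily* death hazard (the data are daily, so no continuous-time
  model): geometric decay from P1 over P0-P8, a symmetric bump peaking at
  P13 over P9-P21. Genotype multipliers (early 0.5/0.8/1.9, late
  0.3/0.5/2.7 for WT/het/KO) average to 1 under 1:2:1 and reproduce the KO
  preponderance of both death waves;
* the construction period doubles the per-pup early hazard
  (`construction_early_ratio = 2`), and whole-litter losses occur with
  probability 0.09 (construction) vs 0.02 (quiescent). The per-pup quiescent
  risk 0.125 was chosen jointly with those loss probabilities so the
  *aggregate* early-death proportions land at the recorded 0.15 and 0.32 —
  total-loss litters count toward the aggregate, as they do in the records;
* first litters of a dam carry a 1.3x early-risk multiplier; only ~19.6% of
  deaths before the genotyping day are genotyped, ~16% of them have no
  recorded day, and pups dying on or after genotyping (~P6) are always
  categorized;
* growth follows a Gompertz curve `A * exp(-b * exp(-k t))` with A = 27 g
  for mWT, -3.5 g for females, -5/-4 g for male/female KO (the maintained
  littermate deficits), b = 2.8, k = 0.35 per week — placing the weaning
  weight near 10 g and the curve's natural sub-2% gain weeks after week 11 —
  with 0.4 g weekly noise and an 8%/week injected pause probability;
* composition points are drawn in-plane around per-category centroids (the
  colony category means projected onto the configured 39/21.5-degree plane)
  with isotropic in-plane scatter and a small out-of-plane deviation.

Features of real data deliberately *not* simulated: intrauterine-position
effects (male-adjacency influences on female categories) have no mechanistic
model — subgroup-deviation signatures can only be induced phenomenologically;
category weight distributions are unimodal (no 6-7 vs 10-11 week bimodality
of first pauses, no weight subgroups that diverge and reconverge); the
in-plane composition scatter is isotropic, so within-category lean-water
regression slopes do not reproduce the recorded ones; and the real category
means of the most deviant categories (fKO, fhet) sit ~0.008 off any single
plane, which the generator reproduces only through out-of-plane noise, not
systematic offsets. Passing tests therefore demonstrate the correctness of
the estimators under the stated generative assumptions, not distributional
fidelity to every feature of the recorded colony.

Determinism: every generator is a pure function of (config, seed), with
child seeds derived per stage so regenerating one stage leaves the others'
streams untouched.

## Numerical choices and problem sizes

* Integer search for Mendelian2 over `[ceil(seed/2), ceil(2 seed)]`,
  smallest total on ties.
* Chi-square tests are uncorrected (no continuity correction), matching the
  published count-table statistics.
* ASH grids extend one full bin width beyond the data so the density decays
  to zero inside the grid; normalization is exact on the grid.
* The plane fit rejects clouds whose second moment matrix is numerically
  rank-deficient (relative eigenvalue below 1e-12).
* Simulation-based checks use one fixed seed each and sizes chosen so the
  asserted bands sit at three or more standard errors: 500 replicate
  40-litter colonies for the type-I calibration, a 1000-litter colony
  (~8500 conceptions) for Mendelian2 recovery at 30% KO deletion, 1500-4000
  litters for hazard-ratio recovery. The full suite runs in well under a
  minute on one core.

## Known limitations

The per-litter deviation-ratio t test treats ratios as independent and
approximately normal; for categories with expected counts near 1 per litter
the ratios are coarse (0, 1, 2, ...) and the test is approximate. The
Mendelian2 estimator's reference-category assumption is untestable from the
counts themselves. The mixed ANOVA used historically for composition
category effects is out of scope; littermate paired t tests with Holm
stepdown are the documented substitute, so tabulated adjusted p-values are
not reproduced. Glucose handling is summarized only by the trapezoid AUC
without baseline subtraction (reported in mole.min/L).
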