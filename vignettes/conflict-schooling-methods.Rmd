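---
title: "Methods: conflict exposure, girls' schooling, and downstream mortality"
author: "conflictedu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conflict exposure, girls' schooling, and downstream mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflictedu)
library(data.table)
```

## The scientific problem

Armed conflict disrupts schooling, and the disruption is not evenly shared:
girls' education appears more vulnerable than boys' in much of sub-Saharan
Africa. Quantifying this requires linking georeferenced survey microdata
(DHS-style individual records attached to cluster GPS coordinates) to
georeferenced violent-event records (UCDP-style, one dated and located
event per row with a casualty estimate), and estimating how exposure to
nearby violence during primary-school ages changes completed schooling
measured in late adolescence.

`conflictedu` implements that pipeline end to end: exposure construction,
eligibility filtering and weighting, weighted high-dimensional fixed-effects
estimation with cluster-robust inference, heterogeneity splits, and a
back-of-the-envelope counterfactual translating schooling losses of mothers
into excess under-5 deaths. Because the survey microdata that motivate this
design are restricted-access, the package ships a first-class synthetic-data
generator with planted effects, so every stage of the pipeline can be
verified by parameter recovery rather than by comparison to data we cannot
redistribute.

## Exposure measurement

A respondent is *exposed* if at least one violent event occurred within
25 km of their cluster's coordinates in any calendar year in which they
turned 6 through 12. The 25 km radius is roughly a day's walk and exceeds
typical school distances; smaller radii would drown in the location noise
of both data sources (cluster coordinates are deliberately jittered before
release, and event locations are only trusted when precise to about 25 km;
events with coarser precision codes are discarded).

Implementation choices a user should know:

* Distances are great-circle (haversine) on a sphere of radius
  6371.0088 km. No ellipsoidal correction: the radii are coarse relative
  to the <0.3% error of the spherical approximation.
* Distance bands are a disc and half-open rings: band 1 is `d <= 25`,
  band 2 `(25, 50]`, band 3 `(50, 75]`, band 4 `(75, 100]`. The boundary
  event at exactly 25.0 km is *inside* band 1. Neither data source defines
  the convention, so we fixed the inclusive-outer-edge rule once and test
  it explicitly.
* Exposure is indexed by calendar year of (birth year + age); birth month
  is ignored for exposure, mirroring the year-level resolution of the
  event data.
* An exposed age counts as *recurring* when a band-1 event also occurred in
  the preceding calendar year, and *new* otherwise. The preceding year is
  evaluated even at age 6 (i.e., the age-5 year), so the first in-window
  age can already be recurring.
* Linkage always uses the released (jittered) cluster coordinates, exactly
  as an analyst of the real data would; no de-jittering is attempted.

## Sample construction

Outcomes are measured at ages 15–18, when primary schooling is essentially
complete. Exposure can only be located for respondents who lived at the
surveyed location during school age, so the main sample keeps respondents
who report living in their current residence since at least age 6
(`years_in_residence == "ALWAYS"` or `>= age - 6`). Variants toggle this
filter (`no_residence_filter`, `movers_only`), drop clusters with conflict
at survey time (`no_recent_conflict`), or switch the treatment to the
50 km disc (`fifty_km`).

Analysis weights multiply the survey weight by the inverse of the fraction
of the relevant population interviewed per (country, survey, sex) stratum,
then are normalized to mean 1. The normalization does not change point
estimates or cluster-robust standard errors (both are invariant to weight
scale, which the tests assert); it only stabilizes numerics.

## Estimation

The estimating equation for years of schooling $y_{ilcmt}$ of individual
$i$ in cluster $l$, country $c$, birth month $m$, birth year $t$ is

$$y_{ilcmt} = \beta_1 A_{lct} + \boldsymbol{\beta} \mathbf{X}_{ilct}
  + \gamma_{lc} + \lambda_{ct} + \tau_{cm} + \epsilon_{ilcmt},$$

with cluster fixed effects $\gamma_{lc}$, country-by-birth-year effects
$\lambda_{ct}$, country-by-birth-month effects $\tau_{cm}$, controls
$\mathbf{X}$ (household size, head's age and sex, mother-in-household,
wealth index, and age-6 nightlight/rainfall/temperature), estimated by
weighted least squares separately by sex, with standard errors clustered on
the survey cluster. Variants replace $A_{lct}$ with per-band indicators
$A^d_{lct}$, per-age indicators $A^a_{lct}$, or new/recurring splits; binary
outcomes (no education, incomplete primary, ever married, parent alive) use
the same right-hand side with a logit link.

Numerical machinery, chosen for exact reproducibility:

* **Fixed-effect absorption** is by weighted alternating projections
  (iterated within-transformation) to a max-absolute-change tolerance of
  `1e-8`, capped at 1000 sweeps (non-convergence is an error, not a
  warning). Observations that are singletons in any FE dimension are
  removed iteratively first. Tests require equality with full
  dummy-variable WLS to `1e-6` on crossed three-dimensional fixtures.
* **Collinearity** is resolved deterministically: the earliest-listed
  maximal independent set of columns is kept, later columns are dropped
  and named in the fit object.
* **Inference** is the CR1 cluster sandwich,
  $\frac{G}{G-1}\frac{N-1}{N-K}\,B^{-1} M B^{-1}$, where $K$ counts
  identified fixed-effect coefficients plus slopes. With every observation
  its own cluster this reduces exactly to HC1. Confidence intervals and
  p-values use the normal reference distribution, not a t with $G-1$
  degrees of freedom; this matters little at hundreds of clusters and
  keeps results platform-exact.
* **Logistic fits** use explicit sparse indicator encoding of the fixed
  effects (adequate at the data sizes this package targets; no
  conditional-likelihood estimator), IRLS to gradient max-norm `1e-8`
  (cap 100), with FE groups lacking outcome variation dropped before
  fitting and separation reported as an error when any coefficient passes
  15 in absolute value. A caveat inherent to this choice: with many small
  FE groups the incidental-parameter bias of the unconditional estimator
  appears; the synthetic defaults use group sizes in the hundreds, where
  the bias is negligible (and the recovery test confirms it).
* **The female-male difference** is estimated by one pooled model in which
  every treatment, control and FE dimension is interacted with sex. This
  is numerically identical to separate by-sex fits (asserted to `1e-8` in
  tests) while the shared cluster dimension makes the contrast's clustered
  SE honour any covariance between the two samples.

## The synthetic world

The generator builds countries as longitude strips with uniformly scattered
clusters; a configurable fraction of clusters are conflict *hotspots*
around which events scatter with an isotropic Gaussian (default SD 15 km).
Event counts are Poisson per hotspot-year; casualty counts are a shifted
negative binomial (minimum 1, dispersion 0.5, mean 6) — a deliberately
heavy-tailed law whose three-event exposure totals have a median near 15
with a long upper tail, matching the shape of real casualty distributions.
Geographic precision codes are drawn so that roughly a quarter of events
fail the 25 km precision filter, as in the real event data.

Schooling is assembled additively: baseline (6.5 years) + cluster effect
(SD 1) + country-by-birth-year effect (SD 0.5) + country-by-birth-month
effect (SD 0.1) + covariate effects + the planted sex-specific exposure
effect (defaults $\beta_F = -0.38$, $\beta_M = 0$) + noise (SD 2), truncated
to $[0, 25]$ and rounded half-up to whole years, since surveys record single
years. A separate logistic channel plants an odds ratio (default 1.87) of
age-6 exposure on having *no* education; respondents drawn into that
category get zero years. Binary outcomes (ever married, mother/father
alive, attending school) come from logistic models with configurable
exposure log-odds. The default hotspot fraction (0.15) and event rate (0.6
per hotspot-year) put the realized exposure rate near 21% of respondents.

Defaults were chosen once to represent the study conditions and are not
tuned per test. What the generator does *not* emulate: real geography and
borders, migration responses to conflict, survey non-response, spatially
correlated noise beyond the cluster effect, or conflict processes with
temporal autocorrelation. Passing recovery tests therefore demonstrate that
the estimator machinery is correct and adequately powered under the planted
model — not that the design identifies causal effects in any particular
real dataset.

Reproducibility: one master seed; the cluster, event, population and jitter
components use deterministically derived sub-streams, so identical configs
give byte-identical tables and a world can be *re-released* under different
jitter magnitudes with paired displacement draws (`jitter_clusters()`).
The jitter rule mimics DHS releases: uniform angle, uniform distance up to
2 km (urban) / 5 km (rural).

## Verification design

Because the motivating microdata are restricted, verification is by oracle
equivalence and planted-parameter recovery, at problem sizes chosen to keep
the full suite in the minutes range:

* linkage equals a brute-force all-pairs computation exactly
  (200 clusters x 500 events);
* absorbed WLS equals dummy-variable WLS (20 fixtures, three crossed FE
  dimensions), CR1 SEs equal a loop-summed sandwich to `1e-10`, and both
  match `sandwich::vcovCL` on the dummy encoding;
* with planted $\beta_F = -0.38$, $\beta_M = 0$, 200 worlds of about
  20,000 analysis rows give a mean estimate within $\pm 0.03$, CI coverage
  in $[90\%, 98\%]$ and a male type-I error near 5%. Recovery worlds use
  zero jitter and disable the no-education channel so the planted
  coefficient is exactly the estimand; jitter attenuation and the logistic
  channel are tested separately. The recovery worlds place all birth
  cohorts at ages 15-18 (the outcome window) so that the generated
  population is the analysis population; 750 clusters of 76 respondents
  with a 0.2 hotspot share keep enough clusters carrying identifying
  variation for honest CR1 coverage (the default 0.15 hotspot share, which
  matches the ~21% descriptive exposure rate, concentrates identification
  in fewer clusters than the coverage band tolerates at this scale).
* age-specific effects planted at ages 6 and 11 (sizes chosen about four
  standard errors apart from zero so that rank errors are rare under the
  planted model) surface as the two largest estimated magnitudes in at
  least 95% of worlds; a new/recurring plant (negative new effect at 6,
  positive recurring effect at 8) reproduces the sign reversal;
* a planted no-education odds ratio of 1.87 is recovered within $\pm 0.15$
  (mean over 100 worlds of about 50,000 rows);
* increasing release jitter through 0/2/5/10 km monotonically attenuates
  the mean recovered $|\beta|$ (100 paired worlds — pairing via the shared
  jitter stream makes the comparison sharp);
* the mortality arithmetic reproduces closed-form hand computations to the
  unit.

## Mortality counterfactual

Let $p$ be the fraction of mothers exposed to school-age conflict, $\Delta$
their schooling loss in years, and $q$ the proportional reduction in
under-5 mortality per additional year of maternal schooling. Under the
assumptions that exposure is unrelated to selection into motherhood, that
the adolescent schooling loss persists to motherhood, that estimated
effects transfer across cohorts and countries, and that exposed and
unexposed mothers share observed birth and death rates, observed deaths
$D_t$ split as

$$\text{excess}_t = D_t \cdot p \cdot f(\Delta, q), \qquad
  f(\Delta, q) = 1 - (1 - q)^{\Delta} \;\text{(compound, default)}
  \;\text{or}\; \Delta q \;\text{(linear)}.$$

The compound form treats $q$ as a per-year multiplicative gradient, the
linear form is its first-order expansion; in the parameter region of
interest ($\Delta \le 1$, $q \le 0.05$) they differ by under 1%, and both
are exposed because the choice is not determined by the published gradient
alone. Low/high series propagate the CI endpoints of $\Delta$ and $q$ and
the low/high deaths series monotonically. Deaths may be given directly or
as rate x population; the two paths agree exactly on consistent inputs.

With $D = 10^6$, $p = 0.21$, $\Delta = 0.38$, $q = 0.0304$:

```{r mortality}
inp <- mortality_inputs(years = 2019, deaths = 1e6, p = 0.21,
                        delta = 0.38, q = 0.0304)
counterfactual_deaths(inp, "compound")$excess
counterfactual_deaths(inp, "linear")$excess
```

## Heterogeneity splits

Cluster classifications follow the survey's own structure: urban/rural from
the sampling frame; wealth quartiles from cluster-mean wealth index (or a
nightlight column) cut at type-1 (inverse-ECDF) quartiles over the clusters
in the regression sample, boundary values to the lower quartile — a rule
that is invariant to monotone transformations of the wealth measure;
baseline-education quartiles from cluster-mean schooling of women aged
40–50 (the mothers' generation; clusters without such women are excluded
from this split only); a gender-gap split at the median admin-2 gap (mean
male minus mean female schooling over all sampled respondents — the
pragmatic reading of "all sampled"); and a country-to-region map (a
synthetic three-region default stands in for published region tables,
which are user-supplied in real use). Quartiles are unweighted over
clusters. Subset fits recompute fixed effects and renormalize weights
within the subset; subsets too small to identify the treatment are skipped
and recorded rather than reported as zero.

## Known limitations

* The spherical distance and the single-year event timestamp are coarser
  than reality; both match the resolution of the emulated sources.
* CR1 with a normal reference undercovers slightly when few clusters carry
  identifying variation; the acceptance band (90–98%) reflects this
  honestly rather than hiding it behind a t correction.
* The logistic path materializes FE indicators; with tens of thousands of
  groups a conditional or absorbed logit would be needed.
* The mortality calculation is an accounting identity under strong stated
  assumptions, not an estimated model; its bounds propagate input CIs and
  nothing else.
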