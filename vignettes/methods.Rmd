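---
title: "Methods: synthetic community food environments and multilevel diet models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic community food environments and multilevel diet models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodenv)
```

## What the package models

`foodenv` implements a complete, testable pipeline for studying how the
retail food environment of a city relates to residents' diet quality:

1. a **synthetic city generator** producing neighbourhood polygons with
   census attributes, a registry of named food establishments, and a
   nested survey sample with a known generative truth;
2. a **grid-covering query engine** that retrieves establishments from
   an abstract point-of-interest provider and de-duplicates the raw
   results;
3. a **term-inventory classifier** mapping establishment names and
   provider type labels to eight outlet categories and three health
   groups;
4. **neighbourhood metrics**: establishment densities per km²,
   population density, and a composite social environment index (SEI);
5. **survey outcome** derivation (non-daily fruit/vegetable
   consumption) with bivariate descriptives; and
6. **two-level random-intercept logistic models** of the outcome on
   z-scored densities, estimated by adaptive Gauss–Hermite quadrature
   (AGHQ), under a progressive three-model adjustment strategy.

Real data of this kind — commercial map extractions, census
microgeography, national health surveys — are typically proprietary.
The generator therefore stands in for them with the same statistical
structure, so every downstream stage can be verified against known
ground truth. No claim is made that the synthetic numbers reproduce any
particular real-data estimate; what is checked is the *machinery* and
its statistical properties (completeness, conservation, unbiased
parameter recovery, nominal CI coverage).

## The synthetic city

**Neighbourhoods.** Each city is tiled with square cells of side
`cell_size_km` (default 0.45 km, giving ≈0.2 km² units, the size of a
census tract of roughly 700 households) on planar km coordinates.
Default scale is 2,442 neighbourhoods split 1,700/386/356 across three
cities. Population density is lognormal (default median ≈9,810
persons/km², `sdlog` 0.6); population = density × area. Four census
dimension scores (interpreted as sanitation, housing, employment,
education) are generated to correlate with log population density at
`sei_popdens_correlation` (default 0.3) and stored on an arbitrary raw
scale, as census variables would be.

Planar rectangles rather than lon/lat polygons are a deliberate choice:
every computation in the pipeline is area- or containment-based, so
projection machinery would add complexity without changing any result.
The metrics and dedup layers still accept a declared CRS flag
(`"planar_km"` or `"lonlat"`), and distance switches to haversine for
geographic coordinates.

**Establishments.** Per-neighbourhood counts are negative binomial
(size `nb_dispersion` = 1.2) with mean
`establishments_per_capita × population × exp(density_sei_gradient × SEI)`.
The overdispersion reproduces the heavy right tail seen in real
registries (means well above medians; many zero cells for rare
categories), and the positive SEI gradient (default 0.3) the empirical
pattern that denser, more favourable-environment neighbourhoods carry
several-fold higher outlet density. Categories are drawn from
`category_mix`, whose default mirrors a realistic registry: about
two-thirds ready-for-consumption outlets, ~11% small food retail, and
only ~1% each of fruit/vegetable stores and fast-food chains. Names are
a category term plus a proper noun ("Supermercado El Sol"); provider
labels are category-consistent subject to `label_noise_rate` (default
5%); a fraction `ambiguous_fraction` (default 3%) gets term-free names
and uninformative labels, which is what ultimately populates the
unclassified residue.

**Participants.** `n_participants` (default 1,275) respondents are
assigned uniformly to `participant_neighbourhoods` (default 319)
randomly chosen neighbourhoods. The binary outcome is drawn from
logit P(non-daily) = intercept + β_exposure·z(exposure density) +
β_age·z(age) + β_male·male + β_educ·low-education + u_j,
u_j ~ N(0, σ_u²). Defaults: β_exposure = 0.18 (OR ≈ 1.20 per SD),
β_age = −0.5, β_male = 0.75, β_educ = 0.3, σ_u = 0.5, female share
61.6%, below-secondary education 56.2% — the direction and rough
magnitude of the associations such surveys report (non-daily
consumption more common in men, younger adults and lower education).
The intercept default (−2.228) is calibrated by numerically averaging
the inverse logit over the covariate and random-intercept distribution
so the *marginal* prevalence is 17.3%; with a nonzero σ_u the marginal
prevalence is not `plogis(intercept)`.

Weekly fruit/vegetable day pairs are back-filled from the binary
outcome, uniformly over the admissible lattice points (sum ≥ 7 for
daily, ≤ 6 for non-daily, each component 0–7). This inverts the
derivation rule used in analysis and guarantees consistency between the
generated days and the generated outcome by construction.

**What the generator does not emulate.** Street networks and
travel-time access, store openings/closures over time, survey weights,
spatial autocorrelation beyond the shared random intercept, and
misreporting of diet. Passing tests therefore demonstrate correctness
of the algorithms and estimators under clustered sampling — not that
real food environments behave like the synthetic one.

## Acquisition and classification

The query grid is a regular lattice at `spacing` covering each city's
bounding box inclusive of edges; the invariant
`search_radius ≥ spacing/√2` guarantees the union of search discs
covers the box, so completeness failures can only come from the term
list, not geometry. Every term is searched at every point; the raw
concatenation is de-duplicated by provider id (first occurrence wins),
and id-less records merge when normalized names are equal within 25 m
(configurable) — far enough to absorb geocoding jitter, near enough to
keep two branches of a chain distinct. Name normalization lowercases,
folds Spanish accents, strips punctuation and collapses whitespace, so
"Almacén" and "almacen" compare equal. A failed provider call is
retried once, then skipped with a warning; the run continues.

Classification is name-first: inventory terms are matched in the
normalized name on **word boundaries** (so a term like "market" can
never fire inside "minimarket"), the highest-priority hit wins, ties
broken by longest term then lexicographic order — making multi-term
names deterministic. Only if the name carries no term do the provider's
primary, then secondary, type labels decide; otherwise the record is
unclassified. The enumeration has **eight** categories under three
health groups (fruit/vegetable stores and fresh food retail = most
healthy; small food retail, supermarkets and ready-for-consumption =
mixed; candy/ice-cream, fast-food chains and convenience stores = less
healthy); the shipped Spanish inventory (~60 terms) is a replaceable
stand-in, so category proportions on any real registry are not claimed
reproducible. Unclassified records are never silently dropped: they
count toward total density, are excluded from stratified outputs, and
are emitted as a review queue with nearest-miss terms (edit distance),
an automatable surrogate for manual review.

## Neighbourhood metrics

Density is count/area (km²). Unclassified establishments enter the
total density only. Point-in-polygon assignment uses closed rectangle
containment with a deterministic tie-break — a point on a shared
boundary goes to the lexicographically smallest neighbourhood id.

The SEI z-scores each dimension **pooled across all cities** (so city
medians are comparable on one common scale), optionally sign-flips
deprivation-coded dimensions via a direction configuration (default:
all four already point "higher = better"), and averages with equal
weight. Z-scoring absorbs any affine rescaling of an input dimension.
Quartile tables use the type-7 (linear interpolation) quantile
convention — R's default, documented because the choice affects bin
edges; heavy ties collapse bins with a warning rather than failing.

## Survey outcome

Records missing age, gender, education or either weekly FV item are
excluded, with per-field counts logged. Weekly fruit and vegetable days
are summed and **capped at 7**; non-daily means a capped sum below 7.
The cap's semantics are applied verbatim: fruit on 4 days plus
vegetables on 3 counts as daily even if the two never coincide on a
day. Education is carried twice: the 4-level variable for descriptive
tables, the binary below-secondary recode for the models. Bivariate
comparisons use the chi-square test without continuity correction
(categorical) and the Mann–Whitney U test with normal approximation and
tie correction (continuous); both choices are stated because neither is
forced by the data.

## The multilevel model

For individuals i nested in neighbourhoods j:

$$\operatorname{logit} P(y_{ij}=1) = \mathbf{x}_{ij}^\top\beta + u_j,
\qquad u_j \sim N(0, \sigma_u^2).$$

The marginal likelihood integrates each group's Bernoulli-logit
likelihood over $u_j$. This integral is evaluated by **adaptive**
Gauss–Hermite quadrature: per group, a Newton search (the integrand is
strictly log-concave, so this is globally convergent) finds the
conditional mode, the curvature there sets the scale, and the
Gauss–Hermite nodes are centred/scaled accordingly; one node is exactly
the Laplace approximation. 15 nodes are the default — estimates change
by less than 1e-4 relative against 25 nodes on standard fits, which is
the documented stability criterion. The log-sum-exp trick guards the
per-group collapse.

Maximization is quasi-Newton (BFGS) over $(\beta, \log\sigma_u)$; the
log parameterization keeps the variance positive without constraints,
and a near-zero $\hat\sigma_u$ is flagged as a boundary fit.
Initialization is deterministic: $\beta$ from an ordinary logistic fit,
$\log\sigma_u = \log 0.5$. `fix_sigma_u = 0` collapses the model
*exactly* to ordinary logistic regression (used as an oracle check).
Standard errors are Wald from the numerically differentiated Hessian;
odds ratios are `exp(coef ± 1.96·SE)`. AIC is `2k − 2ℓ` with k counting
the intercept, slopes, and the variance parameter when estimated.
Profile-likelihood intervals and random slopes are out of scope.

All continuous independent variables (the exposure density, age,
population density, SEI) are z-scored in the analytic sample, so every
OR is per 1 SD; gender enters as male vs female (reference female) and
education as the binary recode (reference completed secondary or
above). The progressive sequence — model 1 unadjusted, model 2 + age,
gender, education, model 3 + population density and SEI — is fitted on
the identical sample so AICs are comparable.

The estimator is authored in the package because it *is* the analysis
core; `lme4::glmer(nAGQ = 15)` serves as an independent cross-check in
the test suite (agreement to ~1e-3 on coefficients, σ_u and
log-likelihood) and a dense-trapezoid integration oracle verifies the
AGHQ log-likelihood to 1e-6 at fixed parameters on small instances.

## Verification strategy and problem sizes

The test suite checks, among others: seeded determinism of every
generator stage; exact registry recovery by the grid query on a
5,000-outlet registry (set equality after dedup); classifier count
conservation and order-invariance on every fixture; exhaustive
enumeration of the 8×8 day-count lattice; the closed-form marginal
prevalence against simulation; parameter recovery for the exposure
effect (100 replicates at n = 5,000 in 250 neighbourhoods, truth
β = 0.18, σ_u = 0.5: mean estimate within 2 Monte-Carlo SEs, 95% CI
coverage between 90% and 99%); and the Q4 > Q1 social-gradient contrast
in ≥95% of 200 replicates. These sizes were chosen to make Monte-Carlo
error small relative to the tolerances while keeping the suite quick to
run on a single CPU. `scripts/acceptance.R` runs the full default-scale
pipeline (2,442 neighbourhoods, ≈50,000 establishments, 1,275
respondents) and reports its headline quantities.

## Known limitations

- Neighbourhood geometry is restricted to axis-aligned rectangular
  cells; arbitrary polygons (real census tract shapes) would need a
  general point-in-polygon routine and are out of scope.
- Wald intervals can undercover when the number of groups is small or
  σ_u is near the boundary; the coverage test operates at 250 groups.
- The shipped term inventory is a compact stand-in; applying the
  classifier to a real registry requires the user's own inventory.
- With a single establishment registry per run, exposure densities are
  measured, not latent; classification noise (label noise, ambiguous
  names) attenuates exposure effects slightly, which is visible if
  recovery is attempted with nonzero noise rates.
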