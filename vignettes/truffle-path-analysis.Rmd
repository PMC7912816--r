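---
title: "Path analysis of truffle fruitbody development with trufflepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path analysis of truffle fruitbody development with trufflepath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trufflepath)
```

## The scientific problem

Black truffle fruitbodies develop through ordered morphogenetic stages:
the mating event fixes where in the soil profile the fruitbody will sit
(fruiting depth), the growth stage determines fresh weight and shape, and
the maturation stage sets spore pigmentation and, indirectly, the harvest
date at which dogs can locate the ripe fruitbody. Harvest surveys record
one row per fruitbody: dig identifier and type (one fruitbody per dig, or
a cluster of several), soil typology (a peat-based substrate amendment or
the bulk soil of replicate blocks), harvest date, depth class in 10-cm
intervals, fresh weight in grams, a nine-category shape index, and — for
single fruitbodies — a spore maturity index, the proportion of at least 50
sampled asci containing mature spores.

The question the package addresses is *causal*: do characters fixed at one
stage influence characters of later stages? Because the characters have
different supports and error structures (counts, positive continuous,
bounded proportions), and because candidate hypotheses differ in their
graph structure rather than in a single parameter, the appropriate
machinery is the d-separation (d-sep) method of path analysis — piecewise
testing of a directed acyclic graph — rather than a classical
covariance-based structural equation model.

## The d-sep procedure

For a candidate DAG the package:

1. **enumerates the Shipley basis set** (`basis_set`): one independence
   claim per non-adjacent vertex pair, conditioned on the union of both
   vertices' parents. Several valid basis constructions exist in the d-sep
   literature; this one is used because it is the standard choice of the
   piecewise-SEM tradition and reproduces the published test degrees of
   freedom of all eight built-in candidate models (df = 2k with
   k = C(|V|, 2) − |E|). Within a claim, the member later in topological
   order is designated the response for regression-based testing; the test
   is asymptotically symmetric in the pair, so the fixed rule only serves
   determinism.
2. **computes each claim's null probability** (`test_claims`). The default
   engine is the partial correlation of the pair given the conditioning
   set, computed from the residuals of linear projections, with the exact
   Student-t reference distribution; variables enter on their analysis
   transform scale (weights log-transformed; depth class and shape index
   treated as numeric, the information-preserving reading of ordinal
   intervals). A second engine fits a generalized regression in the
   response's family (identity-link Gaussian, log-link Poisson or Gamma)
   and uses the Wald p-value of the other pair member. In the
   linear-Gaussian case the two engines agree to numerical precision; the
   choice is a flag because the claim-testing engine behind published
   tables of this kind is usually not stated.
3. **combines the probabilities into Fisher's C** (`fishers_c`):
   C = −2 Σ ln p_i ~ χ²(2k) under the model. A claim p-value that
   underflows to zero is floored at the smallest representable positive
   number with a warning — C is then effectively infinite and the model is
   reported inconsistent, rather than propagating an infinity.
4. **ranks consistent models** (`compare_models`): models with P ≤ α
   (α = 0.05 by default, configurable) are excluded from the weighting,
   matching the convention of leaving K, AICc and W blank for rejected
   models; among the rest, AICc = C + 2Kn/(n − K − 1) and Akaike weights
   are computed. K (`count_parameters`) sums the estimated parameters of
   the structural equations — intercepts, coefficients, and effective
   degrees of freedom of smooth terms, so K is generally fractional.
   Intercept-only equations of parentless vertices are not counted by
   default: the K census behind published tables of this kind is not
   documented, both conventions are defensible, and the default is the
   smaller census with a switch (`count_parentless = TRUE`) for the other.

The d-separation decision itself (`d_separated`) runs by reachability on
the moralized ancestral subgraph (the Bayes-ball-equivalent algorithm);
an exhaustive path-enumeration oracle is kept in the test suite only,
where the two implementations are compared on hundreds of random DAGs
under every conditioning set.

## Fitting the paths of a selected model

`fit_structural_equations` fits one regression per child vertex with
`mgcv::gam`: Gaussian for log-weight and maturity, log-link Poisson for
depth class and shape index (checked for overdispersion via the Pearson
statistic, warning above a ratio of 1.5), log-link Gamma for the combined
weight of the non-largest cluster members. Predictors enter through
penalized thin-plate smooths so relationships may be non-linear.

Numerical choices, made once and documented here:

* **Basis dimension k = 4** per smooth. The relationships of interest are
  smooth monotone or single-bend curves; k = 4 (three effective df at
  most beyond the constant) is enough to express them without inviting
  wiggle, and keeps the parameter census K interpretable.
* **Smoothness by REML.** REML penalizes overfitting of null terms more
  reliably than GCV; a predictor with no real effect is shrunk to an
  essentially linear term of ~1 effective df.
* **No standardization.** Variables keep their original units (days,
  grams, class indices) so fitted shapes remain directly interpretable;
  relative importance is compared through deviance, not coefficients.
* **Percent deviance explained** (`deviance_explained`):
  D² = 100 (dev_reduced − dev_full) / dev_null, where the reduced model
  drops one term while every remaining smooth keeps the smoothing
  parameter estimated in the full fit. Freezing the penalties makes the
  reduced model nested in the full one, so D² is non-negative; tiny
  negative values from floating-point noise are floored at zero. For a
  single linear Gaussian predictor D²/100 equals the OLS R² exactly.
  Following the reporting convention of the field's path tables, D² is
  reported only for terms with p below 0.05 (configurable); other cells
  print `-`.
* **Degenerate inputs.** A constant response, a predictor collinear with
  its conditioning set, zero null deviance, or a non-positive response
  under a log-link family each raise an informative error naming the
  variable or claim; ties for the largest cluster member are broken by
  record order, deterministically.

## The PLS weight estimator

Cluster fruitbodies of one survey season lack direct weight measurements;
their fresh weight is imputed from caliper diameters. `fit_pls` implements
univariate partial least squares (orthogonal-scores NIPALS) of weight on a
geometric feature recipe: dmax, dmin, their squares, their product, and
the two cubic products dmax²·dmin and dmax·dmin². The seven features span
an ellipsoid-volume relationship (with the middle axis near the mean of
the measured two, volume is a linear combination of the cubic terms) and
support the seven-component fit; the published description of the original
estimator names only the two diameters as its main inputs, so this recipe
is a documented reconstruction and fully configurable. Features and
response are centered (features also scaled) internally, so predictions
are invariant to centering conventions; with all components the fit
coincides with least squares on the feature span, which is what makes it
robust to duplicated or collinear features. Weight is modelled on the gram
scale; validation (`validate_pls`) regresses log observed on log predicted
weight in held-out records and reports R², slope and p-value, excluding
non-positive predictions with a warning before taking logs.

## What the synthetic generator emulates — and what it does not

`simulate_harvest` draws whole harvest datasets from an explicit true DAG
(`simulation_scenario`). It emulates the survey design of a two-season,
seven-survey-per-season campaign across four soil typologies, with
harvesting dates on the survey-day grid; a shifted-Poisson depth class
(support ≥ 1, mean class ≈ 1.8); log-normal weights around ~20 g;
a truncated-Poisson shape index on 1–9, redrawn (not clipped) outside the
range to avoid boundary inflation, with a warning if more than 20% of
draws are discarded; maturity as a logistic-in-date mean with Gaussian
noise clipped to [0, 1], so early-season fruitbodies are immature and
late-season ones ripe; and Gamma-distributed combined remaining-member
weight in clusters, decomposed into at least one member via a Dirichlet
split constrained below the largest member's weight (member counts from a
shifted geometric distribution, mean ≈ 2.7). Caliper diameters derive
from weight through the ellipsoid relation with a configurable
multiplicative noise on the volume, which is what makes the PLS recipe
exactly identifiable at zero noise. Preset effect sizes
(`preset_scenarios`) follow the field pattern — weight strongly negative
on shape, harvest date strongly positive on maturity and weakly negative
on weight, the remaining-members weight strongly positive on the largest
member — with magnitudes chosen so each path explains a realistic share of
response deviance (a few percent for date effects, ~15–30% for the strong
paths, ~40–50% for maturity).

The generator does **not** emulate spatial structure (tree positions,
block layout effects), weather forcing, year-to-year differences, sampling
heterogeneity of the maturity index within a fruitbody, or measurement
error in depth and shape scoring. Passing tests therefore demonstrate that
the pipeline is correct and calibrated under its own distributional
assumptions — not that those assumptions hold in any particular orchard.
One RNG stream per dataset, keyed by the scenario seed, makes every
dataset bit-reproducible.

## Calibration and recovery properties

The test suite verifies, at fixed seeds:

* type-I calibration of the full d-sep test: simulating from the
  single-fruitbody model A DAG (linear-Gaussian, n = 200, 1000
  replicates), Fisher's C rejects at α = 0.05 in ~4.6% of replicates and
  the claim p-values are uniform (Kolmogorov–Smirnov);
* structure recovery: simulating from the cluster model D preset (n = 300
  digs, 200 replicates), model D takes the top Akaike weight in ~80% of
  replicates. The margin over its supermodel E is governed by the AICc
  penalty of E's two extra (truly null) depth terms versus the χ²₄
  contribution of the two claims D tests and E does not — which is why
  the effective-df accounting of smooth terms matters to model selection;
* exact reproduction of published deterministic surfaces: the test df of
  all eight candidate DAGs, chi-square tails of published (C, df) pairs,
  and Akaike weights recomputed from published AICc columns.

Problem sizes in the routine suite (hundreds of replicates, n of a few
hundred) are chosen to keep the full run in minutes while leaving Monte
Carlo error well inside the asserted bands.

## Known limitations

* The claim-test engine behind the published comparison tables is not
  documented; both plausible engines are implemented and agree in the
  Gaussian case, but family-specific claim testing can shift borderline
  p-values.
* Published K and AICc values depend on the original field data and are
  not reproducible from scratch; only P-from-C and weights-from-AICc are
  exact reproduction surfaces (and the published W entries that are not
  robust to the one-decimal rounding of the printed AICc column are not
  asserted).
* Cyclic models, latent variables, equivalence-class reasoning and
  structure learning are out of scope; candidate DAGs must be supplied.
* The cluster analyses drop maturity (unavailable for cluster members in
  the emulated protocol) and summarize each cluster as largest member plus
  combined rest — within-cluster member-level structure beyond that
  summary is not modelled.
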