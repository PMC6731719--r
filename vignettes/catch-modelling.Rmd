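---
title: "Modelling Malaise-trap catches: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Malaise-trap catches: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malaisecatch)
```

## The problem

Malaise traps are passive tents that intercept flying insects; each trap
accumulates a catch between service visits, so the unit of observation
is a *sample*: one trap over one service interval of roughly two weeks.
`malaisecatch` models how such catches of rare tropical insects — its
motivating system is the parasitoid wasp subfamily Rhyssinae in a
year-long, 34-trap campaign in Ugandan rainforest spanning a
successional gradient from primary forest down to farmland — depend on
four ecological drivers: the date within the sampling year, rainfall
during the interval, the amount of clearly decaying wood around the
trap (rhyssines parasitize wood-boring larvae), and the forest's
successional type.

## The model

For each species the expected catch of a sample is

$$
\mathbb{E}[\text{Catch}] = \text{days} \cdot
\exp(a_1 + a_2\,\text{date} + a_3\,\text{rain} + a_4\,\text{deadwood} +
a_{\text{foresttype}}),
$$

with negative-binomial (NB2) errors, variance $\mu + \mu^2/\theta$.
The covariates are:

* **days** — sampling effort in fractional days, entering as a fixed
  offset ($\log \text{days}$ on the linear-predictor scale), so the
  model is a daily catch *rate* model;
* **date** — days from a reference instant (default 1 September 2014
  00:00 UTC, configurable) to the midpoint of the interval;
* **rain** — the unweighted mean of daily rainfall (mm/day) over every
  calendar day whose 24-hour window intersects the interval.  Partial
  first and last days count fully; at a ~14-day service interval the
  difference from duration-weighting is negligible, and the unweighted
  mean is the simplest reading of "average daily rainfall";
* **deadwood** — $\sum \mathrm{dbh}^2 / \mathrm{distance}$ over the
  *clearly decaying* trees (decay level 3 of 3) in the two 50 × 2.5 m
  transects centred on the trap.  Dbh is recorded in cm but enters the
  score in metres (units m²·m⁻¹), which puts the study-scale anchor —
  the top trap's score of 0.27 — at the right magnitude; a
  `dbh_scale` argument restores the cm convention if a campaign's
  deposited covariates use it.  Decay levels 1–2 and living trees
  contribute nothing;
* **forest type** — a closed five-level factor (primary, swamp,
  disturbed, clearcut, farm), dummy-coded with primary forest as the
  all-zero reference, so $a_\text{primary} \equiv 0$ and
  $\exp(a_\text{type})$ is the catch relative to primary forest.

### Fitting

`fit_species()` maximises the NB2 likelihood per species.  The
implementation (compiled code) stabilises a crude Poisson start with
two passes of IRLS alternated with a profile update of $\theta$, then
switches to a joint Newton iteration on $(\beta, \log\theta)$ whose
convergence is decided by the Newton decrement — the attainable
remaining likelihood gain — rather than by step-to-step likelihood
change, which can stall far from the optimum on ridged surfaces.
Numerical choices that matter:

* Every coefficient is constrained to $[-15, 15]$.  A habitat with no
  catches at all (the field data's farmland) drives its dummy towards
  $-\infty$ (complete separation); the fit pins it at $-15$, flags it
  `separated`, and reports its relative catch as 0.  This reproduces,
  in controlled form, the large negative farmland values a
  conventional fit reports as convergence artefacts.
* $\theta$ is profiled over $[10^{-2}, 10^{4}]$.  The upper bound is
  numerically Poisson for catch-sized means; the lower bound is the
  coarsest dispersion meaningfully estimable from a campaign of this
  size, and also prevents a degenerate $\hat\theta \to 0$ null fit
  from generating astronomically heavy-tailed resamples.
* $\theta$ is re-estimated under every nested model, so likelihood
  ratios compare fully maximised models.
* Directions with numerically zero curvature (e.g. the dummy of a
  level absent from a subset design) are frozen rather than solved
  through, and standard errors come from the Fisher information of the
  non-separated coefficients.
* Convergence tolerance is $10^{-8}$ (relative), with at most 200
  outer iterations; species below 10 individuals are fitted and pooled
  into assemblage statistics but flagged `low_n`, mirroring the
  field study's display rule.

### Inference: summed likelihood ratios against a site-resampled null

The significance of one ecological variable, for one species, is the
likelihood ratio between the full model and the model with that
variable removed (all four forest dummies drop jointly).  The
assemblage-level statistic is the *sum* of the species-wise ratios.
Both are referred to a null distribution built by resampling trap
sites, which preserves the within-site dependence that would wreck an
iid resampling scheme:

1. fit the null model per species; compute randomized
   probability-integral-transform (PIT) residuals $u_{is}$, uniform
   under the null;
2. draw site blocks with replacement; each target block takes the PIT
   rows of its donor block (rows recycled cyclically when block sizes
   differ — a deterministic mapping, which is what makes exhaustive
   enumeration of assignments well-defined);
3. invert the relocated residuals through each row's null fitted
   NB distribution to get integer counts, refit both models (warm
   started), and recompute the statistics.

p-values use the add-one rule $(1 + \#\{\text{resampled} \ge
\text{observed}\})/(B+1)$, so no p-value is ever 0 and the floor is
$1/(B+1)$; the default is $B = 999$.  Pairwise forest-type contrasts
use the same machinery with the null model formed by merging the two
levels into one.  **No multiple-testing adjustment is applied
anywhere**, deliberately: with catches this sparse, controlling
family-wise error would cost an unacceptable number of false
negatives, so the output may contain false positives and the report
says so in its footer.

Design choices that were genuinely open:

* "Resampling trap sites" is read as resampling *residual blocks* at
  the site level (10 blocks), not the 34 traps; a `blocks = "trap"`
  switch and a `scheme = "parametric"` bootstrap (independent NB draws
  from the null fits) are provided as alternatives.  Residual block
  resampling is the default because it preserves within-site
  dependence without assuming the null fits capture it.
* Whether resamples are shared across terms is unspecified upstream;
  each `term_test()` call draws its own resamples from its own seed,
  so sharing is the caller's choice of seeds.
* Warm-started resample refits run under a bounded iteration budget
  (default 25 outer iterations, against 200 for observed fits).
  Rarely-caught species resampled under the null are frequently
  quasi-separated — their maximum sits at a box corner approached
  arbitrarily slowly — and the budget makes the refit cost predictable.
  Budget-capped refits are counted into the null at their capped
  solution and tallied in the result; the same budget applies to every
  resample, so the statistic is one fixed functional of the data.
* `enumerate_null_exact()` exhaustively enumerates all $k^k$ block
  assignments for designs with at most 4 blocks and shares the PIT
  matrix with the Monte-Carlo path when seeded identically; it exists
  purely as a verification oracle for the resampler.

## The synthetic campaign generator

`make_default_scenario()` encodes a campaign with the structure of the
2014–2015 field study: 10 sites over the five forest types, 34 traps,
service every 14 ± 2 days from 8 September 2014 to 14 September 2015,
two wet seasons (March–May, September–November), and six species.  The
four well-sampled species carry the published coefficient vectors as
their generating truth; the two rare species' intercepts were
calibrated once against the analytic expected total catch so their
expected campaign totals are ≈ 6 and ≈ 1 individuals, echoing the
study's rarest species, and then frozen.

Generator components, and what they do and do not emulate:

* **Weather** is zero-inflated gamma rain with separate wet/dry-season
  regimes (wet: p = 0.6, shape 0.9, scale 13 mm; dry: p = 0.3, shape
  0.8, scale 8 mm — roughly 1600 mm/year, a realistic mid-altitude
  East African profile).  The fitted model only consumes mean rain per
  interval, so no attempt is made at rainfall autocorrelation.
* **Landscape**: per-trap dead-wood scores are log-normal per forest
  type (medians 0.27 / 0.20 / 0.15 / 0.08 down the gradient, log-sd
  0.5; farmland exactly 0 with *no* transect trees, so the covariate
  pipeline's "trap with no tree records" warning path is exercised by
  every default campaign).  Tree lists are constructed so that
  `deadwood_score()` recovers the drawn score exactly, with live and
  lightly-decayed distractor trees added.  The log-sd 0.5 keeps the
  spread realistic: the published top score is 0.27, and a heavy upper
  tail combined with dead-wood coefficients of 3.5–4.4 would produce
  biologically absurd expected catches.
* **Counts** are NB2 draws around the model mean, optionally times a
  shared log-normal site effect (default sd 0.3 per site and species).
  The site effect is what gives the site-resampled null something real
  to protect against; setting it to 0 recovers the iid world in which
  model-based standard errors are exactly calibrated.
* **Not emulated**: spatial autocorrelation between sites, phenology
  beyond the log-linear date term, trap wear, and the true (deposited
  but not printed) covariate distributions of the field campaign.
  Passing the simulation-based tests therefore demonstrates that the
  pipeline recovers what it assumes, not that the field data meet
  those assumptions.

## What the heavier checks compute, and at what size

The acceptance-style tests in `tests/testthat/test-acceptance.R` run:

* coefficient recovery on 100 campaigns at 5× the study's trap count
  (~4 400 samples each), checking median relative error of the date
  and dead-wood coefficients across the four displayed species, plus
  pooled ±2 SE coverage of the non-separated coefficients.  Under the
  default site effect (sd 0.3), model-based SEs of site-constant
  covariates undercover — the clustering is exactly what the
  resampling test exists for — so the coverage band is the strictest
  check in the suite;
* type-I error of the summed-LR test on 200 campaigns with the rain
  coefficients zeroed (B = 199), expecting the 5% rejection rate
  within its binomial band;
* power at the published effect sizes on 50 campaigns (B = 99, p
  floor 0.01), expecting every one of the four variables detected in
  at least 90% of replicates;
* oracle agreement of the likelihood (explicit lgamma arithmetic), of
  the fits (grid + Nelder-Mead polish on small fixtures), and of the
  Monte-Carlo p-values (exhaustive 27-assignment enumeration on a
  3-site toy).

These sizes were chosen so the full suite runs on one CPU in well
under half an hour while keeping every check at the scale the
statistics require.

## Limitations

* The dead-wood unit convention of the published coefficient table is
  internally inconsistent (a cm²·m⁻¹ header against a score of 0.27
  at a trap flanked by a large fallen log); the package adopts the
  m²·m⁻¹ reading and exposes `dbh_scale` for the alternative.
* The fitted model has no zero-inflation, no mixed effects and no
  spatial structure; the site effect is handled by the resampling
  design, not by the likelihood.
* With 10 sites the resampling null is discrete; p-values below
  ~0.001 are not resolvable at B = 999, and with very few blocks the
  test is conservative by construction.
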