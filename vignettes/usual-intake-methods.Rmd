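---
title: "Methods: substitution modeling of usual nutrient intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution modeling of usual nutrient intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealswap)
```

This vignette is the package's own account of its statistical machinery:
the measurement-error model behind usual-intake estimation, the
substitution model, the survey-variance machinery, the composite index, and
the synthetic generator the tests validate everything against — including
the places where the design was genuinely open and the choices we made
there.

## The measurement-error problem

A 24-hour recall records one day of intake. Day-to-day variation within a
person is large relative to the variation between persons, so the empirical
distribution of single-day (or two-day-mean) intakes is wider than the
distribution of usual intakes, and any tail statistic — such as the percent
of a population below an Estimated Average Requirement (EAR) — computed
from raw recall days is biased away from the truth. The classical remedy,
which this package follows, is a mixed-effects measurement-error model fit
to repeated recalls per person.

### Amount model

For daily totals $y_{ij}$ of person $i$ on recall day $j$ we fit, on a
Box-Cox transformed scale,

$$ g_\lambda(y_{ij}) = x_{ij}'\beta + u_i + \epsilon_{ij},
   \qquad u_i \sim N(0, \sigma_u^2),\;
   \epsilon_{ij} \sim N(0, \sigma_e^2), $$

where $g_\lambda$ is the Box-Cox transform ($\lambda = 0$ meaning the
log). The fixed effects always include a second-recall-day indicator and a
weekend indicator; further person-level covariates (age band, sex,
race-ethnicity, education, and so on) are supplied by name. $\lambda$ is
chosen from a grid (default $0, 0.1, \dots, 1$) by maximizing the ML
profile likelihood including the transform's Jacobian; variance components
at the chosen $\lambda$ are then re-estimated by REML (`lme4::lmer`).

**Zeros.** When an amount-only fit sees zero days, a fixed offset of half
the smallest positive observed value is added before transforming and
subtracted after back-transformation. When more than 5% of person-days are
zero, the nutrient is treated as *episodic*: positive amounts are modeled
alone and a logistic mixed model (`lme4::glmer`, adaptive Gauss-Hermite
quadrature with 7 nodes) estimates the consumption probability with its own
person random intercept $v_i \sim N(0, \tau_u^2)$. The 5% rule is a
package choice: daily nutrients (energy, sodium, ...) are consumed
essentially every day and gain nothing from the two-part path, while truly
episodic intakes need it.

**Linking the two parts.** The two submodels are linked through the
correlation $\rho$ of their person effects. A joint likelihood over a
binomial and a Gaussian response with correlated random effects is outside
what standard mixed-model software fits; we estimate $\rho$ as the Pearson
correlation of the two sets of conditional modes (BLUPs), clamped to
$[-1, 1]$. This is a moment-style estimate — shrinkage of the modes
attenuates it somewhat — but it only enters the simulation step below,
where the sensitivity of group-level statistics to $\rho$ is mild.

### From model to usual-intake distribution

Usual intake is the long-run average daily intake,
$T_i = p_i \cdot E[g_\lambda^{-1}(x_i'\beta + u_i + \epsilon)]$ with
$p_i$ the consumption probability (1 for daily nutrients). The package
simulates it per person:

1. Draw $u_i$ from its **conditional** distribution given the person's own
   data — conditional mode plus conditional SD as returned by the mixed
   model. This is a deliberate design choice over drawing from the
   population distribution $N(0, \sigma_u^2)$: under the model the two
   agree in distribution (the variance of conditional draws across persons
   is exactly $\sigma_u^2$), but conditional draws additionally make the
   degenerate limit exact — when $\sigma_e^2 = 0$ every person's usual
   intake collapses to their observed mean, which the test suite asserts to
   relative tolerance $10^{-6}$. Persons absent from the fitting data fall
   back to population draws.
2. Back-transform the conditional mean with the second-order correction
   $g_\lambda^{-1}(m) + \tfrac{1}{2}\sigma_e^2 \, (g_\lambda^{-1})''(m)$,
   the usual-intake macros' standard approach. A 9-node Gauss-Hermite
   integration is available (`backtransform = "gauss-hermite"`) and is
   tested against the exact log-scale form $e^{m + \sigma_e^2/2}$; at the
   within-person variances typical of nutrient recalls
   ($\sigma_e^2 \lesssim 0.4$ on the log scale) the two differ by well
   under one percent.
3. For episodic nutrients, draw the probability person effect from its
   conditional distribution using standard normals coupled to the amount
   draws with correlation $\rho$, and multiply.
4. Subtract the zero-offset, clamp at zero.

Fixed effects are evaluated at the usual-intake reference: the
second-recall indicator at 0 and the weekend indicator at its long-run
share 2/7 (the generator's weekday probability is 5/7); other covariates
stay at each person's own values, so group estimates are marginal over the
group's covariate distribution. Ratio quantities (saturated fat as a
percent of energy) require numerator and denominator simulated from *the
same* underlying normal draws (`simulate_usual_joint()`), preserving the
within-person coupling.

## Substitution model

Dishes are ranked per group × occasion × kind by the percent of
individuals reporting the category at least once — a person counts once per
category no matter how often they ate it. Ranking is by unweighted person
counts by default with a survey-weighted option; ties break
lexicographically so the choice is deterministic. The substitution replaces
every record of the most common main dish at the occasion with the most
common egg dish's composite per-gram profile (the unweighted mean of
per-gram densities over the distinct foods in the category):

* **gram basis** — the record's grams are kept, so grams are conserved
  bitwise;
* **calorie basis** — grams are rescaled by the ratio of source to
  replacement energy density, so each record's energy is conserved to
  floating-point accuracy.

Substituted records are relabeled to the replacement category, which makes
the operation idempotent and auditable. A plan whose most common main dish
*is* an egg category is refused rather than silently self-substituted.

## Survey variance and testing

Standard errors use balanced repeated replication: persons are paired into
pseudo-strata in enumeration order, replicate weights perturb each pair's
members by $2 - f$ and $f$ (Fay coefficient $f$, default 0) according to
the columns of a Hadamard sign matrix, and
$se^2 = \frac{1}{R(1-f)^2}\sum_r (\theta_r - \theta)^2$. Hadamard orders
are built by the Paley construction and Sylvester doubling; the matrix is
row-normalized so its first column is all ones and strata map to the
remaining columns, whose zero column-sums give the exact balance property
(the mean of a person's replicate weights equals their base weight). This
requires $R \ge$ strata $+ 1$ replicates.

Baseline-versus-modeled contrasts share persons. The conventional z-test
treats the two estimates as independent, which is conservative under the
positive correlation substitution induces; `compare_paired()` instead
re-evaluates the *difference* under every replicate, and the pipeline uses
that paired test for prevalence changes. The Bonferroni divisor defaults to
$m = 3$ (three modeled occasions per group per nutrient), giving the 0.017
and 0.003 tiers at $\alpha = 0.05$ and $0.01$.

## Total nutrient index

The index is implemented verbatim as
$\mathrm{TNI} = \sum_i (C_i / se_i) \big/ \sum_i se_i$, with
nutrients-to-limit reverse scored first. Two properties deserve explicit
documentation. First, the $se_i$ used are the BRR standard errors of the
**baseline** mean intakes — the common reference across all modeled
scenarios; the formula itself does not dictate which estimate's SE enters,
and this choice is the one the package makes. Second, the formula's
denominator is $\sum se_i$, not $\sum 1/se_i$: it is therefore *not*
invariant to rescaling the standard errors (doubling every $se$ divides
the index by four, a property the test suite asserts as stated). A
conventional inverse-variance weighted mean is available as
`mode = "normalized"` but is never the default. The leave-largest-out
sensitivity ranks nutrients by $|C_i|$ (ties lexicographic) and recomputes
the index with the top $k$ removed.

## The synthetic generator

The generator is first-class, tested code: it is the package's ground-truth
instrument. Each dish category × occasion carries a per-day consumption
probability (with a person-level logit offset for heterogeneity in *who*
eats the dish), lognormal grams with additive person and day effects on the
log scale, and a fixed per-gram density vector — exactly the structure the
two-part measurement-error model assumes, which keeps parameter recovery
well-posed. Ground truth is recorded per person (true usual intake of
every nutrient, i.e. the long-run expectation under that person's realized
effects) and per group (expected percent reporting each dish, true most
common dishes), and `true_prevalence()` evaluates any recommendation
against the true usual intakes.

Default conditions mirror the target survey's shape at desk scale: four
groups with sizes in roughly the survey's proportions (the WIC group raised
enough to stay estimable), WIC participants all women of childbearing age,
two recalls per person with an optional single-recall fraction (default 0 —
the share of one-recall respondents in the real survey is not published,
so the default assumes complete pairs), a snack ("other") occasion that
substitution never touches, and mildly unequal lognormal survey weights.

What the generator does **not** emulate — and hence what green tests do not
certify about real survey data: food-code-level heterogeneity within a dish
category (densities are constant per category, so composite-profile
averaging is exact by construction), correlated dish choices within a meal,
energy-correlated consumption probabilities, intake reporting error beyond
lognormal day-to-day noise, item nonresponse, and the survey's masked
design strata (pseudo-strata here are synthetic pairs).

The designed vitamin-D scenario (`scenario_vitamin_d_substitution()`)
inverts the closed-form prevalence expression so that swapping the cereal's
density for the egg dish's moves true EAR-below prevalence down by exactly
3 percentage points; the pipeline must recover that reduction and flag it
with the paired BRR z-test.

## Numerical choices and degenerate inputs

* Box-Cox grid $\{0, 0.1, \dots, 1\}$; profile-likelihood ties resolve to
  the first (smallest) $\lambda$.
* "Not meeting" is a strict inequality at the threshold — a measure-zero
  choice fixed for determinism.
* Back-transformed usual intakes are clamped at zero after removing the
  zero-offset.
* All-zero nutrients, single-recall-only data (within-person variance
  unidentifiable), empty groups, empty dish categories, missing
  recommendation strata, zero replacement energy density under the calorie
  basis, and non-Hadamard replicate counts all raise immediate, named
  errors rather than propagating silently.
* Monte-Carlo sizes: tests use 100–500 draws per person. Fewer than 100
  draws triggers a warning because tail statistics (prevalences) become
  unstable.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to make
Monte-Carlo error comfortably smaller than the tolerances they assert:
2,000 persons × 2 recalls for variance-component and prevalence recovery
(±15% and ±2 percentage points respectively), 100 seeded runs of 800
persons for the designed substitution scenario, 500 re-simulations for the
BRR-versus-empirical-SD comparison, and 2,000 simulations for the z-test's
type-I error at the Bonferroni threshold. At 2,000 persons the
finite-population sampling error of a lognormal mean is itself about 1.4%,
which is the dominant term in the ±2% mean-recovery check.

## Known limitations

* The amount and probability submodels are fit unweighted; survey weights
  enter at the estimation stage (group means, prevalences, BRR). Fully
  weighted pseudo-likelihood fitting with per-replicate refits would be
  the survey-exact alternative at roughly R times the cost.
* $\rho$ from BLUP correlation is attenuated relative to a joint-likelihood
  estimate; group-level means and prevalences are insensitive to this, but
  person-level joint tail statements would not be.
* The EAR cut-point method is used for all EAR nutrients, including iron,
  for which the requirement distribution in menstruating-age women is
  skewed and the cut-point is known to be biased; the full-probability
  approach is out of scope.
* Supplement intake is not modeled; estimates are food-intake-only.
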