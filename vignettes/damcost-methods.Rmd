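---
title: "Methods: estimating the state-level cost of disease-associated malnutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the state-level cost of disease-associated malnutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damcost)
```

## The model

`damcost` estimates the annual direct medical cost attributable to
disease-associated malnutrition (DAM) per U.S. state. The estimand is

$$\text{Cost} \;=\; \sum_i \sum_j C_i \cdot
\frac{PMN_{ij}\,\Delta_{MN}}{1 + PMN_{ij}\,\Delta_{MN}} \cdot
\rho_{ij} \cdot POP_j ,$$

summing over eight diseases $i$ and thirty demographic cells $j$
(age bands 0–18, 19–45, 46–55, 56–64, 65+; male/female; white/black/other).
The bracketed factor is the *cost-attributable fraction*: if a fraction
$PMN$ of patients are malnourished and each costs $(1+\Delta_{MN})$
times a non-malnourished patient, then the share of total spending
above the all-non-malnourished counterfactual is exactly
$PMN\,\Delta_{MN}/(1+PMN\,\Delta_{MN})$. This identity is what the
micro-simulation oracle tests assert: for any parameter set,
`cell_cost()` equals an individual-level enumeration with the baseline
cost calibrated so the mean is $C_i$, to relative $10^{-12}$.

Two readings of $\Delta_{MN}$ circulate: a *cost ratio*
(malnourished/non-malnourished) and an *excess ratio* (the proportional
increase). The attributable-fraction algebra is only coherent under the
excess-ratio reading — with a plain ratio the fraction would not vanish
when both groups cost the same — so `damcost` adopts it: malnourished
cost $= (1+\Delta_{MN}) \times$ non-malnourished.

Key model assumptions inherited from this design:

* national prevalence rates apply uniformly within a demographic cell,
  so state variation comes entirely from demographic composition;
* the eight diseases are treated additively (they were chosen to be low
  prevalence precisely to limit double counting of malnourished
  individuals, and no explicit comorbidity correction is applied);
* costs are nominal USD with no inflation adjustment or payer
  decomposition.

## Malnutrition classification

A person is malnourished when **weight < 90% of Hamwi ideal body
weight** and/or **serum albumin < 3.5 g/dL**. Choices the package makes
explicit:

* **Strict thresholds.** Exactly 90% IBW or exactly 3.5 g/dL is *not*
  malnourished. Generated measurements are stored rounded to 0.1 units
  inside bands disjoint from both thresholds, so classification of
  synthetic data is never a tie-break question.
* **Heights below five feet.** The Hamwi rule is only stated above
  60 in; the package extrapolates the same slope downward with a floor
  (default 50 lb, configurable) so IBW stays positive for short adults.
* **Missing albumin** makes the albumin criterion unknown: the overall
  status is `TRUE` if the weight criterion already fires, `NA`
  otherwise, and `NA` records are excluded from both numerator and
  denominator of the malnutrition prevalence (complete case). Records
  missing height or weight cannot be assessed at all and are dropped
  with a warning.
* **Children.** The adult Hamwi form is applied to the 0–18 band for
  lack of a stated pediatric rule; `estimate_pmn(exclude_children =
  TRUE)` removes that band from estimation for sensitivity analyses,
  with child entries then filled from the pooling ladder.

## Design-based prevalence estimation

Both prevalence tables use the weighted ratio estimator
$\hat p = \sum_k w_k y_k / \sum_k w_k$ over in-domain records with a
known indicator. Standard errors come from Taylor linearization within
strata and clusters: the linearized variate $z_k = w_k (y_k - \hat p)$
is totalled per cluster and the variance is
$\sum_h \frac{n_h}{n_h-1}\sum_c (t_{hc}-\bar t_h)^2 / W^2$ over strata
with at least two clusters. When every stratum is degenerate (one
cluster), the SE falls back to the weighted binomial form. Estimates are
weight-scale invariant and confined to $[0,1]$ by construction.

**Sparse cells.** $PMN_{ij}$ cells with fewer than `min_cell_n`
(default 10) contributing diseased records are filled by a deterministic
pooling ladder: all races within (age band, sex), then both sexes within
the age band, then the disease-wide marginal. The assigned rung is
chosen once from unweighted counts, so it is invariant under bootstrap
reweighting. During a bootstrap replicate a domain can still end up with
zero total weight (every cluster holding its records undrawn); the
replicate then climbs the remaining rungs rather than failing. With
original weights a non-empty domain always has positive weight, so the
deterministic run never uses this fallback.

**Routing.** Each disease declares its prevalence source: the interview
survey where its definition matches (larger sample), otherwise the
examination survey (dementia, depression). For interview-sourced
diseases the 0–18 cells fall back to the examination survey. Disease
prevalence cells are not pooled; empty cells are flagged, and a flagged
cell with non-zero population is a hard error at the burden stage rather
than a silent zero.

## Burden computation

`compute_burden()` evaluates the equation over a fixed summation order —
cells in canonical order within disease, diseases in reporting order,
states alphabetical — so outputs are bit-reproducible. Roll-ups: state
totals, per-capita (state population denominator), the 65+ subset
(costs from 65+ cells; per-capita over the 65+ population), national
totals and the national per-disease decomposition. Conservation
(national = Σ states = Σ diseases = Σ cells) is asserted in the tests at
relative $10^{-12}$; sums taken in different orders can differ by
floating-point rounding, which is why the identity is not asserted
bitwise.

## Probabilistic sensitivity analysis

Each replicate (i) reweights both surveys with a **Rao–Wu rescaling
bootstrap** — within a stratum of $n_h$ clusters, $n_h-1$ clusters are
drawn with replacement and each record's weight is scaled by
$m_c\,n_h/(n_h-1)$ — and (ii) redraws cost parameters: gamma via method
of moments (shape $(\mu/\sigma)^2$, scale $\sigma^2/\mu$) where a
standard error is declared, uniform on $[0.8\mu, 1.2\mu]$ otherwise.
The record set never changes, only weights, so the survey structure is
preserved and the expected bootstrap weight equals the original.
Singleton strata are merged into the adjacent stratum by identifier
order before resampling.

Intervals are **empirical percentiles** (0.05/0.95 at the default 90%
level) of the replicate outputs; the point estimate is the unresampled
run, with the replicate mean reported alongside. Two modes mirror the
usual reporting convention: holding the global multiplier $\Delta_{MN}$
fixed across replicates (so states can be compared with each other) or
letting it vary with the rest. Replicate seeds derive from the master
seed by a fixed counter scheme, `(seed + 99991·r) mod (2^31−1)`, so any
replicate is reproducible in isolation; a failing replicate is dropped
and counted, and more than 1% failures aborts the analysis. Percentile
intervals from resampled data need not bracket the point estimate; the
package flags (but does not "fix") genuine violations.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline consumes,
with known ground truth: a cell mix resembling census demography;
age-graded disease prevalences (dementia reaching 12.5% at 65+,
breast cancer zero in males); malnutrition-given-disease around 5–10%;
sex-specific normal heights; a stratified-cluster design (default 15
strata × 2 clusters, log-normal cluster weights, sd 0.5 on the log
scale) with round-robin assignment; and an optional within-cluster
random effect on disease odds (default off) that makes the
design-preserving bootstrap differ from simple random sampling.

Malnutrition is *realized through measurements*: a latent label is
drawn per person (probability = the cell's $PMN$ for their disease;
for the rare comorbid person, the mean over their diseases; a small
background rate, default 0.05, for the disease-free), then malnourished
persons receive either low albumin (uniform 2.5–3.4 g/dL) or low weight
(75–89% of IBW) with equal probability, and non-malnourished persons
albumin 3.6–5.0 g/dL and weight 95–130% of IBW. The bands straddle the
thresholds with margin beyond the 0.1-unit storage rounding, so the
classifier recovers every latent label exactly — making parameter
recovery a sharp test rather than a noisy one.

What the generator does **not** emulate: real variable names or survey
cycles, oversampling/calibrated weights (weights are independent of the
data), informative non-response, measurement error in albumin or
anthropometry, and realistic comorbidity structure (flags are drawn
independently per disease). Passing tests therefore validate the
estimation machinery, not the epidemiology of any real survey.

## Numerical and testing choices

* Fixed seeds make every generated table byte-identical across runs;
  measurements are stored rounded to 0.1 units.
* Exactness claims (burden equation vs closed form, micro-simulation
  equivalence) are asserted at relative $10^{-12}$; identities across
  summation orders at $10^{-12}$–$10^{-10}$.
* Test problem sizes: parameter recovery runs one examination survey of
  20,000 records and one interview survey of 50,000; interval coverage
  runs 100 independent worlds of 8,000/6,000 records with 200 bootstrap
  replicates each; unit tests use worlds of 1,500–6,000 records.
* The coverage check is run in the regime where the percentile method's
  asymptotics hold: constant prevalences (0.30) so every disease domain
  carries hundreds of records, 25 strata × 4 clusters, mild weight
  dispersion (0.2 log-sd), and the survey-resampling channel alone
  (cost parameters held at truth, since mean-centered parameter draws
  widen intervals around a fixed truth and make coverage conservative
  by construction).

## Known limitations

* **Percentile intervals under harsh designs.** With few PSUs per
  stratum and strong weight dispersion (the default generator design
  emulating masked public-use designs), the estimator's sampling
  distribution is noticeably skewed and the percentile interval places
  that skew on the wrong side, yielding one-sided undercoverage for the
  national total at moderate sample sizes. The same applies when a
  disease domain carries only tens of records, where interval width
  tracks the observed prevalence. Users needing calibrated intervals in
  such regimes should increase replicates and treat the 90% intervals
  as approximate.
* **Estimand drift under comorbidity.** The generator's mean-over-
  diseases rule for comorbid persons means the per-disease malnutrition
  prevalence being estimated differs slightly from the per-disease
  ground-truth parameter when prevalences are large and heterogeneous;
  at the default prevalences the effect is far below sampling noise.
* The pooling ladder trades variance for resolution: pooled cells
  inherit the wider domain's prevalence, which is only unbiased when
  prevalence is homogeneous across the pooled dimension.
* All costs are nominal; combining literature values from different
  years is the user's responsibility.
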