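---
title: "Methods: lipid trajectories, VIM, and cognitive-decline risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid trajectories, VIM, and cognitive-decline risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipidtraj)
```

# The problem and the data model

The package models decade-long blood-lipid histories in case-control
studies of Alzheimer's disease and stable mild cognitive impairment. Every
subject carries annual lipid-panel values (total cholesterol, HDL-C, LDL-C,
non-HDL-C, triglycerides, mg/dl) on a relative-year axis of integers
−10…0, with year 0 the *index year*: year of first cognitive symptom in a
case, the matched age year in a control. Subjects qualify with at least
three measurements in distinct years inside that 11-year window; panels are
irregular (a typical subject is observed in roughly 60% of years), so every
longitudinal method here must tolerate gaps.

Derived variables follow clinical convention: non-HDL-C = TC − HDL-C;
LDL-C uses the recorded value when present and otherwise the Friedewald
estimate TC − HDL-C − TG/5, which we treat as valid only for TG ≤ 400 mg/dl
(above that, LDL-C is left missing rather than extrapolated); triglycerides
are natural-log transformed, the scale on which their distribution is
near-normal. Same-year duplicate measurements are averaged before any
transformation — the alternative (taking the first) is defensible, but
averaging preserves the "annual record" semantics and commutes with the
linear derivations. Medication exposure at a year is inferred from order
events: an order with status Sent/Dispensed/Verified placed at or before
the year makes the subject a user unless a discontinuation intervened
before that year, and a discontinuation is ignored when a later qualifying
order superseded it. Comorbidity flags come from ICD-9/10 prefix lists
(shipped as a versioned TSV under `inst/extdata/`), matched on dot-stripped
string prefixes so printed ranges like "401–403" or "C00–C96" expand to
explicit prefix sets.

# Group-based trajectory models

## Model

For lipid value $y_{it}$ of subject $i$ at relative year $t$, group $g$
posits a polynomial mean curve with an additive on-medication shift:

$$\mu_{itg} = \beta_g^\top (1, t, t^2, \dots) + \alpha_g \,\text{med}_{it}.$$

The observation model is censored-normal (tobit): inside bounds
$(y_{\min}, y_{\max})$ the density is $N(\mu_{itg}, \sigma^2)$; at a bound
the contribution is the corresponding tail mass. The subject likelihood is
the product over the years actually observed (gaps drop out), and the
cohort likelihood mixes groups with proportions $\pi_g$. The residual SD
$\sigma$ is shared across groups, the convention of the standard
latent-class growth tools this reimplements; per-group orders are allowed.

## Estimation and numerical choices

* **EM with exact tobit M-step.** The E-step computes subject-level
  posterior group memberships; the M-step replaces each censored
  observation by its truncated-normal conditional mean (with the
  conditional variance entering the $\sigma$ update), then solves weighted
  least squares per group. Because the $\beta$ update does not depend on
  $\sigma$, the pair is a joint exact M-step and the observed-data
  log-likelihood is non-decreasing — a property the test suite asserts on
  the per-iteration trace.
* **Starts and convergence.** Default 10 random starts for a single fit
  (k-means on subject means for the first start, random assignments after),
  relative log-likelihood tolerance 1e-6, 500 iteration cap. The model
  sweep uses 5 starts per grid cell by default: on the well-separated
  mixtures the sweep is meant to rank this recovers the same optimum while
  keeping a 15-cell sweep inside a few seconds at n = 400.
* **Censoring bounds.** Default $(-\infty, \infty)$, i.e. censoring is
  inert until the user supplies bounds (assay detection limits, or the
  observed data range). An earlier draft defaulted to the per-lipid data
  range, but that silently converts the two extreme observations into
  tail-mass contributions, which is not inert; an explicit opt-in is the
  safer default.
* **Label switching** is resolved deterministically by relabeling groups in
  ascending fitted mean at year 0, so "group 1" is always the lowest-level
  trajectory.
* **Degenerate fits.** Mixing proportions are floored at 1e-10 in the
  E-step normalization; a fit with any $\hat\pi_g < 0.01$ or an empty modal
  group is flagged degenerate rather than silently returned, and
  non-convergence at the iteration cap is flagged too.

## Model selection

The sweep fits every (group count, shared polynomial order) cell, reports
log-likelihood/AIC/BIC per cell, and selects the lowest-BIC fit that passes
three admission rules: average posterior probability of assigned members
≥ 0.85 per group, odds of correct classification
$\mathrm{OCC}_g = \frac{\mathrm{APP}_g/(1-\mathrm{APP}_g)}{\pi_g/(1-\pi_g)} \ge 5$,
and a modal share of at least 5% of the cohort (the clinical-relevance
rule; it is what rejects 4–5-group fits whose extra group captures a sliver
of subjects even when BIC prefers them). With a single group APP is 1 and
OCC is reported as +∞. An optional refinement pass then varies one group's
polynomial order at a time around the winner, keeping changes only when
they lower BIC and stay admissible; this bounds the per-group-order grid
without fitting all $5^G$ combinations. BIC uses the number of subjects as
the sample size, the convention for subject-level mixtures. When no cell is
admissible the selection returns an explicit "no admissible model" status —
downstream stages must then omit trajectory-group covariates.

Trajectories are fit on cases and controls pooled within a cohort (the
design that makes group shares comparable between cases and controls); a
caller who wants per-arm fits can simply subset the input.

# Variability independent of the mean

Across-visit SD scales with the subject mean in lipid panels, so raw SD
quintiles mostly re-rank means. VIM fits the power law by ordinary least
squares of $\ln \mathrm{SD}_i$ on $\ln \mathrm{mean}_i$ (subjects with zero
SD excluded), then rescales:

$$\mathrm{VIM}_i = k\,\mathrm{SD}_i / \mathrm{mean}_i^{\,x}, \qquad
  k = (\overline{\mathrm{mean}})^{x},$$

which keeps SD units and is uncorrelated with the mean by construction.
The exact variant in the blood-pressure literature that introduced VIM is
not uniquely pinned down in print; this log-log OLS exponent with the
grand-mean scale factor is the standard reading and is documented here as
the package's reference formula. Degenerate inputs (no variation in
log-means) yield $x = 0$ with a warning, reducing VIM to the raw SD.
VIM is computed from the same annual records used for trajectory fitting —
i.e. after same-year averaging — and quintiles are assigned within a
case/control cohort, mirroring the pooled trajectory fits. Quintile
assignment sorts subjects (ties broken by stable input order) and splits
into five consecutive near-equal blocks, which coincides with type-7
20/40/60/80 percentile cuts whenever values are distinct; all-equal input
is an error rather than an arbitrary labeling.

# Propensity matching

Cases are matched to controls at index age with exact strata on sex, age
group (cutpoints 50–59, 60–64, 65–72, 73–77, 78–81, 82–85, 86–98), BMI
group (<18.5, 18.5–24.9, 25–29.9, 30–34.9, 35–40, >40 kg/m²) and
medication use, and greedy nearest-neighbor refinement on the logit of a
logistic propensity score built from race, APOE ε2/ε4 counts and education
band. Cases are processed in descending propensity order; each takes up to
`ratio` (default 4, spanning the ≈1:2–1:4 control:case ratios such cohorts
produce) nearest unmatched controls, without replacement, optionally inside
a caliper. Matching weights follow the ATT convention — cases 1, controls
sharing 1 per set — and are carried into risk models as a continuous
covariate rather than as frequency weights. Perfect separation in the
propensity fit is flagged and refit with two mean-profile pseudo-
observations (a light data-augmentation shrinkage), keeping scores strictly
inside (0, 1). Unmatched cases are reported, never silently dropped, and a
standardized-mean-difference balance table (pre/post) accompanies every
match.

# Longitudinal correlates

Mixed-effects models per lipid use a subject random intercept and random
slope on age with unstructured 2×2 covariance, ML estimation (so AIC
comparisons across fixed-effect sets are valid), and Wald 95% intervals.
A singular unstructured fit is automatically refit with independent random
effects and flagged. AIC backward selection drops, at each step, the single
candidate whose removal lowers AIC most, never touching locked terms (the
ten genetic principal components are the intended locked set in the
full analysis); the elimination trace is returned for audit. Covariates are
handled complete-case; the greedy path is not guaranteed to equal
exhaustive search in general, but the suite verifies the equivalence on
small candidate sets.

# Risk models

Logistic case models use ML fits with a cluster-robust sandwich covariance
aggregating scores within matched sets (HC0 meat, no small-sample cluster
adjustment, so all-singleton clusters reduce exactly to the
heteroscedasticity-robust sandwich). Odds ratios with robust 95% intervals
are the reporting unit; reference levels follow the convention of
expressing the two lower HDL-C trajectory groups relative to the highest
(group 3) and the lowest VIM quintile relative to quintiles 2–5 pooled.
Diagnostics: Hosmer–Lemeshow on deciles of risk (g − 2 df; tied fitted
values collapse bins, with df following the realized bin count) and a link
test refitting the outcome on the linear predictor and its square (pass =
squared term non-significant at 5%; separation is flagged, not fatal).
Nested covariate sets — base, base+lipids, base+genetics, both — are
compared by DeLong's correlated-AUROC equality test, Bonferroni-corrected
across the family of pairwise comparisons; pROC supplies the DeLong
machinery. Predictive margins fix grid covariates and either average
predicted probability over the estimation sample (default) or evaluate at
covariate means ("atmeans" — the mode used for age-by-genotype displays);
both are provided because published margin plots use each in different
places. Delta-method intervals use the cluster-robust covariance and are
clamped to [0, 1].

# The synthetic cohort

The generator emulates exactly the structure the analysis assumes: an
11-year window; per-year Bernoulli observation (default p = 0.6, matching
the ~60% per-year coverage of such registries) resampled until at least 3
distinct years; latent trajectory groups per lipid with polynomial curves
and a per-group medication effect; a subject random intercept; residual SD
proportional to (subject mean)^x times a log-normal subject multiplier —
the mechanism that makes VIM meaningful; medication histories as order
events (start, optional discontinuation, optional same-year replacement)
run through the same inference rule the derivations module implements; and
case status from a configurable logistic model on trajectory group,
variability quintile, age, education, comorbidity and standardized scores.
Default group means are illustrative three-level shapes (HDL-C 40/55/85
mg/dl with mixing 0.45/0.40/0.15 and the highest group smallest), not
estimates from any cohort; default outcome log-odds are 1.0 and 0.6 for the
two lower HDL-C groups and 0.9 for the lowest variability quintile.
Genetic inputs are simulated directly as standardized Gaussians (scores,
principal components) — computing polygenic scores from genotypes is out of
scope.

What passing tests on these cohorts shows — and does not. Parameter
recovery here demonstrates that the estimators are correct under their own
assumptions (normal residuals, polynomial means, logistic outcomes). Real
EHR panels add assay changes, informative visit timing, medication
adherence dynamics and diagnosis-driven measurement — none of which the
generator produces, so test results certify the machinery, not the clinical
conclusions.

Problem sizes used by the test suite and the acceptance script — chosen as
the smallest cohorts at which the respective properties are comfortably
identified: 400 subjects for trajectory recovery (three flat HDL-C groups,
σ = 4 mg/dl), 500 for the VIM decorrelation property (power-law exponent
0.8, log-normal dispersion 0.2), 100 replicates of 700 subjects for
odds-ratio CI coverage and AUROC nesting, 1000 null replicates of n = 200
for the DeLong test level. Replicate-level sub-seeds are drawn from a
single stream seeded by the user-facing seed, so distinct master seeds give
genuinely disjoint replicates while a fixed seed reproduces every number
exactly.

# Known limitations

* The trajectory mixture assumes a shared residual SD and normal tails;
  heavy-tailed assay noise will inflate group counts.
* Greedy nearest-neighbor matching is order-dependent by design
  (descending propensity); optimal and genetic matching are out of scope.
* The mixed-model stage fits one response at a time; no joint multi-lipid
  model.
* In-sample AUROC comparison of nested models is descriptive — the nesting
  property asserted in tests concerns in-sample fits, not out-of-sample
  discrimination.
* No survival-time modeling: the design is retrospective case-control with
  an index year, so hazards are intentionally absent.
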