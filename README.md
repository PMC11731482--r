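# lipidtraj

Tools for asking whether a decade of routine blood-lipid measurements,
taken before the first cognitive symptom, carries risk information for
Alzheimer's disease (AD) and stable mild cognitive impairment (MCI) beyond
genetics, demographics and comorbidity. The package is aimed at
biostatisticians and epidemiologists working with EHR-derived longitudinal
lipid panels in case-control designs, and ships a synthetic-cohort
generator so the entire pipeline can be developed and tested without
patient data.

## What the package computes

Subjects enter with 3–11 annual measurements of total cholesterol (TC),
HDL-C, LDL-C, non-HDL-C and ln(triglycerides) on a relative-year axis
−10…0, year 0 being the index year (first symptom in cases, matching age in
controls). Three ideas sit at the core:

**Group-based trajectory models.** Each lipid's longitudinal values are fit
to a finite mixture of polynomial mean curves with a censored-normal
(tobit) observation model and a time-varying on-medication covariate. For
subject *i* with observations *y<sub>it</sub>* at years *t*:

    L_i = Σ_g π_g Π_t f(y_it | β_g'x_t + α_g·med_it, σ)

where *f* is the normal density in the interior of the censoring bounds and
the corresponding tail mass at a bound. Estimation is by EM over latent
group membership (censored observations contribute their truncated-normal
conditional moments in the M-step, so the observed-data log-likelihood is
monotone), with multiple random starts. Model sweeps over 1–5 groups and
polynomial orders 0–4 are scored by BIC/AIC/log-likelihood, and a fit is
admissible only when every group has average posterior probability (APP)
≥ 0.85, odds of correct classification (OCC) ≥ 5, and at least 5% of the
cohort.

**Variability independent of the mean (VIM).** Visit-to-visit SD correlates
with the mean; VIM removes that dependence. With *x* the OLS slope of
ln(SD<sub>i</sub>) on ln(mean<sub>i</sub>) across subjects,

    VIM_i = k · SD_i / mean_i^x,   k = (grand mean of subject means)^x

so VIM keeps the units of the SD but is (by construction) uncorrelated with
the subject mean. Subjects are ranked into cohort quintiles, quintile 1
being least variable.

**Cluster-robust risk models.** Controls are propensity-matched to cases
within exact strata (sex, age group, BMI group, medication use) by greedy
nearest-neighbor on the propensity logit. Logistic risk models of
case status on trajectory group, VIM quintile and covariates use a
sandwich covariance clustered on matched set; model quality is checked by
Hosmer–Lemeshow and link tests; nested covariate sets (base, +lipids,
+genetics, +both) are compared by correlated-AUROC (DeLong) tests with
Bonferroni correction; predicted risk is reported as predictive margins
with delta-method intervals. Longitudinal correlates of each lipid are
screened beforehand with mixed-effects models (random intercept and random
age slope, unstructured covariance, ML) under AIC backward selection.

## Worked example

```r
library(lipidtraj)

cfg    <- cohort_config(n_subjects = 400, seed = 42)
cohort <- generate_cohort(cfg)
annual <- aggregate_annual(cohort$measurements)

dat <- annual[, c("id", "rel_year", "hdl", "on_med")]
names(dat)[3] <- "value"
sel <- sweep_and_select(dat, n_groups = 1:4, orders = 0:1,
                        starts = 5, seed = 42, refine = FALSE)
fit <- sel$fit
data.frame(pi = fit$pi, mean_y0 = sapply(fit$beta, `[[`, "t0"),
           APP = fit$app, OCC = fit$occ, share = fit$share)
#>      pi mean_y0   APP     OCC share
#> 1 0.258  32.250 0.942  46.756 0.262
#> 2 0.275  45.361 0.898  23.139 0.275
#> 3 0.325  57.860 0.955  43.763 0.320
#> 4 0.143  85.926 0.991 653.651 0.142
```

On this draw the sweep admits four HDL-C groups (the generator's
subject-level heterogeneity lets BIC split the lower range); each passes
the APP/OCC/5% rules, and groups are labeled by ascending year-0 mean.
VIM for total cholesterol, and a risk model on the derived groupings:

```r
summ <- subject_lipid_summaries(annual, "tc")
vr   <- compute_vim(summ)
round(attr(vr, "exponent"), 3)                     #> 0.644
round(cor(vr$vim, vr$mean), 3)                     #> -0.028  (decorrelated)

s <- cohort$subjects
s$hdl_traj <- fit$assignment[match(s$id, fit$ids)]
s$vim_q1   <- as.integer(assign_quintiles(vr$vim)[match(s$id, vr$id)] == 1L)
rm <- fit_logistic_cluster(s, case ~ age_c + educ_gt12 + prs_ad +
                             I(hdl_traj == 1) + I(hdl_traj == 2) + vim_q1)
rm$coefficients
#>                  term   beta    se   or ci_lo ci_hi       p
#>           (Intercept) -1.471 0.293 0.23  0.13  0.41 5.3e-07
#>                 age_c  0.078 0.018 1.08  1.04  1.12 1.1e-05
#>             educ_gt12 -0.447 0.276 0.64  0.37  1.10 1.1e-01
#>                prs_ad  0.729 0.141 2.07  1.57  2.73 2.6e-07
#>  I(hdl_traj == 1)TRUE  0.802 0.305 2.23  1.23  4.06 8.6e-03
#>  I(hdl_traj == 2)TRUE  0.769 0.304 2.16  1.19  3.92 1.1e-02
#>                vim_q1 -0.109 0.317 0.90  0.48  1.67 7.3e-01
round(rm$auc, 3)                                   #> 0.735
round(hosmer_lemeshow(rm)$p_value, 2)              #> 0.52
```

The odds ratios near 2.2 on the two lower HDL-C trajectory groups recover
the risk the generator attached to low HDL-C membership; the estimated
VIM-quintile indicator is a noisy proxy for the generating variability
quintile on this 400-subject draw, and its CI covers 1.

`run_pipeline(list(cohort = list(n_subjects = 400), seed = 1, outdir = "out"))`
executes the whole chain (simulate → derive → match → trajectories → VIM →
associations → mixed models → risk models) and writes per-stage CSVs plus a
manifest; `inst/cli/lipidtraj.R` is a thin command-line wrapper around it.

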