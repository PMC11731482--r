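Package: lipidtraj
Title: Lipid Trajectories and Variability Independent of the Mean for
    Cognitive-Decline Risk Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling decade-long blood-lipid histories in
    case-control studies of Alzheimer's disease and mild cognitive
    impairment. Implements censored-normal (tobit) group-based trajectory
    mixture models with a time-varying medication covariate and the
    standard admission diagnostics (average posterior probability, odds of
    correct classification, minimum group share); visit-to-visit
    variability independent of the mean (VIM) with cohort quintile
    assignment; propensity-score matching with exact strata and greedy
    nearest-neighbor refinement; multilevel mixed-effects models of the
    longitudinal correlates of lipid levels with AIC backward selection;
    cluster-robust logistic risk models with goodness-of-fit diagnostics,
    correlated-AUROC comparison and predictive margins; the univariate
    statistical toolkit used alongside them; and a synthetic-cohort
    generator emulating the longitudinal structure of such studies so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
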