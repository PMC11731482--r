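# Study-condition cohort configurations used across tests. These encode the
# simulation conditions once; tests and the acceptance checks reuse them
# unchanged.

# Three well-separated flat HDL-C groups (40/55/85 mg/dl, sigma 4 mg/dl,
# mixing 0.45/0.40/0.15), homoscedastic, medication-free: the conditions for
# trajectory parameter recovery.
traj_study_config <- function(n = 400L, seed = 5L) {
  cohort_config(
    n_subjects = n,
    group_specs = list(hdl = list(pi = c(0.45, 0.40, 0.15),
                                  beta = list(c(40), c(55), c(85)),
                                  alpha = c(0, 0, 0))),
    residual_sd = c(hdl = 4), subject_sd = c(hdl = 0),
    vim_exponent = 0, vim_lognoise = 0, med_prevalence = 0,
    outcome_coeffs = c("(Intercept)" = -1), seed = seed)
}

# Heteroscedastic single-lipid cohort where a subject's residual SD is
# proportional to mean^0.8 times log-normal noise: the VIM defining-property
# conditions.
vim_study_config <- function(n = 500L, seed = 11L) {
  cohort_config(
    n_subjects = n,
    group_specs = list(tc = list(pi = c(0.35, 0.45, 0.20),
                                 beta = list(c(110), c(180), c(280)),
                                 alpha = c(0, 0, 0))),
    residual_sd = c(tc = 15), subject_sd = c(tc = 30),
    vim_exponent = 0.8, vim_lognoise = 0.2, med_prevalence = 0,
    outcome_coeffs = c("(Intercept)" = -1), seed = seed)
}

# Two-lipid cohort (HDL-C trajectory groups + TC variability) whose case
# status carries log-odds 1.0 for the lowest HDL-C group and 0.9 for the
# lowest variability quintile: the risk-model recovery conditions.
risk_study_config <- function(n = 700L, seed = 1L) {
  cohort_config(
    n_subjects = n,
    group_specs = default_group_specs()[c("hdl", "tc")],
    residual_sd = c(hdl = 6, tc = 20), subject_sd = c(hdl = 8, tc = 25),
    seed = seed)
}

risk_model_terms <- function() {
  c("hdl_group1", "hdl_group2", "tc_vim_q1", "age_c", "educ_gt12",
    "cerebrovascular", "prs_ad", "prs_tc")
}

cohort_annual <- function(cohort) aggregate_annual(cohort$measurements)
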