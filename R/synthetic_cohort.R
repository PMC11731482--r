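# Synthetic case/control cohorts with the longitudinal structure the
# downstream analysis assumes: an 11-year window on a relative-year axis
# (-10..0, 0 = index year), 3-11 annual lipid panels per subject with a
# per-year observation probability, latent trajectory groups per lipid with
# polynomial mean curves and a medication effect, subject-level residual SD
# scaling as a power of the subject mean (the VIM-generating mechanism), and
# case status from a configurable logistic model.

#' Default trajectory-group specifications for the synthetic cohort
#'
#' Three roughly level groups per lipid; means are illustrative, styled on
#' the shapes recovered in cohorts of this kind (lowest/intermediate/highest
#' level with the highest group smallest), not extracted estimates.
#' @return named list (per lipid) of group specifications.
#' @export
default_group_specs <- function() {
  list(
    hdl = list(pi = c(0.45, 0.40, 0.15),
               beta = list(c(40), c(55), c(85)),
               alpha = c(2, 2, 2)),
    tc  = list(pi = c(0.40, 0.45, 0.15),
               beta = list(c(160), c(200), c(250)),
               alpha = c(-19, -19, -19)),
    tg  = list(pi = c(0.40, 0.45, 0.15),
               beta = list(c(100), c(160), c(250)),
               alpha = c(-15, -15, -15))
  )
}

#' Default case-status log-odds coefficients for the synthetic cohort
#'
#' Log-odds 1.0 and 0.6 for the two lower HDL-C trajectory groups, 0.9 for
#' the lowest variability quintile of total cholesterol, plus age,
#' education, cerebrovascular-disease and polygenic-score terms.
#' @return named numeric vector of log-odds.
#' @export
default_outcome_coeffs <- function() {
  c("(Intercept)" = -2.0,
    hdl_group1 = 1.0, hdl_group2 = 0.6,
    tc_vim_q1 = 0.9,
    age_c = 0.06, educ_gt12 = -0.5, cerebrovascular = 0.4,
    prs_ad = 0.8, prs_tc = 0.24)
}

#' Configuration for a synthetic case/control cohort
#'
#' @param n_subjects number of subjects.
#' @param window_years length of the observation window in years (>= 3);
#'   relative years run from -(window_years - 1) to 0.
#' @param group_specs named list (per lipid) of lists with elements
#'   \code{pi} (mixing proportions, summing to 1), \code{beta} (list of
#'   polynomial coefficient vectors over relative year, intercept first,
#'   mg/dl) and \code{alpha} (additive medication effect per group, mg/dl).
#' @param residual_sd named numeric: within-subject residual SD per lipid,
#'   mg/dl (the base SD before mean scaling).
#' @param subject_sd named numeric: SD of the subject-level random intercept
#'   per lipid, mg/dl (0 disables between-subject level variation).
#' @param vim_exponent true exponent x: a subject's residual SD is
#'   proportional to (subject mean)^x.
#' @param vim_lognoise SD of the log-normal subject noise multiplier (the
#'   mean-independent component of variability; 0 disables it).
#' @param min_visits,p_obs measurement schedule: each year of the window is
#'   observed with probability \code{p_obs}, resampled until at least
#'   \code{min_visits} distinct years are observed.
#' @param med_prevalence fraction of subjects who ever use
#'   cholesterol-lowering medication.
#' @param med_discontinue_prob probability that a user's order is
#'   discontinued before the index year.
#' @param med_replace_prob probability that a discontinuation is followed by
#'   a replacement order the same year (exercises the supersession rule).
#' @param covariates list of prevalences/distribution settings for the
#'   subject covariates (see defaults in the function body).
#' @param outcome_coeffs named log-odds vector for case-status generation;
#'   names must be "(Intercept)" or subject-table columns.
#' @param seed integer RNG seed.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 700L,
                          window_years = 11L,
                          group_specs = default_group_specs(),
                          residual_sd = c(hdl = 6, tc = 20, tg = 40),
                          subject_sd = c(hdl = 8, tc = 25, tg = 30),
                          vim_exponent = 0.8,
                          vim_lognoise = 0.25,
                          min_visits = 3L,
                          p_obs = 0.6,
                          med_prevalence = 0.75,
                          med_discontinue_prob = 0.15,
                          med_replace_prob = 0.5,
                          covariates = list(),
                          outcome_coeffs = default_outcome_coeffs(),
                          seed = 1L) {
  cov_defaults <- list(
    age_mean = 76, age_sd = 7, age_range = c(50, 98),
    p_female = 0.5, p_educ_gt12 = 0.77,
    p_race = c(caucasian = 0.92, black = 0.03, asian = 0.04, other = 0.01),
    p_apoe4 = c(0.62, 0.31, 0.07), p_apoe2 = c(0.88, 0.11, 0.01),
    p_bmi = c(under = 0.02, normal = 0.39, over = 0.42, obese1 = 0.13,
              obese2 = 0.03, obese3 = 0.01),
    p_smoking = 0.02, p_alcohol = 0.11,
    p_comorbidity = c(hypertension = 0.75, atherosclerosis = 0.06,
                      cerebrovascular = 0.18, diabetes = 0.27,
                      ihd_mi = 0.32, malignancy = 0.40),
    n_scores = 3L, n_pcs = 10L)
  covariates <- utils::modifyList(cov_defaults, covariates)

  if (window_years < 3L) stopf("window_years must be >= 3")
  if (min_visits < 3L) stopf("min_visits must be >= 3")
  if (min_visits > window_years)
    stopf("infeasible schedule: min_visits (%d) exceeds window_years (%d)",
          min_visits, window_years)
  if (p_obs <= 0 || p_obs > 1) stopf("p_obs must be in (0, 1]")
  for (lp in names(group_specs)) {
    gs <- group_specs[[lp]]
    if (abs(sum(gs$pi) - 1) > 1e-8)
      stopf("mixing proportions for %s must sum to 1", lp)
    if (any(gs$pi <= 0 | gs$pi >= 1) && length(gs$pi) > 1L)
      stopf("mixing proportions for %s must lie in (0, 1)", lp)
    if (length(gs$beta) != length(gs$pi) ||
        length(gs$alpha) != length(gs$pi))
      stopf("group spec for %s has inconsistent lengths", lp)
  }
  prevs <- c(covariates$p_female, covariates$p_educ_gt12,
             covariates$p_smoking, covariates$p_alcohol,
             covariates$p_comorbidity)
  if (any(prevs < 0 | prevs > 1)) stopf("prevalences must lie in [0, 1]")

  structure(list(n_subjects = as.integer(n_subjects),
                 window_years = as.integer(window_years),
                 group_specs = group_specs, residual_sd = residual_sd,
                 subject_sd = subject_sd, vim_exponent = vim_exponent,
                 vim_lognoise = vim_lognoise,
                 min_visits = as.integer(min_visits), p_obs = p_obs,
                 med_prevalence = med_prevalence,
                 med_discontinue_prob = med_discontinue_prob,
                 med_replace_prob = med_replace_prob,
                 covariates = covariates, outcome_coeffs = outcome_coeffs,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

poly_curve <- function(beta, t) {
  drop(outer(t, seq_along(beta) - 1L, `^`) %*% beta)
}

sample_visit_years <- function(years, p_obs, min_visits) {
  repeat {
    obs <- years[stats::runif(length(years)) < p_obs]
    if (length(obs) >= min_visits) return(obs)
  }
}

#' Generate a synthetic case/control cohort
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list of class \code{synthetic_cohort} with elements
#'   \code{subjects} (one row per subject: covariates, true trajectory group
#'   per lipid, true variability multiplier and quintile, case status),
#'   \code{measurements} (long table: id, rel_year, lipid, value, on_med),
#'   \code{orders} (medication-order events on the relative-year axis), and
#'   \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  cv <- config$covariates
  years <- -(config$window_years - 1L):0L
  ids <- sprintf("S%05d", seq_len(n))

  age <- pmin(pmax(round(stats::rnorm(n, cv$age_mean, cv$age_sd)),
                   cv$age_range[1]), cv$age_range[2])
  subjects <- data.frame(
    id = ids,
    index_year = sample(2012:2023, n, replace = TRUE),
    age = age, age_c = age - 75,
    female = stats::rbinom(n, 1, cv$p_female),
    educ_gt12 = stats::rbinom(n, 1, cv$p_educ_gt12),
    race = sample(names(cv$p_race), n, replace = TRUE, prob = cv$p_race),
    apoe4 = sample(0:2, n, replace = TRUE, prob = cv$p_apoe4),
    apoe2 = sample(0:2, n, replace = TRUE, prob = cv$p_apoe2),
    bmi_group = sample(names(cv$p_bmi), n, replace = TRUE, prob = cv$p_bmi),
    smoking = stats::rbinom(n, 1, cv$p_smoking),
    alcohol = stats::rbinom(n, 1, cv$p_alcohol),
    stringsAsFactors = FALSE)
  for (cm in names(cv$p_comorbidity))
    subjects[[cm]] <- stats::rbinom(n, 1, cv$p_comorbidity[[cm]])
  score_names <- c("prs_ad", "prs_tc", "prs_hdl")[seq_len(cv$n_scores)]
  for (sc in score_names) subjects[[sc]] <- stats::rnorm(n)
  for (k in seq_len(cv$n_pcs)) subjects[[paste0("pc", k)]] <- stats::rnorm(n)

  # medication histories: a single start year per ever-user, optional
  # discontinuation, optionally replaced the same year by another order
  meds <- cholesterol_lowering_medications()
  ever <- stats::runif(n) < config$med_prevalence
  orders <- list()
  for (i in which(ever)) {
    start <- sample(years, 1L)
    drug <- sample(meds, 1L)
    rows <- data.frame(id = ids[i], medication = drug, status = "Sent",
                       year = start, stringsAsFactors = FALSE)
    if (stats::runif(1) < config$med_discontinue_prob && start < 0L) {
      disc <- sample(seq(start + 1L, 0L), 1L)
      rows <- rbind(rows, data.frame(id = ids[i], medication = drug,
                                     status = "Discontinued", year = disc))
      if (stats::runif(1) < config$med_replace_prob)
        rows <- rbind(rows, data.frame(id = ids[i],
                                       medication = sample(meds, 1L),
                                       status = "Sent", year = disc))
    }
    orders[[length(orders) + 1L]] <- rows
  }
  orders <- if (length(orders)) do.call(rbind, orders) else
    data.frame(id = character(), medication = character(),
               status = character(), year = integer())

  on_med <- matrix(FALSE, n, length(years),
                   dimnames = list(ids, as.character(years)))
  for (i in which(ever)) {
    sub_orders <- orders[orders$id == ids[i], ]
    on_med[i, ] <- infer_medication_use(sub_orders, years)
  }

  visit_years <- lapply(seq_len(n), function(i)
    sample_visit_years(years, config$p_obs, config$min_visits))

  measurements <- list()
  for (lp in names(config$group_specs)) {
    gs <- config$group_specs[[lp]]
    G <- length(gs$pi)
    grp <- sample.int(G, n, replace = TRUE, prob = gs$pi)
    subjects[[paste0(lp, "_group")]] <- grp
    b <- stats::rnorm(n, 0, config$subject_sd[[lp]])
    u <- exp(stats::rnorm(n, 0, config$vim_lognoise))
    mu_subject <- vapply(seq_len(n), function(i)
      mean(poly_curve(gs$beta[[grp[i]]], years)) + b[i], numeric(1))
    mu_ref <- mean(mu_subject)
    sigma_i <- config$residual_sd[[lp]] *
      pmax(mu_subject / mu_ref, 1e-6)^config$vim_exponent * u
    subjects[[paste0(lp, "_true_sigma")]] <- sigma_i
    subjects[[paste0(lp, "_true_disp")]] <- config$residual_sd[[lp]] * u
    lens <- lengths(visit_years)
    idx <- rep(seq_len(n), lens)
    t_all <- unlist(visit_years)
    om_all <- on_med[cbind(idx, match(t_all, years))]
    mu_groups <- vapply(seq_len(G), function(g)
      poly_curve(gs$beta[[g]], t_all), numeric(length(t_all)))
    mu <- mu_groups[cbind(seq_along(t_all), grp[idx])] +
      gs$alpha[grp[idx]] * om_all + b[idx]
    measurements[[lp]] <- data.frame(
      id = ids[idx], rel_year = t_all, lipid = lp,
      # floored at 1 mg/dl: assay values cannot be non-positive
      value = pmax(mu + stats::rnorm(length(t_all), 0, sigma_i[idx]), 1),
      on_med = om_all, stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, measurements)
  rownames(measurements) <- NULL

  # true (mean-independent) variability quintile of the outcome lipid
  if ("tc" %in% names(config$group_specs)) {
    disp <- subjects$tc_true_disp
    subjects$tc_vim_q1 <- if (length(unique(disp)) >= 5L)
      as.integer(assign_quintiles(disp) == 1L) else 0L
  }
  if ("hdl" %in% names(config$group_specs)) {
    subjects$hdl_group1 <- as.integer(subjects$hdl_group == 1L)
    subjects$hdl_group2 <- as.integer(subjects$hdl_group == 2L)
  }

  subjects$case <- generate_case_status(subjects, config$outcome_coeffs)

  structure(list(subjects = subjects, measurements = measurements,
                 orders = orders, config = config),
            class = "synthetic_cohort")
}

#' Draw case status from a logistic outcome model
#'
#' P(case) is the inverse logit of the linear predictor built from the named
#' coefficient vector; every name other than "(Intercept)" must be a column
#' of the subject table.
#'
#' @param subjects subject table.
#' @param outcome_coeffs named numeric log-odds vector.
#' @return integer 0/1 vector with attribute \code{prevalence}.
#' @export
generate_case_status <- function(subjects, outcome_coeffs) {
  terms <- setdiff(names(outcome_coeffs), "(Intercept)")
  miss <- setdiff(terms, names(subjects))
  if (length(miss))
    stopf("outcome model covariate(s) missing from subject table: %s",
          paste(miss, collapse = ", "))
  eta <- rep(unname(outcome_coeffs["(Intercept)"] %||% 0), nrow(subjects))
  if (is.na(eta[1])) eta[] <- 0
  for (tm in terms) eta <- eta + outcome_coeffs[[tm]] * subjects[[tm]]
  case <- as.integer(stats::runif(nrow(subjects)) < stats::plogis(eta))
  attr(case, "prevalence") <- mean(case)
  case
}

#' Write a synthetic cohort to CSV tables plus a YAML config record
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("subjects.csv", "measurements.csv",
                            "orders.csv", "cohort_config.yaml"))
  utils::write.csv(cohort$subjects, paths[1], row.names = FALSE)
  utils::write.csv(cohort$measurements, paths[2], row.names = FALSE)
  utils::write.csv(cohort$orders, paths[3], row.names = FALSE)
  cfg <- cohort$config
  cfg_list <- unclass(cfg)
  cfg_list$group_specs <- lapply(cfg_list$group_specs, function(gs)
    list(pi = gs$pi, beta = gs$beta, alpha = gs$alpha))
  yaml::write_yaml(cfg_list, paths[4])
  invisible(paths)
}
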