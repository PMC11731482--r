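# Covariate-adjusted logistic risk models with cluster-robust (sandwich)
# standard errors aggregating scores within matched sets, Hosmer-Lemeshow
# and link-test diagnostics, correlated-AUROC comparison across nested
# covariate sets (DeLong), and predictive margins with delta-method
# confidence intervals.

#' Fit a logistic risk model with cluster-robust standard errors
#'
#' ML logistic fit with a sandwich covariance whose meat aggregates scores
#' at the cluster (matched-set) level (HC0 meat, no small-sample cluster
#' adjustment, so with all-singleton clusters the covariance equals the
#' heteroscedasticity-robust HC0 sandwich). Odds ratios and 95% CIs use the
#' robust SEs.
#'
#' @param data data.frame containing the outcome and covariates.
#' @param formula model formula with a 0/1 outcome on the left.
#' @param cluster cluster id vector aligned with \code{data} (default: one
#'   cluster per row).
#' @param weights optional prior weights (e.g. matching weights as
#'   continuous covariate is usually preferred; weights are supported for
#'   sensitivity fits).
#' @return object of class \code{risk_fit}: \code{model}, \code{vcov}
#'   (cluster-robust), \code{coefficients} (term, beta, se, or, ci_lo,
#'   ci_hi, p), \code{AIC}, \code{pseudo_r2} (McFadden), \code{auc},
#'   \code{separation} flag, \code{cluster}.
#' @export
fit_logistic_cluster <- function(data, formula, cluster = NULL,
                                 weights = NULL) {
  data$.prior_wt <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial(),
                                     weights = .prior_wt))
  if (is.null(cluster)) cluster <- seq_len(nrow(data))
  if (length(cluster) != length(stats::fitted(fit)))
    cluster <- cluster[as.integer(rownames(stats::model.frame(fit)))]
  p <- stats::fitted(fit)
  separation <- any(p < 1e-8 | p > 1 - 1e-8)
  V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0",
                        cadjust = FALSE)
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- est / se
  coefs <- data.frame(term = names(est), beta = unname(est),
                      se = unname(se), or = unname(exp(est)),
                      ci_lo = unname(exp(est - 1.96 * se)),
                      ci_hi = unname(exp(est + 1.96 * se)),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  y <- fit$y
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(y ~ 1,
                                             family = stats::binomial())))
  auc <- if (length(unique(y)) == 2L)
    as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  else NA_real_
  structure(list(model = fit, vcov = V, coefficients = coefs,
                 AIC = stats::AIC(fit), loglik = ll,
                 pseudo_r2 = 1 - ll / ll0, auc = auc,
                 separation = separation, cluster = cluster),
            class = "risk_fit")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into g deciles of fitted risk and compares observed
#' and expected event counts; the statistic is chi-square with g - 2
#' degrees of freedom.
#'
#' @param fit a \code{risk_fit}, or a numeric vector of fitted
#'   probabilities (then \code{y} must be given).
#' @param y 0/1 outcomes (taken from the fit when omitted).
#' @param g number of risk groups (default 10).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{table} (per-group observed/expected).
#' @export
hosmer_lemeshow <- function(fit, y = NULL, g = 10L) {
  if (inherits(fit, "risk_fit")) {
    p <- stats::fitted(fit$model); y <- fit$model$y
  } else p <- fit
  stopifnot(length(p) == length(y))
  qs <- stats::quantile(p, probs = seq(0, 1, length.out = g + 1L), type = 7)
  grp <- cut(p, breaks = unique(qs), include.lowest = TRUE)
  o1 <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  e1 <- tapply(p, grp, sum)
  o0 <- n_g - o1; e0 <- n_g - e1
  stat <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- length(levels(grp)) - 2L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(group = levels(grp), n = as.vector(n_g),
                          observed = as.vector(o1),
                          expected = as.vector(e1)))
}

#' Specification link test for a logistic model
#'
#' Refits the outcome on the linear predictor and its square; the model
#' passes when the squared term is non-significant at the 5% level.
#'
#' @param fit a \code{risk_fit}.
#' @param alpha significance level for the squared term (default 0.05).
#' @return list with \code{pass}, \code{p_value}, \code{flagged} (TRUE when
#'   the refit was degenerate, e.g. separation).
#' @export
link_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "risk_fit"))
  lp <- stats::predict(fit$model, type = "link")
  y <- fit$model$y
  refit <- tryCatch(
    suppressWarnings(stats::glm(y ~ lp + I(lp^2),
                                family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(refit) || is.na(stats::coef(refit)["I(lp^2)"]))
    return(list(pass = NA, p_value = NA_real_, flagged = TRUE))
  sm <- summary(refit)$coefficients
  if (!"I(lp^2)" %in% rownames(sm))
    return(list(pass = NA, p_value = NA_real_, flagged = TRUE))
  pv <- sm["I(lp^2)", 4]
  flagged <- any(stats::fitted(refit) < 1e-8 | stats::fitted(refit) > 1 - 1e-8)
  list(pass = pv >= alpha, p_value = pv, flagged = flagged)
}

#' Compare AUROCs of related models on the same subjects
#'
#' AUC per model via the rank (Mann-Whitney) statistic; pairwise equality
#' tests for correlated curves via DeLong's method, Bonferroni-corrected
#' across the family of comparisons.
#'
#' @param fits list of \code{risk_fit}s fitted on the same observations.
#' @param labels model labels.
#' @return list with \code{auc} (data.frame label/auc) and
#'   \code{comparisons} (data.frame: model_a, model_b, auc_diff, p_raw,
#'   p_bonferroni).
#' @export
compare_aurocs <- function(fits, labels = NULL) {
  k <- length(fits)
  if (is.null(labels)) labels <- paste0("model", seq_len(k))
  y <- fits[[1]]$model$y
  for (f in fits) if (!identical(f$model$y, y))
    stopf("all models must be fitted on the same subjects")
  rocs <- lapply(fits, function(f)
    pROC::roc(y, stats::fitted(f$model), quiet = TRUE,
              direction = "<", levels = c(0, 1)))
  aucs <- vapply(rocs, function(r) as.numeric(pROC::auc(r)), numeric(1))
  prs <- utils::combn(k, 2)
  m <- ncol(prs)
  comps <- lapply(seq_len(m), function(j) {
    i1 <- prs[1, j]; i2 <- prs[2, j]
    pv <- if (isTRUE(all.equal(stats::fitted(fits[[i1]]$model),
                               stats::fitted(fits[[i2]]$model)))) 1 else
      pROC::roc.test(rocs[[i1]], rocs[[i2]], method = "delong",
                     paired = TRUE)$p.value
    data.frame(model_a = labels[i1], model_b = labels[i2],
               auc_diff = aucs[i1] - aucs[i2], p_raw = pv,
               stringsAsFactors = FALSE)
  })
  comps <- do.call(rbind, comps)
  comps$p_bonferroni <- bonferroni_adjust(comps$p_raw, m)
  list(auc = data.frame(label = labels, auc = aucs),
       comparisons = comps)
}

#' Predictive margins with delta-method confidence intervals
#'
#' For each grid value of \code{at_var}, sets that covariate (and any
#' further fixed covariates in \code{fix}) for the whole estimation sample,
#' averages the predicted probability (mode "average"), or predicts at the
#' sample means of the other covariates (mode "atmeans"). Delta-method CIs
#' use the cluster-robust covariance and are clamped to [0, 1].
#'
#' @param fit a \code{risk_fit}.
#' @param at_var covariate to sweep.
#' @param at_values grid of values for \code{at_var}.
#' @param fix optional named list of covariates held at fixed values.
#' @param mode "average" (average over the sample) or "atmeans".
#' @return data.frame with columns \code{at}, \code{margin}, \code{ci_lo},
#'   \code{ci_hi}.
#' @export
predictive_margins <- function(fit, at_var, at_values, fix = list(),
                               mode = c("average", "atmeans")) {
  stopifnot(inherits(fit, "risk_fit"))
  mode <- match.arg(mode)
  mf <- stats::model.frame(fit$model)
  base <- mf[, setdiff(names(mf), "(weights)"), drop = FALSE]
  tt <- stats::terms(fit$model)
  vars <- all.vars(stats::delete.response(tt))
  # a swept covariate absent from the model yields flat margins (e.g. an
  # intercept-only model returns the sample prevalence at every grid point)
  if (mode == "atmeans") {
    means <- base[1L, , drop = FALSE]
    for (v in vars)
      means[[v]] <- if (is.numeric(base[[v]])) mean(base[[v]]) else
        base[[v]][which.max(tabulate(as.factor(base[[v]])))]
    base <- means
  }
  beta <- stats::coef(fit$model)
  V <- fit$vcov
  out <- lapply(at_values, function(a) {
    nd <- base
    nd[[at_var]] <- a
    for (v in names(fix)) nd[[v]] <- fix[[v]]
    X <- stats::model.matrix(stats::delete.response(tt), nd)
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    m <- mean(p)
    grad <- colMeans(stats::dlogis(eta) * X)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    data.frame(at = a, margin = m,
               ci_lo = max(0, m - 1.96 * se),
               ci_hi = min(1, m + 1.96 * se))
  })
  do.call(rbind, out)
}
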