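# Multilevel mixed-effects models for the longitudinal correlates of each
# lipid: subject-level random intercept and random slope on age with an
# unstructured 2x2 covariance, maximum-likelihood estimation, Wald
# confidence intervals, and AIC backward selection over a candidate
# fixed-effect list with locked terms.

#' Fit a mixed-effects model for a longitudinal lipid response
#'
#' Fits \code{response ~ fixed terms + (1 + age | id)} by maximum
#' likelihood. If the unstructured random-effect covariance is singular the
#' model is refit with independent (diagonal) random effects and flagged.
#' Complete cases only.
#'
#' @param data long data.frame with one row per subject-year containing the
#'   response, the fixed-effect columns, \code{age} and \code{id}.
#' @param response response column name.
#' @param fixed_terms character vector of fixed-effect terms (may include
#'   interactions like "age:female").
#' @param random_slope column for the random slope (default "age").
#' @return list of class \code{mixed_fit}: \code{model} (merMod),
#'   \code{coefficients} (term, estimate, ci_lo, ci_hi, p), \code{AIC},
#'   \code{loglik}, \code{ranef_vcov} (2x2), \code{singular} flag.
#' @export
fit_mixed_model <- function(data, response, fixed_terms,
                            random_slope = "age") {
  need <- unique(c(response, "id", random_slope,
                   unlist(strsplit(fixed_terms, ":", fixed = TRUE))))
  assert_cols(data, intersect(need, names(data)), "model data")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 + %s | id)", response, rhs, random_slope))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE, control = ctrl)))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    fml2 <- stats::as.formula(
      sprintf("%s ~ %s + (1 + %s || id)", response, rhs, random_slope))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(fml2, data = data, REML = FALSE, control = ctrl)))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)$id
  structure(list(model = fit, coefficients = coefs,
                 AIC = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 ranef_vcov = if (!is.null(vc)) vc[, , drop = FALSE] else NULL,
                 singular = singular, response = response,
                 terms = fixed_terms),
            class = "mixed_fit")
}

#' Generic AIC backward selection
#'
#' Starting from the full term list, repeatedly drops the single droppable
#' term whose removal lowers AIC the most, until no removal lowers it.
#' Locked terms are never dropped.
#'
#' @param fit_fun function(terms) returning a fitted object whose AIC is
#'   read by \code{aic_fun}.
#' @param terms full candidate term list.
#' @param locked terms never dropped.
#' @param aic_fun AIC extractor (default \code{function(f) f$AIC}).
#' @return list with \code{fit} (final fitted object), \code{terms} (final
#'   term list), \code{trace} (data.frame: step, dropped, AIC).
#' @export
backward_select <- function(fit_fun, terms, locked = character(),
                            aic_fun = function(f) f$AIC) {
  stopifnot(all(locked %in% terms))
  current <- terms
  fit <- fit_fun(current)
  trace <- data.frame(step = 0L, dropped = "(full model)",
                      AIC = aic_fun(fit), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    droppable <- setdiff(current, locked)
    if (!length(droppable)) break
    cand_fits <- lapply(droppable, function(tm)
      fit_fun(setdiff(current, tm)))
    aics <- vapply(cand_fits, aic_fun, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= aic_fun(fit) - 1e-9) break
    step <- step + 1L
    fit <- cand_fits[[best]]
    current <- setdiff(current, droppable[best])
    trace <- rbind(trace, data.frame(step = step, dropped = droppable[best],
                                     AIC = aics[best]))
  }
  list(fit = fit, terms = current, trace = trace)
}

#' AIC backward selection for the longitudinal mixed model
#'
#' @param data,response,random_slope as in \code{\link{fit_mixed_model}}.
#' @param candidate_terms full candidate fixed-effect list.
#' @param locked_terms terms never dropped (e.g. the ten genetic principal
#'   components, which stay in every model).
#' @return list with \code{fit} (final \code{mixed_fit}), \code{terms},
#'   \code{trace}.
#' @export
aic_backward_select <- function(data, response, candidate_terms,
                                locked_terms = character(),
                                random_slope = "age") {
  backward_select(
    function(tms) fit_mixed_model(data, response, tms, random_slope),
    terms = candidate_terms, locked = locked_terms)
}
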