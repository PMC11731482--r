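# Group-based trajectory models: finite mixtures of polynomial mean curves
# over relative year with a censored-normal (tobit) observation model and an
# optional time-varying medication covariate. Estimated by EM over latent
# group membership, with censored observations handled by their conditional
# (truncated-normal) moments in the M-step, so the observed-data mixture
# log-likelihood is non-decreasing across iterations. Subjects may have
# gaps: the subject likelihood is the product over whatever years were
# observed.

#' Specification of a trajectory mixture model
#'
#' @param n_groups number of latent groups (1-5).
#' @param order polynomial order in relative year, either a scalar applied
#'   to every group or a vector of per-group orders (each 0-4).
#' @param y_min,y_max censoring bounds of the tobit observation model, in
#'   the units of the lipid. The defaults (-Inf, Inf) make censoring inert;
#'   set them to assay limits or to the observed data range to activate it.
#' @param include_med_covariate include the on-medication indicator as a
#'   time-varying additive covariate (one coefficient per group).
#' @param starts number of random EM starts (best log-likelihood kept).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed RNG seed for the starts.
#' @return list of class \code{trajectory_spec}.
#' @export
trajectory_spec <- function(n_groups, order = 2L, y_min = -Inf, y_max = Inf,
                            include_med_covariate = TRUE, starts = 10L,
                            max_iter = 500L, tol = 1e-6, seed = 1L) {
  if (n_groups < 1L || n_groups > 5L) stopf("n_groups must be in 1..5")
  order <- as.integer(rep_len(order, n_groups))
  if (any(order < 0L | order > 4L)) stopf("polynomial orders must be in 0..4")
  if (y_min >= y_max) stopf("y_min must be below y_max")
  structure(list(n_groups = as.integer(n_groups), order = order,
                 y_min = y_min, y_max = y_max,
                 include_med_covariate = isTRUE(include_med_covariate),
                 starts = as.integer(starts), max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Censored-normal (tobit) log-density
#'
#' Interior values get the normal log-density; values at (or beyond) a bound
#' get the log of the normal tail mass beyond that bound.
#'
#' @param y observed values.
#' @param mu,sigma normal location and scale (sigma > 0).
#' @param y_min,y_max censoring bounds.
#' @return log-density vector.
#' @export
censored_normal_loglik <- function(y, mu, sigma, y_min = -Inf, y_max = Inf) {
  if (any(sigma <= 0)) stopf("sigma must be positive")
  n <- length(y)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  out <- stats::dnorm(y, mu, sigma, log = TRUE)
  lo <- y <= y_min
  hi <- y >= y_max
  out[lo] <- stats::pnorm(y_min, mu[lo], sigma[lo], log.p = TRUE)
  out[hi] <- stats::pnorm(y_max, mu[hi], sigma[hi], lower.tail = FALSE,
                          log.p = TRUE)
  out
}

# conditional moments of y* ~ N(mu, sigma^2) truncated to y* <= a (lower
# censoring) or y* >= a (upper); returns list(mean, var)
truncnorm_moments <- function(mu, sigma, a, lower = TRUE) {
  z <- (a - mu) / sigma
  if (lower) {
    lr <- stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE)
    r <- exp(lr)                       # phi(z)/Phi(z)
    m <- mu - sigma * r
    v <- sigma^2 * pmax(1 - z * r - r^2, 1e-12)
  } else {
    lr <- stats::dnorm(z, log = TRUE) -
      stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
    r <- exp(lr)                       # phi(z)/(1-Phi(z)), Mills ratio inverse
    m <- mu + sigma * r
    v <- sigma^2 * pmax(1 + z * r - r^2, 1e-12)
  }
  list(mean = m, var = v)
}

# build per-group design matrices for one long table
traj_design <- function(t, on_med, order, include_med) {
  X <- outer(t, 0:order, `^`)
  colnames(X) <- paste0("t", 0:order)
  if (include_med) X <- cbind(X, med = as.numeric(on_med))
  X
}

traj_n_params <- function(spec) {
  sum(spec$order + 1L) +
    (if (spec$include_med_covariate) spec$n_groups else 0L) +
    (spec$n_groups - 1L) + 1L
}

#' Fit a group-based trajectory mixture model
#'
#' @param data data.frame with columns \code{id}, \code{rel_year},
#'   \code{value}, and \code{on_med} (logical) when the medication covariate
#'   is included. Each subject should contribute at least three observed
#'   years; gaps are allowed.
#' @param spec a \code{\link{trajectory_spec}}.
#' @return object of class \code{trajectory_fit} with mixing proportions
#'   \code{pi}, per-group coefficients \code{beta} (named, medication effect
#'   \code{med} last when present), shared residual SD \code{sigma},
#'   \code{loglik}/\code{AIC}/\code{BIC}, per-subject \code{posterior}
#'   matrix and modal \code{assignment}, diagnostics \code{app},
#'   \code{occ}, \code{share}, and flags \code{converged},
#'   \code{degenerate}. Groups are labeled in ascending order of fitted mean
#'   at relative year 0.
#' @export
fit_trajectory_model <- function(data, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  assert_cols(data, c("id", "rel_year", "value"), "trajectory data")
  if (spec$include_med_covariate && !"on_med" %in% names(data))
    stopf("trajectory data needs an on_med column when the medication covariate is included")
  data <- data[!is.na(data$value), ]
  ids <- unique(data$id)
  sub_idx <- match(data$id, ids)
  n_sub <- length(ids)
  G <- spec$n_groups
  y <- data$value
  om <- if (spec$include_med_covariate) data$on_med else rep(FALSE, nrow(data))
  Xg <- lapply(seq_len(G), function(g)
    traj_design(data$rel_year, om, spec$order[g], spec$include_med_covariate))

  cens_lo <- y <= spec$y_min
  cens_hi <- y >= spec$y_max
  interior <- !(cens_lo | cens_hi)

  subj_mean <- tapply(y, sub_idx, mean)

  run_em <- function(init_assign) {
    # initial parameters from a hard assignment
    beta <- vector("list", G)
    for (g in seq_len(G)) {
      rows <- init_assign[sub_idx] == g
      if (sum(rows) <= ncol(Xg[[g]]))
        rows <- rep(TRUE, length(rows))  # fall back to pooled fit
      fit0 <- stats::lm.fit(Xg[[g]][rows, , drop = FALSE], y[rows])
      beta[[g]] <- ifelse(is.na(fit0$coefficients), 0, fit0$coefficients)
    }
    pi_g <- tabulate(init_assign, G) / n_sub
    pi_g <- pmax(pi_g, 1e-3); pi_g <- pi_g / sum(pi_g)
    sigma <- max(stats::sd(y) / 2, 1e-3)

    ll_old <- -Inf; converged <- FALSE; ll_trace <- numeric()
    for (iter in seq_len(spec$max_iter)) {
      mu <- vapply(seq_len(G), function(g) drop(Xg[[g]] %*% beta[[g]]),
                   numeric(length(y)))
      obs_ll <- vapply(seq_len(G), function(g)
        censored_normal_loglik(y, mu[, g], sigma, spec$y_min, spec$y_max),
        numeric(length(y)))
      subj_ll <- rowsum(obs_ll, sub_idx, reorder = TRUE)
      lw <- sweep(subj_ll, 2L, log(pi_g), `+`)
      lse <- row_logsumexp(lw)
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      W <- exp(lw - lse)               # n_sub x G posteriors

      if (is.finite(ll) && is.finite(ll_old) &&
          abs(ll - ll_old) < spec$tol * (abs(ll_old) + 1e-3)) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll

      # M-step
      pi_g <- pmax(colMeans(W), 1e-10); pi_g <- pi_g / sum(pi_g)
      w_obs <- W[sub_idx, , drop = FALSE]
      num <- 0; den <- 0
      for (g in seq_len(G)) {
        ystar <- y; cvar <- numeric(length(y))
        if (any(cens_lo)) {
          tm <- truncnorm_moments(mu[cens_lo, g], sigma, spec$y_min, TRUE)
          ystar[cens_lo] <- tm$mean; cvar[cens_lo] <- tm$var
        }
        if (any(cens_hi)) {
          tm <- truncnorm_moments(mu[cens_hi, g], sigma, spec$y_max, FALSE)
          ystar[cens_hi] <- tm$mean; cvar[cens_hi] <- tm$var
        }
        wf <- stats::lm.wfit(Xg[[g]], ystar, pmax(w_obs[, g], 1e-12))
        beta[[g]] <- ifelse(is.na(wf$coefficients), 0, wf$coefficients)
        mu_new <- drop(Xg[[g]] %*% beta[[g]])
        num <- num + sum(w_obs[, g] * ((ystar - mu_new)^2 + cvar))
        den <- den + sum(w_obs[, g])
      }
      sigma <- max(sqrt(num / den), 1e-6)
    }
    list(loglik = ll_old, pi = pi_g, beta = beta, sigma = sigma, W = W,
         converged = converged, iters = iter, ll_trace = ll_trace)
  }

  set.seed(spec$seed)
  best <- NULL
  for (s in seq_len(spec$starts)) {
    init <- if (G == 1L) rep(1L, n_sub)
    else if (s == 1L)
      stats::kmeans(subj_mean, centers = G, nstart = 5L)$cluster
    else sample.int(G, n_sub, replace = TRUE)
    res <- tryCatch(run_em(init), error = function(e) NULL)
    if (!is.null(res) && is.finite(res$loglik) &&
        (is.null(best) || res$loglik > best$loglik)) best <- res
  }
  if (is.null(best)) stopf("all EM starts failed")

  # deterministic labeling: ascending fitted mean at relative year 0
  year0_mean <- vapply(best$beta, function(b) unname(b["t0"]), numeric(1))
  ord <- order(year0_mean)
  best$pi <- best$pi[ord]
  best$beta <- best$beta[ord]
  best$W <- best$W[, ord, drop = FALSE]

  assignment <- max.col(best$W, ties.method = "first")
  share <- tabulate(assignment, G) / n_sub
  app <- vapply(seq_len(G), function(g) {
    in_g <- assignment == g
    if (!any(in_g)) NA_real_ else mean(best$W[in_g, g])
  }, numeric(1))
  occ <- compute_occ(app, best$pi)
  k <- traj_n_params(spec)

  structure(list(
    spec = spec, ids = ids, pi = best$pi, beta = best$beta,
    sigma = best$sigma, loglik = best$loglik,
    AIC = -2 * best$loglik + 2 * k,
    BIC = -2 * best$loglik + k * log(n_sub),
    n_subjects = n_sub, n_obs = length(y), n_params = k,
    posterior = best$W, assignment = assignment,
    app = app, occ = occ, share = share,
    converged = best$converged, iters = best$iters,
    loglik_trace = best$ll_trace,
    degenerate = any(best$pi < 0.01) || any(is.na(app))),
    class = "trajectory_fit")
}

#' Odds of correct classification
#'
#' OCC_g = [APP_g / (1 - APP_g)] / [pi_g / (1 - pi_g)]: the posterior odds
#' of correct assignment relative to the prior odds implied by the group's
#' mixing proportion. APP_g = 1 yields +Inf.
#'
#' @param app average posterior probability per group.
#' @param pi mixing proportions (in (0, 1)).
#' @return numeric OCC per group.
#' @export
compute_occ <- function(app, pi) {
  stopifnot(length(app) == length(pi))
  if (any(pi <= 0 | pi > 1)) stopf("mixing proportions must lie in (0, 1]")
  ifelse(app >= 1, Inf,
         ifelse(pi >= 1 - 1e-12, NA_real_,   # single group: prior odds infinite
                (app / (1 - app)) / (pi / (1 - pi))))
}

#' Admission rules for a trajectory fit
#'
#' A fit is admissible when every group has average posterior probability
#' >= \code{min_app}, odds of correct classification >= \code{min_occ}
#' (ignored for a single-group fit, where OCC is undefined/infinite), and
#' modal share >= \code{min_share} of the cohort.
#'
#' @param fit a \code{trajectory_fit}.
#' @param min_app,min_occ,min_share admission thresholds (defaults 0.85, 5,
#'   0.05).
#' @return logical scalar with attribute \code{reasons} (character vector of
#'   failed rules, empty when admissible).
#' @export
trajectory_admissible <- function(fit, min_app = 0.85, min_occ = 5,
                                  min_share = 0.05) {
  reasons <- character()
  if (any(is.na(fit$app)) || any(fit$app < min_app))
    reasons <- c(reasons, sprintf("APP below %.2f", min_app))
  if (fit$spec$n_groups > 1L && any(fit$occ < min_occ, na.rm = TRUE))
    reasons <- c(reasons, sprintf("OCC below %.1f", min_occ))
  if (any(fit$share < min_share))
    reasons <- c(reasons, sprintf("group share below %d%%",
                                  round(100 * min_share)))
  structure(length(reasons) == 0L, reasons = reasons)
}

#' Sweep trajectory model specifications and select the best admissible fit
#'
#' Fits every combination of group count and (equal across groups)
#' polynomial order, reports the fit-criteria table, and selects the
#' admissible fit with the lowest BIC. Optionally refines the winner by
#' varying one group's polynomial order at a time, keeping a change only
#' when it lowers BIC and stays admissible.
#'
#' @param data trajectory data (see \code{\link{fit_trajectory_model}}).
#' @param n_groups integer vector of group counts to try.
#' @param orders integer vector of polynomial orders to try.
#' @param refine per-group order refinement around the BIC winner.
#' @param min_app,min_occ,min_share admission thresholds.
#' @param ... further arguments to \code{\link{trajectory_spec}} (e.g.
#'   \code{starts}, \code{y_min}, \code{y_max},
#'   \code{include_med_covariate}, \code{seed}).
#' @return list of class \code{trajectory_selection}: \code{report}
#'   (data.frame of n_groups, order, loglik, AIC, BIC, admissible, reasons),
#'   \code{fit} (chosen \code{trajectory_fit}, or NULL), and \code{status}
#'   ("ok" or "no admissible model").
#' @export
sweep_and_select <- function(data, n_groups = 1:5, orders = 0:2,
                             refine = TRUE, min_app = 0.85, min_occ = 5,
                             min_share = 0.05, ...) {
  grid <- expand.grid(n_groups = n_groups, order = orders)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- trajectory_spec(grid$n_groups[i], grid$order[i], ...)
    fit <- fit_trajectory_model(data, spec)
    adm <- trajectory_admissible(fit, min_app, min_occ, min_share)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      n_groups = grid$n_groups[i], order = grid$order[i],
      loglik = fit$loglik, AIC = fit$AIC, BIC = fit$BIC,
      converged = fit$converged, admissible = as.logical(adm),
      reasons = paste(attr(adm, "reasons"), collapse = "; "))
  }
  report <- do.call(rbind, rows)
  ok <- which(report$admissible)
  if (!length(ok))
    return(structure(list(report = report, fit = NULL,
                          status = "no admissible model"),
                     class = "trajectory_selection"))
  best_i <- ok[which.min(report$BIC[ok])]
  best <- fits[[best_i]]

  if (refine && best$spec$n_groups > 1L) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (g in seq_len(best$spec$n_groups)) {
        for (o in setdiff(orders, best$spec$order[g])) {
          ords <- best$spec$order; ords[g] <- o
          spec <- trajectory_spec(best$spec$n_groups, ords, ...)
          cand <- fit_trajectory_model(data, spec)
          if (cand$BIC < best$BIC &&
              isTRUE(as.logical(trajectory_admissible(cand, min_app,
                                                      min_occ, min_share)))) {
            best <- cand; improved <- TRUE
          }
        }
      }
    }
  }
  structure(list(report = report, fit = best, status = "ok"),
            class = "trajectory_selection")
}

#' Fitted mean curves per group over the window
#'
#' @param fit a \code{trajectory_fit}.
#' @param years relative years at which to evaluate (default -10..0).
#' @param on_med evaluate with the medication covariate on or off.
#' @return data.frame with columns \code{group}, \code{rel_year},
#'   \code{mean}.
#' @export
trajectory_curves <- function(fit, years = -10:0, on_med = FALSE) {
  do.call(rbind, lapply(seq_along(fit$beta), function(g) {
    b <- fit$beta[[g]]
    poly_b <- b[startsWith(names(b), "t")]
    m <- poly_curve(unname(poly_b), years)
    if (on_med && "med" %in% names(b)) m <- m + b[["med"]]
    data.frame(group = g, rel_year = years, mean = m)
  }))
}
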