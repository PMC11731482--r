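# Propensity-score matching of controls to cases at the index age: exact
# strata on coarse variables (sex, age group, BMI group, medication use) and
# greedy nearest-neighbor refinement on the propensity-score logit within
# each stratum, variable ratio, without replacement.

#' Default exact-match age-group cutpoints
#' @return named list of break vectors for age and BMI grouping.
#' @export
match_group_breaks <- function() {
  list(age = c(50, 60, 65, 73, 78, 82, 86, 99),
       bmi = c(0, 18.5, 25, 30, 35, 40, Inf))
}

#' Estimate propensity scores by logistic regression
#'
#' Fits case ~ nearest-match covariates. Perfect or quasi-perfect separation
#' (fitted probabilities at 0/1) is flagged and the fit is repeated with a
#' mild ridge penalty on the linear predictor via iterated reweighting on a
#' jittered response (Firth-style shrinkage toward 0.5 is approximated by
#' augmenting the data with two pseudo-observations per covariate pattern
#' weight; see details in the methods vignette).
#'
#' @param data data.frame with a 0/1 \code{case} column.
#' @param vars character vector of covariate column names.
#' @return numeric propensity scores in (0, 1), with attribute
#'   \code{separation} (logical flag).
#' @export
estimate_propensity <- function(data, vars) {
  assert_cols(data, c("case", vars), "subject table")
  fml <- stats::as.formula(paste("case ~", paste(vars, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
  ps <- stats::fitted(fit)
  eps <- 1e-8
  separated <- any(ps < eps | ps > 1 - eps)
  if (separated) {
    # shrink by augmenting with prior pseudo-observations (data augmentation
    # prior: one pseudo-case and one pseudo-control at the covariate means)
    aug <- data[rep(1L, 2L), c("case", vars), drop = FALSE]
    for (v in vars) {
      col <- data[[v]]
      aug[[v]] <- if (is.numeric(col)) rep(mean(col), 2L) else
        rep(names(sort(table(col), decreasing = TRUE))[1L], 2L)
    }
    aug$case <- c(0L, 1L)
    dat2 <- rbind(data[, c("case", vars), drop = FALSE], aug)
    w <- c(rep(1, nrow(data)), rep(2, 2L))
    fit <- suppressWarnings(stats::glm(fml, data = dat2,
                                       family = stats::binomial(),
                                       weights = w))
    ps <- stats::fitted(fit)[seq_len(nrow(data))]
    ps <- pmin(pmax(ps, eps), 1 - eps)
  }
  structure(unname(ps), separation = separated)
}

smd <- function(x, case, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  x <- as.numeric(x)
  i1 <- case == 1; i0 <- case == 0
  m1 <- stats::weighted.mean(x[i1], w[i1])
  m0 <- stats::weighted.mean(x[i0], w[i0])
  s <- sqrt((stats::var(x[i1]) + stats::var(x[i0])) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (m1 - m0) / s
}

#' Match controls to cases within exact strata by propensity score
#'
#' Within each stratum defined by joint equality on \code{exact_vars}, cases
#' are processed in descending propensity-score order; each case is greedily
#' matched, without replacement, to up to \code{ratio} controls nearest on
#' the propensity-score logit (within \code{caliper} logits, if given).
#' Matching weights follow the ATT convention: cases weigh 1 and each set's
#' controls share a total weight of 1.
#'
#' @param data subject table with a 0/1 \code{case} column and an \code{id}
#'   column.
#' @param exact_vars columns requiring exact equality within a matched set.
#' @param nearest_vars columns entering the propensity model.
#' @param ratio maximum controls per case (default 4).
#' @param caliper optional maximum logit-PS distance.
#' @return list of class \code{matched_cohort}: \code{matched} (id, case,
#'   set_id, ps, weight), \code{unmatched_cases} (ids), \code{balance}
#'   (SMD pre/post per matching covariate), \code{ratio}.
#' @export
match_cohort <- function(data, exact_vars, nearest_vars, ratio = 4L,
                         caliper = NULL) {
  assert_cols(data, c("id", "case", exact_vars, nearest_vars),
              "subject table")
  if (length(intersect(exact_vars, nearest_vars)))
    stopf("exact and nearest variable lists must be disjoint")
  ps <- estimate_propensity(data, nearest_vars)
  lps <- stats::qlogis(pmin(pmax(ps, 1e-10), 1 - 1e-10))
  strata <- interaction(data[exact_vars], drop = TRUE)

  matched <- list(); set_counter <- 0L; unmatched <- character()
  for (st in levels(strata)) {
    in_st <- which(strata == st)
    cases <- in_st[data$case[in_st] == 1]
    ctrls <- in_st[data$case[in_st] == 0]
    if (!length(cases)) next
    cases <- cases[order(-ps[cases])]
    avail <- rep(TRUE, length(ctrls))
    for (cs in cases) {
      if (!any(avail)) { unmatched <- c(unmatched, data$id[cs]); next }
      d <- abs(lps[ctrls] - lps[cs])
      cand <- which(avail)
      if (!is.null(caliper)) cand <- cand[d[cand] <= caliper]
      if (!length(cand)) { unmatched <- c(unmatched, data$id[cs]); next }
      take <- cand[order(d[cand])][seq_len(min(ratio, length(cand)))]
      avail[take] <- FALSE
      set_counter <- set_counter + 1L
      k <- length(take)
      matched[[length(matched) + 1L]] <- data.frame(
        id = c(data$id[cs], data$id[ctrls[take]]),
        case = c(1L, rep(0L, k)),
        set_id = set_counter,
        ps = c(ps[cs], ps[ctrls[take]]),
        weight = c(1, rep(1 / k, k)),
        stringsAsFactors = FALSE)
    }
  }
  # cases whose whole stratum lacked controls
  no_ctrl <- data$id[data$case == 1 &
                       !data$id %in% unlist(lapply(matched, `[[`, "id")) &
                       !data$id %in% unmatched]
  unmatched <- union(unmatched, no_ctrl)
  matched_df <- if (length(matched)) do.call(rbind, matched) else
    data.frame(id = character(), case = integer(), set_id = integer(),
               ps = numeric(), weight = numeric())

  bal_vars <- c(exact_vars, nearest_vars)
  pre <- vapply(bal_vars, function(v)
    smd(as.numeric(as.factor(data[[v]])), data$case), numeric(1))
  mrows <- match(matched_df$id, data$id)
  post <- vapply(bal_vars, function(v)
    smd(as.numeric(as.factor(data[[v]]))[mrows], matched_df$case,
        matched_df$weight), numeric(1))
  balance <- data.frame(variable = bal_vars, smd_pre = unname(pre),
                        smd_post = unname(post))

  structure(list(matched = matched_df, unmatched_cases = unmatched,
                 balance = balance, ratio = ratio,
                 separation = attr(ps, "separation")),
            class = "matched_cohort")
}
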