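# Variability independent of the mean (VIM). A subject's across-visit SD is
# rescaled by a fitted power of the subject mean so the resulting measure is
# uncorrelated with mean level and robust to heteroscedasticity:
#   VIM_i = k * SD_i / mean_i^x,  k = (grand mean of subject means)^x,
# with x the OLS slope of ln(SD_i) on ln(mean_i) across subjects.

#' Per-subject summaries of a lipid from the annual record table
#'
#' @param annual data.frame from \code{\link{aggregate_annual}} (columns
#'   \code{id} and the lipid column).
#' @param lipid name of the lipid column to summarize (e.g. "hdl", "tc").
#' @return data.frame with columns \code{id}, \code{n}, \code{mean},
#'   \code{sd} over each subject's non-missing annual values.
#' @export
subject_lipid_summaries <- function(annual, lipid) {
  assert_cols(annual, c("id", lipid), "annual record table")
  v <- annual[[lipid]]
  keep <- !is.na(v)
  sp <- split(v[keep], annual$id[keep])
  data.frame(id = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, stats::sd, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the VIM exponent x by log-log regression
#'
#' x is the ordinary-least-squares slope of ln(SD_i) on ln(mean_i) over
#' subjects with positive SD. With fewer than two distinct means (or no
#' variance in log-means) the exponent is 0, with a warning.
#'
#' @param subject_summaries data.frame with columns \code{mean}, \code{sd}.
#' @return numeric exponent x.
#' @export
fit_vim_exponent <- function(subject_summaries) {
  assert_cols(subject_summaries, c("mean", "sd"), "subject summaries")
  s <- subject_summaries[subject_summaries$sd > 0 &
                           subject_summaries$mean > 0, ]
  lm_ <- log(s$mean)
  if (nrow(s) < 2L || stats::var(lm_) == 0) {
    warnf("no variation in subject log-means; VIM exponent set to 0")
    return(0)
  }
  unname(stats::coef(stats::lm(log(s$sd) ~ lm_))[2L])
}

#' Compute VIM per subject
#'
#' VIM_i = k * SD_i / mean_i^x with k = (grand mean of subject means)^x, so
#' VIM carries the units of the SD. Subjects with SD 0 get VIM 0.
#'
#' @param subject_summaries data.frame with columns \code{id}, \code{n},
#'   \code{mean}, \code{sd}.
#' @param x VIM exponent; fitted from the summaries when NULL.
#' @return object of class \code{vim_result}: the summaries with a
#'   \code{vim} column, plus attributes \code{exponent} and \code{k}.
#' @export
compute_vim <- function(subject_summaries, x = NULL) {
  assert_cols(subject_summaries, c("id", "mean", "sd"), "subject summaries")
  if (is.null(x)) x <- fit_vim_exponent(subject_summaries)
  if (!is.finite(x)) stopf("VIM exponent must be finite")
  k <- mean(subject_summaries$mean)^x
  out <- subject_summaries
  out$vim <- ifelse(out$sd == 0, 0, k * out$sd / out$mean^x)
  attr(out, "exponent") <- x
  attr(out, "k") <- k
  class(out) <- c("vim_result", class(out))
  out
}

#' Assign cohort quintiles (1 = least variability)
#'
#' Subjects are ordered by value (ties broken by position, i.e. stable
#' subject order) and split into five consecutive blocks of near-equal size,
#' which coincides with cutting at the 20/40/60/80 sample percentiles when
#' values are distinct.
#'
#' @param values numeric vector (>= 5 distinct values required).
#' @return integer vector of quintile labels 1-5, aligned with \code{values}.
#' @export
assign_quintiles <- function(values) {
  n <- length(values)
  if (length(unique(values)) < 5L)
    stopf("need at least 5 distinct values to form quintiles")
  ord <- order(values)               # stable: ties keep input order
  labels <- integer(n)
  labels[ord] <- ceiling(seq_len(n) * 5 / n)
  labels
}
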