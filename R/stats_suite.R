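# Univariate statistical toolkit used in cohort comparisons: Pearson
# chi-square (no continuity correction), Kruskal-Wallis, Bonferroni,
# Epanechnikov kernel density, two-sample Kolmogorov-Smirnov, Pearson
# correlation matrices. Thin, validated wrappers over stats so every report
# in the package goes through one audited surface.

#' Pearson chi-square test of independence on a contingency table
#'
#' No continuity correction is applied (matching the convention under which
#' the case/control cohort tables were evaluated). Rows or columns with a
#' zero marginal are dropped with a warning.
#'
#' @param table matrix of non-negative counts (>= 2 rows and columns after
#'   dropping empty margins).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stopf("counts must be non-negative")
  if (sum(table) <= 0) stopf("contingency table is empty")
  rz <- rowSums(table) == 0
  cz <- colSums(table) == 0
  if (any(rz) || any(cz)) {
    warnf("dropping %d empty row(s) and %d empty column(s)", sum(rz), sum(cz))
    table <- table[!rz, !cz, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L)
    stopf("need at least 2 rows and 2 columns with positive marginals")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with \code{statistic} (tie-corrected H), \code{df},
#'   \code{p_value}.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of raw P values.
#' @param m number of tests in the family (default \code{length(p)}).
#' @return adjusted P values, \code{pmin(1, m * p)}.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Epanechnikov kernel density estimate
#'
#' Density (1/nh) sum K((x - x_i)/h) with K(u) = 0.75 (1 - u^2) on |u| <= 1.
#' The default bandwidth is Silverman's rule of thumb,
#' 0.9 min(sd, IQR/1.34) n^(-1/5).
#'
#' @param values numeric sample.
#' @param grid evaluation points (default 512 points spanning the sample
#'   plus one bandwidth on each side).
#' @param bandwidth kernel bandwidth h (> 0).
#' @return data.frame with columns \code{x}, \code{density}.
#' @export
epanechnikov_density <- function(values, grid = NULL, bandwidth = NULL) {
  n <- length(values)
  stopifnot(n >= 2L)
  if (is.null(bandwidth)) {
    s <- min(stats::sd(values), stats::IQR(values) / 1.34)
    if (s == 0) s <- stats::sd(values)
    bandwidth <- 0.9 * s * n^(-1/5)
  }
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  if (is.null(grid))
    grid <- seq(min(values) - bandwidth, max(values) + bandwidth,
                length.out = 512L)
  dens <- vapply(grid, function(x0) {
    u <- (x0 - values) / bandwidth
    sum(0.75 * (1 - u^2) * (abs(u) <= 1)) / (n * bandwidth)
  }, numeric(1))
  data.frame(x = grid, density = dens)
}

#' Two-sample Kolmogorov-Smirnov test (asymptotic)
#'
#' @param a,b numeric samples.
#' @return list with \code{D} (sup ECDF difference) and \code{p_value}.
#' @export
ks_two_sample <- function(a, b) {
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(ht$statistic), p_value = ht$p.value)
}

#' Pearson correlation matrix
#'
#' @param columns data.frame or matrix of numeric columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_corr_matrix <- function(columns) {
  stats::cor(as.matrix(columns), method = "pearson",
             use = "pairwise.complete.obs")
}

#' Case/control association table for a grouping variable
#'
#' Builds the r x 2 case/control count table for a categorical grouping
#' (trajectory group or VIM quintile), runs the Pearson chi-square test and
#' reports the Bonferroni-adjusted P for a stated family size.
#'
#' @param group factor-like group labels per subject.
#' @param case 0/1 case indicator per subject.
#' @param m_family family size for the Bonferroni adjustment (default 1).
#' @return list with \code{counts}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{p_bonferroni}.
#' @export
group_case_association <- function(group, case, m_family = 1L) {
  counts <- table(group = group, case = factor(case, levels = c(1, 0),
                                               labels = c("case", "control")))
  ht <- chi_square_test(counts)
  ht$counts <- counts
  ht$p_bonferroni <- bonferroni_adjust(ht$p_value, m_family)
  ht
}
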