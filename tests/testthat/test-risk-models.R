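test_that("logistic OR on a 2x2 equals the cross-product ratio", {
  # cerebrovascular-disease-style 2x2: cases 56/215 exposed vs 83/483
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(56, 83, 159, 400)),
                  x = rep(c(1, 0, 1, 0), c(56, 83, 159, 400)))
  f <- fit_logistic_cluster(d, y ~ x)
  expect_equal(f$coefficients$or[f$coefficients$term == "x"],
               (56 * 400) / (83 * 159), tolerance = 1e-10)
})

test_that("singleton clusters reduce to the HC0 sandwich", {
  set.seed(61)
  d <- data.frame(x = rnorm(80))
  d$y <- rbinom(80, 1, plogis(0.5 * d$x))
  f <- fit_logistic_cluster(d, y ~ x, cluster = seq_len(80))
  hc <- sandwich::vcovHC(f$model, type = "HC0")
  expect_equal(max(abs(f$vcov - hc)), 0, tolerance = 1e-10)
})

test_that("null predictor: OR near 1 with nominal CI coverage", {
  set.seed(62)
  covered <- 0L; ors <- numeric(40)
  for (r in 1:40) {
    d <- data.frame(x = rnorm(250))
    d$y <- rbinom(250, 1, 0.35)
    f <- fit_logistic_cluster(d, y ~ x)
    row <- f$coefficients[f$coefficients$term == "x", ]
    ors[r] <- row$or
    covered <- covered + (row$ci_lo < 1 && 1 < row$ci_hi)
  }
  expect_gte(covered, 34L)                 # ~95% coverage over 40 draws
  expect_lt(abs(mean(log(ors))), 0.1)
})

test_that("Hosmer-Lemeshow uses deciles of risk with g - 2 df", {
  set.seed(63)
  n <- 400
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.7 * d$x))
  f <- fit_logistic_cluster(d, y ~ x)
  hl <- hosmer_lemeshow(f, g = 10)
  expect_equal(hl$df, 8)
  expect_gt(hl$p_value, 0.01)   # correctly specified model

  # brute-force oracle on a small instance with fixed groups
  p <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  hl2 <- hosmer_lemeshow(p, y = y, g = 4)
  grp <- cut(p, breaks = quantile(p, seq(0, 1, 0.25)), include.lowest = TRUE)
  o <- tapply(y, grp, sum); e <- tapply(p, grp, sum)
  nn <- tapply(y, grp, length)
  stat <- sum((o - e)^2 / e + ((nn - o) - (nn - e))^2 / (nn - e))
  expect_equal(hl2$statistic, stat, tolerance = 1e-10)
  expect_equal(hl2$df, 2)
})

test_that("link test passes correct models and rejects misspecification", {
  set.seed(64)
  passes <- 0L
  for (r in 1:20) {
    d <- data.frame(x = rnorm(400))
    d$y <- rbinom(400, 1, plogis(-0.4 + 0.8 * d$x))
    lt <- link_test(fit_logistic_cluster(d, y ~ x))
    passes <- passes + isTRUE(lt$pass)
  }
  expect_gte(passes, 18L)   # level: >= 90% of correctly specified fits pass

  # omitted strong quadratic, large n: detected
  d2 <- data.frame(x = rnorm(4000))
  d2$y <- rbinom(4000, 1, plogis(-1 + 0.5 * d2$x + 1.2 * d2$x^2))
  lt2 <- link_test(fit_logistic_cluster(d2, y ~ x))
  expect_false(isTRUE(lt2$pass))

  # perfectly separated degenerate input: flagged, no crash
  d3 <- data.frame(x = rep(c(-2, 2), each = 15))
  d3$y <- as.integer(d3$x > 0)
  f3 <- fit_logistic_cluster(d3, y ~ x)
  expect_true(f3$separation)
  lt3 <- link_test(f3)
  expect_true(is.list(lt3))
})

test_that("AUROC equals the Mann-Whitney statistic and self-comparison is null", {
  y <- c(0, 0, 0, 1, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.3, 0.8, 0.9)
  d <- data.frame(y = y, s = s)
  f <- fit_logistic_cluster(d, y ~ s)
  # exhaustive pair enumeration oracle on the fitted scores
  p <- fitted(f$model)
  U <- sum(outer(p[y == 1], p[y == 0],
                 function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(f$auc, U / 9, tolerance = 1e-12)

  cmp <- compare_aurocs(list(f, f), labels = c("m", "m_again"))
  expect_equal(cmp$comparisons$auc_diff, 0)
  expect_equal(cmp$comparisons$p_bonferroni, 1)
})

test_that("adding lipid covariates never lowers in-sample AUROC", {
  coh <- generate_cohort(risk_study_config(n = 500L, seed = 65L))
  s <- coh$subjects
  base <- fit_logistic_cluster(s, case ~ age_c + educ_gt12 + prs_ad)
  full <- fit_logistic_cluster(
    s, case ~ age_c + educ_gt12 + prs_ad + hdl_group1 + hdl_group2 +
      tc_vim_q1 + prs_tc)
  expect_gte(full$auc, base$auc)
  cmp <- compare_aurocs(list(base, full), c("base", "full"))
  expect_equal(cmp$auc$auc, c(base$auc, full$auc))
})

test_that("predictive margins average the inverse-logit correctly", {
  set.seed(66)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.9 * d$x + 0.4 * d$z))

  # intercept-only model: margin equals sample prevalence everywhere
  f0 <- fit_logistic_cluster(d, y ~ 1)
  m0 <- predictive_margins(f0, "x", c(-2, 0, 2))
  expect_equal(m0$margin, rep(mean(d$y), 3))

  # monotone along a positive coefficient
  f <- fit_logistic_cluster(d, y ~ x + z)
  m <- predictive_margins(f, "x", seq(-2, 2, 0.5))
  expect_true(all(diff(m$margin) > 0))
  expect_true(all(m$ci_lo >= 0 & m$ci_hi <= 1))
  expect_true(all(m$ci_lo <= m$margin & m$margin <= m$ci_hi))

  # atmeans mode gives the curve at covariate means
  ma <- predictive_margins(f, "x", 0, mode = "atmeans")
  eta <- coef(f$model)[1] + coef(f$model)[3] * mean(d$z)
  expect_equal(ma$margin, unname(plogis(eta)), tolerance = 1e-10)
})

test_that("delta-method margin CI agrees with a cluster bootstrap", {
  set.seed(67)
  n <- 150
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$x))
  f <- fit_logistic_cluster(d, y ~ x)
  m <- predictive_margins(f, "x", 0.5)

  boot <- replicate(1000, {
    idx <- sample.int(n, n, replace = TRUE)
    db <- d[idx, ]
    fb <- suppressWarnings(glm(y ~ x, data = db, family = binomial()))
    nd <- db; nd$x <- 0.5
    mean(predict(fb, nd, type = "response"))
  })
  bq <- quantile(boot, c(0.025, 0.975))
  width <- m$ci_hi - m$ci_lo
  expect_lt(abs(m$ci_lo - bq[[1]]), 0.15 * width)
  expect_lt(abs(m$ci_hi - bq[[2]]), 0.15 * width)
})
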