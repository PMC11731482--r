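test_that("censored-normal log-density handles interior and boundary mass", {
  # interior mode equals the normal log-density peak
  expect_equal(censored_normal_loglik(5, 5, 2), -log(2 * sqrt(2 * pi)))

  # value at the lower bound with mu at the bound: half the mass
  expect_equal(censored_normal_loglik(0, 0, 1, y_min = 0), log(0.5))

  # total mass (interior density + boundary point masses) integrates to 1
  mu <- 1.3; sig <- 0.8; lo <- 0.2; hi <- 2.4
  interior <- integrate(function(y)
    exp(censored_normal_loglik(y, mu, sig, lo, hi)),
    lower = lo + 1e-9, upper = hi - 1e-9, rel.tol = 1e-9)$value
  mass <- interior +
    exp(censored_normal_loglik(lo, mu, sig, lo, hi)) +
    exp(censored_normal_loglik(hi, mu, sig, lo, hi))
  expect_equal(mass, 1, tolerance = 1e-6)

  expect_error(censored_normal_loglik(1, 0, -1), "positive")
})

make_flat_groups <- function(n, means, sigma, seed, visits = 6L) {
  set.seed(seed)
  grp <- sample(seq_along(means), n, replace = TRUE)
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- sort(sample(-10:0, visits))
    data.frame(id = i, rel_year = t,
               value = rnorm(visits, means[grp[i]], sigma),
               on_med = FALSE)
  }))
  list(data = dat, group = grp)
}

test_that("single-component order-0 fit recovers the sample mean", {
  sim <- make_flat_groups(40, 60, 3, seed = 31)
  fit <- fit_trajectory_model(sim$data,
                              trajectory_spec(1, 0, starts = 1,
                                              include_med_covariate = FALSE))
  # shared visit count per subject: the MLE is the plain mean
  expect_equal(unname(fit$beta[[1]]["t0"]), mean(sim$data$value),
               tolerance = 1e-8)
  expect_equal(fit$pi, 1)
  expect_equal(fit$app, 1)
  expect_equal(fit$occ, Inf)
})

test_that("two flat groups are recovered with correct proportions", {
  sim <- make_flat_groups(400, c(40, 80), 3, seed = 32)
  fit <- fit_trajectory_model(sim$data,
                              trajectory_spec(2, 0, starts = 3,
                                              include_med_covariate = FALSE))
  means <- vapply(fit$beta, function(b) unname(b["t0"]), numeric(1))
  expect_lt(abs(means[1] - 40), 1.5)
  expect_lt(abs(means[2] - 80), 1.5)
  expect_lt(abs(fit$pi[1] - mean(sim$group == 1)), 0.05)
  acc <- mean(fit$assignment == sim$group[fit$ids])
  expect_gte(acc, 0.99)
  # posterior rows sum to 1; shares sum to 1
  expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$n_subjects),
               tolerance = 1e-12)
  expect_equal(sum(fit$share), 1)
  # EM objective non-decreasing within the winning start
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
})

test_that("tiny-instance EM matches a direct-optimizer oracle", {
  sim <- make_flat_groups(6, c(40, 80), 2, seed = 33, visits = 4L)
  fit <- fit_trajectory_model(sim$data,
                              trajectory_spec(2, 0, starts = 5,
                                              include_med_covariate = FALSE))
  # independent oracle: direct optimization of the mixture log-likelihood
  y <- sim$data$value
  sub <- sim$data$id
  negll <- function(par) {
    m <- par[1:2]; s <- exp(par[3]); p1 <- plogis(par[4])
    ll_g <- vapply(1:2, function(g)
      tapply(dnorm(y, m[g], s, log = TRUE), sub, sum), numeric(6))
    -sum(apply(cbind(log(p1) + ll_g[, 1], log(1 - p1) + ll_g[, 2]),
               1, function(r) max(r) + log(sum(exp(r - max(r))))))
  }
  opt <- optim(c(38, 82, log(2), 0), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-4)

  # wide finite censoring bounds agree with the uncensored oracle too
  fit_c <- fit_trajectory_model(sim$data,
                                trajectory_spec(2, 0, starts = 5,
                                                y_min = -500, y_max = 500,
                                                include_med_covariate = FALSE))
  expect_equal(fit_c$loglik, -opt$value, tolerance = 1e-4)
})

test_that("censoring at an active bound uses tail mass and stays monotone", {
  set.seed(34)
  n <- 120
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- sort(sample(-10:0, 5))
    data.frame(id = i, rel_year = t, value = rnorm(5, 50, 6), on_med = FALSE)
  }))
  dat$value <- pmax(dat$value, 45)   # left-censor at 45
  fit <- fit_trajectory_model(dat,
                              trajectory_spec(1, 0, y_min = 45, starts = 1,
                                              include_med_covariate = FALSE))
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
  # the tobit fit recovers the latent (uncensored) location and scale, both
  # of which the censored sample distorts
  expect_lt(abs(unname(fit$beta[[1]]["t0"]) - 50), 1)
  expect_lt(abs(fit$sigma - 6), 1)
  expect_gt(fit$sigma, sd(dat$value))
})

test_that("the medication covariate effect is recovered", {
  set.seed(35)
  n <- 200
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- sort(sample(-10:0, 6))
    om <- t >= sample(-10:0, 1)
    data.frame(id = i, rel_year = t,
               value = rnorm(6, 180 - 20 * om, 8), on_med = om)
  }))
  fit <- fit_trajectory_model(dat, trajectory_spec(1, 0, starts = 1))
  expect_lt(abs(unname(fit$beta[[1]]["med"]) + 20), 1.5)
})

test_that("odds of correct classification follow the stated formula", {
  # APP equal to the mixing proportion: no better than chance
  expect_equal(compute_occ(0.3, 0.3), 1)
  # APP 0.85 at pi 0.5
  expect_equal(compute_occ(0.85, 0.5), (0.85 / 0.15), tolerance = 1e-10)
  expect_equal(round(compute_occ(0.85, 0.5), 3), 5.667)
  # perfect assignment
  expect_equal(compute_occ(1, 0.4), Inf)
  expect_error(compute_occ(c(0.9, 0.9), c(0, 1)), "proportions")
})

test_that("sweep selects by BIC under the admission rules", {
  sim <- make_flat_groups(150, c(40, 60, 85), 3, seed = 36)
  sel <- sweep_and_select(sim$data, n_groups = 1:4, orders = 0,
                          refine = FALSE, starts = 3,
                          include_med_covariate = FALSE, seed = 1)
  expect_equal(sel$status, "ok")
  expect_equal(sel$fit$spec$n_groups, 3L)
  # groups labeled by ascending year-0 mean
  means <- vapply(sel$fit$beta, function(b) unname(b["t0"]), numeric(1))
  expect_equal(means, sort(means))
  expect_true(all(sel$report$BIC[sel$report$n_groups == 3] <
                    sel$report$BIC[sel$report$n_groups == 2]))

  # a BIC-best fit failing a rule is rejected: demand larger minimum share
  sel2 <- sweep_and_select(sim$data, n_groups = 1:4, orders = 0,
                           refine = FALSE, starts = 3, min_share = 0.30,
                           include_med_covariate = FALSE, seed = 1)
  # the 3-group model has a ~20% group, so it is inadmissible here
  expect_true(sel2$status == "no admissible model" ||
                sel2$fit$spec$n_groups < 3L)

  # single-group data
  sim1 <- make_flat_groups(60, 55, 4, seed = 37)
  sel3 <- sweep_and_select(sim1$data, n_groups = 1:2, orders = 0,
                           refine = FALSE, starts = 3,
                           include_med_covariate = FALSE, seed = 1)
  expect_equal(sel3$fit$spec$n_groups, 1L)
  expect_equal(sel3$fit$app, 1)
})
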