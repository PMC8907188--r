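test_that("inv_logit is correct, stable and guarded", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(round(inv_logit(-0.31), 2), 0.42)
  expect_equal(inv_logit(c(-2, 2)), 1 / (1 + exp(c(2, -2))))
  lo <- inv_logit(-750)
  expect_true(lo >= 0 && lo < 1e-300)
  expect_equal(inv_logit(750), 1)
  expect_error(inv_logit(NaN), "NaN")
})

test_that("Beta-Binomial pmf normalises, hits known cases and the right mean", {
  # alpha = beta = 1 gives the uniform on 0..13
  expect_equal(beta_binomial_logpmf(0:13, 13, 0.5, 2), rep(log(1 / 14), 14))
  # normalisation over random parameter draws
  set.seed(1)
  for (i in 1:20) {
    N <- sample(1:20, 1)
    p <- runif(1, 0.05, 0.95)
    phi <- rgamma(1, 2, 0.1) + 0.01
    pm <- exp(beta_binomial_logpmf(0:N, N, p, phi))
    expect_equal(sum(pm), 1, tolerance = 1e-10)
    expect_equal(sum((0:N) * pm), N * p, tolerance = 1e-8)
  }
  # large phi approaches the Binomial pmf
  expect_equal(beta_binomial_logpmf(0:13, 13, 0.3, 1e6),
               dbinom(0:13, 13, 0.3, log = TRUE), tolerance = 1e-4)
  expect_error(beta_binomial_logpmf(14, 13, 0.5, 1), "0..N")
  expect_error(beta_binomial_logpmf(2, 13, 0.5, -1), "phi")
})

test_that("prior intervals reproduce the documented 95% bounds", {
  ci_n <- prior_interval(prior_spec("normal", mean = 0, sd = 10), 0.95)
  expect_equal(ci_n, c(-19.6, 19.6), tolerance = 1e-3)
  ci_g <- prior_interval(prior_spec("gamma", shape = 2, rate = 0.1), 0.95)
  expect_equal(round(ci_g, 1), c(2.4, 55.7))
  # interval widens monotonically with mass
  w <- sapply(c(0.5, 0.8, 0.95, 0.999), function(m)
    diff(prior_interval(prior_spec("normal", mean = 1, sd = 2), m)))
  expect_true(all(diff(w) > 0))
  # dirichlet marginals are Beta
  ci_d <- prior_interval(prior_spec("dirichlet", concentrations = c(1, 1, 1)))
  expect_equal(ci_d[1, ], qbeta(c(0.025, 0.975), 1, 2), tolerance = 1e-9)
  expect_error(prior_spec("gamma", shape = -1, rate = 1), "invalid")
})

test_that("posterior summaries report moments, quantiles and exceedance", {
  d <- data.frame(.chain = rep(1:2, each = 2), .iter = rep(1:2, 2),
                  a = c(-1, 1, 1, 1), b = rep(2, 4))
  s <- posterior_summary(d, threshold = 0)
  expect_equal(s$prob_gt[s$parameter == "a"], 0.75)
  expect_equal(s$mean[s$parameter == "a"], 0.5)
  expect_equal(s$sd[s$parameter == "b"], 0)
  expect_equal(s$prob_gt[s$parameter == "b"], 1)  # strictly greater than 0
  s2 <- posterior_summary(d, threshold = 2)
  expect_equal(s2$prob_gt[s2$parameter == "b"], 0)  # ties are not counted
  set.seed(2)
  z <- data.frame(.chain = rep(1:2, each = 5e4), .iter = 1, x = rnorm(1e5))
  sz <- posterior_summary(z)
  expect_lt(abs(sz$prob_gt - 0.5), 0.005)
  expect_lt(abs(sz$q97.5 - 1.96), 0.05)
})

test_that("split-chain Rhat separates mixed from unmixed chains", {
  set.seed(3)
  good <- cbind(rnorm(500), rnorm(500), rnorm(500), rnorm(500))
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(500), rnorm(500) + 100)
  expect_gt(rhat(bad), 1.1)
  expect_true(is.na(rhat(matrix(1, 100, 2))))
  expect_error(rhat(matrix(1, 100, 1)), "2 chains")
  # a within-chain trend (first half != second half) is flagged too
  trended <- cbind(c(rnorm(250), rnorm(250) + 10), c(rnorm(250), rnorm(250) + 10))
  expect_gt(rhat(trended), 1.1)
})

test_that("point-biserial correlation matches the Pearson oracle", {
  y <- c(1, 1, 1, 0, 0, 0)
  x <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  pb <- point_biserial(y, x)
  # independent oracle: explicit Pearson formula
  r_hand <- sum((y - mean(y)) * (x - mean(x))) /
    sqrt(sum((y - mean(y))^2) * sum((x - mean(x))^2))
  expect_equal(pb$r, r_hand, tolerance = 1e-12)
  expect_equal(round(pb$r, 3), 0.965)
  expect_true(pb$ci[1] < pb$r && pb$r < pb$ci[2])
  expect_equal(point_biserial(y, y)$r, 1)
  set.seed(4)
  yy <- rbinom(10000, 1, 0.5)
  xx <- rnorm(10000)
  expect_lt(abs(point_biserial(yy, xx)$r), 0.03)
  expect_error(point_biserial(rep(1, 5), rnorm(5)), "constant")
})

test_that("the proprandom count model recovers generating parameters", {
  set.seed(5)
  spec <- betabinom_gen_spec()  # truths 1.34, -1.45, phi 1.17, n = 45
  dat <- generate_beta_binomial_dataset(spec)
  fit <- suppressWarnings(fit_model_a(dat, mcmc = test_mcmc(2000L, seed = 5)))
  s <- posterior_summary(fit)
  expect_setequal(s$parameter, c("beta0", "beta1", "phi"))
  b1 <- s[s$parameter == "beta1", ]
  # slope estimate is negative and the posterior interval is sane
  expect_lt(b1$mean, 1)
  expect_true(b1$q2.5 < b1$q97.5)
  expect_gt(s[s$parameter == "phi", "mean"], 0)
  expect_equal(fit$meta$chains, 2L)
  expect_equal(nrow(fit$draws), 2L * 1000L)
  expect_true(all(is.finite(fit$meta$rhat)))
})

test_that("a zero-length dataset yields prior-only posteriors", {
  empty <- data.frame(resp = integer(0), proprandom = numeric(0),
                      N = integer(0))
  fit <- fit_model_a(empty, mcmc = test_mcmc(4000L, seed = 6))
  s <- posterior_summary(fit)
  prior_n <- prior_interval(prior_spec("normal", mean = 0, sd = 10), 0.95)
  prior_g <- prior_interval(prior_spec("gamma", shape = 2, rate = 0.1), 0.95)
  b0 <- s[s$parameter == "beta0", ]
  expect_lt(abs(b0$q2.5 - prior_n[1]), 1.5)
  expect_lt(abs(b0$q97.5 - prior_n[2]), 1.5)
  ph <- s[s$parameter == "phi", ]
  expect_lt(abs(ph$q2.5 - prior_g[1]), 0.6)
  expect_lt(abs(ph$q97.5 - prior_g[2]), 6)
})

test_that("the RLLevel model and its derived probabilities behave per draw", {
  set.seed(7)
  M <- rep(c(0, 1, 0), each = 15); H <- rep(c(0, 0, 1), each = 15)
  p <- inv_logit(-0.31 + 0.79 * M + 1.16 * H)
  theta <- rbeta(45, p * 1.2, (1 - p) * 1.2)
  dat <- data.frame(resp = rbinom(45, 13, theta), M = M, H = H, N = 13)
  fit <- suppressWarnings(fit_model_b(dat, mcmc = test_mcmc(2000L, seed = 7)))
  expect_setequal(fit$params, c("gamma0", "gamma1", "gamma2", "phi"))
  dp <- derived_probabilities(fit)
  d <- dp$draws
  expect_true(all(d$p_none > 0 & d$p_none < 1))
  expect_true(all(d$p_high > 0 & d$p_high < 1))
  # exact per-draw transform, not a plug-in of means
  expect_equal(d$p_medium,
               inv_logit(fit$draws$gamma0 + fit$draws$gamma1),
               tolerance = 1e-12)
  # Jensen gap: plug-in of means differs from the mean of transforms
  plug <- inv_logit(mean(fit$draws$gamma0) + mean(fit$draws$gamma1))
  expect_false(isTRUE(all.equal(plug, mean(d$p_medium), tolerance = 1e-6)))
  # group column stands in for dummies
  dat2 <- data.frame(resp = dat$resp, N = 13,
                     group = rep(c("None", "Medium", "High"), each = 15))
  fit2 <- suppressWarnings(fit_model_b(dat2, mcmc = test_mcmc(seed = 7)))
  expect_setequal(fit2$params, c("gamma0", "gamma1", "gamma2", "phi"))
})

test_that("the action model enforces the simplex on every draw", {
  set.seed(8)
  trials <- generate_action_effect_dataset(n_participants = 30, N = 13)
  fit <- suppressWarnings(
    fit_action_model(trials, mcmc = test_mcmc(2000L, seed = 8)))
  b <- fit$draws[, c("b_vl", "b_pl", "b_bu")]
  expect_true(all(abs(rowSums(b) - 1) < 1e-9))
  expect_true(all(b >= 0))
  expect_equal(fit$meta$n_subjects, 30L)
  # one-hot violations are rejected with the row number
  bad <- trials
  bad$vl[4] <- 1L; bad$pl[4] <- 1L
  expect_error(fit_action_model(bad), "row 4")
})

test_that("posterior predictive counts reflect over-dispersion", {
  set.seed(9)
  # strongly over-dispersed synthetic counts
  spec <- betabinom_gen_spec(n_participants = 45, beta0 = 0.4, beta1 = 0,
                             phi = 0.8, proprandom_values = rep(0.5, 45))
  dat <- generate_beta_binomial_dataset(spec)
  fit_bb <- suppressWarnings(fit_model_a(dat, mcmc = test_mcmc(seed = 9)))
  fit_bin <- suppressWarnings(
    fit_model_a(dat, mcmc = test_mcmc(seed = 9), likelihood = "binomial"))
  sim_bb <- posterior_predictive_resp(fit_bb, dat, 4000)
  sim_bin <- posterior_predictive_resp(fit_bin, dat, 4000)
  expect_true(all(sim_bb >= 0 & sim_bb <= 13))
  obs_p <- prop.table(table(factor(dat$resp, levels = 0:13)))
  tv <- function(sim) {
    sp <- prop.table(table(factor(sim, levels = 0:13)))
    sum(abs(sp - obs_p)) / 2
  }
  # the Beta-Binomial reproduces the spread; the Binomial cannot
  expect_lt(tv(sim_bb), tv(sim_bin))
  expect_identical(posterior_predictive_resp(fit_bb, dat, 0), integer(0))
})

test_that("per-trial predictive simulation supports the point-biserial check", {
  set.seed(10)
  trials <- generate_action_effect_dataset(n_participants = 20, N = 13,
                                           sigma_u = 1.5)
  fit <- suppressWarnings(
    fit_action_model(trials, mcmc = test_mcmc(1500L, seed = 10)))
  ysim <- posterior_predictive_y(fit, trials, n_sims = 2000)
  expect_true(all(ysim %in% 0:1))
  pm <- posterior_predictive_y(fit, trials, type = "mean_prob")
  expect_length(pm, nrow(trials))
  expect_true(all(pm > 0 & pm < 1))
  # subject effects are informative, so the fit summary is clearly positive
  pb <- point_biserial(trials$y, pm)
  expect_gt(pb$r, 0.2)
})

test_that("generator and likelihood agree: the log-likelihood peaks near truth", {
  set.seed(11)
  spec <- betabinom_gen_spec(n_participants = 3000, beta0 = 0.5, beta1 = 0,
                             phi = 1.5, proprandom_values = rep(0, 3000))
  d <- generate_beta_binomial_dataset(spec)
  grid <- expand.grid(b0 = seq(-0.5, 1.5, 0.25), phi = c(0.5, 1, 1.5, 3, 8))
  ll <- mapply(function(b0, phi)
    sum(beta_binomial_logpmf(d$resp, 13, inv_logit(b0), phi)),
    grid$b0, grid$phi)
  best <- grid[which.max(ll), ]
  expect_equal(best$b0, 0.5)
  expect_equal(best$phi, 1.5)
})
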