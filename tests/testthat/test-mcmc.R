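test_that("the temperature schedule is a power law from prior to posterior", {
  b <- temperature_schedule(16, 5)
  expect_equal(b[1], 0)
  expect_equal(b[16], 1)
  expect_equal(b[2], (1 / 15)^5, tolerance = 1e-15)
  expect_equal(temperature_schedule(2, 1), c(0, 1))
  for (n in c(2, 4, 16)) for (ord in c(1, 3, 5))
    expect_true(all(diff(temperature_schedule(n, ord)) > 0))
  expect_error(temperature_schedule(1, 5), "at least 2")
})

test_that("a conjugate Gaussian posterior is recovered through the sampler", {
  set.seed(33)
  y <- rnorm(20, 1.2, 1)
  tau2 <- 4
  ll <- function(th) sum(dnorm(y, th, 1, log = TRUE))
  lp <- function(th) dnorm(th, 0, sqrt(tau2), log = TRUE)
  cfg <- chain_config(n_chains = 4, schedule_order = 5, n_samples = 6000,
                      n_burnin = 1000, target_accept = 0.44, seed = 2)
  fit <- pt_mcmc(ll, lp, function() rnorm(1), cfg)
  draws <- drop(posterior_draws(fit))
  v_post <- 1 / (length(y) + 1 / tau2)
  m_post <- v_post * sum(y)
  expect_equal(mean(draws), m_post, tolerance = 0.03)
  expect_equal(var(draws), v_post, tolerance = 0.2)
})

test_that("the beta = 0 chain reproduces the prior moments of an invgamma model", {
  # unit-rate mean prior: expectation 0.55, variance 0.5; outlier rate: 0.5
  pr <- default_prior("m6")
  cfg <- chain_config(n_chains = 2, schedule_order = 5, n_samples = 21000,
                      n_burnin = 1000, seed = 9)
  fit <- pt_mcmc(function(th) 0, function(th) log_prior(th, pr),
                 function() drop(sample_prior(pr, 1)), cfg)
  b0 <- fit$theta[1001:21000, , 1]
  batch_se <- function(x, n_batch = 20) {
    bm <- colMeans(matrix(x, ncol = n_batch))
    sd(bm) / sqrt(n_batch)
  }
  mu_r <- exp(b0[, "early_pro.lnmean"])
  expect_lt(abs(mean(mu_r) - 0.55), 3 * batch_se(mu_r))
  s2_r <- exp(b0[, "late_anti.lnvar"])
  expect_lt(abs(mean(s2_r) - 0.1), 3 * batch_se(s2_r))
  eta <- plogis(b0[, "logit_eta"])
  expect_lt(abs(mean(eta) - 0.5), 3 * batch_se(eta))
})

test_that("identical seeds give identical chains; different seeds differ", {
  ll <- function(th) dnorm(th, 2, 1, log = TRUE)
  lp <- function(th) dnorm(th, 0, 3, log = TRUE)
  cfg <- chain_config(n_chains = 3, schedule_order = 2, n_samples = 500,
                      n_burnin = 200, seed = 77)
  f1 <- pt_mcmc(ll, lp, function() rnorm(1), cfg)
  f2 <- pt_mcmc(ll, lp, function() rnorm(1), cfg)
  expect_identical(f1$theta, f2$theta)
  cfg$seed <- 78
  f3 <- pt_mcmc(ll, lp, function() rnorm(1), cfg)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("initialization fails loudly when no finite likelihood exists", {
  cfg <- chain_config(n_chains = 2, n_samples = 100, n_burnin = 10, seed = 1)
  expect_error(pt_mcmc(function(th) NaN, function(th) 0,
                       function() rnorm(1), cfg),
               "could not initialize")
})

test_that("the split Gelman-Rubin statistic separates mixed from stuck chains", {
  set.seed(44)
  same <- lapply(1:2, function(i) rnorm(1e4))
  r_same <- gelman_rubin(same)
  expect_true(r_same > 0.99 && r_same < 1.05)
  apart <- list(rnorm(1e4), rnorm(1e4) + 5)
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(list(1, 2)), "at least 2")
})

test_that("thermodynamic integration recovers closed-form evidences", {
  # Jeffreys Beta-Bernoulli, 2 successes in 6 trials
  n <- 6; k <- 2
  exact <- lbeta(k + 0.5, n - k + 0.5) - lbeta(0.5, 0.5)
  ll <- function(th) {
    p <- plogis(th)
    k * log(p) + (n - k) * log1p(-p)
  }
  lp <- function(th) {
    p <- plogis(th)
    dbeta(p, 0.5, 0.5, log = TRUE) + log(p) + log1p(-p)
  }
  cfg <- chain_config(n_chains = 8, schedule_order = 5, n_samples = 6000,
                      n_burnin = 1000, target_accept = 0.44, seed = 1)
  lme <- thermodynamic_lme(pt_mcmc(ll, lp, function() rnorm(1), cfg))
  expect_lt(abs(lme - exact), 0.05)

  # likelihood identically one: evidence is exactly 0
  flat <- pt_mcmc(function(th) 0, function(th) dnorm(th, log = TRUE),
                  function() rnorm(1),
                  chain_config(n_chains = 4, n_samples = 400, n_burnin = 100,
                               seed = 4))
  expect_identical(thermodynamic_lme(flat), 0)
})

test_that("refining the temperature grid reduces the integration error", {
  set.seed(55)
  n <- 10; k <- 3
  exact <- lbeta(k + 0.5, n - k + 0.5) - lbeta(0.5, 0.5)
  ll <- function(th) {
    p <- plogis(th)
    k * log(p) + (n - k) * log1p(-p)
  }
  lp <- function(th) {
    p <- plogis(th)
    dbeta(p, 0.5, 0.5, log = TRUE) + log(p) + log1p(-p)
  }
  err <- sapply(c(4, 16), function(nc) {
    cfg <- chain_config(n_chains = nc, schedule_order = 5, n_samples = 8000,
                        n_burnin = 1000, target_accept = 0.44, seed = 6)
    fit <- pt_mcmc(ll, lp, function() rnorm(1), cfg)
    abs(thermodynamic_lme(fit, correction = FALSE) - exact)
  })
  expect_lt(err[2], err[1])
})

test_that("the prior support rejects gamma units without finite RT moments", {
  pr <- default_prior("m7") # all-gamma SERIA: constraint active
  th <- drop(sample_prior(pr, 1))
  expect_true(is.finite(log_prior(th, pr)))
  bad <- th
  bad["early_pro.lnmean"] <- log(0.3)
  bad["early_pro.lnvar"] <- log(0.3) # k = 0.3 < 2
  expect_identical(log_prior(bad, pr), -Inf)
  # SERIA_lr late units are exempt
  pr13 <- default_prior("m12") # all-gamma SERIA_lr
  th13 <- drop(sample_prior(pr13, 1))
  th13["late_pro_pro.lnmean"] <- log(0.3)
  th13["late_pro_pro.lnvar"] <- log(0.3)
  expect_true(is.finite(log_prior(th13, pr13)))
  # and prior draws always satisfy the constraint
  draws <- sample_prior(pr, 200)
  k <- exp(2 * draws[, "early_pro.lnmean"] - draws[, "early_pro.lnvar"])
  expect_true(all(k > 2))
})
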