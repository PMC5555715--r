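test_that("late-race win probabilities are symmetric, complementary and exact", {
  a <- rate_spec_from_moments("invgamma", 0.3, 0.02)
  b <- rate_spec_from_moments("invgamma", 0.42, 0.03)
  expect_equal(prob_late_anti(a, a), 0.5, tolerance = 1e-8)
  expect_equal(prob_late_anti(a, b) + prob_late_anti(b, a), 1,
               tolerance = 1e-8)
  # far-dominated unit almost never wins
  slow <- rate_spec_from_moments("invgamma", 0.05, 0.0001)
  fast <- rate_spec_from_moments("invgamma", 2.0, 0.0001)
  expect_lt(prob_late_anti(slow, fast), 0.01)
  # Monte-Carlo cross-check
  set.seed(91)
  for (i in 1:3) {
    x <- random_rate_spec("invgamma")
    y <- random_rate_spec("lognormal")
    n <- 2e5
    phat <- mean(1 / sample_rates(x, n) < 1 / sample_rates(y, n))
    se <- sqrt(phat * (1 - phat) / n)
    expect_lt(abs(prob_late_anti(x, y) - phat), 3 * se + 1e-4)
  }
})

test_that("conditional late response times match symmetry, limits and MC", {
  a <- rate_spec_from_moments("invgamma", 0.3, 0.02)
  b <- rate_spec_from_moments("invgamma", 0.42, 0.03)
  expect_equal(late_response_time(a, a), late_response_time(a, a))
  # loser pushed to +infinity: conditional mean -> unconditional arrival mean
  never <- rate_spec_from_moments("invgamma", 0.001, 1e-8)
  expect_equal(late_response_time(a, never), arrival_mean(a),
               tolerance = 1e-3)
  set.seed(92)
  n <- 2e5
  ta <- 1 / sample_rates(a, n)
  tb <- 1 / sample_rates(b, n)
  win <- ta < tb
  mc <- mean(ta[win])
  se <- sd(ta[win]) / sqrt(sum(win))
  expect_lt(abs(late_response_time(a, b) - mc), 3 * se)
})

test_that("error decomposition sums to one and matches simulator latents", {
  p <- test_params_lr(eta = 0.03)
  for (tt in c("pro", "anti")) {
    d <- error_decomposition(p, tt)
    expect_equal(d$p_inhibition_failure + d$p_late_correct +
                   d$p_late_error + d$p_outlier, 1, tolerance = 1e-4)
    expect_true(all(unlist(d) >= 0))
  }
  set.seed(93)
  n <- 1e5
  sim <- simulate_trials(p, "anti", n = n)
  d <- error_decomposition(p, "anti")
  for (pair in list(
    c(d$p_inhibition_failure, mean(sim$response_class == "early")),
    c(d$p_late_correct, mean(sim$response_class == "late" &
                               sim$action == "anti")),
    c(d$p_late_error, mean(sim$response_class == "late" &
                             sim$action == "pro")),
    c(d$p_outlier, mean(sim$response_class == "outlier")))) {
    se <- sqrt(pair[1] * (1 - pair[1]) / n)
    expect_lt(abs(pair[1] - pair[2]), 3 * se + 1e-4)
  }
})

test_that("error decomposition limits: no inhibition, symmetric late units", {
  # inhibitory unit arriving almost immediately stops every early response
  p <- test_params_lr(eta = 0)
  u <- p$units
  u$inhib <- rate_spec_from_moments("gamma", 500, 100) # arrival ~ 2 ms
  p_fast <- race_params("m13c", u, delta = 0.5, delta_a = 0.3, eta = 0)
  d <- error_decomposition(p_fast, "anti")
  expect_lt(d$p_inhibition_failure, 1e-3)
  expect_equal(d$p_late_correct + d$p_late_error, 1, tolerance = 1e-3)

  shared <- rate_spec_from_moments("invgamma", 0.3, 0.02)
  p_sym <- race_params("m13c", list(
    early = u$early, inhib = test_params_lr()$units$inhib,
    late_pro_pro = shared, late_pro_anti = shared,
    late_anti_pro = shared, late_anti_anti = shared),
    delta = 0.5, delta_a = 0.3, eta = 0)
  ds <- error_decomposition(p_sym, "anti")
  expect_equal(ds$p_late_correct, ds$p_late_error, tolerance = 1e-6)
})

test_that("posterior arrival summaries average draws and convert units", {
  p <- test_params_lr()
  th <- params_to_theta(p)
  # single-draw posterior stub
  fit <- structure(list(
    theta = array(rep(th, each = 2), c(2, length(th), 1),
                  dimnames = list(NULL, names(th), NULL)),
    log_lik = matrix(0, 2, 1), betas = 1, n_burnin = 0,
    par_names = names(th), acceptance = 1, swap_rate = NA,
    model_id = "m13c"), class = "pt_samples")
  out <- mean_arrival_posterior(fit, "early", thin = 1)
  expect_equal(out$mean_ms,
               100 * (arrival_mean(p$units$early) + p$delta),
               tolerance = 1e-9)
  expect_equal(out$frac_infinite, 0)
})

test_that("corrective-antisaccade prediction: shift estimation and normalization", {
  p <- test_params_lr()
  pred0 <- corrective_rt_prediction(p)
  expect_true(is.na(pred0$shift_ms))
  expect_equal(sum(pred0$density) * 1, # 1 ms grid
               1, tolerance = 0.02)
  # observed RTs equal to the predicted mean: zero shift
  predA <- corrective_rt_prediction(p,
    observed_corrective_rt_ms = rep(pred0$predicted_mean_ms, 5))
  expect_equal(predA$shift_ms, 0, tolerance = 1e-9)
  # synthetic corrective saccades delayed by 80 ms recover the shift
  set.seed(94)
  n <- 2e5
  la <- p$units$late_anti_anti
  lp <- p$units$late_pro_anti
  ta <- 1 / sample_rates(la, n)
  tp <- 1 / sample_rates(lp, n)
  win <- ta < tp
  obs_ms <- 100 * (ta[win] + p$delta + p$delta_a) + 80
  predB <- corrective_rt_prediction(p, observed_corrective_rt_ms = obs_ms)
  expect_equal(predB$shift_ms, 80, tolerance = 3)
})

test_that("predicted RT curves integrate to the non-outlier mass", {
  p <- test_params_lr(eta = 0.04)
  # above the outlier band (t < delta) the race carries mass 1 - eta
  d <- predicted_rt_density(p, "anti", grid_ms = seq(100.5, 1500, by = 1))
  area <- sum(d$density_pro + d$density_anti)
  expect_equal(area, 1 - p$eta, tolerance = 0.01)
  expect_error(predicted_rt_density(p, "anti", grid_ms = c(-5, 100)),
               "above")
})

test_that("reciprobit transform linearizes reciprocal-normal latencies", {
  set.seed(95)
  rate <- rnorm(1e4, 0.005, 0.001) # 1/ms scale
  rate <- rate[rate > 0.001]
  rc <- reciprobit_curve(1 / rate)
  keep <- rc$y > qnorm(0.01) & rc$y < qnorm(0.99)
  fit <- lm(y ~ x, data = rc[keep, ])
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_error(reciprobit_curve(c(-1, 100)), "positive")
})
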