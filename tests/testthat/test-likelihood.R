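test_that("compiled densities agree with the adaptive-quadrature reference", {
  set.seed(61)
  grid <- seq(0.05, 7.5, by = 0.41)
  # one prior draw per structural family plus the fixtures
  cases <- list(test_params_prosa(), test_params_seria(), test_params_lr(),
                random_params("m1"), random_params("m9"), random_params("m12"),
                random_params("m5c"))
  for (p in cases) {
    for (tt in c("pro", "anti")) for (a in c("pro", "anti")) {
      fast <- trial_density(p, tt, a, grid)
      ref <- trial_density(p, tt, a, grid, method = "reference")
      expect_equal(fast, ref, tolerance = 1e-8)
      # the sampler's 7-node rule stays close
      fast7 <- trial_density(p, tt, a, grid, n_nodes = 7)
      expect_equal(fast7, ref, tolerance = 1e-5)
    }
  }
})

test_that("both decompositions of the no-early-response probability agree", {
  # P(no early before u) = S_e(u) + int f_e F_i  =  S_e(u)S_i(u) + int f_i S_e
  p <- test_params_lr()
  e <- p$units$early
  i <- p$units$inhib
  for (u in c(0.4, 1.1, 2.7)) {
    a <- arrival_survival(e, u) +
      integrate(function(x) arrival_pdf(e, x) * arrival_cdf(i, x), 0, u,
                rel.tol = 1e-11)$value
    b <- arrival_survival(e, u) * arrival_survival(i, u) +
      integrate(function(x) arrival_pdf(i, x) * arrival_survival(e, x), 0, u,
                rel.tol = 1e-11)$value
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("total probability over actions and time is 1 for random draws", {
  set.seed(71)
  for (id in c("m2", "m7c", "m11")) {
    for (i in 1:4) {
      p <- random_params(id)
      tt <- if (i %% 2) "pro" else "anti"
      expect_equal(density_total_mass(p, tt), 1, tolerance = 1e-4)
    }
  }
})

test_that("PROSA is the SERIA special case pi_e = 1, pi_l = 0", {
  # identical units mapped pro<->early, stop<->inhib, anti<->late
  units_s <- list(early = rate_spec_from_moments("gamma", 0.55, 0.04),
                  inhib = rate_spec_from_moments("gamma", 0.7, 0.06),
                  late = rate_spec_from_moments("invgamma", 0.3, 0.02))
  seria <- race_params("m8c", units_s, delta = 0.5, delta_a = 0.3,
                       eta = 0.02, pi_l = c(pro = 0, anti = 0), pi_e = 1)
  prosa <- race_params("m3c", list(
    pro = units_s$early,
    stop_pro = units_s$inhib, stop_anti = units_s$inhib,
    anti_pro = units_s$late, anti_anti = units_s$late),
    delta = 0.5, delta_a = 0.3, eta = 0.02)
  grid <- seq(0.05, 8, by = 0.13)
  for (tt in c("pro", "anti")) for (a in c("pro", "anti")) {
    ds <- trial_density(seria, tt, a, grid)
    dp <- trial_density(prosa, tt, a, grid)
    expect_equal(ds, dp, tolerance = 1e-10)
  }
})

test_that("a slow stop unit reduces the PROSA antisaccade term to its limit", {
  units <- list(pro = rate_spec_from_moments("gamma", 0.55, 0.04),
                stop_pro = rate_spec_from_moments("gamma", 0.01, 1e-5),
                stop_anti = rate_spec_from_moments("gamma", 0.01, 1e-5),
                anti_pro = rate_spec_from_moments("invgamma", 0.35, 0.02),
                anti_anti = rate_spec_from_moments("invgamma", 0.35, 0.02))
  p <- race_params("m3c", units, delta = 0.4, delta_a = 0.2, eta = 0)
  t <- c(1.2, 2.5, 4)
  u <- t - p$delta
  v <- u - p$delta_a
  lim <- arrival_pdf(units$anti_anti, v) *
    arrival_survival(units$pro, u) # integral term -> 0
  expect_equal(trial_density(p, "anti", "anti", t), lim, tolerance = 1e-6)
})

test_that("identical SERIA_lr late units give identical late-action densities", {
  shared <- rate_spec_from_moments("invgamma", 0.3, 0.02)
  p <- race_params("m13c", list(
    early = rate_spec_from_moments("gamma", 0.55, 0.04),
    inhib = rate_spec_from_moments("gamma", 0.7, 0.06),
    late_pro_pro = shared, late_pro_anti = shared,
    late_anti_pro = shared, late_anti_anti = shared),
    delta = 0.5, delta_a = 0.3, eta = 0)
  grid <- seq(0.9, 6, by = 0.31) # beyond delta + delta_a
  d_anti <- trial_density(p, "anti", "anti", grid)
  d_pro <- trial_density(p, "anti", "pro", grid)
  # subtract the early-response term from the pro-action density
  u <- grid - p$delta
  early_term <- arrival_pdf(p$units$early, u) *
    arrival_survival(p$units$inhib, u) *
    arrival_survival(shared, u - p$delta_a)^2
  expect_equal(d_pro - early_term, d_anti, tolerance = 1e-10)
})

test_that("the early-outlier component has the documented form and mass", {
  p <- test_params_lr(eta = 0.1, delta = 0.6)
  expect_equal(trial_density(p, "pro", "pro", 0.3),
               0.1 / 0.6 * 100 / 101, tolerance = 1e-12)
  expect_equal(trial_density(p, "anti", "anti", 0.3),
               0.1 / 0.6 * 1 / 101, tolerance = 1e-12)
  mass <- integrate(function(t) trial_density(p, "pro", "pro", t) +
                      trial_density(p, "pro", "anti", t), 0, p$delta,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 0.1, tolerance = 1e-10)
  p0 <- test_params_lr(eta = 0)
  expect_identical(trial_density(p0, "pro", "pro", 0.2), 0)
})

test_that("dataset log-likelihood sums per-trial logs and guards bad input", {
  p <- test_params_lr()
  tr <- data.frame(trial_type = c("pro", "anti", "anti"),
                   action = c("pro", "anti", "pro"),
                   rt_ds = c(1.2, 3.1, 1.9))
  one <- dataset_loglik(tr[1, ], p)
  expect_equal(one, log(trial_density(p, "pro", "pro", 1.2)),
               tolerance = 1e-9)
  expect_equal(dataset_loglik(tr, p),
               dataset_loglik(tr[1:2, ], p) + dataset_loglik(tr[3, , drop = FALSE], p),
               tolerance = 1e-9)
  expect_error(dataset_loglik(tr[0, ], p), "nonempty")
  expect_error(dataset_loglik(transform(tr, rt_ds = c(-1, 1, 1)), p),
               "positive")
  # zero-density trial is floored, not -Inf
  p0 <- test_params_lr(eta = 0)
  ll <- dataset_loglik(data.frame(trial_type = "pro", action = "pro",
                                  rt_ds = 0.1), p0)
  expect_true(is.finite(ll))
  expect_equal(ll, log(1e-300))
})

test_that("a stochastically faster inhibitory unit lowers the early-response mass", {
  base <- test_params_lr(eta = 0)
  early_mass <- function(inhib_mean) {
    u <- base$units
    u$inhib <- rate_spec_from_moments("gamma", 1 / inhib_mean, 0.06)
    p <- race_params("m13c", u, delta = 0.5, delta_a = 0.3, eta = 0)
    integrate(function(t) {
      x <- t - 0.5
      arrival_pdf(u$early, x) * arrival_survival(u$inhib, x) *
        arrival_survival(u$late_pro_pro, x - 0.3) *
        arrival_survival(u$late_anti_pro, x - 0.3)
    }, 0.5, Inf, rel.tol = 1e-8)$value
  }
  masses <- vapply(c(2.5, 1.8, 1.2, 0.8), early_mass, numeric(1))
  expect_true(all(diff(masses) < 0))
})

test_that("generating parameters outscore random prior draws in likelihood", {
  set.seed(81)
  p <- test_params_lr()
  trials <- preprocess_trials(simulate_experiment(p, 300, pp = 0.5, seed = 9))
  ll_true <- dataset_loglik(trials, p)
  prior <- default_prior("m13c")
  draws <- sample_prior(prior, 200)
  ll_draws <- apply(draws, 1, function(th)
    dataset_loglik(trials, theta_to_params(th, "m13c")))
  expect_gt(mean(ll_true > ll_draws), 0.95)
})
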