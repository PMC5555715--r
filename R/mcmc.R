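#' Power-law temperature schedule for parallel tempering
#'
#' Inverse temperatures \eqn{\beta_j = (j / (n-1))^{order}} for
#' \eqn{j = 0, \dots, n-1}: the first chain samples the prior
#' (\eqn{\beta = 0}), the last the full posterior (\eqn{\beta = 1}), and a
#' 5th-order schedule concentrates chains near the prior where the
#' integrand of the thermodynamic identity varies fastest.
#'
#' @param n_chains number of chains (>= 2).
#' @param order schedule order (>= 1; default 5).
#' @return increasing vector of inverse temperatures in `[0, 1]`.
#' @export
temperature_schedule <- function(n_chains, order = 5) {
  if (n_chains < 2) stop("parallel tempering needs at least 2 chains")
  stopifnot(order >= 1)
  (seq_len(n_chains) - 1)^order / (n_chains - 1)^order
}

#' Sampler configuration
#'
#' Defaults mirror the reference analysis settings (16 chains, 5th-order
#' schedule, 4.1e4 draws with 1.6e4 burn-in; truncated-normal models use
#' 6e4 / 2e4); scale them down for quick runs.
#'
#' @param n_chains number of tempered chains.
#' @param schedule_order temperature-schedule order.
#' @param n_samples total iterations per chain (including burn-in).
#' @param n_burnin adaptation/burn-in iterations, discarded from summaries.
#' @param swap_every attempt an adjacent-pair swap sweep every this many
#'   iterations.
#' @param target_accept within-chain Metropolis acceptance target.
#' @param seed integer seed, or `NULL`.
#' @export
chain_config <- function(n_chains = 16, schedule_order = 5,
                         n_samples = 41000, n_burnin = 16000,
                         swap_every = 10, target_accept = 0.234,
                         seed = NULL) {
  stopifnot(n_burnin < n_samples, n_chains >= 2)
  structure(list(n_chains = n_chains, schedule_order = schedule_order,
                 n_samples = n_samples, n_burnin = n_burnin,
                 swap_every = swap_every, target_accept = target_accept,
                 seed = seed),
            class = "chain_config")
}

#' Adaptive parallel-tempered Metropolis-Hastings
#'
#' Samples the tempered targets \eqn{p(\theta)\, p(y|\theta)^{\beta_j}}
#' with Gaussian random-walk proposals.  The proposal scale follows a
#' vanishing Robbins-Monro recursion towards the target acceptance rate
#' and the proposal covariance is re-estimated from the chain history at
#' intervals, both only during burn-in; proposals are frozen afterwards.
#' Adjacent chains exchange states by Metropolis swaps.  The function is
#' model-agnostic: any pair of log-density closures can be plugged in,
#' which is how the evidence machinery is validated on conjugate toy
#' problems.
#'
#' @param log_lik function(theta) -> scalar log-likelihood.
#' @param log_prior_fn function(theta) -> scalar log prior density
#'   (`-Inf` outside the support).
#' @param init either a numeric vector (used for every chain) or a
#'   function() -> numeric vector drawing initial states; initialization
#'   retries up to 100 times per chain for a finite posterior density.
#' @param config a [chain_config()].
#' @param init_scale initial per-coordinate proposal standard deviation.
#' @return an object of class `"pt_samples"`: `theta` (iterations x
#'   parameters x chains, unconstrained scale), `log_lik` (iterations x
#'   chains), `betas`, `n_burnin`, acceptance and swap-rate summaries.
#' @export
pt_mcmc <- function(log_lik, log_prior_fn, init, config = chain_config(),
                    init_scale = 0.1) {
  if (!is.null(config$seed)) set.seed(config$seed)
  betas <- temperature_schedule(config$n_chains, config$schedule_order)
  nc <- config$n_chains
  ni <- config$n_samples
  nb <- config$n_burnin

  draw_init <- if (is.function(init)) init else function() init
  d <- length(draw_init())
  theta <- matrix(NA_real_, d, nc)
  lp <- ll <- numeric(nc)
  for (c in seq_len(nc)) {
    ok <- FALSE
    for (try in 1:100) {
      cand <- draw_init()
      lpc <- log_prior_fn(cand)
      if (!is.finite(lpc)) next
      llc <- log_lik(cand)
      if (is.finite(llc)) {
        theta[, c] <- cand; lp[c] <- lpc; ll[c] <- llc; ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not initialize chain ", c,
                  ": no finite log-likelihood in 100 prior draws")
  }
  par_names <- names(draw_init())

  # per-chain proposal state
  log_s <- rep(log(init_scale), nc)
  chol_L <- replicate(nc, diag(d), simplify = FALSE)
  run_n <- 0
  run_mean <- matrix(0, d, nc)
  run_m2 <- replicate(nc, matrix(0, d, d), simplify = FALSE)

  out_theta <- array(NA_real_, c(ni, d, nc),
                     dimnames = list(NULL, par_names, NULL))
  out_ll <- matrix(NA_real_, ni, nc)
  acc <- rep(0, nc)
  swap_try <- swap_acc <- 0

  for (i in seq_len(ni)) {
    for (c in seq_len(nc)) {
      step <- exp(log_s[c]) * drop(chol_L[[c]] %*% stats::rnorm(d))
      cand <- theta[, c] + step
      names(cand) <- par_names
      lpc <- log_prior_fn(cand)
      a <- -Inf
      if (is.finite(lpc)) {
        llc <- log_lik(cand)
        a <- (lpc + betas[c] * llc) - (lp[c] + betas[c] * ll[c])
      }
      if (is.finite(a) && log(stats::runif(1)) < a) {
        theta[, c] <- cand; lp[c] <- lpc; ll[c] <- llc
        acc[c] <- acc[c] + 1
        accepted <- TRUE
      } else accepted <- FALSE
      if (i <= nb) {
        gam <- min(0.25, 3 / sqrt(i))
        log_s[c] <- log_s[c] +
          gam * ((if (accepted) 1 else 0) - config$target_accept)
      }
    }

    if (i <= nb) { # accumulate burn-in history for covariance adaptation
      run_n <- run_n + 1
      for (c in seq_len(nc)) {
        dlt <- theta[, c] - run_mean[, c]
        run_mean[, c] <- run_mean[, c] + dlt / run_n
        run_m2[[c]] <- run_m2[[c]] + tcrossprod(dlt, theta[, c] - run_mean[, c])
      }
      if (run_n >= max(100, 10 * d) && i %% 100 == 0) {
        for (c in seq_len(nc)) {
          S <- run_m2[[c]] / (run_n - 1) + 1e-8 * diag(d)
          Lc <- tryCatch(t(chol(S)), error = function(e) NULL)
          if (!is.null(Lc)) chol_L[[c]] <- Lc
        }
      }
    }

    if (i %% config$swap_every == 0 && nc >= 2) {
      for (c in seq_len(nc - 1)) {
        swap_try <- swap_try + 1
        la <- (betas[c] - betas[c + 1]) * (ll[c + 1] - ll[c])
        if (is.finite(la) && log(stats::runif(1)) < la) {
          swap_acc <- swap_acc + 1
          tmp <- theta[, c]; theta[, c] <- theta[, c + 1]; theta[, c + 1] <- tmp
          tmp <- lp[c]; lp[c] <- lp[c + 1]; lp[c + 1] <- tmp
          tmp <- ll[c]; ll[c] <- ll[c + 1]; ll[c + 1] <- tmp
        }
      }
    }

    out_theta[i, , ] <- theta
    out_ll[i, ] <- ll
  }

  structure(list(theta = out_theta, log_lik = out_ll, betas = betas,
                 n_burnin = nb, par_names = par_names,
                 acceptance = acc / ni,
                 swap_rate = if (swap_try) swap_acc / swap_try else NA_real_,
                 config = config),
            class = "pt_samples")
}

#' @export
print.pt_samples <- function(x, ...) {
  cat(sprintf(
    "<pt_samples> %d chains x %d iterations (%d burn-in), %d parameters\n",
    length(x$betas), nrow(x$log_lik), x$n_burnin, dim(x$theta)[2]))
  cat(sprintf("  acceptance: %.2f-%.2f, swap rate: %.2f\n",
              min(x$acceptance), max(x$acceptance), x$swap_rate))
  invisible(x)
}

#' Posterior draws at the target temperature
#'
#' @param fit a `pt_samples` object.
#' @param keep_burnin retain burn-in draws (default drops them).
#' @return matrix of unconstrained draws (iterations x parameters) from
#'   the `beta = 1` chain.
#' @export
posterior_draws <- function(fit, keep_burnin = FALSE) {
  stopifnot(inherits(fit, "pt_samples"))
  rows <- if (keep_burnin) seq_len(nrow(fit$log_lik))
          else (fit$n_burnin + 1):nrow(fit$log_lik)
  fit$theta[rows, , length(fit$betas), drop = FALSE][, , 1]
}

#' Potential scale reduction (split Gelman-Rubin diagnostic)
#'
#' Splits the post-burn-in target chain into segments and computes the
#' usual between/within variance ratio per parameter; values below 1.1
#' are conventionally taken as converged.
#'
#' @param x a `pt_samples` object, or a list of equally long numeric
#'   chains (vectors/matrices with matching columns).
#' @param n_splits number of segments when `x` is a `pt_samples` object.
#' @return named vector of statistics with attribute `converged`
#'   (all < 1.1).
#' @export
gelman_rubin <- function(x, n_splits = 4) {
  chains <- if (inherits(x, "pt_samples")) {
    draws <- posterior_draws(x)
    n <- nrow(draws) %/% n_splits
    if (n < 2) stop("too few draws for the requested number of splits")
    lapply(seq_len(n_splits), function(s)
      draws[((s - 1) * n + 1):(s * n), , drop = FALSE])
  } else {
    lapply(x, function(ch) if (is.matrix(ch)) ch else matrix(ch, ncol = 1))
  }
  m <- length(chains)
  n <- nrow(chains[[1]])
  if (m < 2 || n < 2) stop("need at least 2 chains with 2 draws each")
  p <- ncol(chains[[1]])
  stat <- vapply(seq_len(p), function(j) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(colMeans(draws))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(stat) <- colnames(chains[[1]])
  attr(stat, "converged") <- all(stat < 1.1)
  stat
}

#' Log model evidence by thermodynamic integration
#'
#' Integrates the posterior expectation of the log-likelihood over the
#' inverse-temperature schedule,
#' \eqn{\log p(y) = \int_0^1 E_\beta[\log p(y|\theta)]\, d\beta},
#' using the variance-corrected trapezoidal rule: since
#' \eqn{dE_\beta/d\beta = Var_\beta[\log p(y|\theta)]}, each segment's
#' trapezoid is corrected by
#' \eqn{-\Delta\beta^2 (V_{j+1} - V_j)/12}, which removes most of the
#' discretization bias of coarse schedules.  Because the mean
#' log-likelihood is nondecreasing in \eqn{\beta}, each segment's
#' trapezoid error is bounded by \eqn{\Delta\beta (E_{j+1} - E_j)/2};
#' the correction is clamped at that bound, which keeps the estimator
#' stable when the near-prior chains have enormous log-likelihood
#' variance.  Set `correction = FALSE` for the plain trapezoid.
#'
#' @param fit a `pt_samples` object with log-likelihood traces for every
#'   chain on the schedule.
#' @param correction apply the second-order variance correction
#'   (default `TRUE`).
#' @return scalar log model evidence (nats).
#' @export
thermodynamic_lme <- function(fit, correction = TRUE) {
  stopifnot(inherits(fit, "pt_samples"))
  rows <- (fit$n_burnin + 1):nrow(fit$log_lik)
  lls <- fit$log_lik[rows, , drop = FALSE]
  ebar <- colMeans(lls)
  if (anyNA(ebar)) stop("missing log-likelihood traces for some temperatures")
  b <- fit$betas
  h <- diff(b)
  e_lo <- ebar[-length(b)]
  e_hi <- ebar[-1]
  lme <- sum(h * (e_lo + e_hi) / 2)
  if (correction) {
    v <- apply(lls, 2, stats::var)
    corr <- h^2 / 12 * (v[-1] - v[-length(b)])
    # E(beta) is nondecreasing, so each segment's trapezoid error cannot
    # exceed h * (E_hi - E_lo) / 2; clamp the second-order correction
    # there — on coarse schedules the raw term can blow up through the
    # enormous log-likelihood variance of the near-prior chains
    cap <- h * pmax(e_hi - e_lo, 0) / 2
    lme <- lme - sum(sign(corr) * pmin(abs(corr), cap))
  }
  lme
}

#' Fit a race model to a preprocessed trial table
#'
#' Wraps [pt_mcmc()] with the trial-table likelihood, the default priors
#' and prior-draw initialization.  `trials` must be one subject and
#' condition, already preprocessed to decisecond reaction times.
#'
#' @param trials preprocessed trial table (needs `rt_ds`, `trial_type`,
#'   `action`).
#' @param model_id a model id from [model_registry()].
#' @param prior a [default_prior()]-shaped prior (defaults to it).
#' @param config a [chain_config()]; defaults follow the reference
#'   settings, with the longer truncated-normal schedule when the model
#'   contains truncnorm units.
#' @param init initialization: `NULL` draws each chain from the prior
#'   (the default), `"map"` starts every chain at a posterior mode found
#'   by a short optimization from the best of 100 prior draws (jittered
#'   per chain), or a numeric unconstrained vector (e.g. from
#'   [params_to_theta()]).
#' @param hmax,n_nodes inner-quadrature settings of the compiled
#'   likelihood (see [trial_density()]).
#' @return a `pt_samples` object with `model_id` attached.
#' @export
fit_model <- function(trials, model_id, prior = default_prior(model_id),
                      config = NULL, init = NULL, hmax = 0.2, n_nodes = 7) {
  info <- model_info(model_id)
  if (is.null(config)) {
    config <- if (info$early_family == "truncnorm" ||
                  info$late_family == "truncnorm")
      chain_config(n_samples = 60000, n_burnin = 20000)
    else chain_config()
  }
  ll <- make_loglik(trials, model_id, hmax = hmax, n_nodes = n_nodes)
  lp <- function(theta) log_prior(theta, prior)
  init_fn <- if (is.null(init)) {
    function() drop(sample_prior(prior, 1))
  } else if (identical(init, "map")) {
    map <- map_estimate(ll, lp, prior)
    function() map + stats::rnorm(length(map), 0, 0.02)
  } else init
  fit <- pt_mcmc(ll, lp, init_fn, config)
  fit$model_id <- model_id
  fit
}

# Posterior mode by multi-start Nelder-Mead (restarted once per start to
# escape simplex stagnation); the posterior can have spurious local modes
# trading the non-decision time against the outlier rate, so several
# starts from the best prior draws are kept.
map_estimate <- function(log_lik, log_prior_fn, prior, n_draws = 200,
                         n_starts = 4, maxit = 400) {
  draws <- sample_prior(prior, n_draws)
  lpost <- apply(draws, 1, function(th) {
    lp <- log_prior_fn(th)
    if (!is.finite(lp)) return(-Inf)
    lp + log_lik(th)
  })
  starts <- draws[order(lpost, decreasing = TRUE)[seq_len(n_starts)], ,
                  drop = FALSE]
  neg <- function(th) {
    names(th) <- prior$name
    lp <- log_prior_fn(th)
    if (!is.finite(lp)) return(1e10)
    -(lp + log_lik(th))
  }
  best_val <- Inf
  best_par <- starts[1, ]
  for (s in seq_len(n_starts)) {
    opt <- stats::optim(starts[s, ], neg, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    opt <- stats::optim(opt$par, neg, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (opt$value < best_val) {
      best_val <- opt$value
      best_par <- opt$par
    }
  }
  stats::setNames(best_par, prior$name)
}
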