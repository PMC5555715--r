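#' Prior distributions over model parameters
#'
#' Every model is sampled in an unconstrained space: unit rate means and
#' variances on the log scale, the non-decision time `delta` and late cost
#' `delta_a` on the log scale, and the probabilities `eta` (early
#' outliers) and `pi_l` (late prosaccade) on the logit scale.  The priors
#' are normal on the log coordinates — so lognormal on the natural scale,
#' with expected rate-mean 0.55 (variance 0.5), expected rate-variance 0.1
#' (variance 0.01), expected `delta` 0.5 ds (variance 1.25) and expected
#' `delta_a` 0.75 ds (variance 1.25) — and Jeffreys Beta(0.5, 0.5) on the
#' probabilities.  Truncated-normal units are parametrized natively:
#' `mu ~ N(0.55, 0.09)` (96% prior mass on positive locations) and the
#' usual log-variance prior.
#'
#' The parameter space is restricted so that the first two moments of the
#' rate and arrival-time distributions exist wherever the restriction can
#' bind: gamma-rate units must have shape `k > 2`.  Late units of SERIA_lr
#' models are exempt, allowing flat late-rate distributions with possibly
#' infinite arrival mean.
#'
#' @param model_id a model id from [model_registry()].
#' @return a data.frame of class `"race_prior"`: one row per unconstrained
#'   coordinate with columns `name`, `dist` (`"normal"` with mean/variance
#'   `a`/`b`, or `"beta"` with shapes `a`/`b` on the natural scale), and
#'   `constrained_unit` (gamma moment-existence restriction applies).
#' @export
default_prior <- function(model_id) {
  info <- model_info(model_id)
  u <- info$units
  rows <- list()
  for (i in seq_len(nrow(u))) {
    if (u$family[i] == "truncnorm") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(u$name[i], ".mu"), dist = "normal",
        a = 0.55, b = 0.09, constrained_unit = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(u$name[i], ".lnsigma2"), dist = "normal",
        a = -2.64, b = 0.69, constrained_unit = FALSE)
    } else {
      gam <- u$family[i] == "gamma" && !u$exempt[i]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(u$name[i], ".lnmean"), dist = "normal",
        a = -1.08, b = 0.97, constrained_unit = gam)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(u$name[i], ".lnvar"), dist = "normal",
        a = -2.64, b = 0.69, constrained_unit = gam)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "lndelta", dist = "normal", a = -1.58, b = 1.79,
    constrained_unit = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "lndelta_a", dist = "normal", a = -0.87, b = 1.17,
    constrained_unit = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "logit_eta", dist = "beta", a = 0.5, b = 0.5,
    constrained_unit = FALSE)
  if (info$structure == "seria") {
    for (tt in c("pro", "anti"))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("logit_pi_l_", tt), dist = "beta", a = 0.5, b = 0.5,
        constrained_unit = FALSE)
  }
  out <- do.call(rbind, rows)
  stopifnot(identical(out$name, param_names(info)))
  attr(out, "model_id") <- model_id
  class(out) <- c("race_prior", class(out))
  out
}

# gamma moment-existence restriction on the unconstrained scale:
# k = m^2/v > 2  <=>  2*lnmean - lnvar > log(2)
gamma_constraint_ok <- function(theta, prior) {
  cn <- prior$name[prior$constrained_unit]
  if (!length(cn)) return(TRUE)
  ln_m <- theta[cn[grepl("\\.lnmean$", cn)]]
  ln_v <- theta[cn[grepl("\\.lnvar$", cn)]]
  all(2 * ln_m - ln_v > log(2))
}

#' Prior log-density on the unconstrained scale
#'
#' Includes the logit Jacobian for Beta-distributed probabilities and
#' returns `-Inf` outside the moment-existence support.
#'
#' @param theta named numeric vector of unconstrained coordinates.
#' @param prior a [default_prior()] object.
#' @return scalar log-density.
#' @export
log_prior <- function(theta, prior) {
  if (!gamma_constraint_ok(theta, prior)) return(-Inf)
  x <- theta[prior$name]
  lp <- 0
  nrm <- prior$dist == "normal"
  lp <- lp + sum(stats::dnorm(x[nrm], prior$a[nrm], sqrt(prior$b[nrm]),
                              log = TRUE))
  if (any(!nrm)) {
    xb <- x[!nrm]
    p <- stats::plogis(xb)
    lp <- lp + sum(stats::dbeta(p, prior$a[!nrm], prior$b[!nrm], log = TRUE) +
                     log(p) + log1p(-p))
  }
  lp
}

#' @rdname log_prior
#' @param n number of draws.
#' @return `sample_prior()` returns an `n` x dim matrix of unconstrained
#'   draws inside the prior support.
#' @export
sample_prior <- function(prior, n = 1) {
  d <- nrow(prior)
  draw1 <- function() {
    x <- numeric(d)
    nrm <- prior$dist == "normal"
    x[nrm] <- stats::rnorm(sum(nrm), prior$a[nrm], sqrt(prior$b[nrm]))
    x[!nrm] <- stats::qlogis(stats::rbeta(sum(!nrm), prior$a[!nrm],
                                          prior$b[!nrm]))
    names(x) <- prior$name
    x
  }
  out <- matrix(NA_real_, n, d, dimnames = list(NULL, prior$name))
  for (i in seq_len(n)) {
    repeat {
      x <- draw1()
      if (gamma_constraint_ok(x, prior)) break
    }
    out[i, ] <- x
  }
  out
}

#' Map unconstrained coordinates to a parameter set (and back)
#'
#' `theta_to_params()` exponentiates log coordinates, inverse-logits the
#' probabilities and converts unit moments to natural rate parameters;
#' `params_to_theta()` is its inverse.
#'
#' @param theta named unconstrained vector (see [default_prior()] for the
#'   coordinate layout).
#' @param model_id a model id.
#' @return a [race_params()] object / a named numeric vector.
#' @export
theta_to_params <- function(theta, model_id) {
  info <- model_info(model_id)
  u <- info$units
  units <- stats::setNames(vector("list", nrow(u)), u$name)
  for (i in seq_len(nrow(u))) {
    units[[i]] <- if (u$family[i] == "truncnorm")
      rate_spec("truncnorm", theta[[paste0(u$name[i], ".mu")]],
                exp(theta[[paste0(u$name[i], ".lnsigma2")]]))
    else
      rate_spec_from_moments(u$family[i],
                             exp(theta[[paste0(u$name[i], ".lnmean")]]),
                             exp(theta[[paste0(u$name[i], ".lnvar")]]))
  }
  pi_l <- if (info$structure == "seria")
    c(pro = stats::plogis(theta[["logit_pi_l_pro"]]),
      anti = stats::plogis(theta[["logit_pi_l_anti"]]))
  race_params(model_id, units, delta = exp(theta[["lndelta"]]),
              delta_a = exp(theta[["lndelta_a"]]),
              eta = stats::plogis(theta[["logit_eta"]]), pi_l = pi_l)
}

#' @rdname theta_to_params
#' @param params a [race_params()] object.
#' @export
params_to_theta <- function(params) {
  info <- params$info
  u <- info$units
  th <- c()
  for (i in seq_len(nrow(u))) {
    sp <- params$units[[u$name[i]]]
    if (sp$family == "truncnorm") {
      th[paste0(u$name[i], ".mu")] <- sp$param1
      th[paste0(u$name[i], ".lnsigma2")] <- log(sp$param2)
    } else {
      th[paste0(u$name[i], ".lnmean")] <- log(rate_mean(sp))
      th[paste0(u$name[i], ".lnvar")] <- log(rate_variance(sp))
    }
  }
  th["lndelta"] <- log(params$delta)
  th["lndelta_a"] <- log(params$delta_a)
  th["logit_eta"] <- stats::qlogis(params$eta)
  if (info$structure == "seria") {
    th["logit_pi_l_pro"] <- stats::qlogis(params$pi_l[["pro"]])
    th["logit_pi_l_anti"] <- stats::qlogis(params$pi_l[["anti"]])
  }
  th[param_names(info)]
}
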