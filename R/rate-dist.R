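#' Parametric increase-rate distributions and induced arrival times
#'
#' A race unit accumulates linearly towards a unit threshold at a stochastic
#' increase rate \eqn{r > 0}, so its arrival time is the reciprocal rate,
#' \eqn{T = 1/r}.  Four rate families are supported: gamma, inverse gamma,
#' lognormal, and the normal distribution truncated to \eqn{r > 0}.  All
#' arrival-time quantities are obtained from the rate density by the change
#' of variables \eqn{f_T(t) = f_R(1/t) / t^2}; rates are in reciprocal
#' deciseconds and arrival times in deciseconds.
#'
#' @param family one of `"gamma"`, `"invgamma"`, `"lognormal"`, `"truncnorm"`.
#' @param param1 shape `k` (gamma, invgamma) or location `mu`
#'   (lognormal, truncnorm).
#' @param param2 scale `theta` (gamma, invgamma) or variance `sigma2`
#'   (lognormal, truncnorm).
#' @return `rate_spec()` returns an object of class `"rate_spec"`.
#' @examples
#' sp <- rate_spec("gamma", 3.025, 0.1818)
#' arrival_pdf(sp, 2)           # density of T = 1/r at 2 ds
#' arrival_mean(sp)             # E[T], finite because k > 1
#' @export
rate_spec <- function(family = c("gamma", "invgamma", "lognormal", "truncnorm"),
                      param1, param2) {
  family <- match.arg(family)
  stopifnot(is.numeric(param1), is.numeric(param2),
            length(param1) == 1L, length(param2) == 1L,
            is.finite(param1), is.finite(param2))
  if (family %in% c("gamma", "invgamma") && param1 <= 0)
    stop("shape parameter must be positive")
  if (param2 <= 0)
    stop("scale/variance parameter must be positive")
  structure(list(family = family, param1 = param1, param2 = param2),
            class = "rate_spec")
}

#' @export
print.rate_spec <- function(x, ...) {
  nm <- switch(x$family,
               gamma = c("shape k", "scale theta"),
               invgamma = c("shape k", "scale theta"),
               lognormal = c("mu", "sigma2"),
               truncnorm = c("mu", "sigma2"))
  cat(sprintf("<rate_spec> %s(%s = %.5g, %s = %.5g)\n",
              x$family, nm[1], x$param1, nm[2], x$param2))
  invisible(x)
}

rate_families <- c("gamma", "invgamma", "lognormal", "truncnorm")

#' Construct a rate distribution from its first two moments
#'
#' Inverts the mean/variance parametrization used for the prior
#' distributions: gamma rates use \eqn{k = m^2/v}, \eqn{\theta = v/m};
#' inverse-gamma rates use \eqn{k = m^2/v + 2}, \eqn{\theta = m(k-1)}
#' (so the requested variance always exists); lognormal rates use
#' \eqn{\sigma^2 = \log(1 + v/m^2)}, \eqn{\mu = \log m - \sigma^2/2}.
#' The truncated normal is parametrized natively by \eqn{(\mu, \sigma^2)}
#' and is not supported here.
#'
#' @param family rate family (not `"truncnorm"`).
#' @param mean,variance requested first two moments of the rate, both > 0.
#' @return a [rate_spec()] whose rate distribution has the requested moments.
#' @export
rate_spec_from_moments <- function(family, mean, variance) {
  family <- match.arg(family, rate_families)
  if (family == "truncnorm")
    stop("truncnorm is parametrized natively by (mu, sigma2), not by moments")
  if (!is.finite(mean) || !is.finite(variance) || mean <= 0 || variance <= 0)
    stop("mean and variance must be positive and finite")
  switch(family,
    gamma = rate_spec("gamma", mean^2 / variance, variance / mean),
    invgamma = {
      k <- mean^2 / variance + 2
      rate_spec("invgamma", k, mean * (k - 1))
    },
    lognormal = {
      s2 <- log1p(variance / mean^2)
      rate_spec("lognormal", log(mean) - s2 / 2, s2)
    })
}

# normalization constant of the zero-truncated normal: P(R > 0)
truncnorm_z <- function(mu, sigma) stats::pnorm(mu / sigma)

#' Density, distribution and sampling functions of a rate specification
#'
#' `rate_pdf()` is the density of the increase rate itself; it vanishes for
#' `r <= 0` in every family.  `rate_mean()` and `rate_variance()` return the
#' first two central moments of the rate (closed form in all families).
#' `sample_rates()` draws i.i.d. rates.
#'
#' @param spec a [rate_spec()].
#' @param r rate value(s), reciprocal deciseconds.
#' @param n number of draws.
#' @return numeric vector.
#' @export
rate_pdf <- function(spec, r) {
  out <- numeric(length(r))
  pos <- is.finite(r) & r > 0
  rp <- r[pos]
  out[pos] <- switch(spec$family,
    gamma = stats::dgamma(rp, shape = spec$param1, scale = spec$param2),
    invgamma = stats::dgamma(1 / rp, shape = spec$param1,
                             rate = spec$param2) / rp^2,
    lognormal = stats::dlnorm(rp, meanlog = spec$param1,
                              sdlog = sqrt(spec$param2)),
    truncnorm = {
      s <- sqrt(spec$param2)
      stats::dnorm(rp, spec$param1, s) / truncnorm_z(spec$param1, s)
    })
  out
}

#' @rdname rate_pdf
#' @export
rate_cdf <- function(spec, r) {
  out <- numeric(length(r))
  pos <- is.finite(r) & r > 0
  rp <- r[pos]
  out[pos] <- switch(spec$family,
    gamma = stats::pgamma(rp, shape = spec$param1, scale = spec$param2),
    invgamma = stats::pgamma(1 / rp, shape = spec$param1, rate = spec$param2,
                             lower.tail = FALSE),
    lognormal = stats::plnorm(rp, meanlog = spec$param1,
                              sdlog = sqrt(spec$param2)),
    truncnorm = {
      s <- sqrt(spec$param2)
      z <- truncnorm_z(spec$param1, s)
      (stats::pnorm(rp, spec$param1, s) - (1 - z)) / z
    })
  out[is.finite(r) & r == Inf] <- 1
  out
}

#' @rdname rate_pdf
#' @export
rate_mean <- function(spec) {
  switch(spec$family,
    gamma = spec$param1 * spec$param2,
    invgamma = if (spec$param1 > 1) spec$param2 / (spec$param1 - 1) else Inf,
    lognormal = exp(spec$param1 + spec$param2 / 2),
    truncnorm = {
      s <- sqrt(spec$param2)
      a <- -spec$param1 / s
      spec$param1 + s * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
    })
}

#' @rdname rate_pdf
#' @export
rate_variance <- function(spec) {
  switch(spec$family,
    gamma = spec$param1 * spec$param2^2,
    invgamma = {
      k <- spec$param1
      if (k > 2) spec$param2^2 / ((k - 1)^2 * (k - 2)) else Inf
    },
    lognormal = (exp(spec$param2) - 1) *
      exp(2 * spec$param1 + spec$param2),
    truncnorm = {
      s <- sqrt(spec$param2)
      a <- -spec$param1 / s
      lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
      spec$param2 * (1 + a * lam - lam^2)
    })
}

#' @rdname rate_pdf
#' @export
sample_rates <- function(spec, n) {
  switch(spec$family,
    gamma = stats::rgamma(n, shape = spec$param1, scale = spec$param2),
    invgamma = 1 / stats::rgamma(n, shape = spec$param1, rate = spec$param2),
    lognormal = stats::rlnorm(n, meanlog = spec$param1,
                              sdlog = sqrt(spec$param2)),
    truncnorm = {
      s <- sqrt(spec$param2)
      # inverse-CDF sampling restricted to the positive tail
      lo <- stats::pnorm(0, spec$param1, s)
      stats::qnorm(stats::runif(n, lo, 1), spec$param1, s)
    })
}

#' Arrival-time distribution induced by a rate specification
#'
#' With unit threshold the arrival time is \eqn{T = 1/r}, so
#' `arrival_pdf(spec, t) == rate_pdf(spec, 1/t) / t^2`,
#' `arrival_cdf(spec, t) == P(r >= 1/t)` and
#' `arrival_survival(spec, t) == 1 - arrival_cdf(spec, t)`.  All three
#' vanish appropriately for `t <= 0`.  `arrival_mean()` returns
#' \eqn{E[1/r]} in closed form where it exists and `Inf` where the moment
#' diverges (gamma rates with \eqn{k \le 1}; every truncated-normal rate,
#' whose density is positive at 0).
#'
#' @param spec a [rate_spec()].
#' @param t arrival time(s), deciseconds.
#' @return numeric vector (a scalar for `arrival_mean`).
#' @export
arrival_pdf <- function(spec, t) {
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  out[pos] <- rate_pdf(spec, 1 / tp) / tp^2
  out
}

#' @rdname arrival_pdf
#' @export
arrival_cdf <- function(spec, t) {
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  # T <= t  <=>  r >= 1/t
  out[pos] <- 1 - rate_cdf(spec, 1 / t[pos])
  out[is.finite(t) & t == Inf] <- 1
  out
}

#' @rdname arrival_pdf
#' @export
arrival_survival <- function(spec, t) {
  out <- rep(1, length(t))
  pos <- is.finite(t) & t > 0
  out[pos] <- rate_cdf(spec, 1 / t[pos])
  out[is.finite(t) & t == Inf] <- 0
  out
}

#' @rdname arrival_pdf
#' @export
arrival_mean <- function(spec) {
  switch(spec$family,
    # 1/r with r ~ Gamma(k, theta): mean 1/(theta (k-1)) iff k > 1
    gamma = if (spec$param1 > 1)
      1 / (spec$param2 * (spec$param1 - 1)) else Inf,
    # 1/r with r ~ InvGamma(k, theta): T ~ Gamma(k, rate theta)
    invgamma = spec$param1 / spec$param2,
    lognormal = exp(-spec$param1 + spec$param2 / 2),
    # truncated-normal rate density is positive at r = 0, so E[1/r] diverges
    truncnorm = Inf)
}

#' @rdname arrival_pdf
#' @export
arrival_variance <- function(spec) {
  switch(spec$family,
    gamma = if (spec$param1 > 2) {
      m <- 1 / (spec$param2 * (spec$param1 - 1))
      m2 <- 1 / (spec$param2^2 * (spec$param1 - 1) * (spec$param1 - 2))
      m2 - m^2
    } else Inf,
    invgamma = spec$param1 / spec$param2^2,
    lognormal = (exp(spec$param2) - 1) * exp(-2 * spec$param1 + spec$param2),
    truncnorm = Inf)
}
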