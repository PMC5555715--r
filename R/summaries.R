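#' Probability that one late unit beats another
#'
#' `prob_late_anti(a, b)` is \eqn{P(U_a < U_b) = \int_0^\infty
#' p(U_a = t)\, p(U_b > t)\, dt}: with `a` the late antisaccade unit and
#' `b` the late prosaccade unit this is the probability of a late
#' antisaccade, the SERIA_lr analogue of `1 - pi_l`.
#'
#' @param winner,loser [rate_spec()] objects for the two late units.
#' @return probability in `[0, 1]`.
#' @export
prob_late_anti <- function(winner, loser) {
  out <- stats::integrate(function(t)
    arrival_pdf(winner, t) * arrival_survival(loser, t),
    0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)
  if (out$message != "OK" && out$message != "the integral is probably divergent")
    stop("late-race integral failed: ", out$message)
  min(max(out$value, 0), 1)
}

#' Conditional mean response time of the winning late unit
#'
#' \eqn{E[U_w \mid U_w < U_l]}, the mean arrival time of the winner given
#' it wins the late race (deciseconds on the arrival scale; add
#' `delta + delta_a` for the observed response-time scale).  Returns `Inf`
#' when the conditional mean does not exist.
#'
#' @param winner,loser [rate_spec()] objects.
#' @return conditional mean arrival time in deciseconds.
#' @export
late_response_time <- function(winner, loser) {
  pw <- prob_late_anti(winner, loser)
  if (pw <= 0) stop("winner has zero probability of winning the late race")
  num <- stats::integrate(function(t)
    t * arrival_pdf(winner, t) * arrival_survival(loser, t),
    0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)
  if (!is.finite(num$value) || num$message == "the integral is probably divergent")
    return(Inf)
  num$value / pw
}

#' Decompose response probabilities into error sources
#'
#' Splits the unit probability mass of one trial type into: early
#' responses that escape inhibition (`p_inhibition_failure`; errors in
#' antisaccade trials, correct reactions in prosaccade trials), late
#' responses whose action matches the cue (`p_late_correct`) or not
#' (`p_late_error`), and early outliers (`p_outlier = eta`).  Components
#' sum to 1 up to quadrature tolerance.
#'
#' @param params a [race_params()] object.
#' @param trial_type `"pro"` or `"anti"`.
#' @return named list of the four components.
#' @export
error_decomposition <- function(params, trial_type) {
  specs <- units_for_tt(params, trial_type)
  st <- params$info$structure
  da <- params$delta_a
  early <- if (st == "prosa") specs$pro else specs$early
  inhib <- if (st == "prosa") specs$stop else specs$inhib
  late_surv <- function(t) switch(st,
    prosa = arrival_survival(specs$anti, t - da),
    seria = arrival_survival(specs$late, t - da),
    seria_lr = arrival_survival(specs$late_pro, t - da) *
      arrival_survival(specs$late_anti, t - da))
  p_early <- stats::integrate(function(t)
    arrival_pdf(early, t) * arrival_survival(inhib, t) * late_surv(t),
    0, Inf, rel.tol = 1e-9, stop.on.error = FALSE)$value
  p_late <- 1 - p_early

  # split the late mass by action
  late_pro_share <- switch(st,
    prosa = 0,
    seria = params$pi_l[[trial_type]],
    seria_lr = {
      # late pro beats late anti, conditional on a late response occurring;
      # equal delta_a shifts cancel inside the late race, and the no-early
      # condition is integrated out by the joint density below
      noearly <- function(u) {
        se <- arrival_survival(early, u)
        J <- vapply(u, function(ui) stats::integrate(function(tau)
          arrival_pdf(early, tau) * arrival_cdf(inhib, tau), 0, ui,
          rel.tol = 1e-9, stop.on.error = FALSE)$value, numeric(1))
        se + J
      }
      num <- stats::integrate(function(v)
        arrival_pdf(specs$late_pro, v) *
          arrival_survival(specs$late_anti, v) * noearly(v + da),
        0, Inf, rel.tol = 1e-8, stop.on.error = FALSE)$value
      if (p_late > 0) min(num / p_late, 1) else 0.5
    })
  eta <- params$eta
  correct_action <- trial_type
  p_late_pro <- p_late * late_pro_share
  p_late_anti <- p_late * (1 - late_pro_share)
  list(
    p_inhibition_failure = (1 - eta) * p_early,
    p_late_correct = (1 - eta) *
      if (correct_action == "pro") p_late_pro else p_late_anti,
    p_late_error = (1 - eta) *
      if (correct_action == "pro") p_late_anti else p_late_pro,
    p_outlier = eta)
}

#' Posterior mean arrival time of a unit
#'
#' Averages \eqn{E[U_i] + \delta} over posterior draws and converts to
#' milliseconds.  Draws whose arrival mean does not exist (possible for
#' exempt SERIA_lr late units and truncated-normal units) are excluded
#' and reported as a fraction.
#'
#' @param fit a `pt_samples` object from [fit_model()].
#' @param unit a unit slot name of the fitted model (see
#'   `model_info(id)$units$name`).
#' @param thin keep every `thin`-th posterior draw.
#' @return list: `mean_ms`, `draws_ms`, `frac_infinite`.
#' @export
mean_arrival_posterior <- function(fit, unit, thin = 10) {
  stopifnot(!is.null(fit$model_id))
  draws <- posterior_draws(fit)
  draws <- draws[seq(1, nrow(draws), by = thin), , drop = FALSE]
  vals <- apply(draws, 1, function(th) {
    p <- theta_to_params(th, fit$model_id)
    arrival_mean(p$units[[unit]]) + p$delta
  })
  finite <- is.finite(vals)
  if (!any(finite)) stop("arrival mean infinite in every posterior draw")
  list(mean_ms = 100 * mean(vals[finite]),
       draws_ms = 100 * vals[finite],
       frac_infinite = mean(!finite))
}

#' Predicted response-time distribution of corrective antisaccades
#'
#' Corrective antisaccades (antisaccades following a prosaccade error) are
#' modelled as delayed late antisaccade actions: their predicted density
#' is the normalized winning-late-antisaccade density
#' \eqn{p(U_a = t) p(U_p > t) / P(U_a < U_p)}, time-shifted by the
#' difference between the observed and predicted mean response times.
#'
#' @param params a SERIA_lr [race_params()] object.
#' @param trial_type trial type whose late units to use (default `"anti"`).
#' @param observed_corrective_rt_ms optional vector of observed corrective
#'   reaction times (ms) used to estimate the shift.
#' @param grid_ms time grid (ms) for the returned density curve.
#' @return list: `predicted_mean_ms` (response-time scale,
#'   `delta + delta_a` included), `shift_ms` (`NA` without observations),
#'   `grid_ms`, `density` (per ms, on the unshifted response-time scale).
#' @export
corrective_rt_prediction <- function(params, trial_type = "anti",
                                     observed_corrective_rt_ms = NULL,
                                     grid_ms = seq(1, 1000, by = 1)) {
  if (params$info$structure != "seria_lr")
    stop("corrective-antisaccade prediction needs a SERIA_lr model")
  specs <- units_for_tt(params, trial_type)
  la <- specs$late_anti
  lp <- specs$late_pro
  p_win <- prob_late_anti(la, lp)
  mean_ds <- late_response_time(la, lp) + params$delta + params$delta_a
  shift <- if (length(observed_corrective_rt_ms))
    mean(observed_corrective_rt_ms) - 100 * mean_ds else NA_real_
  t_ds <- (grid_ms / 100) - params$delta - params$delta_a
  dens <- ifelse(t_ds > 0,
                 arrival_pdf(la, t_ds) * arrival_survival(lp, t_ds) / p_win,
                 0) / 100 # per-ms scale
  list(predicted_mean_ms = 100 * mean_ds, shift_ms = shift,
       p_late_anti = p_win, grid_ms = grid_ms, density = dens)
}

#' Posterior-predictive reaction-time density curves
#'
#' Averages the analytic trial density over posterior draws on a time
#' grid, per action, for one trial type.  With a single draw this equals
#' that draw's density.
#'
#' @param fit a `pt_samples` object from [fit_model()] (or a single
#'   [race_params()] object).
#' @param trial_type `"pro"` or `"anti"`.
#' @param grid_ms positive increasing grid of reaction times (ms, observed
#'   scale including the fixed 50 ms).
#' @param thin keep every `thin`-th posterior draw.
#' @return data.frame: `rt_ms`, `density_pro`, `density_anti` (per ms).
#' @export
predicted_rt_density <- function(fit, trial_type,
                                 grid_ms = seq(51, 1000, by = 1),
                                 thin = 50) {
  if (any(grid_ms <= 50) || is.unsorted(grid_ms))
    stop("grid must be increasing and above the fixed 50 ms")
  t_ds <- (grid_ms - 50) / 100
  dens_for <- function(p) cbind(
    pro = trial_density(p, trial_type, "pro", t_ds),
    anti = trial_density(p, trial_type, "anti", t_ds))
  if (inherits(fit, "race_params")) {
    d <- dens_for(fit)
  } else {
    draws <- posterior_draws(fit)
    draws <- draws[seq(1, nrow(draws), by = thin), , drop = FALSE]
    d <- Reduce(`+`, lapply(seq_len(nrow(draws)), function(i)
      dens_for(theta_to_params(draws[i, ], fit$model_id)))) / nrow(draws)
  }
  data.frame(rt_ms = grid_ms, density_pro = d[, "pro"] / 100,
             density_anti = d[, "anti"] / 100)
}

#' Reciprobit transform of a latency distribution
#'
#' Returns the cumulative latency distribution on reciprocal-latency /
#' probit axes, on which a reciprocal-normal (LATER-style) latency
#' distribution is a straight line.
#'
#' @param rt_ms positive reaction times (ms), or `NULL` when `cdf` is
#'   given.
#' @param grid_ms evaluation grid (ms) when `cdf` is supplied.
#' @param cdf optional model CDF values matching `grid_ms`.
#' @return data.frame: `rt_ms`, `x` (`-1/rt` in 1/ms), `y`
#'   (probit-scale cumulative probability); endpoint probabilities 0/1 are
#'   dropped.
#' @export
reciprobit_curve <- function(rt_ms = NULL, grid_ms = NULL, cdf = NULL) {
  if (is.null(cdf)) {
    if (any(rt_ms <= 0)) stop("reaction times must be positive")
    rt <- sort(rt_ms)
    p <- stats::ppoints(length(rt))
  } else {
    if (any(grid_ms <= 0)) stop("grid must contain positive times")
    rt <- grid_ms
    p <- cdf
  }
  keep <- p > 0 & p < 1
  data.frame(rt_ms = rt[keep], x = -1 / rt[keep], y = stats::qnorm(p[keep]))
}
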