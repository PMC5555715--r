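fam_code <- function(family)
  match(family, c("gamma", "invgamma", "lognormal", "truncnorm"))

# Pack a model's units for one trial type into the (family, p1, p2) matrix
# consumed by the compiled density, rows in the structural role order.
unit_matrix <- function(params, trial_type) {
  specs <- units_for_tt(params, trial_type)
  roles <- switch(params$info$structure,
                  prosa = c("pro", "stop", "anti"),
                  seria = c("early", "inhib", "late"),
                  seria_lr = c("early", "inhib", "late_pro", "late_anti"))
  m <- t(vapply(roles, function(r) {
    sp <- specs[[r]]
    c(fam_code(sp$family), sp$param1, sp$param2)
  }, numeric(3)))
  m
}

structure_code <- function(params)
  match(params$info$structure, c("prosa", "seria", "seria_lr"))

pi_l_vector <- function(params) {
  if (is.null(params$pi_l)) c(0, 0)
  else c(params$pi_l[["pro"]], params$pi_l[["anti"]])
}

#' Joint trial density of action and reaction time
#'
#' Evaluates the exact trial-level density \eqn{p(A = a, T = t)} of the
#' model in `params`, with `t` on the observed decisecond scale (reaction
#' time after the fixed 50 ms pre-subtraction).  Reaction times below the
#' non-decision time `delta` fall into the early-outlier component
#' (uniform on `[0, delta]`, total mass `eta`, split 100:1 between pro-
#' and antisaccades); beyond `delta` the race density applies,
#' renormalized by `1 - eta`.
#'
#' @param params a [race_params()] object.
#' @param trial_type `"pro"` or `"anti"` (scalar or vector along `t`).
#' @param action `"pro"` or `"anti"` (scalar or vector along `t`).
#' @param t reaction times, deciseconds.
#' @param method `"compiled"` (default, Gauss-Legendre inner quadrature) or
#'   `"reference"` (pure R, adaptive `stats::integrate` inner quadrature;
#'   slow, used for cross-validation).
#' @param hmax maximum inner-quadrature segment width (deciseconds).
#' @param n_nodes Gauss-Legendre nodes per segment (15, or 7 for speed).
#' @return vector of density values.
#' @export
trial_density <- function(params, trial_type, action, t,
                          method = c("compiled", "reference"),
                          hmax = 0.2, n_nodes = 15) {
  method <- match.arg(method)
  n <- length(t)
  trial_type <- rep_len(match(trial_type, c("pro", "anti")), n)
  action <- rep_len(match(action, c("pro", "anti")), n)
  if (anyNA(trial_type) || anyNA(action))
    stop("trial_type and action must be 'pro' or 'anti'")
  if (method == "compiled") {
    race_density_cpp(as.numeric(t), as.integer(trial_type),
                     as.integer(action), structure_code(params),
                     unit_matrix(params, "pro"), unit_matrix(params, "anti"),
                     params$delta, params$delta_a, params$eta, params$pi_e,
                     pi_l_vector(params), hmax, n_nodes)
  } else {
    vapply(seq_len(n), function(i)
      trial_density_ref(params, c("pro", "anti")[trial_type[i]],
                        c("pro", "anti")[action[i]], t[i]), numeric(1))
  }
}

# Pure-R reference density for one trial; mirrors the compiled code but
# computes the inhibition integral with stats::integrate.
trial_density_ref <- function(params, trial_type, action, t) {
  delta <- params$delta
  if (t <= 0) return(0)
  if (t < delta)
    return(if (params$eta > 0)
      params$eta / delta * if (action == "pro") 100 / 101 else 1 / 101
      else 0)
  u <- t - delta
  if (u <= 0) return(0)
  v <- u - params$delta_a
  specs <- units_for_tt(params, trial_type)
  st <- params$info$structure
  early <- if (st == "prosa") specs$pro else specs$early
  inhib <- if (st == "prosa") specs$stop else specs$inhib
  J <- if (u > 0)
    stats::integrate(function(tau)
      arrival_pdf(early, tau) * arrival_cdf(inhib, tau),
      0, u, rel.tol = 1e-10, abs.tol = 1e-12)$value
  else 0
  noearly <- arrival_survival(early, u) + J
  d <- switch(st,
    prosa = {
      if (action == "pro")
        arrival_pdf(specs$pro, u) * arrival_survival(specs$stop, u) *
          (if (v > 0) arrival_survival(specs$anti, v) else 1)
      else
        (if (v > 0) arrival_pdf(specs$anti, v) else 0) * noearly
    },
    seria = {
      et <- arrival_pdf(specs$early, u) * arrival_survival(specs$inhib, u) *
        (if (v > 0) arrival_survival(specs$late, v) else 1)
      lt <- (if (v > 0) arrival_pdf(specs$late, v) else 0) * noearly
      pl <- params$pi_l[[trial_type]]
      if (action == "pro") params$pi_e * et + pl * lt
      else (1 - params$pi_e) * et + (1 - pl) * lt
    },
    seria_lr = {
      Sa <- if (v > 0) arrival_survival(specs$late_anti, v) else 1
      Sp <- if (v > 0) arrival_survival(specs$late_pro, v) else 1
      if (action == "pro")
        arrival_pdf(specs$early, u) * arrival_survival(specs$inhib, u) *
          Sa * Sp +
          (if (v > 0) arrival_pdf(specs$late_pro, v) else 0) * Sa * noearly
      else
        (if (v > 0) arrival_pdf(specs$late_anti, v) else 0) * Sp * noearly
    })
  (1 - params$eta) * d
}

#' Dataset log-likelihood
#'
#' Sum of per-trial log densities for one subject and condition.  Trials
#' must carry decisecond reaction times (`rt_ds`, as produced by
#' [preprocess_trials()] or [simulate_experiment()]), a `trial_type` and an
#' `action` column.  Zero-density trials are floored at 1e-300 before the
#' log so samplers remain finite.
#'
#' @param trials a trial table (data.frame).
#' @param params a [race_params()] object.
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(trials, params) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("trials must be a nonempty data.frame")
  cols <- trial_columns(trials)
  if (any(cols$rt <= 0)) stop("reaction times must be positive")
  race_loglik_cpp(cols$rt, cols$tt, cols$action, structure_code(params),
                  unit_matrix(params, "pro"), unit_matrix(params, "anti"),
                  params$delta, params$delta_a, params$eta, params$pi_e,
                  pi_l_vector(params))
}

# Compiled likelihood closure on the unconstrained parameter scale,
# avoiding per-call object construction: theta slots are mapped to the
# (family, p1, p2) unit matrices once, then each call converts moments to
# natural parameters in place.  n_nodes = 7 is the sampler setting.
make_loglik <- function(trials, model_id, hmax = 0.2, n_nodes = 7) {
  info <- model_info(model_id)
  cols <- trial_columns(trials)
  scode <- match(info$structure, c("prosa", "seria", "seria_lr"))
  u <- info$units
  pn <- param_names(info)
  plan <- lapply(c("pro", "anti"), function(tt) {
    sel <- u[u$tt == "both" | u$tt == tt, ]
    roles <- switch(info$structure,
                    prosa = c("pro", "stop", "anti"),
                    seria = c("early", "inhib", "late"),
                    seria_lr = c("early", "inhib", "late_pro", "late_anti"))
    sel <- sel[match(roles, sel$role), ]
    fam <- fam_code(sel$family)
    i1 <- match(paste0(sel$name, ".",
                       ifelse(sel$family == "truncnorm", "mu", "lnmean")), pn)
    i2 <- match(paste0(sel$name, ".",
                       ifelse(sel$family == "truncnorm", "lnsigma2", "lnvar")),
                pn)
    list(fam = fam, i1 = i1, i2 = i2)
  })
  i_delta <- match("lndelta", pn)
  i_delta_a <- match("lndelta_a", pn)
  i_eta <- match("logit_eta", pn)
  i_pl <- if (scode == 2L)
    c(match("logit_pi_l_pro", pn), match("logit_pi_l_anti", pn))
  pi_e <- fixed_pi_e()

  unit_mat <- function(pl, theta) {
    fam <- pl$fam
    a <- theta[pl$i1]; b <- theta[pl$i2]
    tn <- fam == 4L
    p1 <- ifelse(tn, a, exp(a))
    p2 <- exp(b)
    m <- p1; v <- p2
    p1[fam == 1L] <- (m^2 / v)[fam == 1L]
    p2[fam == 1L] <- (v / m)[fam == 1L]
    if (any(fam == 2L)) {
      k <- m^2 / v + 2
      p1[fam == 2L] <- k[fam == 2L]
      p2[fam == 2L] <- (m * (k - 1))[fam == 2L]
    }
    if (any(fam == 3L)) {
      s2 <- log1p(v / m^2)
      p1[fam == 3L] <- (log(m) - s2 / 2)[fam == 3L]
      p2[fam == 3L] <- s2[fam == 3L]
    }
    cbind(fam, p1, p2, deparse.level = 0)
  }

  function(theta) {
    race_loglik_cpp(cols$rt, cols$tt, cols$action, scode,
                    unit_mat(plan[[1]], theta), unit_mat(plan[[2]], theta),
                    exp(theta[i_delta]), exp(theta[i_delta_a]),
                    stats::plogis(theta[i_eta]), pi_e,
                    if (is.null(i_pl)) c(0, 0)
                    else stats::plogis(theta[i_pl]),
                    hmax, n_nodes)
  }
}

# Resolve rt (ds), trial type and action columns to the internal coding.
trial_columns <- function(trials) {
  rt <- if ("rt_ds" %in% names(trials)) trials$rt_ds
        else stop("trials must have an rt_ds column (deciseconds)")
  tt <- match(as.character(trials$trial_type), c("pro", "anti"))
  ac <- match(as.character(trials$action), c("pro", "anti"))
  if (anyNA(rt) || anyNA(tt) || anyNA(ac))
    stop("trials contain missing or invalid rt_ds/trial_type/action values")
  list(rt = as.numeric(rt), tt = as.integer(tt), action = as.integer(ac))
}

#' Total probability mass of a model's trial density
#'
#' Integrates the joint density over reaction time and sums over actions
#' for one trial type, including the early-outlier mass `eta`.  Equals 1
#' up to quadrature error for any valid parameter set; used as a
#' correctness check of the likelihood.
#'
#' @param params a [race_params()] object.
#' @param trial_type `"pro"` or `"anti"`.
#' @param upper upper integration limit in deciseconds; with the default
#'   `Inf` the contribution beyond the early unit's support is added in
#'   closed form (see below) so that arbitrarily heavy late-unit tails —
#'   possible for moment-exempt SERIA_lr late units — are captured exactly.
#' @return total mass (scalar).
#' @export
density_total_mass <- function(params, trial_type, upper = Inf) {
  specs <- units_for_tt(params, trial_type)
  st <- params$info$structure
  early <- if (st == "prosa") specs$pro else specs$early
  inhib <- if (st == "prosa") specs$stop else specs$inhib
  delta <- params$delta
  # cutoff past which the early unit has (numerically) surely responded
  # or been stopped
  grid <- 2^seq(-1, 30)
  hit <- which(arrival_survival(early, grid) < 1e-8)
  ucut <- if (length(hit)) grid[hit[1]] else 2^30
  tcut <- min(delta + ucut, upper)

  # piecewise quadrature over log-spaced panels up to the cutoff: prior
  # draws can place density peaks anywhere from milliseconds upwards
  f <- function(a) function(t) trial_density(params, trial_type, a, t)
  breaks <- unique(pmin(delta + c(0, 2^seq(-1, 31)), tcut))
  mass <- function(a) {
    g <- f(a)
    tot <- 0
    for (i in seq_len(length(breaks) - 1))
      tot <- tot + stats::integrate(g, breaks[i], breaks[i + 1],
                                    rel.tol = 1e-9, abs.tol = 1e-12,
                                    stop.on.error = FALSE)$value
    tot
  }
  total <- params$eta + mass("pro") + mass("anti")

  if (upper == Inf) {
    # beyond tcut the no-early probability is the constant
    # p_stop = P(U_inhib < U_early), and the summed late-race integrand is
    # the exact derivative -d/dv of the product of late survivals, so the
    # remaining mass closes in analytic form (error <= 2 S_early(ucut))
    p_stop <- stats::integrate(function(x)
      arrival_pdf(early, x) * arrival_cdf(inhib, x), 0, ucut,
      rel.tol = 1e-10, abs.tol = 1e-13, stop.on.error = FALSE)$value
    v0 <- tcut - delta - params$delta_a
    s_late <- switch(st,
      prosa = arrival_survival(specs$anti, v0),
      seria = arrival_survival(specs$late, v0),
      seria_lr = arrival_survival(specs$late_pro, v0) *
        arrival_survival(specs$late_anti, v0))
    total <- total + (1 - params$eta) * p_stop * s_late
  }
  total
}
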