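# Shared fixtures: parameter sets are built in code, at test time.

# a well-behaved constrained SERIA_lr set (gamma early/inhib, inverse-gamma
# late units); rates in 1/ds, times in ds
test_params_lr <- function(eta = 0.02, delta = 0.5, delta_a = 0.3) {
  race_params("m13c", list(
    early = rate_spec_from_moments("gamma", 0.55, 0.04),
    inhib = rate_spec_from_moments("gamma", 0.7, 0.06),
    late_pro_pro = rate_spec_from_moments("invgamma", 0.35, 0.02),
    late_pro_anti = rate_spec_from_moments("invgamma", 0.28, 0.02),
    late_anti_pro = rate_spec_from_moments("invgamma", 0.25, 0.02),
    late_anti_anti = rate_spec_from_moments("invgamma", 0.32, 0.02)),
    delta = delta, delta_a = delta_a, eta = eta)
}

test_params_seria <- function(pi_l = c(pro = 0.8, anti = 0.25),
                              eta = 0.02) {
  race_params("m8c", list(
    early = rate_spec_from_moments("gamma", 0.55, 0.04),
    inhib = rate_spec_from_moments("gamma", 0.7, 0.06),
    late = rate_spec_from_moments("invgamma", 0.3, 0.02)),
    delta = 0.5, delta_a = 0.3, eta = eta, pi_l = pi_l)
}

test_params_prosa <- function(eta = 0.02) {
  race_params("m3c", list(
    pro = rate_spec_from_moments("gamma", 0.55, 0.04),
    stop_pro = rate_spec_from_moments("gamma", 0.7, 0.06),
    stop_anti = rate_spec_from_moments("gamma", 0.6, 0.05),
    anti_pro = rate_spec_from_moments("invgamma", 0.3, 0.02),
    anti_anti = rate_spec_from_moments("invgamma", 0.35, 0.02)),
    delta = 0.5, delta_a = 0.3, eta = eta)
}

# a prior-drawn parameter set for a given model (inside prior support)
random_params <- function(model_id) {
  theta_to_params(drop(sample_prior(default_prior(model_id), 1)), model_id)
}

random_rate_spec <- function(family = NULL) {
  if (is.null(family))
    family <- sample(c("gamma", "invgamma", "lognormal", "truncnorm"), 1)
  if (family == "truncnorm")
    rate_spec("truncnorm", stats::runif(1, 0.2, 1.2), stats::runif(1, 0.01, 0.3)^2)
  else
    rate_spec_from_moments(family, stats::runif(1, 0.2, 1.2),
                           stats::runif(1, 0.01, 0.15))
}
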