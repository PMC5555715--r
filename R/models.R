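#' The antisaccade race-model space
#'
#' Thirty models: three structural families (PROSA, SERIA, SERIA_lr) times
#' five increase-rate distribution configurations, each in a "full" variant
#' (separate unit parameters in pro- and antisaccade trials) and a
#' "constrained" variant with parameters tied across trial types.  Model
#' ids follow the `m1`..`m15` / `m1c`..`m15c` convention:
#' m1-m5 PROSA, m6-m10 SERIA, m11-m15 SERIA_lr; within each block the rate
#' configurations are (1) all inverse gamma, (2) all gamma, (3) gamma
#' early/inhibitory with inverse-gamma late, (4) all lognormal, (5) all
#' truncated normal.
#'
#' @return `model_registry()` returns a data.frame with one row per model:
#'   `model_id`, `structure` (`prosa`/`seria`/`seria_lr`),
#'   `early_family`, `late_family`, `constrained`, and `n_params`.
#' @examples
#' model_registry()[c(1, 13, 26), ]
#' model_info("m13c")$units
#' @export
model_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  reg <- build_model_registry()
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

build_model_registry <- function() {
  fam <- data.frame(
    idx = 1:5,
    early_family = c("invgamma", "gamma", "gamma", "lognormal", "truncnorm"),
    late_family  = c("invgamma", "gamma", "invgamma", "lognormal", "truncnorm"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(c("prosa", "seria", "seria_lr"), function(st) {
    base <- switch(st, prosa = 0L, seria = 5L, seria_lr = 10L)
    do.call(rbind, lapply(1:5, function(i) {
      do.call(rbind, lapply(c(FALSE, TRUE), function(con) {
        data.frame(model_id = paste0("m", base + i, if (con) "c" else ""),
                   structure = st,
                   early_family = fam$early_family[i],
                   late_family = fam$late_family[i],
                   constrained = con, stringsAsFactors = FALSE)
      }))
    }))
  }))
  # Parameter counts as conventionally reported: SERIA's pi_e (one per
  # trial type) is counted even though it is fixed in practice (fixed_pi_e)
  # and not sampled.
  out$n_params <- vapply(out$model_id, function(id) {
    info <- model_info_row(out, id)
    length(param_names(info)) + if (info$structure == "seria") 2L else 0L
  }, integer(1))
  rownames(out) <- NULL
  out
}

model_info_row <- function(reg, model_id) {
  row <- reg[reg$model_id == model_id, ]
  if (nrow(row) != 1L) stop("unknown model id: ", model_id)
  as.list(row[1, ])
}

#' @rdname model_registry
#' @param model_id a model id such as `"m13c"`.
#' @export
model_info <- function(model_id) {
  cached <- .registry_cache$info[[model_id]]
  if (!is.null(cached)) return(cached)
  info <- model_info_row(model_registry(), model_id)
  info$units <- model_units(info)
  if (is.null(.registry_cache$info)) .registry_cache$info <- list()
  .registry_cache$info[[model_id]] <- info
  info
}

# Unit layout: a data.frame of unit slots, one per (role, trial type),
# collapsed where the model shares a unit across trial types.  `family`
# assigns the rate distribution; `exempt` marks SERIA_lr late units that
# are allowed arrival distributions without finite moments.
model_units <- function(info) {
  tt2 <- c("pro", "anti")
  u <- switch(info$structure,
    prosa = {
      if (info$constrained)
        data.frame(role = c("pro", "stop", "stop", "anti", "anti"),
                   tt = c("both", tt2, tt2), stringsAsFactors = FALSE)
      else
        expand.grid(role = c("pro", "stop", "anti"), tt = tt2,
                    stringsAsFactors = FALSE)
    },
    seria = {
      if (info$constrained)
        data.frame(role = c("early", "inhib", "late"), tt = "both",
                   stringsAsFactors = FALSE)
      else
        expand.grid(role = c("early", "inhib", "late"), tt = tt2,
                    stringsAsFactors = FALSE)
    },
    seria_lr = {
      if (info$constrained)
        rbind(data.frame(role = c("early", "inhib"), tt = "both",
                         stringsAsFactors = FALSE),
              expand.grid(role = c("late_pro", "late_anti"), tt = tt2,
                          stringsAsFactors = FALSE))
      else
        expand.grid(role = c("early", "inhib", "late_pro", "late_anti"),
                    tt = tt2, stringsAsFactors = FALSE)
    })
  u$role <- as.character(u$role)
  u$tt <- as.character(u$tt)
  late_roles <- c("late", "late_pro", "late_anti", "anti")
  u$family <- ifelse(u$role %in% c("pro", "stop", "early", "inhib"),
                     info$early_family, info$late_family)
  u$exempt <- info$structure == "seria_lr" &
    u$role %in% c("late_pro", "late_anti")
  u$name <- ifelse(u$tt == "both", u$role, paste(u$role, u$tt, sep = "_"))
  u
}

# Names of the unconstrained sampling coordinates of a model.  Each unit
# slot contributes two coordinates; the global parameters are the
# non-decision time delta, the late/antisaccade cost delta_a, and the
# early-outlier rate eta; SERIA adds one late-choice probability pi_l per
# trial type (pi_e is fixed, see `fixed_pi_e`).
param_names <- function(info) {
  u <- model_units(info)
  suffix <- ifelse(u$family == "truncnorm", c("mu", "lnsigma2"),
                   c("lnmean", "lnvar"))
  unit_names <- as.vector(t(cbind(
    paste0(u$name, ".", ifelse(u$family == "truncnorm", "mu", "lnmean")),
    paste0(u$name, ".", ifelse(u$family == "truncnorm", "lnsigma2", "lnvar")))))
  c(unit_names, "lndelta", "lndelta_a", "logit_eta",
    if (info$structure == "seria") c("logit_pi_l_pro", "logit_pi_l_anti"))
}

#' Probability that an early response is a prosaccade
#'
#' Early responses are treated as (almost) always prosaccades: the
#' probability of an early antisaccade is fixed to 1e-3 rather than zero so
#' that rare very fast antisaccades do not force a zero-density trial.
#' @export
fixed_pi_e <- function() 1 - 1e-3

#' Race-model parameter set
#'
#' Bundles everything the likelihood and simulator need for one subject and
#' condition: the per-unit rate specifications (per trial type), the
#' non-decision time `delta` and late-action cost `delta_a` (deciseconds),
#' the early-outlier rate `eta`, and the early/late action probabilities
#' `pi_e`, `pi_l` (SERIA only; in PROSA early responses are prosaccades and
#' late responses antisaccades by construction).
#'
#' @param model_id model id from [model_registry()].
#' @param units named list of [rate_spec()] objects, one per unit slot of
#'   the model (`model_info(model_id)$units$name`).
#' @param delta non-decision time, deciseconds, > 0.
#' @param delta_a late-action (antisaccade) cost, deciseconds, >= 0.
#' @param eta early-outlier probability in `[0, 1)`.
#' @param pi_l for SERIA models, named numeric `c(pro = , anti = )`:
#'   probability that a late response is a prosaccade in each trial type.
#' @param pi_e probability that an early response is a prosaccade
#'   (default [fixed_pi_e()]).
#' @return an object of class `"race_params"`.
#' @export
race_params <- function(model_id, units, delta, delta_a, eta = 0,
                        pi_l = NULL, pi_e = fixed_pi_e()) {
  info <- model_info(model_id)
  need <- info$units$name
  if (!setequal(names(units), need))
    stop("units must be named: ", paste(need, collapse = ", "))
  stopifnot(all(vapply(units, inherits, logical(1), "rate_spec")),
            delta > 0, delta_a >= 0, eta >= 0, eta < 1,
            pi_e >= 0, pi_e <= 1)
  if (info$structure == "seria") {
    if (is.null(pi_l) || !setequal(names(pi_l), c("pro", "anti")))
      stop("SERIA models need pi_l = c(pro = , anti = )")
    stopifnot(all(pi_l >= 0), all(pi_l <= 1))
  } else pi_l <- NULL
  structure(list(model_id = model_id, info = info, units = units[need],
                 delta = delta, delta_a = delta_a, eta = eta,
                 pi_e = pi_e, pi_l = pi_l),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat(sprintf("<race_params> model %s (%s%s)\n", x$model_id,
              x$info$structure, if (x$info$constrained) ", constrained" else ""))
  for (nm in names(x$units)) {
    sp <- x$units[[nm]]
    cat(sprintf("  %-14s %s(%.4g, %.4g)\n", nm, sp$family,
                sp$param1, sp$param2))
  }
  cat(sprintf("  delta = %.3f ds, delta_a = %.3f ds, eta = %.4f\n",
              x$delta, x$delta_a, x$eta))
  if (!is.null(x$pi_l))
    cat(sprintf("  pi_l = (pro %.3f, anti %.3f), pi_e = %.4f\n",
                x$pi_l[["pro"]], x$pi_l[["anti"]], x$pi_e))
  invisible(x)
}

# Units active in a given trial type, resolved to a named list by role.
units_for_tt <- function(params, trial_type) {
  u <- params$info$units
  sel <- u$tt == "both" | u$tt == trial_type
  specs <- params$units[u$name[sel]]
  names(specs) <- u$role[sel]
  specs
}
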