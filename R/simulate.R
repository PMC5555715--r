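#' Simulate trials from a race model
#'
#' Generative sampler with the exact structure of the likelihood: each
#' unit's increase rate is drawn from its rate distribution and inverted to
#' an arrival time; the race rules of the model determine the response
#' class and action; the non-decision time `delta` is added to every
#' response and the late cost `delta_a` to late (PROSA: antisaccade-unit)
#' responses; with probability `eta` the outcome is replaced by an early
#' outlier, uniform on `[0, delta]` with a 100:1 pro:anti action split.
#' Draw order per trial is fixed (unit rates, outlier flag, outlier
#' time/action) so that seeded runs are reproducible.
#'
#' @param params a [race_params()] object.
#' @param trial_type `"pro"` or `"anti"`, scalar or vector of length
#'   `n`.
#' @param n number of trials (defaults to `length(trial_type)`).
#' @param latents if `TRUE` (default) append latent columns: per-unit
#'   arrival times (deciseconds), the response class
#'   (`early`/`late`/`outlier`) and the outlier flag.
#' @return a trial table: `trial_index`, `trial_type`, `action`, `rt_ms`
#'   (observed scale: decision time + 50 ms), `rt_ds` (model scale), plus
#'   latent columns.
#' @export
simulate_trials <- function(params, trial_type, n = length(trial_type),
                            latents = TRUE) {
  trial_type <- rep_len(as.character(trial_type), n)
  stopifnot(all(trial_type %in% c("pro", "anti")))
  st <- params$info$structure

  out <- data.frame(trial_index = seq_len(n), trial_type = trial_type,
                    action = NA_character_, rt_ds = NA_real_,
                    stringsAsFactors = FALSE)
  cls <- character(n)
  arr <- matrix(NA_real_, n, 4)
  colnames(arr) <- c("u1", "u2", "u3", "u4")

  for (tt in c("pro", "anti")) {
    sel <- which(trial_type == tt)
    if (!length(sel)) next
    specs <- units_for_tt(params, tt)
    roles <- switch(st, prosa = c("pro", "stop", "anti"),
                    seria = c("early", "inhib", "late"),
                    seria_lr = c("early", "inhib", "late_pro", "late_anti"))
    # one rate draw per unit per trial, fixed role order
    at <- sapply(roles, function(r) 1 / sample_rates(specs[[r]], length(sel)))
    at <- matrix(at, nrow = length(sel))
    arr[sel, seq_along(roles)] <- at

    if (st == "prosa") {
      t_anti <- at[, 3] + params$delta_a
      pro_wins <- at[, 1] < at[, 2] & at[, 1] < t_anti
      out$action[sel] <- ifelse(pro_wins, "pro", "anti")
      out$rt_ds[sel] <- params$delta + ifelse(pro_wins, at[, 1], t_anti)
      cls[sel] <- ifelse(pro_wins, "early", "late")
    } else if (st == "seria") {
      t_late <- at[, 3] + params$delta_a
      early_wins <- at[, 1] < at[, 2] & at[, 1] < t_late
      u <- stats::runif(length(sel))
      p_pro <- ifelse(early_wins, params$pi_e, params$pi_l[[tt]])
      out$action[sel] <- ifelse(u < p_pro, "pro", "anti")
      out$rt_ds[sel] <- params$delta + ifelse(early_wins, at[, 1], t_late)
      cls[sel] <- ifelse(early_wins, "early", "late")
    } else {
      t_lp <- at[, 3] + params$delta_a
      t_la <- at[, 4] + params$delta_a
      t_late <- pmin(t_lp, t_la)
      early_wins <- at[, 1] < at[, 2] & at[, 1] < t_late
      late_pro <- t_lp < t_la
      out$action[sel] <- ifelse(early_wins | late_pro, "pro", "anti")
      out$rt_ds[sel] <- params$delta + ifelse(early_wins, at[, 1], t_late)
      cls[sel] <- ifelse(early_wins, "early", "late")
    }
  }

  # outlier mechanism replaces the race outcome
  is_out <- stats::runif(n) < params$eta
  if (any(is_out)) {
    k <- sum(is_out)
    out$rt_ds[is_out] <- stats::runif(k, 0, params$delta)
    out$action[is_out] <- ifelse(stats::runif(k) < 100 / 101, "pro", "anti")
    cls[is_out] <- "outlier"
  }

  out$rt_ms <- 100 * out$rt_ds + 50
  if (latents) {
    out$response_class <- cls
    out$outlier <- is_out
    out <- cbind(out, as.data.frame(arr))
  }
  out[c("trial_index", "trial_type", "action", "rt_ms", "rt_ds",
        if (latents) c("response_class", "outlier", "u1", "u2", "u3", "u4"))]
}

#' Simulate a block of the antisaccade experiment
#'
#' Draws a trial-type sequence with prosaccade probability `pp` — either
#' i.i.d. or with exact counts in randomized order (e.g. 38 prosaccade
#' cues in a 192-trial block at `pp = 0.2`) — and simulates every trial
#' under `params`.  Fully reproducible given `seed`.
#'
#' @param params a [race_params()] object.
#' @param n_trials number of trials in the block.
#' @param pp block-level prosaccade-trial probability.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param exact_counts if `TRUE` (default) use exactly
#'   `round(pp * n_trials)` prosaccade cues in shuffled order.
#' @param subject_id,condition optional labels attached as columns.
#' @inheritParams simulate_trials
#' @return a trial table (see [simulate_trials()]) with `subject_id` and
#'   `condition` columns.
#' @export
simulate_experiment <- function(params, n_trials, pp = 0.5, seed = NULL,
                                exact_counts = TRUE, latents = TRUE,
                                subject_id = "sim", condition = NULL) {
  stopifnot(n_trials >= 1, pp >= 0, pp <= 1)
  if (!is.null(seed)) set.seed(seed)
  tt <- if (exact_counts) {
    n_pro <- round(pp * n_trials)
    sample(rep(c("pro", "anti"), c(n_pro, n_trials - n_pro)))
  } else {
    ifelse(stats::runif(n_trials) < pp, "pro", "anti")
  }
  out <- simulate_trials(params, tt, latents = latents)
  out$subject_id <- subject_id
  out$condition <- if (is.null(condition)) sprintf("PP%d", round(100 * pp))
                   else condition
  out[c("subject_id", "condition", setdiff(names(out),
                                           c("subject_id", "condition")))]
}
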