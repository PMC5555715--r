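trial_schema <- c("subject_id", "condition", "trial_index", "trial_type",
                  "action", "rt_ms")

#' Read and write trial tables
#'
#' The canonical on-disk format is delimited text with one row per trial
#' and at least the columns `subject_id`, `condition`, `trial_index`,
#' `trial_type` (`pro`/`anti`), `action` (`pro`/`anti`) and `rt_ms`
#' (milliseconds from cue presentation).  Optional columns: `valid`
#' (logical), `exclusion_reason`, `corrective_rt_ms`, `corrective_valid`;
#' unknown columns are preserved.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"` (`load_trials` guesses from the
#'   extension by default).
#' @return `load_trials()` returns the validated trial table.
#' @export
load_trials <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "csv"
  sep <- if (format == "csv") "," else "\t"
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_schema, names(out))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_tt <- !(out$trial_type %in% c("pro", "anti"))
  bad_ac <- !(out$action %in% c("pro", "anti")) & !is.na(out$rt_ms)
  if (any(bad_tt)) stop(sum(bad_tt), " row(s) with invalid trial_type")
  if (any(bad_ac)) stop(sum(bad_ac), " row(s) with invalid action")
  rt <- suppressWarnings(as.numeric(out$rt_ms))
  bad_rt <- which(!is.na(out$rt_ms) & is.na(rt))
  if (length(bad_rt))
    stop("unparsable rt_ms in row(s): ",
         paste(utils::head(bad_rt, 10), collapse = ", "))
  out$rt_ms <- rt
  out
}

#' @rdname load_trials
#' @param trials a trial table.
#' @export
write_trials <- function(trials, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tsv$|\\.txt$", path)) "tsv" else "csv"
  utils::write.table(trials, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess a trial table for model fitting
#'
#' Applies the tabular exclusion rules and the fixed non-decision
#' subtraction: rows flagged invalid are dropped with their recorded
#' reason; saccades later than 800 ms are excluded (`late_saccade`);
#' reaction times below 50 ms — and below 110 ms for antisaccade
#' responses — are excluded (`early_saccade`); a fixed 50 ms non-decision
#' time is subtracted from the retained reaction times, which are also
#' rescaled to deciseconds in a new `rt_ds` column.  The 110 ms rule is
#' applied per antisaccade `action` by default (`anti_min_by = "action"`);
#' set `anti_min_by = "trial_type"` to apply it to antisaccade trials
#' instead.
#'
#' @param trials a trial table (see [load_trials()]).
#' @param max_rt_ms,min_rt_ms,min_anti_rt_ms exclusion bounds (ms).
#' @param fixed_ndt_ms fixed non-decision time subtracted before
#'   rescaling.
#' @param anti_min_by `"action"` or `"trial_type"`.
#' @return the retained trials with `rt_ds` added; the exclusion audit is
#'   attached as `attr(, "exclusions")`, a named count vector that
#'   partitions the input rows.
#' @export
preprocess_trials <- function(trials, max_rt_ms = 800, min_rt_ms = 50,
                              min_anti_rt_ms = 110, fixed_ndt_ms = 50,
                              anti_min_by = c("action", "trial_type")) {
  anti_min_by <- match.arg(anti_min_by)
  n <- nrow(trials)
  reason <- rep("valid", n)
  if ("valid" %in% names(trials)) {
    flagged <- !is.na(trials$valid) & !trials$valid
    reason[flagged] <- if ("exclusion_reason" %in% names(trials))
      ifelse(is.na(trials$exclusion_reason[flagged]) |
               trials$exclusion_reason[flagged] %in% c("", "none"),
             "invalid", trials$exclusion_reason[flagged])
    else "invalid"
  }
  no_rt <- reason == "valid" & is.na(trials$rt_ms)
  reason[no_rt] <- "missing"
  ok <- reason == "valid"
  late <- ok & trials$rt_ms > max_rt_ms
  reason[late] <- "late_saccade"
  ok <- reason == "valid"
  anti_resp <- if (anti_min_by == "action") trials$action == "anti"
               else trials$trial_type == "anti"
  early <- ok & (trials$rt_ms < min_rt_ms |
                   (anti_resp & trials$rt_ms < min_anti_rt_ms))
  reason[early] <- "early_saccade"

  keep <- trials[reason == "valid", , drop = FALSE]
  keep$rt_ds <- (keep$rt_ms - fixed_ndt_ms) / 100
  counts <- table(factor(reason, levels = c("valid", unique(
    reason[reason != "valid"]))))
  audit <- c(total = n, as.vector(counts))
  names(audit) <- c("total", names(counts))
  if (nrow(keep) == 0L) warning("no trials survive preprocessing")
  attr(keep, "exclusions") <- audit
  keep
}

#' Flag valid corrective antisaccades
#'
#' A corrective antisaccade is counted when the trial is an erroneous
#' prosaccade (a `pro` action in an `anti` trial) and the corrective
#' saccade occurred within `window_ms` of cue presentation.  The spatial
#' accuracy criterion needs gaze positions and must be applied upstream.
#'
#' @param trials trial table with a `corrective_rt_ms` column.
#' @param window_ms latest admissible corrective reaction time (ms).
#' @return the table with a logical `corrective_valid` column.
#' @export
flag_corrective <- function(trials, window_ms = 900) {
  if (!"corrective_rt_ms" %in% names(trials))
    stop("trials need a corrective_rt_ms column")
  err_pro <- trials$trial_type == "anti" & trials$action == "pro"
  trials$corrective_valid <- err_pro & !is.na(trials$corrective_rt_ms) &
    trials$corrective_rt_ms <= window_ms
  trials
}

#' Summary statistics of a trial table
#'
#' Mean reaction times of correct and erroneous responses and error rates
#' per condition and trial type, plus corrective-antisaccade counts when
#' flagged — the standard descriptive table for mixed pro-/antisaccade
#' blocks.
#'
#' @param trials a trial table (raw ms scale).
#' @return list: `rt` (condition x trial type x action mean RT, ms),
#'   `error_rate` (condition x trial type), `n_corrective` and
#'   `corrective_mean_rt_ms` (`NA` unless [flag_corrective()] was
#'   applied).
#' @export
summarize_trials <- function(trials) {
  agg <- stats::aggregate(rt_ms ~ condition + trial_type + action,
                          data = trials, FUN = mean)
  agg$correct <- agg$trial_type == agg$action
  er <- stats::aggregate(I(trials$trial_type != trials$action) ~
                           condition + trial_type, data = trials, FUN = mean)
  names(er)[3] <- "error_rate"
  has_corr <- "corrective_valid" %in% names(trials)
  list(rt = agg, error_rate = er,
       n_corrective = if (has_corr) sum(trials$corrective_valid) else NA,
       corrective_mean_rt_ms = if (has_corr && any(trials$corrective_valid))
         mean(trials$corrective_rt_ms[trials$corrective_valid]) else NA_real_)
}
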