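logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fixed-effects posterior model probabilities
#'
#' Softmax of log model evidences under a uniform model prior, computed
#' with max-subtraction so decisive evidence differences do not overflow.
#'
#' @param lmes numeric vector (or single-subject row) of log model
#'   evidences; for group-level use, sum LMEs over subjects first.
#' @return probability vector summing to 1.
#' @export
fixed_effects_posterior <- function(lmes) {
  if (!length(lmes)) stop("empty evidence vector")
  if (any(!is.finite(lmes))) stop("log evidences must be finite")
  p <- exp(lmes - max(lmes))
  p / sum(p)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a subject-level random effect with a
#' Dirichlet population prior (uniform, `alpha0 = 1`) and estimates the
#' posterior Dirichlet weights by the standard variational fixed point.
#' The expected frequency `r[i]` is the estimated fraction of the
#' population best described by model `i`.
#'
#' @param lmes subjects x models matrix of log model evidences.
#' @param alpha0 Dirichlet prior pseudo-counts (scalar or per-model).
#' @param tol fixed-point convergence tolerance on `alpha`.
#' @param max_iter iteration cap.
#' @return list: `r` expected model frequencies, `alpha` Dirichlet
#'   parameters, `attribution` subjects x models posterior assignment
#'   probabilities.
#' @export
random_effects_bms <- function(lmes, alpha0 = 1, tol = 1e-6,
                               max_iter = 10000) {
  lmes <- as.matrix(lmes)
  if (nrow(lmes) < 1 || ncol(lmes) < 2)
    stop("need at least one subject and two models")
  if (any(!is.finite(lmes))) stop("log evidences must be finite")
  K <- ncol(lmes)
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    lg <- sweep(lmes, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(lg - apply(lg, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  r <- alpha / sum(alpha)
  names(r) <- colnames(lmes)
  list(r = r, alpha = alpha, attribution = g)
}

#' Family-level random-effects comparison
#'
#' Aggregates member-model evidences within each family under an equal
#' within-family model prior (log-sum-exp minus log family size) and runs
#' [random_effects_bms()] over the family-level evidences.  Duplicating a
#' model inside a family leaves the result unchanged.
#'
#' @param lmes subjects x models matrix of log model evidences (typically
#'   summed across conditions per subject).
#' @param family_map character vector along the model columns naming each
#'   model's family.
#' @param ... passed to [random_effects_bms()].
#' @return list as in [random_effects_bms()] with `family_lmes` attached.
#' @export
family_comparison <- function(lmes, family_map, ...) {
  lmes <- as.matrix(lmes)
  if (length(family_map) != ncol(lmes))
    stop("family_map must name a family for every model column")
  fams <- unique(family_map)
  if (length(fams) < 2) stop("need at least two families")
  flme <- vapply(fams, function(f) {
    cols <- which(family_map == f)
    apply(lmes[, cols, drop = FALSE], 1, logsumexp) - log(length(cols))
  }, numeric(nrow(lmes)))
  flme <- matrix(flme, nrow = nrow(lmes), dimnames = list(NULL, fams))
  out <- random_effects_bms(flme, ...)
  out$family_lmes <- flme
  out
}
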