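#' Laplace-corrected Bernoulli conditional estimate
#'
#' Estimates p(x_i = 1 | class) from the number of training instances in
#' the class with bit i on, as (1 + n_on) / (2 + n_class). The +1/+2 form
#' is Laplace smoothing for a two-outcome feature: the estimate is always
#' strictly inside (0, 1), even for an empty class (where it is 1/2), so
#' log-likelihoods stay finite.
#'
#' @param n_on count of class instances with the bit set (vectorised).
#' @param n_class number of instances in the class.
#' @return probability in (0, 1); vectorised over `n_on`.
#' @export
estimate_conditional <- function(n_on, n_class) {
  if (any(n_on < 0) || n_class < 0) stop_tf("negative counts")
  if (any(n_on > n_class)) {
    stop_tf("corrupt counts: n_on (%s) exceeds n_class (%s)",
            max(n_on), n_class)
  }
  (1 + n_on) / (2 + n_class)
}

#' Maximum-likelihood class prior
#'
#' P(class) = n_class / n_total. Unsmoothed by design: the single-label
#' multi-class model requires every modelled class to be non-empty, so a
#' zero count is a hard error rather than a probability of zero.
#'
#' @param n_class instances in the class (must be >= 1).
#' @param n_total total training instances.
#' @return probability in (0, 1].
#' @export
estimate_prior <- function(n_class, n_total) {
  if (n_class < 1) stop_tf("empty class: priors require n_class >= 1")
  if (n_class > n_total) stop_tf("n_class exceeds n_total")
  n_class / n_total
}

#' Sufficient statistics for one class
#'
#' @param fingerprints binary matrix of the class's training instances
#'   (0 rows is allowed: the Laplace correction handles empty classes).
#' @return list with `n_class` (row count) and `n_on` (per-bit on-counts).
#' @export
fit_class <- function(fingerprints) {
  fingerprints <- as.matrix(fingerprints)
  if (nrow(fingerprints) > 0L && !all(fingerprints == 0 | fingerprints == 1)) {
    stop_tf("fingerprint entries must be binary")
  }
  list(n_class = nrow(fingerprints),
       n_on = as.numeric(colSums(fingerprints)))
}

#' Parameter block for one naive Bayes class
#'
#' @param prior class prior in (0, 1].
#' @param cond_on per-bit probabilities p(x_i = 1 | class), each strictly
#'   inside (0, 1) (guaranteed when produced by [estimate_conditional()]).
#' @return list of class `nb_class_params`.
#' @export
nb_class_params <- function(prior, cond_on) {
  if (!(prior > 0 && prior <= 1)) stop_tf("prior must be in (0, 1]")
  if (any(cond_on <= 0) || any(cond_on >= 1)) {
    stop_tf("conditionals must lie strictly inside (0, 1)")
  }
  structure(list(prior = prior, cond_on = as.numeric(cond_on)),
            class = "nb_class_params")
}

#' Log joint likelihood of a fingerprint under one class
#'
#' log P(class) + sum_i [ x_i log p_i + (1 - x_i) log(1 - p_i) ], the
#' log of the Bernoulli naive Bayes numerator. With m = 1024 bits the
#' literal product underflows double precision, so all posterior
#' computation goes through this log form; Laplace smoothing keeps every
#' factor off 0 and 1, hence the result is always finite.
#'
#' @param x binary fingerprint vector of length m.
#' @param params an [nb_class_params()] with `cond_on` of length m.
#' @return finite numeric scalar.
#' @export
log_likelihood <- function(x, params) {
  p <- params$cond_on
  if (length(x) != length(p)) {
    stop_tf("fingerprint length %d != model m %d", length(x), length(p))
  }
  log(params$prior) + sum(ifelse(x == 1, log(p), log1p(-p)))
}

# Vectorised log joint likelihoods: X is n x m binary, cond m x K
# (one column per class block), priors length K. Returns n x K.
# Uses the identity sum_i x_i log(p_i/(1-p_i)) + sum_i log(1-p_i).
log_likelihood_matrix <- function(X, cond, priors) {
  stopifnot(ncol(X) == nrow(cond), length(priors) == ncol(cond))
  W <- log(cond) - log1p(-cond)           # m x K
  base <- colSums(log1p(-cond))           # K
  LL <- X %*% W
  sweep(LL, 2L, base + log(priors), `+`)
}

#' Shared-evidence multi-class posterior
#'
#' Normalises the |L| class joint likelihoods by their sum -- the evidence
#' p(x) = sum_l prod_i p(x_i | l) P(l) -- so the posterior vector sums to
#' one. Computed as a softmax over log-likelihoods (log-sum-exp), which is
#' algebraically identical to the direct ratio but immune to underflow.
#'
#' @param x binary fingerprint, or an n x m matrix of fingerprints.
#' @param params_list list of [nb_class_params()], one per label, in label
#'   order; priors must sum to 1.
#' @return numeric vector (or matrix) of posteriors summing to 1 per row.
#' @export
posterior_shared_evidence <- function(x, params_list) {
  if (length(params_list) < 2L) stop_tf("need at least 2 classes")
  priors <- vapply(params_list, `[[`, numeric(1L), "prior")
  if (abs(sum(priors) - 1) > 1e-9) {
    stop_tf("class priors must sum to 1 (got %.12f)", sum(priors))
  }
  cond <- vapply(params_list, `[[`, numeric(length(params_list[[1L]]$cond_on)),
                 "cond_on")
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  LL <- log_likelihood_matrix(X, cond, priors)
  out <- softmax_rows(LL)
  colnames(out) <- names(params_list)
  if (is.matrix(x)) out else drop(out)
}

softmax_rows <- function(LL) {
  mx <- apply(LL, 1L, max)
  E <- exp(LL - mx)
  E / rowSums(E)
}

#' Per-label binary posterior p(l | x)
#'
#' For one binary-relevance classifier the evidence has exactly two terms,
#' the label and its complement: p(l | x) = e^{LL_l} / (e^{LL_l} +
#' e^{LL_not_l}), computed stably as a logistic of the log-likelihood
#' difference. The two priors must be complementary (P(l) + P(not l) = 1).
#'
#' @param x binary fingerprint (or matrix of fingerprints).
#' @param pos [nb_class_params()] for the label.
#' @param neg [nb_class_params()] for its complement.
#' @return posterior(s) strictly inside (0, 1).
#' @export
posterior_binary <- function(x, pos, neg) {
  if (abs(pos$prior + neg$prior - 1) > 1e-9) {
    stop_tf("binary priors must be complementary (sum = %.12f)",
            pos$prior + neg$prior)
  }
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  LL <- log_likelihood_matrix(X, cbind(pos$cond_on, neg$cond_on),
                              c(pos$prior, neg$prior))
  out <- stats::plogis(LL[, 1L] - LL[, 2L])
  if (is.matrix(x)) out else drop(out)
}
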