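#' Example-based multi-label precision and recall
#'
#' Instance-averaged set-overlap metrics for multi-label prediction:
#' precision is the mean over test compounds of |Y ∩ Z| / |Z| and recall
#' the mean of |Y ∩ Z| / |Y|, where Y is the annotated label set and Z the
#' predicted one. A compound with an empty predicted set contributes 0 to
#' the precision mean (rather than being silently dropped, which would
#' change the instance count); how often that happened is reported.
#'
#' @param truth list of annotated label sets Y (each non-empty).
#' @param predicted list of predicted label sets Z, aligned with `truth`.
#' @return object of class `eval_report` with `scheme = "example_based"`,
#'   `precision`, `recall`, instance count `n` and `n_empty_Z`.
#' @export
example_based_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    stop_tf("truth and predicted must be non-empty aligned lists")
  }
  if (any(lengths(truth) == 0L)) stop_tf("empty truth label set (invalid annotation)")
  inter <- mapply(function(y, z) length(intersect(y, z)), truth, predicted)
  nz <- lengths(predicted)
  prec_terms <- ifelse(nz == 0L, 0, inter / pmax(nz, 1L))
  rec_terms <- inter / lengths(truth)
  structure(list(scheme = "example_based",
                 precision = mean(prec_terms), recall = mean(rec_terms),
                 n = length(truth), n_empty_Z = sum(nz == 0L)),
            class = "eval_report")
}

#' Per-class precision and recall under the top-1 restriction
#'
#' For single-label test compounds each model contributes exactly one
#' predicted label (its rank-1 label; the threshold and the set Z are
#' ignored). Per class, TP is the number of compounds of that class
#' assigned to it, FN the number assigned elsewhere, and FP the number of
#' other-class compounds assigned to it; precision = TP / (TP + FP) and
#' recall = TP / (TP + FN). The summary values are macro-averages over
#' labels (micro-averaging is selectable); a label that is never predicted
#' has undefined precision and is excluded from the macro mean and flagged.
#'
#' @param truth annotated labels: a character vector or a list of singleton
#'   sets.
#' @param predicted_top1 character vector of rank-1 labels.
#' @param labels optional label space (default: union of both vectors).
#' @param average `"macro"` (default) or `"micro"`.
#' @return object of class `eval_report` with `scheme = "per_class"`, the
#'   summary `precision`/`recall`, the per-label table, and the labels whose
#'   precision was undefined.
#' @export
per_class_metrics <- function(truth, predicted_top1, labels = NULL,
                              average = c("macro", "micro")) {
  average <- match.arg(average)
  if (is.list(truth)) {
    if (any(lengths(truth) != 1L)) {
      stop_tf("per-class metrics require singleton truth sets")
    }
    truth <- vapply(truth, `[[`, character(1L), 1L)
  }
  truth <- as.character(truth)
  predicted_top1 <- as.character(predicted_top1)
  if (length(truth) != length(predicted_top1) || length(truth) == 0L) {
    stop_tf("truth and predictions must be non-empty and aligned")
  }
  labels <- labels %||% sort(unique(c(truth, predicted_top1)))
  if (!all(predicted_top1 %in% labels)) {
    stop_tf("prediction outside the label space: %s",
            paste(setdiff(predicted_top1, labels), collapse = ", "))
  }
  if (!all(truth %in% labels)) stop_tf("truth label outside the label space")
  tf <- factor(truth, levels = labels)
  pf <- factor(predicted_top1, levels = labels)
  tab <- table(tf, pf)
  TP <- diag(tab)
  FP <- colSums(tab) - TP
  FN <- rowSums(tab) - TP
  prec <- ifelse(TP + FP == 0, NA_real_, TP / (TP + FP))
  rec <- ifelse(TP + FN == 0, NA_real_, TP / (TP + FN))
  per_label <- data.frame(label = labels, TP = as.integer(TP),
                          FP = as.integer(FP), FN = as.integer(FN),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), row.names = NULL)
  if (average == "macro") {
    precision <- mean(prec, na.rm = TRUE)
    recall <- mean(rec, na.rm = TRUE)
  } else {
    precision <- sum(TP) / sum(TP + FP)
    recall <- sum(TP) / sum(TP + FN)
  }
  structure(list(scheme = "per_class", precision = precision, recall = recall,
                 average = average, per_label = per_label, n = length(truth),
                 undefined_precision = labels[is.na(prec)]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s]: precision = %.4f, recall = %.4f (n = %d)\n",
              x$scheme, x$precision, x$recall, x$n))
  if (!is.null(x$n_empty_Z) && x$n_empty_Z > 0) {
    cat(sprintf("  %d instance(s) with empty predicted set\n", x$n_empty_Z))
  }
  if (length(x$undefined_precision)) {
    cat(sprintf("  precision undefined (never predicted) for %d label(s)\n",
                length(x$undefined_precision)))
  }
  invisible(x)
}

#' Restrict a prediction to its top-ranked label
#'
#' The top-1 restriction used when evaluating on single-label data: only
#' the rank-1 label counts as the prediction, regardless of the threshold
#' and of whether the set Z is empty.
#'
#' @param pred an `ml_prediction`.
#' @return character vector of rank-1 labels, one per compound.
#' @export
top1_restrict <- function(pred) pred$top_label

#' Rank positions of true labels in a posterior ordering
#'
#' Labels are ranked by descending posterior (rank 1 = largest); posterior
#' ties are resolved by label-space order. Returns the 1-based positions of
#' the given true labels.
#'
#' @param posterior named numeric vector of per-label posteriors, or an
#'   unnamed vector with `labels` supplied.
#' @param true_labels labels whose positions are wanted.
#' @param labels optional label ordering (default `names(posterior)`).
#' @return integer vector of rank positions, one per true label.
#' @export
rank_positions <- function(posterior, true_labels, labels = NULL) {
  labels <- labels %||% names(posterior)
  if (is.null(labels)) stop_tf("label ordering required")
  if (!all(true_labels %in% labels)) {
    stop_tf("true label(s) missing from the posterior: %s",
            paste(setdiff(true_labels, labels), collapse = ", "))
  }
  L <- length(labels)
  ord <- order(-as.numeric(posterior), seq_len(L))
  ranks <- integer(L)
  ranks[ord] <- seq_len(L)
  ranks[match(true_labels, labels)]
}

#' Paired label-rank comparison of two models
#'
#' The ranking protocol for multi-label test compounds: both models score
#' every test compound over the full label space with the threshold
#' disabled (every label receives a posterior, so |Z| = |L|); the rank
#' position of each annotated label under model A is paired with its
#' position under model B, giving M = sum over compounds of |Y| paired
#' positions; a Wilcoxon signed-rank test on the paired positions asks
#' whether the two rankings differ. Lower rank positions are better, so
#' the favoured model is the one that ranks more of the annotated labels
#' higher.
#'
#' @param pred_a,pred_b `ml_prediction` objects for the same compounds
#'   over the same label space (for an MMM, predict with
#'   `p_threshold = 0`).
#' @param test the multi-label [activity_dataset()] the predictions were
#'   made on.
#' @param ... passed to [wilcoxon_signed_rank()] (e.g. `zero_policy`).
#' @return list with `records` (data.frame compound_id, label, rank_a,
#'   rank_b), the counts `n_tied`, `n_a_better`, `n_b_better`, `M`, and
#'   `result`, a `paired_test_result` for the Wilcoxon test on
#'   rank_a - rank_b.
#' @export
paired_rank_comparison <- function(pred_a, pred_b, test, ...) {
  if (!identical(pred_a$labels, pred_b$labels)) {
    stop_tf("the two models were scored over different label spaces")
  }
  if (nrow(pred_a$posterior) != n_compounds(test) ||
      nrow(pred_b$posterior) != n_compounds(test)) {
    stop_tf("predictions do not cover every test compound")
  }
  nl <- lengths(test$label_sets)
  cid <- rep(test$compound_ids, nl)
  lab <- unlist(test$label_sets)
  row_idx <- rep(seq_len(n_compounds(test)), nl)
  col_idx <- match(lab, pred_a$labels)
  rank_a <- pred_a$ranks[cbind(row_idx, col_idx)]
  rank_b <- pred_b$ranks[cbind(row_idx, col_idx)]
  records <- data.frame(compound_id = cid, label = lab,
                        rank_a = rank_a, rank_b = rank_b, row.names = NULL)
  diffs <- rank_a - rank_b              # > 0: model B ranks the label better
  result <- wilcoxon_signed_rank(diffs, ...)
  n_a_better <- sum(diffs < 0)
  n_b_better <- sum(diffs > 0)
  result$direction <- if (n_a_better > n_b_better) "model_a"
                      else if (n_b_better > n_a_better) "model_b"
                      else "none"
  list(records = records, M = length(diffs), n_tied = sum(diffs == 0),
       n_a_better = n_a_better, n_b_better = n_b_better, result = result)
}

#' McNemar's test on paired misclassification counts
#'
#' Compares two classifiers on the same test compounds through their
#' discordant pairs: `only_a_wrong` counts compounds misclassified by
#' model A but not B, `only_b_wrong` the converse. The default statistic
#' is the continuity-corrected chi-squared, (|b - c| - 1)^2 / (b + c) on
#' one degree of freedom; the uncorrected form and the exact binomial test
#' are selectable. The favoured model is the one with fewer exclusive
#' errors.
#'
#' @param only_a_wrong,only_b_wrong non-negative discordant counts.
#' @param variant `"continuity"` (default), `"uncorrected"` or `"exact"`.
#' @return a `paired_test_result` (statistic, p-value, direction,
#'   n_effective = discordant total).
#' @export
mcnemar_test <- function(only_a_wrong, only_b_wrong,
                         variant = c("continuity", "uncorrected", "exact")) {
  variant <- match.arg(variant)
  b <- only_a_wrong; c <- only_b_wrong
  if (b < 0 || c < 0) stop_tf("counts must be non-negative")
  if (b + c == 0) stop_tf("no discordant pairs")
  if (variant == "exact") {
    statistic <- min(b, c)
    p <- stats::binom.test(b, b + c, 0.5)$p.value
  } else {
    num <- if (variant == "continuity") (abs(b - c) - 1)^2 else (b - c)^2
    statistic <- num / (b + c)
    p <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  }
  paired_test_result(
    test_name = "mcnemar", statistic = statistic, p_value = p,
    n_effective = b + c,
    direction = if (b < c) "model_a" else if (c < b) "model_b" else "none",
    degenerate = FALSE,
    details = list(variant = variant, only_a_wrong = b, only_b_wrong = c))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Signed-rank test with average ranks for tied magnitudes. Zero
#' differences are discarded by default (the classic procedure); the Pratt
#' variant, which ranks zeros before dropping them, is selectable. The
#' null distribution is enumerated exactly (over all sign assignments, by
#' convolution) when the effective sample size is at most 25 and no exact
#' mode is forced; larger samples use the normal approximation with tie
#' correction. The statistic reported is V, the sum of the ranks of the
#' positive differences.
#'
#' @param differences numeric vector of paired differences.
#' @param zero_policy `"discard"` (default) or `"pratt"`.
#' @param mode `"auto"` (exact when n_effective <= 25), `"exact"`, or
#'   `"normal_approx"`.
#' @param alternative `"two.sided"` (default), `"greater"` (differences
#'   shifted positive) or `"less"`.
#' @return a `paired_test_result`; when every difference is zero the
#'   result is flagged degenerate with p = 1 rather than an error.
#' @export
wilcoxon_signed_rank <- function(differences,
                                 zero_policy = c("discard", "pratt"),
                                 mode = c("auto", "exact", "normal_approx"),
                                 alternative = c("two.sided", "greater", "less")) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  d <- as.numeric(differences)
  if (length(d) == 0L) stop_tf("no differences supplied")
  if (anyNA(d)) stop_tf("differences contain NA")
  n_zero <- sum(d == 0)
  nz <- d[d != 0]
  n_eff <- length(nz)
  if (n_eff == 0L) {
    return(paired_test_result("wilcoxon_signed_rank", statistic = 0,
                              p_value = 1, n_effective = 0L,
                              direction = "none", degenerate = TRUE,
                              details = list(zero_policy = zero_policy,
                                             n_zero = n_zero)))
  }
  if (zero_policy == "discard") {
    r <- rank(abs(nz))
  } else {
    r_all <- rank(abs(d))               # zeros participate in the ranking
    r <- r_all[d != 0]
  }
  V <- sum(r[nz > 0])
  use_exact <- switch(mode, exact = TRUE, normal_approx = FALSE,
                      auto = n_eff <= 25L)
  if (use_exact) {
    p <- exact_signrank_p(r, V, alternative)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    tie_groups <- table(r)
    sigma2 <- sum(r^2) / 4
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (V - mu) / sqrt(sigma2)
      p <- switch(alternative,
                  two.sided = 2 * stats::pnorm(-abs(z)),
                  greater = stats::pnorm(z, lower.tail = FALSE),
                  less = stats::pnorm(z))
      p <- min(p, 1)
    }
    method <- "normal_approx"
  }
  paired_test_result(
    "wilcoxon_signed_rank", statistic = V, p_value = p,
    n_effective = n_eff,
    direction = if (sum(r[nz > 0]) > sum(r[nz < 0])) "positive"
                else if (sum(r[nz > 0]) < sum(r[nz < 0])) "negative"
                else "none",
    degenerate = FALSE,
    details = list(zero_policy = zero_policy, mode = method,
                   alternative = alternative, n_zero = n_zero))
}

# Exact null distribution of V by convolution over the rank magnitudes:
# each rank contributes 0 or r_i with probability 1/2. Average ranks are
# half-integers, so everything is doubled to stay on an integer lattice.
exact_signrank_p <- function(r, V, alternative) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)              # f[s + 1] = #assignments with 2V = s
  f[1L] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] + f[1L:(total + 1L - ri)]
    f <- g
  }
  f <- f / sum(f)
  v2 <- as.integer(round(2 * V))
  p_ge <- sum(f[(v2 + 1L):(total + 1L)])
  p_le <- sum(f[1L:(v2 + 1L)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

paired_test_result <- function(test_name, statistic, p_value, n_effective,
                               direction, degenerate, details = list()) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_effective = n_effective,
                 direction = direction, degenerate = degenerate,
                 details = details),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n_eff = %d, direction = %s%s\n",
              x$test_name, x$statistic, x$p_value, x$n_effective,
              x$direction, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
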