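default_threshold_grid <- c(0.5, 0.9, 0.99, 0.995, 0.999, 0.9999)

#' Train the single-label multi-class naive Bayes model (SMM)
#'
#' One Bernoulli naive Bayes parameter block per target, estimated from the
#' compounds annotated against that target only; the training set must
#' therefore be single-label (apply [reduce_to_single_label()] first).
#' Priors are n_l / N and sum to one, so prediction can normalise by the
#' shared evidence summed over all |L| classes.
#'
#' @param d a single-label [activity_dataset()]; every label must have at
#'   least one training compound.
#' @return object of class `smm_model`: label space, per-class priors and
#'   Laplace-smoothed conditionals, fingerprint length and training size.
#' @export
train_smm <- function(d) {
  if (any(lengths(d$label_sets) != 1L)) {
    stop_tf(paste("SMM requires a single-label training set;",
                  "apply reduce_to_single_label() first"))
  }
  Mb <- membership_matrix(d)
  n_l <- colSums(Mb)
  if (any(n_l == 0L)) {
    stop_tf("empty class(es) in SMM training set: %s",
            paste(d$labels[n_l == 0L], collapse = ", "))
  }
  N <- n_compounds(d)
  counts_on <- crossprod(d$fingerprints, Mb)        # m x |L|
  cond <- sweep(1 + counts_on, 2L, 2 + n_l, `/`)
  priors <- n_l / N
  structure(list(labels = d$labels, m = fp_length(d),
                 priors = priors, cond = cond, n_train = N),
            class = "smm_model")
}

#' Train the binary-relevance multi-label model (MMM)
#'
#' Builds |L| "pseudo one-vs-all" Bernoulli naive Bayes classifiers via the
#' binary-relevance transformation: each D_l keeps all N training
#' instances, labelled positive when l is in the compound's label set and
#' negative otherwise. A promiscuous compound is thus a positive instance
#' of every one of its targets and a negative instance of all others.
#' Per label, P(l) = n_l / N and P(not l) = 1 - n_l / N.
#'
#' @param d an [activity_dataset()] (single- and multi-label compounds).
#' @param p_threshold posterior cutoff for the predicted label set Z
#'   (default 0.999; tune with [tune_threshold()]).
#' @param allow_empty_labels if TRUE, a label with zero positive instances
#'   only warns (its classifier degenerates to the Laplace prior).
#' @return object of class `mmm_model` with per-label positive/negative
#'   conditional blocks, positive priors, and the threshold.
#' @export
train_mmm <- function(d, p_threshold = 0.999, allow_empty_labels = FALSE) {
  if (!is_probability(p_threshold) || length(p_threshold) != 1L) {
    stop_tf("p_threshold must be a probability in [0, 1]")
  }
  Mb <- membership_matrix(d)
  n_l <- colSums(Mb)
  N <- n_compounds(d)
  if (any(n_l == N)) {
    stop_tf("label(s) positive on every instance (no negatives): %s",
            paste(d$labels[n_l == N], collapse = ", "))
  }
  if (any(n_l == 0L)) {
    if (!allow_empty_labels) {
      stop_tf("label(s) with no positive instance: %s (set allow_empty_labels)",
              paste(d$labels[n_l == 0L], collapse = ", "))
    }
    warn_tf("%d label(s) have no positive training instance", sum(n_l == 0L))
  }
  counts_pos <- crossprod(d$fingerprints, Mb)             # m x |L|
  counts_neg <- colSums(d$fingerprints) - counts_pos
  cond_pos <- sweep(1 + counts_pos, 2L, 2 + n_l, `/`)
  cond_neg <- sweep(1 + counts_neg, 2L, 2 + (N - n_l), `/`)
  structure(list(labels = d$labels, m = fp_length(d),
                 pos_prior = n_l / N, cond_pos = cond_pos,
                 cond_neg = cond_neg, p_threshold = p_threshold,
                 n_train = N),
            class = "mmm_model")
}

#' @export
print.smm_model <- function(x, ...) {
  cat(sprintf("smm_model: %d classes, m = %d bits, trained on %d compounds\n",
              length(x$labels), x$m, x$n_train))
  invisible(x)
}

#' @export
print.mmm_model <- function(x, ...) {
  cat(sprintf(
    "mmm_model: %d binary-relevance classifiers, m = %d bits, N = %d, p_threshold = %g\n",
    length(x$labels), x$m, x$n_train, x$p_threshold))
  invisible(x)
}

# Shared post-processing: posteriors -> ranks / top label / Z.
# Rank 1 is the largest posterior; ties go to the label earliest in the
# label-space ordering.
build_prediction <- function(posterior, labels, Z, mode) {
  n <- nrow(posterior)
  L <- length(labels)
  ranks <- matrix(0L, n, L, dimnames = dimnames(posterior))
  for (r in seq_len(n)) {
    ord <- order(-posterior[r, ], seq_len(L))
    ranks[r, ord] <- seq_len(L)
  }
  top <- labels[apply(ranks, 1L, which.min)]
  structure(list(posterior = posterior, ranks = ranks, top_label = top,
                 Z = Z, labels = labels, mode = mode),
            class = "ml_prediction")
}

#' @export
print.ml_prediction <- function(x, ...) {
  cat(sprintf("ml_prediction (%s): %d compounds x %d labels; mean |Z| = %.2f\n",
              x$mode, nrow(x$posterior), length(x$labels),
              mean(lengths(x$Z))))
  invisible(x)
}

#' Predict targets with a fitted model
#'
#' For the SMM, posteriors are shared-evidence (they sum to one across
#' labels) and the predicted set Z is always the single top-ranked label.
#' For the MMM, each label's posterior comes from its own binary
#' classifier (entries need not sum to one) and Z is the union of labels
#' whose posterior reaches `p_threshold` (>= comparison, so boundary
#' equality includes the label); Z may be empty, but the rank-1 label is
#' always defined so top-1 evaluation applies to every compound. Rank ties
#' are broken by label-space order.
#'
#' @param object a fitted `smm_model` or `mmm_model`.
#' @param fingerprints binary matrix (n x m) or single fingerprint vector.
#' @param p_threshold optional per-call override of the model threshold
#'   (MMM only); 0 yields Z = L for every compound.
#' @param ... unused.
#' @return object of class `ml_prediction`: posterior matrix, rank matrix
#'   (a bijection onto 1..|L| per compound), `top_label`, and the list `Z`.
#' @export
predict.smm_model <- function(object, fingerprints, ...) {
  X <- as_fp_matrix(fingerprints, object$m)
  LL <- log_likelihood_matrix(X, object$cond, object$priors)
  post <- softmax_rows(LL)
  colnames(post) <- object$labels
  pred <- build_prediction(post, object$labels, Z = NULL,
                           mode = "shared_evidence")
  pred$Z <- as.list(pred$top_label)
  pred
}

#' @rdname predict.smm_model
#' @export
predict.mmm_model <- function(object, fingerprints, p_threshold = NULL, ...) {
  thr <- p_threshold %||% object$p_threshold
  if (!is_probability(thr) || length(thr) != 1L) {
    stop_tf("p_threshold must be in [0, 1]")
  }
  X <- as_fp_matrix(fingerprints, object$m)
  LLpos <- log_likelihood_matrix(X, object$cond_pos, object$pos_prior)
  LLneg <- log_likelihood_matrix(X, object$cond_neg, 1 - object$pos_prior)
  post <- stats::plogis(LLpos - LLneg)
  dimnames(post) <- list(rownames(X), object$labels)
  Z <- apply(post >= thr, 1L, function(z) object$labels[z], simplify = FALSE)
  build_prediction(post, object$labels, Z = Z, mode = "per_label_binary")
}

as_fp_matrix <- function(x, m) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != m) stop_tf("fingerprint length %d != model m %d", ncol(X), m)
  if (!all(X == 0 | X == 1)) stop_tf("fingerprint entries must be binary")
  X
}

#' Tune the MMM posterior threshold by cross-validation
#'
#' Grid search over candidate thresholds with seeded, label-stratified
#' k-fold cross-validation on a single-label training set: for each fold an
#' MMM is fitted on the remaining folds and the held-out compounds are
#' scored with every candidate; the grid value maximising the mean
#' cross-validated objective wins, with ties resolved towards the larger
#' (more conservative) threshold. The default objective is example-based
#' F1, the harmonic mean of the example-based precision and recall of the
#' thresholded label sets against the singleton truths.
#'
#' If a fold assignment strands a label with no positive training
#' instance, the folds are redrawn once with a perturbed seed before
#' failing.
#'
#' @param train a single-label [activity_dataset()].
#' @param folds number of folds (default 5).
#' @param grid candidate thresholds in `[0, 1]`
#'   (default `c(0.5, 0.9, 0.99, 0.995, 0.999, 0.9999)`).
#' @param objective one of `"f1"`, `"precision"`, `"recall"` (example-based).
#' @param seed integer seed for the fold assignment.
#' @return the selected threshold, with the per-grid mean objective values
#'   attached as attribute `"cv_scores"`.
#' @export
tune_threshold <- function(train, folds = 5L, grid = default_threshold_grid,
                           objective = c("f1", "precision", "recall"),
                           seed = 1L) {
  objective <- match.arg(objective)
  if (folds < 2L) stop_tf("need at least 2 folds")
  if (length(grid) == 0L || !is_probability(grid)) {
    stop_tf("grid must be non-empty with values in [0, 1]")
  }
  if (any(lengths(train$label_sets) != 1L)) {
    stop_tf("threshold tuning expects a single-label training set")
  }
  fold_id <- make_folds(train, folds, seed)
  if (!folds_trainable(train, fold_id, folds)) {
    fold_id <- make_folds(train, folds, seed + 1L)
    if (!folds_trainable(train, fold_id, folds)) {
      stop_tf("a class is empty in some training fold even after redrawing")
    }
  }
  scores <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    model <- train_mmm(subset_dataset(train, which(fold_id != f)),
                       allow_empty_labels = TRUE)
    held <- subset_dataset(train, which(fold_id == f))
    pred <- predict(model, held$fingerprints, p_threshold = 0)
    truth_col <- match(vapply(held$label_sets, `[[`, character(1L), 1L),
                       model$labels)
    truth_post <- pred$posterior[cbind(seq_len(nrow(pred$posterior)),
                                       truth_col)]
    for (g in seq_along(grid)) {
      # singleton truths: |Y ∩ Z| is 1 iff the true label clears the cut
      hit <- truth_post >= grid[g]
      nZ <- rowSums(pred$posterior >= grid[g])
      prec <- mean(ifelse(nZ == 0L, 0, hit / pmax(nZ, 1L)))
      rec <- mean(hit)
      scores[f, g] <- switch(objective,
        f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec),
        precision = prec,
        recall = rec)
    }
  }
  mean_scores <- colMeans(scores)
  best <- max(mean_scores)
  # tie towards the larger threshold
  chosen <- max(grid[mean_scores >= best - 1e-12])
  structure(chosen, cv_scores = stats::setNames(mean_scores, grid))
}

make_folds <- function(d, folds, seed) {
  lab <- vapply(d$label_sets, `[[`, character(1L), 1L)
  fold_id <- integer(n_compounds(d))
  with_seed(seed, {
    for (l in unique(lab)) {
      idx <- which(lab == l)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(sample.int(folds), length(idx))
    }
  })
  fold_id
}

folds_trainable <- function(d, fold_id, folds) {
  lab <- vapply(d$label_sets, `[[`, character(1L), 1L)
  for (f in seq_len(folds)) {
    tab <- table(factor(lab[fold_id != f], levels = d$labels))
    if (any(tab == 0L)) return(FALSE)
  }
  TRUE
}

#' Serialize / restore a fitted model as JSON
#'
#' Versioned plain-text representation (label order, fingerprint length,
#' priors, conditional vectors at full double precision) so fitting and
#' prediction can run as separate invocations and a model round-trips
#' bit-stably through disk.
#'
#' @param model an `smm_model` or `mmm_model`.
#' @param path file path.
#' @return `write_model()`: the path, invisibly. `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  doc <- list(format = "targetfish-model", version = 1L,
              type = class(model)[1L], labels = model$labels,
              m = model$m, n_train = model$n_train)
  if (inherits(model, "smm_model")) {
    doc$priors <- unname(model$priors)
    doc$cond <- unname(apply(model$cond, 2L, identity, simplify = FALSE))
  } else {
    doc$pos_prior <- unname(model$pos_prior)
    doc$p_threshold <- model$p_threshold
    doc$cond_pos <- unname(apply(model$cond_pos, 2L, identity, simplify = FALSE))
    doc$cond_neg <- unname(apply(model$cond_neg, 2L, identity, simplify = FALSE))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "targetfish-model")) {
    stop_tf("'%s' is not a serialized model", path)
  }
  labels <- as.character(doc$labels)
  to_mat <- function(cols) {
    # read_json simplifies a list of equal-length vectors to a label x m
    # matrix; an unsimplified list of columns is handled too
    m <- if (is.matrix(cols)) t(cols) else do.call(cbind, lapply(cols, as.numeric))
    dimnames(m) <- list(NULL, labels)
    m
  }
  if (identical(doc$type, "smm_model")) {
    structure(list(labels = labels, m = as.integer(doc$m),
                   priors = stats::setNames(as.numeric(doc$priors), labels),
                   cond = to_mat(doc$cond),
                   n_train = as.integer(doc$n_train)),
              class = "smm_model")
  } else if (identical(doc$type, "mmm_model")) {
    structure(list(labels = labels, m = as.integer(doc$m),
                   pos_prior = stats::setNames(as.numeric(doc$pos_prior), labels),
                   cond_pos = to_mat(doc$cond_pos),
                   cond_neg = to_mat(doc$cond_neg),
                   p_threshold = as.numeric(doc$p_threshold),
                   n_train = as.integer(doc$n_train)),
              class = "mmm_model")
  } else {
    stop_tf("unknown model type '%s'", doc$type)
  }
}

#' Write predictions as a tidy TSV
#'
#' One row per (compound, label): posterior, rank position, and whether the
#' label entered the predicted set Z.
#'
#' @param pred an `ml_prediction`.
#' @param path output path.
#' @param compound_ids optional ids (default rownames of the posterior).
#' @return the path, invisibly.
#' @export
write_predictions <- function(pred, path, compound_ids = NULL) {
  ids <- compound_ids %||% rownames(pred$posterior) %||%
    as.character(seq_len(nrow(pred$posterior)))
  L <- length(pred$labels)
  in_Z <- t(vapply(seq_along(ids),
                   function(r) as.integer(pred$labels %in% pred$Z[[r]]),
                   integer(L)))
  df <- data.frame(
    compound_id = rep(ids, each = L),
    label = rep(pred$labels, times = length(ids)),
    posterior = as.vector(t(pred$posterior)),
    rank = as.vector(t(pred$ranks)),
    in_Z = as.vector(t(in_Z)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
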