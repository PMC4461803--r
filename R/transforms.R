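#' Filter a dataset by potency cutoff and class size
#'
#' Mirrors the curation applied to large bioactivity extracts before model
#' building: compound--target pairs weaker than a potency cutoff are dropped
#' first, then targets whose remaining ligand count falls outside
#' `[min_class_size, max_class_size]` are removed from the label space, and
#' finally compounds left without any label are discarded. The filter is
#' applied once, in that order -- removing a target can push other targets'
#' counts around, but there is deliberately no iteration to a fixed point.
#'
#' @param d an [activity_dataset()].
#' @param min_class_size,max_class_size inclusive bounds on ligands per
#'   target (defaults 120 and 720).
#' @param min_potency pairs with potency strictly below this are dropped;
#'   default 6.0, i.e. 1 uM on the pIC50 scale. `-Inf` disables the cutoff;
#'   pairs without potency values are kept.
#' @return the filtered `activity_dataset` (label space shrunk accordingly).
#' @export
filter_dataset <- function(d, min_class_size = 120L, max_class_size = 720L,
                           min_potency = 6.0) {
  if (min_class_size > max_class_size) {
    stop_tf("min_class_size must be <= max_class_size")
  }
  label_sets <- d$label_sets
  potencies <- d$potencies
  if (is.finite(min_potency) && !is.null(potencies)) {
    for (j in seq_along(label_sets)) {
      p <- potencies[[j]]
      if (is.null(p)) next
      keep <- label_sets[[j]][is.na(p[label_sets[[j]]]) |
                                p[label_sets[[j]]] >= min_potency]
      label_sets[[j]] <- keep
    }
  }
  counts <- table(factor(unlist(label_sets), levels = d$labels))
  keep_labels <- d$labels[counts >= min_class_size & counts <= max_class_size]
  if (length(keep_labels) < 2L) stop_tf("empty label space after filtering")
  label_sets <- lapply(label_sets, intersect, y = keep_labels)
  keep_cmp <- lengths(label_sets) > 0L
  activity_dataset(d$fingerprints[keep_cmp, , drop = FALSE],
                   label_sets[keep_cmp],
                   labels = keep_labels,
                   potencies = if (is.null(potencies)) NULL else potencies[keep_cmp],
                   compound_ids = d$compound_ids[keep_cmp])
}

#' Collapse multi-label compounds to their most potent target
#'
#' Builds the single-label training set for the SMM model: every compound
#' annotated against several targets keeps only the target with the highest
#' measured potency; single-label compounds pass through unchanged. Equal
#' potencies are resolved in favour of the label earliest in the label-space
#' ordering, so the reduction is deterministic. The number of compounds
#' never changes and no label outside the original Y is ever introduced.
#'
#' @param d an [activity_dataset()]; every multi-label compound must carry a
#'   potency for each of its labels.
#' @return an `activity_dataset` in which every label set is a singleton.
#' @export
reduce_to_single_label <- function(d) {
  label_sets <- d$label_sets
  for (j in seq_along(label_sets)) {
    Y <- label_sets[[j]]
    if (length(Y) == 1L) next
    p <- if (is.null(d$potencies)) NULL else d$potencies[[j]]
    if (is.null(p) || !all(Y %in% names(p)) || anyNA(p[Y])) {
      stop_tf("compound '%s' is multi-label but lacks potencies for all labels",
              d$compound_ids[j])
    }
    pot <- p[Y]
    best <- Y[pot == max(pot)]
    # potency tie: lowest label-space index wins
    label_sets[[j]] <- best[which.min(match(best, d$labels))]
  }
  activity_dataset(d$fingerprints, label_sets, labels = d$labels,
                   potencies = d$potencies, compound_ids = d$compound_ids)
}

#' Binary-relevance view of the dataset for one label
#'
#' The multi-label training set D is transformed into one binary problem
#' D_l per target: every instance of D is retained, labelled positive when
#' l belongs to its label set and negative otherwise. A promiscuous
#' compound therefore appears as a positive instance in several D_l -- this
#' is what distinguishes the resulting "pseudo one-vs-all" classifiers from
#' classifiers trained on single-label reductions.
#'
#' @param d an [activity_dataset()].
#' @param label a single label from the label space.
#' @return list with `fingerprints` (all N rows of `d`), logical `positive`
#'   (TRUE where `label` is annotated), and the counts `n_pos`, `n_neg`.
#' @export
binary_relevance_transform <- function(d, label) {
  if (!(label %in% d$labels)) stop_tf("label '%s' not in label space", label)
  positive <- vapply(d$label_sets, function(Y) label %in% Y, logical(1L))
  list(fingerprints = d$fingerprints, positive = positive,
       n_pos = sum(positive), n_neg = sum(!positive))
}

#' Restrict a dataset to one target family
#'
#' Generic label-grouping support: given a mapping from target ids to
#' group names (e.g. protein families such as 7TM1, kinases, proteases),
#' keeps only the labels of one group, drops the other labels from every
#' compound's label set, and removes compounds left unannotated.
#'
#' @param d an [activity_dataset()].
#' @param groups named character vector mapping `target_id` to group, as
#'   returned by [read_label_groups()].
#' @param group the group to keep.
#' @return the restricted `activity_dataset`.
#' @export
subset_by_group <- function(d, groups, group) {
  keep_labels <- intersect(d$labels, names(groups)[groups == group])
  if (length(keep_labels) < 2L) {
    stop_tf("group '%s' covers fewer than 2 labels of this dataset", group)
  }
  label_sets <- lapply(d$label_sets, intersect, y = keep_labels)
  keep <- lengths(label_sets) > 0L
  activity_dataset(d$fingerprints[keep, , drop = FALSE], label_sets[keep],
                   labels = keep_labels,
                   potencies = if (is.null(d$potencies)) NULL else d$potencies[keep],
                   compound_ids = d$compound_ids[keep])
}

#' @rdname subset_by_group
#' @param path two-column delimited file `target_id`, `group`.
#' @export
read_label_groups <- function(path) {
  df <- read_delimited(path)
  if (!all(c("target_id", "group") %in% names(df))) {
    stop_tf("grouping file needs columns target_id, group")
  }
  stats::setNames(as.character(df$group), as.character(df$target_id))
}

#' Split a dataset into training and test portions
#'
#' Compound-level random split (never by pair): a promiscuous compound goes
#' with all of its annotations to exactly one side. Both halves keep the
#' full label space. The partition is a deterministic function of `seed`.
#'
#' @param d an [activity_dataset()] with at least 2 compounds.
#' @param train_fraction fraction of compounds in the training half,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed integer seed controlling the permutation.
#' @return list with elements `train` and `test`, both `activity_dataset`s.
#' @export
split_dataset <- function(d, train_fraction = 0.7, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_tf("train_fraction must be in (0, 1)")
  }
  n <- n_compounds(d)
  if (n < 2L) stop_tf("need at least 2 compounds to split")
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[(n_train + 1L):n])
  list(train = subset_dataset(d, idx_train),
       test = subset_dataset(d, idx_test))
}
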