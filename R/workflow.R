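#' Run the full comparative target-fishing study on one dataset
#'
#' Reproduces the complete study design: a compound-level 70/30 split; a
#' single-label reduction of the training half (highest potency wins) to
#' build the SMM; an MMM built on the full training half via binary
#' relevance; optional cross-validated tuning of the MMM posterior
#' threshold on the single-label training set; then both evaluation
#' schemes on the two test partitions -- per-class recall/precision under
#' the top-1 restriction plus McNemar's test on the single-label test
#' compounds, and the paired label-rank comparison (thresholds disabled)
#' plus example-based recall/precision on the multi-label test compounds.
#'
#' @param dataset an [activity_dataset()]; alternatively pass `sim_config`
#'   to generate one.
#' @param sim_config a [generator_config()] used when `dataset` is NULL.
#' @param train_fraction training fraction of the compound split.
#' @param p_threshold MMM posterior cutoff; `NULL` (default) tunes it by
#'   cross-validation on the single-label training set.
#' @param folds,grid,objective passed to [tune_threshold()].
#' @param mcnemar_variant passed to [mcnemar_test()].
#' @param seed master seed; split, fold assignment and (if simulating)
#'   data generation all derive named streams from it.
#' @param out_dir if non-NULL, the report (JSON), both models (JSON) and
#'   the paired rank records (TSV) are written there.
#' @return list of class `study_report`: configuration echo, dataset
#'   summary, the fitted models, and the four metric blocks
#'   (`single_label_per_class`, `single_label_example_based`, `mcnemar`,
#'   `multi_label_ranking` with nested Wilcoxon result, plus
#'   `multi_label_example_based`).
#' @export
run_workflow <- function(dataset = NULL, sim_config = NULL,
                         train_fraction = 0.7, p_threshold = NULL,
                         folds = 5L, grid = default_threshold_grid,
                         objective = "f1",
                         mcnemar_variant = "continuity",
                         seed = 1L, out_dir = NULL) {
  ss <- stream_seeds(seed, c("simulate", "split", "folds"))
  if (is.null(dataset)) {
    if (is.null(sim_config)) stop_tf("supply dataset or sim_config")
    sim_config$seed <- ss[["simulate"]]
    dataset <- generate_dataset(sim_config)$dataset
  }
  sp <- split_dataset(dataset, train_fraction, seed = ss[["split"]])
  train_sl <- reduce_to_single_label(sp$train)

  smm <- train_smm(train_sl)
  tuned <- NULL
  if (is.null(p_threshold)) {
    tuned <- tune_threshold(train_sl, folds = folds, grid = grid,
                            objective = objective, seed = ss[["folds"]])
    p_threshold <- as.numeric(tuned)
  }
  mmm <- train_mmm(sp$train, p_threshold = p_threshold,
                   allow_empty_labels = TRUE)

  is_single <- lengths(sp$test$label_sets) == 1L
  report <- list(
    config = list(train_fraction = train_fraction, folds = folds,
                  grid = grid, objective = objective,
                  p_threshold = p_threshold,
                  threshold_tuned = !is.null(tuned),
                  cv_scores = if (is.null(tuned)) NULL else
                    as.list(attr(tuned, "cv_scores")),
                  mcnemar_variant = mcnemar_variant, seed = seed),
    dataset = list(n_compounds = n_compounds(dataset),
                   n_labels = length(dataset$labels),
                   m = fp_length(dataset), n_pairs = n_pairs(dataset),
                   n_train = n_compounds(sp$train),
                   n_test = n_compounds(sp$test),
                   n_test_single = sum(is_single),
                   n_test_multi = sum(!is_single)))
  report$config$config_hash <- config_hash(report$config)

  if (any(is_single)) {
    test_sl <- subset_dataset(sp$test, which(is_single))
    pred_smm <- predict(smm, test_sl$fingerprints)
    pred_mmm <- predict(mmm, test_sl$fingerprints)
    truth <- vapply(test_sl$label_sets, `[[`, character(1L), 1L)
    top_smm <- top1_restrict(pred_smm)
    top_mmm <- top1_restrict(pred_mmm)
    report$single_label_per_class <- list(
      smm = strip_report(per_class_metrics(truth, top_smm,
                                           labels = dataset$labels)),
      mmm = strip_report(per_class_metrics(truth, top_mmm,
                                           labels = dataset$labels)))
    report$single_label_example_based <- list(
      smm = strip_report(example_based_metrics(test_sl$label_sets,
                                               as.list(top_smm))),
      mmm = strip_report(example_based_metrics(test_sl$label_sets,
                                               as.list(top_mmm))))
    ok_smm <- top_smm == truth
    ok_mmm <- top_mmm == truth
    only_mmm_wrong <- sum(ok_smm & !ok_mmm)
    only_smm_wrong <- sum(!ok_smm & ok_mmm)
    report$mcnemar <- if (only_mmm_wrong + only_smm_wrong == 0) {
      list(degenerate = TRUE, note = "no discordant pairs")
    } else {
      res <- mcnemar_test(only_mmm_wrong, only_smm_wrong,
                          variant = mcnemar_variant)
      res$direction <- switch(res$direction, model_a = "mmm",
                              model_b = "smm", "none")
      unclass(res)
    }
  }

  if (any(!is_single)) {
    test_ml <- subset_dataset(sp$test, which(!is_single))
    pred_smm_ml <- predict(smm, test_ml$fingerprints)
    pred_mmm_ml <- predict(mmm, test_ml$fingerprints, p_threshold = 0)
    cmp <- paired_rank_comparison(pred_smm_ml, pred_mmm_ml, test_ml)
    report$multi_label_ranking <- list(
      M = cmp$M, n_tied = cmp$n_tied,
      n_smm_better = cmp$n_a_better, n_mmm_better = cmp$n_b_better,
      mean_rank_smm = mean(cmp$records$rank_a),
      mean_rank_mmm = mean(cmp$records$rank_b),
      wilcoxon = c(unclass(cmp$result)[c("statistic", "p_value",
                                         "n_effective", "degenerate")],
                   list(direction = switch(cmp$result$direction,
                                           model_a = "smm",
                                           model_b = "mmm", "none"))))
    pred_mmm_thr <- predict(mmm, test_ml$fingerprints)
    report$multi_label_example_based <- list(
      smm = strip_report(example_based_metrics(test_ml$label_sets,
                                               pred_smm_ml$Z)),
      mmm = strip_report(example_based_metrics(test_ml$label_sets,
                                               pred_mmm_thr$Z)))
    rank_records <- cmp$records
    names(rank_records)[3:4] <- c("rank_smm", "rank_mmm")
  } else {
    rank_records <- NULL
  }

  out <- structure(list(report = report, smm = smm, mmm = mmm),
                   class = "study_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write_model(smm, file.path(out_dir, "model_smm.json"))
    write_model(mmm, file.path(out_dir, "model_mmm.json"))
    if (!is.null(rank_records)) {
      utils::write.table(rank_records,
                         file.path(out_dir, "paired_ranks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

strip_report <- function(x) {
  x <- unclass(x)
  x$per_label <- NULL
  x$undefined_precision <- NULL
  x
}

# Small stable polynomial hash of the serialized configuration, embedded
# in every artifact so reports can be matched to the settings that made
# them. Exactly representable in doubles (modulus < 2^31).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.study_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("study_report: %d compounds, %d labels, seed %d\n",
              r$dataset$n_compounds, r$dataset$n_labels, r$config$seed))
  cat(sprintf("  p_threshold = %g%s\n", r$config$p_threshold,
              if (isTRUE(r$config$threshold_tuned)) " (tuned by CV)" else ""))
  if (!is.null(r$single_label_per_class)) {
    cat(sprintf("  single-label test (n=%d): SMM recall %.4f / precision %.4f; MMM recall %.4f / precision %.4f\n",
                r$dataset$n_test_single,
                r$single_label_per_class$smm$recall,
                r$single_label_per_class$smm$precision,
                r$single_label_per_class$mmm$recall,
                r$single_label_per_class$mmm$precision))
    if (is.null(r$mcnemar$degenerate) || !isTRUE(r$mcnemar$degenerate)) {
      cat(sprintf("  McNemar chi^2 = %.3f (p = %.3g), favouring %s\n",
                  r$mcnemar$statistic, r$mcnemar$p_value,
                  r$mcnemar$direction))
    }
  }
  if (!is.null(r$multi_label_ranking)) {
    mr <- r$multi_label_ranking
    cat(sprintf("  multi-label ranking (M=%d): tied %d, SMM better %d, MMM better %d\n",
                mr$M, mr$n_tied, mr$n_smm_better, mr$n_mmm_better))
    cat(sprintf("  mean true-label rank: SMM %.3f vs MMM %.3f; Wilcoxon p = %.3g (%s)\n",
                mr$mean_rank_smm, mr$mean_rank_mmm, mr$wilcoxon$p_value,
                mr$wilcoxon$direction))
  }
  invisible(x)
}
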