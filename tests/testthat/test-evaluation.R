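test_that("example-based metrics reproduce the hand-worked two-instance case", {
  truth <- list(c("A", "B"), "A")
  predicted <- list(c("B", "C"), "A")
  ev <- example_based_metrics(truth, predicted)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  # identity and disjoint extremes
  ev1 <- example_based_metrics(truth, truth)
  expect_equal(c(ev1$precision, ev1$recall), c(1, 1))
  ev0 <- example_based_metrics(truth, list("C", "B"))
  expect_equal(c(ev0$precision, ev0$recall), c(0, 0))
  expect_error(example_based_metrics(list(character(0)), list("A")),
               "empty truth")
})

test_that("empty predicted sets contribute zero precision and are counted", {
  ev <- example_based_metrics(list("A", "B"), list(character(0), "B"))
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$n_empty_Z, 1L)
})

test_that("example-based metrics reduce to top-1 accuracy on singletons", {
  withr::with_seed(21, {
    labels <- LETTERS[1:6]
    truth <- as.list(sample(labels, 50, replace = TRUE))
    pred <- as.list(sample(labels, 50, replace = TRUE))
    acc <- mean(unlist(truth) == unlist(pred))
    ev <- example_based_metrics(truth, pred)
    expect_equal(ev$precision, acc)
    expect_equal(ev$recall, acc)
    # invariant to instance order
    perm <- sample(50)
    ev2 <- example_based_metrics(truth[perm], pred[perm])
    expect_equal(ev2$precision, ev$precision)
  })
})

test_that("per-class metrics match TP/FP/FN arithmetic", {
  # one class with TP=8, FP=2, FN=2 -> precision = recall = 0.8
  truth <- c(rep("A", 10), rep("B", 10))
  pred <- c(rep("A", 8), "B", "B", rep("B", 8), "A", "A")
  ev <- per_class_metrics(truth, pred)
  a <- ev$per_label[ev$per_label$label == "A", ]
  expect_equal(c(a$TP, a$FP, a$FN), c(8L, 2L, 2L))
  expect_equal(a$precision, 0.8)
  expect_equal(a$recall, 0.8)
  expect_equal(ev$precision, 0.8)   # symmetric classes -> macro mean 0.8
  # perfect assignment
  evp <- per_class_metrics(truth, truth)
  expect_equal(c(evp$precision, evp$recall), c(1, 1))
  # for single-label truth: sum TP = #correct, sum (TP+FN) = |T|
  expect_equal(sum(ev$per_label$TP), sum(truth == pred))
  expect_equal(sum(ev$per_label$TP + ev$per_label$FN), length(truth))
})

test_that("a never-predicted label is excluded from macro precision and flagged", {
  truth <- c("A", "A", "B", "C")
  pred <- c("A", "A", "A", "A")
  ev <- per_class_metrics(truth, pred, labels = c("A", "B", "C"))
  expect_setequal(ev$undefined_precision, c("B", "C"))
  expect_equal(ev$per_label$recall[ev$per_label$label == "B"], 0)
  expect_equal(ev$precision, 0.5)   # only A's precision (2/4) is defined
  micro <- per_class_metrics(truth, pred, labels = c("A", "B", "C"),
                             average = "micro")
  expect_equal(micro$precision, 0.5)
  expect_equal(micro$recall, 0.5)
  expect_error(per_class_metrics(truth, c("A", "A", "A", "Z"),
                                 labels = c("A", "B", "C")),
               "outside the label space")
})

test_that("top-1 restriction returns the rank-1 label regardless of Z", {
  model <- train_smm(toy_dataset())
  pred <- predict(model, rbind(c(1L, 0L), c(0L, 1L)))
  expect_equal(top1_restrict(pred), c("A", "B"))
})

test_that("rank positions follow descending posteriors with label-order ties", {
  post <- c(A = 0.7, B = 0.2, C = 0.1)
  expect_equal(rank_positions(post, "B"), 2L)
  expect_setequal(rank_positions(post, c("A", "B", "C")), 1:3)
  tied <- c(A = 0.4, B = 0.4, C = 0.2)
  expect_equal(rank_positions(tied, "B"), 2L)
  expect_equal(rank_positions(tied, "A"), 1L)
  expect_error(rank_positions(post, "Z"), "missing")
})

test_that("McNemar's test matches its closed forms and is direction-symmetric", {
  r <- mcnemar_test(10, 20)
  expect_equal(r$statistic, 2.7)
  expect_equal(r$p_value, stats::pchisq(2.7, 1, lower.tail = FALSE))
  expect_equal(r$direction, "model_a")
  r55 <- mcnemar_test(5, 5)
  expect_equal(r55$statistic, 0.1)
  expect_equal(r55$direction, "none")
  expect_error(mcnemar_test(0, 0), "no discordant")
  # symmetry: swapping the discordant counts flips the direction only
  fwd <- mcnemar_test(7, 19)
  rev <- mcnemar_test(19, 7)
  expect_equal(fwd$statistic, rev$statistic)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(rev$direction, "model_b")
  # uncorrected and exact variants agree with stats reference forms
  expect_equal(mcnemar_test(10, 20, variant = "uncorrected")$statistic,
               100 / 30)
  expect_equal(mcnemar_test(10, 20, variant = "exact")$p_value,
               stats::binom.test(10, 30, 0.5)$p.value)
})

test_that("exact Wilcoxon p-values match full 2^n enumeration", {
  r <- wilcoxon_signed_rank(1:5, alternative = "greater")
  expect_equal(r$p_value, 1 / 32)
  expect_equal(r$statistic, 15)
  # {+d, -d}: perfectly symmetric -> two-sided p = 1
  sym <- wilcoxon_signed_rank(c(3, -3))
  expect_equal(sym$p_value, 1)
  withr::with_seed(14, {
    for (i in 1:40) {
      n <- sample(2:10, 1L)
      d <- round(stats::rnorm(n, sd = 2), 1)
      d <- d[d != 0]
      if (length(d) < 2L) next
      for (alt in c("two.sided", "greater", "less")) {
        got <- wilcoxon_signed_rank(d, alternative = alt)
        expect_equal(got$p_value, brute_signrank_p(d, alt),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("exact Wilcoxon agrees with the stats reference when tie-free", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(4:20, 1L)
      d <- stats::rnorm(n)   # continuous: no zeros, no tied magnitudes
      got <- wilcoxon_signed_rank(d)
      ref <- stats::wilcox.test(d, exact = TRUE)
      expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(got$statistic, unname(ref$statistic))
    }
  })
})

test_that("large-sample Wilcoxon uses a tie-corrected normal approximation", {
  withr::with_seed(8, {
    d <- sample(c(-2L, -1L, 1L, 2L, 3L), 400, replace = TRUE)
    got <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, correct = FALSE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(got$details$mode, "normal_approx")
    # direction of a clearly shifted sample
    shifted <- stats::rnorm(500, mean = 0.5)
    r <- wilcoxon_signed_rank(shifted)
    expect_lt(r$p_value, 1e-6)
    expect_equal(r$direction, "positive")
  })
})

test_that("zero differences: discard vs Pratt policies and degeneracy", {
  allz <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(allz$degenerate)
  expect_equal(allz$p_value, 1)
  expect_equal(allz$n_effective, 0L)
  d <- c(0, 0, 1, 2, -1, 3)
  disc <- wilcoxon_signed_rank(d, zero_policy = "discard")
  expect_equal(disc$n_effective, 4L)
  pratt <- wilcoxon_signed_rank(d, zero_policy = "pratt")
  # zeros occupy ranks 1-2 under Pratt, inflating the signed ranks
  expect_gt(pratt$statistic, disc$statistic)
})

test_that("paired rank comparison pairs every annotated label once", {
  gen <- generate_dataset(generator_config(n_labels = 8L, n_compounds = 600L,
                                           m = 128L, seed = 12L))
  sp <- split_dataset(gen$dataset, 0.7, seed = 12L)
  train_sl <- reduce_to_single_label(sp$train)
  smm <- train_smm(train_sl)
  mmm <- suppressWarnings(train_mmm(sp$train, allow_empty_labels = TRUE))
  multi <- subset_dataset(sp$test, which(lengths(sp$test$label_sets) >= 2L))
  pa <- predict(smm, multi$fingerprints)
  pb <- predict(mmm, multi$fingerprints, p_threshold = 0)
  cmp <- paired_rank_comparison(pa, pb, multi)
  expect_equal(cmp$M, n_pairs(multi))
  expect_equal(cmp$n_tied + cmp$n_a_better + cmp$n_b_better, cmp$M)
  expect_equal(nrow(cmp$records), cmp$M)
  # records carry the rank each model assigned to each true label
  j <- match(cmp$records$compound_id[1L], multi$compound_ids)
  expect_equal(cmp$records$rank_a[1L],
               rank_positions(pa$posterior[j, ], cmp$records$label[1L]))
  # identical models -> all differences zero -> degenerate with p = 1
  self <- paired_rank_comparison(pa, pa, multi)
  expect_true(self$result$degenerate)
  expect_equal(self$result$p_value, 1)
  expect_equal(self$n_tied, self$M)
})
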