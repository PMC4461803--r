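test_that("triplet reading groups rows into compounds with label sets", {
  td <- withr::local_tempdir()
  writeLines(c("compound_id,target_id,potency",
               "c1,A,7.0", "c1,B,8.0", "c2,A,6.5"),
             file.path(td, "tr.csv"))
  writeLines(c("compound_id\tb1\tb2",
               "c1\t1\t0", "c2\t0\t1"),
             file.path(td, "fp.tsv"))
  d <- read_activity_triplets(file.path(td, "tr.csv"), file.path(td, "fp.tsv"))
  expect_equal(n_compounds(d), 2L)
  expect_setequal(d$label_sets[[match("c1", d$compound_ids)]], c("A", "B"))
  expect_equal(d$label_sets[[match("c2", d$compound_ids)]], "A")
  expect_equal(n_pairs(d), 3L)
  expect_equal(unname(d$potencies[[match("c1", d$compound_ids)]]["B"]), 8.0)
})

test_that("triplet reading rejects degenerate and inconsistent input", {
  td <- withr::local_tempdir()
  writeLines("compound_id,target_id,potency", file.path(td, "empty.csv"))
  writeLines(c("compound_id\tb1", "c1\t1"), file.path(td, "fp.tsv"))
  expect_error(read_activity_triplets(file.path(td, "empty.csv"),
                                      file.path(td, "fp.tsv")),
               "no annotations")
  writeLines(c("compound_id,target_id,potency", "c9,A,7", "c1,B,6"),
             file.path(td, "bad.csv"))
  expect_error(read_activity_triplets(file.path(td, "bad.csv"),
                                      file.path(td, "fp.tsv")),
               "row 1.*c9")
  writeLines(c("compound_id\tb1", "c1\t2"), file.path(td, "fpbad.tsv"))
  writeLines(c("compound_id,target_id,potency", "c1,A,7", "c1,B,6"),
             file.path(td, "tr.csv"))
  expect_error(read_activity_triplets(file.path(td, "tr.csv"),
                                      file.path(td, "fpbad.tsv")),
               "non-binary")
})

test_that("duplicate (compound, target) rows keep the highest potency", {
  td <- withr::local_tempdir()
  writeLines(c("compound_id,target_id,potency",
               "c1,A,6.0", "c1,A,7.5", "c2,B,5"),
             file.path(td, "tr.csv"))
  writeLines(c("compound_id\tb1", "c1\t1", "c2\t0"), file.path(td, "fp.tsv"))
  expect_warning(
    d <- read_activity_triplets(file.path(td, "tr.csv"),
                                file.path(td, "fp.tsv")),
    "duplicate")
  expect_equal(unname(d$potencies[[match("c1", d$compound_ids)]]["A"]), 7.5)
  expect_equal(n_pairs(d), 2L)
})

test_that("write/read round-trip preserves the dataset exactly", {
  gen <- generate_dataset(generator_config(n_labels = 5L, n_compounds = 60L,
                                           m = 32L, seed = 11L))
  d <- gen$dataset
  td <- withr::local_tempdir()
  write_activity_dataset(d, file.path(td, "tr.tsv"), file.path(td, "fp.tsv"))
  d2 <- read_activity_triplets(file.path(td, "tr.tsv"), file.path(td, "fp.tsv"),
                               labels = d$labels)
  idx <- match(d$compound_ids, d2$compound_ids)
  expect_equal(d2$compound_ids[idx], d$compound_ids)
  expect_equal(unname(d2$fingerprints[idx, ]), unname(d$fingerprints))
  for (j in seq_along(idx)) {
    expect_setequal(d2$label_sets[[idx[j]]], d$label_sets[[j]])
    expect_equal(d2$potencies[[idx[j]]][d$label_sets[[j]]],
                 d$potencies[[j]][d$label_sets[[j]]])
  }
})

test_that("filtering removes weak pairs, out-of-range classes, then orphans", {
  fp <- matrix(0L, 6, 4,
               dimnames = list(sprintf("c%d", 1:6), NULL))
  d <- activity_dataset(
    fp,
    list(c("A", "B"), "A", "A", "B", "B", "C"),
    labels = c("A", "B", "C"),
    potencies = list(c(A = 7, B = 8), c(A = 7), c(A = 5), c(B = 7),
                     c(B = 7), c(C = 9)))
  # potency cutoff 6 drops (c3, A); class sizes then A=2, B=3, C=1;
  # bounds [2, 3] drop C; c3 and c6 left unannotated and removed
  f <- filter_dataset(d, min_class_size = 2L, max_class_size = 3L,
                      min_potency = 6)
  expect_setequal(f$labels, c("A", "B"))
  expect_setequal(f$compound_ids, c("c1", "c2", "c4", "c5"))
  # no cutoff violated -> identity
  f2 <- filter_dataset(d, min_class_size = 1L, max_class_size = 10L,
                       min_potency = -Inf)
  expect_equal(f2$label_sets, d$label_sets)
  expect_error(filter_dataset(d, 100L, 200L, 6), "empty label space")
})

test_that("single-label reduction keeps the most potent target deterministically", {
  fp <- matrix(1L, 3, 2, dimnames = list(c("c1", "c2", "c3"), NULL))
  d <- activity_dataset(
    fp, list(c("A", "B"), "A", c("A", "B")),
    labels = c("A", "B"),
    potencies = list(c(A = 7.2, B = 8.1), c(A = 6), c(A = 7, B = 7)))
  r <- reduce_to_single_label(d)
  expect_equal(lengths(r$label_sets), rep(1L, 3L))
  expect_equal(r$label_sets[[1L]], "B")    # max potency
  expect_equal(r$label_sets[[2L]], "A")    # pass-through
  expect_equal(r$label_sets[[3L]], "A")    # tie -> first label in order
  expect_equal(n_compounds(r), n_compounds(d))
  # never invents labels outside the original Y
  expect_true(all(mapply(function(y, y0) y %in% y0,
                         r$label_sets, d$label_sets)))
  d_bad <- activity_dataset(fp, list(c("A", "B"), "A", "B"),
                            labels = c("A", "B"))
  expect_error(reduce_to_single_label(d_bad), "c1")
})

test_that("binary relevance keeps every instance and conserves pair counts", {
  fp <- matrix(0L, 3, 2, dimnames = list(c("c1", "c2", "c3"), NULL))
  d <- activity_dataset(fp, list(c("A", "B"), "A", "B"),
                        labels = c("A", "B", "C"))
  da <- binary_relevance_transform(d, "A")
  expect_equal(nrow(da$fingerprints), 3L)
  expect_equal(da$n_pos, 2L)
  expect_equal(da$n_neg, 1L)
  # multi-label compound positive in both of its labels' problems
  db <- binary_relevance_transform(d, "B")
  expect_true(da$positive[1L] && db$positive[1L])
  # empty label: 0 positives, N negatives, still valid
  dc <- binary_relevance_transform(d, "C")
  expect_equal(dc$n_pos, 0L)
  expect_equal(dc$n_neg, 3L)
  expect_error(binary_relevance_transform(d, "Z"), "not in label space")
  # sum over labels of positives equals total pair count
  tot <- sum(vapply(d$labels,
                    function(l) binary_relevance_transform(d, l)$n_pos,
                    integer(1L)))
  expect_equal(tot, n_pairs(d))
})

test_that("compound-level split is disjoint, exhaustive and seed-reproducible", {
  gen <- generate_dataset(generator_config(n_labels = 4L, n_compounds = 10L,
                                           m = 8L, signal_bits = 2L,
                                           seed = 2L))
  sp <- split_dataset(gen$dataset, 0.7, seed = 42L)
  expect_equal(n_compounds(sp$train), 7L)
  expect_equal(n_compounds(sp$test), 3L)
  expect_length(intersect(sp$train$compound_ids, sp$test$compound_ids), 0L)
  expect_setequal(c(sp$train$compound_ids, sp$test$compound_ids),
                  gen$dataset$compound_ids)
  sp2 <- split_dataset(gen$dataset, 0.7, seed = 42L)
  expect_identical(sp$train$compound_ids, sp2$train$compound_ids)
  expect_identical(label_space(sp$train), label_space(gen$dataset))
  expect_error(split_dataset(subset_dataset(gen$dataset, 1L), 0.5, 1L),
               "at least 2")
})

test_that("a 70/30 split of a promiscuous set yields both test partitions", {
  gen <- generate_dataset(generator_config(n_labels = 10L, n_compounds = 1500L,
                                           m = 16L, seed = 7L))
  sp <- split_dataset(gen$dataset, 0.7, seed = 7L)
  nl <- lengths(sp$test$label_sets)
  expect_equal(n_compounds(sp$test), 450L)
  expect_gt(sum(nl == 1L), 0L)
  expect_gt(sum(nl >= 2L), 0L)
})

test_that("family grouping restricts the label space and drops orphans", {
  fp <- matrix(0L, 3, 2, dimnames = list(c("c1", "c2", "c3"), NULL))
  d <- activity_dataset(fp, list(c("A", "C"), "B", "C"),
                        labels = c("A", "B", "C"))
  td <- withr::local_tempdir()
  writeLines(c("target_id\tgroup", "A\tkinase", "B\tprotease", "C\tkinase"),
             file.path(td, "groups.tsv"))
  groups <- read_label_groups(file.path(td, "groups.tsv"))
  k <- subset_by_group(d, groups, "kinase")
  expect_setequal(k$labels, c("A", "C"))
  expect_setequal(k$compound_ids, c("c1", "c3"))
  expect_error(subset_by_group(d, groups, "protease"), "fewer than 2")
})
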