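#' Default ligand-promiscuity distribution
#'
#' Probability of a compound being annotated against k targets, shaped like
#' the promiscuity profile of large curated bioactivity extracts: about 83%
#' of compounds single-label, 12% with two targets, a thinning tail towards
#' larger label sets (here extended geometrically up to `max_size`, 57 by
#' default). Probabilities sum to one.
#'
#' @param max_size largest label-set size carried by the tail.
#' @return named numeric vector: P(|Y| = k) for k = 1..max_size.
#' @export
default_promiscuity <- function(max_size = 57L) {
  counts <- c(54563, 7937, 1571, 321, 240, 191, 132, 60, 42)
  total <- sum(counts) + 530          # 530 compounds with |Y| >= 10
  p <- counts / total
  if (max_size > 9L) {
    tail_sizes <- 10:max_size
    w <- 0.85^(tail_sizes - 10L)
    p <- c(p, (530 / total) * w / sum(w))
    names(p) <- as.character(1:max_size)
  } else {
    p <- p[1:max_size] / sum(p[1:max_size])
    names(p) <- as.character(1:max_size)
  }
  p
}

#' Configuration for the synthetic activity-data generator
#'
#' Describes a bipartite ligand--target world with class-conditional
#' Bernoulli fingerprints: each target class elevates a small set of
#' "signal" bits above a sparse background, compounds draw a label set
#' from a promiscuity distribution, and a promiscuous compound's
#' fingerprint carries the signal of all of its targets (per-bit maximum
#' of its classes' profiles). Defaults emulate the structure of the
#' curated bioactivity extract the models are aimed at: 308 targets,
#' 65,587 compounds, 1,024-bit sparse binary fingerprints, ~83%
#' single-label compounds with label sets up to 57, and potencies on the
#' p-scale.
#'
#' @param n_labels number of target classes (>= 2).
#' @param n_compounds number of compounds.
#' @param m fingerprint length in bits.
#' @param promiscuity named probability vector over label-set sizes
#'   (entries beyond `n_labels` are dropped and the rest renormalised).
#' @param signal_bits elevated bits per class.
#' @param signal_prob on-probability of a class's signal bits.
#' @param background_prob on-probability of every other bit.
#' @param signal_mode `"overlap"` (default: each class samples its signal
#'   bits independently, so classes may share features) or `"disjoint"`
#'   (classes get non-overlapping bit sets; requires
#'   `n_labels * signal_bits <= m`).
#' @param potency_mean,potency_sd normal potency distribution on the
#'   p-scale (defaults 7 and 1), drawn independently per pair.
#' @param seed master seed; all randomness (profiles, membership, bits,
#'   potencies) flows from it through named streams.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_labels = 308L, n_compounds = 65587L,
                             m = 1024L,
                             promiscuity = default_promiscuity(),
                             signal_bits = 16L, signal_prob = 0.25,
                             background_prob = 0.015,
                             signal_mode = c("overlap", "disjoint"),
                             potency_mean = 7, potency_sd = 1,
                             seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  if (n_labels < 2L) stop_tf("need at least 2 labels")
  if (n_compounds < 1L || m < 1L || signal_bits < 1L) {
    stop_tf("all counts must be positive")
  }
  if (signal_bits > m) stop_tf("signal_bits (%d) exceeds m (%d)", signal_bits, m)
  if (!(signal_prob > 0 && signal_prob < 1) ||
      !(background_prob > 0 && background_prob < 1)) {
    stop_tf("on-probabilities must lie in (0, 1)")
  }
  sizes <- as.integer(names(promiscuity))
  if (anyNA(sizes) || any(sizes < 1L) || any(promiscuity < 0)) {
    stop_tf("promiscuity must map positive sizes to probabilities")
  }
  keep <- sizes <= n_labels
  promiscuity <- promiscuity[keep] / sum(promiscuity[keep])
  if (abs(sum(promiscuity) - 1) > 1e-9) stop_tf("promiscuity must sum to 1")
  structure(list(n_labels = as.integer(n_labels),
                 n_compounds = as.integer(n_compounds), m = as.integer(m),
                 promiscuity = promiscuity,
                 signal_bits = as.integer(signal_bits),
                 signal_prob = signal_prob,
                 background_prob = background_prob,
                 signal_mode = signal_mode,
                 potency_mean = potency_mean, potency_sd = potency_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate ground-truth class fingerprint profiles
#'
#' Each class's profile is the background on-probability everywhere except
#' on its signal bits, which sit at `signal_prob`. Deterministic from the
#' configuration seed.
#'
#' @param cfg a [generator_config()].
#' @return list of class `generator_truth` with `profiles`
#'   (n_labels x m matrix of on-probabilities, rownames = labels) and
#'   `signal_bits` (list of bit indices per class).
#' @export
generate_profiles <- function(cfg) {
  labels <- sprintf("T%03d", seq_len(cfg$n_labels))
  if (cfg$signal_mode == "disjoint" &&
      cfg$n_labels * cfg$signal_bits > cfg$m) {
    stop_tf("disjoint mode needs n_labels * signal_bits <= m (%d * %d > %d)",
            cfg$n_labels, cfg$signal_bits, cfg$m)
  }
  ss <- stream_seeds(cfg$seed, c("profiles", "membership", "bits", "potencies"))
  profiles <- matrix(cfg$background_prob, cfg$n_labels, cfg$m,
                     dimnames = list(labels, NULL))
  sig <- with_seed(ss[["profiles"]], {
    if (cfg$signal_mode == "disjoint") {
      pool <- sample.int(cfg$m, cfg$n_labels * cfg$signal_bits)
      split(pool, rep(seq_len(cfg$n_labels), each = cfg$signal_bits))
    } else {
      lapply(seq_len(cfg$n_labels),
             function(i) sample.int(cfg$m, cfg$signal_bits))
    }
  })
  names(sig) <- labels
  for (i in seq_len(cfg$n_labels)) profiles[i, sig[[i]]] <- cfg$signal_prob
  structure(list(profiles = profiles, signal_bits = sig, labels = labels),
            class = "generator_truth")
}

#' Generate a synthetic activity dataset
#'
#' Draws, per compound: a label-set size from the promiscuity
#' distribution, a label set uniformly without replacement, fingerprint
#' bits from the per-bit maximum of its classes' profiles (so a
#' promiscuous compound genuinely resembles all of its targets -- the
#' regime where a single-label reduction loses information), and a potency
#' per pair from the configured normal. All four draws run on independent
#' named streams of the master seed.
#'
#' @param cfg a [generator_config()].
#' @return list with `dataset` (an [activity_dataset()]) and `truth` (the
#'   `generator_truth`, for recovery tests).
#' @export
generate_dataset <- function(cfg) {
  truth <- generate_profiles(cfg)
  ss <- stream_seeds(cfg$seed, c("profiles", "membership", "bits", "potencies"))
  n <- cfg$n_compounds
  sizes_avail <- as.integer(names(cfg$promiscuity))
  label_sets <- with_seed(ss[["membership"]], {
    k <- sizes_avail[sample.int(length(sizes_avail), n, replace = TRUE,
                                prob = cfg$promiscuity)]
    lapply(k, function(ki) truth$labels[sample.int(cfg$n_labels, ki)])
  })
  fp <- matrix(0L, n, cfg$m)
  nl <- lengths(label_sets)
  with_seed(ss[["bits"]], {
    block <- 4000L
    for (start in seq(1L, n, by = block)) {
      idx <- start:min(start + block - 1L, n)
      P <- truth$profiles[vapply(label_sets[idx], `[[`, character(1L), 1L),
                          , drop = FALSE]
      for (r in which(nl[idx] > 1L)) {      # promiscuous: per-bit max profile
        pr <- truth$profiles[label_sets[[idx[r]]], , drop = FALSE]
        P[r, ] <- do.call(pmax, asplit(pr, 1L))
      }
      fp[idx, ] <- (matrix(stats::runif(length(idx) * cfg$m),
                           length(idx)) < P) + 0L
    }
  })
  potencies <- with_seed(ss[["potencies"]], {
    lapply(label_sets, function(Y) {
      stats::setNames(stats::rnorm(length(Y), cfg$potency_mean,
                                   cfg$potency_sd), Y)
    })
  })
  ids <- sprintf("C%06d", seq_len(n))
  rownames(fp) <- ids
  d <- activity_dataset(fp, label_sets, labels = truth$labels,
                        potencies = potencies, compound_ids = ids)
  list(dataset = d, truth = truth)
}

#' Write a self-contained benchmark fixture to disk
#'
#' Emits the exact on-disk formats the readers consume -- annotation
#' triplets, dense fingerprint matrix, a JSON ground-truth sidecar, and a
#' 70/30 compound-level split manifest -- at one of two scales: `"tiny"`
#' (20 targets, 2,000 compounds; trains end-to-end in well under a minute)
#' or `"paper_like"` (308 targets, 15,000 compounds; the full label-space
#' structure at desk runtime). Re-running with the same seed reproduces
#' the files byte for byte.
#'
#' @param scale `"tiny"` or `"paper_like"`.
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
make_benchmark_fixture <- function(scale = c("tiny", "paper_like"),
                                   seed = 1L, dir = ".") {
  scale <- match.arg(scale)
  cfg <- switch(scale,
    tiny = generator_config(n_labels = 20L, n_compounds = 2000L,
                            seed = seed),
    paper_like = generator_config(n_labels = 308L, n_compounds = 15000L,
                                  seed = seed))
  gen <- generate_dataset(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(triplets = file.path(dir, "triplets.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"),
             split = file.path(dir, "split.tsv"))
  write_activity_dataset(gen$dataset, paths[["triplets"]],
                         paths[["fingerprints"]])
  jsonlite::write_json(
    list(labels = gen$truth$labels,
         profiles = apply(gen$truth$profiles, 1L, identity,
                          simplify = FALSE),
         signal_bits = gen$truth$signal_bits,
         label_sets = stats::setNames(gen$dataset$label_sets,
                                      gen$dataset$compound_ids)),
    paths[["ground_truth"]], digits = NA)
  sp <- split_dataset(gen$dataset, 0.7,
                      seed = stream_seeds(seed, "split")[["split"]])
  manifest <- data.frame(
    compound_id = c(sp$train$compound_ids, sp$test$compound_ids),
    partition = rep(c("train", "test"),
                    c(n_compounds(sp$train), n_compounds(sp$test))))
  manifest <- manifest[order(manifest$compound_id), ]
  utils::write.table(manifest, paths[["split"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
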