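#' Construct an activity dataset
#'
#' The central container of the package: a set of compounds, each carrying a
#' fixed-length binary fingerprint, a non-empty set of target labels
#' (proteins against which the compound is annotated active), and optionally
#' a potency value per compound--target pair on a "larger is more potent"
#' scale such as pIC50.
#'
#' The label space is an ordered vector of unique target identifiers. Its
#' ordering is fixed at construction (lexicographic unless `labels` is
#' supplied explicitly) and defines all downstream index and tie-break
#' semantics: tied posteriors, tied potencies and tied ranks are always
#' resolved in favour of the label that comes first in this ordering.
#'
#' @param fingerprints numeric/integer matrix with entries in \{0, 1\}, one
#'   row per compound; rownames are taken as compound identifiers (or
#'   `compound_ids` may be given).
#' @param label_sets list of character vectors, one per compound: the set
#'   `Y` of targets the compound is annotated against. Every `Y` must be
#'   non-empty and a subset of the label space.
#' @param labels optional explicit label-space ordering; defaults to the
#'   sorted union of all annotated labels.
#' @param potencies optional list (parallel to `label_sets`) of named numeric
#'   vectors: potency per annotated label, names covering at least `Y`.
#' @param compound_ids optional character vector of unique compound ids;
#'   defaults to `rownames(fingerprints)`.
#'
#' @return An object of class `activity_dataset` with elements
#'   `fingerprints`, `label_sets`, `potencies`, `labels`, `compound_ids`.
#' @export
activity_dataset <- function(fingerprints, label_sets, labels = NULL,
                             potencies = NULL, compound_ids = NULL) {
  fingerprints <- as.matrix(fingerprints)
  if (is.null(compound_ids)) compound_ids <- rownames(fingerprints)
  if (is.null(compound_ids)) {
    stop_tf("compound ids are required (rownames or compound_ids=)")
  }
  compound_ids <- as.character(compound_ids)
  n <- nrow(fingerprints)
  if (length(compound_ids) != n || length(label_sets) != n) {
    stop_tf("fingerprints (%d rows), compound_ids (%d) and label_sets (%d) must agree",
            n, length(compound_ids), length(label_sets))
  }
  if (anyDuplicated(compound_ids)) {
    stop_tf("duplicate compound ids: %s",
            paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  }
  storage.mode(fingerprints) <- "integer"
  if (n > 0L && !all(fingerprints == 0L | fingerprints == 1L)) {
    stop_tf("fingerprint entries must be binary (0/1)")
  }
  rownames(fingerprints) <- compound_ids
  label_sets <- lapply(label_sets, as.character)
  if (any(lengths(label_sets) == 0L)) {
    stop_tf("every compound needs a non-empty label set")
  }
  used <- sort(unique(unlist(label_sets)))
  if (is.null(labels)) {
    labels <- used
  } else {
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop_tf("label space has duplicates")
    missing <- setdiff(used, labels)
    if (length(missing)) {
      stop_tf("annotated labels outside the supplied label space: %s",
              paste(missing, collapse = ", "))
    }
  }
  if (length(labels) < 2L) {
    stop_tf("label space must contain at least 2 targets (got %d)", length(labels))
  }
  if (!is.null(potencies)) {
    if (length(potencies) != n) stop_tf("potencies must parallel label_sets")
    for (j in seq_len(n)) {
      pj <- potencies[[j]]
      if (is.null(pj)) next
      if (!all(label_sets[[j]] %in% names(pj))) {
        stop_tf("compound '%s': potencies must cover every annotated label",
                compound_ids[j])
      }
    }
  }
  structure(
    list(fingerprints = fingerprints, label_sets = label_sets,
         potencies = potencies, labels = labels, compound_ids = compound_ids),
    class = "activity_dataset")
}

#' @export
print.activity_dataset <- function(x, ...) {
  nl <- lengths(x$label_sets)
  cat(sprintf(
    "activity_dataset: %d compounds x %d fingerprint bits, %d targets\n",
    n_compounds(x), fp_length(x), length(x$labels)))
  cat(sprintf("  pairs: %d | single-label compounds: %d (%.1f%%) | max |Y|: %d\n",
              sum(nl), sum(nl == 1L), 100 * mean(nl == 1L), max(nl)))
  invisible(x)
}

#' Dataset dimensions and structure helpers
#'
#' @param d an `activity_dataset`.
#' @return `n_compounds()`: number of compounds; `fp_length()`: fingerprint
#'   length m; `n_pairs()`: total number of compound--target annotations
#'   (the sum of label-set sizes); `label_space()`: the ordered label vector.
#' @export
n_compounds <- function(d) length(d$compound_ids)

#' @rdname n_compounds
#' @export
fp_length <- function(d) ncol(d$fingerprints)

#' @rdname n_compounds
#' @export
n_pairs <- function(d) sum(lengths(d$label_sets))

#' @rdname n_compounds
#' @export
label_space <- function(d) d$labels

#' Binary compound-by-label membership matrix
#'
#' Rows are compounds, columns the ordered label space; entry (j, l) is 1
#' iff label l belongs to Y_j. This is the dense form of the bipartite
#' activity annotation and the workhorse behind class-count computation.
#'
#' @param d an `activity_dataset`.
#' @return integer matrix `n_compounds x |L|` with dimnames.
#' @export
membership_matrix <- function(d) {
  m <- matrix(0L, n_compounds(d), length(d$labels),
              dimnames = list(d$compound_ids, d$labels))
  idx <- cbind(rep(seq_len(n_compounds(d)), lengths(d$label_sets)),
               match(unlist(d$label_sets), d$labels))
  m[idx] <- 1L
  m
}

# Row subset preserving the full label space.
subset_dataset <- function(d, idx) {
  activity_dataset(d$fingerprints[idx, , drop = FALSE],
                   d$label_sets[idx],
                   labels = d$labels,
                   potencies = if (is.null(d$potencies)) NULL else d$potencies[idx],
                   compound_ids = d$compound_ids[idx])
}

#' Read an activity dataset from triplet and fingerprint files
#'
#' Activity annotations are read as delimited text with (at least) the
#' columns `compound_id`, `target_id`, `potency` -- one row per
#' compound--target pair. Fingerprints come either from a dense delimited
#' 0/1 matrix whose first column is `compound_id`, or from a SMILES file
#' routed through a fingerprint adapter function (see
#' [smiles_to_fingerprints()]). When both are supplied the explicit matrix
#' wins.
#'
#' Duplicate (compound, target) rows keep the highest potency and raise a
#' warning. Every compound in the triplet file must resolve to a
#' fingerprint row; an unresolved id is a fatal error reporting the first
#' offending row number.
#'
#' @param triplet_path path to the annotation file (CSV or TSV; the
#'   delimiter is auto-detected from the header unless `sep` is given).
#' @param fingerprint_path path to the dense fingerprint matrix (first
#'   column `compound_id`, remaining columns 0/1 bits).
#' @param smiles_path optional SMILES file (`SMILES<TAB>compound_id` per
#'   line), used only when `fingerprint_path` is missing.
#' @param labels optional explicit label space.
#' @param sep field delimiter; `NULL` auto-detects "," vs tab.
#' @param fingerprint_fun adapter turning a character vector of SMILES into
#'   a binary matrix; defaults to [smiles_to_fingerprints()].
#' @return an [activity_dataset()].
#' @export
read_activity_triplets <- function(triplet_path, fingerprint_path = NULL,
                                   smiles_path = NULL, labels = NULL,
                                   sep = NULL, fingerprint_fun = NULL) {
  tr <- read_delimited(triplet_path, sep)
  need <- c("compound_id", "target_id", "potency")
  if (!all(need %in% names(tr))) {
    stop_tf("triplet file must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(tr) == 0L) stop_tf("no annotations in '%s'", triplet_path)
  tr$compound_id <- as.character(tr$compound_id)
  tr$target_id <- as.character(tr$target_id)
  tr$potency <- as.numeric(tr$potency)

  key <- paste(tr$compound_id, tr$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    warn_tf("%d duplicate (compound, target) rows: keeping highest potency",
            sum(duplicated(key)))
    ord <- order(key, -tr$potency)
    tr <- tr[ord, ][!duplicated(key[ord]), ]
  }

  if (!is.null(fingerprint_path)) {
    fp <- read_fingerprint_matrix(fingerprint_path, sep = sep)
  } else if (!is.null(smiles_path)) {
    fingerprint_fun <- fingerprint_fun %||% smiles_to_fingerprints
    sm <- utils::read.table(smiles_path, sep = "\t", header = FALSE,
                            col.names = c("smiles", "compound_id"),
                            colClasses = "character", quote = "")
    fp <- fingerprint_fun(sm$smiles)
    rownames(fp) <- sm$compound_id
    storage.mode(fp) <- "integer"
  } else {
    stop_tf("supply fingerprint_path or smiles_path")
  }

  unknown <- !(tr$compound_id %in% rownames(fp))
  if (any(unknown)) {
    stop_tf("triplet row %d: compound '%s' has no fingerprint",
            which(unknown)[1L], tr$compound_id[which(unknown)[1L]])
  }

  ids <- unique(tr$compound_id)
  by_cmp <- split(seq_len(nrow(tr)), factor(tr$compound_id, levels = ids))
  label_sets <- lapply(by_cmp, function(i) tr$target_id[i])
  potencies <- lapply(by_cmp, function(i) {
    stats::setNames(tr$potency[i], tr$target_id[i])
  })
  activity_dataset(fp[ids, , drop = FALSE], label_sets, labels = labels,
                   potencies = potencies, compound_ids = ids)
}

read_delimited <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

#' @rdname read_activity_triplets
#' @param path path to the fingerprint matrix file.
#' @export
read_fingerprint_matrix <- function(path, sep = NULL) {
  df <- read_delimited(path, sep)
  if (names(df)[1L] != "compound_id") {
    stop_tf("fingerprint matrix must start with a compound_id column")
  }
  fp <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(fp == 0 | fp == 1)) stop_tf("non-binary fingerprint entry in '%s'", path)
  storage.mode(fp) <- "integer"
  rownames(fp) <- as.character(df$compound_id)
  fp
}

#' Write an activity dataset as triplet + fingerprint files
#'
#' Inverse of [read_activity_triplets()]: writes the annotation triplets
#' (with potencies; pairs lacking a potency are written as NA) and the dense
#' fingerprint matrix. A read of the written pair reproduces compound ids,
#' label sets, fingerprints and potencies exactly.
#'
#' @param d an `activity_dataset`.
#' @param triplet_path,fingerprint_path output paths.
#' @param sep delimiter (default tab).
#' @return invisibly, the two paths.
#' @export
write_activity_dataset <- function(d, triplet_path, fingerprint_path,
                                   sep = "\t") {
  nl <- lengths(d$label_sets)
  cid <- rep(d$compound_ids, nl)
  tid <- unlist(d$label_sets)
  pot <- rep(NA_real_, length(tid))
  if (!is.null(d$potencies)) {
    pot <- unlist(lapply(seq_along(d$label_sets), function(j) {
      p <- d$potencies[[j]]
      if (is.null(p)) rep(NA_real_, nl[j]) else unname(p[d$label_sets[[j]]])
    }))
  }
  utils::write.table(
    data.frame(compound_id = cid, target_id = tid,
               potency = format(pot, digits = 17, trim = TRUE)),
    triplet_path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(compound_id = d$compound_ids, d$fingerprints,
               check.names = FALSE),
    fingerprint_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(c(triplet_path, fingerprint_path))
}

#' Convert SMILES to folded binary fingerprints
#'
#' Adapter hook for structure input. The default implementation uses
#' ChemmineR/ChemmineOB when installed to derive circular-fingerprint-like
#' binary descriptors folded to `nbits`; any function with the same
#' signature can be passed to [read_activity_triplets()] instead (for
#' example an RDKit bridge). Precomputed fingerprint matrices always take
#' precedence, and all shipped fixtures use matrices, so this adapter is a
#' convenience, not a dependency.
#'
#' @param smiles character vector of SMILES strings.
#' @param nbits folded fingerprint length (default 1024).
#' @return binary integer matrix, one row per input SMILES.
#' @export
smiles_to_fingerprints <- function(smiles, nbits = 1024L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_tf(paste("SMILES input needs the ChemmineR + ChemmineOB packages;",
                  "supply a precomputed fingerprint matrix or a custom",
                  "fingerprint_fun instead"))
  }
  sdf <- ChemmineR::smiles2sdf(smiles)
  ap <- ChemmineR::sdf2ap(sdf)
  fp <- ChemmineR::desc2fp(ap, descnames = nbits, type = "matrix")
  storage.mode(fp) <- "integer"
  fp
}
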