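---
title: "Single-label vs multi-label naive Bayes for ligand-based target fishing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-label vs multi-label naive Bayes for ligand-based target fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetfish)
```

## The problem

*Target fishing* asks, for a small molecule described only by its
structure, which protein targets it is likely to be active against.
Many ligands are *promiscuous*: they are annotated active against two
or more targets. A classifier that is forced to pick exactly one
target per compound (the ubiquitous single-label multi-class setup)
throws that information away at training time — a promiscuous training
compound must be collapsed to a single class — and can only ever emit
one target per query. This package implements both modelling choices
over binary molecular fingerprints and the complete protocol for
comparing them, so the question "does multi-label modelling pay off?"
can be answered quantitatively on any activity dataset, or on
synthetic data with known ground truth.

The data model is a bipartite annotation structure: compounds
$j = 1, \dots, N$, each with a fingerprint
$\mathbf{x}_j \in \{0,1\}^m$ (default $m = 1024$, the usual folded
ECFP_4 length), a non-empty label set $Y_j \subseteq L$ over the
target space $L$, and optionally a potency per compound–target pair on
a "larger is more potent" scale such as pIC50.

## The two models

Both models are Bernoulli naive Bayes classifiers: descriptors are
assumed independent given the class, and the class-conditional
probability of bit $i$ being on in class $l$ is estimated with the
Laplace correction

$$p(x_i = 1 \mid l) = \frac{1 + n_{il}^+}{2 + n_l},$$

where $n_{il}^+$ counts the training instances of class $l$ with bit
$i$ set and $n_l$ is the class size. The $+2$ in the denominator
reflects the two outcomes of a binary feature; the estimate is never 0
or 1, so log-likelihoods stay finite even for empty classes. The factor
for an off bit is the complement $1 - p(x_i = 1 \mid l)$ — the model is
a product of Bernoullis, not a product over on-bits only. Class priors
are unsmoothed maximum-likelihood ratios $P(l) = n_l / N$.

**SMM** (single-label multi-class): one parameter block per target,
trained on a single-label dataset. The posterior normalises the joint
likelihood by the evidence summed over all $|L|$ classes, so the
posterior vector sums to one, and the prediction is the arg-max class.
A multi-label training set must first pass through
`reduce_to_single_label()`, which keeps each compound's most potent
target — exactly the information-discarding step the comparison is
about.

**MMM** (multi-label multi-class): the training set is transformed by
*binary relevance* into $|L|$ binary problems $D_l$, each containing
**all** $N$ instances, labelled $l$ vs $\neg l$. Because a promiscuous
compound is a positive instance of every one of its targets, these are
"pseudo one-vs-all" classifiers rather than plain one-vs-all: positives
of different labels overlap. Each label's posterior is a two-term Bayes
ratio with complementary priors $n_l/N$ and $1 - n_l/N$, and the
predicted set is the thresholded union

$$Z = \bigcup_{l \in L} \{\, l : p(l \mid \mathbf{x}) \ge p_{threshold} \,\}.$$

The comparison on a purely single-label training set is a useful
structural check: there the positive blocks of the MMM coincide exactly
with the SMM's class blocks (same counts, same Laplace estimates, same
priors), and the package tests assert this identity.

### Numerical form

With $m = 1024$ bits the literal likelihood products underflow double
precision (a typical log-joint is around $-200$), so all posterior
computation is done in log space: shared-evidence posteriors are a
softmax over log-joints (log-sum-exp) and the binary posterior is a
logistic of the log-likelihood difference. These forms are
algebraically identical to the direct ratios; the test suite verifies
agreement with direct product arithmetic to $10^{-10}$ relative error
on small-$m$ cases where the products are representable.

### Threshold tuning

$p_{threshold}$ is the one free parameter of the MMM. `tune_threshold()`
grid-searches it with seeded, label-stratified $k$-fold
cross-validation (default 5 folds) on a single-label training set. The
objective is not dictated by the prediction rule itself, so it is
selectable; the default is example-based F1, the harmonic mean of the
two metrics the evaluation reports, which balances the recall gain of a
permissive threshold against its precision cost. Ties on the objective
resolve towards the larger (more conservative) threshold. The default
grid is $\{0.5, 0.9, 0.99, 0.995, 0.999, 0.9999\}$ — posteriors of
well-separated binary NB classifiers pile up near 0 and 1, so useful
cutoffs live close to 1; $0.999$ is the conventional choice for this
model family. On the synthetic data below, where class signal is
moderate and the example-based F1 rewards recall, the CV winner is
typically $0.5$; the tuned value is always echoed in the run report.

## The evaluation protocol

Two schemes, matched to the two kinds of test compound:

**Single-label test compounds.** Both models are restricted to their
top-ranked label (`top1_restrict()`; the threshold and $Z$ are
ignored), and per-class precision $TP/(TP+FP)$ and recall
$TP/(TP+FN)$ are computed from the resulting assignment. The summary
is the macro-average over labels (micro selectable); a label that is
never predicted has undefined precision and is excluded from the macro
mean and flagged rather than silently counted as zero. The two models'
paired right/wrong outcomes feed McNemar's test on the discordant
counts — continuity-corrected $\chi^2_1$ by default, with uncorrected
and exact-binomial variants selectable since the literature uses all
three.

**Multi-label test compounds.** Example-based precision and recall
average $|Y \cap Z|/|Z|$ and $|Y \cap Z|/|Y|$ over compounds. An empty
$Z$ contributes zero to the precision mean instead of being dropped —
dropping would quietly change the instance count. For the model
comparison, the ranking protocol disables the threshold (every label is
scored, $|Z| = |L|$), ranks all labels by descending posterior, and
pairs the rank position of every annotated label under one model with
its position under the other, giving $M = \sum_t |Y_t|$ paired
positions; a Wilcoxon signed-rank test on the paired positions decides
whether the rankings differ, and the favoured model is the one that
ranks more of the true labels better.

**The Wilcoxon implementation.** Tied magnitudes get average ranks.
Zero differences — the dominant case here, since most true labels are
ranked identically by both models — are discarded by default (the
classic test); the Pratt variant is selectable. The null distribution
is enumerated exactly by convolution when the effective sample is
$\le 25$ (the test suite checks this against full $2^n$ enumeration and
against `stats::wilcox.test`), and a tie-corrected normal approximation
is used above that. Rank ties from exactly equal posteriors, like all
other ties in the package (potency ties in the single-label reduction,
posterior ties in top-1 assignment), resolve by label-space order:
determinism everywhere is a deliberate design choice, since
"arbitrarily assign" cannot be tested.

## The synthetic-data generator

`generate_dataset()` builds activity datasets with known ground truth
emulating the structure of a large curated bioactivity extract: 308
targets, 65,587 compounds and 1,024-bit sparse fingerprints at full
scale, with a promiscuity distribution of ~83.1% single-label
compounds, ~12.1% with two targets, and a geometrically thinning tail
up to 57 labels. Each class elevates `signal_bits` randomly chosen bits
to `signal_prob` above a sparse `background_prob`; a compound draws its
label-set size from the promiscuity distribution, its labels uniformly,
and its bits from the **per-bit maximum** of its classes' profiles — a
promiscuous compound genuinely resembles all of its targets, which is
precisely the regime where collapsing it to one label loses signal.
Potencies are independent normals on the p-scale (mean 7, sd 1); only
their ordering matters, for the single-label reduction. All randomness
derives from one master seed through named streams (profiles,
membership, bits, potencies), so each component is independently
reproducible and fixtures are byte-stable.

The default signal shape — 16 signal bits per class at on-probability
0.25 over background 0.015 — was chosen to land the classifiers in the
performance regime reported for real fingerprint data of this kind:
top-1 accuracy around 0.75–0.90, roughly 2–3% fingerprint density, and
a majority (but not all) of paired label ranks tied between the two
models. Weaker signal degrades both models towards the prior; much
stronger signal makes every prediction perfect and the comparison
vacuous.

What the generator does **not** emulate: real chemistry (no SMILES, no
correlated substructure bits, no activity cliffs), assay noise or
confidence scores, class-imbalanced promiscuity (every label is equally
likely in a label set, whereas real promiscuity concentrates in
families), and within-family fingerprint correlation. Passing the
directional test on this generator therefore shows that the pipeline
detects a real information advantage of multi-label training when one
exists by construction — not that the advantage holds on any particular
real dataset.

## The study workflow

`run_workflow()` reproduces the full comparative design on any dataset:
a seeded compound-level 70/30 split (never by pair — a promiscuous
compound goes to one side with all its annotations), single-label
reduction of the training half for the SMM, MMM on the full training
half, CV threshold tuning, then both evaluation schemes on the
single-label ($|Y|=1$) and multi-label ($|Y|\ge2$) test partitions,
with McNemar on the former and the paired-rank Wilcoxon on the latter.

```{r workflow, eval = FALSE}
cfg <- generator_config(n_labels = 20, n_compounds = 14000, seed = 1)
res <- run_workflow(sim_config = cfg, seed = 1)
res
```

The package's own test suite runs this study at 20 labels and
14,000 compounds. That scale was picked so the multi-label test
partition carries roughly 2,000 paired label rank positions — enough
for the signed-rank test to have stable power at the effect sizes the
generator produces — while a single run stays in the seconds range;
about 490 training ligands per class also sits inside the 120–720
per-class band that `filter_dataset()` enforces by default on real
extracts. The quick-start fixture (`make_benchmark_fixture("tiny")`)
uses 20 labels and 2,000 compounds for smoke tests, where the ranking
comparison is directionally right but underpowered.

## Degenerate inputs and edge policies

* Empty class in SMM training, or a label positive on every instance in
  MMM training: fatal (the binary problem is degenerate). A label with
  *zero* positives is allowed only with `allow_empty_labels = TRUE`
  (its classifier collapses to the Laplace prior) — needed inside CV
  folds on small classes.
* Empty predicted set $Z$: allowed; the top-ranked label is still
  defined, so top-1 evaluation always applies.
* All paired differences zero: the Wilcoxon result is flagged
  degenerate with $p = 1$ rather than raising, so batch comparisons do
  not abort on a tie-only stratum.
* Duplicate (compound, target) rows on input keep the highest potency
  with a warning; an unknown compound id is fatal with its row number.
* `filter_dataset()` applies potency cutoff, then class-size bounds,
  then orphan removal, exactly once — no fixed-point iteration, so a
  class pushed out of range by another class's removal survives. This
  is documented behaviour, matching how such curation is described for
  the real extracts.

## Limitations

The models inherit naive Bayes' assumptions: bit independence given the
class (false for folded fingerprints, which collide) and
well-calibrated posteriors (binary NB posteriors saturate near 0/1, so
$p_{threshold}$ is a tuning device, not a probability statement). The
binary-relevance transformation ignores label correlations beyond what
shared positives induce; label-powerset and classifier-chain schemes
are out of scope, as are other base learners. The evaluation follows
the protocol it implements — example-based and per-class
recall/precision, top-1 restriction, McNemar, signed-rank — and
deliberately omits Hamming loss, subset accuracy and ROC/PR analyses.
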