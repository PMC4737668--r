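---
title: "Side-view-guided discriminative subgraph mining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Side-view-guided discriminative subgraph mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmsv)
```

## The problem

In case–control neuroimaging studies each subject contributes a brain
connectivity network — nodes are atlas regions (typically 90 cerebral AAL
regions), edges are thresholded functional correlations (fMRI) or structural
connectivity (DTI) — together with a class label and, crucially, hundreds of
auxiliary per-subject measures: neuropsychological scores, flow cytometry,
plasma markers, volumetry, and so on. These measure groups form *side
views*: vector-valued representations of the same subjects, auxiliary to the
primary graph view.

Subgraph-based graph classification represents each graph \(G_j\) by a
binary vector over a set of subgraph patterns, \(x_{ij} = 1\) iff pattern
\(g_i \subseteq G_j\). With only tens of networks, label information alone
is too weak to rank the exponentially many candidate patterns. This package
selects patterns by requiring that the *subgraph-feature geometry agree with
the side views*: subjects similar in a side view should carry similar
subgraph features, dissimilar subjects different ones.

## Side-information consistency

Before the side views are allowed to steer feature selection, their
relevance is testable. For a view with kernel \(\kappa\), collect the
similarities of same-label pairs \(A_s = \{\kappa_{ij} : y_i y_j = 1\}\) and
different-label pairs \(A_d = \{\kappa_{ij} : y_i y_j = -1\}\), draw equally
sized samples from each, and run a one-tailed two-sample t test of
\(H_0: \mu_s - \mu_d \le 0\) against \(H_1: \mu_s - \mu_d > 0\)
(`consistency_test()`).

Three interpretation choices are deliberate and documented here:

* **Pair universe.** Similarities are taken over unordered pairs \(i < j\).
  Diagonal entries are identically 1 under the RBF kernel and would only
  dilute both samples; ordered duplicates would double every observation
  without adding information.
* **Test variant.** Welch's unequal-variance statistic is the default: the
  two pair groups have no a-priori reason to share a variance. A
  pooled-variance mode is available (`var_equal = TRUE`).
* **Sampling.** Equal sample sizes are obtained by drawing
  \(\min(|A_s|, |A_d|)\) elements without replacement, under a caller-seeded
  RNG, so results are reproducible.

The kernel entries entering the test are dependent (pairs share subjects),
but under the null the label assignment is independent of the features, so
the random split of the pair population behaves like a permutation null; the
Monte-Carlo calibration check in the test suite confirms a type-I rate
compatible with the nominal 0.05 under a gap-0 generator.

## The gSide criterion

Each view's features are min-max normalized per column and kernelized,
default RBF with the view's dimensionality \(d\) as bandwidth:
\(\kappa_{ij} = \exp(-\lVert z_i - z_j\rVert_2^2 / d)\).

Pairs are split at the kernel mean \(\mu\) (computed over all \(n^2\)
entries, diagonal included — literal fidelity to the defining formula; the
diagonal provably cannot influence scores, see below). The view's guidance
matrix balances the two groups' mass:

\[
\Theta_{ij} =
\begin{cases}
 1/|H| & \kappa_{ij} \ge \mu \\
 -1/|L| & \kappa_{ij} < \mu
\end{cases}
\]

Ties \(\kappa_{ij} = \mu\) go to the similar group (the \(\ge\) side), as
the defining inequalities state. Labels contribute analogously through
\(\Omega\) with \(+1/|M|\) on same-label ordered pairs and \(-1/|C|\) on
different-label pairs, zero where a label is missing.

With \(\Phi = \Omega + \sum_p \lambda^{(p)} \Theta^{(p)}\),
\(D = \mathrm{diag}(\Phi \mathbf{1})\) and \(L = D - \Phi\), the score of a
pattern with indicator vector \(f\) is the Laplacian quadratic form

\[
q(g) = f^\top L f = \tfrac{1}{2}\sum_{ij} \Phi_{ij} (f_i - f_j)^2 .
\]

Lower is better: a pattern whose presence/absence separates dissimilar
subjects and co-occurs in similar ones scores negative. The view weights
\(\lambda^{(p)}\) default to 1, the convention when every view has passed
the consistency test; they are configurable per view and non-negative.

Two facts worth keeping in mind:

* \(q\) depends on the pattern only through its support set:
  \(q(g) = \sum_{p,q \in \mathcal{G}(g)} L_{pq}\). The implementation uses
  this support-pair sum (\(O(|\mathrm{support}|^2)\) per pattern), which is
  unit-tested to equal the dense quadratic form to 1e-9 relative tolerance.
* Because \(\Phi\) carries negative entries, \(L\) is a **signed**
  Laplacian and need not be positive semi-definite, so \(q \ge 0\) is *not*
  an invariant and is not asserted anywhere. What does hold, and is
  asserted, is the quadratic-form identity above, zero row sums, and the
  invariance of \(q\) under diagonal perturbations of \(\Phi\) (the
  \((f_i - f_i)^2\) terms vanish) — which is also why including the kernel
  diagonal in \(\mu\)'s mean and in \(M\) is harmless.

## The lower bound and branch-and-bound search

Selecting the \(k\) patterns with the smallest \(q\) among all frequent
patterns would require exhaustive enumeration. Pruning rests on truncating
the Laplacian at zero, \(\hat L_{pq} = \min(0, L_{pq})\), and scoring

\[
\hat q(g) = f^\top \hat L f = \sum_{p,q \in \mathcal{G}(g)} \hat L_{pq}.
\]

For any supergraph \(g' \supseteq g\): the support of \(g'\) is contained in
that of \(g\) (anti-monotonicity), \(\hat L \le L\) elementwise, and
removing terms from a sum of non-positive terms can only increase it —
hence \(q(g') \ge \hat q(g)\).

The search (`mine_top_k()`) walks the gSpan DFS-code tree: patterns are
encoded as sequences of edge tuples \((i, j, l_i, l_e, l_j)\), children are
generated by rightmost-path extension, and a pattern is visited only if its
code is the lexicographic minimum over all DFS codes of the graph it
encodes, so every isomorphism class is visited exactly once. Support is
counted incrementally through embedding lists (all embeddings per graph are
kept, so child support is exact); the brute-force isomorphism oracle
(`is_subgraph_isomorphic()`) exists for support verification and tests, and
the miner never calls it.

Search-policy details, all deterministic:

* The top-k container admits a pattern only on **strict** improvement over
  the current worst kept score (or while the container is not yet full).
  Pruning fires when \(\hat q(g) \ge \theta\) with \(\theta\) the worst kept
  score; since every descendant then satisfies \(q \ge \theta\), it could
  not have been admitted under the strict rule either — so pruned and
  unpruned runs keep *identical* patterns and scores, not merely
  equally-scoring ones. This exactness is the core guarantee and is tested
  against a brute-force lattice oracle.
* The visited pattern is scored before its subtree is considered for
  pruning: the bound governs descendants, not the node itself.
* \(\theta\) starts at \(+\infty\) and pruning is inactive until the
  container fills; \(\theta\) is non-increasing afterwards.
* Equal-score ties at eviction keep the pattern with the lexicographically
  smaller minimum DFS code; children are visited in canonical extension
  order (backward before forward, deeper rightmost-path source first, then
  label order). Results are therefore independent of input order.
* Scores being sums of rationals (\(1/|M|\), \(1/|H|\), ...), two patterns
  with *different* supports can tie exactly; any member of such a tied
  class at the k-th position is an optimal selection, and the validation
  suite compares selections up to such ties.

Single-vertex patterns are enumerated and scorable (nothing restricts
patterns to at least one edge; a flag excludes them). `min_sup` is a
fraction of the dataset with threshold \(\lceil \mathrm{min\_sup} \cdot n
\rceil\); an absolute-count override exists. `max_edges` is unbounded by
default — the bound, not size capping, is the intended search control — but
small-scale studies may set it.

## From connectivity matrices to graphs

`read_connectivity_matrix()` accepts square CSV/TSV blocks, symmetrizes by
averaging (with a warning beyond 1e-8 asymmetry), and
`threshold_to_graph()` places an edge where the weight strictly exceeds the
threshold. Strict `>` is a documented convention (switchable to `>=`);
negative weights never become edges (positive correlations are the links);
vertex labels are region indices, so patterns align anatomically across
subjects. Default thresholds follow the field's conventions: 0.9 for fMRI
correlations, 0.3 for DTI after min-max normalization of link weights
(`normalize_link_weights()`). Raising the threshold never adds edges.

## The synthetic-data generator

`generate_dataset()` emulates the shape of a small case–control connectome
study: \(n_\text{pos} + n_\text{neg}\) subjects (default 20 + 20), 90
uniquely-labeled regions, sparse background edges (density 0.05, roughly
what a 0.9 correlation threshold leaves), a planted 3-edge path whose edges
are forced present with probability 0.9 in positives and 0.1 in negatives,
and one 10-dimensional side view whose class means are separated by 3
within-class standard deviations — strong consistency, matching the regime
where every real view passes the consistency test decisively. Background
edges are resampled independently per subject and the planted edges are
OR-ed in afterwards; node labels are unique per graph, so planted-pattern
support is unambiguous. A gap of 0 provides the null generator for
calibration; heterogeneous per-view gaps let one check directionally that
the most label-consistent view contributes most.

For the classification comparison (mined features + views versus views
alone) the harness uses a gap-1 view: at gap 3 the views alone already
classify nearly perfectly and the comparison would be uninformative; at gap
1 the view is informative but unsaturated, so the added value of subgraph
features is visible. This is a design choice of the validation regime, not
a claim about any particular dataset.

What the generator does **not** emulate: spatial correlation structure of
real fMRI connectivity, hub/module organization of connectomes, tractography
count distributions, missing data, or correlated measures within a view.
Passing tests therefore demonstrate correctness of the algorithms under
controlled conditions, not performance on real neuroimaging data.

## Evaluation harness

`feature_matrix()` stacks pattern indicators; `augment_with_views()`
concatenates them with the normalized view columns per subject;
`cross_validate()` runs a stratified 3-fold cross-validation with a
linear-kernel SVM (LibSVM via e1071, regularization at its library default),
reporting accuracy, precision (fraction of positive predictions that are
positive subjects), recall, and F1. Two mining modes exist because the
field's protocols are ambiguous on this point: `cross_validate_end_to_end()`
re-mines patterns and rebuilds the guidance Laplacian inside each training
fold (no test leakage; the honest default for absolute numbers), while
mining once globally and cross-validating the fixed design matrix is
provided for paired model comparisons, where both arms share folds and the
comparison is within-seed. Class balancing, where requested, is seeded
undersampling of the majority class.

## Numerical choices and degenerate inputs

* Score assertions use 1e-9 relative tolerance; pruning compares computed
  doubles with exact `>=` — an epsilon slack could only weaken pruning,
  never correctness, since the true bound lies below.
* A constant kernel (all entries equal) makes \(\Theta\) undefined and is
  an error ("degenerate side view"), as is a single-class label vector for
  \(\Omega\), and a constant off-diagonal weight matrix for link
  normalization.
* Constant feature columns min-max normalize to 0; constant design-matrix
  columns are dropped before the SVM, and with no informative column the
  fold predicts the majority class.
* Empty-support patterns score 0; full-support patterns score 0 because
  Laplacians annihilate constant vectors — both are regression-tested.

## Scale of the validation suite

The test suite exercises the guarantees at sizes where brute force is
feasible and the statistics are stable: oracle-equivalence on 20 datasets of
20 graphs with up to 8 vertices and 10 edges each; recovery and
classification checks on 40-subject, 90-region simulations; 500 null
repetitions for calibration. These sizes are the package's own validation
choices; the miner itself is designed for the tool's intended scale of tens
of networks with ~90 regions.

## Known limitations

* The miner is exact but single-threaded and in-memory; embedding lists
  store all embeddings, which is fine at tens of graphs with unique node
  labels but can grow on dense graphs with heavily repeated labels.
* View weights \(\lambda\) are fixed, not learned; alternating optimization
  of weights and patterns is out of scope.
* The signed Laplacian's indefiniteness means scores have no absolute zero
  point; only comparisons between patterns on the same guidance matrix are
  meaningful.
* Directed graphs, self-loops, multigraphs and weighted-edge isomorphism
  are unsupported by design.
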