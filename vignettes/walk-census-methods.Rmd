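---
title: "Classifying networks by their walk-traceable subgraph census"
author: "walkcensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying networks by their walk-traceable subgraph census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkcensus)
```

## The problem

Structural brain networks (connectomes) built from diffusion tractography
assign one node to each cortical region and one edge to each pair of regions
joined by reconstructed white-matter tracts.  Classical graph statistics —
clustering coefficient, mean geodesic length, transitivity, degree
distribution — often fail to separate clinically distinct groups even when
group differences in wiring exist: the statistics are too coarse.  This
package implements a data-driven alternative: embed every network in a
high-dimensional space of *subgraph walk counts*, reduce the embedding by
principal components analysis, quantify separability with a nested
cross-validated linear support-vector machine, assess significance by label
permutation, and map the classifier back to interpretable subgraph classes
by recursive feature elimination.

The workflow was designed for two-class cohorts of ~100-node binary
connectomes (e.g. neurologically normal vs abnormal outcome), but nothing in
it is specific to brains: any collection of undirected networks with binary
class labels fits.

## The embedding: walk-traceable subgraphs

A *walk of length L* is a vertex sequence $v_0 \dots v_L$ in which
consecutive vertices are adjacent; vertices and edges may repeat, immediate
backtracking is allowed, and a walk and its reversal are distinct sequences.
The set of distinct edges a walk traverses — its *traced subgraph* — is a
connected simple graph with at most $L$ edges.  Grouping all length-$L$
walks of a network by the isomorphism class of their traced subgraph yields
the census vector: one nonnegative integer per class.  At $L = 8$ there are
exactly 149 classes (`build_catalog(8)`), so a cohort of $N$ networks
becomes an $N \times 149$ count matrix.  Walks of length eight can span
large parts of a network whose mean geodesic length is 3–4, which is what
makes the embedding sensitive to mesoscale organisation.

Two conventions had to be fixed for reproducibility and are worth stating:

* **Raw sequence counting.** Every vertex sequence counts once; reversals
  count separately.  Any alternative convention rescales all classes by a
  class-uniform constant and leaves PCA directions, SVM decision boundaries
  and feature rankings unchanged.
* **Exactly L steps.**  "Walks of length eight" is implemented as exactly
  eight steps.  Every class traceable by a shorter walk is also traceable
  by a longer one (pad by stepping back and forth along a covered edge), so
  the class *set* coincides with the "up to eight" reading; the catalogs
  for $L = 1 \dots 8$ are nested, which the test suite asserts.

### Two census algorithms, one answer

`census_walk_counts()` offers two routes:

* **direct** — enumerate every length-$L$ walk and classify its traced edge
  set.  Exponential in $L$ (a 100-node network of mean degree 5.7 has
  $\approx 3 \times 10^8$ length-8 walks), but transparent.  Retained as
  the small-instance oracle.
* **factorized** (default) — for each catalog class $H$, count the distinct
  edge subsets of the network isomorphic to $H$ (compiled backtracking
  monomorphism search divided by $|\mathrm{Aut}(H)|$) and multiply by the
  *covering-walk count* $W_L(H)$: the number of length-$L$ walks inside one
  labeled copy of $H$ that traverse all of its edges, computed once per
  class by dynamic programming over (current vertex, covered-edge subset).

The two routes agree *exactly* — an integer identity, not an approximation —
and the test suite checks this on random graphs, alongside a second
closed-form check: the census entries of any network must sum to
$\sum_{ij} (A^L)_{ij}$, the total walk count.  All counts are integers far
below $2^{53}$, so double-precision storage is exact.

The catalog orders classes by (edge count, vertex count, canonical key), so
column indices are stable across runs and platforms.  Canonical keys come
from canonical graph labeling; the per-subgraph numbering used in other
published figures of this method's literature is implementation-specific and
is deliberately not imitated.

## Classical metrics and the resolution rule

`network_metrics()` implements the standard panel: degree $d_i = \sum_j
A_{ij}$; local clustering $c_i = 2e_i / (d_i(d_i-1))$ averaged over *all*
nodes; mean geodesic $\bar\ell$ over unordered pairs of the giant component;
transitivity $T = 3t/q$ with $t$ the triangle count and $q$ the two-path
count; and the degree survival function $P(d > d_0)$.  Conventions the
definitions leave open were fixed as follows: nodes of degree $< 2$
contribute $c_i = 0$ (the dominant convention, since the mean is over all
$n$ nodes); geodesics are always computed on the giant component, so the
quantity survives thresholding-induced disconnection; ties among
equally-sized components resolve to the one containing the smallest node
index.

`select_resolution()` encodes the rule for choosing the number of nodes
when a family of parcellations is available: take the largest $n$ whose
network is still fully connected ($n_G = n$, with $n_G$ the giant-component
size).  For a cohort, `select_resolution_cohort()` requires the constraint
for *every* subject simultaneously, which is how a single shared $n$ is
fixed; per-subject selection is also exposed because the cohort-level
reading is a design choice, not a mathematical necessity.

## Classification

The embedding (or its leading principal components) feeds a linear
soft-margin SVM minimising $\tfrac12\|w\|^2 + C\sum_i \xi_i$ (hinge slack
$\xi_i$, cost $C$).  The convex dual is solved by LIBSVM; the package never
re-derives $w$ by hand.  Generalization accuracy is estimated by **nested
cross-validation**: an outer loop of repeated stratified 2-fold splits
measures held-out accuracy, and an inner leave-one-out loop on each
training half picks $C$ from a grid ($\{0.01, 0.1, 1, 10, 50, 100\}$ by
default, ties to the smaller $C$ — the stronger regulariser).  The mean and
standard error are reported across the outer repeats (default 50); the
repeat count is a knob because the ±SE of a 2-fold estimate on two dozen
subjects is dominated by split-to-split variance.

Significance comes from a **permutation test**: the labels are shuffled
`n_perm` times and the entire nested CV is rerun per shuffle, giving a null
distribution of test errors; the p-value uses the add-one convention
$p = (1 + \#\{e_{\mathrm{null}} \le e_{\mathrm{obs}}\}) / (n_{\mathrm{perm}} + 1)$,
which is valid at any `n_perm` and can never return 0.

### A note on numerical conditioning

Walk counts are large (a 100-node network has $\sim 10^5$ length-4 walks),
so PC scores reach magnitudes of $10^4$ and the LIBSVM dual solver hits its
iteration cap.  Every SVM entry point therefore divides its training matrix
by a *single global factor* — the pooled standard deviation of all entries —
before solving, and `C` is defined relative to that conditioned scale.
Because the factor is shared by every column this is not per-feature
standardization: relative feature geometry, the $w_i^2$ elimination ranking
and all accuracies are unaffected, while the solver operates on
$O(1)$ numbers.  Per-feature standardization of raw counts, when wanted,
should be applied by the caller before `nested_cv()`.

## Discriminative features

Three selection strategies are provided, all ending in a feature set that
`evaluate_feature_set()` re-scores end-to-end:

* **RFE-raw** — recursive feature elimination on raw census columns:
  repeatedly fit the linear SVM (fixed $C = 50$, the value this method's
  literature reports for the elimination stage), score features by $w_i^2$
  (the first-order change in the margin cost from deleting feature $i$),
  drop the lowest scorer (step 1 by default; score ties drop the
  higher-index column so the procedure is deterministic), until `n_keep`
  remain.
* **RFE-pca** — the same elimination run in PC-score space, each surviving
  component mapped to one subgraph by the **B4 rule**: the feature with the
  largest absolute loading (ties to the lowest index).  Two components may
  map to the same subgraph; duplicates are reported as-is.
* **topPCA** — take the $k$ highest-eigenvalue components and apply B4.
  Included as the variance-driven baseline; nothing guarantees top-variance
  components are discriminative.

Group-level effect direction is displayed with **standard scores**: each
feature is z-scored across the pooled cohort (pooled mean, $n-1$ SD;
constant features get 0) and the z-scores are averaged within class, so
balanced classes deviate symmetrically about zero.

PCA itself uses the covariance matrix with $1/(N-1)$ normalisation
(downstream results are invariant to the divisor), clips sub-machine-epsilon
negative eigenvalues to zero, and fixes each eigenvector's sign by making
its largest-magnitude loading positive.  The scree heuristic
(`scree_cutoff()`: the index of the largest consecutive eigenvalue ratio) is
only ever a reported suggestion — classification takes the component count
explicitly, and `run_pipeline()` reports the full accuracy-vs-$p$ curve
because no single $p$ is canonical.

## The synthetic cohort generator

Real DTI cohorts of this kind are small and rarely shareable, so the
package ships a generator that plants the hypothesised class contrast into
otherwise matched random networks:

* **Base graph**: connected Erdős–Rényi $G(n, m)$ at the target mean degree
  (default 5.7 on 100 nodes, the published cohort's value), with a repair
  pass that bridges components; planting only ever adds edges, so every
  network is connected by construction.
* **Class +1 modules** ("normal-like"): three triangles sharing one edge —
  overlapping 3-cycles, the motif family enriched in the normal-outcome
  group.
* **Class −1 modules** ("abnormal-like"): a degree-4–6 hub with a pendant
  chain and one 4-cycle through the hub, cycles not sharing edges.
* Both module types add the same number of edges (7), and the base density
  is lowered to compensate, so the classes stay density-matched and any
  separability is topological — mirroring the real cohort, whose classical
  metrics were statistically indistinguishable between groups.
* `effect_size` counts modules per network; 0 gives two exchangeable
  classes (the null), and `planted_class_keys()` names the catalog classes
  the modules target (triangle, paw, diamond, 4-cycle, as available at the
  chosen walk length).

What the generator does **not** emulate: spatial embedding.  Real cortical
networks connect mostly nearby regions, which lengthens geodesics (3–4 in
the published cohort) and raises clustering (~0.33).  An ER-like base at
mean degree 5.7 concentrates near $\ln 100 / \ln 5.7 \approx 2.8$ and
clustering near the edge density.  The generator's validation band for the
geodesic is therefore 2.5–4.5, and passing tests certify the *pipeline* —
detection of planted differences at matched density, correct null
behaviour — not the anatomical realism of the graphs.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: censuses
against exhaustive walk enumeration and the $\sum (A^L)$ closed form; PCA
against the algebraic contracts (orthonormality, variance conservation,
exact reconstruction, all at $10^{-8}$) and `prcomp`; the SVM against
closed-form separators; metrics against hand-counted small graphs and the
$G(n,p)$ expectation; the resolution rule and feature selection against
planted ground truth.  End-to-end calibration uses, as the package's own
choice of problem size: 50 independent null cohorts (12+12 subjects, 100
nodes, census at $L = 4$, 200 permutations each, one outer repeat per
nested CV) for the chance-level and p-uniformity checks, and effect
cohorts of 10 planted modules for the power and recovery checks (feature
recovery at $L = 5$, where the 15-class catalog makes a top-10 selection
meaningful).  Cross-cohort means are compared to 0.5 rather than a single
cohort's accuracy, because small-sample cross-validation has a
dataset-conditional bias even under the null.

## Known limitations

* The full $L = 8$ factorized census of a 100-node, mean-degree-6 network
  takes on the order of 20 s per network (dominated by path-like classes
  with $\sim 10^7$ instances); cohort embedding at $L = 8$ is minutes, not
  seconds.
* Directed networks, self-loops, weighted walk kernels and motif
  significance testing against configuration-model nulls are out of scope.
* Catalog construction is limited to $L \le 10$; the abstract-walk state
  space grows quickly beyond that, and no published use of the method goes
  further.
* The subgraph numbering of the original implementation cannot be
  reconstructed from the literature; rankings are reported by canonical
  key instead.
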