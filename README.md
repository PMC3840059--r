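# walkcensus

Data-driven classification of undirected networks by their
**walk-traceable subgraph census** — built for structural brain connectomes
(tractography-derived networks of ~100 cortical regions), usable for any
two-class cohort of binary or weighted networks.

Classical graph statistics — mean degree, clustering coefficient `C̄`, mean
geodesic length `ℓ̄`, transitivity `T = 3t/q` — often cannot separate
clinically distinct groups whose wiring nevertheless differs.  This package
implements the data-driven alternative:

1. **Embed.** Count, for every isomorphism class of subgraph traceable by a
   walk of length `L`, the number of length-`L` walks in the network tracing
   that class.  At `L = 8` there are exactly **149 classes**, so a cohort of
   `N` networks becomes an `N × 149` count matrix `X`.  The census is
   computed in factorized form — (subgraph instances) × (covering-walk count
   `W_L(H)`, by dynamic programming over covered-edge subsets) — with a
   compiled monomorphism counter, and verified against direct walk
   enumeration and the closed-form total `Σ_ij (A^L)_ij`.
2. **Reduce.** PCA of the zero-meaned `X` (`Y = Z U_p`), with a scree
   suggestion but an explicit, reported accuracy-vs-`p` curve.
3. **Classify.** Linear soft-margin SVM (`min ½|w|² + C Σ ξ_i`), nested
   cross-validation: leave-one-out inner loop selects `C`, repeated
   stratified 2-fold outer loop estimates generalization accuracy ± SE.
4. **Test.** Label-permutation null distribution of test errors;
   add-one p-value.
5. **Interpret.** SVM-based recursive feature elimination (scores `w_i²`,
   `C = 50`), PC-space RFE and top-eigenvalue selection with the B4
   PC→subgraph mapping, and per-class standard scores.

Also included: the giant-component rule for choosing network resolution
(largest parcellation with `n_G = n`), threshold-sweep robustness analysis
for weighted networks, readers/writers for adjacency-matrix, edge-list and
GraphML formats, and a synthetic generator that plants
overlapping-cycle vs hub-with-nonoverlapping-cycle motif differences into
density-matched random cohorts.

## Worked example

A synthetic cohort of 12 + 12 connected 100-node networks at mean degree
5.7, class `+1` enriched in overlapping triangles, class `-1` in hubs with
non-overlapping cycles (8 planted modules each), analysed at walk length 4:

```r
library(walkcensus)

coh <- generate_cohort(n_per_class = 12, n_nodes = 100, effect_size = 8, seed = 42)
rep <- run_pipeline(coh$networks, coh$labels, walk_length = 4, p_grid = 1:5,
                    repeats = 20, n_perm = 200, n_keep = 3, seed = 1)
```

The report shows the two classes are indistinguishable by density
(mean degree 5.67 vs 5.67) but cleanly separated in census space:

```
  p  accuracy         se
1 1 0.4520833 0.02551999
2 2 0.8812500 0.01918358
3 3 0.9729167 0.01717296
4 4 0.9750000 0.01493162
5 5 0.9770833 0.01367804

accuracy 0.977 +/- 0.014 (error 0.023), permutation p = 0.004975
```

The accuracy curve is nested-CV accuracy against the number of principal
components `p`; with 200 permutations the smallest attainable p-value is
1/201 ≈ 0.005, so the observed error beat every permuted cohort.  RFE
ranks the paw (triangle + pendant edge), the 3-star and the triangle as
most discriminative, with group standard scores deviating symmetrically:

```
top subgraphs: 4:1-4,2-3,2-4,3-4  4:1-4,2-4,3-4  3:1-2,1-3,2-3
   4:1-4,2-3,2-4,3-4 4:1-4,2-4,3-4 3:1-2,1-3,2-3
-1            -0.734        -0.182        -0.841
1              0.734         0.182         0.841

top-3 subset accuracy 0.929 +/- 0.016
```

Column names are canonical keys, `"<vertices>:<canonical edge list>"` —
`3:1-2,1-3,2-3` is the triangle.  Classifying on just those three census
columns retains 0.93 accuracy: the planted contrast lives in a handful of
interpretable subgraph classes, which is the point of the method.

A command-line front end for every stage (catalog / census / simulate /
select-n / classify / rfe / run) is installed at
`system.file("cli", "walkcensus.R", package = "walkcensus")`.

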