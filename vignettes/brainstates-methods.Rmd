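---
title: "Brain-state classification: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state classification: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI, summarized as time courses over a fixed cortical
parcellation (here 400 parcels assigned to the seven canonical networks
VIS, SMN, DAN, VAN, LIM, FPN, DMN), carries enough information to separate
a baseline brain state from an atypical one — sleep, sedation, a
psychedelic state, or a neuropsychiatric condition — within the same
subjects. This package implements that analysis as a reusable,
fully tested pipeline: 324 features per scan across five families, linear
max-margin classification under repeated nested cross-validation, three
ensemble strategies, cross-condition transfer, and coefficient-based
feature importance. Because the clinical datasets themselves are not
distributable, the package also includes a synthetic cohort generator with
planted, named effects, so every stage can be validated against a known
ground truth.

## The feature model

Each scan (a T × P matrix of z-scored parcel time courses) yields:

* **Connectivity features (58 × 2).** Pearson correlation between every
  pair of parcels; mean and population SD of the off-diagonal entries over
  29 scopes (whole brain, 7 within-network, 21 between-network pairs),
  computed once per unordered pair with the diagonal excluded. Raw r
  enters the statistics (no Fisher transform). Computed on both the
  original ("noGSR") and global-signal-regressed ("GSR") time courses;
  the GSR regressor is the unweighted cross-parcel mean, removed by OLS
  with re-standardization.
* **Graph features (74 × 2).** The connectivity matrix is binarized at
  10% edge density (one global cutoff over all pairs, signed values,
  deterministic index-order tie-breaks). On the resulting whole-brain
  graph and on each network's own re-binarized submatrix we compute:
  global efficiency (mean inverse BFS geodesic; 29 whole-brain-level
  scope means + 7 intra-network efficiencies), binary clustering
  coefficients (8 + 7), Newman modularity (8), and participation
  coefficients (8 + 7) using the deterministic leading-eigenvector
  communities of the same graph.
* **Gradient features (60).** From the GSR matrix only: Fisher z,
  row-wise sparsification keeping the top 10% of entries per row (weights
  retained, not binarized — an all-binary profile would make the cosine
  affinity degenerate), normalized-angle cosine affinity, diffusion-map
  embedding (α = 0.5, multiscale λ/(1−λ) weighting, 3 components),
  Procrustes alignment to a reference, then 24 range, 8 dispersion,
  7 eccentricity and 21 between-network centroid distance features.
  Dispersion is a *sum* (not mean) of squared distances to the scope
  centroid, so it satisfies the exact decomposition
  `disp(WB) = Σ_net [disp(net) + n_net · ecc(net)]`, which the tests
  assert to 1e-8.

The canonical order of the 324 features (`feature_names()`) is fixed and
platform-independent: conn_noGSR, conn_GSR, graph_noGSR, graph_GSR,
gradient.

### The alignment reference

When no external template is supplied, the reference embedding is built
from the cohort's baseline scans: start from the first baseline embedding,
align all baseline embeddings to it, average, and iterate the
align-and-average step twice. Any user-supplied P × 3 matrix can be
passed to `extract_features(gradient_ref = ...)` instead; per-scan
features are invariant to a global rotation applied jointly to embeddings
and reference, since alignment absorbs it.

## The classifier

`brainstate_cv()` trains a linear soft-margin SVM
(min ½‖β‖² + C Σ hinge) per feature family, with the kernel scale
implemented as feature division before the linear kernel. Nested
cross-validation is subject-grouped: outer 10-fold over subjects (a
subject's paired scans never straddle train/test), per-fold
standardization learned on the outer training set only, and an inner
3-fold grid search minimizing mean hinge loss over
C ∈ {10⁻⁶…10³} × scale ∈ {10⁻⁴…10²} (powers of ten; ties break toward
smaller C, then smaller scale). The winning pair is refit on the full
outer training set and scored on the held-out fold; everything repeats
`n_repeats` times with re-randomized partitions from one seeded stream.
For a linear kernel, grid points with equal effective cost C/scale² have
identical decision functions, so the search fits each distinct effective
cost once per fold — a pure computational shortcut with no effect on the
selection.

Three ensembles share the identical fold partitions: feature integration
(one SVM on all 324 features), hard voting (majority of the five base
sign predictions) and soft voting (sum of the five base scores).

## Evaluation

Balanced accuracy = ½(sensitivity + specificity), with the decision
threshold searched over 201 evenly spaced points in [−1, 1] plus all
midpoints of adjacent sorted scores; soft-voting sums are divided by the
number of base models first so they live on the base-score scale. AUC is
the rank-based Mann–Whitney statistic with half-weight ties.

Optimizing the threshold on the evaluation scores (the default,
matching the original procedure) is optimistically biased on small
samples; we quantified roughly +0.09 at 40 pooled null scores. The
headline aggregation therefore pools outer-test scores within each
repetition (rather than per fold, where the bias is much larger) and
averages over repetitions; per-fold metrics are stored alongside, and
`threshold = "fixed"` switches to an unbiased fixed threshold of zero.

Cross-condition transfer scores every fold-model set of the training
condition (soft voting over its five base models, using the training
scalers) on all scans of the test condition; cells are means over
fold-model sets and diagonal cells reuse the within-condition nested-CV
results. Feature importance is the per-model sum-normalized |β| of the
integration models, averaged entrywise; sum-normalization makes models
with different margins commensurable.

## The synthetic generator

`simulate_scan()` draws parcel signals from a factor model:

```
x_p(t) = global_amp · g(t) + net_amp[net(p)] · u_net(p)(t) + noise_sd · ε_p(t)
```

with g, ε white standard normal and the seven network factors u jointly
normal with correlation matrix `coupling` (validated symmetric, unit
diagonal, positive semidefinite). Columns are z-scored, emulating
preprocessed band-limited BOLD. The model-implied correlation is available
in closed form (`implied_correlation()`) and the generator matches it to
< 0.03 mean absolute error at T = 10,000. Every feature family responds
to at least one parameter: `global_amp` moves whole-brain mean FC (and is
removed by GSR), `coupling` moves specific between-network blocks (and
graph/gradient geometry downstream), `net_amp` moves within-network
statistics.

`simulate_condition()` builds paired cohorts: each subject contributes one
baseline and one atypical scan, with multiplicative log-normal jitter
(sdlog 0.1) on the amplitudes shared between a subject's two scans. The
jitter models between-subject variability without breaking positive
semidefiniteness; whether real paired scans share further nuisance
structure is unknowable from summary data, and sharing it is the
conservative choice for a paired design. Defaults (global_amp 0.4,
net_amp 0.6, coupling 0.1, noise_sd 1) give realistic resting-state
correlation levels (within-network r ≈ 0.3, between-network r ≈ 0.15).

What the generator does **not** emulate: temporal autocorrelation (the
features are invariant to time ordering), hemodynamics, motion artifacts,
scanner/site effects, and spatial autocorrelation within networks beyond
the shared factor. Passing recovery tests therefore demonstrates the
pipeline's correctness and sensitivity under the assumed covariance
structure, not performance on real clinical data.

## Study conditions used by the test suite

Calibration and recovery runs use 100 parcels
(15, 15, 14, 14, 14, 14, 14), 10 repetitions of the 10 × 3 nested CV, a
null cohort (baseline ≡ atypical, n = 20, T = 200) and a planted cohort
(VIS–SMN coupling +0.4, n = 40, T = 300), with an oppositely planted
condition (−0.4) for transfer. Expected behavior: null soft-voting
balanced accuracy in [0.40, 0.60]; planted soft-voting ≥ 0.85; transfer
AUC onto the opposite condition < 0.5; the planted features
(`conn_*:mean:VIS-SMN`) at the top of the importance ranking. Unit tests
use smaller ad-hoc sizes because they exercise individual operations, not
study conditions.

## Numerical conventions and edge cases

* Binarization keeps `round(density · P(P−1)/2)` edges (R's round-half-
  to-even); a density yielding zero edges is an error, so network
  submatrices need ≥ 4 parcels at the default density.
* Nodes of degree < 2 have clustering 0; isolated nodes have
  participation 0; unreachable pairs contribute inverse distance 0.
* Community detection is fully deterministic: dense symmetric
  eigendecomposition, zero eigenvector entries join the nonnegative side,
  Kernighan–Lin refinement breaks ties by node index.
* Correlations are clipped to |r| ≤ 1 − 1e-7 before Fisher z so duplicate
  parcels cannot produce infinite weights.
* Features with zero training variance have their SD clamped to 1 during
  standardization (they map to 0 and are flagged).
* Degenerate inputs error early and name the offending parcel, network or
  graph: constant time courses, all-identical parcels under GSR, non-PSD
  coupling, edgeless graphs, zero connectivity profiles, disconnected
  affinity graphs.

## Known limitations

* The leading-eigenvector community detection with KL refinement is a
  good deterministic heuristic, not an exact modularity optimizer; tests
  assert exact optimality only on fixtures where exhaustive search is
  feasible.
* Threshold-on-test balanced accuracy is biased upward at small n (see
  above); use `threshold = "fixed"` for unbiased estimates.
* Intra-network participation uses each subgraph's own communities
  (mirroring the "intra" naming); whole-brain communities restricted to
  the subgraph are a defensible alternative.
* Gradient features use the GSR variant only; sum-based dispersion scales
  with network size.
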