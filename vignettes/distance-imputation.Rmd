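---
title: "Imputing phylogenetic distance matrices with regression forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing phylogenetic distance matrices with regression forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylimp)
```

## The problem and the model

A pairwise evolutionary distance matrix is the input to every
distance-based tree method, but alignments with non-overlapping missing
regions leave individual cells uncomputable. phylimp treats each column of
the matrix as a regression target: the distances from OTU *c* to everything
else are predicted from the distances of the *other* OTUs to everything
else, using the rows where column *c* is observed as training data. This is
the iterative chained-regression idea behind missForest-style imputation,
specialised to the structure of a distance matrix — symmetry, zero
diagonal, nonnegativity, and the fact that a good matrix should be close to
*some* tree.

One imputation iteration is:

1. visit the incompletely observed columns in ascending order of missing
   count (ties to the lowest index);
2. for column *c*, fit a regression forest on `X_obs` (the other columns at
   rows where *c* is observed) and `y_obs` (the observed entries of *c*),
   predict the missing entries, and write them back immediately so later
   columns see the update;
3. symmetrise the resulting (asymmetric) matrix, by default via the
   *split-matrix* step: three symmetric candidates — mirrored lower
   triangle, mirrored upper triangle, elementwise mean — are each given a
   neighbor-joining tree, and the candidate minimising the least-squares
   discrepancy to its own tree's patristic distances,
   \(S=\sum_{i\neq j}(\delta_{ij}-\theta_{ij})^2\), wins;
4. compute the stop-criterion error; continue while it strictly improves
   and return the previous matrix once it does not.

Observed values are re-asserted from the input after every iteration; the
imputer never changes them.

### The forest

The trees are CART-style regression trees: at each node a random subset of
features is drawn, candidate thresholds are midpoints of consecutive
distinct sorted values, and the split minimising the sum of squared
residuals subject to the leaf-size floor is taken. Two details are
specific to this setting:

* **Tie-breaking.** With few, coarse distance values, distinct features
  regularly produce identical SSR (ties are detected at relative tolerance
  1e-9; exact floating-point ties are too rare for the mechanism to matter
  otherwise). The default resolves ties uniformly at random; the
  alternative ranks the tied feature-OTUs by the target OTU's Q-matrix
  priority list, computed once from the initial-guess matrix — phylogenetic
  affinity as a prior over predictors. The priority table is not refreshed
  across iterations: it is defined by the initialisation, and refreshing it
  would make tie-break behaviour depend on the iteration path.
* **Fraction resolution.** The leaf, depth, feature and bootstrap-size
  hyperparameters are fractions of the data dimensions, resolved as
  `max(1, ceiling(fraction * n))`. Ceiling-with-floor keeps every resolved
  count at least 1 on small matrices; a depth fraction of 1 therefore
  resolves to the dataset size, which for these problem sizes is
  effectively unlimited.

Leaf predictions are means of their training targets and forest predictions
are means over trees, so every imputed value lies within the observed range
of its column — nonnegativity comes for free.

### Tunable parameters

| parameter | default (non-bootstrap / bootstrap) | meaning |
|---|---|---|
| `n_trees` | 30 / 50 | trees per forest |
| `bootstrap` | off / on | with-replacement row resampling per tree |
| `bootstrap_size` | — / 1.0 | resample size as a fraction of rows |
| `max_features` | 0.25 / 1.0 | features drawn per node |
| `max_depth` | 1.0 (≈ unlimited) | depth bound as a fraction of rows |
| `min_leaf` | 0.01 / 0.13 | leaf-size floor as a fraction of rows |
| `tiebreak` | random | SSR tie policy (`q_priority` optional) |

All distances are in substitutions/site. The two profiles are the
configurations found to work best on real data; `forest_profile()` returns
either. Strategy switches live in `imputation_config()`: candidate
strategy (`split_three`, or plain symmetrisation per column / per
iteration), selector (`ls`, `me`, `set_difference`) and stop criterion
(`ls`, `set_difference`). The default combination — split-matrix, LS
selector, random tie-break, LS stop — is the recommended profile.

### Stop criteria and numerical choices

The `set_difference` stop rule is the classic convergence test
\(\sum(X_{new}-X_{old})^2 / \sum X_{new}^2\) between consecutive matrices.
The `ls` rule scores each iteration's matrix against its *own* NJ tree:
iteration stops when the matrix stops getting closer to tree-likeness.
A self-referential score is used deliberately — the point of stopping "when
the matrix gets phylogenetically worse" is a per-matrix quality measure,
not a between-matrix distance. The first iteration is always accepted (the
incoming error is infinite), so at least two imputation passes run; a
`max_iterations` cap (default 50) guards against floating-point
oscillation, returning the best-so-far with a warning flag.

NJ pair ties and negative branch lengths are left to the standard
agglomeration: negatives are kept as computed, because clamping them would
silently change every least-squares and patristic score downstream.
Degenerate inputs fail early with specific errors: columns with no
observed off-diagonal entry (no mean to guess), all-zero reference
matrices (normalised difference undefined), fewer than 4 OTUs (no
nontrivial bipartitions to compare).

## What the synthetic generator emulates — and what it does not

`make_instance()` draws a topology uniformly over unrooted bifurcating
shapes, assigns i.i.d. positive branch lengths (uniform on 0.1–1 by
default, roughly the range of divergences where distance methods are
informative), takes patristic distances as the complete matrix, and masks a
chosen fraction of unordered pairs uniformly at random — both cells of a
pair, mirroring how a missing distance arises from non-overlapping
sequence regions. The masked-pair count uses `floor(fraction × N(N−1)/2)`,
never exceeding the requested percentage, and masks always leave every
column at least one observed entry. Optional multiplicative lognormal
noise (unit mean, chosen coefficient of variation) perturbs pairs away
from additivity while keeping distances positive; additive Gaussian noise
was rejected because it can produce negative distances.

Noise-free instances are exactly additive, so NJ recovery is guaranteed on
the complete matrix — which is what makes them a clean oracle: any
topological error after masking is attributable to the imputation. Real
matrices are *not* additive, their estimation errors are correlated with
divergence, and their missingness is not uniform; passing the synthetic
suite therefore demonstrates the machinery recovers recoverable signal,
not that real-data NRF will match the synthetic numbers.

## Problem sizes used in the shipped studies

The test and acceptance studies run at 5–12 OTUs with 20 seeded replicates
per condition and missing fractions of 5/20/40%, and the benchmark-trend
study uses 10 OTUs with reduced mask counts — sizes chosen so the full
suite re-runs in minutes on one core while keeping every contract
(observed-value preservation, symmetry, termination, determinism,
baseline dominance, degradation trend) statistically meaningful. The
benchmark runner itself defaults to the full protocol — percentages 5–60%
by 5, 10 masks per percentage, 5 runs per mask, masks shared across
profiles so comparisons are paired.

```{r, eval = FALSE}
inst <- make_instance(n = 10, missing_fraction = 0, seed = 1)
spec <- benchmark_spec(inst$full_matrix, percentages = c(5, 20, 40),
                       masks_per_pct = 2, runs_per_mask = 1,
                       profiles = list(rf = imputation_config(),
                                       baseline = "baseline"))
run_benchmark(spec)
```

## Known limitations

* Runtime grows steeply with N (forests per column per iteration); the
  profiles here target matrices up to a few hundred OTUs, and no
  parallelism is attempted.
* Imputed values cannot leave the observed range of their column — a
  missing distance larger than everything observed in its column will be
  underestimated.
* The LS candidate selector needs one NJ build per candidate per
  iteration, the dominant cost at small N.
* Only the distance matrix is consumed; methods operating at the alignment
  level can exploit signal this framework never sees.
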