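---
title: "Prioritizing disease lncRNAs on a multi-layer composite network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease lncRNAs on a multi-layer composite network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprior)
```

## The model

`lncprior` scores candidate lncRNAs for a disease phenotype by a random
walk with restart (RWR) on a composite network with three node layers —
coding genes, disease phenotypes, lncRNAs — and six weighted association
blocks: three intra-layer (`W_G`, `W_P`, `W_L`; symmetric, zero diagonal)
and three cross-layer (`W_GP`, `W_GL`, `W_PL`). The weighting convention is
that experimentally validated associations carry weight 1 and
computationally predicted ones carry their correlation coefficient, so all
weights live in (0, 1].

The walker's one-step behaviour is encoded in a row-stochastic transition
matrix `M` with the corresponding 3×3 block structure. For a node `i` in
layer A with potential bridge layers B and C (jump parameters `jB`, `jC`
drawn from `x` for gene↔phenotype, `y` for gene↔lncRNA, `z` for
phenotype↔lncRNA):

* every bridge block row with at least one edge receives total mass equal
  to its jump parameter, spread proportionally to edge weights;
* the intra-layer row, if nonzero, receives the remaining mass
  (`1`, `1 - jB`, `1 - jC`, or `1 - jB - jC`, depending on which bridges
  are present), spread proportionally to `W_A`;
* a row left with positive but sub-unit mass — a node with bridges but no
  intra-layer edges, say — is rescaled to sum exactly 1.

The rescaling step deserves a word: the conditional per-block allocation
alone leaves such rows sub-stochastic (a phenotype with only cross-layer
links would emit `x + z < 1` of mass), which would slowly leak walker
probability. Rescaling preserves the proportional structure among the
blocks while restoring a proper Markov kernel; the alternative behaviour is
retained behind `build_transition(..., rescale = FALSE)` for sensitivity
checks. Edge-free nodes keep an all-zero row and are tracked as *dangling*:
their mass is recovered only through the restart term, so stationary scores
may sum to slightly less than 1 when dangling nodes exist. Ranking is
unaffected. Note that with a jump parameter set to 0, a node whose only
edges cross that bridge behaves like a dangling node — the walker cannot
move anywhere from it.

A query is a seed set: the phenotype of interest `S^P`, its known disease
genes `S^G` and known disease lncRNAs `S^L`. Within each layer the seeds
share that layer's probability uniformly, and the layers are mixed with
weights `alpha` (genes), `beta` (phenotypes), `1 - alpha - beta` (lncRNAs).
When a layer has no seeds its weight is redistributed *proportionally* over
the nonempty layers — this choice (rather than, say, dropping the mass)
keeps the initial vector a probability distribution and supports queries
for diseases with no known lncRNA at all. Propagation iterates

$$p^{t+1} = (1-\delta)\,M^{\top}p^{t} + \delta\,p^{0}$$

until the L1 norm of successive iterates falls below `tol`. We deliberately
measure convergence on *successive* iterates: a criterion comparing `p^t`
to `p^0` can never reach 1e-10 unless the restart probability is 1.
Candidates are ranked by the lncRNA components of the stationary vector,
with exact ties broken by lexicographic id so results are reproducible to
the bit.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `delta` | restart probability per step | 0.7 | high restart keeps scores local to the seeds |
| `x`, `y`, `z` | jump mass between layer pairs | 1/3 | must satisfy pairwise sums ≤ 1 so intra-layer mass is never negative |
| `alpha`, `beta` | seed mix of gene / phenotype layers | 1/3 | lncRNA layer gets `1 - alpha - beta` |
| `tol` | L1 convergence tolerance | 1e-10 | with `delta = 0.7` the iteration contracts by ≥ 0.7 per step, so convergence takes a few dozen iterations |
| `max_iter` | iteration cap | 10000 | exceeding it raises an error reporting the last residual |

The defaults are the balanced setting in which every layer and every bridge
is treated equally; the cross-validation AUC on the built-in benchmark
moves by less than 0.03 across a `delta` sweep from 0.3 to 0.9
(`parameter_sweep()`), so conclusions are not sensitive to them.

A closed-form oracle, `closed_form_stationary()`, solves
$p = \delta\,(I - (1-\delta)M^{\top})^{-1} p^{0}$ densely and is used
throughout the test suite to verify the iterative engine; it refuses
networks above 2000 nodes, where a dense solve stops being sensible.

## Network construction rules

Edge lists are merged per block with `merge_edge_evidence()`: experimental
evidence (weight 1) beats predicted, and among equal evidence the maximum
weight is kept. If an intra-layer pair is reported in both orientations
with different weights, the maximum wins — the intra-layer networks are
undirected and this is the most conservative symmetric completion.

Two construction helpers mirror common preprocessing of the real data
sources:

* `top_k_phenotype_edges()` sparsifies a dense phenotype-similarity table
  to each phenotype's `k` most similar neighbours (`k = 5` is the
  conventional choice for text-mined phenotype similarity). Symmetrization
  is by *union*: an edge survives if either endpoint selects it. Union is
  the right choice for a similarity graph feeding a random walk — an
  intersection rule would disconnect low-degree phenotypes entirely.
* `coexpression_edges()` turns an FPKM-like expression matrix into
  predicted edges by pairwise Pearson correlation. The default policy takes
  `|r| >= 0.6` with weight `|r|`; 0.6 is a conventional co-expression
  cutoff and is configurable, as is a `signed_positive` policy for users
  who consider anti-correlation evidence of nothing. Constant profiles are
  skipped with a warning rather than an error, since all-zero rows are
  routine in expression data. The threshold-0 corner (all variable pairs)
  is permitted for diagnostic use, with exactly-zero correlations dropped
  because a zero weight is not a representable edge.

Node ids must be unique within and across layers; the builder rejects an
id used in two layers instead of guessing. Isolated nodes are legal —
candidate lncRNAs with no associations simply rank last, receiving score
only through bookkeeping of the restart.

## Cross-validation design

`loocv()` removes each known phenotype–lncRNA link in turn, re-seeds with
the phenotype, its remaining known lncRNAs and all its known genes, and
records the held-out lncRNA's rank among all non-seed lncRNAs. Because
folds can have different candidate counts, positives are pooled on a
common percentile axis: a rank `r` of `n` candidates sits at
`(r-1)/(n-1)`, and the fold's `n-1` negatives occupy the remaining grid
positions. The pooled stepwise ROC over these positions has a trapezoidal
area exactly equal to the pairwise Mann–Whitney statistic (ties counted
half), which the test suite verifies against a brute-force pair count.
Per-fold AUC reduces to `(n-r)/(n-1)`.

The `no_known_lncrnas` scenario removes *all* of a phenotype's lncRNA
links and seeds with phenotype and genes only, emulating a disease with no
annotated lncRNA; `keep_layers` restricts the walk to layer subsets,
reproducing the designs of phenotype–lncRNA-only and lncRNA-only baseline
methods inside the same engine. Top-`k` recall is computed per fold
(rank ≤ `ceiling(f * n)` for fractional cutoffs), not over pooled
candidate counts.

`score_landscape()` runs one propagation per phenotype with its full known
seed sets and collects the lncRNA scores into a phenotype × lncRNA matrix;
`hotspot_counts()` counts, at each rank cutoff, the phenotypes for which a
lncRNA is top-ranked — lncRNAs implicated across many diseases show up as
hotspots.

## The synthetic benchmark

Real composite networks are assembled from curated databases and
alignment-scale expression compendia; the package instead ships a layered
stochastic-block-model generator (`generate_network()`) that emulates
their statistical shape. Each planted disease owns one phenotype, a gene
module and a lncRNA module. Intra-layer edges appear with probability
`p_in` inside a module and `p_out` outside; gene–lncRNA bridges with
`q_bridge` inside and `bg_bridge` outside; predicted weights are uniform
on `predicted_weight_range`. Each phenotype is linked by weight-1
experimental edges to a designated subset of its module (the "known"
genes and lncRNAs), which forms the association catalog; phenotypes
sharing a module are connected in `W_P`. All randomness flows through one
seed (`rng_seed`), and identical seeds give bitwise-identical output.

Default conditions: 50 genes, 10 phenotypes, 40 lncRNAs; 5 diseases with
modules of 6 genes and 5 lncRNAs; `p_in = 0.6`, `p_out = 0.02`,
`q_bridge = 0.5`, `bg_bridge = 0.01`; 3 known genes and 3 known lncRNAs
per disease; weights on [0.4, 0.9]; seed 42. These sizes keep a full
LOOCV run (15 folds, each rebuilding a 100-node transition matrix) well
under a second while leaving enough background lncRNAs (25 of 40) for
ranking to be non-trivial. The weight range 0.4–0.9 places predicted
edges clearly below experimental ones without making them negligible, as
correlation-valued edges that survive a 0.6-type cutoff would be.

`generate_expression()` produces a companion matrix in which module
members share a latent per-sample profile plus independent noise with
variance chosen so within-module Pearson correlations concentrate near
`target_cor` (exactly 1 when `target_cor = 1`); baselines are drawn high
enough above zero that the non-negativity floor is a formality and does
not distort correlations.

What passing tests on this benchmark do and do not show: the generator
plants clean modular structure with homogeneous degrees, so high LOOCV AUC
demonstrates that the engine recovers proximity structure through the
layer bridges — it does not certify performance on real networks, whose
hub-dominated degree distributions, annotation biases and incomplete
coverage have no counterpart here. The ablation comparison (full network
versus phenotype+lncRNA layers) is the qualitative check that carries
over: the gene layer holds most of the planted signal, and removing it
costs roughly 0.25 of AUC in the zero-known-lncRNA scenario.

## Numerical choices and degenerate inputs

* Exact score ties (common in symmetric fixtures) are resolved by
  lexicographic lncRNA id everywhere — ranking, percentiles, hotspot
  counting — so every result is deterministic.
* Node ordering is genes, phenotypes, lncRNAs, each sorted
  lexicographically; assembly is therefore invariant to input record
  order.
* A phenotype that loses every seed in a fold (possible under aggressive
  ablation) skips the fold with a warning rather than failing the run; a
  landscape phenotype with no resolvable seeds yields a zero row.
* Stationary scores are not renormalized before ranking (ranking is
  invariant); `rank_lncrnas(..., normalize = TRUE)` divides by the sum for
  reporting.
* Weights are serialized with 17 significant digits so a network
  round-trips through its TSV directory bit for bit; evidence is inferred
  on re-load as experimental iff the weight is exactly 1, matching the
  weighting convention.

## Known limitations

* The transition matrix is dense; at the package's design scale (up to a
  few thousand nodes) this is simpler and faster than sparse bookkeeping,
  but million-node networks would need a sparse backend.
* One walk per phenotype: multi-phenotype joint queries are out of scope,
  as are learned edge re-weightings and teleporting walk variants.
* The closed-form oracle is quadratic in memory and intentionally capped
  at 2000 nodes.
* Evidence provenance beyond the experimental/predicted dichotomy is not
  modelled; if two predicted sources disagree the maximum weight wins.
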