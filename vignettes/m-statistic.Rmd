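---
title: "The M statistic: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The M statistic: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloM)
```

## The model

Phylogenetic signal — related species resembling each other more than
species drawn at random from the tree — is a statement about two pairwise
distances: phylogenetic distance and trait distance. If the mapping from
phylogeny to traits preserved order (a *monotonicity constraint*, in the
language of multidimensional scaling), then whenever species *i* and *j*
are closer on the tree than *i* and *k*, their trait distance should also
be smaller. The M statistic measures how thoroughly a data set satisfies
this constraint, using the tree's own topology to avoid enumerating all
species triples.

Every internal node with at least three descendant tips roots a *subtree*;
its two child branches partition the subtree's tips. Phylogenetic distances
automatically place the cross-branch mean above each within-branch mean, so
the trait distances of a signal-bearing data set should do the same. The
subtree's score is

$$m_i = \tfrac12\,[\bar d^{\,\mathrm{trait}}_{1st} \le \bar d^{\,\mathrm{trait}}_{cross}]
      + \tfrac12\,[\bar d^{\,\mathrm{trait}}_{2nd} \le \bar d^{\,\mathrm{trait}}_{cross}],$$

with a single-tip branch assigned within-branch distance 0 (an entity is at
distance zero from itself), and $M = \frac1n \sum_i m_i$ over the $n$
qualifying subtrees. Consequences worth noting:

* $M \in \{k/(2n)\}$ — a coarse lattice, so exact ties are common,
  especially for discrete traits with few states.
* The inequality is non-strict: equality counts as satisfying the
  constraint. With a strict inequality, a constant trait would score 0
  despite being the *least* discordant data possible; the non-strict form
  makes it score 1, which is the behaviour we adopt everywhere, and ties in
  the null distribution then make the permutation test conservative rather
  than anticonservative.
* M reads only the topology. Rescaling or perturbing branch lengths cannot
  change it, which makes the index robust to poorly calibrated trees (and
  is verified exactly in the test suite).

Trait distances are Gower dissimilarities, which is what lets one index
serve continuous, nominal, ordinal and mixed data: per trait, continuous
values contribute $|x_i - x_j|/\mathrm{range}$, nominal values a 0/1
mismatch, and ordinal values are converted to midranks and range-normalised
(Podani's extension); the per-pair distance is the weighted mean over
traits observed in both species. A trait *combination* is simply Gower's
distance over the group with equal weights — nothing else in the pipeline
changes.

## The permutation test

The null hypothesis is "no association between tree position and trait
values". We permute the assignment of whole trait rows to tips — shuffling
rows jointly preserves trait–trait correlation, which matters for
combinations — and recompute M against the fixed topology. Since Gower's
distance depends only on the two rows compared, permuting rows is identical
to jointly permuting rows and columns of the distance matrix, so the matrix
is computed once and only its indexing is shuffled (a property the test
suite checks by explicit recomputation). The p-value uses add-one
smoothing, $p = (1 + \#\{M_{null} \ge M_{obs}\})/(n_{perm}+1)$, the
standard right-tailed form for Monte-Carlo tests; with the default 999
permutations the smallest attainable p is 0.001.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_perm` | 999 | permutations; 199 is used in the reduced-scale power studies |
| `alpha` | 0.05 | rejection level for `significant` |
| `ordinal` | `"podani"` | midrank encoding; `"raw"` treats integer codes as continuous |
| trait weights | 1 each | Gower weights; unequal weights change M and are deliberately opt-in |
| `prune` | `FALSE` | drop species absent from tree or table instead of erroring |

Sample-size guidance is surfaced as warnings, not errors: below ~25 tips
for continuous traits and ~50 for discrete ones the test is underpowered,
because the subtree count (hence the M lattice) and the permutation
diversity both shrink with the tree.

## The simulation framework

The generators exist to produce data with *known* a priori signal
intensity $w \in [0,1]$:

* `yule_tree(n_tips, birth_rate = 0.05)` — pure-birth trees; with $k$
  lineages the next split waits an Exponential($k\,b$) time and hits a
  uniformly chosen lineage; after reaching `n_tips` lineages one final
  inter-event time is drawn and all tips are cut at that epoch, so trees
  are exactly ultrametric. Expected root-to-tip depth is
  $\sum_{k=2}^{n} 1/(bk)$, which the tests check by simulation.
* `bm_trait(tree, sigma = 0.01, root_value = 0)` — Brownian motion; a
  child's value is the parent's plus Normal$(0, \sigma^2 \ell)$ over a
  branch of length $\ell$.
* `mix_continuous(x, w)` — the continuous signal dial:
  $w\,x + (1-w)\,x_{\pi}$ with $x_\pi$ a fresh uniform permutation of $x$
  per call. $w = 1$ is pure Brownian signal, $w = 0$ pure noise with the
  same marginal values.
* `mk_trait(tree, n_states, rate = 0.01)` — equal-rates Mk evolution with
  a uniformly drawn root state. The underlying generator scales the rate
  matrix by the uniform stationary frequencies, so the effective
  off-diagonal rate is `rate / n_states`; for two states the change
  probability over a branch of length $t$ is $(1 - e^{-\,rate\, t})/2$.
  We keep that convention because it is the one the standard generator
  implements, and document it rather than re-deriving a different scaling.
* `degrade_discrete(x, w)` — the discrete signal dial: `round(w·n)`
  uniformly chosen species keep their state, the rest are permuted among
  themselves (plain permutation, fixed points allowed; rounding to the
  nearest integer is our choice where convention is silent).

Defaults (birth 0.05, σ = 0.01, Mk rate 0.01, states ∈ {2, 3, 5, 10},
w on a 0.1 grid) are the study conditions of the simulation design this
framework mirrors; they are not meant to be tuned per run.

What the generator does *not* emulate: extinction (death rate is 0),
non-ultrametric trees, rate heterogeneity across lineages or traits,
correlated trait evolution, measurement error, and missing data. Passing
power checks on these simulations therefore demonstrates correct behaviour
under idealised Yule/Brownian/Mk conditions, not performance on messy
empirical tables — for those, the missing-value handling and pruning paths
matter and are tested separately at the unit level.

## Power experiments

`power_curve_continuous()`, `power_curve_discrete()` and
`power_surface_pairs()` report detection rates — the fraction of replicates
with $p \le \alpha$ — over a w grid or a $(w_1, w_2)$ grid. Each replicate
draws a fresh tree (we do not reuse one tree across the w grid; cells stay
independent). Per-replicate seeds are derived by an integer hash of the
master seed and the cell coordinates, so any cell can be recomputed alone
and grid ordering is irrelevant — a contract the tests verify by reversing
the grid.

The package's default scale (20 replicates × 199 permutations) is a
deliberate reduction of the original study design (100 × 999) chosen to
keep a full curve at desk scale; detection rates are unbiased under the
reduction, only their Monte-Carlo error grows. The heavier checks in the
test suite use: 100 random trees of 10–30 tips for the exact
fast-vs-brute-force and invariance properties; 300 replicates per trait
kind at $w = 0$ (50 tips, 5 states for the discrete arm — the midpoint of
the state grid, and above the small-sample warning threshold) for type-I
calibration; 20 replicates at $w = 0.7$ on 500-tip trees and 50 replicates
at $w = 0.9$ on 50-tip trees for the power claims; and 20-replicate
ordering checks (10 vs 2 states at 250 tips, $w = 0.4$; two-trait
combination vs single trait at 50 tips, $w = 0.6$).

## Numerical and degenerate-input choices

* **Ties** in the score comparison are satisfied constraints (non-strict
  ≤); ties between observed and null M count toward the null (the `>=` in
  the p-value), both choices conservative.
* **Constant traits** (all pairwise distances equal) give M = 1, p = 1
  with a warning rather than an error — the permutation distribution is
  degenerate at 1.
* **Zero-range continuous columns** contribute distance 0 for every pair,
  with a warning, and still count toward the Gower weight normalisation.
* **Missing values**: pairwise deletion with weight renormalisation over
  jointly observed traits; a pair sharing no observed trait is an error
  naming the pair, not a silent NA.
* **Polytomies** are a hard error naming the node; `bifurcate = TRUE` in
  `read_newick()` randomly resolves them with zero-length branches, which
  is outside the method's stated domain and labelled as such.
* **Branch order** ("first" vs "second") follows the input Newick; the
  score is symmetric in the two branches, so the order is arbitrary.
* The fast evaluator bins the $\binom{n}{2}$ pair distances by the pair's
  most recent common ancestor (the cross pairs of a subtree are exactly
  the pairs whose MRCA is its root), then accumulates within-clade sums
  over descendant internal nodes — $O(n^2)$ per permutation. The naive
  per-subtree enumeration is kept as `method = "naive"` and the two are
  required to agree exactly on random trees in the tests.

## Known limitations

* Restricted to rooted, strictly bifurcating trees; supertrees with
  polytomies must be resolved first (or excluded).
* The M lattice is coarse on small trees, which combined with tied null
  values makes the test conservative there — hence the 25/50-tip guidance.
* Gower extensions for fuzzy-coded dummy variables and multi-column
  characteristics are out of scope.
* Branch lengths are ignored by design; data whose signal lives in
  branch-length structure (e.g. strongly non-clock-like divergence) will
  be summarised only through topology.
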