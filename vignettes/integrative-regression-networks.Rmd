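---
title: "Integrative regression networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative regression networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irnet)
```

## The problem

Association studies between two genomic profiles measured on the same
samples — here gene-level DNA methylation as features `X` (n samples by J
genes) and mRNA expression as traits `Y` (n by K genes) — are usually run
as all-pairs correlation tests. Correlations are cheap but promiscuous:
with strongly co-regulated genes they flag many indirect associations.
`irnet` instead fits multivariate penalized regressions of all traits on
all features, then asks a different question of the coefficient matrix
`B` (J by K): *which features act alike, and which traits respond alike?*
Two features with similar coefficient profiles across hundreds of traits
plausibly sit in one regulatory process, so they are connected in a
*regression network* over features; transposing `B` gives the analogous
network over traits. Because no single sparse regression is reliable on
its own, four differently structured regressions are fitted and their
networks merged by similarity network fusion; a permutation null then
sets the edge-weight cutoff that separates signal from background.

## The four regressions

All solvers standardize inputs (column mean 0, SD 1, denominator n−1) and
profile intercepts out by centring, which is exact because no penalty
touches the intercept. Each objective is implemented exactly as its
conventional form is printed, including the differing loss scalings; the
reduction identities between methods therefore rescale the penalty level
(these identities are verified in the test suite to 1e-5 relative
objective gap).

**Lasso** (per trait): `||y − Xb||² + λ||b||₁`, solved by cyclic
coordinate descent with soft-thresholding; coefficients become exact
zeros through the threshold operator, never by post-hoc rounding. λ is
chosen by k-fold cross-validation over a 30-point geometric grid from
`λ_max` (the smallest all-zero penalty, here `2·max|X'y|`) down to
`0.01·λ_max`.

**Graph-guided fused lasso** (all traits jointly): adds
`γ Σ_{(m,l)∈E} f(r_ml) Σ_j |β_jm − sign(r_ml)·β_jl|` over the trait
graph E, which connects trait pairs with `|Pearson r| ≥ 0.7`. The weight
`f(r) = |r|` (so it is always at least the threshold) and the sign of r
decides whether coefficients are fused toward equality or toward
opposition. The fusion term is non-separable, so it is smoothed (Nesterov
smoothing, `μ = 1e-4`) and the smoothed objective minimized by monotone
accelerated proximal gradient with the L1 term kept exact in the prox.
The recorded objective trajectory is the smoothed surrogate; the exact
objective is reported at the solution. The starting penalty follows the
median-of-nonzeros heuristic — `λ₀ = median|nonzero β| × K` from a
preliminary lasso fit, `γ₀ = 1` — explored over ×{¼, ½, 1, 2, 4}
multipliers, λ first at fixed γ, then γ at the chosen λ, scored by
held-out MSE.

**Sparse group lasso** (per trait):
`(1/2n)||y − Xb||² + (1−α)λ Σ_l √p_l ||b^(l)||₂ + αλ||b||₁` over a
partition of features into groups (Ward.D2 hierarchical clustering of
feature columns, 20 groups by default), with `α = 0.1`. The prox of the
combined penalty is exact — soft-threshold then groupwise shrinkage — so
whole groups and individual features are zeroed exactly. `λ_max` is the
exact all-zero threshold found by bisection of the group stationarity
condition; note that an L1-only bound overestimates it badly at small α,
which silently confines the whole path to the null model.

**Jointly structured lasso** (full matrix):
`½||Y − XB||_F² + λ₁||B||₁ + λ₂ Σ_k Σ_g ||β_k^g||₂ + λ₃ Σ_j Σ_h ||β_h^j||₂`
with feature groups G and trait groups H (same clustering, 20 groups). As
printed, the group terms carry no √(group size) weights. The prox of the
triple penalty has no closed form; the three shrinkage operators are
composed sequentially inside monotone proximal steps with an
objective-decrease safeguard, so trajectories remain non-increasing even
though the composite prox is inexact. The penalty triple keeps the
conventional 1:3:2 ratio (λ₁ = 0.1, λ₂ = 0.3, λ₃ = 0.2 at the reported
scale) and is tuned per dataset by a validation scan over a common scale
and a group-term weight multiplier (0, ½, 1, 2) — the multiplier 0 case
reduces to a pure L1 fit, so the tuned model never does worse than a
coarsely tuned lasso on the validation data.

The optimization engine is shared: monotone FISTA with backtracking line
search. Backtracking matters for the smoothed fusion term, whose global
Lipschitz bound (`~1/μ`) is about two orders of magnitude above the
local curvature; starting from the loss curvature and doubling on
violations restores full-size steps. Convergence requires the relative
objective change to stay below the tolerance (default 1e-7) for five
consecutive iterations, within a 10,000-iteration cap; non-convergence
is flagged in the diagnostics, not fatal.

## From coefficients to networks

Node vectors are the rows of `B` (features) or its columns (traits).
Coefficient weights are normalized per dimension across nodes before the
kernel — the convention of the fusion method this construction follows —
rather than per node vector: sparse fits leave many node vectors exactly
zero, for which per-vector standardization is undefined. Affinities use
the K-nearest-neighbour scaled exponential kernel
`W(i,j) = exp(−d²(i,j)/(α·ε_ij))` with
`ε_ij = (mean d(i, KNN_i) + mean d(j, KNN_j) + d(i,j))/3`, so the
bandwidth adapts to each pair's local scale; coincident vectors get
affinity 1. `K` (neighbourhood size) and `α` (bandwidth multiplier) are
the two tunable parameters; the conventional search ranges are K ∈ 2–20
and α ∈ 0.3–0.8, scanned by `select_k_alpha()` with the consensus score
below; the pipeline default is K = 20, α = 0.5 (the range midpoint).

Fusion runs on the row-stochastic kernel `P = D⁻¹W` and the KNN local
affinity `S` (each row keeps its K strongest neighbours at total weight
½, with a ½ self-weight). Each iteration updates every network through
its own S and the average status of the other networks, then symmetrizes
and renormalizes, so iterates stay row-stochastic; after t = 20
iterations the fused network is the average of the status matrices.
Similarities supported across networks are reinforced; weights supported
nowhere fade. The consensus score
`mean_i SIM(w_f, w_i) + mean_{i<j} (1 − SIM(w_i, w_j))` (Pearson on
off-diagonal upper triangles) equals 1 exactly when fused and inputs all
agree.

## The permutation cutoff

For a candidate cutoff c, write E for the count of edges with weight ≥ c
and C for the largest connected component (in nodes). The cutoff
minimizes `½[mean_k E(perm_k^c)/E(W^c) + mean_k C(perm_k^c)/C(W^c)]`
over 100 permutations, on a candidate grid of empirical weight quantiles
at 0.5% steps (fused weights are ~100× smaller than individual ones, so
a fixed grid would be useless). Ties break toward the larger cutoff.

The choice of null model is the one genuinely open design decision here,
and the naive option fails: shuffling the edge weights themselves
preserves the weight multiset, so the edge-count ratio is identically 1
and the remaining LCC ratio is minimized at trivial extreme cutoffs. The
informative null permutes the *data behind the network* — each dimension
of the node-vector matrix shuffled independently across nodes — and
rebuilds the network through the same kernel (for fused networks:
permute every input's vectors, rebuild, and re-fuse). Because the kernel
bandwidth is locally adaptive, the null networks keep a comparable
weight scale but lose the concentrated high-affinity structure, which is
exactly what makes the ratio criterion informative. On planted two-block
benchmarks the selected cutoff lands at the block boundary (≥90% planted
recall, ≤5% background acceptance). Weight shuffling remains available
(`permute_network()`, and as the fallback null for matrices of unknown
provenance).

## The synthetic study design

`default_scenario()` fixes the conditions every end-to-end check runs
under: n = 100 samples, J = 200 features in 10 equicorrelated groups,
K = 50 traits in 5 blocks, 5% coefficient support aligned with the
groups and shared within each block, effect sizes |β| ∈ [0.5, 1.5],
within-block trait correlation 0.8, noise SD 0.5 — a reduced-scale
version of a typical per-cancer methylation/expression dataset (~100–200
samples, ~600 features, ~400 traits). The within-group feature
correlation is set to 0.5, a moderate within-pathway level that Ward
clustering recovers without making the design collinear. Traits within a
block share their coefficient column exactly and their noise is
block-correlated, so the trait graph at threshold 0.7 is non-trivial and
the fusion penalty's equality prior is correct by construction.

End-to-end checks score two things on this design. *Parameter recovery*:
the fraction of planted nonzeros among each solver's top-|support|
coefficients, using refits on the full dataset at the penalties selected
on the training split (the 2/3–1/3 split exists only for the predictive
comparison; the association network is built from all the data).
*Pipeline recovery*: the fraction of post-cutoff fused edges joining two
features planted to support the same trait block — features co-supporting
a block are one coefficient-support group, which is the structure the
coefficient-similarity network is supposed to surface.

What the generator does *not* emulate: methylation beta-value
distributions (features are Gaussian), batch effects, weak diffuse
signals, and the heavy multiple-testing regime of ~10⁴ traits. Passing
tests therefore certify the machinery — solvers near their objectives'
minima, fusion and cutoff behaving as designed, structure recoverable
when present — not performance on real tumour data.

One honest negative result is worth recording. On this generator, with
every method tuned by its own selection procedure, the mean test-MSE
ordering over seeds 1–5 is GFLasso ≤ SIOL ≤ Lasso ≪ SGL. Both structured
joint methods beat the lasso, as expected; but the fully published
ordering (SIOL best, SGL between GFLasso and lasso) does not emerge.
Two causes are visible in the probes. First, identical-within-block
coefficient columns are precisely the fusion penalty's prior, so GFLasso
enjoys a by-construction advantage no amount of SIOL tuning overcomes
(grid-oracle SIOL still trails GFLasso). Second, at α = 0.1 the sparse
group lasso is group-dominated while only about a quarter of each active
group's members carry signal, so its best achievable test MSE sits above
the lasso's on every seed — on weak-signal tumour data near-null fits of
all methods are "comparable", which is how the published comparison
reads, but on a strong-signal synthetic the handicap is exposed. The
corresponding acceptance assertions are left failing rather than tuned
around.

## Numerical choices and degenerate inputs

- Exact zeros come from the proximal operators; sparsity is reported as
  the fraction of exact zeros.
- KNN ties in `S` break by node order; top-k coefficient ties break by
  (feature, trait) lexicographic order — all deterministic.
- Constant columns are refused by `standardize()` (named in the error);
  constant dimensions in the affinity construction contribute zero
  distance; a coefficient matrix with more than half its node vectors
  all-zero is refused as degenerate.
- Every stochastic step (CV folds, validation splits, permutations,
  generation) takes an explicit seed; sub-seeds derive from the master
  seed by fixed offsets so stages are independently reproducible.
- Problem sizes in the shipped checks: solver-vs-oracle audits run at
  J·K ≤ 4 against a grid-plus-Nelder-Mead minimizer; network and cutoff
  benchmarks use 12–20 nodes; end-to-end runs use the default scenario
  above with 100 permutations per cutoff.

## Known limitations

- The SIOL prox is inexact (sequential composition); the safeguard
  guarantees monotonicity but convergence to the exact minimizer is only
  verified empirically (against brute force at tiny sizes, and by the
  reduction identities at larger ones).
- GFLasso accuracy is bounded by the smoothing parameter μ; with
  μ = 1e-4 the objective gap to the unsmoothed optimum is below the
  1e-4-scale tolerances used in the audits, but μ would need lowering
  for tighter work.
- The correlation-network baseline excludes constant columns with a
  warning rather than failing, which changes its Bonferroni denominator
  relative to a run with those columns imputed.
- `select_k_alpha()` rebuilds affinities and re-fuses for every grid
  cell; at hundreds of nodes the full 19×6 grid is minutes of work, so
  the pipeline leaves it off by default (`grid_search: false`).
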