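# irnet — integrative regression networks for paired genomic profiles

`irnet` builds association networks between two genomic profiles measured
on the same samples — typically gene-level DNA methylation (features, the
matrix `X`, n samples × J genes) and mRNA expression (traits, `Y`, n × K
genes). Plain all-pairs correlation tests on such data are prone to
indirect associations; `irnet` instead fits multivariate penalized
regressions of all traits on all features and derives networks from the
coefficient matrix **B** (J × K): two features with similar coefficient
profiles across the traits — or two traits responding to a similar set of
features — are connected. Because no single sparse regression is reliable
on its own, four differently structured regressions are fitted and their
networks merged by similarity network fusion; a permutation-calibrated
cutoff then selects the significant edges.

## The models

Four penalized regressions (all with standardized inputs, intercepts
profiled out by centring, exact zeros from proximal operators):

- **Lasso**, per trait: `min ‖y − Xβ‖² + λ‖β‖₁`, coordinate descent; λ by
  k-fold cross-validation.
- **Graph-guided fused lasso**, all traits jointly: adds
  `γ Σ_{(m,l)∈E} f(r_ml) Σ_j |β_jm − sign(r_ml)β_jl|` over the trait
  graph E = {pairs with |Pearson r| ≥ 0.7}, `f(r) = |r|`; smoothed
  proximal gradient; λ started at `median|nonzero β| × K` from a
  preliminary lasso, γ at 1, explored over ×{¼…4} multipliers.
- **Sparse group lasso**, per trait:
  `min (1/2n)‖y − Xβ‖² + (1−α)λ Σ_l √p_l ‖β^(l)‖₂ + αλ‖β‖₁` over feature
  groups from Ward (Ward.D2) hierarchical clustering (20 groups), α = 0.1.
- **Jointly structured lasso**, full matrix:
  `min ½‖Y − XB‖²_F + λ₁‖B‖₁ + λ₂ Σ_k Σ_g ‖β_k^g‖₂ + λ₃ Σ_j Σ_h ‖β_h^j‖₂`
  with feature groups G and trait groups H; penalties at the 1:3:2 ratio
  (0.1/0.3/0.2), scaled per dataset.

From a coefficient matrix, node affinities use the K-nearest-neighbour
scaled exponential kernel `W(i,j) = exp(−d²(i,j)/(α·ε_ij))` with a
locally adaptive bandwidth. Fusion iterates
`P⁽ᵛ⁾ ← S⁽ᵛ⁾ · mean(other P) · S⁽ᵛ⁾ᵀ` for t = 20 rounds (`P = D⁻¹W` the
row-stochastic kernel, `S` the KNN local affinity) and averages. The edge
cutoff c* minimizes
`½[ mean_k E(perm_k^c)/E(W^c) + mean_k C(perm_k^c)/C(W^c) ]` over 100
permutation nulls (E = edges, C = largest-component size); the null
permutes the data behind each network and rebuilds it through the same
construction. Network diagnostics (density, clustering coefficient,
diameter, scale-freeness R² of the degree distribution), a
Bonferroni-thresholded correlation-network baseline, and top-k
coefficient-overlap summaries round out the toolkit, along with a
synthetic-data generator that plants group- and block-structured sparse
coefficients for end-to-end validation.

## Worked example

```r
library(irnet)

# planted dataset: 50 features in 5 groups, 16 traits in 4 blocks
sc <- simulation_scenario(n = 60, J = 50, K = 16, n_feature_groups = 5,
                          n_trait_blocks = 4, support_frac = 0.06, seed = 7)
cm <- compare_methods(sc, folds = 3, n_groups = 5)   # 2/3 train, 1/3 test
round(cm$mse, 3)
#>   lasso gflasso     sgl    siol
#>   0.154   0.126   0.126   0.123

Ws <- lapply(cm$fits[c("lasso", "gflasso", "sgl", "siol")],
             function(f) coefficient_affinity(f$beta, "feature", K = 5, alpha = 0.5))
fused <- snf_fuse(Ws, K = 5, t = 20)
cs <- find_cutoff(fused, n_perm = 100, seed = 7)
cs
#> cutoff_search: c* = 0.02276 with 7 edges, LCC 3 ( 100 permutations )
es <- filter_edges(fused, cs$cutoff)
es
#> edge_set: 7 edges over 11 nodes ( 39 isolated dropped; cutoff 0.02276 )
grp <- cm$data$groups
mean(grp[es$edges$a] == grp[es$edges$b])
#> [1] 1
```

The structured solvers out-predict the plain lasso on structure-matched
data (test MSE 0.123–0.126 vs 0.154); the fused network's cutoff lands on
a much smaller weight scale than the individual networks' (fused weights
are near-stochastic, ~1/N), and every retained fused edge here joins two
features of the same planted support group.

A full run — four tuned fits, both network sides, fusion, cutoffs,
filtered edge lists, and JSON reports — is one call:

```r
run_pipeline(list(seed = 1, out_dir = "run1",
                  scenario = list(n = 100, J = 200, K = 50,
                                  n_feature_groups = 10, n_trait_blocks = 5,
                                  support_frac = 0.05)))
```

A thin command-line front end with subcommands
`simulate | fit | network | fuse | cutoff | analyze | overlap | run`
ships in `inst/scripts/irnet.R`.

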