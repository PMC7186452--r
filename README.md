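# monrank

Ranking essential proteins by a coupled random walk with restart on a
three-layer multiplex biological network.

## The problem

Essential proteins are those an organism cannot survive without. Knockout
screens that identify them are slow and expensive, so computational ranking
from protein–protein interaction (PPI) data is a standard first pass.
Plain topological centralities (degree, betweenness, ...) ignore everything
but the interaction graph; this package integrates three complementary
evidence layers over one shared protein set *V*:

1. **Co-neighbor layer** — each PPI edge (i, j) weighted by
   `|N_i ∩ N_j|² / ((|N_i|−1)(|N_j|−1))`, the squared common-neighbor count
   normalized by degrees. Weights lie in (0, 1].
2. **Co-structure layer** — each PPI edge weighted by `P_D(i) · P_D(j)`,
   where `P_D` is the protein's inverse domain-frequency score
   `Σ_j t_ij / NP_j`, min–max normalized over *V*. Rare domains count more.
3. **Co-expression layer** — each PPI edge weighted by `|PCC|`, the absolute
   Pearson correlation of the two genes' expression time courses; undefined
   or zero correlations give no edge.

The layers are stacked into a third-order adjacency tensor
`T ∈ R^{n×n×L}` and normalized into two transition tensors: `T⁽¹⁾`
(column-stochastic over nodes per (node, layer) fiber, uniform 1/n fallback
for empty fibers) and `T⁽²⁾` (stochastic over layers per node pair, uniform
1/L fallback). The coupled walk iterates

```
X_t = α · T⁽¹⁾ X_{t−1} Y_{t−1} + (1−α) · RV
Y_t = T⁽²⁾ X_t²
```

so node scores `X` and layer importances `Y` reinforce each other, until the
L1 residual falls below a threshold. The restart vector combines two priors
per protein: a conservative score `C_S(i) = N(i)/max_j N(j)` (max-normalized
ortholog counts across reference organisms) and an externally supplied
modular score `M_S`, mixed as `dr(i) = β·C_S(i) + (1−β)·M_S(i)` and
normalized to a probability vector. Defaults: α = 0.3, β = 0.5.

Evaluation utilities score a ranking against a benchmark essential set:
top-K precision, precision–recall curves over all cutoffs, jackknife curves
with areas, random-assortment baselines, and top-K overlap statistics
between two rankings.

A seeded synthetic-data generator produces all six inputs with planted
essentiality signal (degree boost, rare domains, module co-expression,
elevated ortholog counts), so the full pipeline is testable offline.

## Worked example

```r
library(monrank)
bundle <- generate_synthetic(synthetic_config(seed = 42))
ranking <- mon_rank(bundle$pin, bundle$domains, bundle$expr, bundle$orth,
                    ms = bundle$ms, alpha = 0.3, beta = 0.5)
print(attr(ranking, "walk"))
#> walk_result: 16 iterations, converged (final residual 6.07e-10 )
#>   layer importances y: 0.3097, 0.3159, 0.3744
head(ranking, 5)
#>   rank protein      score
#> 1    1   P0026 0.01334139
#> 2    2   P0015 0.01262974
#> 3    3   P0018 0.01255402
#> 4    4   P0035 0.01246146
#> 5    5   P0028 0.01241772

bench <- benchmark_set(bundle$essential, bundle$pin$universe)
topk_precision(ranking, bench, 20)   # 1     (all of the top 20 are planted essentials)
topk_precision(ranking, bench, 40)   # 0.95  (38 of the 40 planted essentials in the top 40)
jackknife_curve(ranking, bench)$area # 7180.5 (random baseline ~3830)
```

The scores are the converged node distribution (they sum to 1); the layer
importance vector `y` says how much each evidence layer contributed to the
converged walk — here co-expression carries the most weight.

## Command line

```sh
Rscript inst/cli/mon.R simulate --outdir data --seed 11 --n-proteins 200 --n-essential 40
Rscript inst/cli/mon.R rank --ppi data/ppi.tsv --domains data/domains.tsv \
    --expression data/expression.tsv --orthologs data/orthologs.tsv \
    --modular-scores data/modular_scores.tsv --alpha 0.3 --beta 0.5 -o data/ranking.tsv
Rscript inst/cli/mon.R evaluate --ranking data/ranking.tsv \
    --essential data/essential.txt --topk 20,40,100 --outdir data/eval
```

All inputs are plain TSV (PPI edge list; protein→domain memberships; gene ×
time-point expression matrix; protein→ortholog-count table; optional
protein→modular-score table; benchmark list, one id per line). A JSON config
file (`--config`) can supply any flag; flags win.

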