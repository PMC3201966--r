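# trophicnets

Topological analysis of binary predator–prey food webs, and prediction of
within-host parasite diversity from network position.

Trophically transmitted helminths complete their life cycles when the next
host eats the current one, so the architecture of the free-living food web
constrains which parasite life cycles can persist and which hosts
accumulate parasite species. `trophicnets` is for ecologists and
parasitologists who have (or simulate) binary consumer–resource matrices
and want the full analysis chain behind that question:

* **Web statistics** — species richness *S*, potential links *S²*, observed
  links *L_o*, linkage density *d = L_o/S*, directed connectance
  *C = L_o/S²*; per-species trophic generality *G* (row sums) and
  vulnerability *V* (column sums).
* **Degree distributions** — cumulative *P(k)* (fraction of species with
  *k* or more trophic links, *k = G + V*), fit by nonlinear least squares
  under exponential *ae^(−γk)*, power-law *ak^(−γ)* and truncated power-law
  *ak^(−γ)e^(−k/k_x)* models, ranked by AICc.
* **Nestedness** — Atmar–Patterson matrix temperature *T* (0 = perfectly
  nested), nestedness *N = (100−T)/100*, significance against a Ce null
  ensemble (cell filled with probability equal to the mean of its row and
  column fill), and relative nestedness *n\* = (N − N̄)/N̄*.
* **Centrality and core/periphery** — eigenvector (max-scaled to 1),
  betweenness, closeness on the symmetrised web; continuous MINRES coreness
  minimising Σ\_{i≠j}(A\_ij − c\_i c\_j)².
* **Group (block) model** — directed stochastic block model with per-pair
  link probabilities p\_kl = L\_kl/N\_kl, Bernoulli log-likelihood,
  AIC = −2·loglik + 2g², simulated-annealing partition search and a scan
  over the number of groups.
* **Parasite overlay** — ordered life-cycle stages with suitable-host sets;
  a stage-wise viability filter (every stage hosted, every trophic
  transition supported by a present feeding link); inference of missing
  feeding links from parasitological records; per-host parasite richness.
* **Diversity models** — cost-complexity-pruned regression trees (1-SE
  rule) and 1000-tree random forests predicting per-host richness from nine
  topological predictors, with permutation and impurity importances.
* **Synthetic data** — generators for webs with planted groups and degree
  heterogeneity and for parasite assemblages whose host choice is biased
  toward central hosts by a tunable exponent β, so the whole pipeline is
  testable end to end.

See `vignettes/trophicnets-methods.Rmd` for the models, conventions,
numerical choices and their caveats.

## Worked example

```r
library(trophicnets)

fw <- generateWeb(S = 80, seed = 42)          # marsh-scale synthetic web
basicMetrics(fw)
#>    S   S2  Lo     d         C
#> 1 80 6400 682 8.525 0.1065625
```

80 species, 682 of 6400 potential links realised: connectance 0.107, about
8.5 feeding links per species — squarely in the range of well-resolved
estuarine webs. Its cumulative degree distribution:

```r
fitDegreeModels(cumulativeDegreeDistribution(fw))[, c("model","gamma","r2","AICc","deltaAIC")]
#>                 model        gamma        r2      AICc  deltaAIC
#> 1         exponential 7.670476e-02 0.9637126 -163.0292  0.000000
#> 2 truncated_power_law 1.000000e-12 0.9637126 -160.3796  2.649573
#> 3           power_law 6.161615e-01 0.7557045 -103.9150 59.114184
```

The exponential ranks first; the truncated power law (which contains the
exponential as its γ→0 limit) is statistically indistinguishable from it
(ΔAICc ≈ 2.6), while the pure power law is decisively rejected — few
super-generalists, no scale-free tail. Nestedness against 200 Ce nulls:

```r
nestednessAnalysis(fw, replicates = 200, seed = 42)
#> NestednessResult for web
#>   T = 18.16  N = 0.8184  null N = 0.7013 (sd 0.0220)
#>   n* = 0.167  p = 0.004975  (200 null replicates, seed 42)
```

The web is significantly nested (p < 0.005), 17% more nested than its null
expectation. Now seed a parasite assemblage whose host choice is biased
toward central hosts (β = 2) and ask a random forest which topological
predictors explain per-host parasite richness:

```r
pars <- generateParasites(fw, beta = 2, seed = 42)
rows <- buildPredictorTable(list(marsh = fw),
                            partitions = list(marsh = plantedGroups(fw)),
                            records = pars)
ff <- fitRandomForest(rows, nTrees = 1000, seed = 42)
ff
#> Random forest: 1000 trees, mtry = 3, OOB pseudo-R2 = 0.684
round(sort(ff$importancePermutation, decreasing = TRUE), 3)
#>          degree     eigenvector        coreness               G       closeness
#>           1.664           1.254           1.239           1.218           1.179
#>     betweenness               V marsh_diversity           group
#>           0.945           0.431           0.000          -0.017
```

The forest explains 68% of out-of-bag variance, and the centrality-family
predictors (degree, eigenvector, coreness) top the permutation importances
— the planted host-choice bias is recovered from topology alone.

`runPipeline(config, outDir)` runs every stage from one config (file paths
or synthetic settings plus a master seed) and writes seven CSV reports and
a manifest; two runs from the same config are byte-identical.

## Layout

```
R/                 implementation (S4 classes FoodWeb, NestednessResult,
                   GroupModelResult, CorePeripheryResult, ParasiteRecords)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette
inst/extdata/      small synthetic example inputs
```
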