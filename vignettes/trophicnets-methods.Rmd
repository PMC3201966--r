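---
title: "Food-web topology and parasite diversity: methods and design notes"
author: "trophicnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-web topology and parasite diversity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Trophically transmitted parasites complete their life cycles by riding
feeding links: the parasite's next host must eat its current host.  The
structure of the free-living food web therefore constrains which parasite
life cycles can persist, and the network position of a host — how many
species it eats and is eaten by, how central it sits among feeding paths,
whether it belongs to the densely interacting core — should predict how many
parasite species it harbours.  `trophicnets` implements the full analysis
chain for this question on binary predator–prey webs: web-level summary
statistics, degree-distribution model selection, nestedness against null
models, per-species centrality and core/periphery position, a group (block)
model of web compartments, a parasite life-cycle overlay, and regression
tree / random forest models of per-host parasite richness.

All analyses operate on a `FoodWeb`: a labelled square binary matrix with
rows as consumers and columns as resources (`A[i, j] = 1` means *i* eats
*j*).  That orientation is fixed once, here; file loaders expose a
`transpose` flag because deposited matrices do not always document their
convention.  Diagonal entries (cannibalism) are legal, count once in the
link total `L_o`, and contribute to both the generality and vulnerability of
the species.

# Web statistics and degree distributions

`basicMetrics()` reports S, S², `L_o`, linkage density `d = L_o / S` and
directed connectance `C = L_o / S²` (self-pairs included among the S²
potential links, which is why a complete web with diagonal has `C = 1`).

`cumulativeDegreeDistribution()` uses the total degree `k = G + V`: a
feeding interaction is a trophic link regardless of direction, and a
cannibalistic link counts in both sums.  `P(k)` is the fraction of species
with `k` or more links, evaluated at each distinct observed degree; the
distinct-degree support points (not per-species points) are the regression
observations, because that is the curve the field actually plots and fits.

`fitDegreeModels()` fits three candidates by nonlinear least squares in
linear `P(k)` space — exponential `a e^{-γk}`, power law `a k^{-γ}`, and
truncated power law `a k^{-γ} e^{-k/k_x}` — with log-linear warm starts and
a Levenberg–Marquardt optimiser, ranked by
`AICc = n ln(RSS/n) + 2K + 2K(K+1)/(n−K−1)`, where K counts the amplitude,
the shape parameter(s), and one residual-variance term (so K = 3, 3, 4).
Degree-0 support points are dropped before fitting (the power-law forms are
undefined at zero); models that fail to converge are excluded from the
ranking with a warning.

Two caveats belong in the open.  First, the truncated power law *nests* the
exponential (its `γ → 0` limit), so on genuinely exponential data the two
are separated only by the AICc penalty.  Second, the residuals of an
empirical cumulative curve are strongly autocorrelated, while AICc assumes
independent Gaussian errors; a maximising fit can therefore convert
sampling wiggle into apparent curvature.  In our seeded simulations with
geometric (discrete-exponential) degree draws at food-web sizes, the
exponential is ranked first in roughly 75–90% of replicates, essentially
never loses to the pure power law, and loses the remainder to the truncated
power law by small margins.  That pattern — power law clearly rejected,
exponential and truncated power law effectively indistinguishable — is
exactly what well-resolved marsh webs show, and we treat it as the correct
scientific reading of such fits rather than a defect to be tuned away.
Maximum-likelihood discrete power-law fitting (Clauset-style) would be the
modern alternative; it is deliberately out of scope.

# Nestedness

`matrixTemperature()` returns the Atmar–Patterson matrix temperature
(0 = perfectly nested, 100 = maximally disordered), computed by
`vegan::nestedtemp`, the standard implementation of the packing/isocline
geometry.  The consumer×resource matrix is scored as a bipartite incidence
matrix, exactly as predator–prey matrices are conventionally fed to
nestedness calculators.  Two conventions are fixed by the wrapper: a matrix
with no absences or no presences is perfectly ordered (`T = 0`, with a
warning — the isocline construction is degenerate there), and the RNG is
pinned internally because the packing refinement is stochastic; without
pinning, the same matrix can score differently between calls.  A
consequence worth knowing: the packing heuristic is order-sensitive at
about the 1% level, so temperature is invariant under row/column
permutation only approximately.

Significance uses the **Ce null model**: each null cell `(i, j)` is filled
independently with probability `(f_row_i + f_col_j)/2`, the mean of the
observed row and column fill.  `nestednessAnalysis()` reports nestedness
`N = (100 − T)/100`, the null mean and SD of N, the pseudo-count p-value
`(1 + #{T_null ≤ T_obs}) / (replicates + 1)`, and relative nestedness
`n* = (N − N̄)/N̄`.  The ensemble default is 1000 replicates; p-values from
fewer than 100 draw a warning.  Fixed-marginal (swap) nulls and NODF are
intentionally not provided.

# Centrality and core/periphery

`centralitySuite()` computes eigenvector centrality, betweenness and
closeness on the *symmetrised*, loop-free web: positional importance treats
a feeding interaction as mutual contact, and the mutual-reachability
conventions behind closed closeness ranges presuppose an undirected graph.
Direction is retained only in G and V.  Eigenvector scores are scaled so
the maximum is exactly 1; betweenness is raw geodesic pair counts with
fractional credit among ties and endpoints excluded; closeness is
`(n−1)/Σd`, computed within components (with a warning) when the web is
disconnected.  The implementation is igraph's; an exhaustive hand-written
shortest-path oracle in the test suite checks it on every web up to 50
species.  The ARPACK eigenvector routine draws its start vector from the
RNG, so the suite pins an internal seed — the scores are a deterministic
function of the web.

`corenessMinres()` fits the continuous core/periphery model: find
non-negative scores `c` minimising `Σ_{i≠j} (A_ij − c_i c_j)²` on the
symmetrised matrix, diagonal ignored (MINRES).  The solver is
coordinate-wise least squares — each sweep updates
`c_i ← Σ_{j≠i} A_ij c_j / Σ_{j≠i} c_j²` one species at a time — so the
objective never increases; convergence is declared when the relative
objective change falls below `tol` (default 1e-8).  Because sweeps visit
species in matrix order, permuting the species permutes the solution only
up to that tolerance.  The reported `fit` is the correlation between the
off-diagonal adjacency and the fitted outer-product pattern.

# The group (block) model

`groupLoglikAic()` evaluates a partition of the S species into g groups
under a directed stochastic block model: every ordered group pair `(k, l)`
has its own Bernoulli link probability, estimated as `p_kl = L_kl / N_kl`
with `N_kl = n_k n_l` ordered cells (diagonal self-cells included, keeping
the S² potential-link convention).  The log-likelihood is
`Σ_kl [L_kl ln p_kl + (N_kl − L_kl) ln(1 − p_kl)]` with `0 ln 0 = 0`, and
`AIC = −2 loglik + 2 g²`: the g² block probabilities are the counted
parameters.  The alternative convention that also counts the S group
memberships (`g² + S`) is available behind `paramCount =
"blocks_plus_assign"`; published minimum-AIC values for deposited webs are
the natural calibration point between the two, and with the deposited
matrices in hand the check in the test suite will adjudicate.

`annealPartition()` searches partitions by simulated annealing: move one
uniformly chosen species to a uniformly chosen other group (rejecting moves
that would empty a group), accept if ΔAIC ≤ 0 and with probability
`exp(−ΔAIC/temp)` otherwise.  The initial temperature is calibrated so
about half of uphill moves on a 100-proposal prefix would accept; cooling
is geometric (0.995 per level, S proposals per level), and each restart
ends with a greedy descent to a local optimum.  Proposal evaluation is
incremental — a move touches only block rows/columns of the two groups
involved, so a delta costs O(S + g) rather than a full S² recount — and the
incremental state is tested against full recomputation.  `scanGroupSizes()`
repeats the search across a g range and selects the AIC minimum.

One empirical property deserves emphasis: because the search *maximises*
the likelihood over an enormous partition space, it extracts real
log-likelihood from pure noise — roughly `2 S ln g` per scan point — which
outweighs the `2g²` penalty at small g.  On an Erdős–Rényi web the scanned
AIC therefore keeps improving well past g = 1, and the selected g is not by
itself evidence of structure.  What does separate structured from random
webs is the *size* of the AIC improvement: in our simulations a strongly
blocked web gains several-fold more (relative to its one-group AIC) than a
density-matched random web, and at strong contrast the scan's minimum sits
at the planted g.  Users should read scanned group numbers with that in
mind.

# The parasite overlay

`ParasiteRecords` stores life cycles as ordered stages (1 = first
intermediate host, last = definitive host), each with a set of suitable
host labels and the transmission mode by which the stage is *acquired*
(`trophic`, `direct`, `vector`).  Free-living stages use the reserved host
label `environment`, treated as present in every web.

`filterViableParasites()` implements the viability rule: a parasite stays
in a web's assemblage only if every stage has at least one suitable host
present, and — under the default strict reading — every trophically
acquired transition is supported by at least one present feeding link
(some present next-stage host eats some present current-stage host).  The
looser presence-only reading is available via
`requireTrophicSupport = FALSE`, since the rule's verbal form supports
either.  The filter is monotone: removing species from a web can only
shrink the viable set.

`inferTrophicLinks()` encodes the complementary inference: a parasite
recovered from a consumer implies that the consumer eats the parasite's
previous-stage host, so every present (intermediate host, next-stage host)
pair of a viable parasite gets its link added if missing, with provenance
recorded.  Links are only ever added and the operation is idempotent.
`hostRichness()` then counts, per species, the viable parasites naming it
at any stage (a parasite using a host at two stages counts once); species
with no parasites stay in the table at richness 0.

# Predicting richness from topology

`buildPredictorTable()` joins nine per-host predictors — eigenvector,
betweenness, closeness, degree, group membership, coreness, marsh diversity
(the S of the host's web), G and V — with the richness response, one row
per (web, species).  Group labels are web-qualified factors: group 3 of one
marsh has nothing to do with group 3 of another, so pooled models must not
align them.  A species missing from any component table is a hard error:
the table never contains NAs by construction.

`fitRegressionTree()` grows a CART regression tree (squared-error loss,
surrogate splits disabled — there are no missing values) and prunes along
the cost-complexity path by 10-fold cross-validation.  The default rule is
the 1-SE rule — the smallest tree whose CV error is within one standard
error of the minimum — which is the standard reading of "prune unless the
error loss is significant"; `pruneRule = "min"` selects the CV-minimum tree
instead.  Factor predictors are handled by rpart's exact ordered-means
search, so group factors with up to a few dozen levels need no special
encoding.  Reported `pseudoR2` is training `1 − SSE/SST` (0 for a constant
response); importance is the per-variable summed loss reduction over actual
splits.

`fitRandomForest()` grows 1000 bootstrap trees with `mtry = ⌈p/3⌉` and
reports the out-of-bag pseudo-R² (`1 − MSE_oob / Var(y)`) plus both
importance measures in circulation: the raw permutation increase in OOB MSE
and the mean node-impurity decrease.  A caution on null calibration: the
per-tree importance SD that forests report understates sampling variance
(trees share the data), so on pure-noise predictors individual importances
routinely exceed twice that SD.  The honest null check — used in the test
suite — is error-relative: permuting any noise predictor moves the OOB MSE
by only a few percent and the forest shows no OOB skill.

`importanceReport()` mirrors the usual presentation: per model the
pseudo-R² and top-4 predictors, and for sites with both models the set of
variables important in both.

# The synthetic-data generator

`generateWeb()` emulates what well-resolved brackish-marsh webs look like
statistically: 70–125 species, directed connectance near 0.1, a generalist
core with specialist periphery (nestedness) and modular block structure.
Species are assigned to `nGroups` blocks; species of rank r gets propensity
`w ∝ (r/S)^{−λ}` (normalised to mean 1); cell `(i, j)` links with
probability `min(1, base · w_i w_j)` where base is `pIn` within and `pOut`
between blocks.  Defaults — S = 80, four groups, `pIn = 0.3`,
`pOut = 0.06`, `λ = 0.7` — give expected connectance ≈ 0.12, inside the
published marsh range.  `λ = 0` with one group is exactly Erdős–Rényi;
larger λ measurably raises relative nestedness.  What the generator does
*not* emulate: taxonomic composition, body-size constraints on feeding,
sampling effort biases, spatial habitat structure.  Tests passing on these
webs show the pipeline's statistical machinery works; they are silent about
those field realities.

`generateParasites()` seeds an assemblage of (default) 25 parasites with
1–3-stage life cycles (stage-count probabilities 0.2/0.4/0.4 — mostly
complex cycles, as in marsh helminth assemblages).  Each parasite draws a
host *chain along existing feeding links*: the stage-1 host is sampled with
weight ∝ (eigenvector centrality)^β (degree optionally), each next host
among the consumers of the current one with the same weights.  Because the
chain rides real links, every generated parasite passes the strict
viability filter by construction.  Each stage lists the chain host plus up
to two further suitable hosts (3 per stage by default) — real parasites
tolerate several hosts per stage, and a 25-parasite assemblage with
single-host stages would give an almost degenerate richness response.
β = 0 samples uniformly; β is the tunable effect size of
centrality-biased host choice.

`recoveryExperiment()` closes the loop: generate webs, seed parasites at a
given β, rebuild the predictor table (using the planted group labels for
the group predictor — re-running the annealing scan for every replicate
would add nothing to the importance question), fit the forest, and record
how often centrality-family predictors (eigenvector or degree) reach top-2
permutation importance.  With β = 3 they do in ~90% of seeds.  An honest
subtlety at β = 0: because chains follow feeding links, host use is
proportional to the number of chains through a host even with zero
preference, and that correlates with degree, eigenvector and betweenness.
The unbiased baseline therefore retains genuine positional signal (in our
runs eigenvector still reaches top-2 in ~40% of seeds, and betweenness is
the most frequent winner).  A truly signal-free baseline would need chains
that ignore web structure — which would contradict both the generator's
design and the biology of trophic transmission.

# Numerical choices and conventions

* Blank cells in adjacency files read as 0; labels are case-sensitive exact
  strings; duplicate edges in edge lists collapse.
* Packing/eigenvector RNG is pinned inside `matrixTemperature()` and
  `centralitySuite()`; all user-facing stochastic functions take explicit
  seeds and restore the caller's RNG state.
* Annealing ties: proposals that would empty a group are rejected, not
  re-drawn; the best state across all restarts is returned.
* Tree split ties are resolved by rpart's deterministic order; surrogate
  splits are off throughout.
* `runPipeline()` derives every stage's seed from one master seed through
  named substreams (stable under adding stages), writes seven CSV reports
  plus a YAML manifest with input checksums, keeps completed reports when a
  later stage fails, and is byte-identical across runs of the same config.

Problem sizes in the test suite and acceptance script are chosen to
exercise each property at the smallest scale where it is statistically
decidable: webs of 10–80 species (60 for planted-partition recovery, as a
realistic marsh-web size), null ensembles of 100–1000 replicates, forests
of 300–1000 trees, 20–30 seeds per Monte-Carlo claim.

# Known limitations

* Matrix temperature inherits the order-sensitivity (~1%) of the packing
  heuristic; cross-implementation differences of a few percent in T are
  normal, which is why relative nestedness comparisons should use the same
  implementation on both sides.
* AIC-selected group counts are inflated by search-maximised noise; compare
  AIC improvements, not best-g values, across webs.
* Degree-distribution selection cannot reliably separate an exponential
  from its truncated-power-law superset at single-web sizes; report both,
  as the fits do.
* The parasite overlay treats host suitability as binary and stage order
  as strict; abundance, intensity and facultative cycles are out of scope.
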