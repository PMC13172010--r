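---
title: "Methods: compositional co-occurrence networks, keystones and percolation robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional co-occurrence networks, keystones and percolation robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

## The problem

Gut microbiome profiles are compositional: shotgun taxonomic profilers
report relative abundances, so the observed vectors live on the simplex and
naive correlation networks are confounded by the closure constraint.
`micronet` implements a full workflow for comparing the *structure* of
microbial communities across host phenotypes — for example metabolically
healthy and unhealthy obesity groups — rather than comparing taxon
abundances one at a time:

1. classify subjects into metabolic-health/obesity phenotypes from clinical
   biomarkers (MHNO, MHO, MUNO, MUO);
2. infer a sparse, signed co-occurrence network per phenotype from the
   CLR-transformed abundance table;
3. profile network topology (centralities, k-cores, weighted distances) and
   detect keystone taxa;
4. quantify robustness under node-removal attacks (NR50, percolation
   threshold);
5. validate by subsampled-network ensembles;
6. test everything end to end on synthetic compositional data with known
   ground-truth conditional-dependence structure.

## Model and estimator

### CLR transform

For a composition $x = (x_1, \dots, x_p)$ the centered log-ratio transform
is $\mathrm{clr}(x)_j = \log x_j - \tfrac1p \sum_k \log x_k$. Zeros are
replaced by a pseudocount equal to half the smallest nonzero value of the
whole table (a global, scale-aware choice; configurable), rows are
re-closed, and each CLR row sums to zero.

### Neighborhood selection

The conditional-dependence graph is estimated in the SPIEC-EASI style: for
each taxon $j$ the standardized CLR column is regressed on all the others
with an L1 penalty,
$$\hat\beta^{(j)} = \arg\min_\beta \tfrac{1}{2n}\lVert z_j - Z_{-j}\beta
\rVert_2^2 + \lambda \lVert\beta\rVert_1 ,$$
and the directed neighborhoods are symmetrized with the OR rule: an edge
$(i,j)$ exists when either $\hat\beta^{(j)}_i$ or $\hat\beta^{(i)}_j$ is
nonzero, carrying the larger-magnitude coefficient as its signed weight.
Coefficients are reported on the standardized scale, so weights are
comparable across taxa and in practice fall in $(-1, 1)$; this is what the
$d = 1 - w$ distance transform consumes. Conflicting signs between the two
directions are resolved toward the larger magnitude and counted.

### StARS penalty selection

The penalty path has 30 log-spaced values from $\lambda_{\max}$ (the
largest absolute standardized cross-covariance — the empty-graph endpoint)
down to $0.01\,\lambda_{\max}$. StARS draws 100 subsamples without
replacement of size $b = \min(\lfloor 10\sqrt n\rfloor, \lfloor 0.8
n\rfloor)$, fits the path on each, and computes the average edge
instability $\bar D(\lambda) = \binom{p}{2}^{-1}\sum_{i<j}
2\theta_{ij}(1-\theta_{ij})$ from the per-edge selection frequencies
$\theta_{ij}$. The curve is monotonized with a running maximum along
decreasing $\lambda$ and the selected penalty is the smallest (densest)
one with $\bar D \le \beta = 0.05$. The seed governs the subsample draws
only; the final full-data fit is deterministic.

## Topology conventions

* Order, size, percentage of negative edges and edge density
  ($2m/(n(n-1))$) are reported for the full graph; mean degree, shortest
  path length, betweenness and closeness for the largest connected
  component (LCC), whose ties are broken toward the component containing
  the lexicographically smallest taxon.
* Shortest-path metrics default to weighted distances $d = 1 - w$, applied
  literally: a negative association maps to a distance above 1. Hop-count
  mode is available (`weighted = FALSE`). Which convention produced the
  published summary tables of this kind of study is usually unstated; both
  are provided, weighted being the default because the distance transform
  is defined for exactly this purpose.
* Betweenness is normalized by $(n-1)(n-2)/2$, closeness by $(n-1)$ over
  the sum of distances.
* Coreness uses iterative minimum-degree peeling and the k-core histogram
  is computed on the *full* network so fragments contribute to low-$k$
  bins.

## Keystone taxa

Keystones are nodes whose degree *and* betweenness both strictly exceed
the 90th percentile of their network (quantile type 7 — linear
interpolation between order statistics — fixed for reproducibility).
Percentiles are taken over LCC nodes with weighted betweenness; both
choices are configurable because the convention is typically unstated.
Ensembles of networks produce a keystone presence/absence matrix, union
and core (always-present) sets per group, pairwise intersection counts and
a PCA of the centered binary matrix.

## Robustness

Attacks run on the LCC of the positive-edge subgraph (negative
associations are removed first). Orderings are *static*, computed once on
the intact graph — degree, betweenness, decreasing or increasing mean
relative abundance, or seeded uniform permutations — with ties broken by
ascending taxon identifier; adaptive reordering is deliberately not the
default because the iterative-removal description this package follows
sorts once. After each removal the LCC of the remaining graph is
recomputed (components may re-rank); the implementation adds nodes back in
reverse with a union-find structure, which matches a brute-force component
counter exactly and is linear in nodes plus edges.

* **NR50** $= 100\,k/N_0$, with $N_0$ the initial LCC size and $k$ the
  smallest number of removals with LCC $\le N_0/2$. Whether the
  denominator should be the LCC or the whole graph is ambiguous in the
  source description; the LCC convention is the default (all robustness
  analysis runs on the LCC) and the whole-graph convention is available
  via `nr50(denominator = "graph")`.
* **Percolation threshold** $p_c$: the fraction removed at the most
  negative finite-difference slope of the normalized decay curve (earliest
  index on ties), reported as a percentage. When the steepest slope does
  not exceed 1.5 times the uniform-decay slope the curve shows no phase
  transition and $p_c$ is undefined (`NA`); the 1.5 factor is a concrete
  rule standing in for "no clear phase transition", needed because
  abundance-ordered attacks on near-linear decay curves must report an
  undefined threshold rather than an arbitrary index.
* Random attacks run 1000 repetitions by default; each repetition derives
  its own sub-seed from the root seed, so results do not depend on the
  number of repetitions or their scheduling.

## Phenotype classification

Metabolic health requires *all* of: glucose $\le$ 100 mg/dL,
triglycerides $\le$ 150 mg/dL, HDL $>$ 40 (men) / $>$ 50 (women) mg/dL,
SBP $\le$ 130 and DBP $\le$ 85 mmHg. Any diagnosis / medication /
impaired-glucose-tolerance flag forces MU regardless of biomarkers.
Obesity is BMI $\ge$ 30 kg/m² (inclusive). Policy decisions:

* A subject failing any single evaluable biomarker is MU even when other
  biomarkers are missing (failure is decisive); a subject whose evaluable
  biomarkers all pass but with at least one missing is *indeterminate* —
  excluded, never imputed.
* mmol/L inputs convert with fixed factors (glucose 18.0, triglycerides
  88.57, HDL 38.67). The conventional dual-unit thresholds are not exact
  conversions of each other (6.1 mmol/L is 109.8 mg/dL); the mg/dL bounds
  are canonical here, so a 6.1 mmol/L glucose converts to 109.8 and
  classifies as MU. Override the thresholds via `phenotype_criteria()` if
  the mmol/L convention is wanted.

## The synthetic world

The generator states a known world so that inference, keystones and
robustness are testable offline:

* **Graph**: Erdős–Rényi, scale-free (preferential attachment), band
  (width-$w$ lattice) or modular (stochastic block model), at a target
  edge density.
* **Precision matrix**: signed weights with magnitudes uniform in
  `edge_weight_range` (default 0.15–0.35) on the edge support, diagonal
  boosted until the minimum eigenvalue reaches 0.05 — support is preserved
  exactly, no rejection sampling. Sign convention: a *negative* precision
  off-diagonal implies a *positive* partial correlation, so the default
  `negative_edge_fraction = 0.1` plants 10% negatively associated pairs
  (real co-occurrence networks of this kind carry a few percent negative
  edges).
* **Observation model**: logistic-normal-multinomial — latent
  $z \sim N(0, \Omega^{-1})$, composition $\propto \exp(z)$, multinomial
  counts at log-normal depths (default mean depth $10^5$, a realistic
  species-level shotgun resolution). This matches the generative
  assumptions under which neighborhood selection on CLR data is
  consistent, making parameter recovery a fair test.

### What the generator does and does not emulate

It reproduces compositionality, sequencing-depth variation, sparsity and a
known conditional-dependence structure. It does **not** simulate batch
effects, raw reads, or taxon-specific zero inflation. One consequence of
faithful compositionality deserves emphasis: at desk-scale taxon counts
($p \lesssim 50$) the CLR closure projects out the simplex constraint with
an $O(1/p)$ negative bias, so false-positive edges are predominantly
negative and the *overall* negative-edge share of inferred networks is
far above the planted 10% (measured 0.28–0.50 across $p$ 12–50). Real
networks with $p \approx 250$ show only a few percent negative edges. A
green recovery test therefore establishes support and sign recovery *on
true edges*, not a realistic global sign balance at small $p$.

## Numerical choices

* glmnet coordinate descent with threshold $10^{-9}$ ($10^{-12}$ where
  oracle equality to $10^{-6}$ is asserted); single-predictor neighborhoods
  use the closed soft-threshold solution.
* Coefficients below $10^{-10}$ in magnitude count as zero edges.
* All randomness flows from integer root seeds through named substreams
  (a deterministic string hash below $2^{31}$), so subsample draws,
  attack permutations and ensemble replicates are independent of
  scheduling and of each other.
* Degenerate inputs error early and by name: all-zero samples, constant
  CLR columns (dropped with a warning), empty post-filter tables,
  disconnected graphs passed to node-level metrics, non-permutation attack
  orders.

## Known limitations

* StARS with few subsamples (used in fast tests) is noisy; the selection
  criterion can be unreachable, which is flagged and warned, never
  silently patched.
* The NR50-versus-best-first-removal comparison is a *diagnostic*: greedy
  degree ordering is not guaranteed optimal, counterexamples on small
  graphs are counted and reported by the test suite rather than asserted
  away. Exhaustive enumeration of all graphs on $\le 7$ nodes is not
  attempted (there are $2^{21}$ of them); a randomized sweep stands in.
* Edge-list serialization drops isolated nodes; order computed from a
  re-read edge list can differ from the in-memory network by the isolated
  nodes.
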