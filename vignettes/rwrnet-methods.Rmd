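---
title: "Network inference with restart walks: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network inference with restart walks: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrnet)
```

## The model

`rwrnet` treats network inference as a diffusion problem. Pairwise
mutual information (MI) defines a fully connected weighted graph over
the genes; a random walk with restart (RWR) run from each gene blends
the seed's local neighbourhood with the global topology of that graph,
and the stationary distribution — multiplied by the direct transition
weight — scores candidate edges. The assumptions are those of every
MI-relevance approach: samples are i.i.d. (or treated as such),
dependence implies potential regulation, and direction is not
identifiable — the output network is undirected.

Three quantities adapt the walk to the data rather than being fixed by
the user:

* **Restart probability α.** The normalised Laplacian
  `L = D^{-1/2}(D − W)D^{-1/2}` of the MI graph is pseudo-inverted by
  eigendecomposition (eigenvalues below 1e-10 treated as null — the
  constant eigenvector is always in the null space). Average commute
  times come from the kernel identity
  `ACT(i,j) = L⁺ᵢᵢ + L⁺ⱼⱼ − 2L⁺ᵢⱼ`, and α is the mean reciprocal
  commute time over all N² ordered pairs (diagonal entries contribute 1
  each). Densely connected graphs — short commutes — therefore restart
  more and trust the seed's local neighbourhood; sparse graphs let the
  walk roam. On very small graphs the raw mean reaches 1 (exactly 1 for
  two genes), which would freeze the walk at its seed, so α is clamped
  into [0.01, 0.99]; clamping warns and both raw and clamped values are
  logged.
* **Seed vectors.** A gene's connectivity (`EL`, its MI row sum) decides
  whether it seeds a *module*: genes above the mean connectivity, plus
  abnormally low genes below mean − sd (both inequalities strict, sample
  sd). Centres spread restart mass uniformly over themselves and their
  top `⌈ln N⌉` MI partners; everything else restarts one-hot. The
  uniform split is a package choice — the only published constraint is
  that the masses sum to 1.
* **Roaming network.** The attenuation factor uses MI-ranking asymmetry:
  the walk keeps an edge's full weight when the pair ranks above the
  source row's off-diagonal mean, damps it by `1 − R/N` (R the
  competition rank within the row, ties to the lower index) when only
  the partner's row ranks it highly, and damps it tenfold when neither
  does. Row means exclude the diagonal, which is a structural zero and
  would bias the mean downward. Columns of the attenuated matrix are
  normalised to a stochastic transition matrix; an all-zero column
  (possible for a gene with no MI at all) becomes a uniform teleport
  column so the matrix stays stochastic.

Edges are called per seed gene with the adaptive threshold
`(3α/4)·Σⱼ MIP⁽ⁱ⁾(j)`. The sum runs over j ≠ i and the self-score is
zeroed: the restart term parks ~α of the stationary mass on the seed,
which would otherwise dominate every threshold. The inequality is
strict, and per-gene votes are symmetrised by union (an AND mode exists
behind a flag; union preserves each gene's discoveries and is the
default because the method is declared undirected).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mi_method` | `gaussian` | `-½ln(1−r²)` in nats; exact for Gaussian data, standard for microarray panels. `histogram` (8 equal-width bins) for clearly non-Gaussian data. |
| `alpha_min`, `alpha_max` | 0.01, 0.99 | clamp keeping the RWR a contraction. |
| `log_base` | e | module size `⌈log N⌉`; the source material writes "log n" without a base, so the base is exposed (`e`, 2 or 10). |
| `tol`, `max_iter` | 1e-6, 10000 | L1 convergence of the walk; the contraction factor is 1−α so the cap is never reached in practice. |
| `threshold_coef` | 0.75 | the 3/4 in the adaptive threshold. |
| `ci_eps` | 0.03 nats | conditional-independence cutoff of the repair search (the PC-search lineage convention; no published value). |
| `max_cond` | 3 | conditioning-set cap; exhaustive subsets above ~4 are intractable and add little on small panels. |

## The repair stage

A walk cannot rescue a gene that no threshold passes, and a regulatory
network should have no isolated gene. Each degree-0 gene gets a
parent–child (PC) set by backward elimination: for conditioning sizes
s = 0…`max_cond`, any candidate rendered conditionally independent
(CMI < `ci_eps`, Gaussian partial-correlation estimator) by some size-s
subset of the remaining candidates is removed, with a deterministic scan
order (ascending candidates, lexicographic subsets). Spouse discovery is
deliberately omitted — spouses are not direct neighbours. An empty PC
falls back to one edge to the strongest-MI partner, so the repaired
network always has minimum degree ≥ 1. Repaired edges are final; they
are not re-filtered by the adaptive threshold.

## What the synthetic generator does and does not emulate

`simulate_expression()` draws from a linear-Gaussian structural model:
gold edges are oriented from lower to higher gene index (acyclic by
construction), roots are standard normal, children are weighted parent
sums (weights uniform in [0.5, 1.5]) plus noise of sd 0.1 by default.
This makes the conditional-independence structure analytically known —
exactly what the PC-search tests need — and exercises every pipeline
stage. It does **not** emulate kinetic ODE dynamics, knockout designs,
time-series autocorrelation, or outliers and heteroscedastic noise in
real expression data. A green recovery test therefore establishes that
the pipeline recovers linear-Gaussian dependence structure at realistic
sample sizes, not that it matches any published benchmark score; note
also that in such a model noise propagates, so child–child correlations
stay high however large the noise is made.

Fixture sizes mirror the published benchmark regime (4–100 genes, 9–250
samples): `chain4` = 4×100, `chain8` = 8×250, `sf10` = 10×10,
`sf50` = 50×50, with fixed seeds for bit-reproducibility. Scale-free
gold networks come from preferential attachment (`igraph::sample_pa`),
one edge per arriving node.

## Numerical choices

* Correlations are clamped at 0.99999 before `ln(1−r²)`, so duplicated
  genes give a large finite MI instead of infinity; constant genes
  degrade to MI 0 with a warning rather than aborting.
* Singular conditioning matrices in the CMI estimator are
  ridge-regularised (1e-6 on the diagonal) with a warning.
* Ranking ties break to the ascending gene index everywhere, making
  runs bit-deterministic.
* MI-isolated genes get degree 1e-12 in the Laplacian so `D^{-1/2}`
  exists; commute times below 1e-12 map to commute frequency 1.
* Metrics are computed at full precision and displayed half-up at 3
  decimals (matching published tables; base `round()` is banker's
  rounding, which would give 0.0485 → 0.048 vs the printed 0.049 style).

## Known limitations

* No regulatory direction and no confidence calibration beyond the raw
  walk score.
* The Gaussian MI estimator misses dependence with zero linear
  correlation; switch to the histogram estimator for such data.
* The PC search is exponential in `max_cond`; it is intended for the
  handful of isolated genes on small panels, not genome-scale inference.
* The empty-set fallback edge guarantees degree ≥ 1 but is the weakest-
  evidence edge in the output; downstream users can drop weight-1
  fallback edges if isolation is acceptable.
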