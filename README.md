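# rwrnet

Inference of undirected **gene regulatory networks (GRNs)** from gene
expression matrices, for computational biologists benchmarking
information-theoretic network inference on small panels (roughly 4–100
genes, DREAM-style data). Most similarity-based methods score each gene
pair in isolation and see only local topology; `rwrnet` runs a **random
walk with restart (RWR)** over a mutual-information graph so that each
edge call also reflects the global topology of the network, then repairs
isolated genes with a Markov-blanket-style conditional-independence
search.

## Method

Given an expression matrix with N genes, the pipeline is:

1. **MI matrix.** Pairwise mutual information `MI(i,j)`; by default the
   Gaussian estimator `MI = -½ ln(1 - r²)` with `r` the Pearson
   correlation (a histogram plug-in estimator is available).
2. **Restart probability.** From the normalised Laplacian
   `L = D^{-1/2}(D - W)D^{-1/2}` of the MI graph, its pseudo-inverse
   `L⁺` gives average commute times
   `ACT(i,j) = L⁺ᵢᵢ + L⁺ⱼⱼ - 2L⁺ᵢⱼ`; the restart probability is the mean
   average commute *frequency* `α = mean(1/ACT)` (clamped to [0.01, 0.99]).
3. **Seed vectors.** A gene's "expression level" is its MI row sum.
   Genes above the mean level — plus abnormally low genes below
   mean − sd — become module centres; each centre spreads its restart
   mass uniformly over itself and its top ⌈ln N⌉ MI neighbours, other
   genes restart from themselves alone.
4. **Roaming network.** Each MI entry is attenuated by a rank factor
   exploiting MI-ranking asymmetry: 1 if the pair is above the row mean,
   `1 - R/N` (R = within-row rank) if it matters only to the partner,
   0.1 if below both row means. Columns are normalised to a stochastic
   transition matrix.
5. **Walk, score, threshold.** Per seed gene, iterate
   `p ← (1-α)Wp + αp₀` to convergence (L1 < 1e-6); score
   `MIP⁽ⁱ⁾(j) = p(j)·W*(i→j)`; keep edges scoring above the per-gene
   adaptive threshold `(3α/4)·Σⱼ MIP⁽ⁱ⁾(j)`; symmetrise votes by union.
6. **Repair.** Each isolated gene is reconnected to its parent–child
   (PC) set, found by eliminating candidates that some conditioning set
   (size ≤ 3) renders conditionally independent (CMI < 0.03 nats).

Evaluation against a gold standard uses TPR, FPR, PPV and ACC over the
N(N−1)/2 unordered gene pairs.

## Worked example

```r
library(rwrnet)

fx  <- make_fixture("chain8")       # 8-gene chain, 250 samples, noise sd 0.1
fit <- rwrnet_infer(fx$expr)
fit
#> rwrnet fit: 8 genes, alpha 0.6244, 6 centres, 7 edges (2 before repair)

network_metrics(confusion(fit$network, fx$gold))
#> TPR 1.000  FPR 0.000  PPV 1.000  ACC 1.000
#> TP=7 FP=0 TN=21 FN=0 (8 genes, 28 pairs)
```

The pipeline recovers all 7 chain edges with no false positive on this
fixture — the restart probability α ≈ 0.62 was derived from the
commute-time kernel, 6 of the 8 genes seeded functional modules, and the
repair stage reconnected the genes the adaptive threshold had left
isolated (2 edges survived thresholding; the PC search restored the
rest). Across 20 replicate datasets the mean TPR is ≈ 0.99 with mean
FPR ≈ 0 (see the acceptance report).

Command line:

```sh
Rscript -e 'rwrnet::rwrnet_cli()' simulate --topology chain --genes 8 \
    --samples 250 --noise 0.1 --seed 7 --out demo/
Rscript -e 'rwrnet::rwrnet_cli()' infer --expr demo/expression.tsv \
    --out demo/net.tsv --gold demo/gold.tsv
Rscript -e 'rwrnet::rwrnet_cli()' eval --pred demo/net.tsv \
    --gold demo/gold.tsv --genes 8
```

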