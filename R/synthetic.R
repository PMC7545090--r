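#' Generate a gold-standard benchmark topology
#'
#' `chain` builds the linear reaction-chain graph (edges i, i+1);
#' `scale_free` draws a Barabasi-Albert preferential-attachment graph with
#' `attach_m` edges per arriving node (a tree for `attach_m = 1`). Both
#' are deterministic given the seed.
#'
#' @param topology `"chain"` or `"scale_free"`.
#' @param n_genes Number of genes (>= 2).
#' @param seed Integer RNG seed.
#' @param attach_m Edges added per new node (scale-free only).
#' @param gene_ids Optional identifiers; default `G1..Gn`.
#' @return A [grn_network()].
#' @export
generate_network <- function(topology = c("chain", "scale_free"), n_genes,
                             seed = 1L, attach_m = 1L,
                             gene_ids = paste0("G", seq_len(n_genes))) {
  topology <- match.arg(topology)
  stopifnot(n_genes >= 2L)
  if (topology == "chain") {
    edges <- cbind(seq_len(n_genes - 1L), seq.int(2L, n_genes))
  } else {
    set.seed(seed)
    g <- igraph::sample_pa(n_genes, m = attach_m, directed = FALSE)
    edges <- igraph::as_edgelist(g, names = FALSE)
  }
  grn_network(gene_ids, edges)
}

#' Simulate expression data over a gold network
#'
#' Linear-Gaussian structural model: each undirected gold edge is oriented
#' from the lower to the higher gene index (acyclic by construction), root
#' genes are standard normal, and every child is the weighted sum of its
#' parents plus Gaussian noise. Edge weights are drawn uniformly from
#' `edge_weight_range` once per edge; samples are i.i.d. columns.
#'
#' @param gold A [grn_network()].
#' @param n_samples Number of samples (columns).
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer RNG seed (same seed, same matrix).
#' @param edge_weight_range Length-2 numeric, default `c(0.5, 1.5)`.
#' @return Genes x samples numeric matrix with gene ids as row names.
#' @export
simulate_expression <- function(gold, n_samples, noise_sd = 0.1, seed = 1L,
                                edge_weight_range = c(0.5, 1.5)) {
  n <- length(gold$gene_ids)
  set.seed(seed)
  w <- stats::runif(nrow(gold$edges), edge_weight_range[1L],
                    edge_weight_range[2L])
  expr <- matrix(0, n, n_samples, dimnames = list(gold$gene_ids, NULL))
  for (g in seq_len(n)) {
    parents <- which(gold$edges[, 2L] == g)  # edges oriented low -> high
    if (length(parents) == 0L) {
      expr[g, ] <- stats::rnorm(n_samples)
    } else {
      signal <- colSums(
        expr[gold$edges[parents, 1L], , drop = FALSE] * w[parents])
      expr[g, ] <- signal + stats::rnorm(n_samples, sd = noise_sd)
    }
  }
  expr
}

#' Canned synthetic benchmark fixtures
#'
#' Parameter bundles sized like the published benchmarks: `chain4`
#' (4 genes x 100 samples), `chain8` (8 x 250), `sf10` (10 x 10), `sf50`
#' (50 x 50). All use noise sd 0.1 and fixed seeds, so every call
#' reproduces the identical dataset.
#'
#' @param name One of `"chain4"`, `"chain8"`, `"sf10"`, `"sf50"`.
#' @param seed Optional seed override (default: the fixture's fixed seed).
#' @return List of class `synthetic_dataset`: `gold` ([grn_network()]),
#'   `expr` (matrix) and `params`.
#' @export
make_fixture <- function(name = c("chain4", "chain8", "sf10", "sf50"),
                         seed = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    chain4 = list(topology = "chain", n_genes = 4L, n_samples = 100L,
                  seed = 401L),
    chain8 = list(topology = "chain", n_genes = 8L, n_samples = 250L,
                  seed = 801L),
    sf10 = list(topology = "scale_free", n_genes = 10L, n_samples = 10L,
                seed = 1001L),
    sf50 = list(topology = "scale_free", n_genes = 50L, n_samples = 50L,
                seed = 5001L))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec$noise_sd <- 0.1
  gold <- generate_network(spec$topology, spec$n_genes, seed = spec$seed)
  expr <- simulate_expression(gold, spec$n_samples, spec$noise_sd,
                              seed = spec$seed)
  structure(list(gold = gold, expr = expr, params = spec),
            class = "synthetic_dataset")
}
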