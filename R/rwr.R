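#' Random walk with restart on a transition matrix
#'
#' Iterates `p <- (1 - alpha) * W %*% p + alpha * p0` from `p = p0` until
#' the L1 change drops below `tol` (the update is a contraction with
#' factor `1 - alpha`, so convergence is guaranteed; `max_iter` is a
#' safety valve that warns and returns the current iterate).
#'
#' @param transition Column-stochastic N x N matrix (entry `[j, i]` is the
#'   probability of stepping from gene i to gene j).
#' @param p0 Seed probability vector summing to 1.
#' @param alpha Restart probability in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List with `p` (stationary distribution) and `iterations`.
#' @export
run_rwr <- function(transition, p0, alpha, tol = 1e-6, max_iter = 10000L) {
  stopifnot(alpha > 0, alpha < 1,
            abs(sum(p0) - 1) < 1e-9,
            nrow(transition) == length(p0))
  p <- p0
  restart <- alpha * p0
  for (it in seq_len(max_iter)) {
    p_new <- (1 - alpha) * as.vector(transition %*% p) + restart
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) return(list(p = p, iterations = it))
  }
  warning("RWR did not converge within ", max_iter, " iterations")
  list(p = p, iterations = max_iter)
}

#' Walk-score row for one seed gene
#'
#' The score of candidate j for seed i is the stationary probability of j
#' multiplied by the transition weight of the direct move i -> j, so mass
#' that arrives at j *and* is directly reachable scores high. The
#' self-score is zeroed (the restart term parks mass on the seed).
#'
#' @param stationary Stationary distribution for seed gene `i`.
#' @param transition Column-stochastic transition matrix.
#' @param i Seed gene index.
#' @return Numeric score vector of length N with entry `i` set to 0.
#' @export
score_pairs <- function(stationary, transition, i) {
  s <- stationary * transition[, i]
  s[i] <- 0
  s
}

#' Per-gene adaptive edge threshold
#'
#' The threshold for seed gene i is `3 * alpha / 4` times the sum of its
#' off-diagonal scores: an edge is kept only when its score exceeds this
#' fraction of the total information the seed distributed.
#'
#' @param mip_row Score row from [score_pairs()] (self entry already 0).
#' @param alpha Restart probability.
#' @param coef Threshold coefficient applied to alpha (default 3/4).
#' @return Scalar threshold.
#' @export
adaptive_threshold <- function(mip_row, alpha, coef = 0.75) {
  coef * alpha * sum(mip_row)
}

#' Assemble the undirected network from scores and thresholds
#'
#' Gene i votes for edge (i, j) when `mip[i, j] > thresholds[i]` (strict).
#' Votes are symmetrised by union by default — each per-gene discovery is
#' kept — or by intersection with `mode = "and"`.
#'
#' @param mip N x N score matrix (row i = scores for seed i).
#' @param thresholds Length-N threshold vector.
#' @param gene_ids Gene identifiers.
#' @param mode `"or"` (default) or `"and"` symmetrisation.
#' @return A [grn_network()] with the vote matrix attached.
#' @export
assemble_network <- function(mip, thresholds, gene_ids = rownames(mip),
                             mode = c("or", "and")) {
  mode <- match.arg(mode)
  n <- nrow(mip)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  votes <- mip > thresholds  # recycles thresholds down rows: row i vs t[i]
  diag(votes) <- FALSE
  keep <- if (mode == "or") votes | t(votes) else votes & t(votes)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  grn_network(gene_ids, idx, votes = votes)
}

#' Run RWR for every gene and collect scores
#'
#' @param roam A [build_roaming()] result.
#' @param kernel A [commute_kernel()] result (or a list with `alpha`).
#' @param centres,modules Seeding context from [select_centres()] /
#'   [build_modules()].
#' @param tol,max_iter Passed to [run_rwr()].
#' @param threshold_coef Passed to [adaptive_threshold()].
#' @return Object of class `rwr_scores`: `stationary` (rows = seeds),
#'   `mip`, `thresholds`, `iterations`.
#' @export
rwr_scores <- function(roam, kernel, centres, modules,
                       tol = 1e-6, max_iter = 10000L,
                       threshold_coef = 0.75) {
  trans <- roam$transition
  n <- nrow(trans)
  alpha <- kernel$alpha
  stationary <- matrix(0, n, n)
  mip <- matrix(0, n, n)
  iters <- integer(n)
  for (g in seq_len(n)) {
    p0 <- initial_vector(g, n, centres, modules)
    res <- run_rwr(trans, p0, alpha, tol = tol, max_iter = max_iter)
    stationary[g, ] <- res$p
    iters[g] <- res$iterations
    mip[g, ] <- score_pairs(res$p, trans, g)
  }
  thresholds <- vapply(seq_len(n), function(g)
    adaptive_threshold(mip[g, ], alpha, threshold_coef), numeric(1))
  structure(list(stationary = stationary, mip = mip,
                 thresholds = thresholds, iterations = iters),
            class = "rwr_scores")
}
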