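#' Commute-time kernel and restart probability
#'
#' Treats the MI matrix as the weighted adjacency of a fully connected
#' graph, forms the symmetrically normalised Laplacian
#' `L = D^{-1/2} (D - W) D^{-1/2}`, and takes its Moore-Penrose
#' pseudo-inverse `L+` via eigendecomposition (eigenvalues below 1e-10 are
#' treated as null). The average commute time between genes i and j is
#' `ACT(i,j) = L+[i,i] + L+[j,j] - 2 L+[i,j]`; its reciprocal is the
#' average commute frequency ACF (with ACF = 1 on the diagonal and
#' wherever ACT underflows below 1e-12). The restart probability of the
#' walk is the mean of all N^2 ACF entries, clamped into
#' `[alpha_min, alpha_max]` so the restart iteration remains a strict
#' contraction (the raw mean can reach or exceed 1 on tiny graphs).
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @param alpha_min,alpha_max Clamp bounds for the restart probability.
#' @return A list of class `commute_kernel` with elements `laplacian`,
#'   `pinv`, `act`, `acf`, `alpha_raw`, `alpha`.
#' @export
commute_kernel <- function(mi, alpha_min = 0.01, alpha_max = 0.99) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  if (max(abs(mi - t(mi))) > 1e-8) stop("MI matrix must be symmetric")
  n <- nrow(mi)
  deg <- rowSums(mi)
  deg[deg <= 0] <- 1e-12  # keep D invertible for MI-isolated genes
  dinv <- 1 / sqrt(deg)
  lap <- (diag(deg) - mi) * tcrossprod(dinv)
  lap <- (lap + t(lap)) / 2
  eig <- eigen(lap, symmetric = TRUE)
  keep <- eig$values > 1e-10
  pinv <- if (any(keep)) {
    v <- eig$vectors[, keep, drop = FALSE]
    v %*% (t(v) / eig$values[keep])
  } else {
    matrix(0, n, n)
  }
  pinv <- (pinv + t(pinv)) / 2
  d <- diag(pinv)
  act <- outer(d, d, "+") - 2 * pinv
  act[act < 0] <- 0
  diag(act) <- 0
  acf <- ifelse(act < 1e-12, 1, 1 / act)
  diag(acf) <- 1
  alpha_raw <- mean(acf)
  alpha <- min(max(alpha_raw, alpha_min), alpha_max)
  if (alpha != alpha_raw)
    warning(sprintf("restart probability clamped: raw %.4g -> %.4g",
                    alpha_raw, alpha))
  structure(list(laplacian = lap, pinv = pinv, act = act, acf = acf,
                 alpha_raw = alpha_raw, alpha = alpha),
            class = "commute_kernel")
}

#' @export
print.commute_kernel <- function(x, ...) {
  cat(sprintf("commute_kernel: %d genes, alpha = %.4f (raw %.4f)\n",
              nrow(x$act), x$alpha, x$alpha_raw))
  invisible(x)
}

#' Gene expression levels from MI connectivity
#'
#' The expression level of a gene is defined as the sum of its MI with
#' every other gene — a connectivity score, not a literal abundance.
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @return Numeric vector of length N, named by gene.
#' @export
expression_levels <- function(mi) rowSums(mi)

#' Select functional-module centres
#'
#' Centres are genes whose expression level exceeds the mean, plus genes
#' whose level falls below `mean - sd` (abnormally low, typically noise —
#' still seeded with a module so their neighbourhood is explored). Both
#' inequalities are strict; the sd uses the sample (N-1) denominator. The
#' set may be empty when all levels are equal.
#'
#' @param el Expression-level vector from [expression_levels()].
#' @return Integer vector of centre indices (ascending).
#' @export
select_centres <- function(el) {
  stopifnot(length(el) >= 2L)
  m <- mean(el)
  s <- stats::sd(el)
  which(el > m | el < m - s)
}

#' Build functional modules around centre genes
#'
#' For each centre the module is its `k = min(ceiling(log(N)), N - 1)`
#' strongest MI partners, ranked descending with ties broken by ascending
#' gene index. Non-centres map to an empty module.
#'
#' @param mi MI matrix.
#' @param centres Integer vector from [select_centres()].
#' @param module_size Optional override for `k`.
#' @param log_base Base of the logarithm sizing the module (default `e`).
#' @return List of length N; element g holds the member indices of g's
#'   module (empty for non-centres).
#' @export
build_modules <- function(mi, centres, module_size = NULL,
                          log_base = exp(1)) {
  n <- nrow(mi)
  k <- if (is.null(module_size)) ceiling(log(n, base = log_base))
       else as.integer(module_size)
  k <- min(max(k, 1L), n - 1L)
  modules <- rep(list(integer(0)), n)
  for (g in centres) {
    row <- mi[g, ]
    cand <- setdiff(seq_len(n), g)
    ord <- cand[order(-row[cand], cand)]
    modules[[g]] <- ord[seq_len(k)]
  }
  modules
}

#' Seed (initial probability) vector for one gene
#'
#' A non-centre gene restarts from itself alone (one-hot vector). A centre
#' spreads its restart mass uniformly over itself plus its module members,
#' so each of the k+1 genes gets `1/(k+1)`.
#'
#' @param g Gene index.
#' @param n Number of genes.
#' @param centres Centre indices.
#' @param modules Module list from [build_modules()].
#' @return Length-N probability vector summing to 1.
#' @export
initial_vector <- function(g, n, centres, modules) {
  p0 <- numeric(n)
  if (g %in% centres && length(modules[[g]])) {
    members <- c(g, modules[[g]])
    p0[members] <- 1 / length(members)
  } else {
    p0[g] <- 1
  }
  p0
}

#' Build the roaming network from the MI matrix
#'
#' The roaming network is the graph the walk actually runs on: each MI
#' entry is attenuated by a rank factor that exploits the *asymmetry* of
#' MI ranking. With `rm_i` the mean of row i's off-diagonal MI and `R_ij`
#' the descending rank of gene j within row i (competition ranking, ties
#' to the lower index):
#' * `MI(i,j) >= rm_i` — the pair matters to i: factor 1 (untouched);
#' * `MI(i,j) < rm_i` but `MI(j,i) >= rm_j` — it matters to j only:
#'   factor `1 - R_ij / N`;
#' * below both row means: factor 0.1 (weakened tenfold).
#'
#' Weights are `W = factor * MI` (zero diagonal, generally asymmetric).
#' The transition matrix divides each column of W by its sum; an all-zero
#' column becomes the uniform column `1/N` so the matrix stays stochastic.
#'
#' @param mi Symmetric MI matrix with zero diagonal.
#' @return A list of class `roaming_network` with `rank_factor`, `weights`
#'   and column-stochastic `transition`.
#' @export
build_roaming <- function(mi) {
  n <- nrow(mi)
  stopifnot(n >= 2L)
  row_mean <- rowSums(mi) / (n - 1L)  # off-diagonal mean; diagonal is 0
  # descending competition rank of j within row i, ties to lower index
  rank_in_row <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-mi[i, others], others)]
    rank_in_row[i, ord] <- seq_along(ord)
  }
  above_i <- mi >= row_mean                 # MI(i,j) >= rowmean_i
  above_j <- t(above_i)                     # MI(j,i) >= rowmean_j
  fac <- ifelse(above_i, 1,
                ifelse(above_j, 1 - rank_in_row / n, 0.1))
  diag(fac) <- 1  # never used (diag MI is 0); keeps factors in (0,1]
  w <- fac * mi
  diag(w) <- 0
  csum <- colSums(w)
  trans <- w
  zero <- csum <= 0
  if (any(!zero))
    trans[, !zero] <- sweep(w[, !zero, drop = FALSE], 2L, csum[!zero], "/")
  if (any(zero)) trans[, zero] <- 1 / n
  structure(list(rank_factor = fac, weights = w, transition = trans),
            class = "roaming_network")
}

#' @export
print.roaming_network <- function(x, ...) {
  cat(sprintf("roaming_network: %d genes, %d non-zero directed weights\n",
              nrow(x$weights), sum(x$weights > 0)))
  invisible(x)
}
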