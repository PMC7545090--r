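# shared in-code fixtures

# the 3-gene worked MI matrix used across topology/rwr tests
worked_mi <- function() {
  m <- matrix(c(0, 0.9, 0.1,
                0.9, 0, 0.5,
                0.1, 0.5, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  m
}

# random symmetric MI-like matrix with zero diagonal
random_mi <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("G", seq_len(n)), paste0("G", seq_len(n)))
  m
}

# random column-stochastic matrix
random_transition <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  sweep(m, 2, colSums(m), "/")
}

# two genes with an exact target sample correlation, mean 0, sd 1
pair_with_correlation <- function(r, n = 50, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- stats::rnorm(n)
  # orthogonalise y against x, then recombine to hit r exactly
  x <- scale(x)[, 1]
  y <- scale(stats::residuals(stats::lm(y ~ x)))[, 1]
  z <- r * x + sqrt(1 - r^2) * y
  rbind(G1 = x, G2 = z)
}

write_expr_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  colnames(df)[-1] <- paste0("S", seq_len(ncol(expr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
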