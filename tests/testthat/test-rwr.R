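test_that("iterated walk matches the closed-form linear solve", {
  # p* = alpha (I - (1-alpha) W)^{-1} p0, checked on random instances
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:20, 1)
    w <- random_transition(n, seed = seed)
    p0 <- numeric(n)
    p0[sample(n, 1)] <- 1
    alpha <- 0.5
    res <- run_rwr(w, p0, alpha)
    exact <- alpha * solve(diag(n) - (1 - alpha) * w, p0)
    expect_lt(max(abs(res$p - exact)), 1e-5)
    expect_equal(sum(res$p), 1, tolerance = 1e-9)
  }
})

test_that("restart-dominated walk stays near its seed", {
  w <- random_transition(8, seed = 2)
  p0 <- c(1, rep(0, 7))
  res <- run_rwr(w, p0, alpha = 0.99)
  expect_lt(sum(abs(res$p - p0)), 0.02)
})

test_that("iteration count is non-increasing in alpha", {
  w <- random_transition(10, seed = 5)
  p0 <- rep(1 / 10, 10)
  iters <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a)
    run_rwr(w, p0, a)$iterations, integer(1))
  expect_true(all(diff(iters) <= 0))
})

test_that("run_rwr warns at the iteration cap and validates inputs", {
  w <- random_transition(5, seed = 1)
  p0 <- c(1, 0, 0, 0, 0)
  expect_warning(res <- run_rwr(w, p0, alpha = 0.01, max_iter = 2L),
                 "converge")
  expect_identical(res$iterations, 2L)
  expect_error(run_rwr(w, p0, alpha = 1.5))
  expect_error(run_rwr(w, c(0.5, 0.5, 0.5, 0, 0), alpha = 0.5))
})

test_that("score_pairs multiplies stationary mass by the direct move weight", {
  # zero transition entry -> zero score regardless of stationary mass
  w <- random_transition(4, seed = 3)
  w[2, 1] <- 0
  stat <- c(0.1, 0.6, 0.2, 0.1)
  s <- score_pairs(stat, w, 1L)
  expect_identical(s[2], 0)
  expect_identical(s[1], 0)  # self-score zeroed
  expect_equal(s[3], stat[3] * w[3, 1])

  # uniform stationary x uniform column -> constant 1/N^2 off-diagonal
  n <- 5
  wu <- matrix(1 / n, n, n)
  su <- score_pairs(rep(1 / n, n), wu, 2L)
  expect_equal(su[-2], rep(1 / n^2, n - 1))

  # worked 3-gene roaming case: direct elementwise arithmetic
  roam <- build_roaming(worked_mi())
  k <- commute_kernel(worked_mi())
  res <- run_rwr(roam$transition, c(1, 0, 0), k$alpha)
  s3 <- score_pairs(res$p, roam$transition, 1L)
  expect_equal(unname(s3[2]), res$p[2] * roam$transition[2, 1],
               tolerance = 1e-12)
  expect_equal(unname(s3[3]), res$p[3] * roam$transition[3, 1],
               tolerance = 1e-12)
})

test_that("adaptive threshold is 3 alpha / 4 of the score-row sum", {
  expect_identical(adaptive_threshold(rep(0, 6), alpha = 0.5), 0)
  # row (0.1, 0.2, 0.3), alpha 0.4 -> 0.3 * 0.6 = 0.18; 0.2 and 0.3 pass
  row <- c(0.1, 0.2, 0.3)
  thr <- adaptive_threshold(row, alpha = 0.4)
  expect_equal(thr, 0.18)
  expect_identical(which(row > thr), 2:3)
  # scale equivariance: doubling the row doubles the threshold
  expect_equal(adaptive_threshold(2 * row, 0.4), 2 * thr)
  expect_identical(which(2 * row > adaptive_threshold(2 * row, 0.4)),
                   which(row > thr))
  # coefficient override
  expect_equal(adaptive_threshold(row, 0.4, coef = 1), 0.24)
})

test_that("assemble_network symmetrises votes by union (or intersection)", {
  mip <- matrix(0, 3, 3)
  mip[1, 2] <- 0.9
  thr <- c(0.5, 0.5, 0.5)
  net <- assemble_network(mip, thr)
  expect_identical(unname(net$edges), matrix(c(1L, 2L), ncol = 2))
  expect_true(net$votes[1, 2] && !net$votes[2, 1])
  # AND mode requires both votes
  expect_identical(n_edges(assemble_network(mip, thr, mode = "and")), 0L)
  # no votes -> empty network; edge count bounded by vote count
  expect_identical(n_edges(assemble_network(matrix(0, 3, 3), thr)), 0L)
  set.seed(6)
  m <- matrix(runif(36), 6, 6)
  nt <- assemble_network(m, rep(0.5, 6))
  expect_lte(n_edges(nt), sum(m > 0.5))
})

test_that("within-block pairs outscore between-block pairs on a two-clique graph", {
  # two dense 4-cliques joined by one bridge (4-5): the walk's global view
  # must keep block structure far above background
  set.seed(2)
  n <- 8
  mi <- matrix(0.05 + runif(n * n, 0, 0.01), n, n)
  mi <- (mi + t(mi)) / 2
  for (b in list(1:4, 5:8))
    for (i in b) for (j in b) if (i < j) mi[i, j] <- mi[j, i] <- 0.8 + runif(1, 0, 0.05)
  mi[4, 5] <- mi[5, 4] <- 0.5
  diag(mi) <- 0
  k <- commute_kernel(mi)
  roam <- build_roaming(mi)
  cen <- select_centres(expression_levels(mi))
  sc <- rwr_scores(roam, k, cen, build_modules(mi, cen))
  sym <- pmax(sc$mip, t(sc$mip))
  within <- c(sym[1:4, 1:4][upper.tri(diag(4))],
              sym[5:8, 5:8][upper.tri(diag(4))])
  between <- sym[1:4, 5:8]
  between <- between[-which(outer(1:4, 5:8, function(a, b) a == 4 & b == 5))]
  expect_gt(min(within), max(between))
})

test_that("rwr_scores rows are stationary distributions with finite scores", {
  mi <- random_mi(6, seed = 9)
  k <- commute_kernel(mi)
  roam <- build_roaming(mi)
  cen <- select_centres(expression_levels(mi))
  sc <- rwr_scores(roam, k, cen, build_modules(mi, cen))
  expect_equal(unname(rowSums(sc$stationary)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(sc$stationary >= 0))
  expect_true(all(sc$mip >= 0) && all(is.finite(sc$mip)))
  expect_identical(unname(diag(sc$mip)), rep(0, 6))
  expect_length(sc$thresholds, 6L)
})
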