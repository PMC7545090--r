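test_that("commute kernel reproduces the 2-gene hand case for any MI scale", {
  # L = [[1,-1],[-1,1]], L+ = [[1/4,-1/4],[-1/4,1/4]], ACT = 1, ACF = 1,
  # alpha_raw = 1, clamped to 0.99 — independent of the MI magnitude m
  for (m in c(0.01, 1, 42)) {
    mi <- matrix(c(0, m, m, 0), 2)
    expect_warning(k <- commute_kernel(mi), "clamp")
    expect_equal(k$laplacian, matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
    expect_equal(k$pinv, matrix(c(1, -1, -1, 1) / 4, 2), tolerance = 1e-12)
    expect_equal(k$act[1, 2], 1, tolerance = 1e-12)
    expect_equal(k$acf, matrix(1, 2, 2), tolerance = 1e-12)
    expect_equal(k$alpha_raw, 1, tolerance = 1e-12)
    expect_equal(k$alpha, 0.99)
  }
})

test_that("commute kernel structure: symmetry, zero-diagonal ACT, unit ACF diag", {
  mi <- random_mi(7, seed = 3)
  k <- commute_kernel(mi)
  expect_equal(k$pinv, t(k$pinv), tolerance = 1e-10)
  expect_equal(k$act, t(k$act), tolerance = 1e-10)
  expect_identical(unname(diag(k$act)), rep(0, 7))
  expect_true(all(k$act >= 0))
  expect_identical(unname(diag(k$acf)), rep(1, 7))
  expect_true(k$alpha > 0 && k$alpha < 1)
  expect_error(commute_kernel(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("eigendecomposition pseudo-inverse agrees with a generic routine", {
  skip_if_not_installed("MASS")
  mi <- random_mi(5, seed = 8)
  k <- commute_kernel(mi)
  deg <- rowSums(mi)
  lap <- diag(deg) - mi
  lap <- diag(1 / sqrt(deg)) %*% lap %*% diag(1 / sqrt(deg))
  pinv2 <- MASS::ginv(lap)
  d <- diag(pinv2)
  act2 <- outer(d, d, "+") - 2 * pinv2
  diag(act2) <- 0
  expect_equal(k$act, act2, tolerance = 1e-8)
})

test_that("strengthening a pair never lengthens its commute time", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    mi <- random_mi(n, seed = 100 + rep)
    i <- sample(n, 1)
    j <- sample(setdiff(seq_len(n), i), 1)
    mi2 <- mi
    mi2[i, j] <- mi2[j, i] <- mi2[i, j] + runif(1, 0.1, 1)
    expect_lte(commute_kernel(mi2)$act[i, j],
               commute_kernel(mi)$act[i, j] + 1e-9)
  }
})

test_that("expression levels are MI row sums and permutation-equivariant", {
  mi <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  expect_equal(unname(expression_levels(mi)), c(3, 4, 5))
  expect_equal(unname(expression_levels(matrix(0, 4, 4))), rep(0, 4))
  m <- random_mi(6, seed = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(unname(expression_levels(m[perm, perm])),
               unname(expression_levels(m))[perm])
})

test_that("centre selection uses strict mean / mean - sd cuts", {
  # EL = (3,4,5): mean 4, sd 1 -> only gene 3
  expect_identical(select_centres(c(3, 4, 5)), 3L)
  # all equal -> empty (strict inequalities fail)
  expect_identical(select_centres(rep(2, 5)), integer(0))
  # EL = (10,5,5,0): mean 5, sd 4.082 -> high gene 1 and low gene 4
  expect_identical(select_centres(c(10, 5, 5, 0)), c(1L, 4L))
})

test_that("module size is ceiling(log N) capped at N-1, ties to lower index", {
  mi4 <- random_mi(4, seed = 1)
  mods <- build_modules(mi4, centres = 1L)
  expect_length(mods[[1]], 2L)  # ceiling(ln 4) = 2
  expect_identical(mods[[2]], integer(0))

  mi100 <- random_mi(100, seed = 1)
  expect_length(build_modules(mi100, centres = 5L)[[5]], 5L)  # ceiling(ln 100)

  # tied MI: lower index wins
  mi <- matrix(0.5, 4, 4)
  diag(mi) <- 0
  m <- build_modules(mi, centres = 4L)[[4]]
  expect_identical(m, c(1L, 2L))

  # override and log base knobs
  expect_length(build_modules(mi4, 1L, module_size = 3)[[1]], 3L)
  expect_length(build_modules(mi100, 5L, log_base = 10)[[5]], 2L)
})

test_that("initial vectors are one-hot off-centre, uniform on modules", {
  mi <- random_mi(5, seed = 4)
  mods <- build_modules(mi, centres = 2L)
  # non-centre: one-hot
  expect_identical(initial_vector(3L, 5L, 2L, mods), c(0, 0, 1, 0, 0))
  # centre with k = 2: three entries of 1/3
  p <- initial_vector(2L, 5L, 2L, mods)
  expect_equal(sort(unique(p)), c(0, 1 / 3))
  expect_equal(p[2], 1 / 3)
  # all seed vectors sum to 1
  for (g in 1:5)
    expect_equal(sum(initial_vector(g, 5L, 2L, mods)), 1, tolerance = 1e-12)
})

test_that("roaming network reproduces the hand-evaluated worked matrix", {
  r <- build_roaming(worked_mi())
  # row means (off-diag): 0.5, 0.7, 0.3
  expect_equal(r$rank_factor[1, 3], 0.1)        # below both row means
  expect_equal(r$rank_factor[2, 3], 1 - 2 / 3)  # rank 2 of 3 genes
  expect_equal(r$rank_factor[3, 2], 1)          # above own row mean
  expect_equal(r$weights[1, 3], 0.01)
  expect_equal(r$weights[2, 3], 0.5 * (1 / 3))
  expect_equal(r$weights[3, 2], 0.5)
  expect_equal(r$weights[1, 2], 0.9)            # untouched strong pair
  expect_false(isTRUE(all.equal(r$weights, t(r$weights))))
  expect_identical(unname(diag(r$weights)), rep(0, 3))
})

test_that("roaming network contracts: factors in (0,1], stochastic columns", {
  # all off-diagonal MI equal: first branch everywhere, W == MI
  mi <- matrix(0.4, 5, 5)
  diag(mi) <- 0
  r <- build_roaming(mi)
  expect_equal(r$weights, mi)

  for (seed in 1:5) {
    m <- random_mi(6, seed = seed)
    r <- build_roaming(m)
    expect_true(all(r$rank_factor > 0 & r$rank_factor <= 1))
    expect_equal(unname(colSums(r$transition)), rep(1, 6), tolerance = 1e-9)
  }

  # all-zero MI: uniform teleport columns keep the matrix stochastic
  r0 <- build_roaming(matrix(0, 4, 4))
  expect_equal(r0$transition, matrix(1 / 4, 4, 4))
})

test_that("transition stochasticity is permutation-equivariant", {
  m <- random_mi(6, seed = 12)
  perm <- c(4, 2, 6, 1, 3, 5)
  r1 <- build_roaming(m)
  r2 <- build_roaming(m[perm, perm])
  expect_equal(unname(r2$weights), unname(r1$weights[perm, perm]),
               tolerance = 1e-12)
  expect_equal(unname(colSums(r2$transition)), rep(1, 6), tolerance = 1e-9)
})
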