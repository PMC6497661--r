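test_that("pPCA equals standard PCA on a star tree", {
  tr <- star_tree(10)
  set.seed(3)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(tr$tip.label, NULL))
  mp <- ppca(X, tr)
  ms <- pca(X)
  for (j in seq_len(ncol(mp$scores))) {
    d1 <- max(abs(mp$scores[, j] - ms$scores[, j]))
    d2 <- max(abs(mp$scores[, j] + ms$scores[, j]))
    expect_lt(min(d1, d2), 1e-8)
  }
})

test_that("pPCA reproduces the closed-form GLS quantities on 3 tips", {
  tr <- three_tip_tree()
  X <- matrix(c(1, 2, 4,
                0.5, -1, 3), 3, 2,
              dimnames = list(c("A", "B", "C"), NULL))
  # hand GLS: C = [[2,1,0],[1,2,0],[0,0,2]]
  C <- ape::vcv.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  Ci <- solve(C)
  one <- rep(1, 3)
  a_hand <- as.vector(t(one) %*% Ci %*% X[c("A", "B", "C"), ]) /
    as.numeric(t(one) %*% Ci %*% one)
  Xc <- sweep(X[c("A", "B", "C"), ], 2, a_hand)
  R_hand <- t(Xc) %*% Ci %*% Xc / 2
  ms <- ppca(X, tr)
  expect_lt(max(abs(ms$anc_mean - a_hand)), 1e-10)
  # eigenvalues of the hand R match
  expect_lt(max(abs(sort(ms$eigenvalues, decreasing = TRUE) -
                      sort(eigen(R_hand)$values, decreasing = TRUE))), 1e-10)
})

test_that("pPCA agrees with the phytools reference implementation", {
  tr <- simulate_tree(15, 1, 2)
  X <- simulate_bm_traits(tr, diag(c(2, 1, 0.5, 0.2)), seed = 7)
  ms <- ppca(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  for (j in 1:4) {
    d1 <- max(abs(ms$scores[, j] - ref$S[rownames(ms$scores), j]))
    d2 <- max(abs(ms$scores[, j] + ref$S[rownames(ms$scores), j]))
    expect_lt(min(d1, d2), 1e-6)
  }
  expect_error(ppca(X[1:10, ], ape::keep.tip(tr, tr$tip.label[2:12])),
               "mismatch")
})

test_that("pPCA scores are invariant to species input order", {
  tr <- simulate_tree(12, 1, 4)
  X <- simulate_bm_traits(tr, diag(1, 3), seed = 5)
  m1 <- ppca(X, tr)
  m2 <- ppca(X[sample(12), ], tr)
  for (j in 1:3) {
    d1 <- max(abs(m1$scores[, j] - m2$scores[rownames(m1$scores), j]))
    d2 <- max(abs(m1$scores[, j] + m2$scores[rownames(m1$scores), j]))
    expect_lt(min(d1, d2), 1e-8)
  }
})

test_that("standard PCA has the expected spectral structure", {
  # collinear data: first axis carries all variance
  t_ <- seq(-1, 1, length.out = 8)
  X <- cbind(2 * t_, -t_, 0.5 * t_)
  ms <- pca(X)
  expect_gt(ms$eigenvalues[1] / sum(ms$eigenvalues), 1 - 1e-12)

  set.seed(9)
  Y <- matrix(rnorm(60), 10, 6)
  msy <- pca(Y)
  expect_lt(abs(sum(msy$eigenvalues) - sum(apply(Y, 2, var))), 1e-10)

  # SVD oracle
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(Yc)
  sc_or <- sv$u %*% diag(sv$d)
  for (j in 1:6) {
    d1 <- max(abs(msy$scores[, j] - sc_or[, j]))
    d2 <- max(abs(msy$scores[, j] + sc_or[, j]))
    expect_lt(min(d1, d2), 1e-8)
  }
  expect_error(pca(Y[1, , drop = FALSE]), "2 species")

  # loadings orthonormal
  G <- crossprod(msy$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-8)
})

test_that("parallel analysis retains no axes under the null and finds a planted factor", {
  null_hits <- 0; factor_hits <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(60 * 12), 60, 12)
    if (parallel_analysis(X, n_perm = 100, seed = s) <= 1)
      null_hits <- null_hits + 1
    f <- rnorm(60)
    load <- rnorm(12)
    Xf <- X + 10 / sqrt(12) * f %o% load
    if (parallel_analysis(Xf, n_perm = 100, seed = s) >= 1)
      factor_hits <- factor_hits + 1
  }
  expect_gte(null_hits, 18)
  expect_gte(factor_hits, 19)

  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  expect_identical(parallel_analysis(X, n_perm = 100, seed = 3),
                   parallel_analysis(X, n_perm = 100, seed = 3))
  expect_error(parallel_analysis(X, n_perm = 50), "n_perm")
  expect_error(parallel_analysis(X, n_perm = 100, quantile_prob = 1.2),
               "quantile")
})

test_that("per-axis R2 reduces to relative eigenvalues for PCA scores", {
  set.seed(11)
  Y <- matrix(rnorm(14 * 9), 14, 9)
  ms <- pca(Y)
  r2 <- axis_variance_r2(Y, ms$scores)
  expect_lt(max(abs(r2 - ms$eigenvalues / sum(ms$eigenvalues))), 1e-10)
  expect_lt(sum(r2), 1 + 1e-9)

  # orthogonalized random scores: bounded decomposition
  Q <- qr.Q(qr(matrix(rnorm(14 * 3), 14, 3)))
  r2q <- axis_variance_r2(Y, Q)
  expect_true(all(r2q >= 0) && sum(r2q) <= 1)

  # hand-computed single-axis ratio on a 3-species fixture
  Y3 <- matrix(c(0, 1, 2, 0, 2, 4), 3, 2)
  sc <- matrix(c(-1, 0, 1), 3, 1)
  fitted <- cbind(1, sc) %*% qr.solve(cbind(1, sc), Y3)
  ss_model <- sum((fitted - rep(1, 3) %o% colMeans(Y3))^2)
  ss_tot <- sum(scale(Y3, scale = FALSE)^2)
  expect_equal(unname(axis_variance_r2(Y3, sc)), ss_model / ss_tot)

  expect_error(axis_variance_r2(Y, cbind(ms$scores[, 1], ms$scores[, 1])),
               "rank")
})

test_that("score scaling is invertible and leaves model ranking unchanged", {
  set.seed(2)
  sc <- matrix(rnorm(20), 10, 2)
  expect_lt(max(abs(scale_scores(scale_scores(sc, 100), 0.01) - sc)), 1e-12)
  expect_error(scale_scores(sc, 0), "non-zero")

  tr <- simulate_tree(16, 1, 8)
  Y <- simulate_shifted_ou_traits(tr, 4, 1, 0, list(), seed = 3)
  f1 <- list(BM = fit_bm(tr, Y), OU1 = fit_ou1(tr, Y, n_restarts = 2))
  f100 <- list(BM = fit_bm(tr, scale_scores(Y, 100)),
               OU1 = fit_ou1(tr, scale_scores(Y, 100), n_restarts = 2))
  d1 <- f1$BM$aicc - f1$OU1$aicc
  d100 <- f100$BM$aicc - f100$OU1$aicc
  expect_identical(sign(d1), sign(d100))
  expect_lt(abs(d1 - d100), 2)  # optimizer noise only; the ranking is exact
})
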