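test_that("simulate_tree returns ultrametric unit-depth Yule trees, deterministically", {
  tr2 <- simulate_tree(2, 1, 7)
  expect_s3_class(tr2, "phylo")
  expect_equal(tr2$Nnode, 1)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths[1], depths[2])

  nw1 <- ape::write.tree(simulate_tree(50, 1, 1))
  nw2 <- ape::write.tree(simulate_tree(50, 1, 1))
  expect_identical(nw1, nw2)

  tr <- simulate_tree(30, 2, 5)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)
  expect_identical(tr$tip.label[1], "sp_0001")

  expect_error(simulate_tree(1, 1, 1), "n_tips")
})

test_that("pure-birth lineage count grows log-linearly in relative time", {
  times <- seq(0.1, 0.9, by = 0.2)
  logN <- matrix(NA_real_, 100, length(times))
  for (r in 1:100) {
    tr <- simulate_tree(50, 1, 1000 + r)
    ages <- ape::node.depth.edgelength(tr)
    node_ages <- ages[(ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)]
    logN[r, ] <- log(vapply(times, function(t) 1 + sum(node_ages <= t),
                            numeric(1)))
  }
  m <- colMeans(logN)
  fit <- lm(m ~ times)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("BM trait simulation matches the closed-form tip covariance", {
  # degenerate: zero-length tree leaves every tip at the root state
  tr0 <- three_tip_tree()
  tr0$edge.length[] <- 0
  X <- simulate_bm_traits(tr0, diag(1, 2), c(3, -1), seed = 2)
  expect_equal(unname(X), matrix(rep(c(3, -1), each = 3), 3, 2))

  # 3-tip tree, p = 1, sigma2 = 2: covariance = 2 * C with C from shared
  # path lengths ((A,B) share 1, depths 2)
  tr <- three_tip_tree()
  nrep <- 4000
  tips <- t(vapply(seq_len(nrep), function(r)
    simulate_bm_traits(tr, matrix(2), 0, seed = r)[, 1], numeric(3)))
  emp <- cov(tips)
  want <- 2 * ape::vcv.phylo(tr)
  mc_se <- sqrt(2 * (diag(want) %o% diag(want)) / nrep)  # rough normal-theory SE
  expect_true(all(abs(emp - want) < 3 * mc_se + 0.05))

  # diagonal rate matrix: independent traits
  tips2 <- vapply(seq_len(2000), function(r)
    simulate_bm_traits(tr, diag(c(1, 1)), c(0, 0), seed = 5000 + r)[1, ],
    numeric(2))
  expect_lt(abs(cor(tips2[1, ], tips2[2, ])), 3 / sqrt(2000))

  expect_error(simulate_bm_traits(tr, matrix(c(1, 2, 2, 1), 2), c(0, 0)),
               "semi-definite")
  expect_error(simulate_bm_traits(tr, matrix(c(1, 2, 0, 1), 2), c(0, 0)),
               "symmetric")
})

test_that("shifted-OU simulation obeys its closed-form moments", {
  tr <- simulate_tree(16, 1, 4)
  geom <- morphoshift:::tree_geometry(tr)

  # alpha -> 0: OU covariance collapses to BM (checked on the kernel)
  V_ou <- morphoshift:::ou_cov0(geom, 1e-8)
  expect_lt(max(abs(V_ou - ape::vcv.phylo(tr))), 1e-4)

  # noise-free limit equals the deterministic OU expectation
  sizes <- lengths(geom$desc)
  e <- which(sizes == 4)[1]
  skip_if(is.na(e))
  sh <- list(list(edge = e, delta = 10))
  Y <- simulate_shifted_ou_traits(tr, 3, 1e-12, 0, sh, seed = 1)
  W <- shift_design_matrix(tr, 3)
  theta <- attr(Y, "edge_optima")
  mu <- as.vector(W %*% theta[, 1])  # root optimum 0
  expect_lt(max(abs(Y[, 1] - mu)), 1e-4)

  # a +10 shift on a 4-tip clade separates it in every replicate
  inn <- geom$desc[[e]]
  for (r in 1:100) {
    Yr <- simulate_shifted_ou_traits(tr, 3, 0.01, 0, sh, seed = 100 + r)
    expect_gt(mean(Yr[inn, 1]) - mean(Yr[-inn, 1]), 5)
  }

  expect_error(simulate_shifted_ou_traits(tr, -1, 1, 0, list()), "alpha")
  expect_error(simulate_shifted_ou_traits(tr, 1, -1, 0, list()), "sigma2")
})

test_that("OU stationary variance approaches sigma2 / (2 alpha) on a deep tree", {
  tr <- two_tip_tree(depth = 50)
  alpha <- 0.8; sigma2 <- 1.6
  tips <- vapply(1:2000, function(r)
    simulate_shifted_ou_traits(tr, alpha, sigma2, 0, list(), seed = r)[1, 1],
    numeric(1))
  want <- sigma2 / (2 * alpha)
  se <- want * sqrt(2 / 2000)
  expect_lt(abs(var(tips) - want), 3 * se)
})

test_that("landmark generator masks the requested fraction and respects pairs", {
  tr <- simulate_tree(50, 1, 9)
  tp <- morphoshift:::default_template(30)

  ds0 <- simulate_landmark_dataset(tr, tp$shape, rate = 0.001,
                                   missing_fraction = 0,
                                   bilateral_pairs = tp$pairs,
                                   midline = tp$midline, seed = 1)
  expect_false(any(ds0$mask))

  ds <- simulate_landmark_dataset(tr, tp$shape, rate = 0.001,
                                  missing_fraction = 0.05,
                                  bilateral_pairs = tp$pairs,
                                  midline = tp$midline, seed = 2)
  n_masked <- sum(ds$mask)
  expect_lt(abs(n_masked - 75), 4 * sqrt(75))
  for (i in seq_len(nrow(tp$pairs)))
    expect_false(any(ds$mask[, tp$pairs[i, 1]] & ds$mask[, tp$pairs[i, 2]]))

  expect_error(simulate_landmark_dataset(tr, tp$shape,
                                         missing_fraction = 0.25),
               "missing_fraction")
})

test_that("rate-zero landmark data reduce to the template after GPA", {
  tr <- simulate_tree(8, 1, 3)
  tp <- morphoshift:::default_template(12)
  ds <- simulate_landmark_dataset(tr, tp$shape, rate = 0, seed = 6)
  al <- gpa_align(ds)
  for (i in 1:8)
    expect_lt(procrustes_distance(al$aligned[i, , ], tp$shape), 1e-8)
})

test_that("every generator is seed-deterministic", {
  tr <- simulate_tree(12, 1, 11)
  expect_identical(simulate_bm_traits(tr, diag(1, 2), c(0, 0), seed = 3),
                   simulate_bm_traits(tr, diag(1, 2), c(0, 0), seed = 3))
  sh <- list(list(edge = 2, delta = c(1, 1)))
  expect_identical(
    simulate_shifted_ou_traits(tr, c(1, 1), c(1, 1), c(0, 0), sh, seed = 4),
    simulate_shifted_ou_traits(tr, c(1, 1), c(1, 1), c(0, 0), sh, seed = 4))
  tp <- morphoshift:::default_template(12)
  d1 <- simulate_landmark_dataset(tr, tp$shape, rate = 0.01,
                                  missing_fraction = 0.04,
                                  bilateral_pairs = tp$pairs,
                                  midline = tp$midline, seed = 5)
  d2 <- simulate_landmark_dataset(tr, tp$shape, rate = 0.01,
                                  missing_fraction = 0.04,
                                  bilateral_pairs = tp$pairs,
                                  midline = tp$midline, seed = 5)
  expect_identical(d1$coords, d2$coords)
  expect_identical(d1$mask, d2$mask)
  s1 <- simulate_dataset(n_tips = 12, seed = 9)
  s2 <- simulate_dataset(n_tips = 12, seed = 9)
  expect_identical(s1$traits, s2$traits)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("simulated datasets satisfy their structural invariants", {
  s <- simulate_dataset(n_tips = 20, n_shifts = 2, seed = 13)
  expect_true(ape::is.ultrametric(s$tree, tol = 1e-8))
  ne <- nrow(s$tree$edge)
  for (sh in s$true_shifts) expect_true(sh$edge >= 1 && sh$edge <= ne)
  expect_identical(rownames(s$traits), s$tree$tip.label)
})

test_that("simulated datasets round-trip through the writers", {
  s <- simulate_dataset(n_tips = 8, n_landmarks = 10, seed = 3)
  dir <- withr::local_tempdir()
  write_simulated_dataset(s, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "landmarks.csv",
                                               "traits.csv", "truth.json")))))
  tr2 <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr2$tip.label, s$tree$tip.label)
  expect_equal(unname(ape::cophenetic.phylo(tr2)[s$tree$tip.label,
                                                 s$tree$tip.label]),
               unname(ape::cophenetic.phylo(s$tree)), tolerance = 1e-8)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$shifts$edge, vapply(s$true_shifts, `[[`, numeric(1),
                                         "edge"))
})
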