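test_that("AICc reproduces the published multivariate model-fit values", {
  # n = tips x traits: 202 x 3 = 606 (cranium), 191 x 4 = 764 (mandible)
  expect_equal(aicc(-1476.06, 9, 606), 2970.42, tolerance = 0.01)
  expect_equal(aicc(-1456.83, 10, 606), 2934.03, tolerance = 0.01)
  expect_equal(aicc(-1476.06, 15, 606), 2982.93, tolerance = 0.01)
  expect_equal(aicc(-1333.007, 45, 606), 2763.41, tolerance = 0.01)
  expect_equal(aicc(-1626.32, 24, 764), 3302.26, tolerance = 0.01)
  expect_equal(aicc(-1386.46, 80, 764), 2951.89, tolerance = 0.01)
  # delta between early burst and the adaptive-landscape model
  expect_equal(aicc(-1456.83, 10, 606) - aicc(-1333.007, 45, 606), 170.62,
               tolerance = 0.02)
  expect_error(aicc(-10, 9, 10), "n_obs")
})

test_that("parameter counts match the model structures", {
  tr <- simulate_tree(24, 1, 14)
  Y3 <- simulate_bm_traits(tr, diag(1, 3), seed = 1)
  Y4 <- simulate_bm_traits(tr, diag(1, 4), seed = 2)
  expect_equal(fit_bm(tr, Y3)$k, 9)
  expect_equal(fit_bm(tr, Y4)$k, 14)
  expect_equal(fit_eb(tr, Y3)$k, 10)
  expect_equal(fit_eb(tr, Y4)$k, 15)
  expect_equal(fit_ou1(tr, Y3, n_restarts = 1)$k, 15)
  expect_equal(fit_ou1(tr, Y4, n_restarts = 1)$k, 24)

  # 12-regime diagonal multi-peak OU at p = 3: 36 optima + root + alpha +
  # sigma2 per trait = 45
  tr64 <- simulate_tree(64, 1, 15)
  geom <- morphoshift:::tree_geometry(tr64)
  internal <- which(lengths(geom$desc) >= 2)
  set.seed(3)
  edges11 <- sort(sample(internal, 11))
  pt <- painting_from_shifts(tr64, edges11)
  expect_length(pt$states, 12)
  Y64 <- simulate_bm_traits(tr64, diag(1, 3), seed = 4)
  om <- fit_oum(tr64, Y64, pt, alpha_structure = "diagonal")
  expect_equal(om$k, 45)
  expect_equal(om$regimes, 12L)

  # symmetric structure on 3 regimes at p = 3: 9 optima + 6 + 6 = 21
  pt3 <- painting_from_shifts(tr64, edges11[1:2])
  om3 <- fit_oum(tr64, Y64, pt3, alpha_structure = "symmetric",
                 n_restarts = 1)
  expect_equal(om3$k, 21)
})

test_that("the BM fit matches a hand-evaluated density on two tips", {
  tr <- two_tip_tree(2)
  y <- matrix(c(1.2, -0.4), 2, 1, dimnames = list(c("A", "B"), NULL))
  fit <- fit_bm(tr, y)
  a <- mean(y)
  s2 <- sum((y - a)^2) / (2 * 2)  # GLS rate with C = 2 I
  V <- 2 * s2 * diag(2)
  ll_hand <- -log(2 * pi) - 0.5 * log(det(V)) -
    0.5 * sum((y - a)^2) / (2 * s2)
  expect_equal(fit$loglik, ll_hand, tolerance = 1e-10)
  expect_equal(fit$params$anc, a, tolerance = 1e-12)
})

test_that("early-burst nests Brownian motion and is recoverable", {
  tr <- simulate_tree(32, 1, 5)
  Y <- simulate_bm_traits(tr, diag(c(1, 0.5)), seed = 6)
  bm <- fit_bm(tr, Y)
  eb <- fit_eb(tr, Y)
  expect_gte(eb$loglik, bm$loglik - 1e-8)

  wins <- 0
  for (r in 1:50) {
    tr_r <- simulate_tree(128, 1, 700 + r)
    C_eb <- (exp(-3 * ape::vcv.phylo(tr_r)) - 1) / (-3)
    tr_eb <- tr_r
    # transform branch lengths so BM on the transformed tree is EB(r = -3)
    ages <- ape::node.depth.edgelength(tr_r)
    f <- function(t) (exp(-3 * t) - 1) / (-3)
    tr_eb$edge.length <- f(ages[tr_r$edge[, 2]]) - f(ages[tr_r$edge[, 1]])
    Yr <- simulate_bm_traits(tr_eb, diag(c(1, 1)), seed = r)
    if (fit_eb(tr_r, Yr)$aicc < fit_bm(tr_r, Yr)$aicc) wins <- wins + 1
  }
  expect_gte(wins, 40)
})

test_that("single-optimum OU nests BM and collapses correctly at p = 1", {
  tr <- simulate_tree(24, 1, 8)
  Y <- simulate_bm_traits(tr, diag(1, 2), seed = 3)
  bm <- fit_bm(tr, Y)
  ou <- fit_ou1(tr, Y, n_restarts = 2)
  expect_gte(ou$loglik, bm$loglik - 1e-6)

  # p = 1: single-state multi-peak fit with the root at the optimum agrees
  # with the global OU fit
  y1 <- simulate_shifted_ou_traits(tr, 5, 1, 0.5, list(), seed = 4)
  ou1 <- fit_ou1(tr, y1, n_restarts = 3)
  pt1 <- painting_from_shifts(tr, integer(0))
  om1 <- fit_oum(tr, y1, pt1, alpha_structure = "symmetric", n_restarts = 3)
  expect_lt(abs(ou1$loglik - om1$loglik), 1e-3)
})

test_that("strong attraction is recovered within a factor of two", {
  alpha_true <- 8
  hits <- 0
  for (r in 1:20) {
    tr <- simulate_tree(64, 1, 810 + r)
    y <- simulate_shifted_ou_traits(tr, alpha_true, 2, 0, list(),
                                    seed = 300 + r)
    fit <- fit_ou1(tr, y, n_restarts = 2)
    a_hat <- fit$params$A[1, 1]
    if (a_hat > alpha_true / 2 && a_hat < alpha_true * 2) hits <- hits + 1
  }
  expect_gte(hits, 14)
})

test_that("multi-peak OU recovers planted regime optima", {
  tr <- simulate_tree(64, 1, 9)
  geom <- morphoshift:::tree_geometry(tr)
  e <- which(lengths(geom$desc) >= 12 & lengths(geom$desc) <= 20)[1]
  skip_if(is.na(e))
  stat_sd <- sqrt(1 / (2 * 3))
  hits <- 0
  for (r in 1:25) {
    Y <- simulate_shifted_ou_traits(tr, c(3, 3), c(1, 1), c(0, 0),
                                    list(list(edge = e, delta = rep(4 * stat_sd, 2))),
                                    seed = 40 + r)
    om <- fit_oum(tr, Y, painting_from_shifts(tr, e),
                  alpha_structure = "diagonal")
    opt <- om$params$optima  # regimes x p, regime 1 = root, 2 = shifted
    if (all(abs(opt[2, ] - 4 * stat_sd) < 2 * stat_sd)) hits <- hits + 1
  }
  expect_gte(hits, 20)

  # a painting with an uncovered regime warns
  pt <- painting_from_shifts(tr, e)
  pt$states <- c(pt$states, "ghost")
  Y <- simulate_bm_traits(tr, diag(1, 2), seed = 3)
  expect_warning(fit_oum(tr, Y, pt, alpha_structure = "diagonal"), "ghost")
})

test_that("stochastic character maps match pruning-algorithm posteriors", {
  # all tips in one state: the painting is constant
  tr <- simulate_tree(8, 1, 10)
  same <- setNames(rep("u", 8), tr$tip.label)
  sm0 <- simmap(tr, same, n_maps = 3, seed = 1)
  for (p_ in sm0$paintings)
    expect_true(all(vapply(p_$maps, function(m)
      identical(names(m), "u"), logical(1))))

  # 4-tip tree, 2 states: node marginals against the pruning oracle
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- setNames(c("0", "1", "0", "1"), c("A", "B", "C", "D"))
  n_maps <- 1500
  sm <- simmap(t4, x, model = "ER", n_maps = n_maps, seed = 7)
  # state at each internal node = state of the first segment of its child
  node_states <- sapply(sm$paintings, function(p_) {
    vapply(4 + (1:3), function(v) {
      e <- which(t4$edge[, 1] == v)[1]
      names(p_$maps[[e]])[1]
    }, character(1))
  })
  freq1 <- rowMeans(node_states == "1")
  marg <- oracle_mk_marginals(t4, sm$Q, x, sm$root_prior)
  se <- sqrt(pmax(marg[, 2] * (1 - marg[, 2]), 1e-4) / n_maps)
  expect_true(all(abs(freq1 - marg[, 2]) < 3 * se + 0.02))

  expect_error(simmap(tr, same[1:4], n_maps = 2), "state")
  expect_equal(formals(simmap)$n_maps, 100)
})

test_that("model comparison tables rank and summarize correctly", {
  tr <- simulate_tree(48, 1, 31)
  geom <- morphoshift:::tree_geometry(tr)
  e <- which(lengths(geom$desc) >= 10 & lengths(geom$desc) <= 20)[1]
  stat_sd <- sqrt(1 / 4)
  Y <- simulate_shifted_ou_traits(tr, c(2, 2), c(1, 1), c(0, 0),
                                  list(list(edge = e, delta = rep(6 * stat_sd, 2))),
                                  seed = 3)
  fits <- list(BM = fit_bm(tr, Y), EB = fit_eb(tr, Y),
               OU1 = fit_ou1(tr, Y, n_restarts = 2),
               OUM = fit_oum(tr, Y, painting_from_shifts(tr, e),
                             alpha_structure = "diagonal"))
  cmp <- compare_models(fits)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$dAICc[1], 0)
  expect_identical(cmp$model[1], "OUM")  # generating family wins

  # distribution summaries: median (min, max) across maps
  fl <- list(fit_bm(tr, Y), fit_bm(tr, Y + 0.01), fit_bm(tr, Y - 0.01))
  cmp2 <- compare_models(list(BM = fits$BM, BMdist = fl))
  row <- cmp2[cmp2$model == "BMdist", ]
  expect_true(row$logL_min <= row$logL && row$logL <= row$logL_max)

  expect_error(compare_models(list(a = fits$BM,
                                   b = fit_bm(tr, Y[, 1, drop = FALSE]))),
               "identical data")
})
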