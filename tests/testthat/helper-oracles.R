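# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Partial Procrustes distance for planar (z = 0) shapes by grid search over
# the in-plane rotation angle, refined to ~1e-9.
oracle_planar_procrustes <- function(a, b) {
  cs <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- cs(a); b <- cs(b)
  best_for <- function(bb) {
    f <- function(th) {
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      sqrt(sum((a - bb %*% R)^2))
    }
    grid <- seq(0, 2 * pi, length.out = 3600)
    vals <- vapply(grid, f, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    optimize(f, c(lo, hi), tol = 1e-12)$objective
  }
  # a det +1 rotation in 3D can flip a planar shape within its plane, so
  # the 2D search must cover both orientations of b
  min(best_for(b), best_for(b %*% diag(c(1, -1, 1))))
}

# Multivariate-normal log density with covariance sigma2 * C (BM, known
# root): the alpha -> 0 oracle for the OU likelihood.
oracle_bm_loglik <- function(tree, y, sigma2, root) {
  C <- ape::vcv.phylo(tree)
  V <- sigma2 * C
  n <- length(y)
  ch <- chol(V)
  z <- backsolve(ch, y - root, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(z^2) / 2
}

# Exact marginal posterior state probabilities at internal nodes of a tree
# under an Mk model, by Felsenstein pruning (down partials) plus an upward
# pass, with root prior pi0.
oracle_mk_marginals <- function(tree, Q, tip_states, pi0) {
  states <- rownames(Q)
  ns <- length(states)
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  eg <- eigen(Q)
  Pmat <- function(t) {
    P <- Re(eg$vectors %*% diag(exp(eg$values * t), ns) %*% solve(eg$vectors))
    pmax(P, 0)
  }
  children <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <- c(children[[tree$edge[e, 1]]],
                                     list(c(tree$edge[e, 2], e)))
  down <- matrix(NA_real_, nn, ns)
  for (i in seq_len(nt)) down[i, ] <- as.numeric(states == tip_states[tree$tip.label[i]])
  post <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  order_nodes <- unique(rev(ape::reorder.phylo(tree, "postorder")$edge[, 1]))
  for (v in rev(order_nodes)) {
    down[v, ] <- 1
    for (ch in children[[v]]) {
      P <- Pmat(tree$edge.length[ch[2]])
      down[v, ] <- down[v, ] * as.vector(P %*% down[ch[1], ])
    }
  }
  # upward pass
  up <- matrix(NA_real_, nn, ns)
  root <- nt + 1L
  up[root, ] <- pi0
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e_i in seq_len(nrow(pre))) {
    par <- pre[e_i, 1]; v <- pre[e_i, 2]
    if (v <= nt) next
    e <- which(tree$edge[, 1] == par & tree$edge[, 2] == v)
    sib_part <- up[par, ]
    for (ch in children[[par]]) {
      if (ch[1] == v) next
      P <- Pmat(tree$edge.length[ch[2]])
      sib_part <- sib_part * as.vector(P %*% down[ch[1], ])
    }
    P <- Pmat(tree$edge.length[e])
    up[v, ] <- as.vector(t(P) %*% sib_part)
  }
  marg <- down * up
  marg <- marg / rowSums(marg)
  rownames(marg) <- NULL
  marg[(nt + 1):nn, , drop = FALSE]
}

# Exhaustive tanglegram optimum: minimum over all rotation assignments of
# both structures of the sum of squared matched-position differences.
# Independent recursion over ape edge lists.
oracle_untangle_min <- function(tree, dend) {
  ord_with_flips <- function(phy, flips) {
    nt <- ape::Ntip(phy)
    kids <- vector("list", nt + phy$Nnode)
    pre <- ape::reorder.phylo(phy, "cladewise")$edge
    for (e in seq_len(nrow(pre)))
      kids[[pre[e, 1]]] <- c(kids[[pre[e, 1]]], pre[e, 2])
    rec <- function(v) {
      if (v <= nt) return(phy$tip.label[v])
      kk <- kids[[v]]
      if (flips[v - nt]) kk <- rev(kk)
      unlist(lapply(kk, rec))
    }
    rec(nt + 1L)
  }
  nA <- tree$Nnode; nB <- dend$Nnode
  best <- Inf
  for (ia in seq_len(2^nA) - 1L) {
    fA <- as.logical(bitwAnd(ia, 2^(seq_len(nA) - 1L)) > 0)
    oa <- ord_with_flips(tree, fA)
    pa <- setNames(seq_along(oa), oa)
    for (ib in seq_len(2^nB) - 1L) {
      fB <- as.logical(bitwAnd(ib, 2^(seq_len(nB) - 1L)) > 0)
      ob <- ord_with_flips(dend, fB)
      obj <- sum((pa[ob] - seq_along(ob))^2)
      if (obj < best) best <- obj
    }
  }
  best
}

# Deterministic OU tip expectation by numerical integration of
# dm/dt = alpha (theta(t) - m) along each root-to-tip path (deSolve).
oracle_ou_expectation <- function(tree, alpha, shifts, root_optimum) {
  geom <- morphoshift:::tree_geometry(tree)
  theta_edges <- morphoshift:::edge_optima(
    tree, lapply(seq_along(shifts), function(i)
      list(edge = shifts[[i]]$edge, delta = shifts[[i]]$delta)),
    root_optimum)
  vapply(seq_len(geom$n_tips), function(tip) {
    m <- root_optimum
    for (e in geom$paths[[tip]]) {
      th <- theta_edges[e, 1]
      f <- function(t, y, parms) list(alpha * (th - y))
      sol <- deSolve::ode(y = m, times = c(0, tree$edge.length[e]), func = f,
                          parms = NULL, rtol = 1e-12, atol = 1e-12)
      m <- sol[nrow(sol), 2]
    }
    m
  }, numeric(1))
}
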