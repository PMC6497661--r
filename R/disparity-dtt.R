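# Disparity-through-time with mean pairwise Procrustes distance, the MDI
# statistic, and its one-sided simulation p-value under multivariate BM.

#' Mean pairwise Procrustes disparity of a set of shapes
#'
#' @param shapes members x k x 3 array (a singleton has disparity 0).
#' @return Non-negative scalar.
#' @export
subclade_disparity <- function(shapes) {
  if (length(dim(shapes)) != 3 || dim(shapes)[1] < 1)
    stop("`shapes` must be a non-empty members x k x 3 array", call. = FALSE)
  m <- dim(shapes)[1]
  if (m == 1) return(0)
  D <- pairwise_procrustes(shapes)
  mean(D[upper.tri(D)])
}

# Disparity of a tip subset from a precomputed pairwise matrix.
subset_disparity <- function(D, idx) {
  if (length(idx) < 2) return(0)
  sub <- D[idx, idx]
  mean(sub[upper.tri(sub)])
}

#' Evolutionary rate matrix by GLS
#'
#' Multivariate BM rate matrix estimate R = (X-1a')' C^-1 (X-1a') / n with
#' a the GLS root estimate; eigenvalues are clipped at zero so the estimate
#' is positive semi-definite.
#'
#' @param tree `phylo`; tips must match rows of `traits`.
#' @param traits species x m matrix (row names = species).
#' @return List of class `rate_matrix_estimate` with `R` and root `anc`.
#' @export
estimate_rate_matrix <- function(tree, traits) {
  ms_assert_phylo(tree)
  X <- flatten_shapes(traits)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- ape::vcv.phylo(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  a <- as.vector(colSums(Cinv %*% X) / sum(Cinv))
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, Cinv %*% Xc) / n
  R <- (R + t(R)) / 2
  eg <- eigen(R, symmetric = TRUE)
  R_psd <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  structure(list(R = (R_psd + t(R_psd)) / 2, anc = a,
                 sqrt = eg$vectors %*% (sqrt(pmax(eg$values, 0)) *
                                          t(eg$vectors))),
            class = "rate_matrix_estimate")
}

# times (relative node ages, root first) for a DTT evaluation grid.
dtt_times <- function(tree) {
  nt <- ape::Ntip(tree)
  ages <- node_ages(tree)
  h <- max(ages[seq_len(nt)])
  sort(unique(ages[(nt + 1):(nt + tree$Nnode)])) / h
}

# Observed relative-disparity curve from a precomputed distance matrix.
dtt_curve_from_dist <- function(tree, D) {
  nt <- ape::Ntip(tree)
  ages <- node_ages(tree)
  h <- max(ages[seq_len(nt)])
  rel <- ages / h
  times <- dtt_times(tree)
  total <- subset_disparity(D, seq_len(nt))
  if (total <= 1e-10)
    stop("total disparity is zero; DTT undefined", call. = FALSE)
  desc <- edge_descendant_tips(tree)
  t_start <- rel[tree$edge[, 1]]
  t_end <- rel[tree$edge[, 2]]
  vals <- numeric(length(times))
  vals[1] <- 1
  if (length(times) > 1) {
    for (ti in seq(2, length(times))) {
      t <- times[ti]
      crossing <- which(t_start <= t & t_end > t)
      vals[ti] <- mean(vapply(crossing, function(e)
        subset_disparity(D, desc[[e]]), numeric(1))) / total
    }
  }
  list(times = times, disparity = vals)
}

#' Disparity-through-time curve
#'
#' For each internal-node age (mapped to relative time in [0, 1]) the
#' lineages crossing that time are found; the curve value is the mean of
#' their subclade disparities divided by the whole-clade disparity, and
#' equals 1 at the root by construction.
#'
#' @param tree Ultrametric `phylo`.
#' @param mean_shapes species x k x 3 array of aligned shapes (dimnames
#'   matching tip labels) or species x m trait matrix.
#' @param metric `"procrustes"` (mean pairwise Procrustes distance, the
#'   default) or `"avg.sq"` (mean squared pairwise Euclidean distance, the
#'   classical variant).
#' @return List with `times` and `disparity`.
#' @export
dtt_curve <- function(tree, mean_shapes, metric = c("procrustes", "avg.sq")) {
  ms_assert_ultrametric(tree)
  metric <- match.arg(metric)
  D <- disparity_dist(mean_shapes, metric, tree$tip.label)
  dtt_curve_from_dist(tree, D)
}

disparity_dist <- function(mean_shapes, metric, tip_order = NULL) {
  if (metric == "procrustes") {
    if (length(dim(mean_shapes)) != 3)
      stop("Procrustes disparity needs species x k x 3 shapes", call. = FALSE)
    D <- pairwise_procrustes(mean_shapes)
  } else {
    X <- flatten_shapes(mean_shapes)
    D <- as.matrix(dist(X))^2
  }
  if (!is.null(tip_order) && !is.null(rownames(D)))
    D <- D[tip_order, tip_order]
  D
}

# Signed area between two curves on a common grid (trapezoid rule),
# optionally truncated to the first `truncate` fraction of relative time.
mdi_statistic <- function(times, obs, ref, truncate = 1) {
  keep <- times <= truncate + 1e-12
  t <- times[keep]; d <- (obs - ref)[keep]
  if (length(t) < 2) return(0)
  sum(diff(t) * (head(d, -1) + d[-1]) / 2)
}

#' MDI test against a Brownian-motion null
#'
#' Estimates the evolutionary rate matrix of the (3k-dimensional) shape
#' coordinates, simulates `n_sim` landmark datasets under multivariate BM on
#' the tree, and computes each disparity-through-time curve with the same
#' disparity metric. The morphological disparity index (MDI) is the signed
#' area between a curve and the median simulated curve; negative values
#' indicate disparity established early. The one-sided p-value is the
#' fraction of simulated MDIs at or below the observed MDI (ties counted as
#' lower).
#'
#' @inheritParams dtt_curve
#' @param n_sim Number of BM simulations (>= 100; the tanglegram analysis
#'   convention of 1000 is the default).
#' @param seed Integer seed.
#' @param truncate Fraction of relative time over which MDI is integrated
#'   (1 = full range).
#' @return Object of class `dtt_result`.
#' @export
mdi_test <- function(tree, mean_shapes, n_sim = 1000, seed = 1,
                     metric = c("procrustes", "avg.sq"), truncate = 1) {
  ms_assert_ultrametric(tree)
  metric <- match.arg(metric)
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)
  X <- flatten_shapes(mean_shapes)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  k <- if (length(dim(mean_shapes)) == 3) dim(mean_shapes)[2] else NULL

  obs <- dtt_curve(tree, mean_shapes, metric)
  times <- obs$times

  est <- estimate_rate_matrix(tree, X)
  C <- ape::vcv.phylo(tree)
  Lc <- t(chol(C))
  S <- est$sqrt
  sims <- matrix(NA_real_, n_sim, length(times))
  with_seed(seed, {
    for (b in seq_len(n_sim)) {
      Z <- matrix(rnorm(n * m), n, m)
      Xs <- rep(1, n) %o% est$anc + Lc %*% Z %*% t(S)
      shapes_s <- if (!is.null(k))
        array(Xs, c(n, k, 3)) else Xs
      D <- disparity_dist(shapes_s, metric)
      sims[b, ] <- dtt_curve_from_dist(tree, D)$disparity
    }
  })
  med <- apply(sims, 2, median)
  lo <- apply(sims, 2, quantile, probs = 0.025)
  hi <- apply(sims, 2, quantile, probs = 0.975)
  mdi_obs <- mdi_statistic(times, obs$disparity, med, truncate)
  mdi_sim <- vapply(seq_len(n_sim), function(b)
    mdi_statistic(times, sims[b, ], med, truncate), numeric(1))
  p <- mean(mdi_sim <= mdi_obs)
  structure(list(times = times, observed = obs$disparity,
                 simulated = sims, median_sim = med,
                 envelope = cbind(lower = lo, upper = hi),
                 mdi = mdi_obs, mdi_sim = mdi_sim, p_value = p,
                 n_sim = n_sim, metric = metric, truncate = truncate),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf("DTT: MDI = %.4g, one-sided p = %.4g (%d BM simulations, %s disparity)\n",
              x$mdi, x$p_value, x$n_sim, x$metric))
  invisible(x)
}

#' Plot a disparity-through-time result
#'
#' Observed curve as a solid line, median simulated curve dashed, 95%
#' envelope as a gray polygon.
#'
#' @param x A `dtt_result`.
#' @param ... Passed to `plot`.
#' @export
plot.dtt_result <- function(x, ...) {
  graphics::plot(x$times, x$observed, type = "n",
                 xlab = "relative time", ylab = "relative disparity",
                 ylim = range(0, x$observed, x$envelope), ...)
  graphics::polygon(c(x$times, rev(x$times)),
                    c(x$envelope[, "lower"], rev(x$envelope[, "upper"])),
                    col = "grey85", border = NA)
  graphics::lines(x$times, x$median_sim, lty = 2)
  graphics::lines(x$times, x$observed, lwd = 2)
  invisible(x)
}
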