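# Morphospace construction: standard and phylogenetically corrected PCA,
# parallel-analysis axis retention, and absolute-variation R^2 per axis.

new_morphospace <- function(scores, loadings, eigenvalues, correction,
                            anc_mean = NULL, center = NULL) {
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eigenvalues, r2 = NULL, n_critical = NA_integer_,
                 correction = correction, anc_mean = anc_mean,
                 center = center),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("morphospace (%s): %d species x %d axes\n",
              x$correction, nrow(x$scores), ncol(x$scores)))
  rel <- x$eigenvalues / sum(x$eigenvalues)
  cat("  leading eigenvalue shares:",
      paste(sprintf("%.3f", head(rel, 5)), collapse = " "), "\n")
  if (!is.na(x$n_critical)) cat("  critical axes:", x$n_critical, "\n")
  invisible(x)
}

flatten_shapes <- function(x) {
  if (length(dim(x)) == 3) {
    out <- cbind(x[, , 1], x[, , 2], x[, , 3])
    rownames(out) <- dimnames(x)[[1]]
    out
  } else as.matrix(x)
}

# Fix each loading column so its largest-magnitude entry is positive.
canonical_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Phylogenetic principal component analysis
#'
#' PCA of the evolutionary (GLS-corrected) covariance matrix under Brownian
#' motion: with C the BM tip covariance, the ancestral mean is
#' a = (1'C^-1 1)^-1 1'C^-1 X, the evolutionary covariance
#' R = (X-1a')' C^-1 (X-1a') / (n-1) is eigendecomposed, and scores are
#' (X-1a') V.
#'
#' @param mean_shapes species x 3k matrix (or species x k x 3 array); row
#'   names must match the tree's tip labels.
#' @param tree Ultrametric or non-ultrametric `phylo`.
#' @return A `morphospace` with `correction = "phylogenetic"`.
#' @export
ppca <- function(mean_shapes, tree) {
  X <- flatten_shapes(mean_shapes)
  ms_assert_phylo(tree)
  if (is.null(rownames(X)))
    stop("`mean_shapes` must carry species row names", call. = FALSE)
  unmatched <- c(setdiff(rownames(X), tree$tip.label),
                 setdiff(tree$tip.label, rownames(X)))
  if (length(unmatched))
    stop("species/tip mismatch: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X)
  C <- ape::vcv.phylo(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance matrix", call. = FALSE))
  one <- rep(1, n)
  a <- as.vector(crossprod(one, Cinv %*% X) / sum(Cinv))
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  p <- min(n - 1, ncol(X))
  V <- eg$vectors[, seq_len(p), drop = FALSE]
  scores <- Xc %*% V
  fixed <- canonical_signs(V, scores)
  colnames(fixed$scores) <- colnames(fixed$loadings) <-
    sprintf("pPC%d", seq_len(p))
  rownames(fixed$scores) <- rownames(X)
  new_morphospace(fixed$scores, fixed$loadings,
                  pmax(eg$values[seq_len(p)], 0), "phylogenetic",
                  anc_mean = a)
}

#' Standard principal component analysis of mean shapes
#'
#' @param mean_shapes species x 3k matrix (or species x k x 3 array).
#' @return A `morphospace` with `correction = "none"`.
#' @export
pca <- function(mean_shapes) {
  X <- flatten_shapes(mean_shapes)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 species", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  p <- min(n - 1, ncol(X))
  V <- eg$vectors[, seq_len(p), drop = FALSE]
  scores <- Xc %*% V
  fixed <- canonical_signs(V, scores)
  colnames(fixed$scores) <- colnames(fixed$loadings) <-
    sprintf("PC%d", seq_len(p))
  rownames(fixed$scores) <- rownames(X)
  new_morphospace(fixed$scores, fixed$loadings,
                  pmax(eg$values[seq_len(p)], 0), "none", center = ctr)
}

#' Parallel analysis for axis retention
#'
#' Horn's method: columns of the (GLS-whitened, when a tree is supplied)
#' data are independently permuted `n_perm` times; axes are retained while
#' the observed eigenvalue exceeds the chosen quantile of the permuted
#' eigenvalues at the same rank, stopping at the first failure.
#'
#' @param data species x 3k matrix (rows named by species when `tree` given).
#' @param tree Optional `phylo` for phylogenetic whitening.
#' @param n_perm Number of permutations (>= 100).
#' @param quantile_prob Null quantile in (0, 1), default 0.95.
#' @param seed Integer seed.
#' @param permute `"whitened"` (default, the null respects the tree) or
#'   `"raw"`.
#' @return Integer `n_critical`, with the observed eigenvalues and null
#'   quantiles attached as attributes.
#' @export
parallel_analysis <- function(data, tree = NULL, n_perm = 100,
                              quantile_prob = 0.95, seed = 1,
                              permute = c("whitened", "raw")) {
  permute <- match.arg(permute)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (quantile_prob <= 0 || quantile_prob >= 1)
    stop("`quantile_prob` must be in (0, 1)", call. = FALSE)
  X <- flatten_shapes(data)
  n <- nrow(X)
  if (!is.null(tree) && permute == "whitened") {
    X <- X[tree$tip.label, , drop = FALSE]
    C <- ape::vcv.phylo(tree)
    eg <- eigen(C, symmetric = TRUE)
    W <- eg$vectors %*% (1 / sqrt(eg$values) * t(eg$vectors))  # C^{-1/2}
    Cinv <- eg$vectors %*% (1 / eg$values * t(eg$vectors))
    a <- as.vector(colSums(Cinv %*% X) / sum(Cinv))
    X <- W %*% sweep(X, 2, a)
  } else {
    X <- sweep(X, 2, colMeans(X))
  }
  p <- min(n - 1, ncol(X))
  ev_obs <- eigen(crossprod(X) / (n - 1), symmetric = TRUE,
                  only.values = TRUE)$values[seq_len(p)]
  null_ev <- matrix(NA_real_, n_perm, p)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- apply(X, 2, sample)
      Xp <- sweep(Xp, 2, colMeans(Xp))
      null_ev[b, ] <- eigen(crossprod(Xp) / (n - 1), symmetric = TRUE,
                            only.values = TRUE)$values[seq_len(p)]
    }
  })
  thr <- apply(null_ev, 2, quantile, probs = quantile_prob)
  keep <- ev_obs > thr
  n_critical <- if (!keep[1]) 0L else
    (which(c(!keep, TRUE))[1] - 1L)
  structure(as.integer(n_critical), eigenvalues = ev_obs, threshold = thr)
}

#' Absolute shape variation explained per axis
#'
#' Multiple regression of the full coordinate matrix on all score columns;
#' the per-axis R^2 is the sequential (type-I) sum of squares for that axis
#' divided by the total sum of squares over all coordinates. For standard
#' PCA scores this equals eigenvalue / trace.
#'
#' @param aligned_shapes species x 3k matrix (or array), row-matched to
#'   `scores`.
#' @param scores species x p score matrix.
#' @return Length-p numeric vector of R^2 values.
#' @export
axis_variance_r2 <- function(aligned_shapes, scores) {
  Y <- flatten_shapes(aligned_shapes)
  scores <- as.matrix(scores)
  stopifnot(nrow(Y) == nrow(scores))
  D <- cbind(1, scores)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient scores", call. = FALSE)
  Q <- qr.Q(qrD)
  B <- crossprod(Q, Y)                    # projections onto successive axes
  ss_axis <- rowSums(B^2)[-1]             # drop intercept
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  r2 <- ss_axis / ss_tot
  names(r2) <- colnames(scores)
  r2
}

#' Scale morphospace scores
#'
#' Elementwise multiplication (conventionally by 100 before evolutionary
#' model fitting, to keep estimated rates away from numerical zero);
#' downstream model ranking is invariant to the factor.
#'
#' @param scores Score matrix.
#' @param factor Non-zero scalar.
#' @return Scaled scores.
#' @export
scale_scores <- function(scores, factor = 100) {
  if (!is.numeric(factor) || length(factor) != 1 || factor == 0)
    stop("`factor` must be a single non-zero number", call. = FALSE)
  scores * factor
}
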