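# Adaptive-zone shift detection: per-trait Ornstein-Uhlenbeck models with a
# shared set of shift branches, searched by a group lasso over branch
# optima and scored by phylogenetic BIC, with parametric-bootstrap support.
#
# Each trait j evolves under OU with attraction alpha_j, diffusion
# sigma2_j, and a branch-wise optimum painting induced by the shift set.
# The root state equals the root optimum (stationary-root convention), so
# for an ultrametric tree a shift of size beta on branch s moves every
# descendant tip mean by beta * (1 - exp(-alpha (T - t_start(s)))).

#' Search settings for shift detection
#'
#' @param max_shifts Cap on the number of shifts considered (50 is the
#'   full-tree convention, 20 the subclade convention).
#' @param criterion `"pbic"` (default) or `"bic"`.
#' @param n_bootstrap Bootstrap replicates for support values.
#' @param n_candidates Cap on candidate supports taken from the lasso path.
#' @param nlambda,lambda_min_ratio Lasso path: `nlambda` points spanning
#'   four decades below the smallest penalty with empty support.
#' @param alpha_bounds Search bounds for the per-trait attraction, as a
#'   multiple of 1/tree height; default c(1e-6, 50).
#' @param seed Integer seed (used only by the bootstrap).
#' @return List of class `search_settings`.
#' @export
search_settings <- function(max_shifts = 50, criterion = c("pbic", "bic"),
                            n_bootstrap = 100, n_candidates = 30,
                            nlambda = 50, lambda_min_ratio = 1e-4,
                            alpha_bounds = c(1e-6, 50), seed = 1) {
  criterion <- match.arg(criterion)
  stopifnot(max_shifts >= 0, n_candidates >= 1)
  structure(list(max_shifts = max_shifts, criterion = criterion,
                 n_bootstrap = n_bootstrap, n_candidates = n_candidates,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 alpha_bounds = alpha_bounds, seed = seed),
            class = "search_settings")
}

# Unit-rate OU tip covariance (fixed root): V0[i,j] =
# exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)) / (2 alpha), d = patristic
# distance, t = MRCA depth. alpha -> 0 recovers the BM covariance t_ij.
ou_cov0 <- function(geom, alpha) {
  ta <- geom$ta
  d <- 2 * (geom$height - ta)
  exp(-alpha * d) * ta * expm1_ratio(2 * alpha * ta)
}

#' OU mean design matrix over branches
#'
#' Entry (i, b) is `exp(-alpha (T - t_end(b))) - exp(-alpha (T - t_start(b)))`
#' when branch b lies on the root-to-tip-i path and 0 otherwise; the OU tip
#' mean is this matrix times the per-branch optima plus
#' `exp(-alpha T) * root state`.
#'
#' @param tree Ultrametric `phylo`.
#' @param alpha Positive attraction strength.
#' @return tips x branches matrix.
#' @export
shift_design_matrix <- function(tree, alpha) {
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  geom <- tree_geometry(tree)
  W <- matrix(0, geom$n_tips, geom$n_edges)
  w_edge <- exp(-alpha * (geom$height - geom$t_end)) -
    exp(-alpha * (geom$height - geom$t_start))
  for (e in seq_len(geom$n_edges)) W[geom$desc[[e]], e] <- w_edge[e]
  rownames(W) <- geom$tree$tip.label
  W
}

# Telescoped per-shift design: column s is
# ind(tip below s) * (1 - exp(-alpha (T - t_start(s)))).
shift_columns <- function(geom, edges, alpha) {
  U <- matrix(0, geom$n_tips, length(edges))
  for (i in seq_along(edges)) {
    e <- edges[i]
    U[geom$desc[[e]], i] <- 1 - exp(-alpha * (geom$height - geom$t_start[e]))
  }
  U
}

# Profile log-likelihood of one trait given alpha and a shift support;
# optima by GLS, sigma2 profiled out.
ou_profile_once <- function(geom, y, edges, alpha) {
  n <- geom$n_tips
  V0 <- ou_cov0(geom, alpha)
  R <- chol(V0)
  D <- cbind(1, shift_columns(geom, edges, alpha))
  yw <- backsolve(R, y, transpose = TRUE)
  Dw <- backsolve(R, D, transpose = TRUE)
  fit <- qr(Dw)
  if (fit$rank < ncol(Dw)) return(NULL)  # collinear shift columns
  beta <- qr.coef(fit, yw)
  rss <- sum((yw - Dw %*% beta)^2)
  sigma2 <- rss / n
  ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(R))) - n / 2
  list(ll = ll, alpha = alpha, sigma2 = sigma2, theta0 = beta[1],
       beta = beta[-1])
}

# Maximize the per-trait profile likelihood over alpha.
ou_profile_fit <- function(geom, y, edges, alpha_bounds = c(1e-6, 50)) {
  lo <- log(alpha_bounds[1] / geom$height)
  hi <- log(alpha_bounds[2] / geom$height)
  f <- function(la) {
    r <- ou_profile_once(geom, y, edges, exp(la))
    if (is.null(r)) -Inf else r$ll
  }
  # coarse grid then local refinement: the profile can be multimodal
  grid <- seq(lo, hi, length.out = 12)
  vals <- vapply(grid, f, numeric(1))
  if (all(!is.finite(vals))) return(NULL)
  i0 <- which.max(vals)
  opt <- optimize(f, interval = c(grid[max(1, i0 - 1)],
                                  grid[min(length(grid), i0 + 1)]),
                  maximum = TRUE, tol = 1e-7)
  best_la <- if (opt$objective >= vals[i0]) opt$maximum else grid[i0]
  ou_profile_once(geom, y, edges, exp(best_la))
}

# Full refit of a shift support: independent traits, shared support.
fit_shift_support <- function(geom, Y, edges, alpha_bounds = c(1e-6, 50)) {
  p <- ncol(Y)
  fits <- vector("list", p)
  for (j in seq_len(p)) {
    fits[[j]] <- ou_profile_fit(geom, Y[, j], edges, alpha_bounds)
    if (is.null(fits[[j]])) return(NULL)
  }
  list(edges = edges,
       alpha = vapply(fits, `[[`, numeric(1), "alpha"),
       sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
       root_optima = vapply(fits, `[[`, numeric(1), "theta0"),
       beta = if (length(edges))
         do.call(cbind, lapply(fits, `[[`, "beta")) else
           matrix(0, 0, p),
       loglik = sum(vapply(fits, `[[`, numeric(1), "ll")))
}

#' Multi-peak OU log-likelihood
#'
#' Sum over traits of the Gaussian log-likelihood with covariance
#' `V_j[i,i'] = (sigma2_j / (2 alpha_j)) exp(-alpha_j d_ii') (1 -
#' exp(-2 alpha_j t_ii'))` and the regime-painted OU mean (root state =
#' root optimum).
#'
#' @param tree Ultrametric `phylo`.
#' @param traits species x p matrix in tip-label order (or with row names).
#' @param config List with `alpha`, `sigma2`, `root_optima` (length p) and
#'   `shifts` (list of `list(edge, delta)`) or `edges` + `beta` (s x p).
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(tree, traits, config) {
  geom <- tree_geometry(tree)
  Y <- as.matrix(traits)
  if (!is.null(rownames(Y))) Y <- Y[tree$tip.label, , drop = FALSE]
  if (!all(is.finite(Y))) stop("traits must be finite", call. = FALSE)
  p <- ncol(Y)
  alpha <- config$alpha; sigma2 <- config$sigma2
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  shifts <- config$shifts
  if (is.null(shifts) && !is.null(config$edges)) {
    beta <- config$beta
    shifts <- lapply(seq_along(config$edges), function(i)
      list(edge = config$edges[i], delta = beta[i, ]))
  }
  if (is.null(shifts)) shifts <- list()
  theta <- edge_optima(tree, shifts, config$root_optima)
  ll <- 0
  for (j in seq_len(p)) {
    W <- shift_design_matrix(tree, alpha[j])
    mu <- as.vector(W %*% theta[, j]) +
      exp(-alpha[j] * geom$height) * config$root_optima[j]
    V <- sigma2[j] * ou_cov0(geom, alpha[j])
    R <- chol(V)
    z <- backsolve(R, Y[, j] - mu, transpose = TRUE)
    ll <- ll - geom$n_tips / 2 * log(2 * pi) - sum(log(diag(R))) -
      sum(z^2) / 2
  }
  ll
}

# Criterion scores ------------------------------------------------------

# pBIC: -2 logL + placement charge + sum_j [2 log n +
# log det(D' Vcorr_j^-1 D)].
#
# The placement charge prices the search over branches: each shift is a
# p-dimensional optimum change selected as the best of m = #branches
# candidates, so it is charged the extreme-value scale of the largest of m
# chi-square(p) statistics, 2 log m + p + 2 sqrt(2 p log m), per shift.
# The information term uses the 0/1 shift-membership design (plus
# intercept) under the correlation form of the OU covariance: invariant to
# trait rescaling, strictly positive at zero shifts, and non-degenerate
# when a candidate's attraction estimate collapses to the lower bound
# (where the alpha-weighted design has near-zero columns).
pbic_penalty <- function(geom, fit) {
  s <- length(fit$edges)
  n <- geom$n_tips
  p <- length(fit$alpha)
  m <- geom$n_edges
  U0 <- matrix(0, n, s)
  for (i in seq_len(s)) U0[geom$desc[[fit$edges[i]]], i] <- 1
  pen <- s * (2 * log(m) + p + 2 * sqrt(2 * p * log(m)))
  for (j in seq_len(p)) {
    V0 <- ou_cov0(geom, fit$alpha[j])
    Vc <- stats::cov2cor(V0)
    D <- cbind(1, U0)
    M <- crossprod(D, solve(Vc, D))
    ld <- determinant(M, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)  # collinear shift membership: discard
    pen <- pen + 2 * log(n) + as.numeric(ld$modulus)
  }
  pen
}

bic_penalty <- function(geom, fit) {
  s <- length(fit$edges)
  p <- length(fit$alpha)
  k <- 3 * p + s * p + s   # alpha, sigma2, root optimum per trait;
                           # s*p optimum changes; s shift placements
  k * log(geom$n_tips * p)
}

#' Score a fitted shift configuration
#'
#' @param tree Ultrametric `phylo`.
#' @param traits species x p matrix used for the fit.
#' @param configuration A `shift_configuration` (refit by ML).
#' @param criterion `"pbic"` or `"bic"`.
#' @return Scalar score (smaller is better).
#' @export
pbic_score <- function(tree, traits, configuration,
                       criterion = c("pbic", "bic")) {
  criterion <- match.arg(criterion)
  geom <- tree_geometry(tree)
  pen <- if (criterion == "pbic") pbic_penalty(geom, configuration)
  else bic_penalty(geom, configuration)
  -2 * configuration$loglik + pen
}

# Candidate support collection ------------------------------------------

# Drop the higher-indexed member of any sister pair in a support (a shift
# on both children of one node is unidentifiable against a shift on the
# parent / a root-state change).
prune_sisters <- function(tree, edges) {
  if (length(edges) < 2) return(edges)
  parents <- tree$edge[edges, 1]
  drop <- logical(length(edges))
  for (pp in unique(parents[duplicated(parents)])) {
    idx <- which(parents == pp)
    drop[idx[-1]] <- TRUE
  }
  edges[!drop]
}

#' Detect adaptive-zone shifts
#'
#' Phase 1: a shared search attraction (geometric mean of the per-trait
#' no-shift ML estimates) whitens the data and the branch design, and a
#' lasso path (group penalty across traits) proposes candidate shift-branch
#' supports up to `max_shifts`. Phase 2: every candidate (plus the empty
#' support) is refit by maximum likelihood per trait and scored with the
#' selection criterion; the best-scoring configuration is returned, ties
#' broken toward fewer shifts.
#'
#' @param tree Ultrametric `phylo`.
#' @param scores species x p matrix of (conventionally x100-scaled) axis
#'   scores, row names matching tip labels.
#' @param settings A `search_settings` object.
#' @return Object of class `shift_configuration`.
#' @export
detect_shifts <- function(tree, scores, settings = search_settings()) {
  geom <- tree_geometry(tree)
  Y <- as.matrix(scores)
  if (is.null(rownames(Y)))
    stop("`scores` must carry species row names", call. = FALSE)
  un <- c(setdiff(rownames(Y), tree$tip.label),
          setdiff(tree$tip.label, rownames(Y)))
  if (length(un)) stop("species/tip mismatch: ", paste(un, collapse = ", "),
                       call. = FALSE)
  Y <- Y[tree$tip.label, , drop = FALSE]
  p <- ncol(Y)
  n <- geom$n_tips

  fit0 <- fit_shift_support(geom, Y, integer(0), settings$alpha_bounds)
  alpha_search <- exp(mean(log(fit0$alpha)))

  V0 <- ou_cov0(geom, alpha_search)
  Rw <- chol(V0)
  X <- shift_columns(geom, seq_len(geom$n_edges), alpha_search)
  Xw <- backsolve(Rw, X, transpose = TRUE)
  Yw <- backsolve(Rw, Y, transpose = TRUE)
  onew <- backsolve(Rw, rep(1, n), transpose = TRUE)

  fam <- if (p > 1) "mgaussian" else "gaussian"
  # the root-optimum term is the whitened all-ones column, left unpenalized;
  # glmnet's own intercept is disabled (it would be constant in whitened space)
  gl <- glmnet::glmnet(cbind(onew, Xw), Yw, family = fam,
                       nlambda = settings$nlambda,
                       lambda.min.ratio = settings$lambda_min_ratio,
                       intercept = FALSE, standardize = TRUE,
                       penalty.factor = c(0, rep(1, ncol(Xw))))
  cf <- glmnet::coef.glmnet(gl)
  if (p == 1) cf <- list(cf)
  supports <- list(integer(0))
  for (l in seq_len(length(gl$lambda))) {
    nz <- sort(unique(unlist(lapply(cf, function(cc)
      which(abs(cc[-(1:2), l]) > 0)))))
    nz <- prune_sisters(tree, nz)
    if (length(nz) == 0 || length(nz) > settings$max_shifts) next
    if (!any(vapply(supports, identical, logical(1), nz)))
      supports[[length(supports) + 1L]] <- nz
    if (length(supports) >= settings$n_candidates + 1) break
  }

  cache <- new.env(parent = emptyenv())
  score_support <- function(su) {
    key <- paste0("s", paste(su, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    ft <- fit_shift_support(geom, Y, su, settings$alpha_bounds)
    out <- if (is.null(ft)) list(fit = NULL, score = Inf)
    else list(fit = ft, score = -2 * ft$loglik +
                (if (settings$criterion == "pbic") pbic_penalty(geom, ft)
                 else bic_penalty(geom, ft)))
    cache[[key]] <- out
    out
  }

  scored <- lapply(supports, score_support)
  keep <- !vapply(scored, function(x) is.null(x$fit), logical(1))
  scored <- scored[keep]
  supports <- supports[keep]

  # backward refinement: the lasso path can carry redundant branches that
  # mask a sparser, better-scoring configuration, so each of the leading
  # non-empty candidates is pruned branch-by-branch while the score improves
  refine <- function(start) {
    cur <- start
    repeat {
      if (is.null(cur$fit) || length(cur$fit$edges) == 0) break
      subs <- lapply(seq_along(cur$fit$edges), function(i) cur$fit$edges[-i])
      sub_scored <- lapply(subs, score_support)
      sub_scores <- vapply(sub_scored, `[[`, numeric(1), "score")
      if (min(sub_scores) < cur$score)
        cur <- sub_scored[[which.min(sub_scores)]]
      else break
    }
    cur
  }
  small <- which(lengths(supports) > 0 & lengths(supports) <= 10)
  seeds_ix <- small[order(vapply(scored[small], `[[`, numeric(1), "score"))]
  for (ix in head(seeds_ix, 3)) refine(scored[[ix]])

  keys <- ls(cache)
  all_fits <- lapply(keys, function(k) cache[[k]])
  ok <- !vapply(all_fits, function(x) is.null(x$fit), logical(1))
  all_fits <- all_fits[ok]
  scores_crit <- vapply(all_fits, `[[`, numeric(1), "score")
  sizes <- vapply(all_fits, function(x) length(x$fit$edges), numeric(1))
  pick <- order(scores_crit, sizes)[1]
  best <- all_fits[[pick]]$fit
  best_score <- all_fits[[pick]]$score
  structure(list(edges = best$edges, beta = best$beta,
                 alpha = best$alpha, sigma2 = best$sigma2,
                 root_optima = best$root_optima, loglik = best$loglik,
                 score = best_score,
                 criterion = settings$criterion,
                 loglik_null = fit0$loglik,
                 candidates = data.frame(size = unname(sizes),
                                         score = unname(scores_crit)),
                 support = NULL, settings = settings),
            class = "shift_configuration")
}

#' @export
print.shift_configuration <- function(x, ...) {
  cat(sprintf("shift_configuration: %d shift(s), logL = %.3f, %s = %.3f\n",
              length(x$edges), x$loglik, x$criterion, x$score))
  if (length(x$edges)) {
    df <- data.frame(edge = x$edges, round(x$beta, 3))
    if (!is.null(x$support)) df$support <- x$support
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Parametric-bootstrap support for shift locations
#'
#' Simulates from the fitted shifted-OU model, reruns the shift search, and
#' reports per shift the fraction of replicates whose selected
#' configuration includes that branch. Shifts with support above 0.7 are
#' conventionally called well supported.
#'
#' @param tree Ultrametric `phylo`.
#' @param scores The trait matrix used for the original fit.
#' @param configuration A fitted `shift_configuration`.
#' @param n_bootstrap Replicates (>= 20).
#' @param seed Integer seed.
#' @return The configuration with `$support` filled in (named by edge id).
#' @export
bootstrap_support <- function(tree, scores, configuration,
                              n_bootstrap = 100, seed = 1) {
  if (n_bootstrap < 20) stop("`n_bootstrap` must be >= 20", call. = FALSE)
  stopifnot(inherits(configuration, "shift_configuration"))
  edges <- configuration$edges
  if (!length(edges)) {
    configuration$support <- numeric(0)
    return(configuration)
  }
  shifts <- lapply(seq_along(edges), function(i)
    list(edge = edges[i], delta = configuration$beta[i, ]))
  hits <- matrix(FALSE, n_bootstrap, length(edges))
  for (b in seq_len(n_bootstrap)) {
    sim <- simulate_shifted_ou_traits(tree, configuration$alpha,
                                      configuration$sigma2,
                                      configuration$root_optima,
                                      shifts, seed = seed + 7919L * b)
    det <- detect_shifts(tree, sim, configuration$settings)
    hits[b, ] <- edges %in% det$edges
  }
  configuration$support <- setNames(colMeans(hits), edges)
  configuration
}

# Regime painting round trip --------------------------------------------

#' Branch regimes induced by a shift set
#'
#' Each branch's regime is its nearest ancestral shift (inclusive), or 0
#' for the root regime.
#'
#' @param tree `phylo`.
#' @param edges Shift edge ids.
#' @return Integer vector over edges: 0 = root regime, i = i-th shift.
#' @export
shifts_to_regimes <- function(tree, edges) {
  ne <- nrow(tree$edge)
  regime <- integer(ne)
  parent_edge <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(ne)
  tr_order <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  eid <- match(paste(tr_order$edge[, 1], tr_order$edge[, 2]), key)
  root <- ape::Ntip(tree) + 1L
  for (i in seq_len(ne)) {
    e <- eid[i]
    par <- tree$edge[e, 1]
    inherited <- if (par == root) 0L else regime[parent_edge[par]]
    regime[e] <- if (e %in% edges) match(e, edges) else inherited
  }
  regime
}

#' Recover the shift set from a regime painting
#'
#' A branch is a shift branch iff its regime differs from its parent's
#' (the root regime is 0).
#'
#' @param tree `phylo`.
#' @param regimes Integer vector over edges as from [shifts_to_regimes()].
#' @return Ordered integer vector of shift edge ids.
#' @export
regimes_to_shifts <- function(tree, regimes) {
  ne <- nrow(tree$edge)
  parent_edge <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(ne)
  root <- ape::Ntip(tree) + 1L
  out <- integer(0)
  for (e in seq_len(ne)) {
    par <- tree$edge[e, 1]
    parent_regime <- if (par == root) 0L else regimes[parent_edge[par]]
    if (regimes[e] != parent_regime) out <- c(out, e)
  }
  sort(out)
}
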