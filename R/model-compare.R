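# Fully multivariate evolutionary model fitting (BM, single-optimum OU,
# early burst, multi-peak OU on a regime painting) compared by AICc, plus
# stochastic character mapping of discrete regimes.

new_model_fit <- function(kind, k, loglik, n_obs, params = list(),
                          regimes = 1L, painting = NULL) {
  ic <- tryCatch(aicc(loglik, k, n_obs), error = function(e) NA_real_)
  structure(list(kind = kind, k = k, loglik = loglik,
                 aicc = ic, n_obs = n_obs,
                 params = params, regimes = regimes, painting = painting),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: k = %d, logL = %.3f, AICc = %.3f\n",
              x$kind, x$k, x$loglik, x$aicc))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n_obs - k - 1)`, with `n_obs` the number
#' of tips times the number of traits.
#'
#' @param logL Log-likelihood.
#' @param k Parameter count.
#' @param n_obs Observation count (> k + 1).
#' @return Scalar AICc.
#' @export
aicc <- function(logL, k, n_obs) {
  if (n_obs <= k + 1)
    stop("`n_obs` must exceed k + 1 for the small-sample correction",
         call. = FALSE)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

check_traits <- function(tree, traits) {
  Y <- as.matrix(traits)
  if (!is.null(rownames(Y))) {
    un <- c(setdiff(rownames(Y), tree$tip.label),
            setdiff(tree$tip.label, rownames(Y)))
    if (length(un)) stop("species/tip mismatch: ",
                         paste(un, collapse = ", "), call. = FALSE)
    Y <- Y[tree$tip.label, , drop = FALSE]
  }
  Y
}

# Profile multivariate-BM log-likelihood for a given tip covariance C:
# GLS root, rate matrix at its ML value.
bm_profile_loglik <- function(C, Y) {
  n <- nrow(Y); p <- ncol(Y)
  R <- chol(C)
  one_w <- backsolve(R, rep(1, n), transpose = TRUE)
  Yw <- backsolve(R, Y, transpose = TRUE)
  a <- as.vector(crossprod(one_w, Yw)) / sum(one_w^2)
  E <- Yw - one_w %o% a
  Rhat <- crossprod(E) / n
  ld <- determinant(Rhat, logarithm = TRUE)
  if (ld$sign <= 0) return(list(ll = -Inf))
  ll <- -n * p / 2 * log(2 * pi) - p * sum(log(diag(R))) -
    n / 2 * as.numeric(ld$modulus) - n * p / 2
  list(ll = ll, anc = a, R = Rhat)
}

#' Fit multivariate Brownian motion
#'
#' ML fit of the root mean and the full symmetric rate matrix;
#' `k = p + p(p+1)/2`.
#'
#' @param tree `phylo`.
#' @param traits species x p matrix.
#' @return A `model_fit`.
#' @export
fit_bm <- function(tree, traits) {
  ms_assert_phylo(tree)
  Y <- check_traits(tree, traits)
  n <- nrow(Y); p <- ncol(Y)
  C <- ape::vcv.phylo(tree)
  pr <- bm_profile_loglik(C, Y)
  k <- p + p * (p + 1) / 2
  new_model_fit("BM", k, pr$ll, n * p,
                params = list(anc = pr$anc, R = pr$R))
}

#' Fit the early-burst model
#'
#' Brownian motion with exponentially decaying rate, decay `r <= 0`; the
#' tip covariance is `C_r[i,j] = (exp(r t_mrca) - 1)/r`. `k = p + p(p+1)/2
#' + 1`.
#'
#' @param tree Ultrametric `phylo`.
#' @param traits species x p matrix.
#' @param r_bounds Decay-rate bounds as multiples of 1/tree height
#'   (default c(-10, 0)).
#' @return A `model_fit`.
#' @export
fit_eb <- function(tree, traits, r_bounds = c(-10, 0)) {
  ms_assert_ultrametric(tree)
  Y <- check_traits(tree, traits)
  n <- nrow(Y); p <- ncol(Y)
  C <- ape::vcv.phylo(tree)
  h <- tree_height(tree)
  ebC <- function(r) {
    if (abs(r) < 1e-12) C else (exp(r * C) - 1) / r
  }
  f <- function(r) bm_profile_loglik(ebC(r), Y)$ll
  opt <- optimize(f, interval = r_bounds / h, maximum = TRUE, tol = 1e-8)
  r <- if (f(0) >= opt$objective) 0 else opt$maximum
  pr <- bm_profile_loglik(ebC(r), Y)
  k <- p + p * (p + 1) / 2 + 1
  new_model_fit("EB", k, pr$ll, n * p,
                params = list(anc = pr$anc, R = pr$R, r = r))
}

# -- multivariate OU machinery ------------------------------------------

# chol-parameter helpers: lower-triangular with log-diagonal
chol_from_par <- function(par, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  L
}

par_from_chol <- function(L) {
  d <- diag(L)
  diag(L) <- log(pmax(d, 1e-12))
  L[lower.tri(L, diag = TRUE)]
}

# np x np fixed-root OU covariance for symmetric A and rate matrix R,
# tips in tree order, trait index fastest.
ou_matrix_cov <- function(geom, A, R) {
  p <- nrow(A)
  eg <- eigen(A, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  Rt <- crossprod(U, R %*% U)
  dd <- outer(d, d, "+")
  Tall <- geom$height
  ta_vals <- sort(unique(as.vector(geom$ta)))
  blocks <- lapply(ta_vals, function(t) {
    psi <- t * matrix(expm1_ratio(dd * t), p, p)
    U %*% (Rt * psi * exp(-dd * (Tall - t))) %*% t(U)
  })
  n <- geom$n_tips
  V <- matrix(0, n * p, n * p)
  idx <- match(geom$ta, ta_vals)
  dim(idx) <- dim(geom$ta)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    B <- blocks[[idx[i, j]]]
    ri <- (i - 1) * p + seq_len(p); rj <- (j - 1) * p + seq_len(p)
    V[ri, rj] <- B
    if (i != j) V[rj, ri] <- t(B)
  }
  V
}

#' Fit a single-optimum multivariate OU model
#'
#' Symmetric attraction matrix A and symmetric rate matrix R (both
#' parametrized by Cholesky factors), fixed root at the optimum;
#' `k = p + p(p+1)`. Brownian motion is nested at the A -> 0 boundary.
#'
#' @param tree Ultrametric `phylo`.
#' @param traits species x p matrix.
#' @param n_restarts Deterministic optimizer restarts.
#' @return A `model_fit`.
#' @export
fit_ou1 <- function(tree, traits, n_restarts = 5) {
  geom <- tree_geometry(tree)
  Y <- check_traits(tree, traits)
  n <- nrow(Y); p <- ncol(Y)
  y <- as.vector(t(Y))
  bm <- fit_bm(tree, traits)
  R0 <- bm$params$R
  L_R0 <- t(chol(R0 + diag(1e-10 * mean(diag(R0)) + 1e-300, p)))
  h <- geom$height
  npar_tri <- p * (p + 1) / 2

  negll <- function(par) {
    theta <- par[seq_len(p)]
    La <- chol_from_par(par[p + seq_len(npar_tri)], p)
    Lr <- chol_from_par(par[p + npar_tri + seq_len(npar_tri)], p)
    A <- tcrossprod(La); R <- tcrossprod(Lr)
    V <- ou_matrix_cov(geom, A, R)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    z <- backsolve(ch, y - rep(theta, n), transpose = TRUE)
    nl <- n * p / 2 * log(2 * pi) + sum(log(diag(ch))) + sum(z^2) / 2
    if (!is.finite(nl)) 1e10 else nl
  }
  theta0 <- bm$params$anc
  a_starts <- c(1e-4, 0.5, 2, 8, 0.1) / h
  best <- NULL
  for (s in seq_len(n_restarts)) {
    a0 <- a_starts[((s - 1) %% length(a_starts)) + 1]
    start <- c(theta0, par_from_chol(diag(sqrt(a0), p)), par_from_chol(L_R0))
    op <- tryCatch(
      optim(start, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("OU1 optimizer failed", call. = FALSE)
  par <- best$par
  theta <- par[seq_len(p)]
  A <- tcrossprod(chol_from_par(par[p + seq_len(npar_tri)], p))
  R <- tcrossprod(chol_from_par(par[p + npar_tri + seq_len(npar_tri)], p))
  ll <- -best$value
  # BM is nested at A -> 0; never report less than the boundary value
  if (ll < bm$loglik) {
    ll <- bm$loglik
    theta <- bm$params$anc
    A <- diag(0, p)
    R <- bm$params$R
  }
  k <- p + p * (p + 1)
  new_model_fit("OU1", k, ll, n * p,
                params = list(theta = theta, A = A, R = R))
}

#' Fit a multi-peak OU model on a regime painting
#'
#' `alpha_structure = "diagonal"` (per-trait independent OU with a free
#' per-trait root state; `k = regimes*p + 3p`, matching the adaptive-
#' landscape convention) or `"symmetric"` (full symmetric attraction and
#' rate matrices with the root state at the basal optimum;
#' `k = regimes*p + p(p+1)`, the stochastic-map model convention).
#'
#' @param tree Ultrametric `phylo`.
#' @param traits species x p matrix.
#' @param painting A `regime_painting`.
#' @param alpha_structure `"diagonal"` or `"symmetric"`.
#' @param n_restarts Restarts for the symmetric optimizer.
#' @param alpha_bounds Per-trait attraction bounds (x 1/height) for the
#'   diagonal fit.
#' @return A `model_fit`.
#' @export
fit_oum <- function(tree, traits, painting,
                    alpha_structure = c("diagonal", "symmetric"),
                    n_restarts = 3, alpha_bounds = c(1e-6, 50)) {
  alpha_structure <- match.arg(alpha_structure)
  geom <- tree_geometry(tree)
  Y <- check_traits(tree, traits)
  n <- nrow(Y); p <- ncol(Y)
  stopifnot(inherits(painting, "regime_painting"))
  states <- painting$states
  nr <- length(states)
  segs <- painting_segments(geom, painting)
  covered <- sort(unique(segs$state))
  if (length(covered) < nr)
    warning("regime(s) with no branch segment: ",
            paste(states[setdiff(seq_len(nr), covered)], collapse = ", "),
            call. = FALSE)

  if (alpha_structure == "diagonal") {
    basal <- painting_root_state(geom, painting)
    fits <- lapply(seq_len(p), function(j)
      oum_profile_fit(geom, Y[, j], segs, nr, alpha_bounds, basal))
    ll <- sum(vapply(fits, `[[`, numeric(1), "ll"))
    k <- nr * p + 3 * p
    new_model_fit("OUM", k, ll, n * p,
                  params = list(
                    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
                    sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
                    optima = do.call(cbind, lapply(fits, `[[`, "optima")),
                    root_state = vapply(fits, `[[`, numeric(1), "root_state")),
                  regimes = nr, painting = painting)
  } else {
    fit <- oum_symmetric_fit(geom, Y, segs, nr, n_restarts)
    k <- nr * p + p * (p + 1)
    new_model_fit("OUM", k, fit$ll, n * p, params = fit$params,
                  regimes = nr, painting = painting)
  }
}

# Flatten a painting into per-tip path segments:
# data.frame(tip, state, t0, t1) in absolute ages.
painting_segments <- function(geom, painting) {
  tree <- geom$tree
  out <- list()
  for (e in seq_len(geom$n_edges)) {
    mp <- painting$maps[[e]]
    t0 <- geom$t_start[e]
    tips <- geom$desc[[e]]
    for (si in seq_along(mp)) {
      t1 <- t0 + mp[si]
      out[[length(out) + 1L]] <- list(
        state = match(names(mp)[si], painting$states),
        t0 = t0, t1 = t1, tips = tips)
      t0 <- t1
    }
  }
  st <- vapply(out, `[[`, numeric(1), "state")
  list(segments = out, state = st)
}

# Root state of a painting = state of the first segment of a root child.
painting_root_state <- function(geom, painting) {
  root <- geom$n_tips + 1L
  e <- which(geom$tree$edge[, 1] == root)[1]
  match(names(painting$maps[[e]])[1], painting$states)
}

# Regime design matrix for one alpha: tips x regimes OU mean weights.
oum_design <- function(geom, segs, nr, alpha) {
  W <- matrix(0, geom$n_tips, nr)
  Tall <- geom$height
  for (sg in segs$segments) {
    w <- exp(-alpha * (Tall - sg$t1)) - exp(-alpha * (Tall - sg$t0))
    W[sg$tips, sg$state] <- W[sg$tips, sg$state] + w
  }
  W
}

# Per-trait OUM profile fit with free root state; `basal` is the regime
# holding the root (used when the root-state column is collinear with it
# at small alpha).
oum_profile_fit <- function(geom, y, segs, nr, alpha_bounds, basal = 1L) {
  n <- geom$n_tips
  f_once <- function(alpha) {
    V0 <- ou_cov0(geom, alpha)
    R <- chol(V0)
    W <- oum_design(geom, segs, nr, alpha)
    keep_r <- colSums(abs(W)) > 1e-12
    D <- cbind(exp(-alpha * geom$height), W[, keep_r, drop = FALSE])
    yw <- backsolve(R, y, transpose = TRUE)
    Dw <- backsolve(R, D, transpose = TRUE)
    qf <- qr(Dw)
    drop_root <- qf$rank < ncol(Dw)
    if (drop_root) {
      Dw <- Dw[, -1, drop = FALSE]
      qf <- qr(Dw)
      if (qf$rank < ncol(Dw)) return(NULL)
    }
    co <- qr.coef(qf, yw)
    rss <- sum(qr.resid(qf, yw)^2)
    sigma2 <- rss / n
    if (!is.finite(sigma2) || sigma2 <= 0) return(NULL)
    ll <- -n / 2 * log(2 * pi * sigma2) - sum(log(diag(R))) - n / 2
    optima <- numeric(nr)
    optima[keep_r] <- if (drop_root) co else co[-1]
    root_state <- if (drop_root) optima[basal] else co[1]
    list(ll = ll, alpha = alpha, sigma2 = sigma2,
         root_state = root_state, optima = optima)
  }
  lo <- log(alpha_bounds[1] / geom$height)
  hi <- log(alpha_bounds[2] / geom$height)
  f <- function(la) {
    r <- f_once(exp(la))
    if (is.null(r)) -Inf else r$ll
  }
  grid <- seq(lo, hi, length.out = 12)
  vals <- vapply(grid, f, numeric(1))
  i0 <- which.max(vals)
  opt <- optimize(f, interval = c(grid[max(1, i0 - 1)],
                                  grid[min(length(grid), i0 + 1)]),
                  maximum = TRUE, tol = 1e-7)
  best_la <- if (opt$objective >= vals[i0]) opt$maximum else grid[i0]
  f_once(exp(best_la))
}

# Symmetric-structure OUM: optimize A, R Cholesky factors; optima by GLS.
oum_symmetric_fit <- function(geom, Y, segs, nr, n_restarts) {
  n <- geom$n_tips; p <- ncol(Y)
  y <- as.vector(t(Y))
  npar_tri <- p * (p + 1) / 2
  h <- geom$height
  root_state <- segs$segments[[1]]$state
  Tall <- geom$height

  design_big <- function(A) {
    eg <- eigen(A, symmetric = TRUE)
    U <- eg$vectors; d <- pmax(eg$values, 0)
    G <- matrix(0, n * p, nr * p)
    for (sg in segs$segments) {
      M <- U %*% (diag(exp(-d * (Tall - sg$t1)) - exp(-d * (Tall - sg$t0)),
                       p) %*% t(U))
      cols <- (sg$state - 1) * p + seq_len(p)
      for (tip in sg$tips) {
        rows <- (tip - 1) * p + seq_len(p)
        G[rows, cols] <- G[rows, cols] + M
      }
    }
    # root state at the basal optimum
    M0 <- U %*% (diag(exp(-d * Tall), p) %*% t(U))
    cols <- (root_state - 1) * p + seq_len(p)
    for (tip in seq_len(n)) {
      rows <- (tip - 1) * p + seq_len(p)
      G[rows, cols] <- G[rows, cols] + M0
    }
    G
  }

  negll <- function(par) {
    La <- chol_from_par(par[seq_len(npar_tri)], p)
    Lr <- chol_from_par(par[npar_tri + seq_len(npar_tri)], p)
    A <- tcrossprod(La); R <- tcrossprod(Lr)
    V <- ou_matrix_cov(geom, A, R)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    G <- design_big(A)
    yw <- backsolve(ch, y, transpose = TRUE)
    Gw <- backsolve(ch, G, transpose = TRUE)
    qf <- qr(Gw)
    rss <- sum(qr.resid(qf, yw)^2)
    nl <- n * p / 2 * log(2 * pi) + sum(log(diag(ch))) + rss / 2
    if (!is.finite(nl)) 1e10 else nl
  }
  bm_R <- bm_profile_loglik(ape::vcv.phylo(geom$tree), Y)$R
  L_R0 <- t(chol(bm_R + diag(1e-10 * mean(diag(bm_R)) + 1e-300, p)))
  a_starts <- c(0.5, 2, 8) / h
  best <- NULL
  for (s in seq_len(n_restarts)) {
    a0 <- a_starts[((s - 1) %% length(a_starts)) + 1]
    start <- c(par_from_chol(diag(sqrt(a0), p)), par_from_chol(L_R0))
    op <- tryCatch(optim(start, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-10)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("OUM optimizer failed", call. = FALSE)
  La <- chol_from_par(best$par[seq_len(npar_tri)], p)
  Lr <- chol_from_par(best$par[npar_tri + seq_len(npar_tri)], p)
  A <- tcrossprod(La); R <- tcrossprod(Lr)
  V <- ou_matrix_cov(geom, A, R)
  ch <- chol(V)
  G <- design_big(A)
  theta <- qr.coef(qr(backsolve(ch, G, transpose = TRUE)),
                   backsolve(ch, y, transpose = TRUE))
  list(ll = -best$value,
       params = list(A = A, R = R,
                     optima = matrix(theta, nr, p, byrow = TRUE)))
}

# -- stochastic character mapping ---------------------------------------

#' Construct a regime painting
#'
#' @param tree `phylo`.
#' @param maps List (one element per edge row) of named numeric vectors:
#'   segment durations from parent to child, names = states.
#' @param states Character state set.
#' @param source `"simmap"`, `"shifts"` or `"simulated"`.
#' @return Object of class `regime_painting`.
#' @export
regime_painting <- function(tree, maps, states, source = "simmap") {
  stopifnot(length(maps) == nrow(tree$edge))
  lens <- vapply(maps, sum, numeric(1))
  if (max(abs(lens - tree$edge.length)) > 1e-6 * max(tree$edge.length))
    stop("painting segments do not cover the branches", call. = FALSE)
  structure(list(maps = maps, states = states, source = source),
            class = "regime_painting")
}

#' Regime painting induced by a shift configuration
#'
#' @param tree `phylo`.
#' @param edges Shift edge ids (or a `shift_configuration`).
#' @return A `regime_painting` with states `regime_0` (root) and
#'   `regime_<i>` per shift.
#' @export
painting_from_shifts <- function(tree, edges) {
  if (inherits(edges, "shift_configuration")) edges <- edges$edges
  reg <- shifts_to_regimes(tree, edges)
  states <- c("regime_0", if (length(edges)) sprintf("regime_%d", seq_along(edges)))
  maps <- lapply(seq_len(nrow(tree$edge)), function(e)
    setNames(tree$edge.length[e], states[reg[e] + 1L]))
  regime_painting(tree, maps, states, source = "shifts")
}

#' Stochastic character mapping
#'
#' Fits the Mk transition-rate matrix by maximum likelihood under the given
#' model and samples joint character histories conditional on the tip
#' states (via phytools' simmap machinery), with the root prior set to the
#' stationary distribution of the fitted rate matrix.
#'
#' @param tree `phylo`.
#' @param tip_states Named character vector (every tip present, every state
#'   observed at >= 1 tip).
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param n_maps Number of sampled histories (>= 1; 100 is conventional).
#' @param seed Integer seed.
#' @return List of class `simmap_paintings`: `paintings` (list of
#'   `regime_painting`), fitted `Q`, `root_prior`, `logL`.
#' @export
simmap <- function(tree, tip_states, model = c("ER", "SYM", "ARD"),
                   n_maps = 100, seed = 1) {
  model <- match.arg(model)
  ms_assert_phylo(tree)
  if (n_maps < 1) stop("`n_maps` must be >= 1", call. = FALSE)
  x <- tip_states[tree$tip.label]
  if (any(is.na(x))) stop("every tip needs a state", call. = FALSE)
  states <- sort(unique(as.character(x)))
  if (length(states) < 1) stop("no states observed", call. = FALSE)
  sm <- with_seed(seed, {
    if (length(states) == 1) {
      NULL  # single state: trivial painting below
    } else if (model == "ARD") {
      pre <- suppressMessages(phytools::make.simmap(tree, x, model = model,
                                                    nsim = 1, message = FALSE))
      pi0 <- stationary_dist(pre$Q)
      suppressMessages(phytools::make.simmap(tree, x, model = model,
                                             nsim = n_maps, pi = pi0,
                                             message = FALSE))
    } else {
      suppressMessages(phytools::make.simmap(tree, x, model = model,
                                             nsim = n_maps, message = FALSE))
    }
  })
  if (length(states) == 1) {
    maps <- lapply(tree$edge.length, function(l) setNames(l, states))
    paintings <- replicate(n_maps,
                           regime_painting(tree, maps, states, "simmap"),
                           simplify = FALSE)
    Q <- matrix(0, 1, 1, dimnames = list(states, states))
    return(structure(list(paintings = paintings, Q = Q, root_prior = 1,
                          logL = 0), class = "simmap_paintings"))
  }
  if (n_maps == 1) sm <- list(sm)
  paintings <- lapply(sm, function(m)
    regime_painting(tree, reorder_maps(tree, m), states, "simmap"))
  Q <- sm[[1]]$Q
  structure(list(paintings = paintings, Q = Q,
                 root_prior = stationary_dist(Q),
                 logL = attr(sm[[1]], "logL") %||% sm[[1]]$logL),
            class = "simmap_paintings")
}

# Match a simmap tree's $maps to the input tree's edge row order.
reorder_maps <- function(tree, smap) {
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  ks <- paste(smap$edge[, 1], smap$edge[, 2])
  smap$maps[match(key, ks)]
}

#' Compare fitted evolutionary models
#'
#' Accepts single `model_fit` objects and lists of fits (one per stochastic
#' map); for the latter, log-likelihood/AICc/delta-AICc are summarized as
#' median (min, max) across maps, the convention for models fit over a
#' distribution of character histories.
#'
#' @param fits Named list; each element a `model_fit` or a list of them.
#' @return A `data.frame` of class `model_comparison` ordered by AICc.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  n_obs <- unique(unlist(lapply(fits, function(f)
    if (inherits(f, "model_fit")) f$n_obs else
      vapply(f, `[[`, numeric(1), "n_obs"))))
  if (length(n_obs) != 1)
    stop("fits are not on identical data (n_obs differs)", call. = FALSE)
  summarize <- function(f) {
    if (inherits(f, "model_fit"))
      list(kind = f$kind, regimes = f$regimes, k = f$k,
           logL = f$loglik, logL_min = NA, logL_max = NA,
           aicc = f$aicc, aicc_min = NA, aicc_max = NA)
    else {
      ll <- vapply(f, `[[`, numeric(1), "loglik")
      ac <- vapply(f, `[[`, numeric(1), "aicc")
      list(kind = f[[1]]$kind, regimes = f[[1]]$regimes, k = f[[1]]$k,
           logL = median(ll), logL_min = min(ll), logL_max = max(ll),
           aicc = median(ac), aicc_min = min(ac), aicc_max = max(ac))
    }
  }
  rows <- lapply(fits, summarize)
  df <- data.frame(
    model = names(fits),
    kind = vapply(rows, `[[`, character(1), "kind"),
    regimes = vapply(rows, function(r) as.integer(r$regimes), integer(1)),
    k = vapply(rows, function(r) as.numeric(r$k), numeric(1)),
    logL = vapply(rows, `[[`, numeric(1), "logL"),
    logL_min = vapply(rows, function(r) as.numeric(r$logL_min), numeric(1)),
    logL_max = vapply(rows, function(r) as.numeric(r$logL_max), numeric(1)),
    AICc = vapply(rows, `[[`, numeric(1), "aicc"),
    AICc_min = vapply(rows, function(r) as.numeric(r$aicc_min), numeric(1)),
    AICc_max = vapply(rows, function(r) as.numeric(r$aicc_max), numeric(1)))
  best <- min(df$AICc)
  df$dAICc <- df$AICc - best
  df <- df[order(df$AICc), ]
  rownames(df) <- NULL
  class(df) <- c("model_comparison", "data.frame")
  df
}
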