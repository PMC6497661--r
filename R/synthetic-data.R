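# Synthetic-data generators with known ground truth. Every downstream stage
# of the pipeline is testable against these without external specimen data.

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Generates a pure-birth tree with `n_tips` extant tips, rescales its total
#' depth to 1 (the relative-time axis used by disparity-through-time), and
#' labels tips `sp_0001 ...`. The same seed always yields the same tree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object of depth 1.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (!is.numeric(n_tips) || length(n_tips) != 1 || n_tips < 2)
    stop("`n_tips` must be a single integer >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("`birth_rate` must be positive", call. = FALSE)
  n_tips <- as.integer(n_tips)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  h <- tree_height(tree)
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp_%04d", seq_len(n_tips))
  tree
}

#' Simulate correlated Brownian-motion traits on a tree
#'
#' Per-branch increments are multivariate normal with covariance
#' (branch length x `rate_matrix`); tip values are the root state plus the
#' summed increments along the root-to-tip path.
#'
#' @param tree `phylo` with branch lengths.
#' @param rate_matrix p x p symmetric positive semi-definite rate matrix.
#' @param root_state Length-p root state (default zeros).
#' @param seed Integer seed.
#' @return species x p matrix, rows in tip-label order.
#' @export
simulate_bm_traits <- function(tree, rate_matrix, root_state = NULL, seed = 1) {
  ms_assert_phylo(tree)
  rate_matrix <- as.matrix(rate_matrix)
  p <- nrow(rate_matrix)
  if (!isSymmetric(unname(rate_matrix), tol = 1e-8))
    stop("`rate_matrix` must be symmetric", call. = FALSE)
  ev <- eigen(rate_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`rate_matrix` must be positive semi-definite", call. = FALSE)
  if (is.null(root_state)) root_state <- numeric(p)
  stopifnot(length(root_state) == p)
  L <- psd_sqrt(rate_matrix)
  nt <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  states <- matrix(0, nt + tree$Nnode, p)
  states[nt + 1L, ] <- root_state
  with_seed(seed, {
    z <- matrix(rnorm(nrow(tr$edge) * p), nrow(tr$edge), p)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      states[ch, ] <- states[par, ] +
        sqrt(tr$edge.length[e]) * as.vector(L %*% z[e, ])
    }
  })
  out <- states[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate traits under a multi-peak Ornstein-Uhlenbeck process
#'
#' Each trait evolves independently under OU with per-trait attraction
#' `alpha` and diffusion `sigma2`. The optimum along a branch is the root
#' optimum plus the summed optimum changes on ancestral shift branches
#' (inclusive of the shift branch itself). The root state equals the root
#' optimum.
#'
#' @param tree Ultrametric `phylo`.
#' @param alpha,sigma2 Length-p positive vectors.
#' @param root_optima Length-p root optimum (default zeros).
#' @param shifts List of shifts, each `list(edge = <edge row id>,
#'   delta = <length-p optimum change>)`.
#' @param seed Integer seed.
#' @return species x p matrix in tip-label order, with the per-edge optimum
#'   matrix attached as attribute `"edge_optima"`.
#' @export
simulate_shifted_ou_traits <- function(tree, alpha, sigma2, root_optima = NULL,
                                       shifts = list(), seed = 1) {
  ms_assert_phylo(tree)
  p <- length(alpha)
  if (length(sigma2) != p) stop("`alpha` and `sigma2` lengths differ", call. = FALSE)
  if (any(alpha <= 0)) stop("all `alpha` must be positive", call. = FALSE)
  if (any(sigma2 <= 0)) stop("all `sigma2` must be positive", call. = FALSE)
  if (is.null(root_optima)) root_optima <- numeric(p)
  stopifnot(length(root_optima) == p)
  ne <- nrow(tree$edge)
  shift_edges <- vapply(shifts, function(s) as.integer(s$edge), integer(1))
  if (length(shift_edges) && (any(shift_edges < 1) || any(shift_edges > ne)))
    stop("shift edge id outside the tree", call. = FALSE)

  theta <- edge_optima(tree, shifts, root_optima)
  nt <- ape::Ntip(tree)
  tr_order <- ape::reorder.phylo(tree, "cladewise")
  # map reordered edges back to original edge ids
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  eid <- match(paste(tr_order$edge[, 1], tr_order$edge[, 2]), key)
  states <- matrix(0, nt + tree$Nnode, p)
  states[nt + 1L, ] <- root_optima
  with_seed(seed, {
    for (i in seq_len(nrow(tr_order$edge))) {
      e <- eid[i]
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      th <- theta[e, ]
      w <- exp(-alpha * len)
      v <- sigma2 * len * expm1_ratio(2 * alpha * len)
      states[ch, ] <- th + (states[par, ] - th) * w + rnorm(p, 0, sqrt(v))
    }
  })
  out <- states[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  attr(out, "edge_optima") <- theta
  out
}

# Per-edge optimum matrix (edges x p) induced by a shift list.
edge_optima <- function(tree, shifts, root_optima) {
  p <- length(root_optima)
  ne <- nrow(tree$edge)
  delta <- matrix(0, ne, p)
  for (s in shifts) delta[s$edge, ] <- delta[s$edge, ] + s$delta
  theta <- matrix(rep(root_optima, each = ne), ne, p)
  tr_order <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  eid <- match(paste(tr_order$edge[, 1], tr_order$edge[, 2]), key)
  parent_edge <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(ne)
  root <- ape::Ntip(tree) + 1L
  for (i in seq_len(ne)) {
    e <- eid[i]
    par <- tree$edge[e, 1L]
    base <- if (par == root) root_optima else theta[parent_edge[par], ]
    theta[e, ] <- base + delta[e, ]
  }
  theta
}

#' Simulate a landmark dataset with known ground truth
#'
#' Species mean shapes evolve from `template_shape` by isotropic Brownian
#' motion over the tree (rate per coordinate); each specimen is the species
#' shape plus optional digitizing noise, then randomly rotated, translated
#' and scaled (log-normal scale, sd 0.1). A `missing_fraction` of landmark
#' slots is masked uniformly over the non-paired slots plus one member of
#' each bilateral pair, so a bilateral partner is always available for
#' reflected relabeling. Ground-truth (pre-masking, pre-transform)
#' coordinates are kept in `$truth`, and the device-space coordinates
#' before masking in `$truth_coords`.
#'
#' @param tree Ultrametric `phylo`.
#' @param template_shape k x 3 matrix with at least 4 non-coplanar landmarks.
#' @param rate BM rate per coordinate (>= 0).
#' @param missing_fraction Fraction of landmark slots to mask, in [0, 0.2).
#' @param bilateral_pairs Two-column matrix of (left, right) landmark indices.
#' @param midline Integer indices of midline landmarks.
#' @param curves Curve definitions (list of `list(ids, fixed_ends)`).
#' @param specimens_per_species Specimens digitized per species.
#' @param specimen_sd Isotropic digitizing-noise sd added per specimen.
#' @param mean_offsets Optional species x 3k matrix added to the BM
#'   deviations (rows in tip-label order), e.g. planted adaptive-shift
#'   displacements in shape space.
#' @param asymmetry Fluctuating-asymmetry scale: sd of the asymmetric
#'   deviation residual as a fraction of the per-coordinate BM sd (bilateral
#'   variation is otherwise mirrored left-to-right).
#' @param seed Integer seed.
#' @return A `landmark_dataset`.
#' @export
simulate_landmark_dataset <- function(tree, template_shape, rate = 0.001,
                                      missing_fraction = 0,
                                      bilateral_pairs = NULL, midline = NULL,
                                      curves = NULL,
                                      specimens_per_species = 1,
                                      specimen_sd = 0, mean_offsets = NULL,
                                      asymmetry = 0.1, seed = 1) {
  ms_assert_phylo(tree)
  template_shape <- as.matrix(template_shape)
  k <- nrow(template_shape)
  if (k < 4 || qr(scale(template_shape, scale = FALSE))$rank < 3)
    stop("template must have >= 4 non-coplanar landmarks", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 0.2)
    stop("`missing_fraction` must be in [0, 0.2)", call. = FALSE)
  nt <- ape::Ntip(tree)

  dev <- if (rate > 0)
    simulate_bm_traits(tree, diag(rate, 3 * k), numeric(3 * k), seed = seed)
  else matrix(0, nt, 3 * k, dimnames = list(tree$tip.label, NULL))
  if (!is.null(bilateral_pairs) && rate > 0) {
    # bilateral organisms vary (mostly) symmetrically: mirror the left-side
    # deviations onto the right and keep only a small asymmetric residual,
    # so reflected relabeling is a meaningful estimator
    pr <- as.matrix(bilateral_pairs)
    pl <- fit_plane(template_shape[midline %||% seq_len(min(4, k)), ,
                                   drop = FALSE])
    M <- diag(3) - 2 * tcrossprod(pl$normal)
    asym <- with_seed(seed + 3L,
                      matrix(rnorm(nt * 3 * k, 0, asymmetry * sqrt(rate)),
                             nt, 3 * k))
    for (sp in seq_len(nt)) {
      Dm <- matrix(dev[sp, ], k, 3)
      Dm[pr[, 2], ] <- Dm[pr[, 1], , drop = FALSE] %*% M
      if (length(midline))
        Dm[midline, ] <- (Dm[midline, , drop = FALSE] +
                            Dm[midline, , drop = FALSE] %*% M) / 2
      dev[sp, ] <- as.vector(Dm)
    }
    dev <- dev + asym
  }
  if (!is.null(mean_offsets)) {
    stopifnot(identical(dim(mean_offsets), dim(dev)))
    dev <- dev + mean_offsets
  }
  nspec <- nt * specimens_per_species
  species <- rep(tree$tip.label, each = specimens_per_species)
  specimens <- sprintf("%s_s%d", species, rep(seq_len(specimens_per_species), nt))

  truth <- array(NA_real_, c(nspec, k, 3),
                 dimnames = list(specimens, NULL, NULL))
  coords <- truth
  mask <- matrix(FALSE, nspec, k, dimnames = list(specimens, NULL))

  with_seed(seed + 1L, {
    for (i in seq_len(nspec)) {
      sp <- match(species[i], tree$tip.label)
      shape <- template_shape + matrix(dev[sp, ], k, 3)
      if (specimen_sd > 0) shape <- shape + matrix(rnorm(3 * k, 0, specimen_sd), k, 3)
      truth[i, , ] <- shape
      R <- random_rotation()
      s <- exp(rnorm(1, 0, 0.1))
      tr <- runif(3, -1, 1)
      coords[i, , ] <- s * shape %*% R + rep(tr, each = k)
    }
    truth_coords <- coords  # device-space coordinates before masking
    if (missing_fraction > 0) {
      paired <- if (!is.null(bilateral_pairs)) as.matrix(bilateral_pairs) else
        matrix(integer(0), 0, 2)
      for (i in seq_len(nspec)) {
        eligible <- setdiff(seq_len(k), as.vector(paired))
        if (nrow(paired))
          eligible <- c(eligible, ifelse(runif(nrow(paired)) < 0.5,
                                         paired[, 1], paired[, 2]))
        # per-cell probability chosen so the expected masked count is
        # missing_fraction * k (out of k slots), restricted to eligible slots
        pr <- min(1, missing_fraction * k / length(eligible))
        hit <- eligible[runif(length(eligible)) < pr]
        mask[i, hit] <- TRUE
        coords[i, hit, ] <- NA_real_
      }
    }
  })

  out <- landmark_dataset(coords, specimens = specimens, species = species,
                          mask = mask, curves = curves,
                          bilateral_pairs = bilateral_pairs, midline = midline)
  out$truth <- truth
  out$truth_coords <- truth_coords
  out
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Simulate a discrete character under an Mk model
#'
#' Continuous-time Markov chain along each branch; the root state is drawn
#' from the stationary distribution of `Q`.
#'
#' @param tree `phylo` with branch lengths.
#' @param Q Transition rate matrix (rows sum to zero), dimnames = states.
#' @param seed Integer seed.
#' @return Named character vector of tip states, with the per-branch state
#'   history attached as attribute `"history"` (a regime painting).
#' @export
simulate_mk_states <- function(tree, Q, seed = 1) {
  ms_assert_phylo(tree)
  Q <- as.matrix(Q)
  if (max(abs(rowSums(Q))) > 1e-8) stop("rows of Q must sum to 0", call. = FALSE)
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(nrow(Q)))
  nt <- ape::Ntip(tree)
  pi0 <- stationary_dist(Q)
  tr_order <- ape::reorder.phylo(tree, "cladewise")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  eid <- match(paste(tr_order$edge[, 1], tr_order$edge[, 2]), key)
  node_state <- integer(nt + tree$Nnode)
  segs <- vector("list", nrow(tree$edge))
  with_seed(seed, {
    node_state[nt + 1L] <- sample.int(length(states), 1, prob = pi0)
    for (i in seq_len(nrow(tr_order$edge))) {
      e <- eid[i]
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      s <- node_state[par]
      t0 <- 0
      seg <- list()
      repeat {
        rate <- -Q[s, s]
        dt <- if (rate > 0) rexp(1, rate) else Inf
        if (t0 + dt >= len) {
          seg[[length(seg) + 1L]] <- c(s, len - t0)
          break
        }
        seg[[length(seg) + 1L]] <- c(s, dt)
        t0 <- t0 + dt
        others <- setdiff(seq_along(states), s)
        s <- others[sample.int(length(others), 1, prob = pmax(Q[s, others], 0))]
      }
      node_state[ch] <- seg[[length(seg)]][1]
      segs[[e]] <- seg
    }
  })
  tip_states <- setNames(states[node_state[seq_len(nt)]], tree$tip.label)
  maps <- lapply(segs, function(seg) {
    v <- vapply(seg, `[`, numeric(1), 2)
    names(v) <- states[vapply(seg, `[`, numeric(1), 1)]
    v
  })
  attr(tip_states, "history") <- regime_painting(tree, maps, states,
                                                 source = "simulated")
  tip_states
}

stationary_dist <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(numeric(n), 1)
  pi0 <- qr.solve(A, b)
  pmax(pi0, 0) / sum(pmax(pi0, 0))
}

#' Bundle a simulated study with its ground truth
#'
#' Convenience wrapper producing a tree, a landmark dataset, and a
#' low-dimensional trait matrix carrying planted optimum shifts.
#'
#' @param n_tips Tips in the simulated tree.
#' @param n_landmarks Landmarks in the template (>= 4).
#' @param p Trait dimensions for the shifted-OU matrix.
#' @param n_shifts Number of planted shifts.
#' @param shift_size Optimum change expressed in stationary standard
#'   deviations `sqrt(sigma2 / (2 alpha))`.
#' @param alpha,sigma2 Scalar OU parameters recycled over traits.
#' @param missing_fraction Landmark missingness passed to the generator.
#' @param seed Integer seed.
#' @return A list of class `simulated_dataset` with fields `tree`,
#'   `landmarks`, `traits`, `true_shifts`, `seed`.
#' @export
simulate_dataset <- function(n_tips = 64, n_landmarks = 20, p = 3,
                             n_shifts = 2, shift_size = 4, alpha = 3,
                             sigma2 = 1, missing_fraction = 0, seed = 1) {
  tree <- simulate_tree(n_tips, 1, seed)
  geom <- tree_geometry(tree)
  # plant shifts on internal edges subtending 3..n/4 tips, far enough from
  # the tips that descendants actually reach the new optimum
  sizes <- vapply(geom$desc, length, integer(1))
  cand <- which(sizes >= 3 & sizes <= max(3, n_tips %/% 4))
  stat_sd <- sqrt(sigma2 / (2 * alpha))
  shifts <- list()
  if (n_shifts > 0) {
    picked <- with_seed(seed + 17L, sample(cand, min(n_shifts, length(cand))))
    shifts <- lapply(picked, function(e)
      list(edge = e, delta = rep(shift_size * stat_sd, p)))
  }
  traits <- simulate_shifted_ou_traits(tree, rep(alpha, p), rep(sigma2, p),
                                       numeric(p), shifts, seed = seed + 1L)
  template <- default_template(n_landmarks)
  k <- nrow(template$shape)
  rate <- 0.002
  # plant the same shifts in shape space: each shift displaces its clade's
  # mean shape along a random direction, scaled against the BM spread
  offsets <- matrix(0, n_tips, 3 * k)
  if (length(shifts)) {
    dirs <- with_seed(seed + 23L,
                      matrix(rnorm(length(shifts) * 3 * k), length(shifts)))
    for (i in seq_along(shifts)) {
      u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
      tips <- geom$desc[[shifts[[i]]$edge]]
      delta <- (shift_size / 2) * sqrt(3 * k * rate) * u
      offsets[tips, ] <- sweep(offsets[tips, , drop = FALSE], 2, delta, "+")
    }
  }
  lms <- simulate_landmark_dataset(tree, template$shape, rate = rate,
                                   missing_fraction = missing_fraction,
                                   bilateral_pairs = template$pairs,
                                   midline = template$midline,
                                   curves = template$curves,
                                   mean_offsets = offsets,
                                   seed = seed + 2L)
  structure(list(tree = tree, landmarks = lms, traits = traits,
                 true_shifts = shifts, seed = seed),
            class = "simulated_dataset")
}

# A bilaterally symmetric template: a midline arc plus mirrored side points.
default_template <- function(k = 20) {
  stopifnot(k >= 8)
  n_mid <- max(4, k %/% 4)
  n_side <- (k - n_mid) %/% 2
  n_mid <- k - 2 * n_side
  tmid <- seq(0, 1, length.out = n_mid)
  mid <- cbind(tmid, 0, 0.3 * sin(pi * tmid))
  ts <- seq(0.1, 0.9, length.out = n_side)
  left <- cbind(ts, 0.4 + 0.1 * cos(2 * pi * ts), 0.1 * ts)
  right <- left
  right[, 2] <- -right[, 2]
  shape <- rbind(mid, left, right)
  pairs <- cbind(n_mid + seq_len(n_side), n_mid + n_side + seq_len(n_side))
  curves <- list(list(ids = seq_len(n_mid), fixed_ends = TRUE))
  list(shape = shape, pairs = pairs, midline = seq_len(n_mid), curves = curves)
}

#' Write a simulated dataset to disk
#'
#' Writes the tree as Newick, landmarks in the long CSV dialect, traits as
#' CSV, and ground truth (shift edges and optimum changes) as JSON.
#'
#' @param x A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(x, dir) {
  stopifnot(inherits(x, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(x$tree, file.path(dir, "tree.nwk"))
  write_landmarks(x$landmarks, file.path(dir, "landmarks.csv"))
  write.csv(data.frame(species = rownames(x$traits), x$traits),
            file.path(dir, "traits.csv"), row.names = FALSE)
  truth <- lapply(x$true_shifts, function(s)
    list(edge = s$edge, delta = s$delta))
  jsonlite::write_json(list(seed = x$seed, shifts = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
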