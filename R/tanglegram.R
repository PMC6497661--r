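# Morphology dendrogram vs phylogeny: UPGMA clustering, tanglegram
# untangling by node rotation, and the tip-displacement statistic with a
# Brownian-motion null.

#' UPGMA dendrogram from a dissimilarity matrix
#'
#' Average-linkage agglomerative clustering (stats::hclust) returned as an
#' ultrametric `phylo`; node heights are half the cophenetic dissimilarity.
#' Ties in the minimum dissimilarity are broken deterministically by
#' hclust's lowest-index merge rule.
#'
#' @param dist_matrix n x n symmetric matrix with zero diagonal.
#' @return Ultrametric `phylo`.
#' @export
upgma <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-8)
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  if (any(dist_matrix < 0)) stop("dissimilarities must be non-negative",
                                 call. = FALSE)
  hc <- hclust(stats::as.dist(dist_matrix), method = "average")
  ape::as.phylo(hc)
}

#' Tip order of a rooted tree as plotted
#'
#' @param tree `phylo`.
#' @return Character vector of tip labels in plotting (cladewise) order.
#' @export
tip_order <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  tips <- tr$edge[tr$edge[, 2] <= ape::Ntip(tr), 2]
  tr$tip.label[tips]
}

# children (edge list) of every internal node, in cladewise order
node_children <- function(tree) {
  nt <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ch <- vector("list", nt + tree$Nnode)
  for (e in seq_len(nrow(tr$edge)))
    ch[[tr$edge[e, 1]]] <- c(ch[[tr$edge[e, 1]]], tr$edge[e, 2])
  ch
}

# Tip order (tip indices) given per-internal-node flip assignment.
flipped_order <- function(children, root, n_tip, flips) {
  out <- integer(n_tip)
  pos <- 0L
  stack <- list(root)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (node <= n_tip) {
      pos <- pos + 1L
      out[pos] <- node
      next
    }
    kids <- children[[node]]
    if (isTRUE(flips[node - n_tip])) kids <- rev(kids)
    # push in reverse so the first child is processed first
    for (k in rev(kids)) stack[[length(stack) + 1L]] <- k
  }
  out
}

#' Untangle a tanglegram by node rotations
#'
#' Minimizes the sum of squared differences between matched tip positions
#' over internal-node rotations of both structures. Small problems
#' (<= `exact_limit` internal nodes in total) are solved by exhaustive
#' enumeration; larger ones by alternating lowest-index-first hill-climbing
#' passes, whose objective is non-increasing.
#'
#' @param tree,dendrogram Rooted `phylo` objects on the same label set.
#' @param max_passes Maximum alternating hill-climbing passes.
#' @param exact_limit Total internal-node count at or below which the
#'   exhaustive search is used.
#' @return List with rotated `tree` and `dendrogram`, their tip orders, and
#'   the final `objective`.
#' @export
untangle <- function(tree, dendrogram, max_passes = 10, exact_limit = 14) {
  if (!setequal(tree$tip.label, dendrogram$tip.label)) {
    bad <- c(setdiff(tree$tip.label, dendrogram$tip.label),
             setdiff(dendrogram$tip.label, tree$tip.label))
    stop("label mismatch: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  nt <- ape::Ntip(tree)
  chA <- node_children(tree)
  chB <- node_children(dendrogram)
  rootA <- nt + 1L; rootB <- nt + 1L
  nA <- tree$Nnode; nB <- dendrogram$Nnode
  # map dendrogram tip index -> tree tip index via labels
  mapB <- match(dendrogram$tip.label, tree$tip.label)

  objective <- function(ordA, ordB) {
    posA <- integer(nt); posA[ordA] <- seq_len(nt)
    posB <- integer(nt); posB[mapB[ordB]] <- seq_len(nt)
    sum((posA - posB)^2)
  }

  if (nA + nB <= exact_limit) {
    best <- NULL; best_obj <- Inf
    for (ia in seq_len(2^nA) - 1L) {
      fA <- as.logical(bitwAnd(ia, 2^(seq_len(nA) - 1L)) > 0)
      ordA <- flipped_order(chA, rootA, nt, fA)
      for (ib in seq_len(2^nB) - 1L) {
        fB <- as.logical(bitwAnd(ib, 2^(seq_len(nB) - 1L)) > 0)
        ordB <- flipped_order(chB, rootB, nt, fB)
        ob <- objective(ordA, ordB)
        if (ob < best_obj) { best_obj <- ob; best <- list(fA, fB) }
      }
    }
    fA <- best[[1]]; fB <- best[[2]]
  } else {
    fA <- rep(FALSE, nA); fB <- rep(FALSE, nB)
    binary <- all(lengths(chA[(nt + 1):(nt + nA)]) == 2) &&
      all(lengths(chB[(nt + 1):(nt + nB)]) == 2)
    if (binary) {
      # positions indexed by tree-tip id for both structures
      ordA <- flipped_order(chA, rootA, nt, fA)
      ordB <- flipped_order(chB, rootB, nt, fB)
      posA <- integer(nt); posA[ordA] <- seq_len(nt)
      posB <- integer(nt); posB[mapB[ordB]] <- seq_len(nt)
      # per internal node: tip ids (tree numbering) under each child
      blocks <- function(ch, n_int, map = NULL) {
        desc <- vector("list", nt + n_int)
        for (i in seq_len(nt)) desc[[i]] <- if (is.null(map)) i else map[i]
        fill <- function(node) {
          if (node > nt) {
            for (k in ch[[node]]) fill(k)
            desc[[node]] <<- unlist(desc[ch[[node]]])
          }
          invisible()
        }
        fill(nt + 1L)
        lapply(seq_len(n_int), function(v) desc[ch[[v + nt]]])
      }
      kidA <- blocks(chA, nA)
      kidB <- blocks(chB, nB, mapB)
      # flipping a binary node swaps its two contiguous child blocks
      sweep_side <- function(pos, other, kid, flips) {
        improved <- FALSE
        for (v in seq_along(kid)) {
          t1 <- kid[[v]][[1]]; t2 <- kid[[v]][[2]]
          n1 <- length(t1); n2 <- length(t2)
          s1 <- if (min(pos[t1]) < min(pos[t2])) n2 else -n2
          s2 <- -sign(s1) * n1
          delta <- n1 * s1^2 + 2 * s1 * sum(pos[t1] - other[t1]) +
            n2 * s2^2 + 2 * s2 * sum(pos[t2] - other[t2])
          if (delta < 0) {
            pos[t1] <- pos[t1] + s1
            pos[t2] <- pos[t2] + s2
            flips[v] <- !flips[v]
            improved <- TRUE
          }
        }
        list(pos = pos, flips = flips, improved = improved)
      }
      for (pass in seq_len(max_passes)) {
        ra <- sweep_side(posA, posB, kidA, fA)
        posA <- ra$pos; fA <- ra$flips
        rb <- sweep_side(posB, posA, kidB, fB)
        posB <- rb$pos; fB <- rb$flips
        if (!ra$improved && !rb$improved) break
      }
    } else {
      ordA <- flipped_order(chA, rootA, nt, fA)
      ordB <- flipped_order(chB, rootB, nt, fB)
      cur <- objective(ordA, ordB)
      for (pass in seq_len(max_passes)) {
        improved <- FALSE
        for (side in 1:2) {
          nn <- if (side == 1) nA else nB
          for (v in seq_len(nn)) {
            if (side == 1) {
              fA[v] <- !fA[v]
              ordA2 <- flipped_order(chA, rootA, nt, fA)
              ob <- objective(ordA2, ordB)
              if (ob < cur) { cur <- ob; ordA <- ordA2; improved <- TRUE }
              else fA[v] <- !fA[v]
            } else {
              fB[v] <- !fB[v]
              ordB2 <- flipped_order(chB, rootB, nt, fB)
              ob <- objective(ordA, ordB2)
              if (ob < cur) { cur <- ob; ordB <- ordB2; improved <- TRUE }
              else fB[v] <- !fB[v]
            }
          }
        }
        if (!improved) break
      }
    }
  }
  ordA <- flipped_order(chA, rootA, nt, fA)
  ordB <- flipped_order(chB, rootB, nt, fB)
  list(tree = apply_flips(tree, fA),
       dendrogram = apply_flips(dendrogram, fB),
       order_tree = tree$tip.label[ordA],
       order_dendrogram = dendrogram$tip.label[ordB],
       objective = objective(ordA, ordB))
}

# Rebuild a phylo with the given per-internal-node child-order flips.
apply_flips <- function(tree, flips) {
  if (!any(flips)) return(tree)
  nt <- ape::Ntip(tree)
  ch <- node_children(tree)
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  len_of <- setNames(tree$edge.length, paste(tree$edge[, 1], tree$edge[, 2]))
  rec <- function(node) {
    if (node <= nt) return(invisible())
    kids <- ch[[node]]
    if (isTRUE(flips[node - nt])) kids <- rev(kids)
    for (k in kids) {
      edges <<- rbind(edges, c(node, k))
      lens <<- c(lens, len_of[[paste(node, k)]])
      rec(k)
    }
  }
  rec(nt + 1L)
  out <- tree
  out$edge <- edges
  out$edge.length <- lens
  attr(out, "order") <- "cladewise"
  out
}

#' Tip displacement between two tip orders
#'
#' Per-species displacement is the absolute difference in position (rank)
#' between the two orders; the tree-wide statistic TD is their mean. The
#' number of crossing pairs is also reported.
#'
#' @param order_a,order_b Character vectors holding the same labels, no
#'   duplicates.
#' @return List with `displacement` (named integer vector), `td`, and
#'   `crossings`.
#' @export
tip_displacement <- function(order_a, order_b) {
  if (anyDuplicated(order_a) || anyDuplicated(order_b))
    stop("duplicate labels", call. = FALSE)
  if (!setequal(order_a, order_b))
    stop("orders hold different label sets", call. = FALSE)
  pos_b <- match(order_a, order_b)
  disp <- abs(seq_along(order_a) - pos_b)
  names(disp) <- order_a
  n <- length(order_a)
  crossings <- 0L
  if (n >= 2) {
    cmb <- combn(n, 2)
    crossings <- sum((cmb[1, ] - cmb[2, ]) * (pos_b[cmb[1, ]] - pos_b[cmb[2, ]]) < 0)
  }
  list(displacement = disp, td = mean(disp), crossings = crossings)
}

#' Tanglegram tip-displacement test against a Brownian-motion null
#'
#' The observed statistic is the mean tip displacement between the
#' phylogeny and the UPGMA dendrogram of pairwise Procrustes distances,
#' after untangling. The null distribution is built from `n_sim`
#' multivariate-BM simulated landmark datasets (rate matrix estimated by
#' GLS) passed through the identical pipeline; the one-sided p-value is the
#' fraction of null statistics strictly lower than observed (a small p
#' flags unusually strong morphology-phylogeny concordance).
#'
#' @param tree Ultrametric `phylo`.
#' @param mean_shapes species x k x 3 aligned shapes (dimnames = tip
#'   labels) or species x m trait matrix.
#' @param n_sim Simulations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param metric Disparity metric for the dissimilarity matrix.
#' @param max_passes Hill-climbing passes for untangling.
#' @return Object of class `tanglegram_result`.
#' @export
displacement_null_test <- function(tree, mean_shapes, n_sim = 1000, seed = 1,
                                   metric = c("procrustes", "avg.sq"),
                                   max_passes = 10) {
  ms_assert_ultrametric(tree)
  metric <- match.arg(metric)
  if (n_sim < 100) stop("`n_sim` must be >= 100", call. = FALSE)
  X <- flatten_shapes(mean_shapes)
  if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  k <- if (length(dim(mean_shapes)) == 3) dim(mean_shapes)[2] else NULL

  run_once <- function(shapes) {
    D <- disparity_dist(shapes, metric, tree$tip.label)
    dimnames(D) <- list(tree$tip.label, tree$tip.label)
    dend <- upgma(D)
    ut <- untangle(tree, dend, max_passes = max_passes)
    tip_displacement(ut$order_tree, ut$order_dendrogram)
  }
  obs <- run_once(if (!is.null(k)) mean_shapes else X)

  est <- estimate_rate_matrix(tree, X)
  Lc <- t(chol(ape::vcv.phylo(tree)))
  S <- est$sqrt
  null_td <- numeric(n_sim)
  with_seed(seed, {
    for (b in seq_len(n_sim)) {
      Z <- matrix(rnorm(n * m), n, m)
      Xs <- rep(1, n) %o% est$anc + Lc %*% Z %*% t(S)
      rownames(Xs) <- tree$tip.label
      shapes_s <- if (!is.null(k))
        array(Xs, c(n, k, 3), dimnames = list(tree$tip.label, NULL, NULL))
      else Xs
      null_td[b] <- run_once(shapes_s)$td
    }
  })
  p <- mean(null_td < obs$td)
  structure(list(displacement = obs$displacement, td = obs$td,
                 crossings = obs$crossings, null_td = null_td,
                 p_value = p, n_sim = n_sim, seed = seed),
            class = "tanglegram_result")
}

#' @export
print.tanglegram_result <- function(x, ...) {
  cat(sprintf("tanglegram: TD = %.3f (null %.1f-%.1f), one-sided p = %.4g (%d sims)\n",
              x$td, min(x$null_td), max(x$null_td), x$p_value, x$n_sim))
  invisible(x)
}
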