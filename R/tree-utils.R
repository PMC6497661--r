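# Internal helpers for time-calibrated trees (ape "phylo" objects).
# Edge ids throughout the package are row indices of tree$edge.

ms_assert_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("`tree` must have branch lengths", call. = FALSE)
  invisible(tree)
}

# Ages of all nodes measured from the root (root = 0).
node_ages <- function(tree) {
  ape::node.depth.edgelength(tree)
}

tree_height <- function(tree) {
  max(node_ages(tree)[seq_len(ape::Ntip(tree))])
}

is_ultrametric_rel <- function(tree, tol = 1e-6) {
  d <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol * max(d)
}

ms_assert_ultrametric <- function(tree, tol = 1e-6) {
  ms_assert_phylo(tree)
  if (!is_ultrametric_rel(tree, tol))
    stop("tree must be ultrametric (relative tip-depth spread > ", tol, ")",
         call. = FALSE)
  invisible(tree)
}

# List, per edge row, of tip indices descending from that edge.
edge_descendant_tips <- function(tree) {
  nt <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(desc[[tree$edge[e, 2L]]]))
}

# List, per tip, of edge rows on the root-to-tip path (root end first).
tip_path_edges <- function(tree) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  parent_edge <- integer(nt + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(nt), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(e, path)
      node <- tree$edge[e, 1L]
    }
    path
  })
}

# Geometry bundle used by the OU machinery.
tree_geometry <- function(tree) {
  ms_assert_ultrametric(tree)
  ages <- node_ages(tree)
  nt <- ape::Ntip(tree)
  list(
    tree = tree,
    n_tips = nt,
    n_edges = nrow(tree$edge),
    ages = ages,
    height = max(ages[seq_len(nt)]),
    t_start = ages[tree$edge[, 1L]],
    t_end = ages[tree$edge[, 2L]],
    ta = ape::vcv.phylo(tree),        # shared root-to-MRCA times, tip order
    desc = edge_descendant_tips(tree),
    paths = tip_path_edges(tree)
  )
}

# Evaluate RNG-dependent code under a fixed seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Symmetric PSD square root with eigenvalue clipping at zero.
psd_sqrt <- function(S, tol = 1e-12) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  eg$vectors %*% (sqrt(ev) * t(eg$vectors))
}

# (1 - exp(-x)) / x, stable near 0 (expm1 keeps precision; only x = 0
# needs the limit value).
expm1_ratio <- function(x) {
  out <- -expm1(-x) / x
  out[!is.finite(out)] <- 1
  out
}
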