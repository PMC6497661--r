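# Generalized Procrustes analysis, semilandmark sliding, Procrustes
# distances, curve resampling and species consensus shapes.

#' Resample an ordered 3D curve by arc length
#'
#' Output points lie on the piecewise-linear path through the input, spaced
#' equally in arc length; endpoints are preserved exactly.
#'
#' @param points m x 3 ordered curve points (m >= 2, consecutive points
#'   distinct).
#' @param n_out Number of output points (>= 2).
#' @return n_out x 3 matrix.
#' @export
resample_curve <- function(points, n_out) {
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2) stop("curve needs at least 2 points", call. = FALSE)
  if (n_out < 2) stop("`n_out` must be >= 2", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-m, , drop = FALSE])^2))
  if (any(seg == 0)) stop("duplicate consecutive curve points", call. = FALSE)
  s <- c(0, cumsum(seg))
  target <- seq(0, s[m], length.out = n_out)
  out <- matrix(NA_real_, n_out, 3)
  out[1, ] <- points[1, ]
  out[n_out, ] <- points[m, ]
  for (i in seq(2, n_out - 1)) {
    j <- findInterval(target[i], s, rightmost.closed = TRUE)
    w <- (target[i] - s[j]) / (s[j + 1] - s[j])
    out[i, ] <- (1 - w) * points[j, ] + w * points[j + 1, ]
  }
  out
}

#' Procrustes distance between two configurations
#'
#' Square root of the minimized sum of squared coordinate differences after
#' centering, scaling to unit centroid size, and optimal rotation
#' (reflections excluded).
#'
#' @param shape_a,shape_b k x 3 matrices with identical k.
#' @return Non-negative scalar; zero iff the shapes are identical up to a
#'   similarity transform.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a); shape_b <- as.matrix(shape_b)
  if (!identical(dim(shape_a), dim(shape_b)))
    stop("shapes have mismatched dimensions", call. = FALSE)
  .cpp_procrustes_distance(shape_a, shape_b)
}

#' All pairwise Procrustes distances
#'
#' @param shapes n x k x 3 array.
#' @return n x n symmetric distance matrix (dimnames from the array).
#' @export
pairwise_procrustes <- function(shapes) {
  stopifnot(length(dim(shapes)) == 3, dim(shapes)[3] == 3)
  D <- .cpp_pairwise_procrustes(aperm(shapes, c(2, 3, 1)))
  dimnames(D) <- list(dimnames(shapes)[[1]], dimnames(shapes)[[1]])
  D
}

center_scale_config <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(X^2))
  if (cs <= 0) stop("degenerate configuration", call. = FALSE)
  X / cs
}

# Optimal rotation (det +1) aligning X onto Y.
kabsch_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes alignment
#'
#' Iteratively centers, scales to unit centroid size and rotates all
#' configurations to the running consensus; optionally slides semilandmarks
#' along their curve tangents to minimize Procrustes distance to the
#' consensus. Terminates when the consensus moves less than `tol`
#' (Procrustes distance) or after `max_iter` iterations. The final
#' orientation is canonicalized to the consensus principal axes so the
#' result is invariant to specimen order.
#'
#' @param dataset A `landmark_dataset` without missing cells, or an
#'   n x k x 3 array.
#' @param slide Slide semilandmarks along curve tangents (needs curves).
#' @param max_iter,tol Convergence controls.
#' @param slide_iters Number of early iterations in which sliding is
#'   applied (sliding has a near-null direction along each curve, so it is
#'   bounded rather than run to convergence).
#' @return Object of class `procrustes_alignment` with fields `aligned`
#'   (n x k x 3), `centroid_sizes`, `consensus`, `iterations`, `converged`.
#' @export
gpa_align <- function(dataset, slide = FALSE, max_iter = 100, tol = 1e-8,
                      slide_iters = 5) {
  if (inherits(dataset, "landmark_dataset")) {
    if (any(dataset$mask))
      stop("dataset has missing cells; run estimate_missing() first",
           call. = FALSE)
    shapes <- dataset$coords
    curves <- dataset$curves
    specimens <- dataset$specimens
  } else {
    shapes <- dataset
    curves <- NULL
    specimens <- dimnames(shapes)[[1]] %||% sprintf("s%d", seq_len(dim(shapes)[1]))
  }
  if (slide && is.null(curves))
    stop("`slide = TRUE` requires curve definitions", call. = FALSE)
  n <- dim(shapes)[1]; k <- dim(shapes)[2]
  cs <- numeric(n)
  X <- array(NA_real_, dim(shapes))
  for (i in seq_len(n)) {
    cfg <- shapes[i, , ]
    ctr <- colMeans(cfg)
    cfg <- sweep(cfg, 2, ctr)
    cs[i] <- sqrt(sum(cfg^2))
    if (cs[i] <= 0)
      stop("degenerate specimen (all points coincident): ", specimens[i],
           call. = FALSE)
    X[i, , ] <- cfg / cs[i]
  }
  consensus <- X[1, , ]
  consensus <- center_scale_config(consensus)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(n))
      X[i, , ] <- X[i, , ] %*% kabsch_rotation(X[i, , ], consensus)
    if (slide && iter <= slide_iters) {
      for (i in seq_len(n))
        X[i, , ] <- center_scale_config(
          slide_semilandmarks(X[i, , ], consensus, curves))
    }
    new_cons <- center_scale_config(apply(X, c(2, 3), mean))
    dc <- procrustes_distance(new_cons, consensus)
    consensus <- new_cons
    if (dc < tol) { converged <- TRUE; break }
  }
  # final pass: rotate onto converged consensus, canonical orientation
  for (i in seq_len(n))
    X[i, , ] <- X[i, , ] %*% kabsch_rotation(X[i, , ], consensus)
  consensus <- apply(X, c(2, 3), mean)
  R <- principal_axes_rotation(consensus)
  for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% R
  consensus <- apply(X, c(2, 3), mean)
  dimnames(X)[[1]] <- specimens
  structure(list(aligned = X, centroid_sizes = cs, consensus = consensus,
                 iterations = iter, converged = converged,
                 specimens = specimens),
            class = "procrustes_alignment")
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat(sprintf("procrustes_alignment: %d specimens, %d landmarks, %d iterations (%s)\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Deterministic orientation: rotate into the principal axes of the
# consensus, signs fixed so the largest-magnitude coordinate on each axis
# is positive, det +1 enforced.
principal_axes_rotation <- function(consensus) {
  V <- eigen(cov(consensus), symmetric = TRUE)$vectors
  Y <- consensus %*% V
  for (j in 1:3) if (Y[which.max(abs(Y[, j])), j] < 0) V[, j] <- -V[, j]
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# One sliding pass: each interior curve point moves along its local tangent
# (central differences) by the tangential component of its offset from the
# consensus — the Procrustes-distance sliding criterion.
slide_semilandmarks <- function(X, consensus, curves) {
  for (cv in curves) {
    ids <- cv$ids
    if (length(ids) < 3) next
    interior <- if (isTRUE(cv$fixed_ends)) 2:(length(ids) - 1) else
      seq_along(ids)
    for (jj in interior) {
      j <- ids[jj]
      prv <- ids[max(jj - 1, 1)]
      nxt <- ids[min(jj + 1, length(ids))]
      tg <- X[nxt, ] - X[prv, ]
      nt <- sqrt(sum(tg^2))
      if (nt == 0) next
      tg <- tg / nt
      X[j, ] <- X[j, ] + sum((consensus[j, ] - X[j, ]) * tg) * tg
    }
  }
  X
}

# Total Procrustes sum of squares of an alignment about its consensus.
gpa_objective <- function(alignment) {
  n <- dim(alignment$aligned)[1]
  sum(vapply(seq_len(n), function(i)
    procrustes_distance(alignment$aligned[i, , ], alignment$consensus)^2,
    numeric(1)))
}

#' Per-species consensus shapes
#'
#' Arithmetic mean of the aligned specimens of each species; when bilateral
#' pairs are supplied the mean shape is then symmetrized by averaging it
#' with its mirrored, relabeled copy (mirror plane fitted through the
#' midline landmarks by total least squares).
#'
#' @param alignment A `procrustes_alignment`.
#' @param species Character vector, one species per specimen.
#' @param bilateral_pairs Optional (left, right) index matrix.
#' @param midline Optional midline landmark indices (used to fit the
#'   midsagittal plane; pair midpoints are used when fewer than 3).
#' @return species x k x 3 array (dimnames = species names).
#' @export
species_consensus <- function(alignment, species, bilateral_pairs = NULL,
                              midline = NULL) {
  stopifnot(inherits(alignment, "procrustes_alignment"))
  n <- dim(alignment$aligned)[1]
  stopifnot(length(species) == n)
  sp <- unique(species)
  k <- dim(alignment$aligned)[2]
  out <- array(NA_real_, c(length(sp), k, 3), dimnames = list(sp, NULL, NULL))
  for (i in seq_along(sp)) {
    rows <- which(species == sp[i])
    m <- apply(alignment$aligned[rows, , , drop = FALSE], c(2, 3), mean)
    if (!is.null(bilateral_pairs))
      m <- symmetrize_shape(m, as.matrix(bilateral_pairs), midline)
    out[i, , ] <- m
  }
  out
}

# Reflect `shape` across its midsagittal plane, swap paired landmarks, and
# average with the original: the result is exactly bilaterally symmetric.
symmetrize_shape <- function(shape, pairs, midline = NULL) {
  pl <- if (!is.null(midline) && length(midline) >= 3)
    fit_plane(shape[midline, , drop = FALSE])
  else
    fit_plane((shape[pairs[, 1], , drop = FALSE] +
                 shape[pairs[, 2], , drop = FALSE]) / 2)
  refl <- reflect_across_plane(shape, pl)
  swapped <- refl
  swapped[pairs[, 1], ] <- refl[pairs[, 2], ]
  swapped[pairs[, 2], ] <- refl[pairs[, 1], ]
  (shape + swapped) / 2
}

# Total-least-squares plane: point + unit normal.
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(point = ctr, normal = sv$v[, 3])
}

reflect_across_plane <- function(X, plane) {
  d <- as.vector(sweep(X, 2, plane$point) %*% plane$normal)
  X - 2 * outer(d, plane$normal)
}
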