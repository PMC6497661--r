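# Shared fixtures, all built in code.

three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

two_tip_tree <- function(depth = 1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", depth, depth))
}

star_tree <- function(n = 8, depth = 1) {
  txt <- paste0("(", paste(sprintf("t%d:%g", seq_len(n), depth),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Planar triangle as a k x 3 configuration (z = 0).
planar_triangle <- function(v) {
  cbind(matrix(v, ncol = 2, byrow = TRUE), 0)
}

random_shape <- function(k, seed) {
  set.seed(seed)
  matrix(rnorm(3 * k), k, 3)
}

# Random similarity transform of a configuration.
transformed_copy <- function(shape, seed) {
  set.seed(seed)
  R <- morphoshift:::random_rotation()
  s <- exp(rnorm(1, 0, 0.3))
  tr <- rnorm(3)
  sweep(s * shape %*% R, 2, tr, "+")
}
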