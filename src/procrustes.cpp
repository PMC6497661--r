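#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Ordinary (partial) Procrustes distance between two centered, unit-size
// k x 3 configurations: sqrt(2 - 2 * (s1 + s2 +/- s3)), reflections excluded.
static double pair_dist(const mat &A, const mat &B) {
  mat M = B.t() * A;  // 3 x 3
  mat U, V;
  vec s;
  if (!svd(U, s, V, M)) Rcpp::stop("SVD failure in Procrustes distance");
  double sg = (det(U) * det(V) < 0.0) ? -1.0 : 1.0;
  mat D = eye(3, 3);
  D(2, 2) = sg;
  mat R = U * D * V.t();  // optimal rotation of B onto A, det +1
  // explicit residual norm: stable when the shapes nearly coincide
  // (2 - 2*sum(s) cancels catastrophically there)
  return norm(A - B * R, "fro");
}

static void center_scale(mat &A) {
  rowvec c = mean(A, 0);
  A.each_row() -= c;
  double cs = norm(A, "fro");
  if (cs <= 0.0) Rcpp::stop("degenerate configuration (all landmarks coincident)");
  A /= cs;
}

// [[Rcpp::export(name = ".cpp_pairwise_procrustes")]]
arma::mat cpp_pairwise_procrustes(const arma::cube &X) {
  // X: k x 3 x n
  const uword n = X.n_slices;
  std::vector<mat> pre(n);
  for (uword i = 0; i < n; ++i) {
    mat A = X.slice(i);
    center_scale(A);
    pre[i] = A;
  }
  mat D(n, n, fill::zeros);
  for (uword i = 0; i + 1 < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      double d = pair_dist(pre[i], pre[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".cpp_procrustes_distance")]]
double cpp_procrustes_distance(const arma::mat &A0, const arma::mat &B0) {
  mat A = A0, B = B0;
  center_scale(A);
  center_scale(B);
  return pair_dist(A, B);
}
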