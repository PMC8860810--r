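// Graphical lasso: block coordinate descent on the covariance (Friedman-style),
// with a coordinate-descent lasso inner solver and warm starts along the
// penalty path. Solves, for each lambda,
//   maximize  log det K - trace(S K) - lambda * sum_{i != j} |K_ij|
// over positive definite K (penalty on off-diagonals only).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Lasso subproblem: minimize (1/2) b' V b - s' b + lambda ||b||_1.
// V is (p-1)x(p-1) SPD; b updated in place (warm start).
static void lasso_cd(const mat& V, const vec& s, double lambda, vec& b,
                     double tol, int maxit) {
  const uword m = b.n_elem;
  vec Vb = V * b; // running V %*% b
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (uword j = 0; j < m; ++j) {
      double bj_old = b(j);
      double grad = s(j) - (Vb(j) - V(j, j) * bj_old);
      double bj = 0.0;
      if (grad > lambda)       bj = (grad - lambda) / V(j, j);
      else if (grad < -lambda) bj = (grad + lambda) / V(j, j);
      if (bj != bj_old) {
        b(j) = bj;
        Vb += V.col(j) * (bj - bj_old);
        double d = std::abs(bj - bj_old);
        if (d > maxdel) maxdel = d;
      }
    }
    if (maxdel < tol) break;
  }
}

// One glasso solve at a given lambda. W and B are warm-start state
// (estimated covariance and per-column lasso coefficients).
static bool glasso_one(const mat& S, double lambda, mat& W, mat& B,
                       mat& K, double tol, int maxit, int& iters) {
  const uword p = S.n_rows;
  // scale-aware convergence threshold, as in the reference algorithm
  double thr = tol * mean(mean(abs(S - diagmat(S.diag()))));
  if (!(thr > 0)) thr = tol * 1e-4;
  W.diag() = S.diag(); // off-diagonal-only penalty: diagonal is unshrunk

  uvec all = regspace<uvec>(0, p - 1);
  bool converged = (p == 1);
  iters = 0;
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    double maxdel = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      lasso_cd(W11, s12, lambda, b, thr * 0.1, 1000);
      vec w12 = W11 * b;
      for (uword t = 0; t < idx.n_elem; ++t) {
        double d = std::abs(W(idx(t), j) - w12(t));
        if (d > maxdel) maxdel = d;
        W(idx(t), j) = w12(t);
        W(j, idx(t)) = w12(t);
        B(idx(t), j) = b(t);
      }
    }
    if (maxdel < thr) { converged = true; break; }
  }

  // Recover K from W and the lasso coefficients: K_jj = 1/(w_jj - w12' b),
  // K_12 = -b K_jj. Exact zeros in b give exact zeros in K.
  K.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = B.col(j);
    b = b.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - dot(w12, b);
    if (!(denom > 0)) return false;
    double kjj = 1.0 / denom;
    K(j, j) = kjj;
    for (uword t = 0; t < idx.n_elem; ++t) K(idx(t), j) = -b(t) * kjj;
  }
  // the two triangles agree up to solver tolerance; average for exact symmetry
  // (a zero stays zero: both triangles are zero together by the lasso pattern)
  K = 0.5 * (K + K.t());
  return converged;
}

// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  cube Ks(p, p, nl);
  Rcpp::IntegerVector iterations(nl);
  Rcpp::LogicalVector converged(nl);

  mat W = S;   // warm-start state carried along the path
  mat B(p, p, fill::zeros);
  mat K(p, p, fill::zeros);
  for (uword l = 0; l < nl; ++l) {
    int iters = 0;
    bool ok = glasso_one(S, lambdas(l), W, B, K, tol, maxit, iters);
    Ks.slice(l) = K;
    iterations[l] = iters;
    converged[l] = ok;
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks,
                            Rcpp::Named("iterations") = iterations,
                            Rcpp::Named("converged") = converged);
}
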