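#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares for one right-hand
// side, using precomputed normal-equation blocks. A is m x k with k small
// (15 x 6 for the default five-LED / six-fluorochrome optics), so the
// passive-set solves are tiny dense systems.
static void nnls_one(const mat& AtA, const vec& Atb, vec& x, double tol) {
  const uword k = AtA.n_rows;
  x.zeros(k);
  std::vector<bool> passive(k, false);
  vec w = Atb;                      // gradient of -0.5*||Ax-b||^2 at x = 0
  const uword maxit = 30 * k;
  uword iter = 0;

  while (true) {
    // most positive gradient among the active (zero-bound) set
    int t = -1;
    double wmax = tol;
    for (uword i = 0; i < k; ++i)
      if (!passive[i] && w(i) > wmax) { wmax = w(i); t = (int)i; }
    if (t < 0) break;               // KKT satisfied
    passive[(uword)t] = true;

    while (true) {
      uvec idx(k);
      uword np = 0;
      for (uword i = 0; i < k; ++i) if (passive[i]) idx(np++) = i;
      idx = idx.head(np);

      vec z;
      bool ok = solve(z, AtA.submat(idx, idx), Atb.elem(idx),
                      solve_opts::no_approx);
      if (!ok) {
        // rank-deficient passive set: minimum-norm solution (documented
        // tie-break for degenerate fingerprints)
        z = pinv(AtA.submat(idx, idx)) * Atb.elem(idx);
      }

      if (z.min() > tol) {
        x.zeros();
        x.elem(idx) = z;
        break;
      }
      // step toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword j = 0; j < np; ++j) {
        if (z(j) <= tol) {
          double xi = x(idx(j));
          double a = xi / (xi - z(j));
          if (a < alpha) alpha = a;
        }
      }
      for (uword j = 0; j < np; ++j)
        x(idx(j)) += alpha * (z(j) - x(idx(j)));
      for (uword j = 0; j < np; ++j)
        if (x(idx(j)) <= tol) { passive[idx(j)] = false; x(idx(j)) = 0.0; }
    }

    w = Atb - AtA * x;
    if (++iter > maxit) break;      // safeguard; never hit in practice
  }
}

//' @useDynLib ChromaPlex, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export(name = ".nnls_batch")]]
Rcpp::List nnls_batch(const arma::mat& A, const arma::mat& B) {
  const uword k = A.n_cols, n = B.n_cols;
  if (A.n_rows != B.n_rows)
    Rcpp::stop("signal length (%d) does not match fingerprint rows (%d)",
               (int)B.n_rows, (int)A.n_rows);
  mat AtA = A.t() * A;
  mat X(k, n, fill::zeros);
  vec resid(n, fill::zeros);
  double tol = 10.0 * datum::eps * norm(A, 1) * (double)std::max(A.n_rows, k);
  vec x(k);
  for (uword j = 0; j < n; ++j) {
    vec b = B.col(j);
    vec Atb = A.t() * b;
    nnls_one(AtA, Atb, x, tol);
    X.col(j) = x;
    resid(j) = norm(A * x - b, 2);
  }
  return Rcpp::List::create(Rcpp::Named("coef") = X,
                            Rcpp::Named("resid") = resid);
}
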