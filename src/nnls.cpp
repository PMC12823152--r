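#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Lawson-Hanson active-set non-negative least squares, operating on the
// design matrix itself (QR-based subproblem solves keep the attainable
// precision at the conditioning of A, not of A'A). Terminates at the KKT
// point: x >= 0, gradient w = A'(b - Ax) <= tol on the zero set. Supports
// a warm start with an initial passive set, which the TI/RI noise
// alternation and Monte Carlo refits exploit.

static arma::vec solve_ls(const arma::mat& A, const arma::vec& b,
                          const arma::uvec& P) {
  arma::vec z;
  if (!arma::solve(z, A.cols(P), b)) {
    z = arma::pinv(A.cols(P)) * b;
  }
  return z;
}

// [[Rcpp::export(name = ".nnls_lh_cpp")]]
Rcpp::List nnls_lh_cpp(const arma::mat& A, const arma::vec& b,
                       double tol_rel, int max_iter,
                       Rcpp::Nullable<Rcpp::IntegerVector> init_passive =
                           R_NilValue) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);

  // gradient tolerance relative to the initial gradient magnitude
  arma::vec g0 = arma::abs(A.t() * b);
  double tol = tol_rel * g0.max();
  if (!(tol > 0)) tol = 1e-14;

  auto inner_feasible = [&](arma::uvec& P) -> bool {
    // solve on the passive set and walk back until feasible
    for (int guard = 0; guard < 2 * (int)n + 10; ++guard) {
      if (P.n_elem == 0) return true;
      arma::vec z = solve_ls(A, b, P);
      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        return true;
      }
      double alpha = arma::datum::inf;
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0) {
          double xk = x(P(k));
          double a = (xk - z(k) != 0.0) ? xk / (xk - z(k)) : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      arma::vec xP = x.elem(P);
      xP += alpha * (z - xP);
      x.zeros();
      x.elem(P) = xP;
      // drop coordinates that reached zero
      std::vector<arma::uword> keep;
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        if (z(k) > 0 || x(P(k)) > 0) keep.push_back(P(k));
        else passive[P(k)] = false;
      }
      if (keep.size() == P.n_elem) {
        // numerical stall: drop the most negative direction
        arma::uword kmin = z.index_min();
        passive[P(kmin)] = false;
        x(P(kmin)) = 0.0;
        keep.clear();
        for (arma::uword k = 0; k < P.n_elem; ++k)
          if (k != kmin) keep.push_back(P(k));
      }
      P = arma::uvec(keep);
    }
    return false;
  };

  int outer = 0;
  // warm start: seed the passive set and make it feasible
  if (init_passive.isNotNull()) {
    Rcpp::IntegerVector ip(init_passive);
    std::vector<arma::uword> seed;
    for (int k = 0; k < ip.size(); ++k) {
      int j = ip[k] - 1;  // 1-based from R
      if (j >= 0 && j < (int)n && !passive[j]) {
        passive[j] = true;
        seed.push_back((arma::uword)j);
      }
    }
    arma::uvec P(seed);
    inner_feasible(P);
  }

  arma::vec w = A.t() * (b - A * x);
  bool converged = false;
  while (outer < max_iter) {
    double wmax = -arma::datum::inf;
    arma::sword jmax = -1;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = (arma::sword)j; }
    if (jmax < 0 || wmax <= tol) { converged = true; break; }
    ++outer;
    passive[(arma::uword)jmax] = true;
    std::vector<arma::uword> idx;
    for (arma::uword j = 0; j < n; ++j) if (passive[j]) idx.push_back(j);
    arma::uvec P(idx);
    inner_feasible(P);
    w = A.t() * (b - A * x);
  }

  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("iterations") = outer,
                            Rcpp::Named("converged") = converged);
}
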