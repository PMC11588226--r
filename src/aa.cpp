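// Alternating constrained least-squares solver for archetype analysis.
//
// Both simplex-constrained subproblems (mixture weights alpha of archetypes
// per observation, and beta of observations per archetype) are solved with
// the classical penalty device: a row of constant M is appended to the
// design and the target so that the sum-to-one constraint is enforced
// approximately, and the padded system is solved by non-negative least
// squares (Lawson-Hanson active set).  Solutions are renormalised to sum
// exactly to one.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson NNLS: minimise ||A x - b||_2 subject to x >= 0.
static vec nnls(const mat& A, const vec& b, int max_pass = 0) {
  const uword n = A.n_cols;
  if (max_pass <= 0) max_pass = 3 * static_cast<int>(n) + 30;
  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = A.t() * (b - A * x);
  const double tol = 1e-10 * std::max(1.0, norm(b, 2)) * std::max(1.0, norm(A, "inf"));

  int pass = 0;
  while (pass++ < max_pass) {
    // pick the most violated dual coordinate among the active (zero) set
    int jbest = -1;
    double wbest = tol;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wbest) { wbest = w(j); jbest = j; }
    if (jbest < 0) break;
    passive[jbest] = true;

    for (int inner = 0; inner < max_pass; ++inner) {
      std::vector<uword> pidx;
      for (uword j = 0; j < n; ++j) if (passive[j]) pidx.push_back(j);
      uvec P = conv_to<uvec>::from(pidx);
      vec s;
      bool ok = solve(s, A.cols(P), b, solve_opts::fast + solve_opts::allow_ugly);
      if (!ok) s = pinv(A.cols(P)) * b;
      if (s.min() > 0) {
        x.zeros();
        x(P) = s;
        break;
      }
      // step back along the segment to the feasibility boundary
      double step = datum::inf;
      for (uword t = 0; t < P.n_elem; ++t)
        if (s(t) <= 0) {
          double d = x(P(t)) / (x(P(t)) - s(t));
          if (d < step) step = d;
        }
      vec xP = x(P) + step * (s - x(P));
      x.zeros();
      x(P) = xP;
      for (uword t = 0; t < P.n_elem; ++t)
        if (x(P(t)) <= 1e-12) { passive[P(t)] = false; x(P(t)) = 0.0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// Solve one simplex-constrained least-squares row: min ||D' v - target||
// with v >= 0, sum(v) = 1, via the penalty row and renormalisation.
static rowvec simplex_ls(const mat& Daug, const vec& target_aug) {
  vec v = nnls(Daug, target_aug);
  double s = accu(v);
  if (s <= 0) v.fill(1.0 / v.n_elem); else v /= s;
  return v.t();
}

// Rows of `alpha` solving min ||X - alpha Z||_F^2 over row simplices.
// [[Rcpp::export]]
arma::mat aa_alpha_step(const arma::mat& X, const arma::mat& Z, double M) {
  const uword n = X.n_rows, p = Z.n_rows, m = X.n_cols;
  mat Daug(m + 1, p);
  Daug.rows(0, m - 1) = Z.t();
  Daug.row(m).fill(M);
  mat alpha(n, p);
  vec rhs(m + 1);
  for (uword i = 0; i < n; ++i) {
    rhs.subvec(0, m - 1) = X.row(i).t();
    rhs(m) = M;
    alpha.row(i) = simplex_ls(Daug, rhs);
  }
  return alpha;
}

// Sweep of block-coordinate updates over the beta rows: given alpha, the
// true residual objective ||X - alpha beta X||_F^2 is minimised exactly in
// each beta row in turn (the row subproblem reduces to one simplex-
// constrained least squares against the observations), so the sweep never
// increases the objective.  Z (= beta X) is kept in sync.
static void beta_sweep(const mat& X, const mat& alpha, mat& beta, mat& Z,
                       double M) {
  const uword p = beta.n_rows, m = X.n_cols;
  mat Daug(m + 1, X.n_rows);
  Daug.rows(0, m - 1) = X.t();
  Daug.row(m).fill(M);
  vec rhs(m + 1);
  for (uword j = 0; j < p; ++j) {
    const vec aj = alpha.col(j);
    const double cj = dot(aj, aj);
    if (cj < 1e-300) continue;  // unused archetype: leave its row be
    // residual with archetype j removed, collapsed along observations
    mat R = X - alpha * Z + aj * Z.row(j);
    rhs.subvec(0, m - 1) = R.t() * aj / cj;
    rhs(m) = M;
    beta.row(j) = simplex_ls(Daug, rhs);
    Z.row(j) = beta.row(j) * X;
  }
}

// One full alternating fit from a given initial beta.  Returns alpha, beta,
// the per-iteration RSS path (recorded after each complete alternation) and
// a convergence flag.  Both half-steps descend the same residual objective
// (up to the penalty approximation), so the path is non-increasing; as a
// safeguard an alternation that fails to improve is rolled back and the
// iteration stops.
// [[Rcpp::export]]
Rcpp::List aa_fit_cpp(const arma::mat& X, const arma::mat& beta_init,
                      int max_iter, double tol) {
  const double M = 200.0 * std::max(1e-8, abs(X).max());
  mat beta = beta_init;
  mat Z = beta * X;
  mat alpha = aa_alpha_step(X, Z, M);
  double rss = accu(square(X - alpha * Z));
  std::vector<double> path;
  path.push_back(rss);
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    mat beta_new = beta;
    mat Z_new = Z;
    beta_sweep(X, alpha, beta_new, Z_new, M);
    mat alpha_new = aa_alpha_step(X, Z_new, M);
    double rss_new = accu(square(X - alpha_new * Z_new));

    if (rss_new > rss) { converged = true; break; }  // no further progress
    double rel = (rss - rss_new) / std::max(rss, 1e-300);
    beta = beta_new; alpha = alpha_new; Z = Z_new; rss = rss_new;
    path.push_back(rss);
    if (rel < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("rss_path") = path,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged);
}
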