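// Hill-function gene-circuit kinetics: right-hand side, analytic Jacobian,
// damped Newton-Raphson steady-state search, and the batch screening loop
// over Latin-hypercube parameter sets.
//
// Conventions (shared with the R wrappers):
//   A(i,j)  in {-1, 0, +1}: sign of the regulation of node i BY node j,
//           so A is oriented like the Jacobian (J_ij = df_i/dx_j).
//   K(i,j), n(i,j): threshold and Hill coefficient of that edge.
//   f_i = b_i + V_i * prod_j h_ij(x_j) - mu_i x_i, with
//   h = x^n/(x^n + K^n) for activation and K^n/(x^n + K^n) for repression;
//   regulators combine multiplicatively (non-competitive binding).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec hill_rhs(const arma::imat& A, const arma::mat& K,
                          const arma::mat& nmat, const arma::vec& b,
                          const arma::vec& V, const arma::vec& mu,
                          const arma::vec& x) {
  const arma::uword N = x.n_elem;
  arma::vec f(N);
  for (arma::uword i = 0; i < N; ++i) {
    double prod = 1.0;
    bool regulated = false;
    for (arma::uword j = 0; j < N; ++j) {
      if (A(i, j) == 0) continue;
      regulated = true;
      const double xn = std::pow(x[j], nmat(i, j));
      const double Kn = std::pow(K(i, j), nmat(i, j));
      prod *= (A(i, j) > 0) ? xn / (xn + Kn) : Kn / (xn + Kn);
    }
    // unregulated nodes have no promoter input: basal production only
    f[i] = b[i] + (regulated ? V[i] * prod : 0.0) - mu[i] * x[i];
  }
  return f;
}

static arma::mat hill_jac(const arma::imat& A, const arma::mat& K,
                          const arma::mat& nmat, const arma::vec& b,
                          const arma::vec& V, const arma::vec& mu,
                          const arma::vec& x) {
  const arma::uword N = x.n_elem;
  arma::mat J(N, N, arma::fill::zeros);
  for (arma::uword i = 0; i < N; ++i) {
    for (arma::uword j = 0; j < N; ++j) {
      if (A(i, j) == 0) continue;
      // product of all regulating factors of node i except edge (i,j)
      double rest = 1.0;
      for (arma::uword l = 0; l < N; ++l) {
        if (l == j || A(i, l) == 0) continue;
        const double xn = std::pow(x[l], nmat(i, l));
        const double Kn = std::pow(K(i, l), nmat(i, l));
        rest *= (A(i, l) > 0) ? xn / (xn + Kn) : Kn / (xn + Kn);
      }
      const double n = nmat(i, j);
      const double xn = std::pow(x[j], n);
      const double Kn = std::pow(K(i, j), n);
      const double denom = (xn + Kn) * (xn + Kn);
      // d/dx [x^n/(x^n+K^n)] =  n K^n x^(n-1) / (x^n+K^n)^2
      // d/dx [K^n/(x^n+K^n)] = -n K^n x^(n-1) / (x^n+K^n)^2
      double dfac = n * Kn * std::pow(x[j], n - 1.0) / denom;
      if (A(i, j) < 0) dfac = -dfac;
      J(i, j) += V[i] * rest * dfac;
    }
    J(i, i) -= mu[i];
  }
  return J;
}

// Damped Newton iteration from one guess; stays in the positive orthant.
static bool newton_root(const arma::imat& A, const arma::mat& K,
                        const arma::mat& nmat, const arma::vec& b,
                        const arma::vec& V, const arma::vec& mu, arma::vec x,
                        double tol, int max_iter, arma::vec& root) {
  for (int it = 0; it < max_iter; ++it) {
    arma::vec f = hill_rhs(A, K, nmat, b, V, mu, x);
    if (arma::norm(f, "inf") < tol) {
      root = x;
      return x.min() > 0.0;
    }
    arma::mat J = hill_jac(A, K, nmat, b, V, mu, x);
    arma::vec dx;
    if (!arma::solve(dx, J, f, arma::solve_opts::no_approx)) return false;
    double step = 1.0;
    arma::vec xn = x - dx;
    int halvings = 0;
    while (xn.min() <= 0.0 && halvings < 60) {
      step *= 0.5;
      xn = x - step * dx;
      ++halvings;
    }
    if (xn.min() <= 0.0 || !xn.is_finite() || xn.max() > 1e12) return false;
    x = xn;
  }
  return false;
}

static double rel_linf(const arma::vec& x, const arma::vec& y) {
  const double scale = std::max(arma::norm(y, "inf"), 1e-12);
  return arma::norm(x - y, "inf") / scale;
}

// [[Rcpp::export]]
arma::vec hill_rhs_cpp(const arma::imat& A, const arma::mat& K,
                       const arma::mat& nmat, const arma::vec& b,
                       const arma::vec& V, const arma::vec& mu,
                       const arma::vec& x) {
  return hill_rhs(A, K, nmat, b, V, mu, x);
}

// [[Rcpp::export]]
arma::mat hill_jac_cpp(const arma::imat& A, const arma::mat& K,
                       const arma::mat& nmat, const arma::vec& b,
                       const arma::vec& V, const arma::vec& mu,
                       const arma::vec& x) {
  return hill_jac(A, K, nmat, b, V, mu, x);
}

// Multi-start Newton search. `guesses` holds one starting point per row.
// Returns the deduplicated strictly-positive roots plus per-guess diagnostics.
// [[Rcpp::export]]
List hill_steady_states_cpp(const arma::imat& A, const arma::mat& K,
                            const arma::mat& nmat, const arma::vec& b,
                            const arma::vec& V, const arma::vec& mu,
                            const arma::mat& guesses, double tol = 1e-9,
                            int max_iter = 100, double dedup_tol = 1e-4) {
  std::vector<arma::vec> roots;
  LogicalVector converged(guesses.n_rows);
  for (arma::uword g = 0; g < guesses.n_rows; ++g) {
    arma::vec root;
    const bool ok = newton_root(A, K, nmat, b, V, mu, guesses.row(g).t(), tol,
                                max_iter, root);
    converged[g] = ok;
    if (!ok) continue;
    bool dup = false;
    for (const arma::vec& r : roots) {
      if (rel_linf(root, r) < dedup_tol) {
        dup = true;
        break;
      }
    }
    if (!dup) roots.push_back(root);
  }
  arma::mat out(roots.size(), A.n_rows);
  for (size_t r = 0; r < roots.size(); ++r) out.row(r) = roots[r].t();
  return List::create(_["states"] = out, _["converged"] = converged);
}

// Batch screen: for each parameter set (row of `params`) find all steady
// states and return them with their Jacobians (flattened column-major).
//
// params columns: b_1..b_N, V_1..V_N, mu_1..mu_N, K_e for each edge e in
// `edge_rows`/`edge_cols` order. `guesses` has n_sets * n_guesses rows.
// [[Rcpp::export]]
List hill_screen_cpp(const arma::imat& A, const arma::mat& nmat,
                     const arma::mat& params, const arma::uvec& edge_rows,
                     const arma::uvec& edge_cols, const arma::mat& guesses,
                     int n_guesses, double tol = 1e-9, int max_iter = 100,
                     double dedup_tol = 1e-4) {
  const arma::uword N = A.n_rows;
  const arma::uword n_sets = params.n_rows;
  const arma::uword n_edges = edge_rows.n_elem;

  std::vector<double> state_buf, jac_buf;
  std::vector<int> set_ids;

  arma::mat K(N, N, arma::fill::zeros);
  for (arma::uword s = 0; s < n_sets; ++s) {
    const arma::vec b = params(arma::span(s, s), arma::span(0, N - 1)).t();
    const arma::vec V = params(arma::span(s, s), arma::span(N, 2 * N - 1)).t();
    const arma::vec mu =
        params(arma::span(s, s), arma::span(2 * N, 3 * N - 1)).t();
    for (arma::uword e = 0; e < n_edges; ++e)
      K(edge_rows[e], edge_cols[e]) = params(s, 3 * N + e);

    std::vector<arma::vec> roots;
    for (int g = 0; g < n_guesses; ++g) {
      arma::vec root;
      const arma::vec x0 = guesses.row(s * n_guesses + g).t();
      if (!newton_root(A, K, nmat, b, V, mu, x0, tol, max_iter, root)) continue;
      bool dup = false;
      for (const arma::vec& r : roots)
        if (rel_linf(root, r) < dedup_tol) {
          dup = true;
          break;
        }
      if (!dup) roots.push_back(root);
    }
    for (const arma::vec& r : roots) {
      const arma::mat J = hill_jac(A, K, nmat, b, V, mu, r);
      set_ids.push_back(static_cast<int>(s) + 1);
      for (arma::uword i = 0; i < N; ++i) state_buf.push_back(r[i]);
      for (arma::uword j = 0; j < N; ++j)
        for (arma::uword i = 0; i < N; ++i) jac_buf.push_back(J(i, j));
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }

  const arma::uword n_states = set_ids.size();
  NumericMatrix states(n_states, N), jacs(n_states, N * N);
  for (arma::uword r = 0; r < n_states; ++r) {
    for (arma::uword i = 0; i < N; ++i) states(r, i) = state_buf[r * N + i];
    for (arma::uword q = 0; q < N * N; ++q) jacs(r, q) = jac_buf[r * N * N + q];
  }
  return List::create(_["set_id"] = wrap(set_ids), _["states"] = states,
                      _["jacobians"] = jacs);
}
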