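// Dispersion-relation numerics for J(k) = J0 - k^2 D.
//
// Only numeric summaries are computed here; the instability classification
// itself (stable / unstable-without-diffusion / Turing I / II / Turing-Hopf)
// lives on the R side so the decision rules exist in exactly one place.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Leading eigenvalue: maximal real part; among (near-exact) ties pick the one
// with largest |Im| so complex pairs are never missed by the Hopf test.
static inline void lead_eig(const arma::cx_vec& ev, double& re, double& im) {
  re = -arma::datum::inf;
  im = 0.0;
  for (arma::uword i = 0; i < ev.n_elem; ++i) {
    const double r = ev[i].real();
    const double m = ev[i].imag();
    if (r > re || (r == re && std::abs(m) > std::abs(im))) {
      re = r;
      im = m;
    }
  }
}

// 2x2 closed form: eigenvalues of [[a,b],[c,d]] from trace/determinant.
static inline void lead_eig_2x2(double a, double b, double c, double d,
                                double& re, double& im) {
  const double tr = a + d;
  const double disc = tr * tr - 4.0 * (a * d - b * c);
  if (disc >= 0.0) {
    re = 0.5 * (tr + std::sqrt(disc));
    im = 0.0;
  } else {
    re = 0.5 * tr;
    im = 0.5 * std::sqrt(-disc);  // conjugate pair; report +|Im|
  }
}

static void sweep_curves(const arma::mat& j0, const arma::vec& dvec,
                         const arma::vec& kvals, arma::vec& re_out,
                         arma::vec& im_out) {
  const arma::uword n = j0.n_rows;
  const arma::uword nk = kvals.n_elem;
  arma::mat M(n, n);
  arma::cx_vec ev;
  for (arma::uword t = 0; t < nk; ++t) {
    const double k2 = kvals[t] * kvals[t];
    if (n == 2) {
      lead_eig_2x2(j0(0, 0) - k2 * dvec[0], j0(0, 1), j0(1, 0),
                   j0(1, 1) - k2 * dvec[1], re_out[t], im_out[t]);
    } else {
      M = j0;
      M.diag() -= k2 * dvec;
      ev = arma::eig_gen(M);
      lead_eig(ev, re_out[t], im_out[t]);
    }
  }
}

// [[Rcpp::export]]
List dispersion_sweep_cpp(const arma::mat& j0, const arma::vec& dvec,
                          const arma::vec& kvals) {
  arma::vec re(kvals.n_elem), im(kvals.n_elem);
  sweep_curves(j0, dvec, kvals, re, im);
  return List::create(_["lead_real"] = re, _["lead_imag"] = im);
}

// Per-matrix summary over the k grid (kvals sorted ascending, kvals[0] == 0):
//   col 0: Re lambda_max at k = 0
//   col 1: max over k > 0 of Re lambda_max
//   col 2: Im of the leading eigenvalue at the k attaining col 1
//   col 3: Re lambda_max at k_max (last grid point)
//   col 4: k attaining col 1 (first index on ties)
// When the matrix is already unstable at k = 0 the sweep is skipped and
// cols 1-4 are NaN: the classification needs nothing beyond col 0 there.
// [[Rcpp::export]]
NumericMatrix dispersion_summary_cpp(const arma::cube& jmats,
                                     const arma::vec& dvec,
                                     const arma::vec& kvals,
                                     bool early_exit = true) {
  const arma::uword nmat = jmats.n_slices;
  const arma::uword nk = kvals.n_elem;
  NumericMatrix out(nmat, 5);
  arma::vec re(nk), im(nk);

  for (arma::uword s = 0; s < nmat; ++s) {
    const arma::mat& j0 = jmats.slice(s);
    double re0, im0;
    if (j0.n_rows == 2) {
      lead_eig_2x2(j0(0, 0), j0(0, 1), j0(1, 0), j0(1, 1), re0, im0);
    } else {
      arma::cx_vec ev = arma::eig_gen(j0);
      lead_eig(ev, re0, im0);
    }
    out(s, 0) = re0;
    if (early_exit && re0 >= 0.0) {
      out(s, 1) = NA_REAL;
      out(s, 2) = NA_REAL;
      out(s, 3) = NA_REAL;
      out(s, 4) = NA_REAL;
      continue;
    }
    sweep_curves(j0, dvec, kvals, re, im);
    double peak = -arma::datum::inf, peak_im = 0.0, peak_k = kvals[nk - 1];
    for (arma::uword t = 1; t < nk; ++t) {
      if (re[t] > peak) {
        peak = re[t];
        peak_im = im[t];
        peak_k = kvals[t];
      }
    }
    out(s, 1) = peak;
    out(s, 2) = peak_im;
    out(s, 3) = re[nk - 1];
    out(s, 4) = peak_k;
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Sum of eigenvalues of J(k) (used by the trace-conservation checks).
// [[Rcpp::export]]
NumericVector eigen_sum_cpp(const arma::mat& j0, const arma::vec& dvec,
                            const arma::vec& kvals) {
  NumericVector out(kvals.size());
  arma::mat M;
  for (int t = 0; t < kvals.size(); ++t) {
    M = j0;
    M.diag() -= kvals[t] * kvals[t] * dvec;
    arma::cx_vec ev = arma::eig_gen(M);
    out[t] = arma::sum(arma::real(ev));
  }
  return out;
}
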