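// Compiled signal-processing cores: the VMD ADMM iteration and the
// direct-form-II-transposed IIR filter recursion. Both are O(n) per pass but
// run thousands of times over 4000-sample windows, so they live in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Variational mode decomposition of a real signal.
//
// Operates on the analytic (positive-frequency) half-spectrum. Mode update is
// the Wiener-filter form u_k = (f - sum_{i!=k} u_i + lambda/2) /
// (1 + 2*alpha*(w - w_k)^2); center frequencies are the power-weighted mean
// frequency of each mode; the Lagrangian multiplier enforces reconstruction
// via dual ascent with step tau.
//
// x is assumed already mirror-extended by the R wrapper if desired.
// Returns modes (columns, time domain), center frequencies (cycles/sample),
// iteration count and convergence flag.
// [[Rcpp::export(name = ".vmd_core")]]
List vmd_core(const arma::vec& x, int K, double alpha, double tau,
              double tol, int max_iter) {
  const arma::uword N = x.n_elem;
  const arma::uword H = N / 2;  // first positive-frequency bin count

  arma::cx_vec f_hat = arma::fft(x);
  // positive half-spectrum [0, 0.5): bins 0..H-1
  arma::cx_vec f_plus = f_hat.head(H);

  arma::vec freqs = arma::regspace<arma::vec>(0, H - 1) / double(N);

  arma::cx_mat u_hat(H, K, arma::fill::zeros);
  arma::vec omega(K);
  for (int k = 0; k < K; ++k) omega[k] = 0.5 * k / K;

  arma::cx_vec lambda_hat(H, arma::fill::zeros);
  arma::cx_vec sum_u(H, arma::fill::zeros);

  double diff = tol + 1.0;
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    arma::cx_mat u_prev = u_hat;
    for (int k = 0; k < K; ++k) {
      sum_u -= u_hat.col(k);
      arma::vec denom = 1.0 + 2.0 * alpha * arma::square(freqs - omega[k]);
      u_hat.col(k) = (f_plus - sum_u + lambda_hat / 2.0) / denom;
      arma::vec pw = arma::square(arma::abs(u_hat.col(k)));
      double tot = arma::accu(pw);
      if (tot > 0) omega[k] = arma::dot(freqs, pw) / tot;
      sum_u += u_hat.col(k);
    }
    if (tau > 0) lambda_hat += tau * (sum_u - f_plus);
    ++it;
    diff = 0.0;
    for (int k = 0; k < K; ++k) {
      double nrm = std::max(arma::accu(arma::square(arma::abs(u_prev.col(k)))), 1e-30);
      diff += arma::accu(arma::square(arma::abs(u_hat.col(k) - u_prev.col(k)))) / nrm;
    }
    if (diff < tol) { converged = true; break; }
  }

  // back to time domain: rebuild full Hermitian spectrum per mode
  arma::mat modes(N, K);
  for (int k = 0; k < K; ++k) {
    arma::cx_vec full(N, arma::fill::zeros);
    full.head(H) = u_hat.col(k);
    for (arma::uword j = 1; j < H; ++j) full[N - j] = std::conj(full[j]);
    modes.col(k) = arma::real(arma::ifft(full));
  }

  return List::create(_["modes"] = modes,
                      _["omega"] = omega,
                      _["iterations"] = it,
                      _["converged"] = converged);
}

// One pass of an IIR filter in direct form II transposed with explicit
// initial state, so that zero-phase filtering can seed the steady state.
// [[Rcpp::export(name = ".iir_df2t")]]
NumericVector iir_df2t(const NumericVector& b, const NumericVector& a,
                       const NumericVector& x, const NumericVector& zi) {
  const int n = x.size();
  const int m = zi.size();  // state dimension = max(len(a), len(b)) - 1
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (m > 0) z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
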