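// Hot loops of the spectral stage. Semantics are defined by the R
// wrappers (welch_matrix, synth_series, reject_artifact_epochs); these
// kernels only accelerate them. FFTs use FFTW (r2c / c2r with plan
// reuse), which is what makes cohort-scale Monte-Carlo studies practical.
#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Mean Hamming-windowed segment periodogram of every column of X.
// X: [n_samples x n_series]; w: window of length nperseg; segments start
// every `step` samples. Returns the one-sided (unscaled) mean |F|^2,
// [nperseg/2 + 1 x n_series].
// [[Rcpp::export]]
arma::mat cpp_welch(const arma::mat& X, const int nperseg, const int step,
                    const arma::vec& w) {
  const int n = X.n_rows;
  const int ns = X.n_cols;
  const int nseg = (n - nperseg) / step + 1;
  const int nf = nperseg / 2 + 1;
  arma::mat out(nf, ns, arma::fill::zeros);
  std::vector<double> in(nperseg);
  std::vector<fftw_complex> fo(nf);
  fftw_plan plan = fftw_plan_dft_r2c_1d(nperseg, in.data(), fo.data(),
                                        FFTW_ESTIMATE);
  for (int s = 0; s < ns; ++s) {
    double* acc = out.colptr(s);
    for (int g = 0; g < nseg; ++g) {
      const double* col = X.colptr(s) + g * step;
      for (int i = 0; i < nperseg; ++i) in[i] = col[i] * w(i);
      fftw_execute(plan);
      for (int k = 0; k < nf; ++k)
        acc[k] += fo[k][0] * fo[k][0] + fo[k][1] * fo[k][1];
    }
  }
  fftw_destroy_plan(plan);
  return out / nseg;
}

// Real signal from the positive-frequency half of a Hermitian spectrum.
// z: [kmax x n_series] complex coefficients for frequency bins 1..kmax of
// an n-point DFT (DC and, for even n, the Nyquist bin are zero). Returns
// (1/n) * sum_k Z_k exp(+2*pi*i*k*t/n) with conjugate-symmetric negative
// bins, i.e. Re(ifft) under R's convention, as [n x n_series].
// [[Rcpp::export]]
arma::mat cpp_hermitian_ifft(const arma::cx_mat& z, const int n) {
  const int ns = z.n_cols;
  const int kmax = z.n_rows;
  const int nf = n / 2 + 1;
  arma::mat out(n, ns);
  std::vector<fftw_complex> in(nf);
  std::vector<double> o(n);
  fftw_plan plan = fftw_plan_dft_c2r_1d(n, in.data(), o.data(),
                                        FFTW_ESTIMATE);
  for (int s = 0; s < ns; ++s) {
    std::memset(in.data(), 0, sizeof(fftw_complex) * nf);
    const arma::cx_double* col = z.colptr(s);
    for (int k = 0; k < kmax; ++k) {
      in[k + 1][0] = col[k].real();
      in[k + 1][1] = col[k].imag();
    }
    fftw_execute(plan);  // c2r overwrites its input; refilled each column
    double* op = out.colptr(s);
    for (int i = 0; i < n; ++i) op[i] = o[i] / n;
  }
  fftw_destroy_plan(plan);
  return out;
}

// Per-row peak-to-peak and standard deviation of a matrix whose rows are
// (epoch, channel) pairs and columns are samples.
// [[Rcpp::export]]
List cpp_row_ptp_sd(const arma::mat& M) {
  const int nr = M.n_rows;
  arma::vec ptp(nr), sd(nr);
  for (int i = 0; i < nr; ++i) {
    ptp(i) = M.row(i).max() - M.row(i).min();
    sd(i) = arma::stddev(M.row(i));
  }
  return List::create(_["ptp"] = ptp, _["sd"] = sd);
}
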