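#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dense matrix exponential (scaling-and-squaring with Pade approximation).
// [[Rcpp::export]]
arma::mat expm_dense(const arma::mat& A) {
  return expmat(A);
}

// One exact step of M' = expm(A*dt) * (M + A^-1 C) - A^-1 C.
// [[Rcpp::export]]
arma::vec bm_step_cpp(const arma::vec& M, const arma::mat& A,
                      const arma::vec& C, double dt) {
  vec f;
  bool ok = solve(f, A, C);
  if (!ok) Rcpp::stop("evolution matrix is singular; cannot form A^-1 C");
  return expmat(A * dt) * (M + f) - f;
}

// Propagate one saturation event: n_pulses repetitions of (RF-on segment of
// length dt_p under A_pulse, RF-off gap of length dt_g under A_free), followed
// by a recovery interval dt_rec under A_free. Each distinct (matrix, dt) pair
// costs a single matrix exponential; repetitions reuse it.
// [[Rcpp::export]]
arma::vec bm_event_cpp(const arma::vec& M0, const arma::mat& A_pulse,
                       const arma::mat& A_free, const arma::vec& C,
                       double dt_p, double dt_g, int n_pulses, double dt_rec) {
  vec M = M0;
  vec fp, fg;
  mat Ep, Eg;
  bool has_pulse = (n_pulses > 0 && dt_p > 0.0);
  bool has_gap = (dt_g > 0.0);
  bool has_rec = (dt_rec > 0.0);

  if (has_pulse) {
    if (!solve(fp, A_pulse, C))
      Rcpp::stop("pulse evolution matrix is singular");
    Ep = expmat(A_pulse * dt_p);
  }
  if (has_gap || has_rec) {
    if (!solve(fg, A_free, C))
      Rcpp::stop("free evolution matrix is singular");
  }
  if (has_gap) Eg = expmat(A_free * dt_g);

  for (int i = 0; i < n_pulses; ++i) {
    if (has_pulse) M = Ep * (M + fp) - fp;
    if (has_gap)   M = Eg * (M + fg) - fg;
  }
  if (has_rec) {
    mat Er = expmat(A_free * dt_rec);
    M = Er * (M + fg) - fg;
  }
  if (!M.is_finite())
    Rcpp::stop("magnetization became non-finite during event propagation");
  return M;
}
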