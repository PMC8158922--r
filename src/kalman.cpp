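// Kalman filter / RTS smoother for the DFA state-space model
//   y_t = Z x_t + v_t,        v_t ~ N(0, diag(rdiag))
//   x_t = Phi x_{t-1} + w_t,  w_t ~ N(0, I_m)   (process noise fixed at 1)
//   x_1 ~ N(0, P1)
// Missing observations are encoded as NaN and simply dropped from the
// update step, so the returned log-likelihood is the exact Gaussian
// log-density of the observed cells.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// one filter step update; returns loglik increment
static double filter_update(const vec& ycol, const mat& Z, const vec& rdiag,
                            vec& x, mat& P) {
  uvec obs = find_finite(ycol);
  if (obs.n_elem == 0) return 0.0;
  mat Zt = Z.rows(obs);
  vec yo = ycol.elem(obs);
  vec ro = rdiag.elem(obs);
  mat PZ = P * Zt.t();
  mat S = Zt * PZ;
  S.diag() += ro;
  S = 0.5 * (S + S.t());
  mat Sc;
  if (!chol(Sc, S, "lower"))
    Rcpp::stop("innovation covariance not positive definite");
  vec innov = yo - Zt * x;
  vec z1 = solve(trimatl(Sc), innov);
  double ll = -0.5 * (obs.n_elem * LOG2PI + dot(z1, z1)) -
              accu(log(Sc.diag()));
  mat K = solve(trimatu(Sc.t()), solve(trimatl(Sc), PZ.t())).t();
  x += K * innov;
  // Joseph-form covariance update for numerical stability
  mat IKZ = eye(P.n_rows, P.n_rows) - K * Zt;
  P = IKZ * P * IKZ.t() + K * diagmat(ro) * K.t();
  P = 0.5 * (P + P.t());
  return ll;
}

// [[Rcpp::export]]
double kalman_loglik_cpp(const arma::mat& y, const arma::mat& Z,
                         const arma::vec& rdiag, const arma::vec& phi,
                         const arma::mat& P1) {
  const uword T = y.n_cols, m = Z.n_cols;
  vec x = zeros<vec>(m);
  mat P = P1;
  double ll = 0.0;
  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      x = phi % x;
      P = P.each_col() % phi;
      P = P.each_row() % phi.t();
      P.diag() += 1.0;
    }
    ll += filter_update(y.col(t), Z, rdiag, x, P);
  }
  return ll;
}

// Full filter + RTS smoother with lag-one covariances (for the EM E-step).
// [[Rcpp::export]]
Rcpp::List kalman_smooth_cpp(const arma::mat& y, const arma::mat& Z,
                             const arma::vec& rdiag, const arma::vec& phi,
                             const arma::mat& P1) {
  const uword T = y.n_cols, m = Z.n_cols;
  mat xp(m, T), xf(m, T);
  cube Pp(m, m, T), Pf(m, m, T);
  vec x = zeros<vec>(m);
  mat P = P1;
  double ll = 0.0;
  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      x = phi % x;
      P = P.each_col() % phi;
      P = P.each_row() % phi.t();
      P.diag() += 1.0;
    }
    xp.col(t) = x;
    Pp.slice(t) = P;
    ll += filter_update(y.col(t), Z, rdiag, x, P);
    xf.col(t) = x;
    Pf.slice(t) = P;
  }
  // RTS smoother
  mat xs(m, T);
  cube Ps(m, m, T), Plag(m, m, T, fill::zeros), J(m, m, T, fill::zeros);
  xs.col(T - 1) = xf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  for (uword t = T - 1; t-- > 0;) {
    // J_t = Pf_t Phi' Pp_{t+1}^{-1}
    mat PfPhi = Pf.slice(t);
    PfPhi = PfPhi.each_row() % phi.t();
    mat Jt = solve(Pp.slice(t + 1).t(), PfPhi.t()).t();
    J.slice(t) = Jt;
    xs.col(t) = xf.col(t) + Jt * (xs.col(t + 1) - xp.col(t + 1));
    mat Pst = Pf.slice(t) + Jt * (Ps.slice(t + 1) - Pp.slice(t + 1)) * Jt.t();
    Ps.slice(t) = 0.5 * (Pst + Pst.t());
  }
  // Cov(x_t, x_{t-1} | Y) = Ps_t * J_{t-1}'
  for (uword t = 1; t < T; ++t)
    Plag.slice(t) = Ps.slice(t) * J.slice(t - 1).t();
  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("xs") = xs,
      Rcpp::Named("Ps") = Ps, Rcpp::Named("Plag") = Plag);
}
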