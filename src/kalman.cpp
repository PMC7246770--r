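// Exact Kalman filter / RTS smoother for the daily state-space form of the
// functional spatio-temporal model.
//
// State: z_t (m = n * p), component-major stacking (component j's n station
// values contiguous), diagonal transition gdiag (g_j replicated over
// stations) and block-diagonal innovation covariance Q.  Observations within
// a day have diagonal measurement-error covariance, so they are processed
// sequentially (univariate updates), which also handles missing entries
// (NaN) by exact marginalization: a missing entry is skipped.
//
// The observation loading never materializes: the cell of station i at hour
// h loads state entries (j*n + i, j = 0..p-1) with weights Phiz(h, j), the
// latent basis evaluated at h.  The rank-one covariance update is done in
// place to keep the per-observation cost at ~m^2/2 flops with no
// allocations.
//
// y      : nq x T observations (NaN = missing), hour-minor station-major
// d      : nq x T observation offsets (fixed-effects mean)
// rdiag  : nq measurement-error variances
// Phiz   : q x p latent basis values
// gdiag  : m transition diagonal
// Q      : m x m innovation covariance
// a0, P0 : initial state law at day 0

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void symmetrize(mat& A) { A = 0.5 * (A + A.t()); }

// [[Rcpp::export(name = ".kalman_core")]]
Rcpp::List kalman_core(const arma::mat& y, const arma::mat& d,
                       const arma::vec& rdiag, const arma::mat& Phiz,
                       const arma::vec& gdiag, const arma::mat& Q,
                       const arma::vec& a0, const arma::mat& P0,
                       int n, bool smooth = true, bool moments = true) {
  const uword nq = y.n_rows, T = y.n_cols, m = gdiag.n_elem;
  const uword q = Phiz.n_rows, p = Phiz.n_cols;
  if (d.n_rows != nq || d.n_cols != T || rdiag.n_elem != nq ||
      Q.n_rows != m || P0.n_rows != m || a0.n_elem != m ||
      (uword)n * q != nq || (uword)n * p != m)
    Rcpp::stop("kalman_core: inconsistent dimensions");

  const bool keep = smooth || moments;
  mat a_filt, a_pred;
  cube P_filt, P_pred;
  if (keep) {
    a_filt.set_size(m, T + 1); a_pred.set_size(m, T);
    P_filt.set_size(m, m, T + 1); P_pred.set_size(m, m, T);
  }

  vec a = a0;
  mat P = P0;
  symmetrize(P);
  if (keep) { a_filt.col(0) = a; P_filt.slice(0) = P; }

  vec M(m);
  double loglik = 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (uword t = 0; t < T; ++t) {
    // time update (diagonal transition)
    a %= gdiag;
    for (uword c = 0; c < m; ++c)
      for (uword rr = 0; rr < m; ++rr)
        P(rr, c) = gdiag(rr) * gdiag(c) * P(rr, c) + Q(rr, c);
    if (keep) { a_pred.col(t) = a; P_pred.slice(t) = P; }

    // measurement updates, one scalar observation at a time
    for (uword r = 0; r < nq; ++r) {
      const double yv = y(r, t);
      if (!std::isfinite(yv)) continue;
      const uword i = r / q, h = r % q;
      // M = P phi_row', f = phi_row M + r, v = y - d - phi_row a
      M.zeros();
      double v = yv - d(r, t);
      for (uword j = 0; j < p; ++j) {
        const double w = Phiz(h, j);
        if (w == 0.0) continue;
        const uword c = j * (uword)n + i;
        M += w * P.col(c);
        v -= w * a(c);
      }
      double f = rdiag(r);
      for (uword j = 0; j < p; ++j) {
        const double w = Phiz(h, j);
        if (w != 0.0) f += w * M(j * (uword)n + i);
      }
      if (!(f > 0.0) || !std::isfinite(f))
        Rcpp::stop("non-positive innovation variance at day %d", (int)(t + 1));
      const double vf = v / f;
      a += vf * M;
      // in-place symmetric rank-one downdate P -= M M' / f
      const double invf = 1.0 / f;
      for (uword c = 0; c < m; ++c) {
        const double mc = M(c) * invf;
        if (mc == 0.0) continue;
        double* Pc = P.colptr(c);
        for (uword rr = c; rr < m; ++rr) Pc[rr] -= M(rr) * mc;
      }
      for (uword c = 1; c < m; ++c)
        for (uword rr = 0; rr < c; ++rr) P(rr, c) = P(c, rr);
      loglik += -0.5 * (LOG2PI + std::log(f) + v * vf);
    }
    symmetrize(P);
    if (keep) { a_filt.col(t + 1) = a; P_filt.slice(t + 1) = P; }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = loglik);
  if (!keep) return out;
  out["a_filt"] = a_filt; out["P_filt"] = P_filt;
  out["a_pred"] = a_pred; out["P_pred"] = P_pred;
  if (!smooth) return out;

  // fixed-interval RTS smoother with lag-one cross-covariances
  mat a_sm(m, T + 1);
  cube P_sm(m, m, T + 1), P_lag(m, m, T);
  a_sm.col(T) = a_filt.col(T);
  P_sm.slice(T) = P_filt.slice(T);

  for (uword t = T; t >= 1; --t) {
    mat Ppred = P_pred.slice(t - 1);  // P_{t | t-1}
    symmetrize(Ppred);
    mat Pinv;
    if (!inv_sympd(Pinv, Ppred)) Pinv = pinv(Ppred);
    // J = P_{t-1|t-1} G' Ppred^{-1}; G diagonal
    mat J = (P_filt.slice(t - 1).each_row() % gdiag.t()) * Pinv;
    a_sm.col(t - 1) = a_filt.col(t - 1) +
      J * (a_sm.col(t) - a_pred.col(t - 1));
    mat Ps = P_filt.slice(t - 1) +
      J * (P_sm.slice(t) - Ppred) * J.t();
    symmetrize(Ps);
    P_sm.slice(t - 1) = Ps;
    // Cov(z_t, z_{t-1} | Y) = P_{t|T} J'
    P_lag.slice(t - 1) = P_sm.slice(t) * J.t();
  }

  out["a_sm"] = a_sm;
  out["P_sm"] = P_sm;
  out["P_lag"] = P_lag;
  return out;
}
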