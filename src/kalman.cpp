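// Kalman filter / RTS smoother core for time-invariant linear-Gaussian
// state-space models with missing observations. Covariances are
// re-symmetrised every step; the likelihood is the prediction-error
// decomposition over observed steps only.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
List kf_core(const arma::mat& y, const arma::uvec& obs_flag,
             const arma::mat& F, const arma::mat& G, const arma::mat& H,
             const arma::mat& Q, const arma::mat& R,
             const arma::vec& x0, const arma::mat& V0) {
  const arma::uword T = y.n_rows;
  const arma::uword p = F.n_rows;
  const arma::uword d = H.n_rows;

  arma::mat xp(p, T), xf(p, T);
  arma::cube Vp(p, p, T), Vf(p, p, T);

  arma::vec x = x0;
  arma::mat V = V0;
  const arma::mat GQG = G * Q * G.t();
  const double l2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  int n_used = 0;

  for (arma::uword t = 0; t < T; ++t) {
    arma::vec xpred = F * x;
    arma::mat Vpred = F * V * F.t() + GQG;
    Vpred = 0.5 * (Vpred + Vpred.t());
    xp.col(t) = xpred;
    Vp.slice(t) = Vpred;

    if (obs_flag(t)) {
      arma::mat S = H * Vpred * H.t() + R;
      S = 0.5 * (S + S.t());
      arma::mat Sinv;
      if (!arma::inv_sympd(Sinv, S))
        stop("innovation covariance numerically singular at step %d", (int)(t + 1));
      arma::vec innov = y.row(t).t() - H * xpred;
      double ldet, sgn;
      arma::log_det(ldet, sgn, S);
      ll += -0.5 * (d * l2pi + ldet + arma::as_scalar(innov.t() * Sinv * innov));
      arma::mat K = Vpred * H.t() * Sinv;
      x = xpred + K * innov;
      V = Vpred - K * H * Vpred;
      V = 0.5 * (V + V.t());
      ++n_used;
    } else {
      // gap: filtering distribution equals the one-step-ahead prediction
      x = xpred;
      V = Vpred;
    }
    xf.col(t) = x;
    Vf.slice(t) = V;
  }

  return List::create(_["xp"] = xp.t(), _["Vp"] = Vp,
                      _["xf"] = xf.t(), _["Vf"] = Vf,
                      _["loglik"] = ll, _["n_used"] = n_used);
}

// [[Rcpp::export]]
List ks_core(const arma::mat& xp, const arma::cube& Vp,
             const arma::mat& xf, const arma::cube& Vf,
             const arma::mat& F) {
  const arma::uword T = xp.n_rows;
  const arma::uword p = F.n_rows;

  arma::mat xs(p, T);
  arma::cube Vs(p, p, T);
  xs.col(T - 1) = xf.row(T - 1).t();
  Vs.slice(T - 1) = Vf.slice(T - 1);
  int pinv_tally = 0;

  for (arma::uword t = T - 1; t-- > 0;) {
    const arma::mat& Vpred = Vp.slice(t + 1);
    arma::mat Vpinv;
    if (!arma::inv_sympd(Vpinv, Vpred)) {
      Vpinv = arma::pinv(Vpred);
      ++pinv_tally;
    }
    arma::mat A = Vf.slice(t) * F.t() * Vpinv;
    xs.col(t) = xf.row(t).t() + A * (xs.col(t + 1) - xp.row(t + 1).t());
    arma::mat V = Vf.slice(t) + A * (Vs.slice(t + 1) - Vpred) * A.t();
    Vs.slice(t) = 0.5 * (V + V.t());
  }

  return List::create(_["xs"] = xs.t(), _["Vs"] = Vs,
                      _["pinv_tally"] = pinv_tally);
}
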