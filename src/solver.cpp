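// Analytic solution of the depot -> HCQ -> {DesCQ, DesHCQ, DiDesCQ} linear
// cascade under multiple dosing, plus the per-subject observation likelihood
// used by the Laplace inner loop.
//
// theta layout (length 10), all rates first-order, volumes apparent (/F):
//   0 lag (h), 1 ka (1/h), 2 v (L), 3 cl_parent (L/h),
//   4-6 cl_form  DesCQ, DesHCQ, DiDesCQ (L/h),
//   7-9 cl_met   DesCQ, DesHCQ, DiDesCQ (L/h)
// Compartments: 0 depot, 1 HCQ, 2 DesCQ, 3 DesHCQ, 4 DiDesCQ.
// eta layout (length 5): cl_parent, v, cl_met[DesCQ, DesHCQ, DiDesCQ].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double REL_GAP = 1e-9;

static bool near_rate(double a, double b) {
  double m = std::max(std::max(std::fabs(a), std::fabs(b)), 1e-12);
  return std::fabs(a - b) / m < REL_GAP;
}

static arma::mat make_A(const arma::vec& th) {
  double ka = th[1], v = th[2];
  arma::mat A(5, 5, arma::fill::zeros);
  double kout = (th[3] + th[4] + th[5] + th[6]) / v;
  A(0, 0) = -ka;
  A(1, 0) = ka;
  A(1, 1) = -kout;
  for (int m = 0; m < 3; ++m) {
    A(2 + m, 1) = th[4 + m] / v;
    A(2 + m, 2 + m) = -th[7 + m] / v;
  }
  return A;
}

// Unit depot bolus response at elapsed time tau >= 0 (closed form; requires
// pairwise-distinct rates ka, kP, km[m] as guaranteed by the caller).
static void unit_response(double tau, double ka, double kP,
                          const arma::vec& kf, const arma::vec& km,
                          arma::vec& a) {
  double eka = std::exp(-ka * tau), ekP = std::exp(-kP * tau);
  a[0] = eka;
  a[1] = ka / (ka - kP) * (ekP - eka);
  for (int m = 0; m < 3; ++m) {
    double ekm = std::exp(-km[m] * tau);
    a[2 + m] = ka * kf[m] * (eka / ((kP - ka) * (km[m] - ka)) +
                             ekP / ((ka - kP) * (km[m] - kP)) +
                             ekm / ((ka - km[m]) * (kP - km[m])));
  }
}

// Molar amounts (same unit as dose_amt) in the 5 compartments at each
// requested time, by superposition of single-dose responses.
// [[Rcpp::export]]
arma::mat cpp_amounts(const arma::vec& theta, const arma::vec& dose_time,
                      const arma::vec& dose_amt, const arma::vec& times) {
  const double lag = theta[0], ka = theta[1], v = theta[2];
  const double kP = (theta[3] + theta[4] + theta[5] + theta[6]) / v;
  arma::vec kf = theta.subvec(4, 6) / v;
  arma::vec km = theta.subvec(7, 9) / v;

  bool analytic = !near_rate(ka, kP);
  for (int m = 0; m < 3 && analytic; ++m)
    if (near_rate(ka, km[m]) || near_rate(kP, km[m])) analytic = false;

  arma::mat out(5, times.n_elem, arma::fill::zeros);
  arma::vec a(5);
  arma::mat A;
  if (!analytic) A = make_A(theta);

  for (arma::uword t = 0; t < times.n_elem; ++t) {
    for (arma::uword d = 0; d < dose_time.n_elem; ++d) {
      double tau = times[t] - dose_time[d] - lag;
      if (tau < 0.0 || dose_amt[d] == 0.0) continue;
      if (analytic) {
        unit_response(tau, ka, kP, kf, km, a);
      } else {
        arma::mat E = arma::expmat(A * tau);  // scaling-and-squaring fallback
        a = E.col(0);
      }
      out.col(t) += dose_amt[d] * a;
    }
  }
  out.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return out;
}

static arma::vec theta_with_eta(const arma::vec& theta, const arma::vec& eta) {
  arma::vec th = theta;
  th[3] *= std::exp(eta[0]);
  th[2] *= std::exp(eta[1]);
  for (int m = 0; m < 3; ++m) th[7 + m] *= std::exp(eta[2 + m]);
  return th;
}

// Predicted concentrations (amount/volume) for observation records.
// obs_cmt: 1 = HCQ, 2 = DesCQ, 3 = DesHCQ, 4 = DiDesCQ.
// [[Rcpp::export]]
arma::vec cpp_pred_obs(const arma::vec& theta, const arma::vec& dose_time,
                       const arma::vec& dose_amt, const arma::vec& obs_time,
                       const arma::ivec& obs_cmt) {
  arma::mat amt = cpp_amounts(theta, dose_time, dose_amt, obs_time);
  arma::vec pred(obs_time.n_elem);
  for (arma::uword j = 0; j < obs_time.n_elem; ++j)
    pred[j] = amt(obs_cmt[j], j) / theta[2];
  return pred;
}

// [[Rcpp::export]]
arma::vec cpp_pred_eta(const arma::vec& eta, const arma::vec& theta,
                       const arma::vec& dose_time, const arma::vec& dose_amt,
                       const arma::vec& obs_time, const arma::ivec& obs_cmt) {
  return cpp_pred_obs(theta_with_eta(theta, eta), dose_time, dose_amt,
                      obs_time, obs_cmt);
}

// Negative log joint density of one subject's observations and eta:
// sum_j 0.5*(log(2*pi*var_j) + (y_j - f_j)^2/var_j)
//   + sum_{k: omega_k > 0} 0.5*(eta_k^2/omega_k^2 + log(2*pi*omega_k^2)).
// prop/add are per-compound (length 4), add in the working concentration unit.
// [[Rcpp::export]]
double cpp_subject_nll(const arma::vec& eta, const arma::vec& theta,
                       const arma::vec& dose_time, const arma::vec& dose_amt,
                       const arma::vec& obs_time, const arma::ivec& obs_cmt,
                       const arma::vec& y, const arma::vec& prop,
                       const arma::vec& add, const arma::vec& omega,
                       bool include_prior) {
  static const double LOG2PI = 1.8378770664093453;
  arma::vec pred = cpp_pred_eta(eta, theta, dose_time, dose_amt,
                                obs_time, obs_cmt);
  double nll = 0.0;
  for (arma::uword j = 0; j < pred.n_elem; ++j) {
    int c = obs_cmt[j] - 1;
    double var = prop[c] * prop[c] * pred[j] * pred[j] + add[c] * add[c];
    double r = y[j] - pred[j];
    nll += 0.5 * (LOG2PI + std::log(var) + r * r / var);
  }
  if (include_prior) {
    for (arma::uword k = 0; k < omega.n_elem; ++k) {
      if (omega[k] > 0.0)
        nll += 0.5 * (eta[k] * eta[k] / (omega[k] * omega[k]) +
                      LOG2PI + 2.0 * std::log(omega[k]));
    }
  }
  return nll;
}
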