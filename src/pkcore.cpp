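// Core numerics: closed-form two-compartment IV-infusion kinetics and the
// FOCE-I (first-order conditional estimation with eta-eps interaction)
// objective for log-transformed concentration data. Kept in compiled code
// because the inner empirical-Bayes optimisation runs once per subject per
// outer objective evaluation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Disp {
  double CL, V1, Q, V2;
  double k10, k12, k21, alpha, beta;
  double A, B;        // bolus coefficients: C = (D/V1)(A e^-at + B e^-bt)
  bool onecmt;        // Q == 0 degenerate
  bool repeated;      // alpha ~ beta guarded limit
  double lambda;      // repeated root
};

Disp make_disp(double CL, double V1, double Q, double V2) {
  Disp d;
  d.CL = CL; d.V1 = V1; d.Q = Q; d.V2 = V2;
  d.k10 = CL / V1;
  if (Q <= 0.0) {
    d.k12 = 0.0; d.k21 = 0.0;
    d.alpha = d.k10; d.beta = 0.0;
    d.A = 1.0; d.B = 0.0;
    d.onecmt = true; d.repeated = false; d.lambda = d.k10;
    return d;
  }
  d.onecmt = false;
  d.k12 = Q / V1;
  d.k21 = Q / V2;
  double s = d.k10 + d.k12 + d.k21;
  double p = d.k10 * d.k21;
  double disc = s * s - 4.0 * p;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  d.alpha = 0.5 * (s + disc);
  d.beta  = 0.5 * (s - disc);
  // beta = p/alpha is numerically safer when disc ~ s
  if (d.alpha > 0.0) d.beta = p / d.alpha;
  if (std::fabs(d.alpha - d.beta) < 1e-10 * d.alpha) {
    d.repeated = true;
    d.lambda = 0.5 * (d.alpha + d.beta);
    d.A = 0.0; d.B = 0.0;
  } else {
    d.repeated = false;
    d.lambda = 0.0;
    d.A = (d.alpha - d.k21) / (d.alpha - d.beta);
    d.B = (d.k21 - d.beta) / (d.alpha - d.beta);
  }
  return d;
}

// Central concentration at time tau after the start of a never-ending
// constant-rate infusion R (mg/h). A finite infusion of duration D is the
// superposition cinf(tau) - cinf(tau - D).
inline double cinf(double tau, double R, const Disp& d) {
  if (tau <= 0.0) return 0.0;
  if (d.onecmt)
    return (R / d.CL) * (-std::expm1(-d.k10 * tau));
  if (d.repeated) {
    double l = d.lambda, e = std::exp(-l * tau);
    return (R / d.V1) * ((1.0 - e) / l +
           (d.k21 - l) * (1.0 - e * (1.0 + l * tau)) / (l * l));
  }
  return (R / d.V1) * (d.A / d.alpha * (-std::expm1(-d.alpha * tau)) +
                       d.B / d.beta  * (-std::expm1(-d.beta  * tau)));
}

inline double conc_one(double t,
                       const double* dt, const double* damt,
                       const double* ddur, int ndose,
                       const Disp& d) {
  double c = 0.0;
  for (int k = 0; k < ndose; ++k) {
    double tau = t - dt[k];
    if (tau <= 0.0) continue;
    double R = damt[k] / ddur[k];
    c += cinf(tau, R, d);
    double tau2 = tau - ddur[k];
    if (tau2 > 0.0) c -= cinf(tau2, R, d);
  }
  return c;
}

// Maintenance dosing is typically a long run of identical, equally spaced
// infusions; superposition over such a run collapses to a geometric series
// in exp(-lambda * delta), evaluated from the most recent dose backwards so
// every term is <= 1 (no overflow).
struct DoseRun { double s0, amt, dur, delta; int n; };

std::vector<DoseRun> build_runs(const double* dt, const double* damt,
                                const double* ddur, int nd) {
  std::vector<DoseRun> runs;
  int i = 0;
  while (i < nd) {
    DoseRun r; r.s0 = dt[i]; r.amt = damt[i]; r.dur = ddur[i];
    r.delta = 0.0; r.n = 1;
    int j = i + 1;
    if (j < nd && damt[j] == r.amt && ddur[j] == r.dur && dt[j] > dt[i]) {
      double delta = dt[j] - dt[i];
      while (j < nd && damt[j] == r.amt && ddur[j] == r.dur &&
             std::fabs(dt[j] - (r.s0 + r.n * delta)) < 1e-9 * (1.0 + delta)) {
        ++r.n; ++j;
      }
      r.delta = delta;
    }
    runs.push_back(r);
    i += r.n;
  }
  return runs;
}

// sum over `m` equally spaced unit exponentials ending at tau_last:
//   sum_{k=0}^{m-1} exp(-lam * (tau_last + k * delta))
inline double geom_exp_sum(double lam, double tau_last, double delta, int m) {
  double q = std::exp(-lam * delta);
  double head = std::exp(-lam * tau_last);
  if (q >= 1.0) return head * m;          // lam ~ 0 degenerate
  return head * (1.0 - std::pow(q, m)) / (1.0 - q);
}

inline double conc_runs(double t, const std::vector<DoseRun>& runs,
                        const Disp& d) {
  double c = 0.0;
  for (const DoseRun& run : runs) {
    if (t <= run.s0) continue;
    double R = run.amt / run.dur;
    bool simple = run.n == 1 || run.dur >= run.delta || d.repeated;
    if (simple) {
      for (int k = 0; k < run.n; ++k) {
        double tau = t - (run.s0 + k * run.delta);
        if (tau <= 0.0) break;
        c += cinf(tau, R, d);
        if (tau > run.dur) c -= cinf(tau - run.dur, R, d);
      }
      continue;
    }
    // doses started strictly before t
    int m = (int)std::floor((t - run.s0) / run.delta - 1e-12) + 1;
    if (m > run.n) m = run.n;
    if (m < 1) continue;
    double s_last = run.s0 + (m - 1) * run.delta;
    int mf = (t >= s_last + run.dur) ? m : m - 1;
    if (mf > 0) {
      double tau_lf = t - (run.s0 + (mf - 1) * run.delta);
      if (d.onecmt) {
        c += (R / d.CL) * std::expm1(d.k10 * run.dur) *
             geom_exp_sum(d.k10, tau_lf, run.delta, mf);
      } else {
        double Sa = std::expm1(d.alpha * run.dur) *
                    geom_exp_sum(d.alpha, tau_lf, run.delta, mf);
        double Sb = std::expm1(d.beta * run.dur) *
                    geom_exp_sum(d.beta, tau_lf, run.delta, mf);
        c += (R / d.V1) * (d.A / d.alpha * Sa + d.B / d.beta * Sb);
      }
    }
    if (mf < m) c += cinf(t - s_last, R, d);  // mid-infusion dose
  }
  return c;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector t,
                       NumericVector dose_t, NumericVector dose_amt,
                       NumericVector dose_dur,
                       double CL, double V1, double Q, double V2) {
  Disp d = make_disp(CL, V1, Q, V2);
  int n = t.size(), nd = dose_t.size();
  std::vector<DoseRun> runs = build_runs(dose_t.begin(), dose_amt.begin(),
                                         dose_dur.begin(), nd);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = conc_runs(t[i], runs, d);
  return out;
}

namespace {

// log-predictions for one subject at random effects eta (mapped onto CL, V1)
void lnf_subject(const arma::vec& obs_t,
                 const std::vector<DoseRun>& runs,
                 double tvcl, double tvv1, double tvq, double tvv2,
                 double eta_cl, double eta_v1,
                 arma::vec& out) {
  Disp d = make_disp(tvcl * std::exp(eta_cl), tvv1 * std::exp(eta_v1),
                     tvq, tvv2);
  for (arma::uword i = 0; i < obs_t.n_elem; ++i) {
    double c = conc_runs(obs_t[i], runs, d);
    out[i] = c > 0.0 ? std::log(c) : -745.0; // log of smallest double
  }
}

struct SubjFit {
  double ofv;
  arma::vec eta;      // length 2 (inactive dims zero)
  bool ok;
  arma::vec ipred, pred, cwres, iwres;
};

// Inner empirical-Bayes problem + FOCE-I marginal contribution for one
// subject. Active eta dimensions are those with positive omega^2.
SubjFit foce_subject(const arma::vec& lny, const arma::vec& obs_t,
                     const std::vector<DoseRun>& runs,
                     double tvcl, double tvv1, double tvq, double tvv2,
                     double om2cl, double om2v1, double W,
                     arma::vec eta0, bool want_diag) {
  const int nobs = lny.n_elem;
  SubjFit res;
  res.eta = arma::zeros(2);
  res.ok = true;
  const double W2 = W * W;

  std::vector<int> act;
  if (om2cl > 0.0) act.push_back(0);
  if (om2v1 > 0.0) act.push_back(1);
  const int ne = (int)act.size();

  arma::vec f(nobs);
  auto eval_f = [&](const arma::vec& eta_full, arma::vec& out) {
    lnf_subject(obs_t, runs, tvcl, tvv1, tvq, tvv2,
                eta_full[0], eta_full[1], out);
  };

  arma::vec eta = arma::zeros(2);
  if (ne > 0 && eta0.n_elem == 2) eta = eta0;
  for (int j = 0; j < 2; ++j)
    if ((j == 0 && om2cl <= 0.0) || (j == 1 && om2v1 <= 0.0)) eta[j] = 0.0;

  arma::vec om2(2);
  om2[0] = om2cl; om2[1] = om2v1;

  arma::mat J(nobs, std::max(ne, 1), arma::fill::zeros);
  const double h = 1e-5;

  auto jacobian = [&](const arma::vec& at) {
    arma::vec fp(nobs), fm(nobs);
    for (int j = 0; j < ne; ++j) {
      arma::vec e1 = at, e2 = at;
      e1[act[j]] += h; e2[act[j]] -= h;
      eval_f(e1, fp); eval_f(e2, fm);
      J.col(j) = (fp - fm) / (2.0 * h);
    }
  };

  if (ne > 0) {
    // damped Gauss-Newton on g(eta) = |r|^2/W^2 + eta' Oinv eta
    arma::vec oinv(ne);
    for (int j = 0; j < ne; ++j) oinv[j] = 1.0 / om2[act[j]];
    eval_f(eta, f);
    arma::vec r = lny - f;
    double g = arma::dot(r, r) / W2;
    for (int j = 0; j < ne; ++j) g += oinv[j] * eta[act[j]] * eta[act[j]];
    double damp = 1e-8;
    bool conv = false;
    for (int it = 0; it < 100; ++it) {
      jacobian(eta);
      arma::vec ea(ne);
      for (int j = 0; j < ne; ++j) ea[j] = eta[act[j]];
      arma::vec grad = -J.t() * r / W2 + oinv % ea;         // 0.5 * dg/deta
      if (arma::norm(grad, 2) < 1e-8) { conv = true; break; }
      arma::mat Hgn = J.t() * J / W2;
      Hgn.diag() += oinv;
      bool stepped = false;
      for (int tries = 0; tries < 12 && !stepped; ++tries) {
        arma::mat Hd = Hgn;
        Hd.diag() += damp;
        arma::vec step;
        bool okslv = arma::solve(step, Hd, -grad, arma::solve_opts::no_approx);
        if (okslv) {
          arma::vec etan = eta;
          for (int j = 0; j < ne; ++j) etan[act[j]] += step[j];
          arma::vec fn(nobs);
          eval_f(etan, fn);
          arma::vec rn = lny - fn;
          double gn = arma::dot(rn, rn) / W2;
          for (int j = 0; j < ne; ++j)
            gn += oinv[j] * etan[act[j]] * etan[act[j]];
          if (std::isfinite(gn) && gn <= g + 1e-12) {
            double rel = std::fabs(g - gn) / (std::fabs(g) + 1.0);
            eta = etan; f = fn; r = rn; g = gn;
            damp = std::max(damp * 0.25, 1e-10);
            stepped = true;
            if (rel < 1e-13 && arma::norm(step, 2) < 1e-9) {
              conv = true;
            }
          }
        }
        if (!stepped) damp *= 10.0;
      }
      if (!stepped) { conv = arma::norm(grad, 2) < 1e-5; break; }
      if (conv) break;
    }
    if (!conv) {
      // fall through with best eta found; flag if gradient is still large
      jacobian(eta);
      arma::vec ea(ne);
      for (int j = 0; j < ne; ++j) ea[j] = eta[act[j]];
      arma::vec grad = -J.t() * r / W2 + oinv % ea;
      if (arma::norm(grad, 2) > 1e-4) res.ok = false;
    }
    jacobian(eta);  // G at eta-hat

    // FOCE-I marginal: Sigma = G Omega G' + W^2 I, rm = y - f(etahat) + G etahat
    arma::mat G = J.cols(0, ne - 1);
    arma::mat Sig = W2 * arma::eye(nobs, nobs);
    for (int j = 0; j < ne; ++j)
      Sig += om2[act[j]] * (G.col(j) * G.col(j).t());
    arma::vec ea(ne);
    for (int j = 0; j < ne; ++j) ea[j] = eta[act[j]];
    arma::vec rm = (lny - f) + G * ea;
    arma::mat L;
    if (!arma::chol(L, Sig, "lower")) {
      res.ofv = 1e10; res.ok = false; res.eta = eta;
      return res;
    }
    arma::vec z = arma::solve(arma::trimatl(L), rm);
    double logdet = 0.0;
    for (int i = 0; i < nobs; ++i) logdet += 2.0 * std::log(L(i, i));
    res.ofv = logdet + arma::dot(z, z);
    res.eta = eta;
    if (want_diag) {
      res.cwres = z;
      res.ipred = f;
      res.iwres = (lny - f) / W;
      arma::vec f0(nobs);
      eval_f(arma::zeros(2), f0);
      res.pred = f0;
    }
  } else {
    // no random effects: plain log-normal regression -2LL (no 2*pi constant)
    eval_f(eta, f);
    arma::vec r = lny - f;
    res.ofv = nobs * std::log(W2) + arma::dot(r, r) / W2;
    res.eta = eta;
    if (want_diag) {
      res.cwres = r / W;
      res.ipred = f;
      res.iwres = r / W;
      res.pred = f;
    }
  }
  if (!std::isfinite(res.ofv)) { res.ofv = 1e10; res.ok = false; }
  return res;
}

} // namespace

// Dataset layout: observations and doses flattened across subjects with
// 0-based pointer vectors obs_ptr/dose_ptr of length n_subjects + 1.
//' @noRd
// [[Rcpp::export]]
List cpp_foce(NumericVector lny, NumericVector obs_t, IntegerVector obs_ptr,
              NumericVector dose_t, NumericVector dose_amt,
              NumericVector dose_dur, IntegerVector dose_ptr,
              NumericVector tvcl, NumericVector tvv1,
              NumericVector tvq, NumericVector tvv2,
              double om2cl, double om2v1, double W,
              NumericMatrix eta_start, bool want_diag) {
  const int ns = obs_ptr.size() - 1;
  double ofv = 0.0;
  NumericVector ofv_i(ns);
  NumericMatrix eta(ns, 2);
  LogicalVector ok(ns);
  int ntot = lny.size();
  NumericVector pred(want_diag ? ntot : 0), ipred(want_diag ? ntot : 0),
                cwres(want_diag ? ntot : 0), iwres(want_diag ? ntot : 0);

  for (int i = 0; i < ns; ++i) {
    int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    int d0 = dose_ptr[i], d1 = dose_ptr[i + 1];
    arma::vec y(o1 - o0), tt(o1 - o0);
    for (int k = o0; k < o1; ++k) { y[k - o0] = lny[k]; tt[k - o0] = obs_t[k]; }
    arma::vec e0(2);
    e0[0] = eta_start(i, 0); e0[1] = eta_start(i, 1);
    std::vector<DoseRun> runs = build_runs(dose_t.begin() + d0,
                                           dose_amt.begin() + d0,
                                           dose_dur.begin() + d0, d1 - d0);
    SubjFit sf = foce_subject(y, tt, runs,
                              tvcl[i], tvv1[i], tvq[i], tvv2[i],
                              om2cl, om2v1, W, e0, want_diag);
    ofv += sf.ofv;
    ofv_i[i] = sf.ofv;
    eta(i, 0) = sf.eta[0]; eta(i, 1) = sf.eta[1];
    ok[i] = sf.ok;
    if (want_diag) {
      for (int k = o0; k < o1; ++k) {
        pred[k]  = sf.pred[k - o0];
        ipred[k] = sf.ipred[k - o0];
        cwres[k] = sf.cwres[k - o0];
        iwres[k] = sf.iwres[k - o0];
      }
    }
  }
  List out = List::create(_["ofv"] = ofv, _["ofv_i"] = ofv_i,
                          _["eta"] = eta, _["ok"] = ok);
  if (want_diag) {
    out["pred"] = pred; out["ipred"] = ipred;
    out["cwres"] = cwres; out["iwres"] = iwres;
  }
  return out;
}
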