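// Closed-form two-compartment IV-infusion kinetics and the FOCE
// (first-order conditional, optionally with interaction) marginal
// likelihood. Hot path of the estimation engine: called thousands of
// times per fit, hence C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Disposition macro-constants of the linear mammillary model.
// Q <= 0 or V2 <= 0 collapses to the one-compartment limit (single
// exponential CL/V1); alpha > beta always holds for valid inputs.
struct Macro {
  int nterm;
  double lam[2]; // alpha, beta (1/h)
  double coef[2]; // unit-bolus central coefficients A, B (1/L)
};

static inline Macro macro_constants(double V1, double V2, double CL, double Q) {
  Macro m;
  if (Q <= 0.0 || V2 <= 0.0) {
    m.nterm = 1;
    m.lam[0] = CL / V1;
    m.coef[0] = 1.0 / V1;
    return m;
  }
  double k10 = CL / V1, k12 = Q / V1, k21 = Q / V2;
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  if (disc < 0.0) disc = 0.0;
  double root = std::sqrt(disc);
  double alpha = 0.5 * (s + root);
  double beta = 0.5 * (s - root);
  // guard the (measure-zero) repeated-root case
  double gap = alpha - beta;
  if (gap < 1e-12 * alpha) {
    alpha *= (1.0 + 1e-9);
    beta *= (1.0 - 1e-9);
    gap = alpha - beta;
  }
  m.nterm = 2;
  m.lam[0] = alpha;
  m.lam[1] = beta;
  m.coef[0] = (alpha - k21) / (V1 * gap);
  m.coef[1] = (k21 - beta) / (V1 * gap);
  return m;
}

// Concentration (mg/L == ug/mL) at times t from superposed
// constant-rate infusions: dose j delivers amt[j] mg over dur[j] h
// starting at dt[j].
static arma::vec conc_profile(const arma::vec& t,
                              const arma::vec& dt, const arma::vec& da,
                              const arma::vec& dd,
                              double V1, double V2, double CL, double Q) {
  Macro m = macro_constants(V1, V2, CL, Q);
  const int nt = t.n_elem, nd = dt.n_elem;
  arma::vec out(nt, arma::fill::zeros);
  for (int j = 0; j < nd; ++j) {
    double rate = da[j] / dd[j];
    for (int i = 0; i < nt; ++i) {
      double tau = t[i] - dt[j];
      if (tau <= 0.0) continue;
      double c = 0.0;
      for (int k = 0; k < m.nterm; ++k) {
        double lam = m.lam[k], cf = m.coef[k];
        if (tau < dd[j]) {
          c += rate * cf / lam * (1.0 - std::exp(-lam * tau));
        } else {
          c += rate * cf / lam * (1.0 - std::exp(-lam * dd[j])) *
               std::exp(-lam * (tau - dd[j]));
        }
      }
      out[i] += c;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec conc_cpp(const arma::vec& t, const arma::vec& dose_time,
                   const arma::vec& dose_amt, const arma::vec& dose_dur,
                   double V1, double V2, double CL, double Q) {
  return conc_profile(t, dose_time, dose_amt, dose_dur, V1, V2, CL, Q);
}

struct SubjData {
  arma::vec dt, da, dd, t, y;
};

// residual variance per observation given predictions
static arma::vec res_var(const arma::vec& f, int res_type,
                         double sig_add, double sig_prop) {
  arma::vec s2(f.n_elem);
  for (arma::uword i = 0; i < f.n_elem; ++i) {
    double v = 0.0;
    if (res_type == 0) v = sig_add * sig_add;
    else if (res_type == 1) v = sig_prop * f[i] * sig_prop * f[i];
    else v = sig_prop * f[i] * sig_prop * f[i] + sig_add * sig_add;
    s2[i] = std::max(v, 1e-12);
  }
  return s2;
}

class InnerProblem {
public:
  const SubjData& d;
  arma::rowvec tp; // typical individual params V1 V2 CL Q (eta = 0)
  const arma::uvec& eta_cols;
  const arma::vec& omega;
  int res_type;
  double sig_add, sig_prop;
  bool interaction;

  InnerProblem(const SubjData& d_, const arma::rowvec& tp_,
               const arma::uvec& cols, const arma::vec& om,
               int rt, double sa, double sp, bool inter)
    : d(d_), tp(tp_), eta_cols(cols), omega(om), res_type(rt),
      sig_add(sa), sig_prop(sp), interaction(inter) {}

  arma::vec pred(const arma::vec& eta) const {
    double p[4] = {tp[0], tp[1], tp[2], tp[3]};
    for (arma::uword k = 0; k < eta_cols.n_elem; ++k)
      p[eta_cols[k]] *= std::exp(eta[k]);
    return conc_profile(d.t, d.dt, d.da, d.dd, p[0], p[1], p[2], p[3]);
  }

  // -2 log joint (up to the 2*pi constant) of data and eta
  double objective(const arma::vec& eta) const {
    arma::vec f = pred(eta);
    arma::vec s2 = res_var(f, res_type, sig_add, sig_prop);
    double h = 0.0;
    for (arma::uword i = 0; i < f.n_elem; ++i) {
      double e = d.y[i] - f[i];
      h += e * e / s2[i];
      if (interaction) h += std::log(s2[i]);
    }
    for (arma::uword k = 0; k < eta.n_elem; ++k)
      h += eta[k] * eta[k] / (omega[k] * omega[k]);
    return std::isfinite(h) ? h : 1e12;
  }
};

// damped Newton with finite-difference derivatives on the inner
// objective; gradient tolerance 1e-8, dimension is tiny (<= 4)
static arma::vec inner_newton(const InnerProblem& ip, arma::vec eta,
                              bool& ok) {
  const double step = 1e-4, gtol = 1e-8;
  const int q = eta.n_elem;
  ok = true;
  double h0 = ip.objective(eta);
  for (int iter = 0; iter < 100; ++iter) {
    arma::vec g(q);
    arma::mat H(q, q);
    for (int k = 0; k < q; ++k) {
      arma::vec ep = eta, em = eta;
      ep[k] += step; em[k] -= step;
      double fp = ip.objective(ep), fm = ip.objective(em);
      g[k] = (fp - fm) / (2 * step);
      H(k, k) = (fp - 2 * h0 + fm) / (step * step);
    }
    for (int k = 0; k < q; ++k)
      for (int l = k + 1; l < q; ++l) {
        arma::vec epp = eta, epm = eta, emp = eta, emm = eta;
        epp[k] += step; epp[l] += step;
        epm[k] += step; epm[l] -= step;
        emp[k] -= step; emp[l] += step;
        emm[k] -= step; emm[l] -= step;
        H(k, l) = H(l, k) = (ip.objective(epp) - ip.objective(epm) -
                             ip.objective(emp) + ip.objective(emm)) /
                            (4 * step * step);
      }
    if (arma::norm(g, 2) < gtol) break;
    // Levenberg damping until a descent step is found
    double mu = 0.0;
    arma::vec d;
    bool solved = false;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Hd = H + mu * arma::eye(q, q);
      if (arma::solve(d, Hd, -g, arma::solve_opts::no_approx)) {
        arma::vec cand = eta + d;
        double hc = ip.objective(cand);
        if (std::isfinite(hc) && hc <= h0 + 1e-12) {
          eta = cand; h0 = hc; solved = true; break;
        }
      }
      mu = (mu == 0.0) ? 1.0 : mu * 10.0;
    }
    if (!solved) { ok = arma::norm(g, 2) < 1e-4; break; }
    if (arma::norm(d, 2) < 1e-10) break;
  }
  return eta;
}

// [[Rcpp::export]]
List foce_eval_cpp(List subjects, const arma::mat& tp,
                   const arma::uvec& eta_cols, const arma::vec& omega,
                   int res_type, double sig_add, double sig_prop,
                   bool interaction, bool detail,
                   const arma::mat& eta_start) {
  const int ns = subjects.size();
  const int qfull = eta_cols.n_elem;
  const double LOG2PI = std::log(2.0 * M_PI);

  // random-effect dimensions with negligible variance are fixed at 0
  arma::uvec active = arma::find(omega > 1e-8);
  const int q = active.n_elem;
  arma::uvec acols(q);
  arma::vec aomega(q);
  for (int k = 0; k < q; ++k) {
    acols[k] = eta_cols[active[k]];
    aomega[k] = omega[active[k]];
  }

  double ofv = 0.0;
  bool all_ok = true;
  arma::mat eta_hat(ns, qfull, arma::fill::zeros);
  List pred_l(ns), ipred_l(ns), cwres_l(ns);
  arma::vec li(ns, arma::fill::zeros);

  for (int i = 0; i < ns; ++i) {
    List s = subjects[i];
    SubjData d;
    d.dt = as<arma::vec>(s["dt"]);
    d.da = as<arma::vec>(s["da"]);
    d.dd = as<arma::vec>(s["dd"]);
    d.t = as<arma::vec>(s["t"]);
    d.y = as<arma::vec>(s["y"]);
    const int n = d.t.n_elem;
    if (n == 0) {
      if (detail) {
        pred_l[i] = NumericVector(0);
        ipred_l[i] = NumericVector(0);
        cwres_l[i] = NumericVector(0);
      }
      continue;
    }
    InnerProblem ip(d, tp.row(i), acols, aomega, res_type, sig_add,
                    sig_prop, interaction);
    arma::vec eta(q, arma::fill::zeros);
    if (q > 0) {
      for (int k = 0; k < q; ++k) eta[k] = eta_start(i, active[k]);
      bool ok = true;
      eta = inner_newton(ip, eta, ok);
      if (!ok) all_ok = false;
    }
    arma::vec fi = ip.pred(eta);
    arma::vec s2 = res_var(fi, res_type, sig_add, sig_prop);
    // linearization G = df/deta at eta-hat
    arma::mat G(n, q);
    const double step = 1e-4;
    for (int k = 0; k < q; ++k) {
      arma::vec ep = eta, em = eta;
      ep[k] += step; em[k] -= step;
      G.col(k) = (ip.pred(ep) - ip.pred(em)) / (2 * step);
    }
    arma::mat V = arma::diagmat(s2);
    if (q > 0) V += G * arma::diagmat(arma::square(aomega)) * G.t();
    arma::vec r = d.y - fi;
    if (q > 0) r += G * eta;
    arma::mat L;
    if (!arma::chol(L, V, "lower")) {
      ofv += 1e10;
      all_ok = false;
      continue;
    }
    arma::vec z = arma::solve(arma::trimatl(L), r);
    double ld = 2.0 * arma::sum(arma::log(L.diag()));
    double contrib = n * LOG2PI + ld + arma::dot(z, z);
    if (!std::isfinite(contrib)) {
      contrib = 1e10;
      all_ok = false;
    }
    ofv += contrib;
    li[i] = contrib;
    if (detail) {
      for (int k = 0; k < q; ++k) eta_hat(i, active[k]) = eta[k];
      arma::vec p0 = ip.pred(arma::vec(q, arma::fill::zeros));
      pred_l[i] = wrap(p0);
      ipred_l[i] = wrap(fi);
      cwres_l[i] = wrap(z);
    }
  }
  if (!detail)
    return List::create(_["ofv"] = ofv, _["ok"] = all_ok);
  return List::create(_["ofv"] = ofv, _["ok"] = all_ok,
                      _["eta"] = eta_hat, _["pred"] = pred_l,
                      _["ipred"] = ipred_l, _["cwres"] = cwres_l,
                      _["li"] = li);
}
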