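#include <Rcpp.h>
using namespace Rcpp;

// Anticipation value coefficient A = R/(nu-gamma) (e^{-gamma T} - e^{-nu T}),
// with the removable singularity at nu == gamma handled analytically.
static inline double acoef(double R, double nu, double gam, double T) {
  if (std::fabs(nu - gam) < 1e-9) return R * T * std::exp(-gam * T);
  return R / (nu - gam) * (std::exp(-gam * T) - std::exp(-nu * T));
}

// Supremum of admissible boosting gain contributed by one valence branch:
// 1 / max_{T >= 0} |A(T)|.
static inline double branch_bound(double Rabs, double nu, double gam) {
  if (Rabs <= 0.0) return R_PosInf;
  if (gam <= 0.0) return nu / Rabs;                  // sup |A| = R/nu as T -> Inf
  if (std::fabs(nu - gam) < 1e-9) return gam * M_E / Rabs;
  return gam / Rabs * std::pow(gam / nu, nu / (gam - nu));
}

// [[Rcpp::export]]
double stability_bound_cpp(double R_minus, double nu_plus, double nu_minus,
                           double gamma) {
  double bp = branch_bound(1.0, nu_plus, gamma);
  double bm = branch_bound(std::fabs(R_minus), nu_minus, gamma);
  return std::min(bp, bm);
}

// par layout (natural scale): R_minus, eta0, C, nu_plus, nu_minus, gamma, sigma
static inline double choice_prob_one(const double *par, double q, double T,
                                     bool *ok) {
  const double Rm = par[0], eta0 = par[1], C = par[2], nup = par[3],
               num = par[4], gam = par[5], sig = par[6];
  const double Ap = acoef(1.0, nup, gam, T);
  const double Am = acoef(Rm, num, gam, T);
  const double Bp = std::exp(-gam * T);
  const double Bm = Rm * std::exp(-gam * T);
  const double numer = eta0 * (Ap - Am) + Bp - Bm;
  const double den = 1.0 - C * ((1.0 - q) * Ap - q * Am);
  if (!(den > 0.0)) { *ok = false; return NA_REAL; }
  const double dp = (1.0 - q) * numer / den;
  const double dm = -q * numer / den;
  const double Qp = (eta0 + C * std::fabs(dp)) * Ap + Bp;
  const double Qm = (eta0 + C * std::fabs(dm)) * Am + Bm;
  const double VII = q * Qp + (1.0 - q) * Qm;
  const double VNI = eta0 * (q * Ap + (1.0 - q) * Am) + q * Bp + (1.0 - q) * Bm;
  const double p = 1.0 / (1.0 + std::exp(-(VII - VNI) / sig));
  if (!R_finite(p)) { *ok = false; return NA_REAL; }
  return p;
}

// [[Rcpp::export]]
NumericVector choice_prob_cpp(NumericVector par, NumericVector q,
                              NumericVector T) {
  const int n = q.size();
  NumericVector out(n);
  bool ok = true;
  for (int i = 0; i < n; ++i) {
    out[i] = choice_prob_one(REAL(par), q[i], T[i], &ok);
    if (!ok) stop("stability violation: self-consistency denominator <= 0");
  }
  return out;
}

static double loglik_counts(const double *par, const double *q, const double *T,
                            const double *n1, const double *n0, int ncond,
                            double floor_log, bool *ok) {
  double ll = 0.0;
  for (int i = 0; i < ncond; ++i) {
    double p = choice_prob_one(par, q[i], T[i], ok);
    if (!*ok) return NA_REAL;
    double lp = std::log(p), lq = std::log1p(-p);
    if (!(lp > floor_log)) lp = floor_log;
    if (!(lq > floor_log)) lq = floor_log;
    ll += n1[i] * lp + n0[i] * lq;
  }
  return ll;
}

// [[Rcpp::export]]
double loglik_counts_cpp(NumericVector par, NumericVector q, NumericVector T,
                         NumericVector n_info, NumericVector n_noinfo,
                         double floor_log) {
  bool ok = true;
  double ll = loglik_counts(REAL(par), REAL(q), REAL(T), REAL(n_info),
                            REAL(n_noinfo), q.size(), floor_log, &ok);
  if (!ok) stop("stability violation: self-consistency denominator <= 0");
  return ll;
}

// Batched likelihood over rows of a K x 7 natural-parameter matrix;
// rows violating stability get the floored likelihood (counted by caller).
// [[Rcpp::export]]
NumericVector loglik_counts_batch_cpp(NumericMatrix par, NumericVector q,
                                      NumericVector T, NumericVector n_info,
                                      NumericVector n_noinfo,
                                      double floor_log) {
  const int K = par.nrow(), ncond = q.size();
  NumericVector out(K);
  double ntot = 0.0;
  for (int i = 0; i < ncond; ++i) ntot += n_info[i] + n_noinfo[i];
  for (int k = 0; k < K; ++k) {
    double p7[7];
    for (int j = 0; j < 7; ++j) p7[j] = par(k, j);
    bool ok = true;
    double ll = loglik_counts(p7, REAL(q), REAL(T), REAL(n_info),
                              REAL(n_noinfo), ncond, floor_log, &ok);
    out[k] = ok ? ll : ntot * floor_log;
  }
  return out;
}

// Negative log posterior in transformed (h) space for one subject's
// condition-level choice counts. `free_idx` gives the 0-based coordinates of
// the free parameters; `base_par` carries fixed values on the natural scale.
// Transform: R- = -exp(h); eta0 = softplus(h); C = C_max(rates, R-) * logistic(h);
// nu+, nu-, gamma, sigma = exp(h). Rates are applied before C so the
// stability reparameterization always sees current rates.
// [[Rcpp::export]]
double neg_log_post_cpp(NumericVector hfree, IntegerVector free_idx,
                        NumericVector base_par, NumericVector q,
                        NumericVector T, NumericVector n_info,
                        NumericVector n_noinfo, NumericVector prior_mean,
                        NumericVector prior_var, double floor_log) {
  double par[7];
  for (int j = 0; j < 7; ++j) par[j] = base_par[j];
  const int nf = hfree.size();
  double hC = 0.0;
  bool C_free = false;
  for (int i = 0; i < nf; ++i) {
    double h = hfree[i];
    if (!R_finite(h)) return 1e10;
    if (h > 40.0) h = 40.0;
    if (h < -40.0) h = -40.0;
    const int j = free_idx[i];
    switch (j) {
    case 0: par[0] = -std::exp(h); break;
    case 1: par[1] = std::log1p(std::exp(h)); break;
    case 2: C_free = true; hC = h; break;
    default: par[j] = std::exp(h);
    }
  }
  if (C_free) {
    double b = stability_bound_cpp(par[0], par[3], par[4], par[5]);
    par[2] = b / (1.0 + std::exp(-hC));
  }
  bool ok = true;
  double ll = loglik_counts(par, REAL(q), REAL(T), REAL(n_info),
                            REAL(n_noinfo), q.size(), floor_log, &ok);
  if (!ok || !R_finite(ll)) return 1e10;
  double lp = 0.0;
  for (int i = 0; i < nf; ++i) {
    const double d = hfree[i] - prior_mean[i];
    lp += -0.5 * std::log(2.0 * M_PI * prior_var[i]) -
          0.5 * d * d / prior_var[i];
  }
  double out = -(ll + lp);
  if (!R_finite(out)) return 1e10;
  return out;
}

// Central-difference gradient of neg_log_post_cpp in one call (keeps the
// optimizer's gradient loop out of R).
// [[Rcpp::export]]
NumericVector neg_log_post_grad_cpp(NumericVector hfree,
                                    IntegerVector free_idx,
                                    NumericVector base_par, NumericVector q,
                                    NumericVector T, NumericVector n_info,
                                    NumericVector n_noinfo,
                                    NumericVector prior_mean,
                                    NumericVector prior_var,
                                    double floor_log) {
  const int d = hfree.size();
  NumericVector g(d), hp = clone(hfree);
  for (int j = 0; j < d; ++j) {
    const double s = 1e-6 * std::max(1.0, std::fabs(hfree[j]));
    const double h0 = hp[j];
    hp[j] = h0 + s;
    const double fp = neg_log_post_cpp(hp, free_idx, base_par, q, T, n_info,
                                       n_noinfo, prior_mean, prior_var,
                                       floor_log);
    hp[j] = h0 - s;
    const double fm = neg_log_post_cpp(hp, free_idx, base_par, q, T, n_info,
                                       n_noinfo, prior_mean, prior_var,
                                       floor_log);
    hp[j] = h0;
    g[j] = (fp - fm) / (2.0 * s);
  }
  return g;
}
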