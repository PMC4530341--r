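#include <Rcpp.h>
using namespace Rcpp;

// Single-covariate Cox proportional-hazards fit by Newton-Raphson on the
// Efron partial likelihood. Input must be sorted by time ascending; tie
// groups share identical time values. Returns beta, the likelihood-ratio
// chi-square (1 df) and a convergence/cap flag.
//
// The greedy subnetwork search evaluates this fit once per candidate move,
// so the whole routine is allocation-free per iteration.

struct CoxFit {
  double beta;
  double chisq;
  int capped;
};

static const double BETA_CAP = 20.0;

// log partial likelihood, gradient and observed information at beta.
// Walks samples from last (largest time) to first, accumulating risk-set
// sums, applying the Efron correction within each tied event group.
static void efron_eval(const double *x, const double *time, const int *event,
                       int n, double beta,
                       double *ll_out, double *grad_out, double *info_out) {
  double S0 = 0.0, S1 = 0.0, S2 = 0.0; // risk-set sums of w, wx, wx^2
  double ll = 0.0, grad = 0.0, info = 0.0;
  int i = n - 1;
  while (i >= 0) {
    int j = i;
    while (j >= 0 && time[j] == time[i]) j--;
    // group is (j, i]; add all members to the risk set first
    double d = 0.0, sx = 0.0, w0d = 0.0, w1d = 0.0, w2d = 0.0;
    for (int k = i; k > j; k--) {
      double w = std::exp(beta * x[k]);
      S0 += w;
      S1 += w * x[k];
      S2 += w * x[k] * x[k];
      if (event[k]) {
        d += 1.0;
        sx += x[k];
        w0d += w;
        w1d += w * x[k];
        w2d += w * x[k] * x[k];
      }
    }
    if (d > 0.0) {
      ll += beta * sx;
      for (double l = 0.0; l < d; l += 1.0) {
        double f = l / d;
        double den = S0 - f * w0d;
        double m1 = (S1 - f * w1d) / den;
        double m2 = (S2 - f * w2d) / den;
        ll -= std::log(den);
        grad -= m1;
        info += m2 - m1 * m1;
      }
      grad += sx;
    }
    i = j;
  }
  *ll_out = ll;
  *grad_out = grad;
  *info_out = info;
}

static CoxFit cox_newton(const double *x, const double *time,
                         const int *event, int n) {
  CoxFit fit;
  fit.beta = 0.0;
  fit.chisq = 0.0;
  fit.capped = 0;

  double ll0, g, h;
  efron_eval(x, time, event, n, 0.0, &ll0, &g, &h);
  if (!(h > 1e-12)) return fit; // no information: constant x or no events

  double beta = 0.0, ll = ll0;
  for (int iter = 0; iter < 30; iter++) {
    double step = g / h;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    double beta_new = beta + step;
    if (beta_new > BETA_CAP) beta_new = BETA_CAP;
    if (beta_new < -BETA_CAP) beta_new = -BETA_CAP;
    double ll_new, g_new, h_new;
    efron_eval(x, time, event, n, beta_new, &ll_new, &g_new, &h_new);
    int halves = 0;
    while (ll_new < ll - 1e-12 && halves < 20) {
      beta_new = beta + (beta_new - beta) / 2.0;
      efron_eval(x, time, event, n, beta_new, &ll_new, &g_new, &h_new);
      halves++;
    }
    double moved = std::fabs(beta_new - beta);
    beta = beta_new;
    ll = ll_new;
    g = g_new;
    h = h_new;
    if ((std::fabs(g) < 1e-9 && moved < 1e-9) || !(h > 1e-12)) break;
    if (std::fabs(beta) >= BETA_CAP && g * beta > 0.0) {
      fit.capped = 1; // monotone likelihood pushing past the cap
      break;
    }
  }
  fit.beta = beta;
  double chisq = 2.0 * (ll - ll0);
  fit.chisq = chisq > 0.0 ? chisq : 0.0;
  return fit;
}

// [[Rcpp::export]]
NumericVector cox_lrt1(NumericVector x, NumericVector time,
                       IntegerVector event) {
  int n = x.size();
  std::vector<double> xc(n);
  double mu = 0.0;
  for (int i = 0; i < n; i++) mu += x[i];
  mu /= n;
  for (int i = 0; i < n; i++) xc[i] = x[i] - mu;
  CoxFit fit = cox_newton(xc.data(), REAL(time), INTEGER(event), n);
  return NumericVector::create(fit.beta, fit.chisq, (double)fit.capped);
}

// Column-wise version: score every column of X against the same survival
// outcome (one call per greedy-search move set).
// [[Rcpp::export]]
NumericMatrix cox_lrt_cols(NumericMatrix X, NumericVector time,
                           IntegerVector event) {
  int n = X.nrow(), k = X.ncol();
  NumericMatrix out(k, 3);
  std::vector<double> xc(n);
  for (int c = 0; c < k; c++) {
    double mu = 0.0;
    for (int i = 0; i < n; i++) mu += X(i, c);
    mu /= n;
    for (int i = 0; i < n; i++) xc[i] = X(i, c) - mu;
    CoxFit fit = cox_newton(xc.data(), REAL(time), INTEGER(event), n);
    out(c, 0) = fit.beta;
    out(c, 1) = fit.chisq;
    out(c, 2) = (double)fit.capped;
  }
  return out;
}
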