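#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Mixed-effect autoregressive ordinal logistic likelihood, marginalised over
// a per-patient normal random intercept by adaptive Gauss-Hermite quadrature.
//
// Parameter vector theta (length 4 + p + 4 + 1):
//   beta[0..3]   coefficients of the previous-score indicators (score 4 = reference)
//   gamma[0..p)  covariate coefficients
//   c1, d1..d3   cutpoints: c_k = c1 + sum_{j<=k} exp(d_j), k = 0..3 (K = 5 categories)
//   log_sigma    log SD of the random intercept
//
// Pairs are grouped by patient via 0-based offsets pstart (length K_pat + 1).

static inline double plogis_(double x) {
  if (x > 0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}
static inline double dlogis_(double x) {
  double ax = std::fabs(x);
  double e = std::exp(-ax);
  double d = (1.0 + e);
  return e / (d * d);
}

struct CatDeriv {
  double logp;
  double dleta;   // d logP / d eta
  double d2leta;  // d2 logP / d eta2
  double fa, fb;  // logistic densities at upper/lower cut minus eta
  double P;
};

// category probability and eta-derivatives for outcome m given location eta
static inline CatDeriv cat_deriv(int m, double eta, const double *cuts) {
  CatDeriv out;
  double fa, fb, fpa, fpb, a = 0.0, b = 0.0;
  bool has_a = m < 4, has_b = m > 0;
  if (has_a) {
    a = cuts[m] - eta;
    fa = dlogis_(a);
    fpa = fa * (1.0 - 2.0 * plogis_(a));
  } else { fa = 0.0; fpa = 0.0; }
  if (has_b) {
    b = cuts[m - 1] - eta;
    fb = dlogis_(b);
    fpb = fb * (1.0 - 2.0 * plogis_(b));
  } else { fb = 0.0; fpb = 0.0; }
  // category mass, evaluated in the numerically small tail to avoid the
  // catastrophic cancellation of F(a) - F(b) when both CDFs are near 1
  double P;
  if (!has_a) P = plogis_(-b);                      // m = 4: upper tail
  else if (!has_b) P = plogis_(a);                  // m = 0: lower tail
  else if (a + b > 0) P = plogis_(-b) - plogis_(-a);
  else P = plogis_(a) - plogis_(b);
  if (P < 1e-300) P = 1e-300;
  double dP = fb - fa;        // d P / d eta
  double d2P = fpa - fpb;     // d2 P / d eta2
  out.logp = std::log(P);
  out.dleta = dP / P;
  out.d2leta = d2P / P - (dP / P) * (dP / P);
  out.fa = fa; out.fb = fb; out.P = P;
  return out;
}

// [[Rcpp::export]]
List agq_objective_cpp(NumericVector theta,
                       IntegerVector sprev, IntegerVector snext,
                       NumericMatrix X, IntegerVector pstart,
                       NumericVector gh_z, NumericVector gh_w,
                       double lambda, bool want_grad, bool want_modes) {
  const int p = X.ncol();
  const int npar = 4 + p + 4 + 1;
  if (theta.size() != npar) stop("theta has wrong length");
  const int npat = pstart.size() - 1;
  const int n = sprev.size();
  const int Q = gh_z.size();

  const double *beta = &theta[0];
  const double *gamma = (p > 0) ? &theta[4] : (double *)nullptr;
  const double c1 = theta[4 + p];
  const double *d = &theta[4 + p + 1];
  const double logsig = theta[4 + p + 4];
  const double sigma = std::exp(logsig);
  const double sig2 = sigma * sigma;

  double cuts[4];
  double ed[3];
  cuts[0] = c1;
  for (int j = 0; j < 3; ++j) {
    ed[j] = std::exp(d[j]);
    cuts[j + 1] = cuts[j] + ed[j];
  }

  // fixed part of the linear predictor per pair
  std::vector<double> eta0(n);
  for (int i = 0; i < n; ++i) {
    double e = (sprev[i] <= 3) ? beta[sprev[i]] : 0.0;
    for (int j = 0; j < p; ++j) e += gamma[j] * X(i, j);
    eta0[i] = e;
  }

  std::vector<double> logw(Q);
  for (int q = 0; q < Q; ++q) logw[q] = std::log(gh_w[q]);

  double nll = 0.0;
  NumericVector grad(npar);
  NumericVector modes(want_modes ? npat : 0);
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> node_logint(Q), node_alpha(Q);

  for (int k = 0; k < npat; ++k) {
    const int i0 = pstart[k], i1 = pstart[k + 1];

    // Newton search for the conditional mode of alpha (concave objective)
    double alpha = 0.0;
    double h = 0.0, g1 = 0.0, g2 = 0.0;
    for (int it = 0; it < 100; ++it) {
      h = -alpha * alpha / (2.0 * sig2);
      g1 = -alpha / sig2;
      g2 = -1.0 / sig2;
      for (int i = i0; i < i1; ++i) {
        CatDeriv cd = cat_deriv(snext[i], eta0[i] + alpha, cuts);
        h += cd.logp; g1 += cd.dleta; g2 += cd.d2leta;
      }
      double step = -g1 / g2;
      if (!std::isfinite(step)) break;
      // dampen overly large steps
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      alpha += step;
      if (std::fabs(step) < 1e-10) break;
    }
    // curvature at the mode
    g2 = -1.0 / sig2;
    for (int i = i0; i < i1; ++i) {
      CatDeriv cd = cat_deriv(snext[i], eta0[i] + alpha, cuts);
      g2 += cd.d2leta;
    }
    double shat = 1.0 / std::sqrt(-g2);
    if (!std::isfinite(shat) || shat <= 0) shat = sigma;
    if (want_modes) modes[k] = alpha;

    // adaptive nodes
    double lmax = -std::numeric_limits<double>::infinity();
    for (int q = 0; q < Q; ++q) {
      double a = alpha + M_SQRT2 * shat * gh_z[q];
      node_alpha[q] = a;
      double ll = -0.5 * LOG2PI - logsig - a * a / (2.0 * sig2);  // log prior
      for (int i = i0; i < i1; ++i) {
        CatDeriv cd = cat_deriv(snext[i], eta0[i] + a, cuts);
        ll += cd.logp;
      }
      double li = logw[q] + gh_z[q] * gh_z[q] + ll;
      node_logint[q] = li;
      if (li > lmax) lmax = li;
    }
    double ssum = 0.0;
    for (int q = 0; q < Q; ++q) ssum += std::exp(node_logint[q] - lmax);
    double logLk = std::log(M_SQRT2 * shat) + lmax + std::log(ssum);
    nll -= logLk;

    if (want_grad) {
      // posterior node weights; score identity for the gradient
      for (int q = 0; q < Q; ++q) {
        double pq = std::exp(node_logint[q] - lmax) / ssum;
        if (pq < 1e-14) continue;
        double a = node_alpha[q];
        // prior contribution to d/d log sigma
        grad[4 + p + 4] -= pq * (a * a / sig2 - 1.0);
        for (int i = i0; i < i1; ++i) {
          CatDeriv cd = cat_deriv(snext[i], eta0[i] + a, cuts);
          double w = pq;
          // eta-mediated terms
          if (sprev[i] <= 3) grad[sprev[i]] -= w * cd.dleta;
          for (int j = 0; j < p; ++j) grad[4 + j] -= w * cd.dleta * X(i, j);
          // cutpoint terms: d logP/d c_u = fa/P (upper cut u = m, if m<=3),
          //                 d logP/d c_l = -fb/P (lower cut l = m-1, if m>=1)
          int m = snext[i];
          double gu = (m <= 3) ? cd.fa / cd.P : 0.0;
          double gl = (m >= 1) ? -cd.fb / cd.P : 0.0;
          grad[4 + p] -= w * (gu + gl);  // c1 shifts every cut
          for (int j = 0; j < 3; ++j) {
            double dc = 0.0;
            if (m <= 3 && m >= j + 1) dc += gu;      // c_m depends on d_j iff m >= j+1
            if (m >= 1 && m - 1 >= j + 1) dc += gl;  // c_{m-1} likewise
            grad[4 + p + 1 + j] -= w * dc * ed[j];
          }
        }
      }
    }
  }

  // ridge penalty on beta and gamma
  for (int j = 0; j < 4 + p; ++j) {
    nll += lambda * theta[j] * theta[j];
    if (want_grad) grad[j] += 2.0 * lambda * theta[j];
  }

  List out = List::create(Named("nll") = nll);
  if (want_grad) out["grad"] = grad;
  if (want_modes) out["modes"] = modes;
  return out;
}
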