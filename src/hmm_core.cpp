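// Compiled inner loops for the hidden Markov machinery: scaled forward
// recursion, Viterbi decoding, forward-backward smoothing, and the packed
// negative log-likelihood evaluated by the quasi-Newton optimiser.
//
// Conventions shared with the R side (see R/fit.R):
//  * state 1 is the multinomial-logit baseline; linear predictors are kept
//    only for targets j = 2..n and the baseline predictor is identically 0;
//  * transition matrices are stored column-major as P[i + j*n] (from i, to j),
//    one n*n block per distinct hour value;
//  * `newseg[t]` marks the first observation of a contiguous segment; each
//    segment restarts from the prior and segments are independent replicates;
//  * the transition into time t uses the hour covariate of time t.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_2PI = 1.837877066409345483560659472811;

// Row of the multinomial-logit link: eta holds predictors for targets 2..n,
// the baseline (target 1) predictor is 0.  Guarded against overflow by
// subtracting the running maximum.
static void softmaxRow(const double* eta, int nm1, double* out) {
  double m = 0.0;
  for (int j = 0; j < nm1; ++j) if (eta[j] > m) m = eta[j];
  double denom = std::exp(-m);
  for (int j = 0; j < nm1; ++j) denom += std::exp(eta[j] - m);
  out[0] = std::exp(-m) / denom;
  for (int j = 0; j < nm1; ++j) out[j + 1] = std::exp(eta[j] - m) / denom;
}

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix logemis, NumericVector prior,
                       NumericVector tpm, IntegerVector hourIdx,
                       LogicalVector newseg) {
  const int T = logemis.nrow(), n = logemis.ncol();
  std::vector<double> alpha(n), tmp(n);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int j = 0; j < n; ++j) if (logemis(t, j) > m) m = logemis(t, j);
    if (!std::isfinite(m)) return R_NegInf;
    double c = 0.0;
    if (newseg[t]) {
      for (int j = 0; j < n; ++j) {
        tmp[j] = prior[j] * std::exp(logemis(t, j) - m);
        c += tmp[j];
      }
    } else {
      const double* P = &tpm[(size_t)hourIdx[t] * n * n];
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += alpha[i] * P[i + j * n];
        tmp[j] = s * std::exp(logemis(t, j) - m);
        c += tmp[j];
      }
    }
    if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
    for (int j = 0; j < n; ++j) alpha[j] = tmp[j] / c;
    ll += std::log(c) + m;
  }
  return ll;
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logemis, NumericVector logprior,
                              NumericVector logtpm, IntegerVector hourIdx,
                              LogicalVector newseg) {
  const int T = logemis.nrow(), n = logemis.ncol();
  NumericMatrix delta(T, n);
  IntegerMatrix psi(T, n);
  for (int t = 0; t < T; ++t) {
    if (newseg[t]) {
      for (int j = 0; j < n; ++j) {
        delta(t, j) = logprior[j] + logemis(t, j);
        psi(t, j) = -1;
      }
    } else {
      const double* L = &logtpm[(size_t)hourIdx[t] * n * n];
      for (int j = 0; j < n; ++j) {
        // strict '>' keeps the lowest predecessor index on ties
        double best = R_NegInf;
        int arg = 0;
        for (int i = 0; i < n; ++i) {
          double v = delta(t - 1, i) + L[i + j * n];
          if (v > best) { best = v; arg = i; }
        }
        delta(t, j) = best + logemis(t, j);
        psi(t, j) = arg;
      }
    }
  }
  IntegerVector path(T);
  int t = T - 1;
  while (t >= 0) {
    int s = t;
    while (!newseg[s]) --s;         // start of the segment ending at t
    double best = R_NegInf;
    int arg = 0;
    for (int j = 0; j < n; ++j)
      if (delta(t, j) > best) { best = delta(t, j); arg = j; }
    path[t] = arg + 1;
    for (int k = t; k > s; --k) path[k - 1] = psi(k, path[k] - 1) + 1;
    t = s - 1;
  }
  return path;
}

// [[Rcpp::export]]
List hmm_posterior_cpp(NumericMatrix logemis, NumericVector prior,
                       NumericVector tpm, IntegerVector hourIdx,
                       LogicalVector newseg) {
  const int T = logemis.nrow(), n = logemis.ncol();
  NumericMatrix alpha(T, n), w(T, n);
  NumericVector cs(T), ms(T);
  double ll = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int j = 0; j < n; ++j) if (logemis(t, j) > m) m = logemis(t, j);
    ms[t] = m;
    double c = 0.0;
    if (newseg[t]) {
      for (int j = 0; j < n; ++j) {
        w(t, j) = std::exp(logemis(t, j) - m);
        alpha(t, j) = prior[j] * w(t, j);
        c += alpha(t, j);
      }
    } else {
      const double* P = &tpm[(size_t)hourIdx[t] * n * n];
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += alpha(t - 1, i) * P[i + j * n];
        w(t, j) = std::exp(logemis(t, j) - m);
        alpha(t, j) = s * w(t, j);
        c += alpha(t, j);
      }
    }
    if (!(c > 0.0) || !std::isfinite(c)) stop("underflow in forward pass at time %d", t + 1);
    cs[t] = c;
    for (int j = 0; j < n; ++j) alpha(t, j) /= c;
    ll += std::log(c) + m;
  }

  NumericMatrix gamma(T, n);
  std::vector<double> beta(n, 1.0), nb(n);
  for (int t = T - 1; t >= 0; --t) {
    bool segEnd = (t == T - 1) || newseg[t + 1];
    if (segEnd) std::fill(beta.begin(), beta.end(), 1.0);
    double rs = 0.0;
    for (int j = 0; j < n; ++j) { gamma(t, j) = alpha(t, j) * beta[j]; rs += gamma(t, j); }
    for (int j = 0; j < n; ++j) gamma(t, j) /= rs;
    if (t > 0 && !newseg[t]) {
      const double* P = &tpm[(size_t)hourIdx[t] * n * n];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) s += P[i + j * n] * w(t, j) * beta[j];
        nb[i] = s / cs[t];
      }
      beta = nb;
    }
  }
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// Packed negative log-likelihood.  `aux` is prepared once per fit in R
// (see .makeAux in R/fit.R) and holds the data, the hour design matrix for
// the distinct hour values, and the model dimensions.
//
// Parameter packing order (must match packTheta/unpackTheta in R):
//   [prior logits, n-1] [transition coefficients: row, then target 2..n,
//   then covariate; a single shared row when fmm] [per state: emission
//   parameters (meanlog, log sdlog) or (log shape, log scale), then
//   (mu, log kappa) when angles are included].
// [[Rcpp::export]]
double hmm_nll_cpp(NumericVector par, List aux) {
  NumericVector logs = aux["logs"];     // log of floored step lengths
  NumericVector ang = aux["angle"];
  LogicalVector hasAng = aux["hasAngle"];
  NumericMatrix basis = aux["basis"];   // H x kt design for distinct hours
  IntegerVector hourIdx = aux["hourIdx"];
  LogicalVector newseg = aux["newseg"];
  const int n = as<int>(aux["n"]);
  const int kt = as<int>(aux["kt"]);
  const bool fmm = as<bool>(aux["fmm"]);
  const int fam = as<int>(aux["family"]);   // 0 log-Normal, 1 Weibull
  const bool useAng = as<bool>(aux["angles"]);

  const int T = logs.size(), H = basis.nrow(), nm1 = n - 1;
  int p = 0;

  std::vector<double> prior(n);
  {
    std::vector<double> eta(nm1 > 0 ? nm1 : 1);
    for (int j = 0; j < nm1; ++j) eta[j] = par[p++];
    softmaxRow(eta.data(), nm1, prior.data());
  }

  const int nrow = fmm ? 1 : n;
  std::vector<double> coef((size_t)nrow * nm1 * kt);
  for (size_t q = 0; q < coef.size(); ++q) coef[q] = par[p++];

  // transition matrix per distinct hour, column-major P[i + j*n]
  std::vector<double> tpm((size_t)H * n * n);
  std::vector<double> eta(nm1 > 0 ? nm1 : 1), row(n);
  for (int h = 0; h < H; ++h) {
    for (int i = 0; i < n; ++i) {
      const int ic = fmm ? 0 : i;
      for (int j = 0; j < nm1; ++j) {
        double e = 0.0;
        for (int m = 0; m < kt; ++m)
          e += coef[((size_t)ic * nm1 + j) * kt + m] * basis(h, m);
        eta[j] = e;
      }
      softmaxRow(eta.data(), nm1, row.data());
      for (int j = 0; j < n; ++j) tpm[(size_t)h * n * n + i + j * n] = row[j];
    }
  }

  std::vector<double> e1(n), e2(n), mu(n), kap(n), lognorm(n);
  for (int i = 0; i < n; ++i) {
    if (fam == 0) {            // log-Normal: meanlog, sdlog
      e1[i] = par[p++];
      e2[i] = std::exp(par[p++]);
    } else {                   // Weibull: shape, scale
      e1[i] = std::exp(par[p++]);
      e2[i] = std::exp(par[p++]);
    }
    if (!std::isfinite(e2[i]) || e2[i] <= 0.0) return 1e10;
    if (useAng) {
      mu[i] = par[p++];
      kap[i] = std::exp(par[p++]);
      if (!std::isfinite(kap[i])) return 1e10;
      // log I0(kappa) from the exponentially scaled Bessel function
      lognorm[i] = std::log(R::bessel_i(kap[i], 0.0, 2.0)) + kap[i] + std::log(2.0 * M_PI);
    }
  }

  // per-state constants hoisted out of the time loop
  std::vector<double> c0(n), c1(n), c2(n);
  for (int j = 0; j < n; ++j) {
    if (fam == 0) {            // -log(sdlog) - log(sqrt(2 pi)); 1/sdlog
      c0[j] = -std::log(e2[j]) - 0.5 * LOG_2PI;
      c1[j] = 1.0 / e2[j];
    } else {                   // log(shape) - shape*log(scale); shape; log(scale)
      c2[j] = std::log(e2[j]);
      c0[j] = std::log(e1[j]) - e1[j] * c2[j];
      c1[j] = e1[j];
    }
  }

  std::vector<double> alpha(n), tmp(n), le(n);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int j = 0; j < n; ++j) {
      double v;
      if (fam == 0) {
        double z = (logs[t] - e1[j]) * c1[j];
        v = -logs[t] + c0[j] - 0.5 * z * z;
      } else {
        v = c0[j] + (c1[j] - 1.0) * logs[t] - std::exp(c1[j] * (logs[t] - c2[j]));
      }
      if (useAng && hasAng[t])
        v += kap[j] * std::cos(ang[t] - mu[j]) - lognorm[j];
      le[j] = v;
      if (v > m) m = v;
    }
    if (!std::isfinite(m)) return 1e10;
    double c = 0.0;
    if (newseg[t]) {
      for (int j = 0; j < n; ++j) { tmp[j] = prior[j] * std::exp(le[j] - m); c += tmp[j]; }
    } else {
      const double* P = &tpm[(size_t)hourIdx[t] * n * n];
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += alpha[i] * P[i + j * n];
        tmp[j] = s * std::exp(le[j] - m);
        c += tmp[j];
      }
    }
    if (!(c > 0.0) || !std::isfinite(c)) return 1e10;
    for (int j = 0; j < n; ++j) alpha[j] = tmp[j] / c;
    ll += std::log(c) + m;
  }
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}
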