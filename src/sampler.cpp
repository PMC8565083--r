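// Slice-within-Gibbs MCMC for penalized Bayesian cumulative-logit models.
//
// Non-conjugate conditionals (thresholds alpha_k, coefficients beta_j) are
// updated by univariate slice sampling (stepping out + shrinkage); lambda,
// gamma and pi have conjugate Gibbs updates. Model codes: 1 = Bayesian
// LASSO, 2 = spike-and-slab normal, 3 = spike-and-slab LASSO, 4 =
// inclusion-indicator regression (gamma multiplies beta in the predictor).
// All randomness flows through R's RNG so a set.seed() in R fixes the run.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double logF(double x) {
  // log logistic CDF, stable for large |x|
  return x > 0.0 ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

// log(F(b) - F(a)) for b > a, stable: F(b)-F(a) = F(b)F(-a)(1 - e^{a-b})
static inline double logFdiff(double b, double a) {
  return logF(b) + logF(-a) + log1p(-std::exp(a - b));
}

class OrdSampler {
public:
  int n, p, K, Km1, model;
  NumericMatrix X;
  IntegerVector y;
  // prior
  double a, b, s20, s21, lam0, tfix, cc, dd;
  std::vector<double> s2a;  // per-threshold prior variance
  int piMode;               // 0 fixed, 1 beta
  // state
  std::vector<double> alpha, beta, piv, eta;
  std::vector<int> gam;
  double lambda;
  // slice widths
  std::vector<double> wA, wB;
  bool adapting;
  std::vector<std::vector<int> > catIdx;  // observation indices per category

  OrdSampler(NumericMatrix X_, IntegerVector y_, int K_, List prior)
      : X(X_), y(y_) {
    n = X.nrow(); p = X.ncol(); K = K_; Km1 = K - 1;
    model = as<int>(prior["model"]);
    a = as<double>(prior["a"]); b = as<double>(prior["b"]);
    s20 = as<double>(prior["sigma2_0"]); s21 = as<double>(prior["sigma2_1"]);
    lam0 = as<double>(prior["lambda0"]);
    piMode = as<int>(prior["piMode"]);
    tfix = as<double>(prior["t"]);
    cc = as<double>(prior["c"]); dd = as<double>(prior["d"]);
    NumericVector sa = prior["sigma2Alpha"];
    s2a.resize(Km1);
    for (int k = 0; k < Km1; ++k)
      s2a[k] = sa[sa.size() == 1 ? 0 : k];
    catIdx.resize(K);
    for (int i = 0; i < n; ++i) catIdx[y[i] - 1].push_back(i);
    adapting = false;
    wA.assign(Km1, 1.0);
    wB.assign(p, 1.0);
  }

  void setState(List st) {
    NumericVector al = st["alpha"], be = st["beta"];
    alpha.assign(al.begin(), al.end());
    beta.assign(be.begin(), be.end());
    gam.assign(p, 1);
    if (model >= 2) {
      IntegerVector g = st["gamma"];
      for (int j = 0; j < p; ++j) gam[j] = g[j];
    }
    piv.assign(p, tfix);
    if (model >= 2 && piMode == 1) {
      NumericVector pv = st["pi"];
      for (int j = 0; j < p; ++j) piv[j] = pv[j];
    }
    lambda = (model != 2) ? as<double>(st["lambda"]) : 0.0;
    recomputeEta();
  }

  void recomputeEta() {
    eta.assign(n, 0.0);
    for (int j = 0; j < p; ++j) {
      double c = (model == 4) ? gam[j] * beta[j] : beta[j];
      if (c == 0.0) continue;
      for (int i = 0; i < n; ++i) eta[i] += c * X(i, j);
    }
  }

  inline double obsLL(int yi, double e) const {
    if (yi == 1) return logF(alpha[0] - e);
    if (yi == K) return logF(e - alpha[Km1 - 1]);
    return logFdiff(alpha[yi - 1] - e, alpha[yi - 2] - e);
  }

  double loglik() const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += obsLL(y[i], eta[i]);
    return s;
  }

  // generic univariate slice update on (lo, hi)
  template <class F>
  double slice(double x0, double lo, double hi, double &w, F logf) {
    double fx0 = logf(x0);
    double logy = fx0 - R::exp_rand();
    double L = x0 - w * R::unif_rand();
    double Rr = L + w;
    const int m = 40;
    int jl = (int)std::floor(m * R::unif_rand());
    int jr = m - 1 - jl;
    if (L <= lo) L = lo;
    else while (jl-- > 0 && logf(L) > logy) {
      L -= w;
      if (L <= lo) { L = lo; break; }
    }
    if (Rr >= hi) Rr = hi;
    else while (jr-- > 0 && logf(Rr) > logy) {
      Rr += w;
      if (Rr >= hi) { Rr = hi; break; }
    }
    double x1 = x0;
    for (int it = 0; it < 1000; ++it) {
      double xc = L + R::unif_rand() * (Rr - L);
      if (logf(xc) >= logy) { x1 = xc; break; }
      if (xc < x0) L = xc; else Rr = xc;
    }
    if (adapting) {
      double mv = std::fabs(x1 - x0);
      w = 0.95 * w + 0.05 * std::max(2.0 * mv, 0.02);
      if (w < 1e-3) w = 1e-3;
      if (w > 100.0) w = 100.0;
    }
    return x1;
  }

  void updateAlpha(int k) {
    // only categories k+1 (upper bound alpha_k) and k+2 (lower bound) matter
    double lo = (k == 0) ? -1e6 : alpha[k - 1];
    double hi = (k == Km1 - 1) ? 1e6 : alpha[k + 1];
    const std::vector<int> &up = catIdx[k];      // y == k+1
    const std::vector<int> &dn = catIdx[k + 1];  // y == k+2
    double pv = s2a[k];
    int kk = k;
    auto logf = [&](double aval) {
      double s = -aval * aval / (2.0 * pv);
      for (size_t t = 0; t < up.size(); ++t) {
        double e = eta[up[t]];
        if (kk == 0) s += logF(aval - e);
        else s += logFdiff(aval - e, alpha[kk - 1] - e);
      }
      for (size_t t = 0; t < dn.size(); ++t) {
        double e = eta[dn[t]];
        if (kk == Km1 - 1) s += logF(e - aval);
        else s += logFdiff(alpha[kk + 1] - e, aval - e);
      }
      return s;
    };
    alpha[k] = slice(alpha[k], lo, hi, wA[k], logf);
  }

  inline double logPriorBeta(int j, double v) const {
    switch (model) {
      case 1: case 4: return -lambda * std::fabs(v);
      case 2: {
        double s2 = gam[j] ? s21 : s20;
        return -v * v / (2.0 * s2);
      }
      default: {  // model 3
        double rate = gam[j] ? lambda : lam0;
        return -rate * std::fabs(v);
      }
    }
  }

  // scale of the conditional prior of beta_j; the slice width is floored at
  // twice this so that heavy-tailed states (tiny lambda) remain traversable
  inline double priorScaleBeta(int j) const {
    switch (model) {
      case 1: case 4: return 1.0 / std::max(lambda, 1e-300);
      case 2: return std::sqrt(gam[j] ? s21 : s20);
      default: return 1.0 / std::max(gam[j] ? lambda : lam0, 1e-300);
    }
  }

  void updateBeta(int j) {
    if (model == 4 && gam[j] == 0) {
      // feature omitted from the likelihood: conditional is the DE prior
      double mag = R::exp_rand() / std::max(lambda, 1e-300);
      beta[j] = (R::unif_rand() < 0.5) ? -mag : mag;
      return;
    }
    std::vector<double> em(n);
    for (int i = 0; i < n; ++i) em[i] = eta[i] - X(i, j) * beta[j];
    auto logf = [&](double v) {
      double s = logPriorBeta(j, v);
      for (int i = 0; i < n; ++i) s += obsLL(y[i], em[i] + X(i, j) * v);
      return s;
    };
    double w = std::max(wB[j], std::min(2.0 * priorScaleBeta(j), 1e8));
    beta[j] = slice(beta[j], -1e12, 1e12, w, logf);
    if (adapting) wB[j] = std::min(std::max(w, 1e-3), 100.0);
    for (int i = 0; i < n; ++i) eta[i] = em[i] + X(i, j) * beta[j];
  }

  void updateGamma() {
    for (int j = 0; j < p; ++j) {
      double d10;  // log odds of gamma_j = 1 vs 0 given everything else
      if (model == 2) {
        d10 = R::dnorm(beta[j], 0.0, std::sqrt(s21), 1) -
              R::dnorm(beta[j], 0.0, std::sqrt(s20), 1);
      } else if (model == 3) {
        d10 = (std::log(lambda / 2.0) - lambda * std::fabs(beta[j])) -
              (std::log(lam0 / 2.0) - lam0 * std::fabs(beta[j]));
      } else {  // model 4: likelihood ratio with/without the feature
        double ll1 = 0.0, ll0 = 0.0;
        if (gam[j] == 1) {
          ll1 = loglikCached();
          ll0 = loglikShift(j, -beta[j]);
        } else {
          ll0 = loglikCached();
          ll1 = loglikShift(j, beta[j]);
        }
        d10 = ll1 - ll0;
      }
      double lo = std::log(piv[j]) - std::log(1.0 - piv[j]) + d10;
      double p1 = 1.0 / (1.0 + std::exp(-lo));
      int newg = (R::unif_rand() < p1) ? 1 : 0;
      if (model == 4 && newg != gam[j]) {
        double shift = (newg == 1 ? beta[j] : -beta[j]);
        for (int i = 0; i < n; ++i) eta[i] += shift * X(i, j);
      }
      gam[j] = newg;
    }
  }

  double loglikCached() const { return loglik(); }

  double loglikShift(int j, double coefDelta) const {
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      s += obsLL(y[i], eta[i] + coefDelta * X(i, j));
    return s;
  }

  void updateLambdaDraw() {
    double shape, rate;
    if (model == 3) {
      shape = a; rate = b;
      for (int j = 0; j < p; ++j)
        if (gam[j]) { shape += 1.0; rate += std::fabs(beta[j]); }
    } else {
      shape = a + p; rate = b;
      for (int j = 0; j < p; ++j) rate += std::fabs(beta[j]);
    }
    lambda = std::max(R::rgamma(shape, 1.0 / rate), 1e-300);
  }

  void updatePiDraw() {
    for (int j = 0; j < p; ++j)
      piv[j] = R::rbeta(cc + gam[j], dd + 1 - gam[j]);
  }

  void sweep() {
    for (int k = 0; k < Km1; ++k) updateAlpha(k);
    for (int j = 0; j < p; ++j) updateBeta(j);
    if (model >= 2) updateGamma();
    if (model != 2) updateLambdaDraw();
    if (model >= 2 && piMode == 1) updatePiDraw();
  }

  List stateList() const {
    List st = List::create(
      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
      _["beta"] = NumericVector(beta.begin(), beta.end()));
    if (model >= 2) {
      st["gamma"] = IntegerVector(gam.begin(), gam.end());
      if (piMode == 1) st["pi"] = NumericVector(piv.begin(), piv.end());
    }
    if (model != 2) st["lambda"] = lambda;
    return st;
  }
};

// [[Rcpp::export(name = ".bvs_run_chain")]]
List bvs_run_chain(NumericMatrix X, IntegerVector y, int K, List prior,
                   List init, int nAdapt, int nBurnin, int thin, int nSave) {
  OrdSampler s(X, y, K, prior);
  s.setState(init);
  int p = s.p, Km1 = s.Km1;
  bool hasG = s.model >= 2, hasL = s.model != 2,
       hasP = s.model >= 2 && s.piMode == 1;
  NumericMatrix Aout(nSave, Km1), Bout(nSave, p);
  IntegerMatrix Gout(hasG ? nSave : 0, hasG ? p : 0);
  NumericMatrix Pout(hasP ? nSave : 0, hasP ? p : 0);
  NumericVector Lout(hasL ? nSave : 0);
  int total = nAdapt + nBurnin + thin * nSave;
  int saved = 0;
  for (int it = 0; it < total; ++it) {
    s.adapting = it < nAdapt;
    s.sweep();
    int post = it - nAdapt - nBurnin;
    if (post >= 0 && (post + 1) % thin == 0 && saved < nSave) {
      for (int k = 0; k < Km1; ++k) Aout(saved, k) = s.alpha[k];
      for (int k = 1; k < Km1; ++k)
        if (s.alpha[k] <= s.alpha[k - 1])
          stop("internal invariant violation: thresholds out of order");
      for (int j = 0; j < p; ++j) Bout(saved, j) = s.beta[j];
      if (hasG) for (int j = 0; j < p; ++j) Gout(saved, j) = s.gam[j];
      if (hasP) for (int j = 0; j < p; ++j) Pout(saved, j) = s.piv[j];
      if (hasL) Lout[saved] = s.lambda;
      ++saved;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["alpha"] = Aout, _["beta"] = Bout);
  if (hasG) out["gamma"] = Gout;
  if (hasP) out["pi"] = Pout;
  if (hasL) out["lambda"] = Lout;
  return out;
}

// One full Gibbs sweep from a given state; used for kernel-validation runs.
// [[Rcpp::export(name = ".bvs_one_sweep")]]
List bvs_one_sweep(NumericMatrix X, IntegerVector y, int K, List prior,
                   List state) {
  OrdSampler s(X, y, K, prior);
  s.setState(state);
  s.adapting = false;
  s.sweep();
  return s.stateList();
}
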