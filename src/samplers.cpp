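#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Bernoulli step-model log likelihood from the dichotomized sufficient
// statistics.  An empty stratum contributes nothing; a probability pinned at
// 0 or 1 against a non-zero count yields -Inf rather than an error.
static double loglik_counts(int n1, int s1, int n2, int s2,
                            double p1, double p2) {
  double ll = 0.0;
  if (s1 > 0) {
    if (p1 <= 0.0) return R_NegInf;
    ll += s1 * std::log(p1);
  }
  if (n1 - s1 > 0) {
    if (p1 >= 1.0) return R_NegInf;
    ll += (n1 - s1) * std::log1p(-p1);
  }
  if (s2 > 0) {
    if (p2 <= 0.0) return R_NegInf;
    ll += s2 * std::log(p2);
  }
  if (n2 - s2 > 0) {
    if (p2 >= 1.0) return R_NegInf;
    ll += (n2 - s2) * std::log1p(-p2);
  }
  return ll;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// log |d(bounded)/dz| for the logistic transform, up to the constant
// log(hi - lo) which cancels in Metropolis ratios
static inline double log_jac(double z) {
  double s = sigmoid(z);
  return std::log(s) + std::log1p(-s);
}

// number of sorted values <= cp
static inline int n_below(const std::vector<double>& xs, double cp) {
  return (int)(std::upper_bound(xs.begin(), xs.end(), cp) - xs.begin());
}

// One MCMC chain for the step-function cutoff model.
//
// xs must be sorted ascending; cum_events[i] is the number of events among
// xs[0..i].  Priors: cp1 ~ U(cp1_lo, cp1_hi), cp2 ~ U(cp2_lo, cp2_hi),
// w ~ U(0,1), p2 ~ U(0,1), p1 | p2 ~ U(0, p2); cp = w*cp1 + (1-w)*cp2.
// p1 and p2 are Gibbs-updated from truncated Beta full conditionals;
// cp1, cp2, w get random-walk Metropolis updates on the logit scale with
// scales adapted during burn-in only.  Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
List step_mcmc_chain(NumericVector xs_in, IntegerVector cum_events,
                     double cp1_lo, double cp1_hi,
                     double cp2_lo, double cp2_hi,
                     int burn, int keep, int thin,
                     NumericVector init_scales) {
  RNGScope scope;
  const int n = xs_in.size();
  const int S = (n > 0) ? cum_events[n - 1] : 0;
  std::vector<double> xs(xs_in.begin(), xs_in.end());

  const double eps = 1e-12;

  // initial state drawn from the prior
  double z1 = R::qlogis(R::runif(0.0, 1.0), 0.0, 1.0, 1, 0);
  double z2 = R::qlogis(R::runif(0.0, 1.0), 0.0, 1.0, 1, 0);
  double zw = R::qlogis(R::runif(0.0, 1.0), 0.0, 1.0, 1, 0);
  double p2 = R::runif(eps, 1.0 - eps);
  double p1 = R::runif(0.0, p2);
  if (p1 < eps) p1 = eps;

  double sc1 = init_scales[0], sc2 = init_scales[1], scw = init_scales[2];

  const int total_iter = burn + keep * thin;
  NumericMatrix draws(keep, 6);
  NumericVector accept(3);   // post-burn-in acceptance counts
  NumericVector attempts(3);

  int adapt_acc[3] = {0, 0, 0};
  int adapt_cnt = 0;

  double cp1 = cp1_lo + (cp1_hi - cp1_lo) * sigmoid(z1);
  double cp2 = cp2_lo + (cp2_hi - cp2_lo) * sigmoid(z2);
  double w   = sigmoid(zw);
  double cp  = w * cp1 + (1.0 - w) * cp2;
  int n1 = n_below(xs, cp);
  int s1 = (n1 > 0) ? cum_events[n1 - 1] : 0;
  double ll = loglik_counts(n1, s1, n - n1, S - s1, p1, p2);

  int kept = 0;
  for (int it = 0; it < total_iter; ++it) {
    const bool in_burn = (it < burn);
    const int n2c = n - n1, s2c = S - s1;

    // -- Gibbs: p1 | rest ~ Beta(s1+1, n1-s1+1) truncated to (0, p2)
    {
      double a = s1 + 1.0, b = n1 - s1 + 1.0;
      double uhi = R::pbeta(p2, a, b, 1, 0);
      if (uhi > 0.0) {
        double u = R::runif(0.0, uhi);
        p1 = R::qbeta(u, a, b, 1, 0);
      } else {
        p1 = p2 / 2.0;  // entire Beta mass above p2: fall back to midpoint
      }
      if (p1 < eps) p1 = eps;
      if (p1 > p2 * (1.0 - eps)) p1 = p2 * (1.0 - eps);
    }

    // -- p2 | rest: Beta(s2, n2-s2+1) truncated to (p1, 1) when s2 >= 1;
    //    when s2 == 0 the conditional ~ x^{-1}(1-x)^{n2} has a zero first
    //    shape, so use an independence-Metropolis step with a U(p1,1)
    //    proposal against the exact conditional density.
    if (s2c >= 1) {
      double a = (double)s2c, b = n2c - s2c + 1.0;
      double ulo = R::pbeta(p1, a, b, 1, 0);
      if (ulo < 1.0) {
        double u = R::runif(ulo, 1.0);
        p2 = R::qbeta(u, a, b, 1, 0);
      } else {
        p2 = (p1 + 1.0) / 2.0;
      }
    } else {
      double prop = R::runif(p1, 1.0);
      double lr = (-std::log(prop) + n2c * std::log1p(-prop)) -
                  (-std::log(p2)   + n2c * std::log1p(-p2));
      if (std::log(R::runif(0.0, 1.0)) < lr) p2 = prop;
    }
    if (p2 > 1.0 - eps) p2 = 1.0 - eps;
    if (p2 < p1 / (1.0 - eps)) p2 = std::min(p1 / (1.0 - eps), 1.0 - eps);
    ll = loglik_counts(n1, s1, n - n1, S - s1, p1, p2);

    // -- Metropolis updates for (cp1, cp2, w) on the logit scale
    for (int k = 0; k < 3; ++k) {
      double scale = (k == 0) ? sc1 : (k == 1) ? sc2 : scw;
      double zc = (k == 0) ? z1 : (k == 1) ? z2 : zw;
      double zp = zc + scale * R::norm_rand();

      double cp1p = cp1, cp2p = cp2, wp = w;
      if (k == 0) cp1p = cp1_lo + (cp1_hi - cp1_lo) * sigmoid(zp);
      if (k == 1) cp2p = cp2_lo + (cp2_hi - cp2_lo) * sigmoid(zp);
      if (k == 2) wp   = sigmoid(zp);
      double cpp = wp * cp1p + (1.0 - wp) * cp2p;

      int n1p = n_below(xs, cpp);
      int s1p = (n1p > 0) ? cum_events[n1p - 1] : 0;
      double llp = loglik_counts(n1p, s1p, n - n1p, S - s1p, p1, p2);
      double lr = (llp + log_jac(zp)) - (ll + log_jac(zc));

      if (!in_burn) attempts[k] += 1.0;
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        if (k == 0) { z1 = zp; cp1 = cp1p; }
        if (k == 1) { z2 = zp; cp2 = cp2p; }
        if (k == 2) { zw = zp; w = wp; }
        cp = cpp; n1 = n1p; s1 = s1p; ll = llp;
        if (!in_burn) accept[k] += 1.0;
        if (in_burn) adapt_acc[k] += 1;
      }
    }

    // adapt proposal scales toward ~0.44 acceptance, burn-in only
    if (in_burn) {
      ++adapt_cnt;
      if (adapt_cnt == 50) {
        double rates[3];
        for (int k = 0; k < 3; ++k) rates[k] = adapt_acc[k] / 50.0;
        sc1 *= std::exp(rates[0] - 0.44);
        sc2 *= std::exp(rates[1] - 0.44);
        scw *= std::exp(rates[2] - 0.44);
        sc1 = std::min(std::max(sc1, 1e-3), 50.0);
        sc2 = std::min(std::max(sc2, 1e-3), 50.0);
        scw = std::min(std::max(scw, 1e-3), 50.0);
        adapt_acc[0] = adapt_acc[1] = adapt_acc[2] = 0;
        adapt_cnt = 0;
      }
    }

    if (!in_burn) {
      int post = it - burn;
      if (post % thin == 0 && kept < keep) {
        draws(kept, 0) = cp;
        draws(kept, 1) = p1;
        draws(kept, 2) = p2;
        draws(kept, 3) = cp1;
        draws(kept, 4) = cp2;
        draws(kept, 5) = w;
        ++kept;
      }
    }
  }

  NumericVector acc_rate(3);
  for (int k = 0; k < 3; ++k)
    acc_rate[k] = attempts[k] > 0 ? accept[k] / attempts[k] : NA_REAL;

  return List::create(_["draws"] = draws,
                      _["acceptance"] = acc_rate,
                      _["scales"] = NumericVector::create(sc1, sc2, scw));
}

// One chain of random-walk Metropolis for a two-parameter Bayesian logistic
// regression logit P(Y=1) = b0 + b1 * I(x > cutoff), with independent
// N(0, prior_sd^2) priors.  Data enter through the per-level counts
// (n0, s0) and (n1, s1).  Coordinates updated one at a time; scales adapted
// during burn-in only.
// [[Rcpp::export]]
List logistic_mcmc_chain(int n0, int s0, int n1, int s1,
                         double prior_sd, int burn, int keep, int thin,
                         NumericVector init_scales) {
  RNGScope scope;
  double b0 = R::norm_rand() * 0.5, b1 = R::norm_rand() * 0.5;
  double sc0 = init_scales[0], sc1 = init_scales[1];

  auto logpost = [&](double a, double b) {
    double e0 = a, e1 = a + b;
    double ll = s0 * e0 - n0 * std::log1p(std::exp(e0)) +
                s1 * e1 - n1 * std::log1p(std::exp(e1));
    double lp = -0.5 * (a * a + b * b) / (prior_sd * prior_sd);
    return ll + lp;
  };

  double lp = logpost(b0, b1);
  const int total_iter = burn + keep * thin;
  NumericMatrix draws(keep, 2);
  NumericVector accept(2), attempts(2);
  int adapt_acc[2] = {0, 0};
  int adapt_cnt = 0;
  int kept = 0;

  for (int it = 0; it < total_iter; ++it) {
    const bool in_burn = (it < burn);
    for (int k = 0; k < 2; ++k) {
      double prop0 = b0, prop1 = b1;
      if (k == 0) prop0 += sc0 * R::norm_rand();
      else        prop1 += sc1 * R::norm_rand();
      double lpp = logpost(prop0, prop1);
      if (!in_burn) attempts[k] += 1.0;
      if (std::log(R::runif(0.0, 1.0)) < lpp - lp) {
        b0 = prop0; b1 = prop1; lp = lpp;
        if (!in_burn) accept[k] += 1.0;
        if (in_burn) adapt_acc[k] += 1;
      }
    }
    if (in_burn) {
      ++adapt_cnt;
      if (adapt_cnt == 50) {
        sc0 *= std::exp(adapt_acc[0] / 50.0 - 0.44);
        sc1 *= std::exp(adapt_acc[1] / 50.0 - 0.44);
        sc0 = std::min(std::max(sc0, 1e-3), 50.0);
        sc1 = std::min(std::max(sc1, 1e-3), 50.0);
        adapt_acc[0] = adapt_acc[1] = 0;
        adapt_cnt = 0;
      }
    }
    if (!in_burn) {
      int post = it - burn;
      if (post % thin == 0 && kept < keep) {
        draws(kept, 0) = b0;
        draws(kept, 1) = b1;
        ++kept;
      }
    }
  }

  NumericVector acc_rate(2);
  for (int k = 0; k < 2; ++k)
    acc_rate[k] = attempts[k] > 0 ? accept[k] / attempts[k] : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate);
}
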